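# Loaders for the packaged consortium datasets: propionate time series,
# dominant bacterial clone counts with their guild map, and the archaeal
# clone composition. Counts cover only the dominant clusters, so the
# nominal library size (60 bacterial / 12 archaeal clones per sample) is
# carried separately as the proportion denominator.

.extdata <- function(file)
  system.file("extdata", file, package = "propsyn", mustWork = TRUE)

#' Packaged propionate degradation series
#'
#' Propionate concentrations of the four consortia (Ap1a, G12, N12, Wp2a)
#' over the 8-week batch experiment, sampled at days 0, 14, 39 and 56.
#'
#' @return data.frame with columns `consortium`, `day`, `propionate`
#'   (mmol/L).
#' @export
propionate_series <- function() {
  utils::read.delim(.extdata("propionate_series.tsv"))
}

#' Packaged clone counts of the dominant clusters
#'
#' Long-format clone counts per cluster and sample. Bacterial counts cover
#' the thirteen dominant 16S rRNA sequence clusters at timepoints t1--t3
#' (days 14, 39, 56) of each consortium; archaeal counts cover the t2
#' libraries only. Absent combinations mean zero clones.
#'
#' @param domain `"bacteria"` or `"archaea"`.
#' @return data.frame with columns `cluster`, `consortium`, `timepoint`,
#'   `count` (archaeal counts also carry `metabolism`).
#' @export
clone_counts <- function(domain = c("bacteria", "archaea")) {
  domain <- match.arg(domain)
  utils::read.delim(.extdata(switch(domain,
    bacteria = "bacterial_clone_counts.tsv",
    archaea = "archaeal_clone_counts.tsv")))
}

#' Packaged guild map for the bacterial clusters
#'
#' Maps each dominant bacterial cluster to one of the five functional
#' guilds: propionate-oxidizing, acetate-oxidizing, H2-oxidizing,
#' propionate-forming, sugar-metabolizing. Putative members are mapped to
#' their guild.
#'
#' @return named character vector (names = cluster labels, values =
#'   guilds).
#' @export
guild_map <- function() {
  g <- utils::read.delim(.extdata("bacterial_guilds.tsv"))
  stats::setNames(g$guild, g$cluster)
}

#' Expand a count table into per-clone assignments
#'
#' Inverse of tallying: materialises one assignment row per clone so count
#' tables can drive [build_count_matrix()].
#'
#' @param counts data.frame with columns `cluster`, `consortium`,
#'   `timepoint`, `count`.
#' @return data.frame with columns `clone`, `consortium`, `timepoint`,
#'   `cluster`.
#' @export
counts_to_assignments <- function(counts) {
  stopifnot(all(c("cluster", "consortium", "timepoint", "count") %in%
                  names(counts)))
  idx <- rep(seq_len(nrow(counts)), counts$count)
  out <- data.frame(consortium = counts$consortium[idx],
                    timepoint = counts$timepoint[idx],
                    cluster = counts$cluster[idx])
  key <- .sample_key(out$consortium, out$timepoint)
  out$clone <- paste0(key, "_", stats::ave(seq_along(key), key,
                                           FUN = seq_along))
  out[c("clone", "consortium", "timepoint", "cluster")]
}

#' Nominal library totals for a count table
#'
#' Published count tables list only dominant clusters, so per-sample totals
#' are not recoverable from the counts themselves; the cloning protocol
#' fixed the library size instead (60 bacterial, 12 archaeal clones per
#' sample). This helper emits that nominal total for every sample present.
#'
#' @param counts data.frame with columns `consortium`, `timepoint`.
#' @param nominal clones sequenced per library (default 60).
#' @return data.frame with columns `consortium`, `timepoint`, `total`.
#' @export
library_totals <- function(counts, nominal = 60) {
  u <- unique(counts[c("consortium", "timepoint")])
  u <- u[order(u$consortium, u$timepoint), ]
  rownames(u) <- NULL
  u$total <- as.integer(nominal)
  u
}
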