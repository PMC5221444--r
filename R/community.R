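# Community analytics over clone-library count matrices: dominance
# filtering, guild summaries, succession trends and substrate-degradation
# verdicts.

.sample_key <- function(consortium, timepoint) paste(consortium, timepoint,
                                                     sep = ".")

#' Build a cluster-by-sample clone count matrix
#'
#' Tallies clone assignments into a matrix of clone counts with one row per
#' sequence cluster and one column per (consortium, timepoint) sample.
#' Library totals are stored separately because published tables list only
#' dominant clusters, so column sums may fall short of the number of clones
#' actually sequenced.
#'
#' @param assignments data.frame with columns `clone`, `consortium`,
#'   `timepoint`, `cluster` (clone ids must be unique).
#' @param totals data.frame with columns `consortium`, `timepoint`, `total`:
#'   clones sequenced per library. Every sample present in `assignments`
#'   must be covered.
#' @return object of class `"count_matrix"`: an integer matrix (rows =
#'   clusters ordered by decreasing total count then label, columns =
#'   `consortium.timepoint` keys) with attribute `totals`, a named integer
#'   vector of library sizes.
#' @export
build_count_matrix <- function(assignments, totals) {
  stopifnot(is.data.frame(assignments),
            all(c("clone", "consortium", "timepoint", "cluster") %in%
                  names(assignments)),
            is.data.frame(totals),
            all(c("consortium", "timepoint", "total") %in% names(totals)))
  if (anyDuplicated(assignments$clone))
    stop("duplicate clone id(s): ",
         paste(unique(assignments$clone[duplicated(assignments$clone)]),
               collapse = ", "))
  tot <- stats::setNames(as.integer(totals$total),
                         .sample_key(totals$consortium, totals$timepoint))
  if (nrow(assignments)) {
    keys <- .sample_key(assignments$consortium, assignments$timepoint)
    missing <- setdiff(unique(keys), names(tot))
    if (length(missing))
      stop("assignments reference sample(s) missing from totals: ",
           paste(missing, collapse = ", "))
    m <- table(factor(assignments$cluster),
               factor(keys, levels = names(tot)))
    m <- matrix(as.integer(m), nrow = nrow(m), dimnames = dimnames(m))
  } else {
    m <- matrix(integer(), nrow = 0L, ncol = length(tot),
                dimnames = list(NULL, names(tot)))
  }
  if (nrow(m))
    m <- m[order(-rowSums(m), rownames(m)), , drop = FALSE]
  structure(m, totals = tot, class = c("count_matrix", "matrix"))
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("<count_matrix> clone counts (library totals in last row)\n")
  m <- rbind(unclass(x), `[library total]` = attr(x, "totals"))
  attr(m, "totals") <- NULL
  print(m)
  invisible(x)
}

.consortium_cols <- function(cm, consortium,
                             timepoints = c("t1", "t2", "t3")) {
  keys <- .sample_key(consortium, timepoints)
  missing <- setdiff(keys, colnames(cm))
  if (length(missing))
    stop("missing sample(s) for consortium '", consortium, "': ",
         paste(missing, collapse = ", "))
  keys
}

#' Dominant clusters of a consortium
#'
#' A cluster counts as dominant when it is detectable (count > 0) in all
#' three timepoint samples of the consortium, or reaches at least
#' `min_prop` of the clone library in at least one sample.
#'
#' @param cm a [build_count_matrix()] result.
#' @param consortium consortium label.
#' @param min_prop single-sample proportion threshold (default 0.08,
#'   inclusive).
#' @param timepoints the sample labels making up the series (default
#'   t1--t3).
#' @return character vector of dominant cluster ids.
#' @export
dominant_clusters <- function(cm, consortium, min_prop = 0.08,
                              timepoints = c("t1", "t2", "t3")) {
  keys <- .consortium_cols(cm, consortium, timepoints)
  tot <- attr(cm, "totals")[keys]
  if (any(tot <= 0)) stop("zero library total in consortium '",
                          consortium, "'")
  counts <- unclass(cm)[, keys, drop = FALSE]
  all_samples <- rowSums(counts > 0) == length(keys)
  prop <- sweep(counts, 2L, tot, "/")
  high <- apply(prop, 1L, max) >= min_prop
  rownames(cm)[all_samples | high]
}

#' Per-sample functional-guild summary
#'
#' Maps every cluster to its functional guild and accumulates clone counts
#' and proportions per guild and sample. Clusters absent from the guild map
#' are collected under `"unassigned"`, so guild counts always add back up to
#' the column sums.
#'
#' @param cm a [build_count_matrix()] result.
#' @param guilds named character vector mapping cluster labels to guilds.
#' @return list with matrices `counts` (guild x sample clone counts) and
#'   `proportions` (counts over library totals).
#' @export
guild_summary <- function(cm, guilds) {
  if (length(guilds) == 0L || is.null(names(guilds)))
    stop("empty guild map")
  g <- ifelse(rownames(cm) %in% names(guilds),
              guilds[rownames(cm)], "unassigned")
  counts <- rowsum(unclass(cm), group = g)
  props <- sweep(counts, 2L, attr(cm, "totals")[colnames(counts)], "/")
  list(counts = counts, proportions = props)
}

#' Succession trend of each cluster across a consortium's timepoints
#'
#' Computes the clone-library proportion of every cluster at t1--t3 and
#' calls the trend: increasing when the proportions rise with a strict
#' increase in at least one step (p1 < p2 <= p3 or p1 <= p2 < p3),
#' decreasing by the mirror rule, otherwise none.
#'
#' @inheritParams dominant_clusters
#' @return data.frame with columns `cluster`, `p1`, `p2`, `p3`, `trend`.
#' @export
succession_trend <- function(cm, consortium,
                             timepoints = c("t1", "t2", "t3")) {
  keys <- .consortium_cols(cm, consortium, timepoints)
  tot <- attr(cm, "totals")[keys]
  if (any(tot <= 0)) stop("zero library total in consortium '",
                          consortium, "'")
  prop <- sweep(unclass(cm)[, keys, drop = FALSE], 2L, tot, "/")
  trend <- apply(prop, 1L, function(p) {
    if ((p[1] < p[2] && p[2] <= p[3]) || (p[1] <= p[2] && p[2] < p[3]))
      "increasing"
    else if ((p[1] > p[2] && p[2] >= p[3]) || (p[1] >= p[2] && p[2] > p[3]))
      "decreasing"
    else "none"
  })
  data.frame(cluster = rownames(cm), p1 = prop[, 1L], p2 = prop[, 2L],
             p3 = prop[, 3L], trend = unname(trend), row.names = NULL)
}

#' Classify a propionate-degradation series
#'
#' A consortium is scored as a positive degrader when the final propionate
#' concentration has fallen to at most `threshold` times the initial one.
#'
#' @param series numeric vector of concentrations in time order (mmol/L),
#'   or a data.frame with columns `day` and `propionate`.
#' @param threshold residual fraction cutoff (default 0.10, inclusive).
#' @return `"positive"` or `"negative"`.
#' @examples
#' classify_degradation(c(25, 21, 8, 0))   # positive
#' classify_degradation(c(26, 28, 27, 24)) # negative
#' @export
classify_degradation <- function(series, threshold = 0.10) {
  if (is.data.frame(series)) {
    stopifnot(all(c("day", "propionate") %in% names(series)))
    series <- series$propionate[order(series$day)]
  }
  stopifnot(is.numeric(series), length(series) >= 2L, all(series >= 0))
  if (series[1L] == 0) stop("initial concentration is zero")
  if (series[length(series)] / series[1L] <= threshold) "positive"
  else "negative"
}
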