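# Seeded mock-data generators: marker genes with embedded primer sites and
# controlled divergence structure, multinomial clone libraries with
# partial-length reads, first-order substrate decay, and an end-to-end
# round-trip harness over the whole pipeline.

.BASES <- c("A", "C", "G", "T")

# evaluate expr under a fixed seed without disturbing the caller's RNG
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic sub-stream seeds, kept within 32-bit integer range
.sub_seed <- function(seed, offset) (as.numeric(seed) * 1009 + offset) %%
  .Machine$integer.max

.random_dna <- function(n) paste(sample(.BASES, n, replace = TRUE),
                                 collapse = "")

# resolve IUPAC ambiguity codes to concrete bases (seeded by caller's RNG)
.instantiate_iupac <- function(x) {
  chars <- strsplit(x, "")[[1L]]
  paste(vapply(chars, function(ch) {
    opts <- strsplit(.IUPAC[[ch]], "")[[1L]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, ""), collapse = "")
}

# substitute k random positions of chars (among 'allowed') to different bases
.mutate_positions <- function(chars, allowed, k) {
  if (k == 0L || !length(allowed)) return(chars)
  pos <- if (length(allowed) == 1L) allowed else
    sample(allowed, min(k, length(allowed)))
  for (p in pos)
    chars[p] <- sample(setdiff(.BASES, chars[p]), 1L)
  chars
}

.GUILDS <- c("propionate-oxidizing", "acetate-oxidizing", "H2-oxidizing",
             "propionate-forming", "sugar-metabolizing")

#' Generate a mock reference community of marker genes
#'
#' Builds `n_taxa` full-length marker genes by mutating a random ancestor at
#' disjoint position sets, so realised pairwise divergences are exactly
#' `2k/L` for `k` mutations per taxon and land just above `between`. Each
#' gene carries the forward primer site at its 5' end and the reverse
#' complement of the reverse primer at its 3' end (ambiguity codes resolved
#' to concrete bases); primer sites are never mutated, reflecting the
#' conservation that universal primers rely on.
#'
#' @param n_taxa number of taxa (>= 1).
#' @param between minimum pairwise divergence between taxa (fraction,
#'   (0, 0.3]).
#' @param within nominal within-taxon divergence later applied to clones
#'   (fraction, `0 <= within < between`); recorded on the result.
#' @param primers list of two [primer()]s (forward, reverse); defaults to
#'   the bacterial pair E5F/E1541r.
#' @param gene_length total gene length in nt (default 1500).
#' @param seed integer seed; identical seeds give identical output.
#' @return data.frame with columns `name`, `guild`, `gene`, and attributes
#'   `within` and `primers`.
#' @export
make_reference_community <- function(n_taxa, between = 0.10, within = 0.02,
                                     primers = NULL, gene_length = 1500,
                                     seed = 1) {
  stopifnot(n_taxa >= 1, within >= 0, within < between, between <= 0.3)
  if (is.null(primers)) {
    p <- std_primers()
    primers <- list(p$E5F, p$E1541r)
  }
  .with_seed(seed, {
    fwd <- .instantiate_iupac(primers[[1L]]$sequence)
    rev <- .revcomp(.instantiate_iupac(primers[[2L]]$sequence))
    core_len <- gene_length - nchar(fwd) - nchar(rev)
    if (core_len <= 0) stop("gene_length too short for the primer pair")
    k <- ceiling(between * gene_length / 2) + 1L
    if (n_taxa > 1L && (2 * k / gene_length > 0.3 ||
                        n_taxa * k > core_len))
      stop("unattainable divergence constraints: ", n_taxa, " taxa at ",
           between, " divergence do not fit a ", gene_length, " nt gene")
    ancestor <- strsplit(.random_dna(core_len), "")[[1L]]
    pool <- sample(core_len)           # disjoint mutation position sets
    genes <- vapply(seq_len(n_taxa), function(i) {
      chars <- ancestor
      if (n_taxa > 1L) {
        pos <- pool[seq.int((i - 1L) * k + 1L, i * k)]
        chars <- .mutate_positions(chars, pos, k)
      }
      paste0(fwd, paste(chars, collapse = ""), rev)
    }, "")
    out <- data.frame(
      name = sprintf("taxon_%02d", seq_len(n_taxa)),
      guild = .GUILDS[(seq_len(n_taxa) - 1L) %% length(.GUILDS) + 1L],
      gene = genes)
    attr(out, "within") <- within
    attr(out, "primers") <- primers
    out
  })
}

#' Define a community scenario
#'
#' A scenario bundles the mock taxa, their time-varying composition, and
#' the substrate-decay parameters from which clone libraries and a
#' propionate series are drawn.
#'
#' @param taxa a [make_reference_community()] result.
#' @param compositions numeric matrix of taxon probabilities, one row per
#'   timepoint (rownames, e.g. t1--t3), one column per taxon; every row
#'   must sum to 1 (within 1e-9) with no negative entries.
#' @param initial initial propionate concentration, mmol/L (default 25).
#' @param rate first-order decay rate per day (default 0.06, which empties
#'   a 25 mmol/L batch within 8 weeks); must be >= 0.
#' @param lag lag phase in days before decay starts (default 0).
#' @param failure logical; a failed consortium keeps its propionate
#'   (rate forced to 0 with small seeded measurement jitter).
#' @param seed integer master seed for everything drawn from the scenario.
#' @return object of class `"community_scenario"`.
#' @export
community_scenario <- function(taxa, compositions, initial = 25,
                               rate = 0.06, lag = 0, failure = FALSE,
                               seed = 1) {
  stopifnot(is.data.frame(taxa), is.matrix(compositions),
            ncol(compositions) == nrow(taxa))
  if (is.null(rownames(compositions)))
    rownames(compositions) <- paste0("t", seq_len(nrow(compositions)))
  if (any(compositions < 0) ||
      any(abs(rowSums(compositions) - 1) > 1e-9))
    stop("each composition row must be a probability vector summing to 1")
  if (rate < 0) stop("negative decay rate")
  stopifnot(initial > 0, lag >= 0)
  structure(list(taxa = taxa, compositions = compositions,
                 initial = initial, rate = rate, lag = lag,
                 failure = isTRUE(failure), seed = seed),
            class = "community_scenario")
}

#' @export
print.community_scenario <- function(x, ...) {
  cat(sprintf(
    "<community_scenario> %d taxa, %d timepoint(s), initial %g mmol/L, rate %g/day%s\n",
    nrow(x$taxa), nrow(x$compositions), x$initial, x$rate,
    if (x$failure) " (failed consortium)" else ""))
  invisible(x)
}

#' Draw a clone library from a scenario timepoint
#'
#' Clone taxa are drawn multinomially from the timepoint's composition.
#' Each clone is a copy of its taxon's amplified gene with within-taxon
#' point substitutions applied at the scenario's `within` rate (primer
#' sites excluded), and its single-pass sequencing read is a 5'-anchored
#' window of the clone with length drawn uniformly from
#' `read_range` (clone fragments cover one end of the gene, as
#' vector-primer Sanger reads do).
#'
#' @param scenario a [community_scenario()].
#' @param timepoint row name of `scenario$compositions`.
#' @param n_clones library size (default 60).
#' @param read_range inclusive read-length bounds in nt (default
#'   `c(747, 1141)`).
#' @param seed optional seed; defaults to a sub-stream derived from the
#'   scenario seed and the timepoint.
#' @return data.frame with columns `clone`, `taxon`, `amplicon` (the full
#'   mutated insert digested in ARDRA) and `read` (the partial sequence
#'   used for clustering).
#' @export
sample_clone_library <- function(scenario, timepoint, n_clones = 60,
                                 read_range = c(747, 1141), seed = NULL) {
  stopifnot(inherits(scenario, "community_scenario"), n_clones >= 1)
  tp <- match(timepoint, rownames(scenario$compositions))
  if (is.na(tp))
    stop("timepoint '", timepoint, "' not in scenario")
  if (is.null(seed)) seed <- .sub_seed(scenario$seed, 100 + tp)
  comp <- scenario$compositions[tp, ]
  within <- attr(scenario$taxa, "within")
  primers <- attr(scenario$taxa, "primers")
  fwd_len <- nchar(primers[[1L]]$sequence)
  rev_len <- nchar(primers[[2L]]$sequence)
  .with_seed(seed, {
    counts <- as.vector(stats::rmultinom(1L, n_clones, comp))
    taxon_idx <- rep(seq_along(counts), counts)
    rows <- lapply(seq_along(taxon_idx), function(i) {
      gene <- scenario$taxa$gene[taxon_idx[i]]
      mutable <- seq.int(fwd_len + 1L, nchar(gene) - rev_len)
      n_mut <- stats::rbinom(1L, length(mutable), within)
      amplicon <- if (n_mut > 0L)
        paste(.mutate_positions(strsplit(gene, "")[[1L]], mutable, n_mut),
              collapse = "")
      else gene
      len <- min(sample(seq.int(read_range[1L], read_range[2L]), 1L),
                 nchar(amplicon))
      data.frame(clone = sprintf("%s_clone_%03d", timepoint, i),
                 taxon = scenario$taxa$name[taxon_idx[i]],
                 amplicon = amplicon,
                 read = substr(amplicon, 1L, len))
    })
    do.call(rbind, rows)
  })
}

#' Simulate a propionate degradation series
#'
#' First-order decay with an optional lag:
#' `c(t) = initial * exp(-rate * max(0, t - lag))`. A failed consortium
#' keeps its substrate: the rate is forced to zero and small multiplicative
#' measurement jitter (seeded, lognormal, sd 0.03) is applied instead.
#'
#' @param scenario a [community_scenario()].
#' @param timepoints strictly increasing sampling days (default
#'   `c(0, 14, 39, 56)`).
#' @return data.frame with columns `day` and `propionate` (mmol/L).
#' @export
simulate_degradation <- function(scenario, timepoints = c(0, 14, 39, 56)) {
  stopifnot(inherits(scenario, "community_scenario"),
            all(diff(timepoints) > 0))
  rate <- if (scenario$failure) 0 else scenario$rate
  conc <- scenario$initial * exp(-rate * pmax(0, timepoints - scenario$lag))
  if (scenario$failure)
    conc <- conc * .with_seed(.sub_seed(scenario$seed, 7L),
                              exp(stats::rnorm(length(conc), 0, 0.03)))
  data.frame(day = timepoints, propionate = pmax(conc, 0))
}

# greedy one-to-one matching of recovered clusters to true taxa by shared
# clone count; returns named vector cluster -> taxon (NA when unmatched)
.match_clusters <- function(truth, recovered) {
  tab <- table(recovered, truth)
  map <- stats::setNames(rep(NA_character_, nrow(tab)), rownames(tab))
  used <- character()
  repeat {
    tab_open <- tab
    tab_open[rownames(tab) %in% names(map)[!is.na(map)], ] <- -1L
    tab_open[, colnames(tab) %in% used] <- -1L
    if (all(tab_open < 0) || max(tab_open) <= 0) break
    best <- which(tab_open == max(tab_open), arr.ind = TRUE)[1L, ]
    map[rownames(tab)[best[1L]]] <- colnames(tab)[best[2L]]
    used <- c(used, colnames(tab)[best[2L]])
  }
  map
}

#' Run the full reconstruction pipeline on a simulated community
#'
#' Draws a clone library per timepoint, fingerprints every clone by in-silico
#' ARDRA (HhaI and HinfI digests, gel-binned), groups identical fingerprints,
#' clusters one representative read per group at the identity/coverage
#' thresholds, tallies clones into a count matrix, and scores the
#' reconstruction against the generator's truth labels.
#'
#' @param scenario a [community_scenario()].
#' @param n_clones clones per library (default 60).
#' @param identity,coverage clustering thresholds (defaults 97 / 80).
#' @param tolerance,detection_limit gel parameters (defaults 0.05 / 50).
#' @param timepoints which scenario timepoints to process (default all).
#' @return list with elements `n_taxa`, `n_clusters`,
#'   `membership_agreement` (fraction of clones placed with their taxon
#'   under the best cluster-to-taxon matching), `tv_distance` (named vector
#'   of total variation distances between recovered and true composition
#'   per timepoint), `matrix` (the recovered [build_count_matrix()]), and
#'   `clusters`.
#' @export
run_round_trip <- function(scenario, n_clones = 60, identity = 97,
                           coverage = 80, tolerance = 0.05,
                           detection_limit = 50, timepoints = NULL) {
  stopifnot(inherits(scenario, "community_scenario"))
  tps <- rownames(scenario$compositions)
  if (!is.null(timepoints)) {
    stopifnot(all(timepoints %in% tps))
    tps <- timepoints
  }
  libs <- lapply(tps, function(tp)
    sample_clone_library(scenario, tp, n_clones))
  names(libs) <- tps

  # ARDRA per library, then one representative read per group
  reps <- list()
  clone_group_rep <- character()
  for (tp in tps) {
    lib <- libs[[tp]]
    prof <- ardra_profiles(stats::setNames(lib$amplicon, lib$clone),
                           tolerance = tolerance,
                           detection_limit = detection_limit)
    groups <- group_profiles(prof)
    for (g in groups) {
      rep_id <- g$representative
      reps[[rep_id]] <- lib$read[lib$clone == rep_id]
      clone_group_rep[g$members] <- rep_id
    }
  }
  cl <- cluster_sequences(unlist(reps), identity = identity,
                          coverage = coverage)
  rep_cluster <- character()
  for (nm in names(cl)) rep_cluster[cl[[nm]]$members] <- nm

  all_lib <- do.call(rbind, libs)
  all_lib$timepoint <- rep(tps, vapply(libs, nrow, 0L))
  all_lib$cluster <- rep_cluster[clone_group_rep[all_lib$clone]]

  cm <- build_count_matrix(
    data.frame(clone = all_lib$clone, consortium = "sim",
               timepoint = all_lib$timepoint, cluster = all_lib$cluster),
    data.frame(consortium = "sim", timepoint = tps, total = n_clones))

  map <- .match_clusters(all_lib$taxon, all_lib$cluster)
  matched_taxon <- map[all_lib$cluster]
  agreement <- mean(!is.na(matched_taxon) &
                      matched_taxon == all_lib$taxon)

  tv <- vapply(tps, function(tp) {
    sub <- all_lib[all_lib$timepoint == tp, ]
    p_true <- scenario$compositions[tp, ]
    names(p_true) <- scenario$taxa$name
    p_hat <- stats::setNames(numeric(length(p_true)), names(p_true))
    mt <- map[sub$cluster]
    for (t in names(p_hat)) p_hat[t] <- sum(mt == t, na.rm = TRUE)
    unmatched <- sum(is.na(mt))
    n <- nrow(sub)
    0.5 * sum(abs(p_hat / n - p_true)) + 0.5 * unmatched / n
  }, 0)

  list(n_taxa = nrow(scenario$taxa), n_clusters = length(cl),
       membership_agreement = agreement, tv_distance = tv,
       matrix = cm, clusters = cl)
}
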