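# Pairwise identity, single-linkage clustering at identity/coverage
# thresholds, and species/genus taxonomy assignment.

.SUBMAT <- Biostrings::nucleotideSubstitutionMatrix(
  match = 2, mismatch = -1, baseOnly = FALSE, type = "DNA")

# semi-global (ends-free) alignments of several queries against one
# subject; returns identity plus the coverage of both sequences so a
# single alignment serves either query direction
.align_set <- function(queries, b) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(queries), Biostrings::DNAString(b),
    type = "overlap", substitutionMatrix = .SUBMAT,
    gapOpening = 10, gapExtension = 4)
  p <- Biostrings::pattern(pa)
  s <- Biostrings::subject(pa)
  cols <- nchar(as.character(p))           # aligned columns, end gaps excluded
  ident <- ifelse(cols > 0L, 100 * Biostrings::nmatch(pa) / cols, 0)
  list(identity = ident,
       cov_a = 100 * (Biostrings::end(p) - Biostrings::start(p) + 1L) /
         nchar(queries),
       cov_b = 100 * (Biostrings::end(s) - Biostrings::start(s) + 1L) /
         nchar(b))
}

.align_pair <- function(a, b) {
  al <- .align_set(a, b)
  list(identity = al$identity[1L], cov_a = al$cov_a[1L],
       cov_b = al$cov_b[1L])
}

#' Pairwise sequence identity and query coverage
#'
#' Aligns the query `a` against `b` with an optimal global alignment whose
#' terminal gaps are free (semi-global), the stable approximation for clone
#' fragments that read into one gene from either end. Identity is the
#' percentage of matching columns among alignment columns excluding
#' terminal-gap columns (internal gaps count as mismatches); coverage is the
#' percentage of the query spanned by the aligned region.
#'
#' @param a query nucleotide string.
#' @param b subject nucleotide string.
#' @return list with elements `identity` and `coverage`, both percentages.
#' @examples
#' pairwise_identity("ACGTACGT", "ACGTACGT")
#' @export
pairwise_identity <- function(a, b) {
  a <- .check_iupac(a, "query"); b <- .check_iupac(b, "subject")
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  al <- .align_pair(a, b)
  list(identity = al$identity, coverage = al$cov_a)
}

#' Single-linkage sequence clustering at identity/coverage thresholds
#'
#' Builds a graph with an edge between two sequences whenever their pairwise
#' identity is at least `identity` percent and the aligned region covers at
#' least `coverage` percent of the query in either query direction, then
#' reports the connected components (single-linkage semantics, as in
#' BLASTclust). The representative of a cluster is its longest member, ties
#' broken by the lexicographically smallest id. Clusters are sorted by
#' decreasing size.
#'
#' @param seqs named character vector of sequences; names must be unique.
#' @param identity identity threshold in percent (default 97, inclusive).
#' @param coverage query-coverage threshold in percent (default 80,
#'   inclusive).
#' @return object of class `"sequence_clusters"`: a list of clusters, each
#'   `list(members, representative)`.
#' @export
cluster_sequences <- function(seqs, identity = 97, coverage = 80) {
  stopifnot(is.character(seqs), length(seqs) > 0L)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named")
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence ids")
  ids <- names(seqs)
  n <- length(ids)
  edges <- matrix(character(), ncol = 2L)
  if (n > 1L) {
    el <- list()
    for (j in seq.int(2L, n)) {
      al <- .align_set(seqs[seq_len(j - 1L)], seqs[[j]])
      hit <- al$identity >= identity &
        (al$cov_a >= coverage | al$cov_b >= coverage)
      for (i in which(hit))
        el[[length(el) + 1L]] <- c(ids[i], ids[j])
    }
    if (length(el)) edges <- do.call(rbind, el)
  }
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE))
  comp <- igraph::components(g)$membership
  clusters <- lapply(split(names(comp), comp), function(members) {
    lens <- nchar(seqs[members])
    cand <- members[lens == max(lens)]
    list(members = members, representative = min(cand))
  })
  clusters <- clusters[order(-lengths(lapply(clusters, `[[`, "members")),
                             vapply(clusters, `[[`, "", "representative"))]
  names(clusters) <- paste0("cluster_", seq_along(clusters))
  structure(clusters, identity = identity, coverage = coverage,
            class = "sequence_clusters")
}

#' @export
print.sequence_clusters <- function(x, ...) {
  cat(sprintf("<sequence_clusters> %d cluster(s) at >= %g%% identity, >= %g%% coverage\n",
              length(x), attr(x, "identity"), attr(x, "coverage")))
  for (nm in names(x))
    cat(sprintf("  %s (n = %d, rep = %s)\n", nm,
                length(x[[nm]]$members), x[[nm]]$representative))
  invisible(x)
}

#' Assign taxonomy to cluster representatives
#'
#' Compares a representative sequence against a local reference set and
#' reports the best reference by identity (ties broken by higher coverage,
#' then reference name order). An assignment is made at species rank when
#' the identity strictly exceeds 97 percent; otherwise it falls back to the
#' genus rank, following the convention that 16S identities at or below 97
#' percent only support genus-level placement.
#'
#' @param x a `"sequence_clusters"` object or a single sequence string.
#' @param references data.frame with columns `name`, `species`, `genus`,
#'   `sequence` (see [read_reference_fasta()]).
#' @param seqs named character vector of the clustered sequences (needed
#'   when `x` is a `"sequence_clusters"` object, to look up representatives).
#' @param species_identity species-rank cutoff in percent (default 97,
#'   exclusive).
#' @return data.frame with columns `cluster`, `taxon`, `identity`,
#'   `coverage`, `rank`.
#' @export
assign_taxonomy <- function(x, references, seqs = NULL,
                            species_identity = 97) {
  if (!is.data.frame(references) || nrow(references) == 0L)
    stop("empty reference set")
  stopifnot(all(c("name", "species", "genus", "sequence") %in%
                  names(references)))
  reps <- if (inherits(x, "sequence_clusters")) {
    if (is.null(seqs)) stop("'seqs' needed to look up representatives")
    stats::setNames(seqs[vapply(x, `[[`, "", "representative")], names(x))
  } else {
    stats::setNames(as.character(x), if (is.null(names(x)))
      paste0("query_", seq_along(x)) else names(x))
  }
  out <- lapply(names(reps), function(cl) {
    hits <- lapply(references$sequence, function(ref)
      .align_set(reps[[cl]], ref))
    ident <- vapply(hits, function(h) h$identity[1L], 0)
    cov <- vapply(hits, function(h) h$cov_a[1L], 0)
    best <- order(-ident, -cov, references$name)[1L]
    rank <- if (ident[best] > species_identity) "species" else "genus"
    data.frame(cluster = cl,
               taxon = if (rank == "species") references$species[best]
                       else references$genus[best],
               identity = ident[best], coverage = cov[best], rank = rank)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write cluster membership as TSV
#'
#' @param clusters a `"sequence_clusters"` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(clusters, path) {
  rows <- do.call(rbind, lapply(names(clusters), function(nm) {
    cl <- clusters[[nm]]
    data.frame(cluster = nm, member = cl$members,
               representative = as.integer(cl$members == cl$representative))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
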