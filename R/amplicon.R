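# In-silico PCR and ARDRA: degenerate-primer site discovery, amplicon
# extraction, restriction digestion, gel-resolution binning, and grouping
# of clones by identical fragment patterns.

.IUPAC <- Biostrings::IUPAC_CODE_MAP

# logical compatibility matrix over the 15-letter IUPAC alphabet:
# two letters are compatible when their base sets intersect
.iupac_compat <- local({
  letters <- names(.IUPAC)
  sets <- strsplit(.IUPAC, "")
  m <- matrix(FALSE, length(letters), length(letters),
              dimnames = list(letters, letters))
  for (i in seq_along(letters))
    for (j in seq_along(letters))
      m[i, j] <- length(intersect(sets[[i]], sets[[j]])) > 0L
  m
})

.check_iupac <- function(x, what = "sequence") {
  bad <- setdiff(unique(strsplit(toupper(x), "")[[1L]]), names(.IUPAC))
  if (length(bad))
    stop("invalid IUPAC character(s) in ", what, ": ",
         paste(bad, collapse = ", "))
  invisible(toupper(x))
}

# per-position incompatibility count of pattern against window (equal length)
.count_mismatches <- function(pattern_chars, window_chars) {
  sum(!.iupac_compat[cbind(pattern_chars, window_chars)])
}

.revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

#' Define a PCR primer
#'
#' @param name label.
#' @param sequence IUPAC nucleotide string, written 5' to 3'.
#' @return an object of class `"primer"`.
#' @export
primer <- function(name, sequence) {
  sequence <- .check_iupac(sequence, paste0("primer ", name))
  if (!nzchar(sequence)) stop("empty primer sequence")
  structure(list(name = name, sequence = sequence), class = "primer")
}

#' @export
print.primer <- function(x, ...) {
  cat(sprintf("<primer> %s 5'-%s-3'\n", x$name, x$sequence))
  invisible(x)
}

#' Packaged primer registry
#'
#' The two domain-specific 16S rRNA primer pairs: bacterial E5F/E1541r and
#' archaeal Met86f/Ar1530, loaded from the packaged YAML config.
#'
#' @return named list of [primer()] objects.
#' @export
std_primers <- function() {
  path <- system.file("extdata", "primers.yaml", package = "propsyn",
                      mustWork = TRUE)
  docs <- yaml::read_yaml(path)
  out <- lapply(docs, function(d) primer(d$name, d$sequence))
  stats::setNames(out, vapply(out, `[[`, "", "name"))
}

#' Locate primer-binding sites on a template
#'
#' Scans both strands for positions where the primer matches the template
#' under IUPAC compatibility (two letters match when their base sets
#' intersect) with at most `max_mismatch` incompatible positions. The
#' primer's 3'-terminal base must always match, mimicking the polymerase
#' extension requirement.
#'
#' Coordinates are 1-based on the plus strand of the template and give the
#' span covered by the primer; for minus-strand hits the primer anneals to
#' the plus strand shown, i.e. its reverse complement matches at the
#' reported span.
#'
#' @param template nucleotide string.
#' @param prm a [primer()] (or plain IUPAC string).
#' @param max_mismatch maximum number of mismatches (default 0).
#' @return data.frame with columns `start`, `end`, `strand` (`"+"`/`"-"`),
#'   `mismatches`.
#' @export
find_primer_sites <- function(template, prm, max_mismatch = 0) {
  if (is.character(prm)) prm <- primer("primer", prm)
  stopifnot(inherits(prm, "primer"), max_mismatch >= 0)
  template <- .check_iupac(template, "template")
  if (!nzchar(template)) stop("empty template")

  scan_one <- function(pat, anchor_pos) {
    # anchor_pos: index within pat of the primer's 3'-terminal base
    if (nchar(pat) > nchar(template))
      return(data.frame(start = integer(), mismatches = integer()))
    hits <- Biostrings::matchPattern(
      Biostrings::DNAString(pat), Biostrings::DNAString(template),
      max.mismatch = max_mismatch, with.indels = FALSE, fixed = FALSE)
    st <- Biostrings::start(hits)
    if (!length(st))
      return(data.frame(start = integer(), mismatches = integer()))
    pat_chars <- strsplit(pat, "")[[1L]]
    tpl_chars <- strsplit(template, "")[[1L]]
    mm <- vapply(st, function(s) {
      win <- tpl_chars[s:(s + nchar(pat) - 1L)]
      .count_mismatches(pat_chars, win)
    }, 0L)
    anchored <- vapply(st, function(s) {
      .iupac_compat[pat_chars[anchor_pos], tpl_chars[s + anchor_pos - 1L]]
    }, NA)
    keep <- mm <= max_mismatch & anchored
    data.frame(start = st[keep], mismatches = mm[keep])
  }

  n <- nchar(prm$sequence)
  plus <- scan_one(prm$sequence, n)              # 3' end rightmost
  minus <- scan_one(.revcomp(prm$sequence), 1L)  # 3' end leftmost
  out <- rbind(
    if (nrow(plus)) data.frame(start = plus$start,
                               end = plus$start + n - 1L,
                               strand = "+", mismatches = plus$mismatches),
    if (nrow(minus)) data.frame(start = minus$start,
                                end = minus$start + n - 1L,
                                strand = "-", mismatches = minus$mismatches))
  if (is.null(out))
    out <- data.frame(start = integer(), end = integer(),
                      strand = character(), mismatches = integer())
  out[order(out$start, out$strand), , drop = FALSE]
}

# plus-strand amplicons: forward site paired with the nearest downstream
# minus-strand reverse site whose product length is within bounds
.amplify_plus <- function(template, forward, reverse, max_mismatch, bounds) {
  fh <- find_primer_sites(template, forward, max_mismatch)
  fh <- fh[fh$strand == "+", , drop = FALSE]
  rh <- find_primer_sites(template, reverse, max_mismatch)
  rh <- rh[rh$strand == "-", , drop = FALSE]
  out <- list()
  if (nrow(fh) && nrow(rh)) {
    for (i in seq_len(nrow(fh))) {
      cand <- rh[rh$start > fh$end[i], , drop = FALSE]
      if (!nrow(cand)) next
      j <- which.min(cand$start)          # nearest downstream
      len <- cand$end[j] - fh$start[i] + 1L
      if (len >= bounds[1L] && len <= bounds[2L])
        out[[length(out) + 1L]] <- data.frame(
          start = fh$start[i], end = cand$end[j], strand = "+",
          sequence = substr(template, fh$start[i], cand$end[j]))
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(start = integer(), end = integer(), strand = character(),
               sequence = character())
}

#' Extract in-silico PCR products
#'
#' Pairs every forward-primer site with the nearest downstream
#' reverse-primer site (on the opposite strand) and reports the spanned
#' product when its length lies within `bounds`. Both template orientations
#' are scanned; minus-strand amplicons are reported with mirrored plus-strand
#' coordinates and the minus-strand product sequence. Amplicons include both
#' primer-binding regions, as cloned PCR products do.
#'
#' @param template nucleotide string (plus strand).
#' @param forward,reverse [primer()] objects (5' to 3').
#' @param bounds numeric length-2 vector, inclusive product-length bounds
#'   (default `c(200, 5000)`).
#' @param max_mismatch allowed mismatches per primer site (default 0).
#' @return data.frame with columns `start`, `end` (1-based inclusive, plus
#'   strand), `strand`, `sequence`. Zero rows when no product forms.
#' @export
simulate_pcr <- function(template, forward, reverse,
                         bounds = c(200, 5000), max_mismatch = 0) {
  stopifnot(length(bounds) == 2L, bounds[1L] > 0, bounds[1L] <= bounds[2L])
  template <- .check_iupac(template, "template")
  plus <- .amplify_plus(template, forward, reverse, max_mismatch, bounds)
  rc <- .revcomp(template)
  minus <- .amplify_plus(rc, forward, reverse, max_mismatch, bounds)
  if (nrow(minus)) {
    L <- nchar(template)
    minus <- data.frame(start = L - minus$end + 1L,
                        end = L - minus$start + 1L,
                        strand = "-", sequence = minus$sequence)
  }
  out <- rbind(plus, minus)
  rownames(out) <- NULL
  out
}

#' Define a restriction enzyme
#'
#' @param name label.
#' @param recognition IUPAC recognition site.
#' @param cut_offset 0-based position of the cut within the site on the top
#'   strand: the enzyme cuts after `cut_offset` bases of the site.
#' @return an object of class `"restriction_enzyme"`.
#' @export
restriction_enzyme <- function(name, recognition, cut_offset) {
  recognition <- .check_iupac(recognition, paste0("recognition of ", name))
  if (!nzchar(recognition)) stop("empty recognition site")
  stopifnot(cut_offset >= 0, cut_offset <= nchar(recognition))
  structure(list(name = name, recognition = recognition,
                 cut_offset = as.integer(cut_offset)),
            class = "restriction_enzyme")
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  site <- paste0(substr(x$recognition, 1, x$cut_offset), "^",
                 substr(x$recognition, x$cut_offset + 1,
                        nchar(x$recognition)))
  cat(sprintf("<restriction enzyme> %s %s\n", x$name, site))
  invisible(x)
}

#' Packaged restriction-enzyme registry
#'
#' Catalogue values for the five ARDRA enzymes: HhaI (GCG^C), HinfI
#' (G^ANTC), HaeIII (GG^CC), SmaI (CCC^GGG), XhoI (C^TCGAG). All five
#' recognition sites are reverse-complement palindromes, which is asserted
#' at load (the digest scanner relies on it to scan one strand only).
#'
#' @return named list of [restriction_enzyme()] objects.
#' @export
std_enzymes <- function() {
  path <- system.file("extdata", "enzymes.yaml", package = "propsyn",
                      mustWork = TRUE)
  docs <- yaml::read_yaml(path)
  out <- lapply(docs, function(d)
    restriction_enzyme(d$name, d$recognition, d$cut_offset))
  for (e in out)
    if (.revcomp(e$recognition) != e$recognition)
      stop("recognition site of ", e$name,
           " is not palindromic; one-strand scanning would miss sites")
  stats::setNames(out, vapply(out, `[[`, "", "name"))
}

#' Restriction digest of a linear molecule
#'
#' Finds every IUPAC match of each enzyme's recognition site on the top
#' strand (all packaged sites are palindromic, so this covers both strands),
#' places cuts at site start + cut offset, deduplicates cut positions across
#' enzymes, and returns the fragment lengths between consecutive cuts.
#' Fragment lengths always sum to the input length.
#'
#' @param sequence nucleotide string (linear, double-stranded).
#' @param enzymes a [restriction_enzyme()] or list of them (a list simulates
#'   a double digest in one reaction).
#' @return sorted (decreasing) integer vector of fragment lengths.
#' @examples
#' hha <- std_enzymes()$HhaI
#' digest("AAGCGCAA", hha)  # fragments 5 and 3
#' @export
digest <- function(sequence, enzymes) {
  if (inherits(enzymes, "restriction_enzyme")) enzymes <- list(enzymes)
  stopifnot(is.list(enzymes), length(enzymes) > 0L)
  sequence <- .check_iupac(sequence, "sequence")
  n <- nchar(sequence)
  subj <- Biostrings::DNAString(sequence)
  cuts <- integer()
  for (e in enzymes) {
    hits <- Biostrings::matchPattern(Biostrings::DNAString(e$recognition),
                                     subj, fixed = FALSE)
    if (length(hits))
      cuts <- c(cuts, Biostrings::start(hits) - 1L + e$cut_offset)
  }
  cuts <- sort(unique(cuts[cuts > 0L & cuts < n]))
  sort(diff(c(0L, cuts, n)), decreasing = TRUE)
}

#' Bin a fragment pattern at gel resolution
#'
#' Emulates reading fragment sizes off an agarose gel: fragments below the
#' detection limit are invisible and dropped; the rest are sorted by
#' decreasing length and adjacent lengths are merged into one band when they
#' differ by less than `tolerance` times the larger length. Each band is
#' reported as the rounded mean of its members.
#'
#' @param fragments integer vector of fragment lengths (nt).
#' @param tolerance relative resolution of the gel (default 0.05).
#' @param detection_limit smallest visible fragment in nt (default 50).
#' @return sorted (decreasing) integer vector of band lengths.
#' @export
gel_bin <- function(fragments, tolerance = 0.05, detection_limit = 50) {
  stopifnot(tolerance >= 0, detection_limit >= 0)
  f <- sort(fragments[fragments >= detection_limit], decreasing = TRUE)
  if (!length(f)) return(integer())
  band <- cumsum(c(1L, as.integer(-diff(f) >= tolerance * f[-length(f)])))
  as.integer(vapply(split(f, band),
                    function(v) round_half_away(mean(v)), 0))
}

#' ARDRA fingerprints of a clone set
#'
#' Digests every sequence with each assay (an assay is one restriction
#' reaction: a single enzyme or an enzyme mixture) and bins the fragments at
#' gel resolution, yielding one binned pattern per assay per clone.
#'
#' @param seqs named character vector of clone sequences.
#' @param assays named list of assays; each assay is a
#'   [restriction_enzyme()] or a list of them. Defaults to the bacterial
#'   HhaI and HinfI single digests.
#' @param tolerance,detection_limit passed to [gel_bin()].
#' @return list of profiles, one per clone: `list(clone, patterns)` where
#'   `patterns` is a named list of binned band-length vectors.
#' @export
ardra_profiles <- function(seqs, assays = NULL,
                           tolerance = 0.05, detection_limit = 50) {
  if (is.null(assays)) {
    enz <- std_enzymes()
    assays <- list(HhaI = enz$HhaI, HinfI = enz$HinfI)
  }
  if (is.null(names(seqs)))
    names(seqs) <- paste0("clone_", seq_along(seqs))
  lapply(stats::setNames(names(seqs), names(seqs)), function(id) {
    pats <- lapply(assays, function(a)
      gel_bin(digest(seqs[[id]], a), tolerance, detection_limit))
    list(clone = id, patterns = pats)
  })
}

#' Group clones by identical ARDRA fingerprints
#'
#' Clones whose binned fragment patterns are identical across all assays
#' fall into one group; one member per group would be sequenced in the
#' wet-lab workflow. Groups are returned in order of first appearance and
#' partition the clone set.
#'
#' @param profiles list of profiles as returned by [ardra_profiles()]; all
#'   must carry the same assay list.
#' @return list of groups, each `list(key, members, representative)`; the
#'   representative is the first member.
#' @export
group_profiles <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) > 0L)
  assay_names <- lapply(profiles, function(p) names(p$patterns))
  if (length(unique(assay_names)) != 1L)
    stop("all profiles must carry the same assay list")
  keys <- vapply(profiles, function(p)
    paste(vapply(names(p$patterns), function(a)
      paste0(a, ":", paste(p$patterns[[a]], collapse = ",")), ""),
      collapse = ";"), "")
  clone_ids <- vapply(profiles, `[[`, "", "clone")
  out <- list()
  for (k in unique(keys)) {
    members <- clone_ids[keys == k]
    out[[length(out) + 1L]] <- list(key = k, members = members,
                                    representative = members[[1L]])
  }
  out
}
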