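# Thin FASTA wrappers: the package-level currency for sequences is a named
# character vector; Biostrings does the parsing and 80-column wrapping.

#' Read and write FASTA files
#'
#' @param path file path.
#' @return `read_fasta()` returns a named character vector of uppercase
#'   sequences; `write_fasta()` returns `path` invisibly.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector of nucleotide sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Read a taxonomic reference set from FASTA
#'
#' Headers must have three pipe-separated fields:
#' `name|species label|genus label`.
#'
#' @param path FASTA file path.
#' @return data.frame with columns `name`, `species`, `genus`, `sequence`.
#' @export
read_reference_fasta <- function(path) {
  seqs <- read_fasta(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  if (any(lengths(parts) != 3L))
    stop("reference headers must be 'name|species|genus'")
  data.frame(name = vapply(parts, `[`, "", 1L),
             species = vapply(parts, `[`, "", 2L),
             genus = vapply(parts, `[`, "", 3L),
             sequence = unname(seqs))
}
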