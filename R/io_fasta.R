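#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of scaffold sequences (names are the first
#'   whitespace-delimited token of each header).
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  names(ss) <- sub("\\s.*$", "", names(ss))
  setNames(as.character(ss), names(ss))
}

#' Write a genome FASTA
#'
#' @param genome Named character vector of scaffold sequences.
#' @param path Output file.
#' @export
write_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

# Extract genomic subsequence; strand "-" returns the reverse complement.
genome_seq <- function(genome, scaffold, start, end, strand = "+") {
  if (!scaffold %in% names(genome))
    stop(sprintf("unknown scaffold '%s'", scaffold))
  L <- nchar(genome[[scaffold]])
  if (start < 1 || end > L)
    stop(sprintf("interval [%d,%d] outside scaffold %s (length %d)",
                 start, end, scaffold, L))
  s <- substr(genome[[scaffold]], start, end)
  if (strand == "-") revcomp(s) else s
}
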