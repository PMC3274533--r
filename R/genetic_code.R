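# Ciliate nuclear genetic code (NCBI translation table 6).
#
# In Tetrahymena (and other ciliates using this code) TAA and TAG encode
# glutamine; TGA is the only termination codon.  All ORF and premature-stop
# logic in the package therefore treats TGA, and only TGA, as a stop.

#' The ciliate nuclear genetic code (translation table 6)
#'
#' Returns the codon table used throughout the package: the standard genetic
#' code with TAA and TAG reassigned to glutamine (Q), leaving TGA as the sole
#' stop codon.
#'
#' @return Named character vector mapping codons to one-letter amino acids
#'   ("*" for stop).
#' @export
ciliate_genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  gc[c("TAA", "TAG")] <- "Q"
  gc
}

#' Translate a nucleotide sequence under the ciliate code
#'
#' Translates complete codons from position 1 of `seq`; any trailing partial
#' codon is dropped.
#'
#' @param seq Character scalar of DNA (A/C/G/T).
#' @return Character vector of one-letter amino acids ("*" = TGA stop, "X"
#'   for codons with ambiguous bases).
#' @export
translate_ciliate <- function(seq) {
  n <- nchar(seq)
  if (n < 3) return(character(0))
  starts <- seq.int(1L, n - 2L, by = 3L)
  codons <- substring(seq, starts, starts + 2L)
  gc <- ciliate_genetic_code()
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  aa
}

#' Find open reading frames under the ciliate code
#'
#' Scans all six frames of `seq` for ATG...TGA open reading frames (TAA/TAG
#' do not terminate ORFs in ciliates).  ORFs are maximal: for each stop the
#' 5'-most in-frame ATG is reported.
#'
#' @param seq Character scalar of DNA.
#' @param min_codons Minimum ORF length in codons, ATG and stop included.
#' @return data.frame with columns start, end (1-based on the input strand
#'   given by `strand`), strand, n_codons; zero rows if none found.
#' @export
find_orfs <- function(seq, min_codons = 100) {
  scan_one <- function(s, strand) {
    n <- nchar(s)
    out <- list()
    for (off in 0:2) {
      if (n - off < 3) next
      starts <- seq.int(1L + off, n - 2L, by = 3L)
      codons <- substring(s, starts, starts + 2L)
      stop_i <- which(codons == "TGA")
      atg_i <- which(codons == "ATG")
      prev_stop <- 0L
      for (si in stop_i) {
        cand <- atg_i[atg_i > prev_stop & atg_i < si]
        if (length(cand)) {
          a <- cand[1L]
          nc <- si - a + 1L
          if (nc >= min_codons) {
            out[[length(out) + 1L]] <- data.frame(
              start = starts[a], end = starts[si] + 2L,
              strand = strand, n_codons = nc
            )
          }
        }
        prev_stop <- si
      }
    }
    out
  }
  res <- c(
    scan_one(seq, "+"),
    scan_one(revcomp(seq), "-")
  )
  if (!length(res)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), n_codons = integer(0)))
  }
  do.call(rbind, res)
}

#' Reverse-complement a DNA string
#' @param seq Character scalar.
#' @return Character scalar.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Scan an isoform for an in-frame premature termination codon
#'
#' Walks codons of a (spliced or intron-retaining) isoform sequence from the
#' CDS start and reports whether an in-frame TGA occurs strictly upstream of
#' the annotated stop codon.  Under the ciliate code TAA/TAG encode glutamine
#' and never terminate, so only TGA counts.
#'
#' @param isoform Character scalar: the transcript-orientation sequence of the
#'   alternative isoform.
#' @param cds_start 1-based position of the first base of the start codon in
#'   `isoform`.
#' @param annotated_stop 1-based position of the first base of the annotated
#'   stop codon in `isoform`, or `NA` if the annotated stop is absent from
#'   this isoform (e.g. removed by exon skipping); in that case any in-frame
#'   TGA is premature.
#' @return `TRUE` if a premature in-frame TGA exists.
#' @export
scan_ptc <- function(isoform, cds_start, annotated_stop = NA) {
  if (is.na(cds_start) || cds_start < 1 || cds_start + 2 > nchar(isoform))
    stop("CDS start not found in isoform")
  n <- nchar(isoform)
  starts <- seq.int(cds_start, n - 2L, by = 3L)
  codons <- substring(isoform, starts, starts + 2L)
  hit <- which(codons == "TGA")
  if (!length(hit)) return(FALSE)
  first_stop <- starts[hit[1L]]
  if (is.na(annotated_stop)) TRUE else first_stop < annotated_stop
}
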