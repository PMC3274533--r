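# Junction validation and filtering under the pipeline's acceptance rules:
# canonical GT-AG terminal dinucleotides (in transcript orientation), >= 8 bp
# anchors on both sides, intron length within [10, 10000], and a minimum
# non-redundant read support (1 for the detection universe; AS calling
# re-filters at 2).

#' Validate junctions against the genome
#'
#' Extracts the terminal intron dinucleotides and sets the canonical GT-AG
#' flag.  On the minus strand the genomic CT...AC motif reads GT-AG in
#' transcript orientation.  Unstranded junctions (strand ".") have their
#' strand inferred from the dinucleotides (GT-AG implies "+", CT-AC implies
#' "-"); junctions that are non-canonical in both orientations are dropped
#' with a log entry.
#'
#' @param js An `sr_junctions`.
#' @param genome Named character vector of scaffold sequences.
#' @return The junction set with donor/acceptor/canonical (and inferred
#'   strand) filled in.
#' @export
validate_junctions <- function(js, genome) {
  if (!nrow(js)) return(js)
  for (i in seq_len(nrow(js))) {
    sc <- js$scaffold[i]
    if (!sc %in% names(genome) || js$start[i] < 1 ||
        js$end[i] > nchar(genome[[sc]]))
      stop(sprintf("junction %s:%d-%d out of scaffold bounds",
                   sc, js$start[i], js$end[i]))
  }
  left <- substr_vec(genome, js$scaffold, js$start, js$start + 1L)
  right <- substr_vec(genome, js$scaffold, js$end - 1L, js$end)
  plus_can <- left == "GT" & right == "AG"
  minus_can <- left == "CT" & right == "AC"
  unstranded <- !(js$strand %in% c("+", "-"))
  inferred <- ifelse(plus_can, "+", ifelse(minus_can, "-", NA))
  drop <- unstranded & is.na(inferred)
  if (any(drop))
    sr_log("dropping %d unstranded junction(s) non-canonical in both orientations",
           sum(drop))
  js$strand[unstranded] <- inferred[unstranded]
  # transcript-orientation dinucleotides
  minus <- js$strand == "-" & !is.na(js$strand)
  js$donor <- ifelse(minus, vapply(right, revcomp, ""), left)
  js$acceptor <- ifelse(minus, vapply(left, revcomp, ""), right)
  js$canonical <- !is.na(js$donor) & js$donor == "GT" & js$acceptor == "AG"
  js[!drop, , drop = FALSE]
}

substr_vec <- function(genome, scaffold, start, end) {
  vapply(seq_along(scaffold), function(i)
    substr(genome[[scaffold[i]]], start[i], end[i]), "")
}

#' Count non-redundant read spans
#'
#' Reads supporting a junction are deduplicated by alignment span: reads with
#' identical (start, end) count once.
#'
#' @param spans data.frame or matrix with columns start, end (one row per
#'   aligned read).
#' @return Integer count of distinct spans.
#' @export
count_nonredundant <- function(spans) {
  spans <- as.data.frame(spans)
  if (!nrow(spans)) return(0L)
  nrow(unique(spans[, c("start", "end")]))
}

#' Filter a junction set by the pipeline's acceptance thresholds
#'
#' Retains canonical GT-AG junctions with `min_anchor >= min_anchor`,
#' intron length within `[min_intron, max_intron]`, and total (pooled over
#' samples) non-redundant support `>= min_support`.  Filtering is idempotent
#' and monotone in every threshold.
#'
#' @param js A validated `sr_junctions`.
#' @param min_anchor Minimum anchor length in bp (default 8).
#' @param min_support Minimum pooled non-redundant read support (default 1;
#'   AS calling uses 2).
#' @param min_intron,max_intron Intron length bounds in bp (defaults 10 and
#'   10000).
#' @return The filtered junction set.
#' @export
filter_junctions <- function(js, min_anchor = 8, min_support = 1,
                             min_intron = 10, max_intron = 10000) {
  if (!nrow(js)) return(js)
  if (any(is.na(js$canonical)))
    stop("junctions must be validated (canonical flag set) before filtering")
  len <- js$end - js$start + 1L
  keep <- js$canonical &
    js$min_anchor >= min_anchor &
    len >= min_intron & len <= max_intron &
    junction_support(js) >= min_support
  out <- js[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
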