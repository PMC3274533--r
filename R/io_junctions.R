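# Splice-junction evidence.  A junction set is a data.frame (class
# `sr_junctions`) with one row per distinct intron interval:
#   scaffold, start, end   intron interval (1-based inclusive)
#   strand                 "+", "-" or "." (unstranded input)
#   donor, acceptor        terminal dinucleotides in transcript orientation
#                          (NA until validated against a genome)
#   canonical              TRUE iff donor=="GT" and acceptor=="AG"
#   min_anchor             shortest aligned flank (bp) among supporting reads
#   support.<sample>       non-redundant read support per sample
# Serialized as BED12 junction records (blocks = anchors, gap = intron) plus
# a support TSV keyed by junction name.

#' Construct a junction set
#'
#' @param df data.frame with at least scaffold, start, end, strand,
#'   min_anchor and one or more `support.<sample>` columns.
#' @return An `sr_junctions` data.frame.
#' @export
junctions <- function(df) {
  needed <- c("scaffold", "start", "end", "strand", "min_anchor")
  stopifnot(all(needed %in% names(df)))
  if (!any(startsWith(names(df), "support.")))
    stop("junction set needs at least one support.<sample> column")
  if (!"donor" %in% names(df)) df$donor <- rep(NA_character_, nrow(df))
  if (!"acceptor" %in% names(df)) df$acceptor <- rep(NA_character_, nrow(df))
  if (!"canonical" %in% names(df)) df$canonical <- rep(NA, nrow(df))
  if (any(df$end < df$start)) stop("junction with negative intron length")
  if (any(df$min_anchor < 0)) stop("junction with negative anchor")
  df <- df[order(df$scaffold, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("sr_junctions", "data.frame")
  df
}

#' Sample names carried by a junction set
#' @param js An `sr_junctions`.
#' @return Character vector of sample labels.
#' @export
junction_samples <- function(js) {
  sub("^support\\.", "", grep("^support\\.", names(js), value = TRUE))
}

#' Per-junction support, summed over samples (or a subset)
#' @param js An `sr_junctions`.
#' @param samples Samples to sum over (default all).
#' @return Integer vector.
#' @export
junction_support <- function(js, samples = junction_samples(js)) {
  cols <- paste0("support.", samples)
  as.integer(round(rowSums(as.data.frame(js)[, cols, drop = FALSE])))
}

#' Write a junction set as BED12 + support TSV
#'
#' The BED12 record encodes each junction TopHat-style: two blocks of
#' `min_anchor` bp flanking the intron gap; the score is the total support.
#'
#' @param js An `sr_junctions`.
#' @param bed_path,support_path Output files.
#' @export
write_junctions <- function(js, bed_path, support_path) {
  js <- junctions(as.data.frame(js))  # deterministic order
  n <- nrow(js)
  if (n == 0L) {
    writeLines(character(0), bed_path)
    sup <- data.frame(name = character(0), strand = character(0),
                      donor = character(0), acceptor = character(0),
                      min_anchor = integer(0), stringsAsFactors = FALSE)
    for (s in junction_samples(js)) sup[[paste0("support.", s)]] <- integer(0)
    write.table(sup, support_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    return(invisible(bed_path))
  }
  name <- sprintf("JUNC%06d", seq_len(n))
  anchor <- pmax(1L, as.integer(js$min_anchor))
  ilen <- js$end - js$start + 1L
  gr <- GenomicRanges::GRanges(
    js$scaffold,
    IRanges::IRanges(js$start - anchor, js$end + anchor),
    strand = ifelse(js$strand %in% c("+", "-"), js$strand, "*")
  )
  S4Vectors::mcols(gr)$name <- name
  S4Vectors::mcols(gr)$score <- junction_support(js)
  blocks <- IRanges::IRangesList(lapply(seq_len(n), function(i)
    IRanges::IRanges(start = c(1L, anchor[i] + ilen[i] + 1L),
                     width = c(anchor[i], anchor[i]))))
  S4Vectors::mcols(gr)$blocks <- blocks
  rtracklayer::export(gr, bed_path, format = "BED")
  sup <- data.frame(name = name, strand = js$strand,
                    donor = js$donor, acceptor = js$acceptor,
                    min_anchor = js$min_anchor,
                    stringsAsFactors = FALSE)
  for (s in junction_samples(js)) sup[[paste0("support.", s)]] <-
    js[[paste0("support.", s)]]
  write.table(sup, support_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(bed_path)
}

#' Read a junction set from BED12 + support TSV
#'
#' The intron interval is recovered from the block structure (gap between
#' the two anchor blocks); a negative gap or anchor is a format error.
#'
#' @param bed_path BED12 junction records.
#' @param support_path Per-sample non-redundant support TSV (written by
#'   [write_junctions()]).
#' @return An `sr_junctions`; empty input gives a zero-row set.
#' @export
read_junctions <- function(bed_path, support_path) {
  sup <- read.delim(support_path, stringsAsFactors = FALSE,
                    check.names = FALSE)
  gr <- rtracklayer::import(bed_path, format = "BED")
  if (!length(gr)) {
    df <- data.frame(scaffold = character(0), start = integer(0),
                     end = integer(0), strand = character(0),
                     donor = character(0), acceptor = character(0),
                     canonical = logical(0), min_anchor = integer(0),
                     stringsAsFactors = FALSE)
    df[["support.pooled"]] <- integer(0)
    return(junctions(df))
  }
  blocks <- S4Vectors::mcols(gr)$blocks
  nb <- vapply(blocks, length, 0L)
  if (any(nb != 2L)) stop("junction BED record without exactly 2 blocks")
  w1 <- vapply(blocks, function(b) IRanges::width(b)[1], 0L)
  w2 <- vapply(blocks, function(b) IRanges::width(b)[2], 0L)
  istart <- GenomicRanges::start(gr) + w1
  iend <- GenomicRanges::end(gr) - w2
  if (any(iend < istart)) stop("junction with negative intron gap")
  if (any(w1 < 1 | w2 < 1)) stop("junction with non-positive anchor block")
  df <- data.frame(
    scaffold = as.character(GenomicRanges::seqnames(gr)),
    start = istart, end = iend,
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  df$strand[df$strand == "*"] <- "."
  m <- match(S4Vectors::mcols(gr)$name, sup$name)
  if (any(is.na(m))) stop("junction name missing from support TSV")
  df$strand <- sup$strand[m]
  df$donor <- sup$donor[m]
  df$acceptor <- sup$acceptor[m]
  df$min_anchor <- sup$min_anchor[m]
  for (col in grep("^support\\.", names(sup), value = TRUE))
    df[[col]] <- sup[[col]][m]
  js <- junctions(df)
  js$canonical <- !is.na(js$donor) & js$donor == "GT" &
    !is.na(js$acceptor) & js$acceptor == "AG"
  js
}
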