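# Per-base coverage tracks.  A track is a named list of integer vectors (one
# per scaffold, full scaffold length, depth 0 where no reads map); bedGraph
# serialization goes through rtracklayer.

#' Construct a coverage track
#'
#' @param depths Named list of integer vectors, one per scaffold.
#' @param sample Sample label.
#' @return An object of class `sr_coverage`.
#' @export
coverage_track <- function(depths, sample = "pooled") {
  stopifnot(is.list(depths), !is.null(names(depths)))
  depths <- lapply(depths, function(v) {
    v <- as.numeric(v)
    if (any(v < 0)) stop("negative depth in coverage track")
    v
  })
  structure(depths, class = "sr_coverage", sample = sample)
}

#' @export
print.sr_coverage <- function(x, ...) {
  cat(sprintf("<sr_coverage> sample=%s, %d scaffolds, %d covered bases\n",
              attr(x, "sample"), length(x),
              sum(vapply(x, function(v) sum(v > 0), 0))))
  invisible(x)
}

#' Query per-base depth over an interval
#'
#' Positions beyond the recorded track (or scaffolds absent from it) have
#' depth 0.
#'
#' @param cov An `sr_coverage`.
#' @param scaffold Scaffold name.
#' @param start,end 1-based inclusive interval.
#' @return Numeric vector of length `end - start + 1`.
#' @export
coverage_query <- function(cov, scaffold, start, end) {
  stopifnot(start >= 1, end >= start)
  n <- end - start + 1L
  if (!scaffold %in% names(cov)) return(numeric(n))
  v <- cov[[scaffold]]
  out <- numeric(n)
  hi <- min(end, length(v))
  if (hi >= start) out[seq_len(hi - start + 1L)] <- v[start:hi]
  out
}

# sum several tracks (e.g. samples of a stage group, or all samples pooled)
pool_coverage <- function(tracks, sample = "pooled") {
  stopifnot(length(tracks) >= 1)
  scafs <- unique(unlist(lapply(tracks, names)))
  out <- lapply(scafs, function(sc) {
    L <- max(vapply(tracks, function(t)
      if (sc %in% names(t)) length(t[[sc]]) else 0L, 0L))
    acc <- numeric(L)
    for (t in tracks) if (sc %in% names(t)) {
      v <- t[[sc]]
      acc[seq_along(v)] <- acc[seq_along(v)] + v
    }
    acc
  })
  coverage_track(setNames(out, scafs), sample = sample)
}

#' Read a per-base coverage track from bedGraph
#'
#' Overlapping intervals are rejected as a format error.  `seqlengths`, if
#' given, fixes the scaffold lengths; otherwise each scaffold's vector ends
#' at its last covered base (queries past it return 0).
#'
#' @param path bedGraph file.
#' @param seqlengths Optional named integer vector of scaffold lengths.
#' @param sample Sample label.
#' @return An `sr_coverage`.
#' @export
read_coverage <- function(path, seqlengths = NULL, sample = basename(path)) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) && any(GenomicRanges::countOverlaps(gr, gr) > 1))
    stop("overlapping intervals in bedGraph ", path)
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  scafs <- if (!is.null(seqlengths)) names(seqlengths) else unique(df$seqnames)
  depths <- lapply(scafs, function(sc) {
    d <- df[df$seqnames == sc, , drop = FALSE]
    L <- if (!is.null(seqlengths)) seqlengths[[sc]]
         else if (nrow(d)) max(d$end) else 0L
    v <- numeric(L)
    for (i in seq_len(nrow(d))) v[d$start[i]:d$end[i]] <- d$score[i]
    v
  })
  coverage_track(setNames(depths, scafs), sample = sample)
}

#' Write a coverage track as bedGraph
#'
#' Only nonzero runs are emitted, in deterministic (scaffold, start) order.
#'
#' @param cov An `sr_coverage`.
#' @param path Output file.
#' @export
write_coverage <- function(cov, path) {
  rows <- list()
  for (sc in sort(names(cov))) {
    v <- cov[[sc]]
    if (!length(v)) next
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values > 0
    if (any(keep))
      rows[[length(rows) + 1L]] <- data.frame(
        seqnames = sc, start = starts[keep], end = ends[keep],
        score = r$values[keep], stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$seqnames,
                               IRanges::IRanges(df$start, df$end),
                               score = df$score)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
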