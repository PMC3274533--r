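# Simplified coverage-island transcript assembly: maximal intervals with
# depth >= min_cov (bridging gaps <= max_gap) become candidate exonic
# islands; accepted junctions whose anchors land in covered islands link
# them; each maximal linked chain is one transcript, with exons cut at the
# junction boundaries of a non-conflicting junction chain chosen by support.

#' Assemble transcripts from coverage and accepted junctions
#'
#' @param cov A [coverage_track()] (typically pooled over samples).
#' @param js A filtered `sr_junctions` (see [filter_junctions()]).
#' @param min_cov Minimum per-base depth for exonic sequence (default 2).
#' @param max_gap Sub-threshold gaps up to this length are bridged
#'   (default 25).
#' @return An `sr_transcripts`: data.frame transcript_id, scaffold, strand,
#'   start, end, n_exons plus an `exons` attribute (data.frame
#'   transcript_id, start, end, mean_cov).
#' @export
assemble_transcripts <- function(cov, js, min_cov = 2, max_gap = 25) {
  tx_rows <- list(); ex_rows <- list()
  tid <- 0L
  for (sc in names(cov)) {
    v <- cov[[sc]]
    isl <- coverage_islands(v, min_cov, max_gap)
    if (!nrow(isl)) next
    js_sc <- js[js$scaffold == sc, , drop = FALSE]
    # a junction is usable iff both anchor bases fall inside islands
    isl_of <- function(pos) {
      hit <- which(isl$start <= pos & isl$end >= pos)
      if (length(hit)) hit[1] else NA_integer_
    }
    if (nrow(js_sc)) {
      js_sc$left_isl <- vapply(js_sc$start - 1L, isl_of, 0L)
      js_sc$right_isl <- vapply(js_sc$end + 1L, isl_of, 0L)
      js_sc <- js_sc[!is.na(js_sc$left_isl) & !is.na(js_sc$right_isl), ,
                     drop = FALSE]
    }
    # connected components of islands under junction links
    comp <- seq_len(nrow(isl))
    find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
    if (nrow(js_sc)) for (i in seq_len(nrow(js_sc))) {
      a <- find(js_sc$left_isl[i]); b <- find(js_sc$right_isl[i])
      if (a != b) comp[max(a, b)] <- min(a, b)
    }
    roots <- vapply(seq_len(nrow(isl)), find, 0L)
    for (r in unique(roots)) {
      members <- which(roots == r)
      span <- c(min(isl$start[members]), max(isl$end[members]))
      jc <- if (nrow(js_sc))
        js_sc[js_sc$left_isl %in% members | js_sc$right_isl %in% members, ,
              drop = FALSE]
      else js_sc
      chain <- select_junction_chain(jc)
      tid <- tid + 1L
      id <- sprintf("TX%05d", tid)
      # exons: span cut at chain introns
      bounds_s <- c(span[1], chain$end + 1L)
      bounds_e <- c(chain$start - 1L, span[2])
      ex <- data.frame(transcript_id = id, start = bounds_s, end = bounds_e)
      ex <- ex[ex$end >= ex$start, , drop = FALSE]
      ex$mean_cov <- vapply(seq_len(nrow(ex)), function(i)
        mean(v[ex$start[i]:ex$end[i]]), 0)
      strand <- if (nrow(chain)) {
        st <- unique(chain$strand[chain$strand %in% c("+", "-")])
        if (length(st) == 1) st else "."
      } else "."
      tx_rows[[length(tx_rows) + 1L]] <- data.frame(
        transcript_id = id, scaffold = sc, strand = strand,
        start = span[1], end = span[2], n_exons = nrow(ex),
        stringsAsFactors = FALSE)
      ex_rows[[length(ex_rows) + 1L]] <- ex
    }
  }
  tx <- if (length(tx_rows)) do.call(rbind, tx_rows)
  else data.frame(transcript_id = character(0), scaffold = character(0),
                  strand = character(0), start = integer(0),
                  end = integer(0), n_exons = integer(0),
                  stringsAsFactors = FALSE)
  ex <- if (length(ex_rows)) do.call(rbind, ex_rows)
  else data.frame(transcript_id = character(0), start = integer(0),
                  end = integer(0), mean_cov = numeric(0))
  ord <- order(tx$scaffold, tx$start, tx$transcript_id)
  tx <- tx[ord, , drop = FALSE]
  rownames(tx) <- NULL
  rownames(ex) <- NULL
  structure(tx, exons = ex, class = c("sr_transcripts", "data.frame"))
}

coverage_islands <- function(v, min_cov, max_gap) {
  ok <- v >= min_cov
  if (!any(ok)) return(data.frame(start = integer(0), end = integer(0)))
  r <- rle(ok)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  iv <- data.frame(start = starts[r$values], end = ends[r$values])
  # bridge short gaps
  if (nrow(iv) > 1) {
    keep_sep <- iv$start[-1] - iv$end[-nrow(iv)] - 1L > max_gap
    grp <- cumsum(c(TRUE, keep_sep))
    iv <- data.frame(start = as.integer(tapply(iv$start, grp, min)),
                     end = as.integer(tapply(iv$end, grp, max)))
  }
  iv
}

# Deterministic non-conflicting junction chain: order by support (desc),
# then leftmost, then shortest; accept greedily if the intron does not
# overlap an accepted one.
select_junction_chain <- function(jc) {
  if (is.null(jc) || !nrow(jc))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0)))
  sup <- junction_support(jc)
  ord <- order(-sup, jc$start, jc$end - jc$start)
  jc <- jc[ord, , drop = FALSE]
  acc <- integer(0)
  for (i in seq_len(nrow(jc))) {
    if (!length(acc) ||
        !any(iv_overlaps(jc$start[i], jc$end[i],
                         jc$start[acc], jc$end[acc])))
      acc <- c(acc, i)
  }
  out <- jc[acc, c("start", "end", "strand"), drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' Exons of an assembled transcript set
#' @param ts An `sr_transcripts`.
#' @return data.frame transcript_id, start, end, mean_cov.
#' @export
transcript_exons <- function(ts) attr(ts, "exons")

# intron chain (data.frame start, end) of one transcript
transcript_introns <- function(ts, id) {
  e <- transcript_exons(ts)
  e <- e[e$transcript_id == id, , drop = FALSE]
  e <- e[order(e$start), , drop = FALSE]
  if (nrow(e) < 2) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = e$end[-nrow(e)] + 1L, end = e$start[-1] - 1L)
}
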