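# Internal data model: all coordinates are 1-based inclusive genomic
# positions (the IRanges/GenomicRanges convention); rtracklayer performs the
# 0-based conversions for BED/bedGraph at the I/O boundary.

#' Construct a gene-model annotation
#'
#' Container for a set of gene models: per-gene metadata (scaffold, strand,
#' CDS span) plus an exon table.  Exons are the *transcribed* exons; where
#' UTRs are unknown (ab initio annotations) they coincide with the CDS exons.
#'
#' @param genes data.frame with columns gene_id, scaffold, strand ("+"/"-"),
#'   cds_start, cds_end.
#' @param exons data.frame with columns gene_id, start, end.  Exons are
#'   sorted per gene by coordinate; unsorted input is sorted with a warning.
#' @param seqlengths Named integer vector of scaffold lengths.
#' @param provenance Free-text tag (e.g. "simulated truth", "corrected").
#' @return An object of class `sr_annotation`.
#' @export
annotation <- function(genes, exons, seqlengths, provenance = "unspecified") {
  stopifnot(all(c("gene_id", "scaffold", "strand", "cds_start", "cds_end")
                %in% names(genes)),
            all(c("gene_id", "start", "end") %in% names(exons)))
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  rownames(genes) <- NULL
  # deterministic ordering: scaffold, start, id
  ord <- order(exons$gene_id, exons$start)
  if (is.unsorted(ord)) {
    if (any(tapply(exons$start, exons$gene_id, is.unsorted)))
      warning("exons were not sorted by coordinate; sorting")
    exons <- exons[ord, , drop = FALSE]
  }
  rownames(exons) <- NULL
  obj <- structure(
    list(genes = genes, exons = exons,
         seqlengths = seqlengths, provenance = provenance),
    class = "sr_annotation"
  )
  validate_annotation(obj)
  obj
}

#' @export
print.sr_annotation <- function(x, ...) {
  cat(sprintf("<sr_annotation> %d gene models on %d scaffolds (%s)\n",
              nrow(x$genes), length(x$seqlengths), x$provenance))
  invisible(x)
}

# Structural invariants: exons sorted and non-overlapping within a gene,
# CDS span contained in the exon span, features inside scaffold bounds.
validate_annotation <- function(ann) {
  ex <- ann$exons
  for (gid in unique(ex$gene_id)) {
    e <- ex[ex$gene_id == gid, , drop = FALSE]
    if (any(e$end < e$start))
      stop(sprintf("gene %s: exon with end < start", gid))
    if (nrow(e) > 1 && any(e$start[-1] <= e$end[-nrow(e)]))
      stop(sprintf("gene %s: overlapping exons", gid))
  }
  g <- ann$genes
  sl <- ann$seqlengths
  bad <- !(g$scaffold %in% names(sl))
  if (any(bad))
    stop(sprintf("gene %s: unknown scaffold %s",
                 g$gene_id[bad][1], g$scaffold[bad][1]))
  span <- gene_spans(ann)
  m <- match(span$gene_id, g$gene_id)
  out <- span$end > unname(sl[g$scaffold[m]]) | span$start < 1
  if (any(out))
    stop(sprintf("gene %s: exon outside scaffold bounds", span$gene_id[out][1]))
  cds_bad <- !is.na(g$cds_start) &
    (g$cds_start < span$start[match(g$gene_id, span$gene_id)] |
       g$cds_end > span$end[match(g$gene_id, span$gene_id)])
  if (any(cds_bad))
    stop(sprintf("gene %s: CDS outside exon span", g$gene_id[cds_bad][1]))
  invisible(ann)
}

#' Genomic span of each gene model
#' @param ann An `sr_annotation`.
#' @return data.frame gene_id, scaffold, strand, start, end.
#' @export
gene_spans <- function(ann) {
  ex <- ann$exons
  s <- tapply(ex$start, ex$gene_id, min)
  e <- tapply(ex$end, ex$gene_id, max)
  ids <- names(s)
  m <- match(ids, ann$genes$gene_id)
  data.frame(gene_id = ids,
             scaffold = ann$genes$scaffold[m],
             strand = ann$genes$strand[m],
             start = as.integer(s), end = as.integer(e),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Introns of a gene model
#'
#' Introns are the gaps between consecutive exons, in genomic coordinate
#' order (1-based inclusive intervals).
#'
#' @param ann An `sr_annotation`.
#' @param gene_id Gene identifier.
#' @return data.frame start, end, length (zero rows for single-exon genes).
#' @export
gene_introns <- function(ann, gene_id) {
  e <- ann$exons[ann$exons$gene_id == gene_id, , drop = FALSE]
  if (nrow(e) < 2)
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0)))
  s <- e$end[-nrow(e)] + 1L
  en <- e$start[-1] - 1L
  data.frame(start = s, end = en, length = en - s + 1L)
}

#' Exonic length of each gene model
#' @param ann An `sr_annotation`.
#' @return Named integer vector (bp of exon union per gene).
#' @export
exon_lengths <- function(ann) {
  ex <- ann$exons
  v <- tapply(ex$end - ex$start + 1L, ex$gene_id, sum)
  setNames(as.integer(v), names(v))
}

#' UTR intervals implied by exon span vs CDS span
#'
#' The 5' and 3' UTRs are the transcribed exonic regions upstream of the CDS
#' start and downstream of the CDS end, assigned to 5'/3' by strand.
#'
#' @param ann An `sr_annotation`.
#' @return data.frame gene_id, utr5_len, utr3_len (bp of exonic sequence).
#' @export
utr_lengths <- function(ann) {
  g <- ann$genes
  res <- data.frame(gene_id = g$gene_id, utr5_len = 0L, utr3_len = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(g))) {
    if (is.na(g$cds_start[i])) next
    e <- ann$exons[ann$exons$gene_id == g$gene_id[i], , drop = FALSE]
    left <- sum(pmax(0L, pmin(e$end, g$cds_start[i] - 1L) - e$start + 1L))
    right <- sum(pmax(0L, e$end - pmax(e$start, g$cds_end[i] + 1L) + 1L))
    if (g$strand[i] == "+") {
      res$utr5_len[i] <- left; res$utr3_len[i] <- right
    } else {
      res$utr5_len[i] <- right; res$utr3_len[i] <- left
    }
  }
  res
}
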