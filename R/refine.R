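# Gene-model confirmation/correction, novel transcribed regions and UTR
# inference.

strand_compatible <- function(tx_strand, model_strand) {
  tx_strand == "." | tx_strand == model_strand
}

# exonic overlap (bp) between a transcript and a model
exonic_overlap <- function(tx_ex, mod_ex) {
  tot <- 0L
  for (i in seq_len(nrow(tx_ex))) {
    o <- pmin(tx_ex$end[i], mod_ex$end) - pmax(tx_ex$start[i], mod_ex$start) + 1L
    tot <- tot + sum(pmax(0L, o))
  }
  tot
}

#' Compare assembled transcripts to an annotation and correct it
#'
#' Classifies every reference model into exactly one status:
#' \describe{
#'   \item{complete_match}{some transcript's intron chain equals the model's
#'     intron chain exactly}
#'   \item{fused}{one transcript spans this model and at least one neighbour
#'     end-to-end (the models should be one gene)}
#'   \item{split}{two or more non-overlapping transcripts lie over the
#'     model, separated by a zero-coverage gap of at least `zero_gap` bp
#'     (the model should be several genes)}
#'   \item{boundary_mismatch}{same number of introns, each overlapping its
#'     counterpart, at least one boundary differing}
#'   \item{missing_or_extra_intron}{any other chain disagreement}
#'   \item{undetected}{no transcript overlaps the model}
#' }
#' The corrected annotation replaces the intron chains of mispredicted
#' models with the supporting transcript chains, merges fused models and
#' splits split models; UTRs are added separately by [infer_utrs()].
#'
#' @param ts An `sr_transcripts` from [assemble_transcripts()].
#' @param ann The reference [annotation()].
#' @param cov Pooled [coverage_track()] (used for the zero-coverage gap rule).
#' @param zero_gap Minimum zero-coverage gap calling a split (default 50).
#' @return List with `status` (data.frame gene_id, status, transcripts) and
#'   `corrected` (an [annotation()]).
#' @export
compare_to_annotation <- function(ts, ann, cov, zero_gap = 50) {
  g <- ann$genes
  span <- gene_spans(ann)
  m <- match(g$gene_id, span$gene_id)
  tx_ex_all <- transcript_exons(ts)
  # transcript assignment: >=1 bp exonic overlap, compatible strand
  assign <- vector("list", nrow(g))
  tx_models <- vector("list", nrow(ts))
  for (i in seq_len(nrow(g))) {
    mod_ex <- ann$exons[ann$exons$gene_id == g$gene_id[i], , drop = FALSE]
    hits <- character(0)
    cand <- which(ts$scaffold == g$scaffold[i] &
                    strand_compatible(ts$strand, g$strand[i]) &
                    ts$start <= span$end[m[i]] & ts$end >= span$start[m[i]])
    for (t in cand) {
      te <- tx_ex_all[tx_ex_all$transcript_id == ts$transcript_id[t], ,
                      drop = FALSE]
      ov <- exonic_overlap(te, mod_ex)
      if (ov >= 1) {
        hits <- c(hits, ts$transcript_id[t])
        tx_models[[t]] <- c(tx_models[[t]], g$gene_id[i])
      }
    }
    assign[[i]] <- hits
  }

  status <- rep(NA_character_, nrow(g))
  names(status) <- g$gene_id
  corrected_genes <- list(); corrected_exons <- list()
  consumed <- rep(FALSE, nrow(g))

  add_gene <- function(id, scaf, strand, exons, cds) {
    corrected_genes[[length(corrected_genes) + 1L]] <<- data.frame(
      gene_id = id, scaffold = scaf, strand = strand,
      cds_start = cds[1], cds_end = cds[2], stringsAsFactors = FALSE)
    corrected_exons[[length(corrected_exons) + 1L]] <<- data.frame(
      gene_id = id, start = exons$start, end = exons$end,
      stringsAsFactors = FALSE)
  }

  # ---- fused models: one transcript overlapping >= 2 models -------------
  for (t in seq_len(nrow(ts))) {
    mods <- tx_models[[t]]
    if (length(mods) < 2) next
    idx <- match(mods, g$gene_id)
    if (any(consumed[idx])) next
    status[mods] <- "fused"
    consumed[idx] <- TRUE
    te <- tx_ex_all[tx_ex_all$transcript_id == ts$transcript_id[t], ,
                    drop = FALSE]
    ord <- order(span$start[match(mods, span$gene_id)])
    add_gene(paste(mods[ord], collapse = "+"),
             g$scaffold[idx[1]], g$strand[idx[1]],
             te[order(te$start), c("start", "end")],
             range(c(g$cds_start[idx], g$cds_end[idx]), na.rm = TRUE))
  }

  # ---- remaining models -------------------------------------------------
  for (i in seq_len(nrow(g))) {
    if (consumed[i]) next
    gid <- g$gene_id[i]
    hits <- assign[[i]]
    mod_ex <- ann$exons[ann$exons$gene_id == gid, , drop = FALSE]
    mod_int <- gene_introns(ann, gid)
    cds <- c(g$cds_start[i], g$cds_end[i])
    if (!length(hits)) {
      status[gid] <- "undetected"
      add_gene(gid, g$scaffold[i], g$strand[i],
               mod_ex[, c("start", "end")], cds)
      next
    }
    # split: >=2 non-overlapping assigned transcripts separated by a
    # zero-coverage gap >= zero_gap
    if (length(hits) >= 2) {
      ht <- ts[match(hits, ts$transcript_id), , drop = FALSE]
      ht <- ht[order(ht$start), , drop = FALSE]
      seps <- logical(nrow(ht) - 1L)
      for (j in seq_len(nrow(ht) - 1L)) {
        gap_s <- ht$end[j] + 1L; gap_e <- ht$start[j + 1L] - 1L
        if (gap_e - gap_s + 1L >= zero_gap) {
          depth <- coverage_query(cov, g$scaffold[i], gap_s, gap_e)
          runs <- rle(depth == 0)
          seps[j] <- any(runs$lengths[runs$values] >= zero_gap)
        }
      }
      if (any(seps)) {
        status[gid] <- "split"
        consumed[i] <- TRUE
        part <- cumsum(c(1L, as.integer(seps)))
        for (p in unique(part)) {
          pt <- ht[part == p, , drop = FALSE]
          te <- tx_ex_all[tx_ex_all$transcript_id %in% pt$transcript_id, ,
                          drop = FALSE]
          te <- te[order(te$start), , drop = FALSE]
          cds_p <- c(max(cds[1], min(te$start)), min(cds[2], max(te$end)))
          add_gene(sprintf("%s.%d", gid, p), g$scaffold[i], g$strand[i],
                   te[, c("start", "end")], cds_p)
        }
        next
      }
    }
    # chain comparison against the best-overlapping transcript
    ovs <- vapply(hits, function(h) {
      te <- tx_ex_all[tx_ex_all$transcript_id == h, , drop = FALSE]
      exonic_overlap(te, mod_ex)
    }, 0L)
    ht <- ts[match(hits, ts$transcript_id), , drop = FALSE]
    best <- hits[order(-ovs, ht$start, hits)][1]
    tin <- transcript_introns(ts, best)
    if (nrow(tin) == nrow(mod_int) &&
        (nrow(tin) == 0 ||
           (all(tin$start == mod_int$start) && all(tin$end == mod_int$end)))) {
      status[gid] <- "complete_match"
      add_gene(gid, g$scaffold[i], g$strand[i],
               mod_ex[, c("start", "end")], cds)
    } else {
      pairwise <- nrow(tin) == nrow(mod_int) && nrow(tin) > 0 &&
        all(iv_overlaps(tin$start, tin$end, mod_int$start, mod_int$end))
      status[gid] <- if (pairwise) "boundary_mismatch"
                     else "missing_or_extra_intron"
      te <- tx_ex_all[tx_ex_all$transcript_id == best, , drop = FALSE]
      te <- te[order(te$start), , drop = FALSE]
      # corrected model: transcript chain, cropped to the evidence span
      add_gene(gid, g$scaffold[i], g$strand[i], te[, c("start", "end")],
               c(max(cds[1], min(te$start)), min(cds[2], max(te$end))))
    }
  }

  corrected <- annotation(do.call(rbind, corrected_genes),
                          do.call(rbind, corrected_exons),
                          ann$seqlengths, provenance = "corrected")
  status_df <- data.frame(
    gene_id = g$gene_id,
    status = unname(status[g$gene_id]),
    transcripts = vapply(assign, paste, "", collapse = ","),
    stringsAsFactors = FALSE)
  list(status = status_df, corrected = corrected)
}

#' Detect novel transcribed regions
#'
#' A novel transcribed region is an assembled transcript whose full span
#' lies strictly within intergenic space (no overlap with any annotated
#' model span) and whose span length is at least `min_len` (300 bp by
#' default, chosen because most UTRs are shorter, so UTR fragments are not
#' mistaken for novel genes).  Each region is ORF-scanned under the ciliate
#' code and tagged coding/non-coding.
#'
#' @param ts An `sr_transcripts`.
#' @param ann The (corrected) [annotation()].
#' @param genome Named character vector of scaffolds (for the ORF scan);
#'   omit to skip coding classification.
#' @param min_len Minimum span length in bp (default 300).
#' @param min_orf_codons ORF length (codons) above which a region is tagged
#'   coding (default 100).
#' @return data.frame region_id, scaffold, start, end, length, strand,
#'   n_exons, coding.
#' @export
detect_novel_regions <- function(ts, ann, genome = NULL, min_len = 300,
                                 min_orf_codons = 100) {
  span <- gene_spans(ann)
  keep <- logical(nrow(ts))
  for (t in seq_len(nrow(ts))) {
    len <- ts$end[t] - ts$start[t] + 1L
    if (len < min_len) next
    sp <- span[span$scaffold == ts$scaffold[t], , drop = FALSE]
    if (!any(iv_overlaps(ts$start[t], ts$end[t], sp$start, sp$end)))
      keep[t] <- TRUE
  }
  out <- ts[keep, , drop = FALSE]
  res <- data.frame(
    region_id = sprintf("NTR%04d", seq_len(nrow(out))),
    scaffold = out$scaffold, start = out$start, end = out$end,
    length = out$end - out$start + 1L, strand = out$strand,
    n_exons = out$n_exons, coding = rep(NA, nrow(out)),
    stringsAsFactors = FALSE)
  if (!is.null(genome) && nrow(res)) {
    tx_ex <- transcript_exons(ts)
    for (i in seq_len(nrow(res))) {
      te <- tx_ex[tx_ex$transcript_id == out$transcript_id[i], , drop = FALSE]
      te <- te[order(te$start), , drop = FALSE]
      seq <- paste(vapply(seq_len(nrow(te)), function(j)
        genome_seq(genome, res$scaffold[i], te$start[j], te$end[j]), ""),
        collapse = "")
      orfs <- find_orfs(seq, min_codons = min_orf_codons)
      res$coding[i] <- nrow(orfs) > 0
    }
  }
  res
}

#' Infer UTRs for confirmed gene models from read coverage
#'
#' For each model with status complete_match, the UTR extends outward from
#' each CDS end through contiguous positions of depth >= 1, stopping at the
#' first zero-depth base or at the nearest neighbouring gene span, whichever
#' comes first; the extension is assigned to 5'/3' by strand.
#'
#' @param cov Pooled [coverage_track()].
#' @param ann The corrected [annotation()].
#' @param status Status data.frame from [compare_to_annotation()]; only
#'   complete_match models are extended.
#' @return The annotation with first/last exons extended by the inferred
#'   UTRs (see [utr_lengths()]).
#' @export
infer_utrs <- function(cov, ann, status) {
  confirmed <- status$gene_id[status$status == "complete_match"]
  span <- gene_spans(ann)
  g <- ann$genes
  ex <- ann$exons
  for (gid in confirmed) {
    i <- which(g$gene_id == gid)
    sc <- g$scaffold[i]
    sp <- span[span$gene_id == gid, ]
    neighb <- span[span$scaffold == sc & span$gene_id != gid, , drop = FALSE]
    left_lim <- max(c(0L, neighb$end[neighb$end < sp$start])) + 1L
    right_lim <- min(c(ann$seqlengths[[sc]] + 1L,
                       neighb$start[neighb$start > sp$end])) - 1L
    rows <- which(ex$gene_id == gid)
    first <- rows[which.min(ex$start[rows])]
    last <- rows[which.max(ex$end[rows])]
    # extend left
    p <- ex$start[first] - 1L
    while (p >= left_lim && coverage_query(cov, sc, p, p) >= 1) p <- p - 1L
    ex$start[first] <- p + 1L
    # extend right
    p <- ex$end[last] + 1L
    while (p <= right_lim && coverage_query(cov, sc, p, p) >= 1) p <- p + 1L
    ex$end[last] <- p - 1L
  }
  annotation(g, ex, ann$seqlengths,
             provenance = paste0(ann$provenance, "+utr"))
}
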