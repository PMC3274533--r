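# Expression quantification (RPKM), stage-specific up-regulation calls,
# microarray probe reassignment/renormalization, cross-platform correlation
# and GO term enrichment.

#' Reads per kilobase of exon model per million mapped reads
#'
#' @param count Reads mapped to the gene.
#' @param exon_len Exonic length of the gene model in bp.
#' @param total Total uniquely mapped reads of the sample.
#' @return `1e9 * count / (exon_len * total)`; vectorized.
#' @export
compute_rpkm <- function(count, exon_len, total) {
  if (any(total <= 0)) stop("total mapped reads must be positive")
  if (any(exon_len <= 0)) stop("exon length must be positive")
  1e9 * as.numeric(count) / (as.numeric(exon_len) * as.numeric(total))
}

#' RPKM matrix from a per-gene count table
#'
#' Totals (the per-sample RPKM denominators) are the column sums of the
#' count table, so per-gene counts sum exactly to the mapped-read total.
#'
#' @param counts data.frame gene_id, exon_len, count.<sample> columns.
#' @return Matrix gene x sample of RPKM values, with the totals in
#'   attribute `totals`.
#' @export
rpkm_matrix <- function(counts) {
  cols <- grep("^count\\.", names(counts), value = TRUE)
  samples <- sub("^count\\.", "", cols)
  cm <- as.matrix(counts[, cols, drop = FALSE])
  rownames(cm) <- counts$gene_id
  colnames(cm) <- samples
  totals <- colSums(cm)
  totals[totals == 0] <- NA  # degenerate sample: no mapped reads
  out <- sweep(1e9 * cm / counts$exon_len, 2, totals, "/")
  out[is.na(out)] <- 0
  attr(out, "totals") <- totals
  out
}

#' Call stage-specifically up-regulated genes
#'
#' A gene is up-regulated in stage X iff its stage-level RPKM (arithmetic
#' mean over the stage's samples) exceeds `min_rpkm` and is at least
#' `min_fold` times the stage-level RPKM of every other stage.  A zero
#' denominator with positive numerator counts as infinite fold change.  The
#' three stage sets are pairwise disjoint by construction.
#'
#' @param rpkm Matrix gene x sample.
#' @param samples Sample/group table (see [stage_samples()]).
#' @param min_rpkm Expression floor (default 5, strict inequality).
#' @param min_fold Fold-change threshold (default 5).
#' @return Named list of gene-id vectors, one per stage group.
#' @export
call_stage_upregulated <- function(rpkm, samples = stage_samples(),
                                   min_rpkm = 5, min_fold = 5) {
  groups <- unique(samples$group)
  stage <- do.call(cbind, lapply(groups, function(g)
    rowMeans(rpkm[, samples$sample[samples$group == g], drop = FALSE])))
  colnames(stage) <- groups
  out <- lapply(groups, function(g) {
    x <- stage[, g]
    others <- stage[, setdiff(groups, g), drop = FALSE]
    ok <- x > min_rpkm
    for (j in seq_len(ncol(others)))
      ok <- ok & (x >= min_fold * others[, j] |
                    (others[, j] == 0 & x > 0))
    rownames(rpkm)[ok]
  })
  setNames(out, groups)
}

#' Reassign microarray probes to corrected models and renormalize
#'
#' Each probe is assigned to the unique corrected gene whose exon union
#' contains its interval; probes contained in no gene, or in two
#' overlapping genes, are dropped with a log entry.  The renormalized
#' per-gene expression is the median intensity of the member probes, per
#' sample.
#'
#' @param probes data.frame probe_id, scaffold, start, end,
#'   intensity.<sample> columns.
#' @param corrected The corrected [annotation()].
#' @return List with `values` (matrix gene x sample of medians; genes with
#'   no assigned probe are absent) and `assignment` (data.frame probe_id,
#'   gene_id).
#' @export
reassign_and_renormalize <- function(probes, corrected) {
  cols <- grep("^intensity\\.", names(probes), value = TRUE)
  samples <- sub("^intensity\\.", "", cols)
  ex <- corrected$exons
  g <- corrected$genes
  scaf <- g$scaffold[match(ex$gene_id, g$gene_id)]
  assigned <- rep(NA_character_, nrow(probes))
  for (i in seq_len(nrow(probes))) {
    hit <- unique(ex$gene_id[scaf == probes$scaffold[i] &
                               ex$start <= probes$start[i] &
                               ex$end >= probes$end[i]])
    if (length(hit) == 1) assigned[i] <- hit
    else if (length(hit) > 1)
      sr_log("probe %s contained in %d overlapping genes; unassigned",
             probes$probe_id[i], length(hit))
    else
      sr_log("probe %s not contained in any corrected gene; dropped",
             probes$probe_id[i])
  }
  keep <- !is.na(assigned)
  genes <- sort(unique(assigned[keep]))
  values <- matrix(NA_real_, length(genes), length(samples),
                   dimnames = list(genes, samples))
  for (gid in genes) {
    rows <- which(assigned == gid)
    for (s in samples)
      values[gid, s] <- median(probes[rows, paste0("intensity.", s)])
  }
  list(values = values,
       assignment = data.frame(probe_id = probes$probe_id,
                               gene_id = assigned,
                               stringsAsFactors = FALSE))
}

#' Pearson correlation between RNA-seq and microarray expression
#'
#' Computed on the log2 scale; RPKM values are offset by +1 before log2 to
#' handle zeros (microarray intensities are already log2).
#'
#' @param rpkm Named numeric vector of per-gene RPKM values.
#' @param array Named numeric vector of per-gene log2 intensities.
#' @param array_is_log2 Set FALSE if the array values are on the linear
#'   scale (they are then log2(x+1)-transformed too).
#' @return Pearson r over the genes present on both platforms.
#' @export
correlate_platforms <- function(rpkm, array, array_is_log2 = TRUE) {
  shared <- intersect(names(rpkm), names(array))
  if (length(shared) < 3) stop("fewer than 3 genes shared between platforms")
  x <- log2(rpkm[shared] + 1)
  y <- if (array_is_log2) array[shared] else log2(array[shared] + 1)
  cor(x, y)
}

#' GO term enrichment by hypergeometric test with Bonferroni correction
#'
#' For each GO term with at least one gene in the test set, the
#' hypergeometric upper-tail probability of observing at least the seen
#' number of annotated genes is computed; Bonferroni correction multiplies
#' by the number of terms tested, and a term is significantly
#' overrepresented iff the corrected p-value is below `alpha`.
#'
#' @param test_set Character vector of gene ids (must be a subset of the
#'   universe).
#' @param universe Named list mapping gene id to a character vector of GO
#'   terms (the reference set: all annotated genes).
#' @param alpha Corrected significance threshold (default 0.01, strict).
#' @return data.frame term, k, K, n, N, p, p_bonferroni, significant,
#'   ordered by p.
#' @export
go_enrichment <- function(test_set, universe, alpha = 0.01) {
  if (!length(universe)) stop("empty universe")
  if (!all(test_set %in% names(universe)))
    stop("test set contains genes absent from the universe")
  N <- length(universe)
  n <- length(test_set)
  term_genes <- list()
  for (g in names(universe)) for (tm in universe[[g]])
    term_genes[[tm]] <- c(term_genes[[tm]], g)
  tested <- names(term_genes)[vapply(term_genes, function(gs)
    any(gs %in% test_set), TRUE)]
  if (!length(tested))
    return(data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      p_bonferroni = numeric(0), significant = logical(0)))
  res <- do.call(rbind, lapply(tested, function(tm) {
    K <- length(unique(term_genes[[tm]]))
    k <- sum(test_set %in% term_genes[[tm]])
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  }))
  res$p_bonferroni <- pmin(1, res$p * length(tested))
  res$significant <- res$p_bonferroni < alpha
  res[order(res$p, res$term), , drop = FALSE]
}
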