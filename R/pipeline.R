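# End-to-end orchestration: filter -> assemble -> compare -> novel/UTR ->
# AS -> expression -> enrichment, with a summary report mirroring the
# headline tabulations of an annotation-refinement study.

#' Run the full refinement and splicing pipeline
#'
#' @param genome Named character vector of scaffold sequences.
#' @param ann Reference [annotation()] to confirm/correct.
#' @param js Raw junction evidence (`sr_junctions`, per-sample support).
#' @param coverage Named list of per-sample [coverage_track()]s.
#' @param counts Per-gene count table (gene_id, exon_len, count.<sample>).
#' @param probes Optional microarray probe table (see
#'   [simulate_microarray()] for the layout).
#' @param go_map Optional named list gene id -> GO terms for enrichment of
#'   the stage-up-regulated sets.
#' @param samples Sample/group table (default [stage_samples()]).
#' @param params Named list overriding thresholds: min_anchor (8),
#'   min_support_detect (1), min_support_as (2), min_intron (10),
#'   max_intron (10000), min_cov (2), max_gap (25), zero_gap (50),
#'   novel_min_len (300), ir_min_depth (10), min_rpkm (5), min_fold (5),
#'   go_alpha (0.01).
#' @param outdir Optional directory; when given, corrected annotation
#'   (GFF3), model status, novel regions, AS events, IR summary and
#'   expression tables are written there as deterministic text files.
#' @return List of class `sr_report` with elements: status, corrected,
#'   utr_annotation, novel, events, stage_specific_events, rpkm,
#'   upregulated, array (renormalized values or NULL), enrichment,
#'   ir_table, summary (named list of headline numbers).
#' @export
run_pipeline <- function(genome, ann, js, coverage, counts, probes = NULL,
                         go_map = NULL, samples = stage_samples(),
                         params = list(), outdir = NULL) {
  p <- modifyList(list(
    min_anchor = 8, min_support_detect = 1, min_support_as = 2,
    min_intron = 10, max_intron = 10000, min_cov = 2, max_gap = 25,
    zero_gap = 50, novel_min_len = 300, ir_min_depth = 10,
    min_rpkm = 5, min_fold = 5, go_alpha = 0.01), params)

  ## junction universe
  js <- validate_junctions(js, genome)
  js <- filter_junctions(js, min_anchor = p$min_anchor,
                         min_support = p$min_support_detect,
                         min_intron = p$min_intron,
                         max_intron = p$max_intron)

  ## assembly on pooled evidence
  pooled <- pool_coverage(coverage)
  ts <- assemble_transcripts(pooled, js, min_cov = p$min_cov,
                             max_gap = p$max_gap)

  ## model confirmation / correction
  cmp <- compare_to_annotation(ts, ann, pooled, zero_gap = p$zero_gap)
  corrected <- cmp$corrected
  novel <- detect_novel_regions(ts, corrected, genome,
                                min_len = p$novel_min_len)
  utr_ann <- infer_utrs(pooled, corrected, cmp$status)

  ## alternative splicing on the corrected models
  groups <- unique(samples$group)
  cov_groups <- lapply(setNames(groups, groups), function(g)
    pool_coverage(coverage[samples$sample[samples$group == g]], sample = g))
  cov_groups$pooled <- pooled
  events <- list()
  for (i in seq_len(nrow(corrected$genes))) {
    gid <- corrected$genes$gene_id[i]
    gene <- corrected$genes[i, ]
    ge <- corrected$exons[corrected$exons$gene_id == gid, , drop = FALSE]
    gi <- gene_introns(corrected, gid)
    # internal exons of the pre-correction model(s) still count as
    # annotated for cassette events
    orig_ids <- unlist(strsplit(sub("\\.\\d+$", "", gid), "+", fixed = TRUE))
    extra <- do.call(rbind, lapply(orig_ids, function(oid) {
      e <- ann$exons[ann$exons$gene_id == oid, , drop = FALSE]
      if (nrow(e) > 2) e[-c(1, nrow(e)), c("start", "end")] else NULL
    }))
    ev <- enumerate_as_events(gene, ge, gi, js, cov_groups, samples,
                              extra_internal_exons = extra,
                              min_support = p$min_support_as,
                              min_depth = p$ir_min_depth, genome = genome)
    if (nrow(ev)) events[[length(events) + 1L]] <- ev
  }
  events <- if (length(events)) do.call(rbind, events) else empty_events()
  rownames(events) <- NULL
  specific <- stage_specific_as(events)

  ## expression
  rpkm <- rpkm_matrix(counts)
  upreg <- call_stage_upregulated(rpkm, samples, min_rpkm = p$min_rpkm,
                                  min_fold = p$min_fold)
  array <- if (!is.null(probes)) reassign_and_renormalize(probes, corrected)
           else NULL
  enrichment <- if (!is.null(go_map))
    lapply(upreg, function(set)
      go_enrichment(intersect(set, names(go_map)), go_map,
                    alpha = p$go_alpha))
  else NULL

  ir_table <- summarize_ir_table(events, corrected, cov_groups, cmp$status,
                                 samples)

  n_models <- nrow(ann$genes)
  st <- table(factor(cmp$status$status,
                     levels = c("complete_match", "boundary_mismatch",
                                "missing_or_extra_intron", "fused",
                                "split", "undetected")))
  as_genes <- unique(events$gene_id)
  summary <- list(
    n_models = n_models,
    n_transcripts = nrow(ts),
    status_counts = as.list(st),
    pct_detected = as_percent(n_models - st[["undetected"]], n_models),
    pct_confirmed = as_percent(st[["complete_match"]], n_models),
    n_novel = nrow(novel),
    as_counts = as.list(table(factor(events$type,
                                     levels = c("cassette", "alt5", "alt3",
                                                "ir")))),
    n_as_events = nrow(events),
    n_as_genes = length(as_genes),
    pct_as_genes = as_percent(length(as_genes), n_models),
    n_stage_specific_events = nrow(specific),
    n_upregulated = lapply(upreg, length)
  )

  rep <- structure(list(
    status = cmp$status, corrected = corrected, utr_annotation = utr_ann,
    transcripts = ts, novel = novel, events = events,
    stage_specific_events = specific, rpkm = rpkm, upregulated = upreg,
    array = array, enrichment = enrichment, ir_table = ir_table,
    summary = summary, params = p), class = "sr_report")
  if (!is.null(outdir)) write_report(rep, outdir)
  rep
}

#' @export
print.sr_report <- function(x, ...) {
  s <- x$summary
  cat("<sr_report>\n")
  cat(sprintf("  models: %d (%.1f%% detected, %.1f%% completely confirmed)\n",
              s$n_models, s$pct_detected, s$pct_confirmed))
  cat(sprintf("  transcripts assembled: %d; novel transcribed regions: %d\n",
              s$n_transcripts, s$n_novel))
  cat(sprintf(
    "  AS events: %d (cassette %d, alt5 %d, alt3 %d, IR %d) over %d genes (%.1f%%)\n",
    s$n_as_events, s$as_counts$cassette, s$as_counts$alt5,
    s$as_counts$alt3, s$as_counts$ir, s$n_as_genes, s$pct_as_genes))
  cat(sprintf("  stage-specific AS events: %d\n", s$n_stage_specific_events))
  cat(sprintf("  up-regulated genes: growth %d, starvation %d, conjugation %d\n",
              s$n_upregulated$growth, s$n_upregulated$starvation,
              s$n_upregulated$conjugation))
  invisible(x)
}

#' Intron-retention distribution and specificity table
#'
#' Restricted to genes with at least two introns whose models were
#' completely confirmed (complete_match).  Rows are binned by intron count
#' (2..8, >8) with gene counts, IR gene counts, counts by number of introns
#' retained (all / exactly one / 2..n-1), and the mean most-retained-intron
#' frequency per stage-group pair (growth & starvation vs conjugation); the
#' total row carries IR-gene-count-weighted averages.  The per-intron
#' retention read count is the minimum per-base depth over the intron, a
#' conservative proxy for reads indicating retention.
#'
#' @param events AS event table from [enumerate_as_events()].
#' @param ann Corrected [annotation()].
#' @param cov_groups Named list of stage-group coverage tracks.
#' @param status Model status table.
#' @param samples Sample/group table.
#' @return data.frame, one row per intron-count bin plus a Total row.
#' @export
summarize_ir_table <- function(events, ann, cov_groups, status,
                               samples = stage_samples()) {
  confirmed <- status$gene_id[status$status == "complete_match"]
  nint <- vapply(confirmed, function(g) nrow(gene_introns(ann, g)), 0L)
  confirmed <- confirmed[nint >= 2]
  nint <- nint[nint >= 2]
  bins <- c(as.character(2:8), ">8")
  bin_of <- function(n) if (n > 8) ">8" else as.character(n)
  ir_ev <- events[events$type == "ir", , drop = FALSE]

  gs_cov <- pool_coverage(cov_groups[c("growth", "starvation")],
                          sample = "growth_starvation")
  conj_cov <- cov_groups$conjugation

  rows <- lapply(bins, function(b) {
    gs_genes <- confirmed[vapply(nint, bin_of, "") == b]
    irg <- intersect(gs_genes, ir_ev$gene_id)
    n_ret <- vapply(irg, function(g)
      sum(ir_ev$gene_id == g), 0L)
    ni <- nint[match(irg, confirmed)]
    freq_of <- function(g, cv) {
      gi <- gene_introns(ann, g)
      scaf <- ann$genes$scaffold[ann$genes$gene_id == g]
      cnt <- vapply(seq_len(nrow(gi)), function(j)
        min(coverage_query(cv, scaf, gi$start[j], gi$end[j])), 0)
      if (sum(cnt) <= 0) NA_real_ else ir_specificity(cnt)
    }
    f_gs <- vapply(irg, freq_of, 0, cv = gs_cov)
    f_cj <- vapply(irg, freq_of, 0, cv = conj_cov)
    data.frame(
      introns = b,
      n_genes = length(gs_genes),
      n_ir_genes = length(irg),
      all_retained = sum(n_ret == ni),
      one_retained = sum(n_ret == 1),
      multi_retained = sum(n_ret > 1 & n_ret < ni),
      freq_growth_starvation =
        if (any(!is.na(f_gs))) round(mean(f_gs, na.rm = TRUE), 2) else NA,
      freq_conjugation =
        if (any(!is.na(f_cj))) round(mean(f_cj, na.rm = TRUE), 2) else NA,
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  w <- tab$n_ir_genes
  tot <- data.frame(
    introns = "Total",
    n_genes = sum(tab$n_genes), n_ir_genes = sum(w),
    all_retained = sum(tab$all_retained),
    one_retained = sum(tab$one_retained),
    multi_retained = sum(tab$multi_retained),
    freq_growth_starvation = if (any(w > 0 & !is.na(tab$freq_growth_starvation)))
      ir_weighted_average(w[w > 0 & !is.na(tab$freq_growth_starvation)],
                          tab$freq_growth_starvation[w > 0 & !is.na(tab$freq_growth_starvation)])
      else NA,
    freq_conjugation = if (any(w > 0 & !is.na(tab$freq_conjugation)))
      ir_weighted_average(w[w > 0 & !is.na(tab$freq_conjugation)],
                          tab$freq_conjugation[w > 0 & !is.na(tab$freq_conjugation)])
      else NA,
    stringsAsFactors = FALSE)
  rbind(tab, tot)
}

write_report <- function(rep, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name)
    write.table(df, file.path(outdir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  wt(rep$status, "model_status.tsv")
  wt(rep$novel, "novel_regions.tsv")
  wt(rep$events, "as_events.tsv")
  wt(rep$ir_table, "ir_summary.tsv")
  wt(data.frame(gene_id = rownames(rep$rpkm),
                as.data.frame(rep$rpkm, check.names = FALSE)),
     "rpkm.tsv")
  write_annotation(rep$utr_annotation,
                   file.path(outdir, "corrected_annotation.gff3"))
  up <- rep$upregulated
  wt(data.frame(group = rep(names(up), lengths(up)),
                gene_id = unlist(up, use.names = FALSE)),
     "stage_upregulated.tsv")
  summ <- rep$summary
  flat <- unlist(summ)
  wt(data.frame(key = names(flat), value = unname(flat)), "summary.tsv")
  invisible(outdir)
}
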