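# Observable evidence derived from the truth set.  Reads are not simulated
# at sequence level: the generator emits alignment-level evidence, matching
# the pipeline's true inputs.
#   coverage  deterministic: depth * expression per exonic base, scaled by
#             isoform fraction over event-specific regions
#   junctions Poisson(junction_read_factor * depth * expression * isoform
#             fraction) non-redundant support per sample
#   counts    deterministic: depth * expression * transcribed_len / 100

#' Simulate alignment-level evidence from a truth set
#'
#' @param truth An `sr_truth` from [generate_truth()].
#' @param config The same [sim_config()].
#' @return List with `junctions` (an `sr_junctions` with per-sample
#'   support), `coverage` (named list of per-sample [coverage_track()]s)
#'   and `counts` (data.frame gene_id, exon_len, count.<sample>).
#' @export
simulate_observables <- function(truth, config) {
  stopifnot(inherits(truth, "sr_truth"))
  with_seed(config$seed + 1L, simulate_observables_impl(truth, config))
}

simulate_observables_impl <- function(truth, cfg) {
  samples <- truth$samples
  scafs <- names(truth$annotation$seqlengths)
  L <- truth$annotation$seqlengths
  cov <- lapply(samples$sample, function(s)
    setNames(lapply(scafs, function(sc) numeric(L[[sc]])), scafs))
  names(cov) <- samples$sample

  jkey <- character(0)
  jrows <- list()
  jsupport <- list()
  reg_junction <- function(scaf, start, end, strand) {
    key <- paste(scaf, start, end, strand, sep = ":")
    if (!key %in% jkey) {
      jkey <<- c(jkey, key)
      jrows[[key]] <<- data.frame(scaffold = scaf, start = start, end = end,
                                  strand = strand, stringsAsFactors = FALSE)
      jsupport[[key]] <<- setNames(rep(0L, nrow(samples)), samples$sample)
    }
    key
  }

  E <- truth$expression
  g_tab <- truth$genes
  counts <- matrix(0L, nrow(g_tab), nrow(samples),
                   dimnames = list(g_tab$gene_id, samples$sample))
  exon_len <- setNames(integer(nrow(g_tab)), g_tab$gene_id)

  for (k in seq_len(nrow(g_tab))) {
    gid <- g_tab$gene_id[k]
    scaf <- g_tab$scaffold[k]
    strand <- g_tab$strand[k]
    ex <- truth$exons[truth$exons$gene_id == gid, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    introns <- if (nrow(ex) > 1)
      data.frame(start = ex$end[-nrow(ex)] + 1L, end = ex$start[-1] - 1L)
    else data.frame(start = integer(0), end = integer(0))
    exon_len[gid] <- sum(ex$end - ex$start + 1L)
    ev <- truth$as_events[truth$as_events$gene_id == gid, , drop = FALSE]
    ev <- if (nrow(ev)) ev[1, ] else NULL
    minor <- cfg$minor_isoform_fraction

    for (si in seq_len(nrow(samples))) {
      s <- samples$sample[si]
      grp <- samples$group[si]
      c0 <- cfg$depth * E[gid, s]
      counts[gid, s] <- as.integer(round(c0 * exon_len[gid] / 100))
      if (c0 <= 0) next
      active <- !is.null(ev) && (is.na(ev$group) || ev$group == grp)
      # exonic coverage
      for (j in seq_len(nrow(ex))) {
        d <- round(c0)
        if (active && ev$type == "cassette" &&
            ex$start[j] == ev$exon_start && ex$end[j] == ev$exon_end)
          d <- round(c0 * (1 - minor))
        if (d > 0)
          cov[[s]][[scaf]][ex$start[j]:ex$end[j]] <-
            cov[[s]][[scaf]][ex$start[j]:ex$end[j]] + d
      }
      # event-specific coverage inside the reference intron
      if (active && ev$type == "ir") {
        d <- round(c0 * minor)
        if (d > 0)
          cov[[s]][[scaf]][ev$intron_start:ev$intron_end] <-
            cov[[s]][[scaf]][ev$intron_start:ev$intron_end] + d
      }
      if (active && ev$type %in% c("alt5", "alt3")) {
        # the intron bases exonified in the minor isoform
        reg <- if (ev$alt_start > ev$intron_start)
          c(ev$intron_start, ev$alt_start - 1L)
        else c(ev$alt_end + 1L, ev$intron_end)
        d <- round(c0 * minor)
        if (d > 0)
          cov[[s]][[scaf]][reg[1]:reg[2]] <-
            cov[[s]][[scaf]][reg[1]:reg[2]] + d
      }
      # junction support
      for (j in seq_len(nrow(introns))) {
        frac <- 1
        if (active) {
          if (ev$type %in% c("ir", "alt5", "alt3") &&
              introns$start[j] == ev$intron_start &&
              introns$end[j] == ev$intron_end) frac <- 1 - minor
          if (ev$type == "cassette" &&
              ((introns$start[j] == ev$intron_start &&
                  introns$end[j] == ev$intron_end) ||
                 (introns$start[j] == ev$intron2_start &&
                    introns$end[j] == ev$intron2_end))) frac <- 1 - minor
        }
        key <- reg_junction(scaf, introns$start[j], introns$end[j], strand)
        jsupport[[key]][s] <- jsupport[[key]][s] +
          rpois(1, cfg$junction_read_factor * c0 * frac)
      }
      if (active && !is.na(ev$alt_start)) {
        key <- reg_junction(scaf, ev$alt_start, ev$alt_end, strand)
        jsupport[[key]][s] <- jsupport[[key]][s] +
          rpois(1, cfg$junction_read_factor * c0 * minor)
      }
    }
  }

  # junction table; anchors drawn once per junction, always >= 8
  if (length(jkey)) {
    jdf <- do.call(rbind, jrows[jkey])
    jdf$min_anchor <- sample(8:40, length(jkey), replace = TRUE)
    supp <- do.call(rbind, jsupport[jkey])
    for (s in samples$sample) jdf[[paste0("support.", s)]] <- supp[, s]
    keep <- rowSums(supp) > 0
    jdf <- jdf[keep, , drop = FALSE]
  } else {
    jdf <- data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      min_anchor = integer(0), stringsAsFactors = FALSE)
    for (s in samples$sample) jdf[[paste0("support.", s)]] <- integer(0)
  }
  js <- junctions(jdf)

  counts_df <- data.frame(gene_id = g_tab$gene_id,
                          exon_len = as.integer(exon_len[g_tab$gene_id]),
                          stringsAsFactors = FALSE)
  for (s in samples$sample) counts_df[[paste0("count.", s)]] <- counts[, s]

  list(
    junctions = js,
    coverage = lapply(setNames(samples$sample, samples$sample), function(s)
      coverage_track(cov[[s]], sample = s)),
    counts = counts_df
  )
}

#' Simulate microarray probes and intensities from a truth set
#'
#' Probes are placed inside the CDS exons of the true gene models; the
#' intensity of a probe in a sample is the log2 true expression of its gene
#' plus Gaussian noise of SD `probe_noise_sd` (exactly log2 truth when the
#' noise SD is 0).  Where the generator planted a gene fusion, the published
#' annotation assigns one model to two true genes; the probe table always
#' carries the *true* gene so renormalization against corrected models can
#' be scored.
#'
#' @param truth An `sr_truth`.
#' @param config The same [sim_config()].
#' @return data.frame probe_id, scaffold, start, end, gene_id (truth),
#'   intensity.<sample>.
#' @export
simulate_microarray <- function(truth, config) {
  stopifnot(inherits(truth, "sr_truth"), config$probe_count_per_gene >= 1)
  with_seed(config$seed + 2L, simulate_microarray_impl(truth, config))
}

simulate_microarray_impl <- function(truth, cfg) {
  samples <- truth$samples
  g_tab <- truth$genes[!truth$genes$is_novel, , drop = FALSE]
  rows <- list()
  for (k in seq_len(nrow(g_tab))) {
    gid <- g_tab$gene_id[k]
    ex <- truth$exons[truth$exons$gene_id == gid, , drop = FALSE]
    # CDS portion of each exon (probes were designed on predicted ORFs)
    ex$start <- pmax(ex$start, g_tab$cds_start[k])
    ex$end <- pmin(ex$end, g_tab$cds_end[k])
    ex <- ex[ex$end >= ex$start, , drop = FALSE]
    lens <- ex$end - ex$start + 1L
    if (cfg$probe_length > min(lens))
      stop(sprintf("probe length %d exceeds smallest exon (%d bp) of gene %s",
                   cfg$probe_length, min(lens), gid))
    for (p in seq_len(cfg$probe_count_per_gene)) {
      j <- ((p - 1L) %% nrow(ex)) + 1L
      off <- sample.int(lens[j] - cfg$probe_length + 1L, 1L) - 1L
      start <- ex$start[j] + off
      row <- data.frame(
        probe_id = sprintf("%s_P%02d", gid, p),
        scaffold = g_tab$scaffold[k],
        start = start, end = start + cfg$probe_length - 1L,
        gene_id = gid, stringsAsFactors = FALSE)
      for (s in samples$sample)
        row[[paste0("intensity.", s)]] <-
          log2(max(truth$expression[gid, s], 2^-20)) +
          rnorm(1, 0, cfg$probe_noise_sd)
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
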