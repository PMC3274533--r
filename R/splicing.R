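# Alternative-splicing detection under stringent evidence criteria:
# every junction involved must carry >= 2 non-redundant reads; intron
# retention additionally requires >= 10x coverage at every retained base
# plus spliced-junction evidence of the excised form.
#
# Event geometry (strand-aware; donor = 5' splice site of the intron):
#   alt5      two junctions sharing the acceptor, differing donors
#   alt3      two junctions sharing the donor, differing acceptors
#   cassette  a skipping junction from intron i's donor to intron i+1's
#             acceptor coexisting with both inclusion junctions; the skipped
#             exon must be an annotated internal exon
#   ir        an annotated intron with full-depth retention coverage and
#             spliced support (both isoforms evidenced)

donor_site <- function(js) ifelse(js$strand == "-", js$end, js$start)
acceptor_site <- function(js) ifelse(js$strand == "-", js$start, js$end)

#' Detect intron retention for one intron
#'
#' @param intron List or one-row data.frame with start, end.
#' @param cov A [coverage_track()] (sample, stage-group or pooled).
#' @param scaffold Scaffold of the intron.
#' @param spliced_support Non-redundant support of the spliced junction for
#'   this intron.
#' @param min_depth Minimum per-base depth over every retained position
#'   (default 10).
#' @param min_spliced Minimum spliced-junction support (default 2): without
#'   evidence of the excised form a fully covered intron is
#'   indistinguishable from a mispredicted intron.
#' @return `TRUE` iff the intron qualifies as retained.
#' @export
detect_intron_retention <- function(intron, cov, scaffold, spliced_support,
                                    min_depth = 10, min_spliced = 2) {
  if (spliced_support < min_spliced) return(FALSE)
  depth <- coverage_query(cov, scaffold, intron$start, intron$end)
  all(depth >= min_depth)
}

#' Enumerate alternative-splicing events for one gene
#'
#' Junctions are assigned to the gene by span containment (junctions
#' crossing the gene boundary are ignored with a log entry).  Events are
#' detected from the pooled evidence and additionally flagged per stage
#' group (growth / starvation / conjugation) by re-applying the full
#' criteria within each group.
#'
#' @param gene One row of an annotation's `genes` table.
#' @param gene_exons,gene_introns Exon and intron tables of the gene
#'   (genomic order) from the corrected annotation.
#' @param js Validated, filtered junction set (the detection universe; the
#'   support >= 2 rule is applied internally per event).
#' @param cov_groups Named list of stage-group [coverage_track()]s.
#' @param samples Sample/group table (see [stage_samples()]).
#' @param extra_internal_exons Optional data.frame (start, end) of
#'   additional annotated internal exons accepted for cassette events (e.g.
#'   from the pre-correction annotation, so that a skipped exon dropped
#'   during model correction still counts as annotated).
#' @param min_support Per-junction non-redundant read threshold (default 2).
#' @param min_depth Per-base retention depth threshold (default 10).
#' @param genome Optional genome (named character vector) for PTC scanning;
#'   if omitted the ptc flag is NA.
#' @return data.frame of events: gene_id, type, coordinates, per-group
#'   detected flags, mean_as_intron_length, ptc.
#' @export
enumerate_as_events <- function(gene, gene_exons, gene_introns, js,
                                cov_groups, samples,
                                extra_internal_exons = NULL,
                                min_support = 2, min_depth = 10,
                                genome = NULL) {
  span <- c(min(gene_exons$start), max(gene_exons$end))
  in_gene <- js$scaffold == gene$scaffold &
    js$start >= span[1] & js$end <= span[2] &
    (js$strand == gene$strand | js$strand == ".")
  crossing <- js$scaffold == gene$scaffold &
    iv_overlaps(js$start, js$end, span[1], span[2]) & !in_gene
  if (any(crossing))
    sr_log("gene %s: ignoring %d junction(s) crossing the gene boundary",
           gene$gene_id, sum(crossing))
  jg <- js[in_gene, , drop = FALSE]
  groups <- unique(samples$group)
  grp_support <- function(j)
    vapply(groups, function(g)
      junction_support(jg, samples$sample[samples$group == g])[j], 0L)
  total <- junction_support(jg)
  pooled_cov <- cov_groups$pooled
  if (is.null(pooled_cov)) pooled_cov <- pool_coverage(cov_groups)

  events <- list()
  add_event <- function(type, introns, alt, exon, flags, mean_len, ptc) {
    events[[length(events) + 1L]] <<- data.frame(
      gene_id = gene$gene_id, type = type,
      intron_start = introns[[1]][1], intron_end = introns[[1]][2],
      intron2_start = if (length(introns) > 1) introns[[2]][1] else NA_integer_,
      intron2_end = if (length(introns) > 1) introns[[2]][2] else NA_integer_,
      alt_start = alt[1], alt_end = alt[2],
      exon_start = exon[1], exon_end = exon[2],
      growth = flags[["growth"]], starvation = flags[["starvation"]],
      conjugation = flags[["conjugation"]],
      mean_as_intron_length = mean_len, ptc = ptc,
      stringsAsFactors = FALSE)
  }
  jl <- function(j) jg$end[j] - jg$start[j] + 1L

  ## ---- cassette: triples (x, y, skip) -------------------------------
  used_pairs <- character(0)
  internal <- gene_exons[-c(1, nrow(gene_exons)), , drop = FALSE]
  if (!is.null(extra_internal_exons) && nrow(extra_internal_exons))
    internal <- rbind(internal[, c("start", "end")],
                      extra_internal_exons[, c("start", "end")])
  n <- nrow(jg)
  if (n >= 3) for (x in seq_len(n)) for (y in seq_len(n)) {
    if (x == y || jg$end[x] + 1L >= jg$start[y]) next
    z <- which(jg$start == jg$start[x] & jg$end == jg$end[y])
    if (!length(z)) next
    z <- z[1]
    exon <- c(jg$end[x] + 1L, jg$start[y] - 1L)
    if (!any(internal$start == exon[1] & internal$end == exon[2])) next
    if (min(total[c(x, y, z)]) < min_support) next
    gs <- rbind(grp_support(x), grp_support(y), grp_support(z))
    flags <- setNames(apply(gs >= min_support, 2, all), groups)
    ptc <- cassette_ptc(gene, gene_exons, exon, genome)
    add_event("cassette", list(c(jg$start[x], jg$end[x]),
                               c(jg$start[y], jg$end[y])),
              c(jg$start[z], jg$end[z]), exon, flags,
              round(mean(c(jl(x), jl(y), jl(z))), 2), ptc)
    used_pairs <- c(used_pairs,
                    paste(x, z), paste(z, x), paste(y, z), paste(z, y))
  }

  ## ---- alt5 / alt3: junction pairs sharing one site ------------------
  if (n >= 2) for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    if (paste(a, b) %in% used_pairs || paste(b, a) %in% used_pairs) next
    if (min(total[c(a, b)]) < min_support) next
    da <- donor_site(jg)[a]; db <- donor_site(jg)[b]
    aa <- acceptor_site(jg)[a]; ab <- acceptor_site(jg)[b]
    type <- if (aa == ab && da != db) "alt5"
            else if (da == db && aa != ab) "alt3"
            else next
    gs <- rbind(grp_support(a), grp_support(b))
    flags <- setNames(apply(gs >= min_support, 2, all), groups)
    # reference = the junction matching an annotated intron, if either does
    ref <- a; alt <- b
    is_ann <- function(j) any(gene_introns$start == jg$start[j] &
                                gene_introns$end == jg$end[j])
    if (!is_ann(a) && is_ann(b)) { ref <- b; alt <- a }
    ptc <- altss_ptc(gene, gene_exons,
                     c(jg$start[ref], jg$end[ref]),
                     c(jg$start[alt], jg$end[alt]), genome)
    add_event(type, list(c(jg$start[ref], jg$end[ref])),
              c(jg$start[alt], jg$end[alt]), c(NA_integer_, NA_integer_),
              flags, round(mean(c(jl(a), jl(b))), 2), ptc)
  }

  ## ---- intron retention ---------------------------------------------
  if (nrow(gene_introns)) for (j in seq_len(nrow(gene_introns))) {
    iv <- list(start = gene_introns$start[j], end = gene_introns$end[j])
    jm <- which(jg$start == iv$start & jg$end == iv$end)
    sup_pool <- if (length(jm)) total[jm[1]] else 0L
    if (!detect_intron_retention(iv, pooled_cov, gene$scaffold, sup_pool,
                                 min_depth = min_depth,
                                 min_spliced = min_support)) next
    flags <- setNames(vapply(groups, function(grp) {
      sup <- if (length(jm))
        junction_support(jg, samples$sample[samples$group == grp])[jm[1]]
      else 0L
      detect_intron_retention(iv, cov_groups[[grp]], gene$scaffold, sup,
                              min_depth = min_depth,
                              min_spliced = min_support)
    }, TRUE), groups)
    ptc <- ir_ptc(gene, gene_exons, c(iv$start, iv$end), genome)
    add_event("ir", list(c(iv$start, iv$end)), c(NA_integer_, NA_integer_),
              c(NA_integer_, NA_integer_), flags,
              as.numeric(iv$end - iv$start + 1L), ptc)
  }

  if (!length(events)) return(empty_events())
  out <- do.call(rbind, events)
  out[order(out$type, out$intron_start), , drop = FALSE]
}

empty_events <- function() {
  data.frame(gene_id = character(0), type = character(0),
             intron_start = integer(0), intron_end = integer(0),
             intron2_start = integer(0), intron2_end = integer(0),
             alt_start = integer(0), alt_end = integer(0),
             exon_start = integer(0), exon_end = integer(0),
             growth = logical(0), starvation = logical(0),
             conjugation = logical(0),
             mean_as_intron_length = numeric(0), ptc = logical(0),
             stringsAsFactors = FALSE)
}

#' Mean AS intron length of an event
#'
#' The average of the two intron lengths for alternative 5'/3' splice-site
#' events, of the three intron lengths (two inclusion + one skip) for
#' cassette events, and simply the intron length for intron retention.
#'
#' @param event One event row from [enumerate_as_events()].
#' @return Mean length in bp.
#' @export
as_intron_mean_length <- function(event) {
  l1 <- event$intron_end - event$intron_start + 1L
  if (event$type == "ir") return(as.numeric(l1))
  la <- event$alt_end - event$alt_start + 1L
  if (event$type %in% c("alt5", "alt3"))
    return(round(mean(c(l1, la)), 2))
  l2 <- event$intron2_end - event$intron2_start + 1L
  round(mean(c(l1, l2, la)), 2)
}

#' Intron-retention specificity of a gene
#'
#' The number of reads indicating retention of the most commonly retained
#' intron divided by the number of reads indicating retention of any
#' intron.  Ties are broken by the 5'-most intron (reported; the value is
#' unaffected).
#'
#' @param counts Numeric vector of per-intron retention read counts.
#' @return Proportion in (0, 1]; errors if the total is zero.
#' @export
ir_specificity <- function(counts) {
  if (sum(counts) <= 0) stop("undefined: no retention reads")
  max(counts) / sum(counts)
}

#' Weighted average of per-category IR specificities
#'
#' @param counts Per-category gene counts.
#' @param freqs Per-category most-retained-intron frequencies.
#' @param digits Rounding for reporting (default 2).
#' @return sum(counts * freqs) / sum(counts), rounded.
#' @export
ir_weighted_average <- function(counts, freqs, digits = 2) {
  if (length(counts) != length(freqs))
    stop("counts and freqs must have equal length")
  stopifnot(all(counts > 0))
  round(sum(counts * freqs) / sum(counts), digits)
}

#' Stage-specific AS events
#'
#' Events whose full stringent criteria are met in exactly one of the three
#' stage groups.
#'
#' @param events Event data.frame from [enumerate_as_events()].
#' @return The stage-specific subset, with a `specific_group` column.
#' @export
stage_specific_as <- function(events) {
  flags <- as.matrix(events[, c("growth", "starvation", "conjugation")])
  k <- rowSums(flags)
  out <- events[k == 1, , drop = FALSE]
  if (nrow(out)) {
    f <- as.matrix(out[, c("growth", "starvation", "conjugation")])
    out$specific_group <- colnames(f)[apply(f, 1, which)]
  } else out$specific_group <- character(0)
  out
}

## ---- PTC scanning for each isoform type --------------------------------

# spliced transcript sequence of an exon chain, plus the isoform positions
# of the CDS start and annotated stop
spliced_seq <- function(gene, exons, genome) {
  exons <- exons[order(exons$start), , drop = FALSE]
  segs <- vapply(seq_len(nrow(exons)), function(j)
    genome_seq(genome, gene$scaffold, exons$start[j], exons$end[j]), "")
  if (gene$strand == "-") {
    segs <- rev(vapply(segs, revcomp, ""))
  }
  paste(segs, collapse = "")
}

# genomic position -> position in the spliced isoform (NA if intronic)
g2iso <- function(gene, exons, gpos) {
  exons <- exons[order(exons$start), , drop = FALSE]
  if (gene$strand == "-") {
    exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
  }
  off <- 0L
  for (j in seq_len(nrow(exons))) {
    s <- exons$start[j]; e <- exons$end[j]
    if (gpos >= s && gpos <= e) {
      within <- if (gene$strand == "-") e - gpos else gpos - s
      return(off + within + 1L)
    }
    off <- off + (e - s + 1L)
  }
  NA_integer_
}

iso_ptc <- function(gene, iso_exons, genome) {
  if (is.null(genome) || is.na(gene$cds_start)) return(NA)
  seq <- spliced_seq(gene, iso_exons, genome)
  cds_first <- if (gene$strand == "+") gene$cds_start else gene$cds_end
  stop_first <- if (gene$strand == "+") gene$cds_end - 2L else gene$cds_start + 2L
  cs <- g2iso(gene, iso_exons, cds_first)
  st <- g2iso(gene, iso_exons, stop_first)
  if (is.na(cs) || cs + 2 > nchar(seq)) return(NA)
  scan_ptc(seq, cs, st)
}

# subtract an interval from an exon chain (exon skipping / intron extension)
exons_minus <- function(exons, iv) {
  rows <- list()
  for (j in seq_len(nrow(exons))) {
    s <- exons$start[j]; e <- exons$end[j]
    if (e < iv[1] || s > iv[2]) {
      rows[[length(rows) + 1L]] <- data.frame(start = s, end = e)
    } else {
      if (s < iv[1]) rows[[length(rows) + 1L]] <-
          data.frame(start = s, end = iv[1] - 1L)
      if (e > iv[2]) rows[[length(rows) + 1L]] <-
          data.frame(start = iv[2] + 1L, end = e)
    }
  }
  do.call(rbind, rows)
}

ir_ptc <- function(gene, gene_exons, intron, genome) {
  if (is.null(genome)) return(NA)
  # retained isoform: merge the two exons flanking the intron
  ex <- gene_exons[order(gene_exons$start), c("start", "end"), drop = FALSE]
  j <- which(ex$end == intron[1] - 1L)
  if (!length(j)) return(NA)
  ex$end[j] <- ex$end[j + 1L]
  ex <- ex[-(j + 1L), , drop = FALSE]
  iso_ptc(gene, ex, genome)
}

altss_ptc <- function(gene, gene_exons, ref_intron, alt_intron, genome) {
  if (is.null(genome)) return(NA)
  ex <- gene_exons[order(gene_exons$start), c("start", "end"), drop = FALSE]
  # isoform exons: fill the reference intron back in, then cut the
  # alternative intron out
  j <- which(ex$end == ref_intron[1] - 1L)
  if (length(j)) {
    ex$end[j] <- ex$end[j + 1L]
    ex <- ex[-(j + 1L), , drop = FALSE]
  }
  ex <- exons_minus(ex, alt_intron)
  iso_ptc(gene, ex, genome)
}

cassette_ptc <- function(gene, gene_exons, exon, genome) {
  if (is.null(genome)) return(NA)
  ex <- gene_exons[order(gene_exons$start), c("start", "end"), drop = FALSE]
  ex <- exons_minus(ex, exon)
  iso_ptc(gene, ex, genome)
}
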