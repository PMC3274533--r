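# Synthetic-data generator configuration.
#
# Defaults emulate the statistical structure of the Tetrahymena thermophila
# macronuclear transcriptome: highly A+T-rich noncoding sequence (0.87, within
# the 85-90% range), moderately A+T-rich coding sequence, short introns (mean
# 135 bp within hard bounds [10, 10000]), multi-intron gene models, the four
# AS classes planted at rates proportional to the observed event counts
# (cassette 139 : alt5 258 : alt3 245 : IR 832 over 24,725 genes, IR
# dominant), and stage-dependent expression over the five samples
# G-m / S-3 / S-15 / C-2 / C-8 grouped into growth, starvation, conjugation.

#' Sample-to-stage-group table
#'
#' The five profiled samples and their life-cycle stage groups: growth
#' (G-m), starvation (S-3, S-15) and conjugation (C-2, C-8).
#'
#' @return data.frame with columns sample, group.
#' @export
stage_samples <- function() {
  data.frame(
    sample = c("G_m", "S_3", "S_15", "C_2", "C_8"),
    group = c("growth", "starvation", "starvation",
              "conjugation", "conjugation"),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic transcriptome generator
#'
#' @param seed Integer RNG seed; identical configurations (including seed)
#'   give identical outputs.
#' @param n_scaffolds,scaffold_length Toy genome dimensions.
#' @param n_genes Number of protein-coding gene models.
#' @param exons_per_gene Integer range (lo, hi) of exons per gene.
#' @param intron_mean Mean intron length in bp; introns are drawn as
#'   10 + Gamma(shape = 2) and redrawn above 10000, so all lengths lie in
#'   the alignment bounds [10, 10000].
#' @param at_noncoding,at_coding A+T fraction of noncoding (intergenic,
#'   intron, UTR) and coding sequence.
#' @param exon_len_range Range of coding-exon lengths (bp).
#' @param utr5_mean,utr3_mean Mean UTR lengths (bp, exponential, capped at
#'   290 so UTRs stay below the 300 bp novel-region threshold).
#' @param as_rates Named per-type planting probabilities
#'   (cassette, alt5, alt3, ir); at most one event is planted per gene.
#' @param minor_isoform_fraction Fraction of a gene's transcripts using the
#'   planted alternative form.
#' @param as_stage_specific_fraction Fraction of planted AS events restricted
#'   to a single stage group.
#' @param as_stage_probs Stage-group probabilities for restricted events
#'   (conjugation-skewed, as observed).
#' @param stage_up_fraction Fraction of genes specifically up-regulated in
#'   one stage group.
#' @param stage_up_probs Stage-group probabilities for up-regulated genes.
#' @param stage_up_fold Expression fold applied in the up-regulated group.
#' @param stage_profiles Named per-sample global expression multipliers.
#' @param expression_log10_sd SD of per-gene log10 base expression (1.0
#'   spans roughly six orders of magnitude across genes at +/- 3 SD).
#' @param depth Mean per-base exon coverage of a gene at relative
#'   expression 1.
#' @param junction_read_factor Junction read support is
#'   Poisson(junction_read_factor * depth * expression * isoform fraction).
#' @param novel_fraction Novel transcribed regions per coding gene.
#' @param novel_short_fraction Fraction of additional planted intergenic
#'   transcripts shorter than 300 bp (below the reporting threshold).
#' @param misannotation_rates Named rates of planted annotation errors:
#'   fuse (two true genes under one model), split (one true gene under two
#'   models), boundary (one intron boundary shifted 3 bp), missing_intron
#'   (two exons merged).
#' @param probe_count_per_gene,probe_length Microarray probes per gene and
#'   probe length (bp).
#' @param probe_noise_sd SD of log2-scale multiplicative probe noise.
#' @param intergenic_min Minimum intergenic spacer (bp) between transcribed
#'   units; kept >= 600 so novel-region and gene-fusion calls are
#'   unambiguous.
#' @return A validated list of class `sr_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_scaffolds = 2L,
                       scaffold_length = 60000L,
                       n_genes = 30L,
                       exons_per_gene = c(2L, 7L),
                       intron_mean = 135,
                       at_noncoding = 0.87,
                       at_coding = 0.75,
                       exon_len_range = c(60L, 300L),
                       utr5_mean = 80,
                       utr3_mean = 160,
                       as_rates = c(cassette = 0.0056, alt5 = 0.0104,
                                    alt3 = 0.0099, ir = 0.0337),
                       minor_isoform_fraction = 0.5,
                       as_stage_specific_fraction = 0.13,
                       as_stage_probs = c(growth = 0.15, starvation = 0.15,
                                          conjugation = 0.70),
                       stage_up_fraction = 0.12,
                       stage_up_probs = c(growth = 0.32, starvation = 0.07,
                                          conjugation = 0.61),
                       stage_up_fold = 25,
                       stage_profiles = c(G_m = 1, S_3 = 1, S_15 = 1,
                                          C_2 = 1, C_8 = 1),
                       expression_log10_sd = 1.0,
                       depth = 40,
                       junction_read_factor = 0.5,
                       novel_fraction = 0.05,
                       novel_short_fraction = 0.2,
                       misannotation_rates = c(fuse = 0.04, split = 0.04,
                                               boundary = 0.04,
                                               missing_intron = 0.04),
                       probe_count_per_gene = 5L,
                       probe_length = 50L,
                       probe_noise_sd = 0.1,
                       intergenic_min = 600L) {
  cfg <- as.list(environment())
  props <- c(cfg$at_noncoding, cfg$at_coding, cfg$as_rates,
             cfg$minor_isoform_fraction, cfg$as_stage_specific_fraction,
             cfg$stage_up_fraction, cfg$novel_fraction,
             cfg$novel_short_fraction, cfg$misannotation_rates)
  if (any(props < 0 | props > 1))
    stop("all proportions must lie in [0, 1]")
  if (cfg$intron_mean < 10 || cfg$intron_mean > 10000)
    stop("intron_mean must lie within the intron bounds [10, 10000]")
  stopifnot(length(exons_per_gene) == 2, exons_per_gene[1] >= 1,
            exons_per_gene[2] >= exons_per_gene[1],
            all(sort(names(as_rates)) ==
                  c("alt3", "alt5", "cassette", "ir")),
            depth >= 0, probe_count_per_gene >= 1,
            setequal(names(stage_profiles), stage_samples()$sample))
  cfg$stage_profiles <- stage_profiles[stage_samples()$sample]
  structure(cfg, class = "sr_sim_config")
}
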