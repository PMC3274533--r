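# Shared fixtures: small simulator configurations and hand-built objects.

# Recovery conditions: uniform expression so that every gene has >= 20x
# effective coverage, minor isoform fraction 0.5, elevated planting rates
# for test power, fixed seed.
recovery_config <- function(...) {
  args <- modifyList(list(
    seed = 11, n_genes = 60, n_scaffolds = 4, scaffold_length = 70000,
    expression_log10_sd = 0, depth = 40, minor_isoform_fraction = 0.5,
    as_rates = c(cassette = 0.08, alt5 = 0.08, alt3 = 0.08, ir = 0.12),
    probe_noise_sd = 0), list(...))
  do.call(sim_config, args)
}

with_n_introns <- function(n, mean_len) {
  set.seed(99)
  splicerefine:::draw_intron_lengths(n, mean_len)
}

# a tiny hand-built 3-gene annotation on two scaffolds (one minus-strand,
# one single-exon, one with UTRs)
tiny_annotation <- function() {
  genes <- data.frame(
    gene_id = c("g1", "g2", "g3"),
    scaffold = c("scf1", "scf1", "scf2"),
    strand = c("+", "-", "+"),
    cds_start = c(151L, 2081L, 101L),
    cds_end = c(680L, 2900L, 400L),
    stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c("g1", "g1", "g2", "g2", "g2", "g3"),
    start = c(101L, 401L, 2001L, 2401L, 2801L, 101L),
    end = c(300L, 700L, 2300L, 2700L, 2950L, 400L),
    stringsAsFactors = FALSE)
  annotation(genes, exons, seqlengths = c(scf1 = 5000L, scf2 = 3000L),
             provenance = "fixture")
}

# coverage track from explicit vectors
cov_of <- function(..., sample = "pooled") {
  coverage_track(list(...), sample = sample)
}

# junction table builder with a single pooled support column by default
jx <- function(scaffold, start, end, strand = "+", min_anchor = 20,
               support = 5, donor = "GT", acceptor = "AG",
               canonical = TRUE) {
  df <- data.frame(scaffold = scaffold, start = start, end = end,
                   strand = strand, min_anchor = min_anchor,
                   donor = donor, acceptor = acceptor,
                   canonical = canonical, stringsAsFactors = FALSE)
  df$support.pooled <- support
  junctions(df)
}

run_sim_pipeline <- function(cfg, probes = FALSE, params = list()) {
  sim <- generate_truth(cfg)
  obs <- simulate_observables(sim$truth, cfg)
  pr <- if (probes) simulate_microarray(sim$truth, cfg) else NULL
  rep <- suppressMessages(run_pipeline(sim$genome, sim$annotation,
                                       obs$junctions, obs$coverage,
                                       obs$counts, probes = pr,
                                       params = params))
  list(sim = sim, obs = obs, probes = pr, report = rep)
}
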