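test_that("no planting means no events; truth events reference real introns", {
  cfg0 <- recovery_config(as_rates = c(cassette = 0, alt5 = 0, alt3 = 0,
                                       ir = 0))
  sim0 <- generate_truth(cfg0)
  expect_identical(nrow(sim0$truth$as_events), 0L)

  cfg <- recovery_config(seed = 21)
  sim <- generate_truth(cfg)
  ev <- sim$truth$as_events
  expect_gt(nrow(ev), 0)
  for (i in seq_len(nrow(ev))) {
    gi <- gene_introns(sim$truth$annotation, ev$gene_id[i])
    expect_true(any(gi$start == ev$intron_start[i] &
                      gi$end == ev$intron_end[i]))
  }
})

test_that("intergenic A+T fraction and intron lengths match the configuration", {
  cfg <- sim_config(seed = 4, n_genes = 60, n_scaffolds = 4,
                    scaffold_length = 80000)
  sim <- generate_truth(cfg)
  sp <- gene_spans(sim$truth$annotation)
  inter <- character(0)
  for (sc in names(sim$genome)) {
    mask <- rep(TRUE, nchar(sim$genome[[sc]]))
    s2 <- sp[sp$scaffold == sc, , drop = FALSE]
    for (i in seq_len(nrow(s2))) mask[s2$start[i]:s2$end[i]] <- FALSE
    inter <- c(inter, strsplit(sim$genome[[sc]], "")[[1]][mask])
  }
  expect_gt(length(inter), 100000)
  expect_lt(abs(mean(inter %in% c("A", "T")) - 0.87), 0.02)

  # intron length distribution: sample mean within +/- 10 bp of 135
  lens <- with_n_introns(1000, cfg$intron_mean)
  expect_true(all(lens >= 10 & lens <= 10000))
  expect_lt(abs(mean(lens) - 135), 10)
})

test_that("generation is deterministic: same config gives identical output", {
  cfg <- recovery_config(seed = 13)
  a <- generate_truth(cfg)
  b <- generate_truth(cfg)
  expect_identical(a, b)
  obs_a <- simulate_observables(a$truth, cfg)
  obs_b <- simulate_observables(b$truth, cfg)
  expect_identical(obs_a, obs_b)
  expect_identical(simulate_microarray(a$truth, cfg),
                   simulate_microarray(b$truth, cfg))
  # and files written from them are byte-identical
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_coverage(obs_a$coverage$G_m, f1)
  write_coverage(obs_b$coverage$G_m, f2)
  expect_identical(readLines(f1), readLines(f2))
  d <- generate_truth(recovery_config(seed = 14))
  expect_false(identical(a$genome, d$genome))
})

test_that("every intron begins GT and ends AG in transcript orientation", {
  cfg <- recovery_config(seed = 23)
  sim <- generate_truth(cfg)
  ann <- sim$truth$annotation
  for (gid in ann$genes$gene_id) {
    gi <- gene_introns(ann, gid)
    if (!nrow(gi)) next
    g <- ann$genes[ann$genes$gene_id == gid, ]
    for (j in seq_len(nrow(gi))) {
      s <- splicerefine:::genome_seq(sim$genome, g$scaffold, gi$start[j],
                                     gi$end[j], g$strand)
      expect_identical(substr(s, 1, 2), "GT")
      expect_identical(substr(s, nchar(s) - 1, nchar(s)), "AG")
    }
  }
})

test_that("CDS begins ATG and ends TGA with no internal in-frame stop", {
  cfg <- recovery_config(seed = 24)
  sim <- generate_truth(cfg)
  ann <- sim$truth$annotation
  g <- ann$genes[!startsWith(ann$genes$gene_id, "NOVEL"), , drop = FALSE]
  for (i in seq_len(min(nrow(g), 20))) {
    gid <- g$gene_id[i]
    ex <- ann$exons[ann$exons$gene_id == gid, , drop = FALSE]
    ex$start <- pmax(ex$start, g$cds_start[i])
    ex$end <- pmin(ex$end, g$cds_end[i])
    ex <- ex[ex$end >= ex$start, , drop = FALSE]
    cds <- splicerefine:::spliced_seq(g[i, ], ex, sim$genome)
    expect_identical(substr(cds, 1, 3), "ATG")
    expect_identical(substr(cds, nchar(cds) - 2, nchar(cds)), "TGA")
    aa <- translate_ciliate(cds)
    expect_identical(which(aa == "*"), length(aa))
  }
})

test_that("zero depth gives empty evidence; zero expression gives zero counts", {
  cfg <- recovery_config(depth = 0)
  sim <- generate_truth(cfg)
  obs <- simulate_observables(sim$truth, cfg)
  expect_identical(nrow(obs$junctions), 0L)
  expect_true(all(vapply(obs$coverage, function(cv)
    sum(vapply(cv, sum, 0)), 0) == 0))
  expect_true(all(as.matrix(obs$counts[, -(1:2)]) == 0))

  cfg2 <- recovery_config(stage_profiles = c(G_m = 0, S_3 = 1, S_15 = 1,
                                             C_2 = 1, C_8 = 1))
  sim2 <- generate_truth(cfg2)
  obs2 <- simulate_observables(sim2$truth, cfg2)
  expect_true(all(obs2$counts$count.G_m == 0))
  expect_true(any(obs2$counts$count.C_2 > 0))
})

test_that("planted retained introns reach full 10x coverage at depth 20, minor 0.5", {
  cfg <- recovery_config(seed = 31, depth = 20, minor_isoform_fraction = 0.5,
                         as_rates = c(cassette = 0, alt5 = 0, alt3 = 0,
                                      ir = 0.5),
                         as_stage_specific_fraction = 0)
  sim <- generate_truth(cfg)
  obs <- simulate_observables(sim$truth, cfg)
  ir <- sim$truth$as_events[sim$truth$as_events$type == "ir", ]
  expect_gt(nrow(ir), 3)
  pooled_one <- obs$coverage$G_m  # single sample: depth*minor = 10 exactly
  for (i in seq_len(nrow(ir))) {
    g <- sim$truth$genes[sim$truth$genes$gene_id == ir$gene_id[i], ]
    d <- coverage_query(pooled_one, g$scaffold, ir$intron_start[i],
                        ir$intron_end[i])
    expect_true(all(d >= 10))
  }
})

test_that("noiseless probes equal log2 truth; placement errors are caught", {
  cfg <- recovery_config(seed = 41, probe_noise_sd = 0)
  sim <- generate_truth(cfg)
  pr <- simulate_microarray(sim$truth, cfg)
  for (s in stage_samples()$sample) {
    expect_equal(pr[[paste0("intensity.", s)]],
                 unname(log2(sim$truth$expression[pr$gene_id, s])))
  }
  # probe -> gene map references genes that exist
  expect_true(all(pr$gene_id %in% sim$truth$genes$gene_id))
  cfg_bad <- recovery_config(probe_length = 500L)
  sim_bad <- generate_truth(recovery_config())
  expect_error(simulate_microarray(sim_bad$truth, cfg_bad),
               "exceeds smallest exon")
})

test_that("infeasible packing raises a sizing error", {
  cfg <- sim_config(seed = 1, n_genes = 50, n_scaffolds = 1,
                    scaffold_length = 5000)
  expect_error(generate_truth(cfg), "infeasible packing")
})
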