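# toy gene scaffolding for direct classifier calls
toy_gene <- function(exons, strand = "+", scaffold = "s",
                     cds = c(min(exons$start), max(exons$end))) {
  data.frame(gene_id = "g", scaffold = scaffold, strand = strand,
             cds_start = cds[1], cds_end = cds[2], stringsAsFactors = FALSE)
}

# single-group evidence: one sample per stage group for simplicity
toy_samples <- stage_samples()

toy_js <- function(df, spread = TRUE) {
  df$min_anchor <- 20L
  df$donor <- "GT"; df$acceptor <- "AG"; df$canonical <- TRUE
  for (s in toy_samples$sample)
    df[[paste0("support.", s)]] <- if (spread || s == "G_m") df$support
                                   else 0L
  df$support <- NULL
  junctions(df)
}

flat_cov <- function(len, depth, sample = "pooled")
  cov_of(s = rep(depth, len), sample = sample)

toy_cov_groups <- function(len, depth = 0) {
  g <- list(growth = flat_cov(len, depth, "growth"),
            starvation = flat_cov(len, depth, "starvation"),
            conjugation = flat_cov(len, depth, "conjugation"))
  g$pooled <- splicerefine:::pool_coverage(g[1:3])
  g
}

enumerate_toy <- function(gene, exons, js, cov_groups, ...) {
  gi <- data.frame(start = exons$end[-nrow(exons)] + 1L,
                   end = exons$start[-1] - 1L)
  gi$length <- gi$end - gi$start + 1L
  suppressMessages(enumerate_as_events(gene, exons, gi, js, cov_groups,
                                       toy_samples, ...))
}

test_that("shared donor with differing acceptors is alternative 3' selection", {
  exons <- data.frame(start = c(1L, 201L), end = c(100L, 400L))
  gene <- toy_gene(exons)
  # introns [101,200] and [101,230]: donors equal, acceptors differ
  js <- toy_js(data.frame(scaffold = "s",
                          start = c(101L, 101L), end = c(200L, 230L),
                          strand = "+", support = 5L))
  ev <- enumerate_toy(gene, exons, js, toy_cov_groups(400))
  expect_identical(ev$type, "alt3")
  expect_identical(c(ev$intron_start, ev$intron_end), c(101L, 200L))
  expect_identical(c(ev$alt_start, ev$alt_end), c(101L, 230L))
  # on the minus strand the same geometry is alternative 5' selection
  ev2 <- enumerate_toy(toy_gene(exons, strand = "-"), exons,
                       toy_js(data.frame(scaffold = "s",
                                         start = c(101L, 101L),
                                         end = c(200L, 230L),
                                         strand = "-", support = 5L)),
                       toy_cov_groups(400))
  expect_identical(ev2$type, "alt5")
})

test_that("a supported skip junction over an annotated internal exon is a cassette", {
  exons <- data.frame(start = c(1L, 201L, 351L), end = c(100L, 250L, 500L))
  gene <- toy_gene(exons)
  js <- toy_js(data.frame(scaffold = "s",
                          start = c(101L, 251L, 101L),
                          end = c(200L, 350L, 350L),
                          strand = "+", support = 5L))
  ev <- enumerate_toy(gene, exons, js, toy_cov_groups(500))
  expect_identical(ev$type, "cassette")
  expect_identical(c(ev$exon_start, ev$exon_end), c(201L, 250L))
  # the skip/inclusion pairs are not double-reported as alt5/alt3
  expect_identical(nrow(ev), 1L)
  # mean AS intron length: mean of the two inclusion introns and the skip
  expect_equal(ev$mean_as_intron_length, mean(c(100, 100, 250)))
})

test_that("intron retention needs full 10x depth and spliced support", {
  exons <- data.frame(start = c(1L, 201L), end = c(100L, 400L))
  gene <- toy_gene(exons)
  js <- toy_js(data.frame(scaffold = "s", start = 101L, end = 200L,
                          strand = "+", support = 5L))
  # all intron bases at 12x (per group; spliced support 5) -> IR
  ev <- enumerate_toy(gene, exons, js, toy_cov_groups(400, depth = 12))
  expect_identical(ev$type, "ir")
  expect_identical(ev$mean_as_intron_length, 100)
  expect_true(all(ev$growth, ev$starvation, ev$conjugation))
  # one base at 9x, the rest 50x -> not IR ("each nucleotide position")
  cg <- toy_cov_groups(400, depth = 50)
  cg$growth$s[150] <- 3; cg$starvation$s[150] <- 3; cg$conjugation$s[150] <- 3
  cg$pooled <- splicerefine:::pool_coverage(cg[1:3])
  ev2 <- enumerate_toy(gene, exons, js, cg)
  expect_identical(nrow(ev2), 0L)
  # full coverage but spliced support 0 -> unspliced intron, not AS
  js0 <- toy_js(data.frame(scaffold = "s", start = 101L, end = 200L,
                           strand = "+", support = 0L))
  ev3 <- enumerate_toy(gene, exons, js0, toy_cov_groups(400, depth = 12))
  expect_identical(nrow(ev3), 0L)
})

test_that("direct IR calls honour both thresholds", {
  intr <- list(start = 11L, end = 40L)
  cv <- cov_of(s = c(rep(0, 10), rep(12, 30), rep(0, 10)))
  expect_true(detect_intron_retention(intr, cv, "s", spliced_support = 5))
  expect_false(detect_intron_retention(intr, cv, "s", spliced_support = 1))
  cv$s[20] <- 9
  expect_false(detect_intron_retention(intr, cv, "s", spliced_support = 5))
})

test_that("junctions below support 2 or crossing the gene are excluded", {
  exons <- data.frame(start = c(1L, 201L), end = c(100L, 400L))
  gene <- toy_gene(exons)
  js <- toy_js(data.frame(scaffold = "s",
                          start = c(101L, 101L, 301L),
                          end = c(200L, 230L, 600L),
                          strand = "+",
                          support = c(5L, 0L, 5L)))
  js$support.G_m[2] <- 1L   # total support 1 < 2
  expect_message(
    ev <- enumerate_as_events(gene, exons,
                              data.frame(start = 101L, end = 200L,
                                         length = 100L),
                              js, toy_cov_groups(400), toy_samples),
    "crossing the gene boundary")
  expect_identical(nrow(ev), 0L)
})

test_that("mean AS intron length follows the per-type averaging rule", {
  ev_ir <- data.frame(type = "ir", intron_start = 1L, intron_end = 80L,
                      intron2_start = NA, intron2_end = NA,
                      alt_start = NA, alt_end = NA)
  expect_identical(as_intron_mean_length(ev_ir), 80)
  ev_a5 <- data.frame(type = "alt5", intron_start = 1L, intron_end = 150L,
                      intron2_start = NA, intron2_end = NA,
                      alt_start = 1L, alt_end = 226L)
  expect_equal(as_intron_mean_length(ev_a5), 188)
  ev_cx <- data.frame(type = "cassette", intron_start = 1L,
                      intron_end = 100L, intron2_start = 1L,
                      intron2_end = 120L, alt_start = 1L, alt_end = 300L)
  expect_equal(as_intron_mean_length(ev_cx), 173.33)
})

test_that("IR specificity is max over sum of retention counts", {
  expect_equal(ir_specificity(c(9, 1)), 0.9)
  expect_equal(ir_specificity(5), 1.0)
  expect_error(ir_specificity(c(0, 0)), "undefined")
  set.seed(12)
  for (i in 1:20) {
    x <- rpois(sample(2:8, 1), 4) + c(1, rep(0, 0))
    x[1] <- x[1] + 1  # ensure positive total
    expect_equal(ir_specificity(x), max(x) / sum(x))
  }
})

test_that("weighted averaging of specificities", {
  expect_equal(ir_weighted_average(10, 0.73), 0.73)
  expect_equal(ir_weighted_average(c(1, 3), c(0.5, 0.9)), 0.8)
  expect_error(ir_weighted_average(c(1, 2), 0.5), "equal length")
})

test_that("stage-specific events are those meeting criteria in exactly one group", {
  ev <- empty <- splicerefine:::empty_events()
  row <- function(g, s, c) data.frame(
    gene_id = "g", type = "ir", intron_start = 1L, intron_end = 50L,
    intron2_start = NA_integer_, intron2_end = NA_integer_,
    alt_start = NA_integer_, alt_end = NA_integer_,
    exon_start = NA_integer_, exon_end = NA_integer_,
    growth = g, starvation = s, conjugation = c,
    mean_as_intron_length = 50, ptc = NA)
  # detected in C-2 and C-8 only -> conjugation-specific
  ev <- rbind(row(FALSE, FALSE, TRUE),   # conjugation-specific
              row(TRUE, FALSE, TRUE),    # growth + conjugation: not specific
              row(TRUE, TRUE, TRUE))     # constitutive
  sp <- stage_specific_as(ev)
  expect_identical(nrow(sp), 1L)
  expect_identical(sp$specific_group, "conjugation")
  expect_identical(nrow(stage_specific_as(empty)), 0L)
})

test_that("classifier equals brute-force enumeration on random toy genes", {
  res <- oracle_sweep(n_cases = 150, seed = 101)
  expect_identical(res$mismatches, 0L)
  expect_gt(res$n_events, 100)  # the sweep must actually exercise events
})

test_that("raising thresholds never increases the event count", {
  cfg <- recovery_config(seed = 29)
  sim <- generate_truth(cfg)
  obs <- simulate_observables(sim$truth, cfg)
  base <- run_sim_pipeline(cfg)$report
  for (p in list(list(min_support_as = 4), list(ir_min_depth = 25),
                 list(min_support_as = 8, ir_min_depth = 40))) {
    rep2 <- run_sim_pipeline(cfg, params = p)$report
    expect_lte(nrow(rep2$events), nrow(base$events))
    counts2 <- unlist(rep2$summary$as_counts)
    expect_true(all(counts2 <= unlist(base$summary$as_counts)))
  }
})
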