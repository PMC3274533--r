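test_that("RPKM closed form, scaling invariance and edge errors", {
  expect_equal(compute_rpkm(100, 2000, 5e6), 10)
  expect_equal(compute_rpkm(0, 2000, 5e6), 0)
  set.seed(8)
  for (i in 1:50) {
    count <- sample(0:1e5, 1); len <- sample(100:1e4, 1)
    total <- round(runif(1, 1e5, 1e8))
    expect_equal(compute_rpkm(count, len, total),
                 1e9 * count / (len * total), tolerance = 1e-9)
    lambda <- runif(1, 0.1, 20)
    expect_equal(compute_rpkm(lambda * count, len, lambda * total),
                 compute_rpkm(count, len, total), tolerance = 1e-9)
  }
  expect_error(compute_rpkm(10, 0, 100), "exon length")
  expect_error(compute_rpkm(10, 100, 0), "total mapped")
})

test_that("rpkm_matrix totals are the column sums of the count table", {
  cfg <- recovery_config(seed = 33)
  sim <- generate_truth(cfg)
  obs <- simulate_observables(sim$truth, cfg)
  m <- rpkm_matrix(obs$counts)
  tot <- attr(m, "totals")
  for (s in stage_samples()$sample) {
    expect_equal(unname(tot[s]), sum(obs$counts[[paste0("count.", s)]]))
    expect_equal(m[, s],
                 compute_rpkm(obs$counts[[paste0("count.", s)]],
                              obs$counts$exon_len, tot[s]),
                 ignore_attr = TRUE)
  }
  expect_true(all((m == 0) == (as.matrix(
    obs$counts[, paste0("count.", stage_samples()$sample)]) == 0)))
})

test_that("stage up-regulation needs RPKM > 5 and 5-fold dominance", {
  samples <- stage_samples()
  mk <- function(g, s, c) {
    m <- cbind(G_m = g, S_3 = s, S_15 = s, C_2 = c, C_8 = c)
    rownames(m) <- "gene1"
    m
  }
  expect_identical(call_stage_upregulated(mk(30, 5, 5), samples)$growth,
                   "gene1")
  # max RPKM 4.9 <= 5: not called anywhere
  up <- call_stage_upregulated(mk(4.9, 0.1, 0.1), samples)
  expect_identical(sum(lengths(up)), 0L)
  # fold 25/6 < 5: not growth-specific
  up2 <- call_stage_upregulated(mk(25, 6, 1), samples)
  expect_identical(length(up2$growth), 0L)
  # zero in all other stages counts as infinite fold
  expect_identical(call_stage_upregulated(mk(6, 0, 0), samples)$growth,
                   "gene1")
  # boundary: exactly 5 RPKM fails the strict "greater than 5"
  expect_identical(sum(lengths(call_stage_upregulated(mk(5, 1, 1),
                                                      samples))), 0L)
})

test_that("the three up-regulated sets are pairwise disjoint", {
  cfg <- recovery_config(seed = 37, expression_log10_sd = 1)
  sim <- generate_truth(cfg)
  obs <- simulate_observables(sim$truth, cfg)
  up <- call_stage_upregulated(rpkm_matrix(obs$counts))
  expect_identical(length(intersect(up$growth, up$starvation)), 0L)
  expect_identical(length(intersect(up$growth, up$conjugation)), 0L)
  expect_identical(length(intersect(up$starvation, up$conjugation)), 0L)
  # monotone in min_fold: raising the fold threshold shrinks every set
  up2 <- call_stage_upregulated(rpkm_matrix(obs$counts), min_fold = 10)
  for (g in names(up)) expect_true(all(up2[[g]] %in% up[[g]]))
})

test_that("probe medians renormalize per corrected gene", {
  ann <- annotation(
    data.frame(gene_id = c("A", "B"), scaffold = "s", strand = "+",
               cds_start = c(101L, 501L), cds_end = c(300L, 700L)),
    data.frame(gene_id = c("A", "B"), start = c(101L, 501L),
               end = c(300L, 700L)),
    seqlengths = c(s = 1000L))
  probes <- data.frame(
    probe_id = sprintf("p%d", 1:7),
    scaffold = "s",
    start = c(110L, 150L, 200L, 510L, 550L, 600L, 850L),
    end = c(140L, 180L, 230L, 540L, 580L, 630L, 880L),
    stringsAsFactors = FALSE)
  probes$intensity.G_m <- c(1, 2, 9, 5, 6, 7, 3)
  out <- suppressMessages(reassign_and_renormalize(probes, ann))
  expect_equal(out$values["A", "G_m"], 2)   # median(1,2,9)
  expect_equal(out$values["B", "G_m"], 6)   # median(5,6,7)
  # probe p7 lies in no gene: dropped
  expect_true(is.na(out$assignment$gene_id[7]))
  # single-probe gene: median is that probe's value
  one <- probes[3, , drop = FALSE]
  out1 <- suppressMessages(reassign_and_renormalize(one, ann))
  expect_equal(out1$values["A", "G_m"], 9)
})

test_that("probes inside two overlapping genes are unassigned", {
  ann <- annotation(
    data.frame(gene_id = c("A", "B"), scaffold = "s", strand = c("+", "-"),
               cds_start = c(101L, 151L), cds_end = c(300L, 400L)),
    data.frame(gene_id = c("A", "B"), start = c(101L, 151L),
               end = c(300L, 400L)),
    seqlengths = c(s = 1000L))
  probes <- data.frame(probe_id = "p1", scaffold = "s", start = 200L,
                       end = 230L, stringsAsFactors = FALSE)
  probes$intensity.G_m <- 4
  out <- suppressMessages(reassign_and_renormalize(probes, ann))
  expect_true(is.na(out$assignment$gene_id))
  expect_identical(nrow(out$values), 0L)
})

test_that("platform correlation on log2 scale matches the closed form", {
  x <- c(a = 1, b = 2, c = 4, d = 8, e = 16)
  expect_equal(correlate_platforms(x, log2(2 * x + 2) - 1,
                                   array_is_log2 = TRUE), 1)
  y <- -log2(x + 1); names(y) <- names(x)
  expect_equal(correlate_platforms(x, y), -1)
  set.seed(14)
  for (i in 1:10) {
    a <- stats::setNames(rexp(20, 0.1), paste0("g", 1:20))
    b <- stats::setNames(rexp(20, 0.1), paste0("g", 1:20))
    la <- log2(a + 1); lb <- log2(b + 1)
    r_manual <- sum((la - mean(la)) * (lb - mean(lb))) /
      sqrt(sum((la - mean(la))^2) * sum((lb - mean(lb))^2))
    expect_equal(correlate_platforms(a, b, array_is_log2 = FALSE),
                 r_manual, tolerance = 1e-12)
  }
  expect_error(correlate_platforms(x[1:2], x[1:2]), "fewer than 3")
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  # universe of 10 genes, 5 with term T; test set of 2, both with T:
  # p = C(5,2)/C(10,2)
  uni <- setNames(lapply(1:10, function(i)
    if (i <= 5) "T" else character(0)), paste0("g", 1:10))
  res <- go_enrichment(c("g1", "g2"), uni, alpha = 0.01)
  expect_equal(res$p, choose(5, 2) / choose(10, 2), tolerance = 1e-12)
  expect_equal(res$p, 0.2222, tolerance = 1e-3)
  # exhaustive oracle over all 2-subsets: P(both annotated)
  pairs <- combn(10, 2)
  expect_equal(res$p, mean(colSums(pairs <= 5) == 2), tolerance = 1e-12)
  # single term tested: corrected p equals raw p
  expect_equal(res$p_bonferroni, res$p)
  # a term with k=0 in the test set is not tested; upper tail at k=0 is 1
  expect_equal(stats::phyper(-1, 5, 5, 2, lower.tail = FALSE), 1)
})

test_that("Bonferroni correction bounds and significance behaviour", {
  uni <- list(g1 = c("T1", "T2"), g2 = "T1", g3 = "T2", g4 = "T3",
              g5 = "T1", g6 = character(0), g7 = "T2", g8 = "T1")
  res <- go_enrichment(c("g1", "g2", "g5"), uni, alpha = 0.05)
  expect_true(all(res$p_bonferroni >= res$p))
  expect_true(all(res$p_bonferroni <= 1))
  strict <- go_enrichment(c("g1", "g2", "g5"), uni, alpha = 1e-6)
  expect_true(sum(strict$significant) <= sum(res$significant))
  expect_error(go_enrichment("gX", uni), "absent from the universe")
  expect_error(go_enrichment("g1", list()), "empty universe")
})
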