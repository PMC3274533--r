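# Hand-built scenario on one 3000 bp scaffold:
#   model mA [101,500]  two exons [101,300] [401,500], intron [301,400]
#   model mB [701,900]  single exon
#   model mC [1001,1100] and mD [1301,1400]: truly one gene (one transcript
#     spans both including the junction between them) -> fused
#   model mE [1701,2400]: truly two genes separated by a zero-coverage gap
#     -> split
mk_refine_fixture <- function() {
  genes <- data.frame(
    gene_id = c("mA", "mB", "mC", "mD", "mE"),
    scaffold = "scf1", strand = "+",
    cds_start = c(101L, 701L, 1001L, 1301L, 1701L),
    cds_end = c(500L, 900L, 1100L, 1400L, 2400L),
    stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c("mA", "mA", "mB", "mC", "mD", "mE"),
    start = c(101L, 401L, 701L, 1001L, 1301L, 1701L),
    end = c(300L, 500L, 900L, 1100L, 1400L, 2400L),
    stringsAsFactors = FALSE)
  ann <- annotation(genes, exons, seqlengths = c(scf1 = 3000L),
                    provenance = "fixture")
  v <- numeric(3000)
  v[101:300] <- 20; v[401:500] <- 20          # mA exons
  v[701:900] <- 20                            # mB
  v[1001:1400] <- 20                          # mC..mD continuous transcript
  v[1701:2000] <- 20; v[2101:2400] <- 20      # mE: two blocks, 100 bp gap
  cov <- cov_of(scf1 = v)
  js <- jx("scf1", 301L, 400L)                # mA's intron
  list(ann = ann, cov = cov, js = js)
}

test_that("model statuses cover confirmation, fusion, split and undetected", {
  fx <- mk_refine_fixture()
  ts <- assemble_transcripts(fx$cov, fx$js)
  cmp <- compare_to_annotation(ts, fx$ann, fx$cov)
  st <- setNames(cmp$status$status, cmp$status$gene_id)
  expect_identical(st[["mA"]], "complete_match")
  expect_identical(st[["mB"]], "complete_match")
  expect_identical(st[["mC"]], "fused")
  expect_identical(st[["mD"]], "fused")
  expect_identical(st[["mE"]], "split")
  # corrected annotation merges mC+mD and splits mE into two genes
  ids <- cmp$corrected$genes$gene_id
  expect_true("mC+mD" %in% ids)
  expect_true(all(c("mE.1", "mE.2") %in% ids))
  expect_identical(nrow(cmp$corrected$genes), 5L)
  validate_annotation(cmp$corrected)
})

test_that("undetected models keep their annotation and status", {
  fx <- mk_refine_fixture()
  ts <- assemble_transcripts(cov_of(scf1 = numeric(3000)), fx$js[0, ])
  cmp <- compare_to_annotation(ts, fx$ann, cov_of(scf1 = numeric(3000)))
  expect_true(all(cmp$status$status == "undetected"))
  expect_identical(nrow(cmp$corrected$genes), nrow(fx$ann$genes))
})

test_that("boundary and intron-count errors are told apart", {
  fx <- mk_refine_fixture()
  # evidence says intron [311,400]: coverage runs 10 bp into the predicted
  # intron and the junction sits at the shifted boundary
  v <- fx$cov$scf1
  v[301:310] <- 20
  ts <- assemble_transcripts(cov_of(scf1 = v), jx("scf1", 311L, 400L))
  st <- setNames(compare_to_annotation(ts, fx$ann,
                                       cov_of(scf1 = v))$status$status,
                 fx$ann$genes$gene_id)
  expect_identical(st[["mA"]], "boundary_mismatch")
  # coverage bridges the predicted intron with no junction: the transcript
  # is intron-less where the model has one intron
  v2 <- fx$cov$scf1
  v2[301:400] <- 20
  ts2 <- assemble_transcripts(cov_of(scf1 = v2), fx$js[0, ])
  st2 <- setNames(compare_to_annotation(ts2, fx$ann,
                                        cov_of(scf1 = v2))$status$status,
                  fx$ann$genes$gene_id)
  expect_identical(st2[["mA"]], "missing_or_extra_intron")
})

test_that("novel regions need >= 300 bp of strictly intergenic span", {
  fx <- mk_refine_fixture()
  v <- numeric(3000)
  v[2600:2999] <- 20    # 400 bp intergenic transcript -> reported
  cov <- cov_of(scf1 = v)
  ts <- assemble_transcripts(cov, fx$js[0, ])
  nr <- detect_novel_regions(ts, fx$ann)
  expect_identical(nrow(nr), 1L)
  expect_identical(c(nr$start, nr$end, nr$length), c(2600L, 2999L, 400L))
  # 250 bp intergenic transcript -> rejected
  v2 <- numeric(3000); v2[2600:2849] <- 20
  nr2 <- detect_novel_regions(assemble_transcripts(cov_of(scf1 = v2),
                                                   fx$js[0, ]), fx$ann)
  expect_identical(nrow(nr2), 0L)
  # 400 bp transcript overlapping an annotated exon by 1 bp -> rejected
  v3 <- numeric(3000); v3[2400:2799] <- 20   # touches mE's last base 2400
  nr3 <- detect_novel_regions(assemble_transcripts(cov_of(scf1 = v3),
                                                   fx$js[0, ]), fx$ann)
  expect_identical(nrow(nr3), 0L)
})

test_that("UTRs extend through contiguous coverage and stop at zero depth", {
  genes <- data.frame(gene_id = "g", scaffold = "scf1", strand = "+",
                      cds_start = 501L, cds_end = 1000L,
                      stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = "g", start = 501L, end = 1000L)
  ann <- annotation(genes, exons, seqlengths = c(scf1 = 2000L))
  status <- data.frame(gene_id = "g", status = "complete_match")
  v <- numeric(2000)
  v[441:1120] <- 3    # 60 bp past the start codon, 120 bp past the stop
  utr <- infer_utrs(cov_of(scf1 = v), ann, status)
  ul <- utr_lengths(utr)
  expect_identical(ul$utr5_len, 60L)
  expect_identical(ul$utr3_len, 120L)
  # zero coverage immediately outside the CDS: UTR length 0
  v0 <- numeric(2000); v0[501:1000] <- 3
  ul0 <- utr_lengths(infer_utrs(cov_of(scf1 = v0), ann, status))
  expect_identical(c(ul0$utr5_len, ul0$utr3_len), c(0L, 0L))
})

test_that("UTR extension stops at a neighbouring gene boundary", {
  genes <- data.frame(gene_id = c("g", "n"), scaffold = "scf1",
                      strand = "+", cds_start = c(501L, 1101L),
                      cds_end = c(1000L, 1200L), stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = c("g", "n"), start = c(501L, 1101L),
                      end = c(1000L, 1200L))
  ann <- annotation(genes, exons, seqlengths = c(scf1 = 2000L))
  status <- data.frame(gene_id = "g", status = "complete_match")
  v <- numeric(2000); v[501:1200] <- 3   # continuous into the neighbour
  ul <- utr_lengths(infer_utrs(cov_of(scf1 = v), ann, status))
  expect_identical(ul$utr3_len[ul$gene_id == "g"], 100L)
})

test_that("simulated UTR lengths are recovered exactly at high depth", {
  cfg <- recovery_config(seed = 19,
                         as_rates = c(cassette = 0, alt5 = 0, alt3 = 0,
                                      ir = 0),
                         misannotation_rates = c(fuse = 0, split = 0,
                                                 boundary = 0,
                                                 missing_intron = 0))
  sim <- generate_truth(cfg)
  obs <- simulate_observables(sim$truth, cfg)
  js <- filter_junctions(validate_junctions(obs$junctions, sim$genome))
  pooled <- splicerefine:::pool_coverage(obs$coverage)
  ts <- assemble_transcripts(pooled, js)
  cmp <- compare_to_annotation(ts, sim$annotation, pooled)
  utr <- infer_utrs(pooled, cmp$corrected, cmp$status)
  ul <- utr_lengths(utr)
  tg <- sim$truth$genes
  coding <- tg$gene_id[!tg$is_novel]
  confirmed <- cmp$status$gene_id[cmp$status$status == "complete_match"]
  expect_gt(length(intersect(coding, confirmed)), 20)
  for (gid in intersect(coding, confirmed)) {
    expect_identical(ul$utr5_len[ul$gene_id == gid],
                     tg$utr5_len[tg$gene_id == gid])
    expect_identical(ul$utr3_len[ul$gene_id == gid],
                     tg$utr3_len[tg$gene_id == gid])
  }
})
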