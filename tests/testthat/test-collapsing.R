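test_that("carrier_status follows the dominant-coding and missing-data
           rules", {
  gt <- matrix(c(1L, 0L, NA, 0L,
                 0L, 0L, NA, 2L), 4, 2,
               dimnames = list(paste0("S", 1:4), c("v1", "v2")))
  cs <- carrier_status(gt, c("v1", "v2"))
  expect_true(cs[["S1"]])        # one het at one qualifying variant
  expect_false(cs[["S2"]])       # homozygous reference everywhere
  expect_true(is.na(cs[["S3"]])) # missing at every qualifying variant
  expect_true(cs[["S4"]])
  expect_error(carrier_status(gt, character(0)), "empty qualifying")
  expect_error(carrier_status(gt, "v9"), "absent")
})

test_that("fisher_two_sided matches enumeration on the worked example and
           handles degenerate margins", {
  # 5 carrier cases of 92 vs 0 carrier controls of 102
  expect_equal(fisher_two_sided(5, 87, 0, 102), 0.02262024, tolerance = 1e-6)
  expect_warning(p <- fisher_two_sided(0, 92, 0, 102), "degenerate")
  expect_equal(p, 1)
})

test_that("fisher_two_sided agrees with stats::fisher.test and is
           transpose-symmetric on random tables", {
  set.seed(99)
  for (i in 1:200) {
    tab <- rpois(4, 8) + c(1, 0, 0, 1)
    if (tab[1] + tab[3] == 0) tab[1] <- 1
    a <- tab[1]; b <- tab[2]; cc <- tab[3]; d <- tab[4]
    p <- fisher_two_sided(a, b, cc, d)
    expect_equal(p, stats::fisher.test(matrix(tab, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-10)
    # swapping case/control together with carrier/noncarrier = transpose
    expect_equal(p, fisher_two_sided(a, cc, b, d), tolerance = 1e-12)
  }
})

test_that("odds_ratio applies the Haldane-Anscombe correction only on zero
           cells and respects table symmetries", {
  expect_equal(odds_ratio(5, 87, 0, 102), (5.5 * 102.5) / (87.5 * 0.5))
  expect_equal(odds_ratio(5, 87, 0, 102), 12.886, tolerance = 1e-4)
  expect_equal(odds_ratio(1, 1, 1, 1), 1)
  expect_equal(odds_ratio(6, 10, 3, 20), (6 * 20) / (10 * 3))
  expect_equal(odds_ratio(6, 10, 3, 20),
               1 / odds_ratio(3, 20, 6, 10))
  expect_true(is.infinite(odds_ratio(5, 87, 0, 102, correction = "none")))
  # conditional-MLE option delegates to the noncentral hypergeometric fit
  expect_equal(odds_ratio(6, 10, 3, 20, correction = "cmle"),
               unname(stats::fisher.test(matrix(c(6, 10, 3, 20), 2,
                                                byrow = TRUE))$estimate))
})

test_that("collapsed_maf counts minor alleles over non-missing slots", {
  gt <- matrix(0L, 194, 2, dimnames = list(NULL, c("v1", "v2")))
  gt[1, 1] <- 1L
  expect_equal(collapsed_maf(gt, "v1"), 1 / 388)
  gt[1, 2] <- 1L
  expect_equal(collapsed_maf(gt, c("v1", "v2")), 2 / 776)
  expect_equal(collapsed_maf(gt * 0L, c("v1", "v2")), 0)
  expect_equal(collapsed_maf(gt, c("v1", "v2"), mode = "carrier"), 1 / 194)
  gt[, 1] <- NA
  expect_error(collapsed_maf(gt[, 1, drop = FALSE], "v1"), "missing")
})

test_that("burden_scan ranks a planted gene first and behaves at the null", {
  hits <- 0L
  for (r in 1:20) {
    cfg <- sim_config(
      n_cases = 100, n_controls = 100, n_genes = 40, variants_per_gene = 4,
      planted_burden_genes = data.frame(gene = "G0007", case_prob = 0.25,
                                        control_prob = 0.01),
      seed = 300 + r)
    co <- simulate_annotations(simulate_genotypes(cfg), cfg)
    gs <- build_gene_sets(co$annotations, co$annotations$variant_id)
    res <- burden_scan(gs, co$genotypes, co$labels)
    if (res$gene[which.min(res$p)] == "G0007") hits <- hits + 1L
  }
  expect_gte(hits, 15L)

  # equal carrier rates in both arms: p near 1 on average
  cfg0 <- sim_config(n_cases = 150, n_controls = 150, n_genes = 30,
                     variants_per_gene = 4, seed = 77)
  co0 <- simulate_annotations(simulate_genotypes(cfg0), cfg0)
  gs0 <- build_gene_sets(co0$annotations, co0$annotations$variant_id)
  res0 <- burden_scan(gs0, co0$genotypes, co0$labels)
  expect_gt(mean(res0$p), 0.5)
  # deterministic ordering by gene then set
  expect_false(is.unsorted(res0$gene))
})

test_that("burden rows are emitted only for non-empty qualifying cells", {
  ann <- rbind(ann_row("v1", "G1", "nonsense", maf = 0.01),
               ann_row("v2", "G2", "synonymous", maf = 0.01))
  gt <- matrix(c(1L, 0L, 0L, 0L, 0L, 1L, 0L, 0L), 4, 2,
               dimnames = list(paste0("S", 1:4), c("v1", "v2")))
  gs <- build_gene_sets(ann, c("v1", "v2"))
  res <- burden_scan(gs, gt, c("case", "case", "control", "control"))
  expect_false("G2" %in% res$gene)    # synonymous qualifies nowhere
  expect_equal(sum(res$gene == "G1"), 5L)
  expect_equal(attr(res, "n_tests"), nrow(res))
})

test_that("threshold_screen keeps p < 0.05 with OR > 3.5 and deduplicates
           genes", {
  rows <- published_burden_rows()
  kept <- threshold_screen(rows)
  expect_true("TOE1" %in% kept$genes)     # OR 33.6, p 0.002
  expect_false("LOWOR" %in% kept$genes)   # OR 3.4
  expect_false("HIGHP" %in% kept$genes)   # p 0.06
  dup <- rbind(rows, transform(rows[1, ], set = "broad"))
  expect_equal(sum(threshold_screen(dup)$genes == "TOE1"), 1L)
})
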