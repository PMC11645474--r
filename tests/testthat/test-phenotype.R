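test_that("carrier_regression returns the carrier-noncarrier mean
           difference with the OLS t-test", {
  fit <- carrier_regression(c(110, 130, 80, 90, 100),
                            c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(fit$beta, 30)
  expect_equal(fit$n_carriers, 2L)
  lmref <- summary(stats::lm(y ~ x, data = data.frame(
    y = c(110, 130, 80, 90, 100),
    x = c(TRUE, TRUE, FALSE, FALSE, FALSE))))$coefficients
  expect_equal(fit$p, lmref["xTRUE", "Pr(>|t|)"])

  expect_warning(
    dg <- carrier_regression(c(5, 5, 5, 5), c(TRUE, TRUE, FALSE, FALSE)),
    "degenerate")
  expect_equal(dg$beta, 0)
  expect_equal(dg$p, 1)
  expect_error(carrier_regression(1:4, rep(TRUE, 4)), "noncarrier")
})

test_that("the regression beta equals the raw mean difference on arbitrary
           inputs", {
  set.seed(5)
  for (i in 1:50) {
    n <- sample(10:60, 1)
    y <- rnorm(n, 50, 20)
    x <- runif(n) < 0.3
    if (!any(x) || all(x)) next
    fit <- carrier_regression(y, x)
    expect_equal(fit$beta, mean(y[x]) - mean(y[!x]), tolerance = 1e-10)
  }
})

test_that("planted phenotype shifts are recovered without systematic bias", {
  betas <- vapply(1:50, function(r) {
    set.seed(600 + r)
    carrier <- runif(92) < 0.15
    if (!any(carrier)) carrier[1] <- TRUE
    y <- 76 + rnorm(92, 0, 10) + 30 * carrier
    carrier_regression(y, carrier)$beta
  }, numeric(1))
  mcse <- stats::sd(betas) / sqrt(length(betas))
  expect_lt(abs(mean(betas) - 30), 3 * mcse)
})

test_that("phenotype_scan is case-only and logs skipped cells", {
  gt <- matrix(0L, 8, 2, dimnames = list(paste0("S", 1:8), c("v1", "v2")))
  gt[7:8, 1] <- 1L   # carriers are controls only
  gs <- data.frame(gene = "G1", set = "nonsynonymous", variant_id = "v1",
                   stringsAsFactors = FALSE)
  ph <- data.frame(sample_id = paste0("S", 1:8), LDL_C = rnorm(8, 76, 10))
  case_mask <- rep(c(TRUE, FALSE), each = 4)
  res <- phenotype_scan("G1", gs, gt, ph, case_mask)
  expect_equal(nrow(res), 0L)
  expect_equal(attr(res, "skipped")$reason, "no carrier with phenotype")

  # missing phenotype for every carrier -> skipped with log entry
  gt[1:2, 1] <- 1L
  ph$LDL_C[1:2] <- NA
  res2 <- phenotype_scan("G1", gs, gt, ph, case_mask)
  expect_equal(nrow(res2), 0L)
  expect_equal(nrow(attr(res2, "skipped")), 1L)

  ph$LDL_C[1:2] <- c(120, 140)
  res3 <- phenotype_scan("G1", gs, gt, ph, case_mask)
  expect_equal(res3$beta,
               mean(c(120, 140)) - mean(ph$LDL_C[3:4]))
  expect_equal(res3$n_carriers, 2L)
})

test_that("a planted lipid gene gives the largest positive LDL-C beta in
           most replicates", {
  wins <- 0L
  for (r in 1:10) {
    cfg <- sim_config(
      n_cases = 92, n_controls = 10, n_genes = 25, variants_per_gene = 3,
      planted_burden_genes = data.frame(gene = "G0003", case_prob = 0.15,
                                        control_prob = 0.01),
      planted_phenotype_effects = data.frame(
        gene = "G0003", phenotype = "LDL_C", shift = 73.87),
      phenotype_baselines = list(LDL_C = c(mean = 76, sd = 33.03)),
      seed = 900 + r)
    co <- simulate_cohort(cfg)
    gs <- build_gene_sets(co$annotations, co$annotations$variant_id)
    res <- phenotype_scan(unique(gs$gene), gs, co$genotypes, co$phenotypes,
                          co$labels == "case")
    ldl <- res[res$phenotype == "LDL_C", ]
    if (nrow(ldl) && ldl$gene[which.max(ldl$beta)] == "G0003") {
      wins <- wins + 1L
    }
  }
  expect_gte(wins, 6L)
})

test_that("any_significant_filter and lipid_filter route the worked-example
           rows correctly", {
  rows <- published_regression_rows()
  expect_true("CABP1" %in% any_significant_filter(rows))
  boundary <- data.frame(gene = c("A", "B"), set = "broad",
                         phenotype = "TC", beta = 1,
                         p = c(0.049, 0.05), n_carriers = 2L)
  expect_equal(any_significant_filter(boundary), "A")

  lip <- lipid_filter(rows)
  expect_true("CABP1" %in% lip$gene)       # beta 73.87, p 0.03
  expect_false("TP53BP1" %in% lip$gene)    # beta -32.51, p 0.1
  expect_false("POSNS" %in% lip$gene)      # beta > 0 but p = 0.07
  expect_equal(lip$traits[lip$gene == "CABP1"], "LDL_C")
  neg <- lipid_filter(rows, direction = "negative")
  expect_false("CABP1" %in% neg$gene)
})

test_that("thrombosis_filter separates shortened from prolonged coagulation
           times", {
  rows <- published_regression_rows()
  th <- thrombosis_filter(rows)
  expect_equal(th$thrombosis, "SHORT")
  expect_true("FGB" %in% th$bleeding)     # PT and APTT both increased
  expect_false("PTONLY" %in% c(th$thrombosis, th$bleeding))
})

test_that("inflammation_filter requires the full four-marker pattern", {
  rows <- published_regression_rows()
  out <- inflammation_filter(rows, anchor = "fibrinogen")
  expect_equal(as.character(out), "KLHL8")
  expect_false("MONOPOS" %in% out)   # monocyte beta positive
  expect_false("WBCNS" %in% out)     # WBC p = 0.2
  # genes missing a required row are skipped and logged
  expect_true("CABP1" %in% attr(out, "skipped")$gene)
})

test_that("under the null the inflammation pattern passes at most 5% of
           genes", {
  set.seed(12)
  n_genes <- 500
  rows <- list()
  for (g in seq_len(n_genes)) {
    carrier <- runif(92) < 0.15
    if (!any(carrier)) carrier[1] <- TRUE
    for (pn in c("fibrinogen", "WBC", "neutrophil_pct", "monocyte_pct")) {
      fit <- carrier_regression(rnorm(92), carrier)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = paste0("N", g), set = "broad", phenotype = pn,
        beta = fit$beta, p = fit$p, n_carriers = fit$n_carriers,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  passed <- inflammation_filter(res, anchor = "fibrinogen")
  expect_lte(length(passed) / n_genes, 0.05)
})

test_that("cohort_compare reproduces exact Wilcoxon and Fisher references", {
  ph <- data.frame(sample_id = paste0("S", 1:6),
                   marker = c(1, 2, 3, 4, 5, 6))
  labels <- stats::setNames(rep(c("case", "control"), each = 3),
                            ph$sample_id)
  out <- cohort_compare(ph, labels)
  expect_equal(out$p, 0.1)              # exact enumeration of 20 assignments
  expect_equal(out$test, "wilcoxon_exact")

  # symmetric arms: exact two-sided p is 1
  ph2 <- data.frame(sample_id = paste0("S", 1:8),
                    marker = c(1, 4, 5, 8, 2, 3, 6, 7))
  labels2 <- stats::setNames(rep(c("case", "control"), each = 4),
                             ph2$sample_id)
  expect_equal(cohort_compare(ph2, labels2)$p, 1)

  # categorical arm: 5/92 cases vs 0/102 controls flagged
  ph3 <- data.frame(sample_id = sprintf("S%03d", 1:194),
                    acs = c(rep(1, 5), rep(0, 87), rep(0, 102)))
  labels3 <- stats::setNames(rep(c("case", "control"), c(92, 102)),
                             ph3$sample_id)
  out3 <- cohort_compare(ph3, labels3, categorical = "acs")
  expect_equal(out3$p, 0.02262024, tolerance = 1e-6)
  expect_equal(out3$case_mean, 100 * 5 / 92)

  # large arms fall back to the tie-corrected normal approximation
  ph4 <- data.frame(sample_id = sprintf("S%03d", 1:80),
                    marker = c(rnorm(40, 1), rnorm(40, 1)))
  labels4 <- stats::setNames(rep(c("case", "control"), each = 40),
                             ph4$sample_id)
  expect_equal(cohort_compare(ph4, labels4)$test, "wilcoxon_normal")
})
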