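test_that("sim_config rejects invalid probabilities, counts and effects", {
  expect_error(sim_config(n_cases = 1), "integer >= 2")
  expect_error(sim_config(predictor_concordance = 1.2), "probability")
  expect_error(sim_config(maf_law = c(0.01, 0.2)), "maf_law")
  expect_error(
    sim_config(planted_burden_genes = data.frame(
      gene = "G0001", case_prob = 0.01, control_prob = 0.1)),
    "cases must be >= controls")
  expect_error(
    sim_config(
      planted_burden_genes = data.frame(gene = "G0001", case_prob = 0.1,
                                        control_prob = 0.01),
      planted_phenotype_effects = data.frame(gene = "G0001",
                                             phenotype = "NOT_A_TRAIT",
                                             shift = 1)),
    "unknown phenotype")
})

test_that("zero carrier probability plants no carriers; fixed seed is
           bit-identical", {
  cfg <- sim_config(
    n_cases = 20, n_controls = 20, n_genes = 5, variants_per_gene = 3,
    planted_burden_genes = data.frame(gene = "G0002", case_prob = 0,
                                      control_prob = 0),
    seed = 11)
  co <- simulate_genotypes(cfg)
  planted_cols <- co$variant_meta$gene == "G0002"
  expect_true(all(co$genotypes[, planted_cols] == 0L))
  co2 <- simulate_genotypes(cfg)
  expect_identical(co$genotypes, co2$genotypes)
  full1 <- simulate_cohort(cfg)
  full2 <- simulate_cohort(cfg)
  expect_identical(full1$phenotypes, full2$phenotypes)
  expect_identical(full1$annotations, full2$annotations)
})

test_that("planted carrier fraction matches the configured binomial law", {
  reps <- 500
  carriers <- 0L
  n_cases <- 200L
  for (r in seq_len(reps)) {
    cfg <- sim_config(
      n_cases = n_cases, n_controls = 200, n_genes = 5,
      variants_per_gene = 2,
      planted_burden_genes = data.frame(gene = "G0001", case_prob = 0.12,
                                        control_prob = 0.01),
      seed = 1000 + r)
    co <- simulate_genotypes(cfg)
    cols <- co$variant_meta$gene == "G0001"
    is_case <- co$labels == "case"
    carriers <- carriers +
      sum(rowSums(co$genotypes[is_case, cols, drop = FALSE]) >= 1)
  }
  frac <- carriers / (reps * n_cases)
  se <- sqrt(0.12 * 0.88 / (reps * n_cases))
  expect_lt(abs(frac - 0.12), 3 * se)
})

test_that("predictor calls agree with the latent state at the configured
           concordance", {
  # all-missense, all-deleterious configuration: the per-predictor
  # deleterious fraction estimates the concordance directly
  cfg <- sim_config(
    n_cases = 2, n_controls = 2, n_genes = 1250, variants_per_gene = 8,
    functional_class_weights = c(missense = 1, nonsense = 0, splice = 0,
                                 frameshift_indel = 0, synonymous = 0),
    predictor_concordance = 0.8, latent_deleterious_prob = 1,
    predictor_missing_rate = 0, seed = 3)
  co <- simulate_annotations(simulate_genotypes(cfg), cfg)
  ann <- co$annotations
  expect_equal(nrow(ann), 10000)
  se <- sqrt(0.8 * 0.2 / nrow(ann))
  del <- c("deleterious", "possibly_damaging", "probably_damaging")
  for (p in c("lrt", "mutationtaster", "polyphen_humdiv",
              "polyphen_humvar", "sift")) {
    expect_lt(abs(mean(ann[[p]] %in% del) - 0.8), 3 * se)
  }
})

test_that("annotation MAF equals the cohort allele frequency and
           non-missense variants carry no predictor calls", {
  cfg <- sim_config(n_cases = 30, n_controls = 30, n_genes = 20,
                    variants_per_gene = 4, seed = 5)
  co <- simulate_annotations(simulate_genotypes(cfg), cfg)
  af <- colSums(co$genotypes) / (2 * nrow(co$genotypes))
  expect_equal(unname(co$annotations$maf), unname(af))
  nonmis <- co$annotations$functional_class != "missense"
  expect_true(all(co$annotations$sift[nonmis] == "missing"))
  expect_true(all(co$annotations$polyphen_humdiv[nonmis] == "missing"))
})

test_that("noiseless planted shift moves carrier means by exactly the
           shift", {
  baselines <- list(LDL_C = c(mean = 76, sd = 0))
  cfg <- sim_config(
    n_cases = 40, n_controls = 40, n_genes = 3, variants_per_gene = 2,
    planted_burden_genes = data.frame(gene = "G0001", case_prob = 0.3,
                                      control_prob = 0.3),
    planted_phenotype_effects = data.frame(gene = "G0001",
                                           phenotype = "LDL_C", shift = 30),
    phenotype_baselines = baselines, seed = 7)
  co <- simulate_phenotypes(simulate_genotypes(cfg), cfg)
  cols <- co$variant_meta$gene == "G0001"
  carrier <- rowSums(co$genotypes[, cols, drop = FALSE]) >= 1
  expect_gt(sum(carrier), 0)
  expect_equal(mean(co$phenotypes$LDL_C[carrier]) -
                 mean(co$phenotypes$LDL_C[!carrier]), 30)
})

test_that("simulated baseline mean matches its configured value", {
  cfg <- sim_config(n_cases = 92, n_controls = 2, n_genes = 2,
                    variants_per_gene = 2, seed = 9)
  co <- simulate_phenotypes(simulate_genotypes(cfg), cfg)
  ldl <- co$phenotypes$LDL_C[co$labels == "case"]
  expect_lt(abs(mean(ldl) - 76.0), 3 * 33.03 / sqrt(92))
})

test_that("with no planted effects the carrier-regression p-value is
           uniform", {
  base <- sim_config(
    n_cases = 60, n_controls = 2, n_genes = 2, variants_per_gene = 2,
    planted_burden_genes = data.frame(gene = "G0001", case_prob = 0.3,
                                      control_prob = 0.3),
    phenotype_baselines = list(LDL_C = c(mean = 76, sd = 33)),
    seed = 1)
  geno <- simulate_genotypes(base)
  cols <- geno$variant_meta$gene == "G0001"
  carrier <- rowSums(geno$genotypes[, cols, drop = FALSE]) >= 1
  pvals <- vapply(seq_len(400), function(r) {
    cfg <- base
    cfg$seed <- 5000 + r
    ph <- simulate_phenotypes(geno, cfg)$phenotypes
    carrier_regression(ph$LDL_C, carrier)$p
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("write_cohort round-trips the genotype, depth and allele-depth
           matrices through the VCF", {
  cfg <- sim_config(
    n_cases = 15, n_controls = 15, n_genes = 6, variants_per_gene = 3,
    planted_burden_genes = data.frame(gene = "G0003", case_prob = 0.3,
                                      control_prob = 0.05),
    seed = 13)
  co <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  expect_true(all(file.exists(paths)))
  vs <- read_vcf(paths[["vcf"]])
  expect_identical(vs$genotypes, co$variants$genotypes)
  expect_identical(unname(vs$depth), unname(co$variants$depth))
  expect_identical(unname(vs$ad_alt), unname(co$variants$ad_alt))
  ann <- utils::read.table(paths[["annotations"]], header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  expect_equal(ann$variant_id, co$annotations$variant_id)
  truth <- utils::read.table(paths[["truth"]], header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  expect_equal(truth$gene, "G0003")
})

test_that("an empty variant set writes a valid header-only VCF", {
  cfg <- sim_config(n_cases = 3, n_controls = 3, n_genes = 1,
                    variants_per_gene = 1, seed = 2)
  co <- simulate_cohort(cfg)
  empty <- rarecascade:::subset_variants(co$variants, integer(0))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(empty, path)
  lines <- readLines(path)
  expect_true(startsWith(lines[1], "##fileformat=VCFv4.2"))
  expect_true(startsWith(lines[length(lines)], "#CHROM"))
})
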