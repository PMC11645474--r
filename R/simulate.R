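#' @importFrom stats rbinom rnorm rpois runif
NULL

FUNCTIONAL_CLASSES <- c("missense", "nonsense", "splice", "frameshift_indel",
                        "synonymous")
NONSYN_CLASSES <- c("missense", "nonsense", "splice", "frameshift_indel")
DISRUPTIVE_CLASSES <- c("nonsense", "splice", "frameshift_indel")
PREDICTORS <- c("lrt", "mutationtaster", "polyphen_humdiv", "polyphen_humvar",
                "sift")

#' Default phenotype baselines
#'
#' Mean and standard deviation, per quantitative phenotype, used by the
#' cohort simulator. Values are typical of a young coronary-disease
#' case series free of conventional risk factors: lipids in mg/dL
#' (apolipoproteins in g/L or mg/L as labelled), blood counts in 10^9/L,
#' differentials in percent, coagulation times in seconds.
#'
#' @return Named list; each element is `c(mean =, sd =)`.
#' @export
default_phenotype_baselines <- function() {
  list(
    TC             = c(mean = 132.5, sd = 36.29),
    TG             = c(mean = 86.6,  sd = 28.27),
    LDL_C          = c(mean = 76.0,  sd = 33.03),
    HDL_C          = c(mean = 42.0,  sd = 8.36),
    ApoA1          = c(mean = 1.2,   sd = 0.19),
    ApoB           = c(mean = 0.6,   sd = 0.20),
    ApoE           = c(mean = 28.3,  sd = 9.99),
    NHDL_C         = c(mean = 2.4,   sd = 0.94),
    CRP            = c(mean = 5.5,   sd = 16.22),
    fibrinogen     = c(mean = 3.8,   sd = 4.61),
    WBC            = c(mean = 7.1,   sd = 2.62),
    neutrophil_pct = c(mean = 63.4,  sd = 11.60),
    lymphocyte_pct = c(mean = 27.3,  sd = 10.02),
    monocyte_pct   = c(mean = 7.0,   sd = 2.45),
    PT             = c(mean = 16.9,  sd = 39.65),
    APTT           = c(mean = 31.6,  sd = 14.03),
    D_dimer        = c(mean = 0.2,   sd = 0.18),
    uric_acid      = c(mean = 335.9, sd = 91.59),
    PDW            = c(mean = 13.9,  sd = 2.89)
  )
}

#' Simulation configuration for a synthetic case-control exome cohort
#'
#' Defines the generative model used by [simulate_cohort()]: rare variants
#' (cohort MAF below 5%) grouped into genes, optional planted risk genes
#' whose per-sample carrier probability differs between cases and controls,
#' five predictor calls per missense variant that agree with a latent
#' deleterious state with probability `predictor_concordance`, and Gaussian
#' phenotypes with additive carrier shifts for planted gene-phenotype
#' effects.
#'
#' @param n_cases,n_controls Arm sizes (both >= 2).
#' @param n_genes Number of simulated genes.
#' @param variants_per_gene Variants simulated per gene.
#' @param maf_law Range `c(min, max)` of the uniform law the per-variant
#'   allele frequency is drawn from; support must lie inside (0, 0.05).
#' @param planted_burden_genes `NULL`, or a data frame with columns
#'   `gene`, `case_prob`, `control_prob`: per-sample carrier probability of
#'   a qualifying allele in each arm (case >= control).
#' @param planted_phenotype_effects `NULL`, or a data frame with columns
#'   `gene`, `phenotype`, `shift`: additive mean shift (phenotype units)
#'   applied to carriers of the planted gene.
#' @param predictor_concordance Probability each of the five predictors
#'   agrees with a missense variant's latent deleterious state.
#' @param latent_deleterious_prob Probability a background missense variant
#'   is latently deleterious (planted-gene missense variants always are).
#' @param predictor_missing_rate Probability a predictor call is missing.
#' @param functional_class_weights Named probabilities over
#'   `r paste(FUNCTIONAL_CLASSES, collapse = ", ")`; must sum to 1.
#' @param phenotype_baselines Named list of `c(mean, sd)` per phenotype;
#'   see [default_phenotype_baselines()].
#' @param mean_depth Mean sequencing depth (reads) for simulated sites.
#' @param mapping_quality Site-level mapping quality written to the VCF.
#' @param seed Integer seed; all outputs are bit-identical under a fixed
#'   seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_cases = 92L,
                       n_controls = 102L,
                       n_genes = 200L,
                       variants_per_gene = 8L,
                       maf_law = c(0.001, 0.02),
                       planted_burden_genes = NULL,
                       planted_phenotype_effects = NULL,
                       predictor_concordance = 0.9,
                       latent_deleterious_prob = 0.3,
                       predictor_missing_rate = 0.02,
                       functional_class_weights = c(
                         missense = 0.55, nonsense = 0.05, splice = 0.05,
                         frameshift_indel = 0.05, synonymous = 0.30),
                       phenotype_baselines = default_phenotype_baselines(),
                       mean_depth = 100,
                       mapping_quality = 60,
                       seed = 1L) {
  n_cases <- assert_count(n_cases, "n_cases", min = 2L)
  n_controls <- assert_count(n_controls, "n_controls", min = 2L)
  n_genes <- assert_count(n_genes, "n_genes", min = 1L)
  variants_per_gene <- assert_count(variants_per_gene, "variants_per_gene",
                                    min = 1L)
  if (length(maf_law) != 2L || maf_law[1] <= 0 || maf_law[2] >= 0.05 ||
      maf_law[1] > maf_law[2]) {
    stop_config("maf_law must be c(min, max) with 0 < min <= max < 0.05")
  }
  assert_prob(predictor_concordance, "predictor_concordance")
  assert_prob(latent_deleterious_prob, "latent_deleterious_prob")
  assert_prob(predictor_missing_rate, "predictor_missing_rate")
  if (!setequal(names(functional_class_weights), FUNCTIONAL_CLASSES)) {
    stop_config("functional_class_weights must name exactly: ",
                paste(FUNCTIONAL_CLASSES, collapse = ", "))
  }
  assert_prob(functional_class_weights, "functional_class_weights")
  if (abs(sum(functional_class_weights) - 1) > 1e-8) {
    stop_config("functional_class_weights must sum to 1")
  }
  functional_class_weights <- functional_class_weights[FUNCTIONAL_CLASSES]

  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  if (!is.null(planted_burden_genes)) {
    planted_burden_genes <- as.data.frame(planted_burden_genes,
                                          stringsAsFactors = FALSE)
    need <- c("gene", "case_prob", "control_prob")
    if (!all(need %in% names(planted_burden_genes))) {
      stop_config("planted_burden_genes needs columns: ",
                  paste(need, collapse = ", "))
    }
    if (anyDuplicated(planted_burden_genes$gene)) {
      stop_config("duplicate gene in planted_burden_genes")
    }
    if (!all(planted_burden_genes$gene %in% gene_ids)) {
      stop_config("planted_burden_genes$gene must be among the simulated ",
                  "gene ids (G0001 ...)")
    }
    assert_prob(planted_burden_genes$case_prob, "case_prob")
    assert_prob(planted_burden_genes$control_prob, "control_prob")
    if (any(planted_burden_genes$case_prob <
            planted_burden_genes$control_prob)) {
      stop_config("planted carrier probability in cases must be >= controls")
    }
  }
  if (!is.null(planted_phenotype_effects)) {
    planted_phenotype_effects <- as.data.frame(planted_phenotype_effects,
                                               stringsAsFactors = FALSE)
    need <- c("gene", "phenotype", "shift")
    if (!all(need %in% names(planted_phenotype_effects))) {
      stop_config("planted_phenotype_effects needs columns: ",
                  paste(need, collapse = ", "))
    }
    bad <- setdiff(planted_phenotype_effects$phenotype,
                   names(phenotype_baselines))
    if (length(bad)) {
      stop_config("unknown phenotype in planted effects: ",
                  paste(bad, collapse = ", "))
    }
    if (is.null(planted_burden_genes) ||
        !all(planted_phenotype_effects$gene %in% planted_burden_genes$gene)) {
      stop_config("planted_phenotype_effects$gene must be planted burden genes")
    }
  }

  structure(list(
    n_cases = n_cases, n_controls = n_controls, n_genes = n_genes,
    variants_per_gene = variants_per_gene, maf_law = maf_law,
    planted_burden_genes = planted_burden_genes,
    planted_phenotype_effects = planted_phenotype_effects,
    predictor_concordance = predictor_concordance,
    latent_deleterious_prob = latent_deleterious_prob,
    predictor_missing_rate = predictor_missing_rate,
    functional_class_weights = functional_class_weights,
    phenotype_baselines = phenotype_baselines,
    mean_depth = mean_depth, mapping_quality = mapping_quality,
    gene_ids = gene_ids,
    seed = assert_count(seed, "seed")
  ), class = "sim_config")
}

#' Simulate genotypes, labels and planted truth
#'
#' Background variants draw an allele frequency from `maf_law` and
#' genotypes as binomial(2, freq) identically in both arms. For planted
#' genes, per-sample carrier status is drawn with the configured
#' case/control probabilities and the carrier receives one heterozygous
#' qualifying allele at a randomly chosen variant of the gene, so the
#' planted carrier fraction is the direct estimand of the collapsing test.
#'
#' @param config A [sim_config()].
#' @return A `sim_cohort` object holding `genotypes` (sample x variant
#'   allele-count matrix), `variant_meta`, `labels` (named character,
#'   "case"/"control") and `truth` (the planted parameters).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_cases + config$n_controls
  sample_ids <- sprintf("S%04d", seq_len(n))
  labels <- stats::setNames(
    rep(c("case", "control"), c(config$n_cases, config$n_controls)),
    sample_ids)

  genes <- rep(config$gene_ids, each = config$variants_per_gene)
  vidx <- rep(seq_len(config$variants_per_gene), times = config$n_genes)
  variant_ids <- sprintf("%s_v%02d", genes, vidx)
  nv <- length(variant_ids)
  gidx <- rep(seq_len(config$n_genes), each = config$variants_per_gene)
  variant_meta <- data.frame(
    variant_id = variant_ids,
    gene = genes,
    chrom = as.character((gidx - 1L) %% 22L + 1L),
    pos = gidx * 100000L + vidx * 100L,
    ref = "A", alt = "G",
    stringsAsFactors = FALSE)

  planted <- config$planted_burden_genes
  planted_genes <- if (is.null(planted)) character() else planted$gene

  geno <- matrix(0L, n, nv, dimnames = list(sample_ids, variant_ids))
  bg <- !(genes %in% planted_genes)
  if (any(bg)) {
    freqs <- runif(sum(bg), config$maf_law[1], config$maf_law[2])
    geno[, bg] <- matrix(rbinom(n * sum(bg), 2L, rep(freqs, each = n)),
                         n, sum(bg))
  }
  if (length(planted_genes)) {
    is_case <- labels == "case"
    for (i in seq_along(planted_genes)) {
      g <- planted_genes[i]
      pr <- ifelse(is_case, planted$case_prob[i], planted$control_prob[i])
      carrier <- runif(n) < pr
      cols <- which(genes == g)
      if (any(carrier)) {
        at <- cols[sample.int(length(cols), sum(carrier), replace = TRUE)]
        geno[cbind(which(carrier), at)] <- 1L
      }
    }
  }

  truth <- if (is.null(planted)) {
    data.frame(gene = character(), case_prob = numeric(),
               control_prob = numeric(), stringsAsFactors = FALSE)
  } else planted

  structure(list(
    genotypes = geno,
    variant_meta = variant_meta,
    labels = labels,
    truth = truth,
    annotations = NULL,
    phenotypes = NULL,
    variants = NULL
  ), class = "sim_cohort")
}

#' Simulate per-variant annotations
#'
#' Each variant draws a functional class from the configured weights
#' (planted-gene variants are restricted to non-synonymous classes so every
#' planted allele is a qualifying allele). Missense variants receive a
#' latent deleterious state and five predictor calls, each agreeing with
#' the latent state with probability `predictor_concordance`,
#' conditionally independently; non-missense variants carry no predictor
#' calls. The MAF field is the cohort allele frequency.
#'
#' @param cohort A `sim_cohort` from [simulate_genotypes()].
#' @param config The same [sim_config()].
#' @return The cohort with an `annotations` data frame added (columns
#'   `variant_id`, `gene`, `functional_class`, the five predictor columns,
#'   `maf`).
#' @export
simulate_annotations <- function(cohort, config) {
  stopifnot(inherits(cohort, "sim_cohort"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  meta <- cohort$variant_meta
  nv <- nrow(meta)
  planted_genes <- cohort$truth$gene
  w <- config$functional_class_weights

  cls <- character(nv)
  bg <- !(meta$gene %in% planted_genes)
  if (any(bg)) {
    cls[bg] <- sample(names(w), sum(bg), replace = TRUE, prob = w)
  }
  if (any(!bg)) {
    wp <- w[NONSYN_CLASSES]
    if (sum(wp) <= 0) wp[] <- 1
    cls[!bg] <- sample(names(wp), sum(!bg), replace = TRUE, prob = wp)
  }

  latent <- rep(NA, nv)
  mis <- cls == "missense"
  latent[mis] <- runif(sum(mis)) < config$latent_deleterious_prob
  latent[mis & !bg] <- TRUE

  calls <- matrix("missing", nv, length(PREDICTORS),
                  dimnames = list(NULL, PREDICTORS))
  if (any(mis)) {
    m <- sum(mis)
    for (p in PREDICTORS) {
      agree <- runif(m) < config$predictor_concordance
      del <- ifelse(agree, latent[mis], !latent[mis])
      call <- ifelse(del, "deleterious", "tolerated")
      if (p == "polyphen_humdiv") {
        # HumDiv reports PolyPhen-2 categories; both damaging grades map to
        # deleterious downstream
        call[del] <- sample(c("possibly_damaging", "probably_damaging"),
                            sum(del), replace = TRUE)
        call[!del] <- "benign"
      }
      call[runif(m) < config$predictor_missing_rate] <- "missing"
      calls[mis, p] <- call
    }
  }

  nonmiss <- colSums(!is.na(cohort$genotypes))
  maf <- colSums(cohort$genotypes, na.rm = TRUE) / (2 * pmax(nonmiss, 1L))

  ann <- data.frame(
    variant_id = meta$variant_id,
    gene = meta$gene,
    functional_class = cls,
    stringsAsFactors = FALSE)
  for (p in PREDICTORS) ann[[p]] <- calls[, p]
  ann$maf <- unname(maf)
  cohort$annotations <- ann
  cohort
}

#' Simulate phenotypes with planted carrier shifts
#'
#' Each phenotype is its baseline mean plus independent Gaussian noise;
#' samples carrying at least one allele of a planted gene with a configured
#' phenotype effect receive the additive shift. Percentage-scaled
#' phenotypes (names ending `_pct`) are clamped to \[0, 100\].
#'
#' @inheritParams simulate_annotations
#' @return The cohort with a `phenotypes` data frame (column `sample_id`
#'   plus one column per phenotype) added.
#' @export
simulate_phenotypes <- function(cohort, config) {
  stopifnot(inherits(cohort, "sim_cohort"), inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  n <- nrow(cohort$genotypes)
  ph <- data.frame(sample_id = rownames(cohort$genotypes),
                   stringsAsFactors = FALSE)
  for (name in names(config$phenotype_baselines)) {
    b <- config$phenotype_baselines[[name]]
    ph[[name]] <- b[["mean"]] + rnorm(n, 0, b[["sd"]])
  }
  eff <- config$planted_phenotype_effects
  if (!is.null(eff) && nrow(eff)) {
    for (i in seq_len(nrow(eff))) {
      cols <- which(cohort$variant_meta$gene == eff$gene[i])
      carrier <- rowSums(cohort$genotypes[, cols, drop = FALSE],
                         na.rm = TRUE) >= 1
      ph[[eff$phenotype[i]]][carrier] <-
        ph[[eff$phenotype[i]]][carrier] + eff$shift[i]
    }
  }
  pct <- grepl("_pct$", names(ph))
  ph[pct] <- lapply(ph[pct], function(x) pmin(pmax(x, 0), 100))
  cohort$phenotypes <- ph
  cohort
}

# Per-site sequencing metadata: depths ~ Poisson(mean_depth), allele depths
# binomial at the expected allelic fraction, balanced strands.
simulate_site_data <- function(cohort, config) {
  set.seed(config$seed + 3L)
  gt <- cohort$genotypes
  n <- nrow(gt); nv <- ncol(gt)
  dp <- matrix(pmax(rpois(n * nv, config$mean_depth), 1L), n, nv,
               dimnames = dimnames(gt))
  frac <- gt / 2
  ad_alt <- matrix(rbinom(n * nv, as.vector(dp), as.vector(frac)), n, nv,
                   dimnames = dimnames(gt))
  ad_alt[gt == 0L] <- 0L
  ad_alt[gt == 2L] <- dp[gt == 2L]
  ad_ref <- dp - ad_alt

  ref_tot <- colSums(ad_ref); alt_tot <- colSums(ad_alt)
  ref_fwd <- rbinom(nv, ref_tot, 0.5)
  alt_fwd <- rbinom(nv, alt_tot, 0.5)
  meta <- cohort$variant_meta
  meta$mq <- config$mapping_quality
  meta$sb_ref_fwd <- ref_fwd
  meta$sb_ref_rev <- ref_tot - ref_fwd
  meta$sb_alt_fwd <- alt_fwd
  meta$sb_alt_rev <- alt_tot - alt_fwd

  cohort$variants <- variant_set(meta, gt, dp, ad_ref, ad_alt)
  cohort
}

#' Simulate a complete cohort
#'
#' Runs [simulate_genotypes()], [simulate_annotations()],
#' [simulate_phenotypes()] and attaches per-site sequencing metadata
#' (depths, allele depths, mapping quality, strand counts) so the cohort
#' can be written as a multi-sample VCF.
#'
#' @param config A [sim_config()].
#' @return A complete `sim_cohort`.
#' @export
simulate_cohort <- function(config) {
  cohort <- simulate_genotypes(config)
  cohort <- simulate_annotations(cohort, config)
  cohort <- simulate_phenotypes(cohort, config)
  simulate_site_data(cohort, config)
}

#' Simulate gene-evidence tables for a cohort
#'
#' Builds miniature synthetic counterparts of the four gene-evidence
#' sources (lipid-trait association p-values, CAD GWAS consortium flags,
#' mouse phenotype categories, GWAS-catalog flags) over the simulated gene
#' ids. Planted genes with lipid-trait effects get a lipid p-value entry;
#' every planted burden gene gets a cardiovascular/metabolism mouse
#' annotation, so planted genes survive the evidence filter by
#' construction. Background genes enter each source independently at the
#' configured rates.
#'
#' @param cohort A `sim_cohort`.
#' @param rates Named per-source inclusion probabilities for background
#'   genes (`glgc`, `cardiogram`, `mgi`, `gwas_catalog`).
#' @param seed Integer seed.
#' @return An `evidence_tables` object (see [load_evidence()]).
#' @export
simulate_evidence <- function(cohort,
                              rates = c(glgc = 0.2, cardiogram = 0.2,
                                        mgi = 0.3, gwas_catalog = 0.1),
                              seed = 1L) {
  stopifnot(inherits(cohort, "sim_cohort"))
  set.seed(seed)
  genes <- unique(cohort$variant_meta$gene)
  planted <- cohort$truth$gene
  lipid_traits <- c(TC = "tc_p", TG = "tg_p", LDL_C = "ldl_p",
                    HDL_C = "hdl_p")

  in_src <- function(rate, force = character()) {
    genes[runif(length(genes)) < rate | genes %in% force]
  }

  glgc_genes <- in_src(rates[["glgc"]])
  glgc <- data.frame(gene = glgc_genes,
                     tc_p = NA_real_, tg_p = NA_real_,
                     ldl_p = NA_real_, hdl_p = NA_real_,
                     stringsAsFactors = FALSE)
  for (g in glgc$gene) {
    k <- sample(2:5, 1L) - 1L
    cols <- sample(unname(lipid_traits), k)
    glgc[glgc$gene == g, cols] <- 10^(-runif(k, 5, 20))
  }
  mgi_cats <- c("cardiovascular", "adipose", "metabolism",
                "endocrine/exocrine", "liver")
  mgi_genes <- in_src(rates[["mgi"]], force = planted)
  mgi <- do.call(rbind, lapply(mgi_genes, function(g) {
    cats <- if (g %in% planted) c("cardiovascular", "metabolism")
            else sample(mgi_cats, sample(1:2, 1L))
    data.frame(gene = g, category = cats, stringsAsFactors = FALSE)
  }))
  if (is.null(mgi)) mgi <- data.frame(gene = character(),
                                      category = character())
  cardiogram <- data.frame(gene = in_src(rates[["cardiogram"]]),
                           stringsAsFactors = FALSE)
  gwas <- data.frame(gene = in_src(rates[["gwas_catalog"]]),
                     stringsAsFactors = FALSE)
  new_evidence_tables(glgc = glgc, cardiogram = cardiogram, mgi = mgi,
                      gwas_catalog = gwas)
}

#' Write a simulated cohort to disk
#'
#' Emits a multi-sample VCF (FORMAT GT, DP, AD; INFO MQ and SB) plus
#' annotation, phenotype, labels and truth TSVs. Files round-trip
#' losslessly through [read_vcf()] and the TSV readers.
#'
#' @param cohort A complete `sim_cohort` (from [simulate_cohort()]).
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (is.null(cohort$variants) || is.null(cohort$annotations) ||
      is.null(cohort$phenotypes)) {
    stop("cohort is incomplete; run simulate_cohort()")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir)
  paths <- c(
    vcf = file.path(dir, "cohort.vcf"),
    annotations = file.path(dir, "annotations.tsv"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    labels = file.path(dir, "labels.tsv"),
    truth = file.path(dir, "truth.tsv"))
  write_vcf(cohort$variants, paths[["vcf"]])
  write_tsv(cohort$annotations, paths[["annotations"]])
  write_tsv(cohort$phenotypes, paths[["phenotypes"]])
  write_tsv(data.frame(sample_id = names(cohort$labels),
                       status = unname(cohort$labels),
                       stringsAsFactors = FALSE), paths[["labels"]])
  write_tsv(cohort$truth, paths[["truth"]])
  invisible(paths)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}

read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}
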