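#' Site-level QC thresholds
#'
#' Thresholds for the six exclusion rules applied by [apply_qc()]. The
#' depth cutoffs (minor-allele average depth below 4, average depth below
#' 8) are fixed points of the method; the remaining cutoffs follow common
#' exome-QC practice and are overridable here.
#'
#' @param min_minor_allele_mean_depth Exclude when the mean depth over
#'   samples carrying at least one minor allele is below this (reads).
#' @param min_mean_depth Exclude when the mean depth over non-missing
#'   samples is below this (reads).
#' @param min_mapping_quality Exclude when site mapping quality is below
#'   this.
#' @param strand_bias_p Exclude when the two-sided exact test on the
#'   ref/alt x fwd/rev strand table is below this.
#' @param allelic_imbalance_band Admissible interval for the mean
#'   heterozygote alternate-allele fraction.
#' @param hwe_p Exclude when the exact Hardy-Weinberg p-value, computed in
#'   control samples, is below this.
#' @param minor_depth_mode `"total_depth"` reads "minor allele average
#'   depth" as the mean total depth among minor-allele carriers;
#'   `"minor_ad"` uses the mean of the minor allele's own read depth.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_minor_allele_mean_depth = 4,
                          min_mean_depth = 8,
                          min_mapping_quality = 40,
                          strand_bias_p = 1e-3,
                          allelic_imbalance_band = c(0.25, 0.75),
                          hwe_p = 1e-6,
                          minor_depth_mode = c("total_depth", "minor_ad")) {
  if (min_minor_allele_mean_depth <= 0 || min_mean_depth <= 0 ||
      min_mapping_quality <= 0 || strand_bias_p <= 0 || hwe_p <= 0) {
    stop_config("all thresholds must be positive")
  }
  if (length(allelic_imbalance_band) != 2L ||
      allelic_imbalance_band[1] <= 0 || allelic_imbalance_band[2] >= 1 ||
      allelic_imbalance_band[1] >= allelic_imbalance_band[2]) {
    stop_config("allelic_imbalance_band must be an interval inside (0, 1)")
  }
  structure(list(
    min_minor_allele_mean_depth = min_minor_allele_mean_depth,
    min_mean_depth = min_mean_depth,
    min_mapping_quality = min_mapping_quality,
    strand_bias_p = strand_bias_p,
    allelic_imbalance_band = allelic_imbalance_band,
    hwe_p = hwe_p,
    minor_depth_mode = match.arg(minor_depth_mode)
  ), class = "qc_thresholds")
}

#' Exact Hardy-Weinberg equilibrium p-value
#'
#' Two-sided exact test conditioning on the observed allele counts: the
#' p-value is the sum, over all heterozygote counts compatible with the
#' allele margin, of the probabilities no larger than that of the observed
#' heterozygote count.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (major homozygote, heterozygote,
#'   minor homozygote).
#' @return A p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be >= 0")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("no genotypes observed; HWE p undefined")
  n_minor <- min(2L * n_aa + n_Aa, 2L * n_AA + n_Aa)
  if (n_minor == 0L) return(1)
  hets <- seq.int(n_minor %% 2L, n_minor, by = 2L)
  hom_minor <- (n_minor - hets) / 2
  hom_major <- n - hets - hom_minor
  logp <- lfactorial(n) - lfactorial(hom_minor) - lfactorial(hets) -
    lfactorial(hom_major) + hets * log(2) +
    lfactorial(n_minor) + lfactorial(2L * n - n_minor) - lfactorial(2L * n)
  p <- exp(logp)
  p_obs <- p[hets == n_Aa]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

QC_RULES <- c("mean_depth", "minor_allele_depth", "mapping_quality",
              "strand_bias", "allelic_imbalance", "hwe")

#' Apply site-level quality control
#'
#' Excludes a variant when any of six rules fires: (i) mean depth over
#' non-missing samples below `min_mean_depth`; (ii) mean depth over
#' minor-allele carriers below `min_minor_allele_mean_depth`; (iii) site
#' mapping quality below `min_mapping_quality`; (iv) two-sided exact test
#' on the ref/alt x fwd/rev strand-count table below `strand_bias_p`;
#' (v) mean heterozygote alternate-allele fraction outside
#' `allelic_imbalance_band`; (vi) exact Hardy-Weinberg p-value in control
#' samples below `hwe_p`. Depth means ignore missing genotypes; rules (ii),
#' (v) and (vi) are skipped when no informative sample exists.
#'
#' @param vs A [variant_set()].
#' @param thresholds A [qc_thresholds()].
#' @param control_mask Logical vector (one per sample): `TRUE` for control
#'   samples, used by the Hardy-Weinberg rule.
#' @return A list with `retained` (the filtered [variant_set()]) and `log`,
#'   a data frame (`variant_id`, `rule`, `value`, `threshold`) with one row
#'   per fired rule; a variant may appear under several rules.
#' @export
apply_qc <- function(vs, thresholds = qc_thresholds(), control_mask) {
  stopifnot(inherits(vs, "variant_set"), inherits(thresholds, "qc_thresholds"))
  ns <- nrow(vs$genotypes)
  if (length(control_mask) != ns || !is.logical(control_mask)) {
    stop_config("control_mask must be a logical vector, one entry per sample")
  }
  if (!any(control_mask)) {
    stop_config("control_mask selects zero samples; the Hardy-Weinberg ",
                "rule needs controls")
  }
  th <- thresholds
  nv <- nrow(vs$meta)
  logs <- list()
  fail <- logical(nv)
  add <- function(i, rule, value, threshold) {
    logs[[length(logs) + 1L]] <<- data.frame(
      variant_id = vs$meta$variant_id[i], rule = rule,
      value = value, threshold = threshold, stringsAsFactors = FALSE)
    fail[i] <<- TRUE
  }

  for (i in seq_len(nv)) {
    gt <- vs$genotypes[, i]
    dp <- vs$depth[, i]
    ok <- !is.na(gt)

    mean_dp <- mean(dp[ok], na.rm = TRUE)
    if (is.finite(mean_dp) && mean_dp < th$min_mean_depth) {
      add(i, "mean_depth", mean_dp, th$min_mean_depth)
    }

    af <- sum(gt[ok]) / (2 * sum(ok))
    alt_minor <- af <= 0.5
    carrier <- if (alt_minor) ok & gt >= 1L else ok & gt <= 1L
    if (any(carrier)) {
      md <- if (th$minor_depth_mode == "total_depth") {
        mean(dp[carrier], na.rm = TRUE)
      } else {
        ad <- if (alt_minor) vs$ad_alt[, i] else vs$ad_ref[, i]
        mean(ad[carrier], na.rm = TRUE)
      }
      if (is.finite(md) && md < th$min_minor_allele_mean_depth) {
        add(i, "minor_allele_depth", md, th$min_minor_allele_mean_depth)
      }
    }

    mq <- vs$meta$mq[i]
    if (!is.na(mq) && mq < th$min_mapping_quality) {
      add(i, "mapping_quality", mq, th$min_mapping_quality)
    }

    sb <- c(vs$meta$sb_ref_fwd[i], vs$meta$sb_ref_rev[i],
            vs$meta$sb_alt_fwd[i], vs$meta$sb_alt_rev[i])
    if (!anyNA(sb) && sb[1] + sb[2] > 0 && sb[3] + sb[4] > 0) {
      sp <- fisher_two_sided(sb[1], sb[2], sb[3], sb[4])
      if (sp < th$strand_bias_p) add(i, "strand_bias", sp, th$strand_bias_p)
    }

    het <- ok & gt == 1L
    if (any(het)) {
      tot <- vs$ad_ref[het, i] + vs$ad_alt[het, i]
      frac <- vs$ad_alt[het, i][tot > 0] / tot[tot > 0]
      if (length(frac)) {
        mf <- mean(frac)
        if (mf < th$allelic_imbalance_band[1] ||
            mf > th$allelic_imbalance_band[2]) {
          add(i, "allelic_imbalance", mf, th$allelic_imbalance_band[1])
        }
      }
    }

    gtc <- gt[control_mask & ok]
    if (length(gtc)) {
      hp <- hwe_exact_p(sum(gtc == 0L), sum(gtc == 1L), sum(gtc == 2L))
      if (hp < th$hwe_p) add(i, "hwe", hp, th$hwe_p)
    }
  }

  log_df <- if (length(logs)) do.call(rbind, logs) else
    data.frame(variant_id = character(), rule = character(),
               value = numeric(), threshold = numeric(),
               stringsAsFactors = FALSE)
  list(retained = subset_variants(vs, which(!fail)), log = log_df)
}
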