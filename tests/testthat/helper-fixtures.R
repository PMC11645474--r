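# Fixture builders used across the suite.

# A variant_set with sane defaults: deep balanced coverage, high mapping
# quality, balanced strands, allele depths consistent with the genotype.
# Any column can be perturbed afterwards to trip a single QC rule.
make_variant_set <- function(gt, depth = 100, mq = 60) {
  ns <- nrow(gt)
  nv <- ncol(gt)
  if (is.null(rownames(gt))) rownames(gt) <- sprintf("S%03d", seq_len(ns))
  if (is.null(colnames(gt))) colnames(gt) <- sprintf("v%03d", seq_len(nv))
  dp <- matrix(depth, ns, nv, dimnames = dimnames(gt))
  ad_alt <- matrix(0L, ns, nv, dimnames = dimnames(gt))
  ad_alt[gt == 1L] <- as.integer(round(dp[gt == 1L] / 2))
  ad_alt[gt == 2L] <- dp[gt == 2L]
  ad_ref <- dp - ad_alt
  ref_tot <- colSums(ad_ref * !is.na(gt), na.rm = TRUE)
  alt_tot <- colSums(ad_alt * !is.na(gt), na.rm = TRUE)
  meta <- data.frame(
    variant_id = colnames(gt), chrom = "1",
    pos = seq_len(nv) * 100L, ref = "A", alt = "G", mq = mq,
    sb_ref_fwd = ceiling(ref_tot / 2), sb_ref_rev = floor(ref_tot / 2),
    sb_alt_fwd = ceiling(alt_tot / 2), sb_alt_rev = floor(alt_tot / 2),
    stringsAsFactors = FALSE)
  variant_set(meta, gt, dp, ad_ref, ad_alt)
}

# One annotation row as the classifier expects it.
ann_row <- function(variant_id = "v1", gene = "G1",
                    functional_class = "missense",
                    lrt = "missing", mutationtaster = "missing",
                    polyphen_humdiv = "missing", polyphen_humvar = "missing",
                    sift = "missing", maf = 0.01) {
  data.frame(variant_id = variant_id, gene = gene,
             functional_class = functional_class, lrt = lrt,
             mutationtaster = mutationtaster,
             polyphen_humdiv = polyphen_humdiv,
             polyphen_humvar = polyphen_humvar, sift = sift, maf = maf,
             stringsAsFactors = FALSE)
}

# Published worked-example rows, used as routing fixtures for the screen
# and the pathway filters.
published_burden_rows <- function() {
  data.frame(
    gene = c("TOE1", "LDLR", "CABP1", "HPSE2", "LOWOR", "HIGHP"),
    set = c("strict", "nonsynonymous", "nonsynonymous", "polyphen",
            "broad", "broad"),
    cmaf = c(0.004, 0.027, 0.003, 0.004, 0.010, 0.010),
    or_estimate = c(33.6, 4.25, 22.19, 11.1, 3.4, 5.0),
    p = c(0.002, 0.002, 0.02, 0.04, 0.01, 0.06),
    stringsAsFactors = FALSE)
}

published_regression_rows <- function() {
  row <- function(gene, set, phenotype, beta, p) {
    data.frame(gene = gene, set = set, phenotype = phenotype, beta = beta,
               p = p, n_carriers = 5L, stringsAsFactors = FALSE)
  }
  rbind(
    # lipid worked examples
    row("CABP1", "nonsynonymous", "LDL_C", 73.87, 0.03),
    row("TP53BP1", "strict", "LDL_C", -32.51, 0.1),
    row("POSNS", "broad", "LDL_C", 25.0, 0.07),
    # fibrinogen-anchored inflammation pattern
    row("KLHL8", "broad", "fibrinogen", 9.94, 0.003),
    row("KLHL8", "broad", "WBC", 4.91, 0.01),
    row("KLHL8", "broad", "neutrophil_pct", 16.9, 0.04),
    row("KLHL8", "broad", "monocyte_pct", -5.17, 0.002),
    # monocyte sign violation
    row("MONOPOS", "broad", "fibrinogen", 8.0, 0.01),
    row("MONOPOS", "broad", "WBC", 3.0, 0.01),
    row("MONOPOS", "broad", "neutrophil_pct", 10.0, 0.01),
    row("MONOPOS", "broad", "monocyte_pct", 2.0, 0.01),
    # anchor significant but WBC not
    row("WBCNS", "broad", "fibrinogen", 8.0, 0.01),
    row("WBCNS", "broad", "WBC", 3.0, 0.2),
    row("WBCNS", "broad", "neutrophil_pct", 10.0, 0.01),
    row("WBCNS", "broad", "monocyte_pct", -2.0, 0.01),
    # coagulation patterns: shortened, prolonged, one-sided
    row("SHORT", "broad", "PT", -2.1, 0.01),
    row("SHORT", "broad", "APTT", -3.0, 0.02),
    row("FGB", "nonsynonymous", "PT", 4.1, 0.01),
    row("FGB", "nonsynonymous", "APTT", 5.2, 0.02),
    row("PTONLY", "broad", "PT", -2.0, 0.01),
    row("PTONLY", "broad", "APTT", -1.0, 0.5))
}
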