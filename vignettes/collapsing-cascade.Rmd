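---
title: "The collapsing burden cascade: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The collapsing burden cascade: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarecascade)
```

## The problem

In early-onset coronary artery disease (EOCAD), a small minority of
patients carry none of the standard modifiable risk factors — obesity,
smoking, hypertension, hypertriglyceridemia, elevated LDL-C. Whatever
drives their disease is *residual risk*, and rare coding variants are a
natural place to look: a gene whose rare, deleterious alleles are enriched
in risk-factor-free cases relative to elderly CAD-free controls is a
candidate residual-risk gene. `rarecascade` implements the full discovery
cascade for this design: site-level variant QC, construction of qualifying
variant sets, a per-gene collapsing burden test with a p-value/odds-ratio
screen, database evidence mapping, and carrier-versus-noncarrier phenotype
regression with pathway-pattern filters for lipid, thrombosis and
inflammation signatures.

## The collapsing burden test

For a gene $g$ and a qualifying-variant set $S_g$, each sample is coded as
a **carrier** if it has at least one minor allele at at least one variant
in $S_g$ (CAST-style dominant coding). The 2x2 table of carrier status
against case/control label is tested with the two-sided Fisher exact test:
conditioning on both margins, the p-value is the sum of the hypergeometric
probabilities of all tables no more probable than the observed one. The
effect size is the cross-product odds ratio; when a cell is zero the
Haldane-Anscombe correction (adding 0.5 to every cell) keeps it finite.
Each (gene, set) cell also reports its collapsed minor allele frequency
(cMAF): the total minor-allele count over the cell's variants divided by
the number of non-missing allele slots (two per sample per variant).

A cell survives the screen when $p < 0.05$ **and** $\mathrm{OR} > 3.5$,
both strict; a gene survives when any of its set-level cells survives. No
multiple-testing correction is applied at this stage — the screen is a
deliberate raw-p triage, and the scan attaches the number of tests
performed (attribute `n_tests`) so users can apply their own correction.

### Qualifying-variant sets

Five nested definitions, built from the functional class and five
deleteriousness predictors (LRT, MutationTaster, PolyPhen-2 HumDiv,
PolyPhen-2 HumVar, SIFT) annotated per missense variant:

* **nonsynonymous** — missense, nonsense, splice-site, frameshift indel;
* **polyphen** — disruptive variants plus missense called possibly or
  probably damaging by PolyPhen-2 HumDiv;
* **broad** — disruptive plus missense deleterious by *at least one* of
  the five predictors;
* **strict** — disruptive plus missense deleterious by *all five*;
* **disruptive** — nonsense, splice-site, frameshift indel only.

Only QC-retained variants with MAF strictly below 5% qualify. The nesting
`disruptive ⊆ strict ⊆ broad ⊆ nonsynonymous` and
`disruptive ⊆ polyphen ⊆ broad` holds by construction and is asserted
property-style in the test suite. Two decisions the definitions leave
open were resolved as follows: a **missing** predictor call counts as *not
deleterious* (it can never create strict membership and contributes
nothing to broad — the conservative reading), and both HumDiv damaging
grades count as deleterious wherever HumDiv acts as one of the five
algorithms, so a single mapping is used everywhere.

### Variant QC

Six exclusion rules, any of which removes a site: mean depth over
non-missing samples < 8 reads; mean depth over minor-allele carriers < 4
reads; mapping quality < 40; strand-bias exact test p < 1e-3 on the
ref/alt x forward/reverse read-count table; mean heterozygote
alternate-allele fraction outside [0.25, 0.75]; exact Hardy-Weinberg
p < 1e-6. The two depth cutoffs are fixed points of the method; the other
four are unstated in the original design and default to common exome-QC
practice — results obtained with them should not be presented as an exact
replication of any particular study's QC. All are overridable via
`qc_thresholds()`. Two further choices: HWE is tested in **controls
only**, since genuine case enrichment violates HWE by design; and "minor
allele average depth" is read as the mean *total* depth among samples
carrying at least one minor allele, with the alternative (mean of the
minor allele's own read depth) behind `minor_depth_mode = "minor_ad"`.
Depth means ignore missing genotypes. The Hardy-Weinberg p-value is the
exact conditional test: enumeration over all heterozygote counts
compatible with the observed allele margin, summing probabilities no
larger than the observed one.

### Phenotype analysis

Within cases only, each candidate gene's carriers are compared to
noncarriers by ordinary least squares of the phenotype on the carrier
indicator, with no covariates — the slope then equals the raw
carrier-minus-noncarrier mean difference, which keeps the effect size in
phenotype units and directly interpretable. A covariate-adjusted variant
was considered and deliberately left out: with roughly 10 carriers per
gene, adjustment costs more in stability than it buys in confounding
control, and the downstream filters only consume the sign and
significance. Genes pass the significance gate if any (set, phenotype) row
has p < 0.05, and then three pattern filters are applied at gene level (a
gene passes if *any* of its set-level rows satisfies the pattern):

* **lipid**: at least one lipid trait (TC, LDL-C, TG, HDL-C, ApoA1, ApoB,
  ApoE, non-HDL-C) significant with positive beta;
* **thrombosis**: PT *and* APTT both significant with negative betas
  (shortened clotting times); genes with both significantly *prolonged*
  are reported separately as bleeding-direction, since prolonged clotting
  carries no thrombotic risk;
* **inflammation**: an anchor acute-phase marker (CRP or fibrinogen)
  significantly increased together with higher WBC count, higher
  neutrophil percentage and lower monocyte percentage — the leukocyte
  signature seen in the case cohort.

The case-versus-control cohort table uses the Wilcoxon rank-sum test for
quantitative phenotypes (exact when both arms have ≤ 25 observations and
no ties, the tie-corrected normal approximation otherwise) and the same
Fisher exact test for categorical flags.

### Evidence mapping

Screened genes are joined, case-insensitively on the symbol, against four
evidence sources: lipid-trait association p-values (GLGC-style), a CAD
GWAS consortium gene list (CARDIoGRAMplusC4D-style), mouse phenotype
categories (MGI-style: cardiovascular, adipose, metabolism,
endocrine/exocrine, liver), and a GWAS-catalog flag. A gene survives with
evidence in at least one of the first three; the GWAS-catalog flag is
recorded as annotation only. GLGC evidence means *any* of the four trait
p-values is present (no re-thresholding), and MGI evidence means any of
the five categories. No alias or ortholog resolution is attempted. The
package ships miniature **synthetic** fixtures of all four sources
(`inst/extdata/synthetic_evidence/`) for tests and examples; point
`load_evidence()` at full exports for real work.

## The synthetic cohort generator

Because the original cohort data are access-restricted, every stage is
exercised against `simulate_cohort()`, whose defaults are the package's
statement of realistic study conditions:

| parameter | default | rationale |
|---|---|---|
| `n_cases` / `n_controls` | 92 / 102 | the study scale the method targets |
| `n_genes` x `variants_per_gene` | 200 x 8 | desk-scale exome surrogate |
| `maf_law` | uniform on (0.001, 0.02) | keeps variants rare (MAF < 5%) with realistic carrier counts at n ≈ 200 |
| `predictor_concordance` | 0.9 | predictors agree with the latent state often, not always |
| `latent_deleterious_prob` | 0.3 | a minority of background missense is deleterious |
| `predictor_missing_rate` | 0.02 | occasional absent calls |
| `functional_class_weights` | missense .55, synonymous .30, nonsense/splice/frameshift .05 each | typical exonic class mix |
| `phenotype_baselines` | per-trait mean/SD of a young risk-factor-free case series (e.g. LDL-C 76.0 ± 33.03 mg/dL) | Table-1-style clinical baselines |

Planted risk genes are simulated through **carrier status** directly: each
sample becomes a carrier with the configured per-arm probability and
receives one heterozygous allele at a random variant of the gene, whose
functional class is restricted to the non-synonymous classes so the
allele qualifies. This makes the planted carrier fraction the direct
estimand of the collapsing test. Planted phenotype effects are additive
mean shifts applied to carriers; the default pipeline plants one lipid
gene (G0001, LDL-C +73.87 mg/dL) and one inflammation gene (G0002,
fibrinogen +9.94, WBC +4.91, neutrophils +16.9, monocytes −5.17), effect
sizes of the magnitude the method is meant to detect, with carrier
probabilities 0.12 in cases versus 0.01 in controls.

What the generator deliberately does **not** emulate: linkage between
variants (independent draws — collapsing statistics depend only on carrier
status), correlation between phenotypes (independent Gaussian noise;
real lipid and inflammation markers are strongly correlated, and several
are right-skewed where the Gaussian model can produce negative values),
population stratification, covariate confounding, and read-level
artifacts. Percentage-valued phenotypes are clamped to [0, 100]. Passing
tests therefore demonstrate the statistical machinery under a clean
generative model, not robustness to the full messiness of cohort data.

## Numerical choices

* Exact-test tie handling uses a relative tolerance of 1e-7 when comparing
  point probabilities to the observed one (the same convention as
  `stats::fisher.test`), in both the Fisher and Hardy-Weinberg tests.
* Degenerate 2x2 margins return p = 1 with a warning; a zero-variance
  regression fit returns its mean-difference beta with p = 1 and a
  warning; samples missing at every qualifying variant are excluded from
  carrier counts.
* MAF thresholds and all significance bounds are strict inequalities.
* The cohort MAF is used for set construction by default; an external
  (e.g. reference-panel) MAF can be supplied via `maf_override`.
* All simulation is seeded; a run is bit-identical under a fixed seed, and
  sub-generators use fixed offsets from the configured seed so each
  simulation stage is reproducible in isolation.

## Problem sizes in the test and acceptance suites

The suite checks the exact tests against exhaustive enumeration on every
2x2 table with N ≤ 60 and every Hardy-Weinberg configuration with ≤ 30
samples; null calibration of the burden scan over 200 simulated null
cohorts (200 genes, 100 cases / 100 controls); screen power over 200
replicates at planted carrier rates 12% vs 1% with 200 samples per arm;
phenotype-shift recovery (+30 units, SD 33, 92 cases) over 200 replicates;
and ten end-to-end default cascades. These sizes give Monte-Carlo errors
comfortably below the tolerances asserted while keeping the default run
desk-scale.

## Known limitations

* The burden test is carrier-based; it has no power against genes whose
  signal is variance-inflation rather than carrier enrichment
  (SKAT-style dispersion tests are out of scope).
* The raw-p screen with an OR floor is a triage device, not an inference:
  genes surviving it require the downstream evidence and phenotype stages,
  and still no family-wise guarantee is made.
* Odds ratios under the Haldane-Anscombe correction are conventional, and
  other zero-cell conventions (conditional MLE is available via
  `or_correction = "cmle"`) give different printed values for the same
  table; published odds ratios computed with an unknown convention should
  not be expected to reproduce exactly.
* Evidence mapping is exact-symbol matching after case-folding; genes
  published under aliases will be missed.
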