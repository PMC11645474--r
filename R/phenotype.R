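#' Carrier-versus-noncarrier phenotype regression
#'
#' Ordinary least squares of the phenotype on the carrier indicator with no
#' covariates, so the slope equals the carrier-minus-noncarrier mean
#' difference exactly; the p-value is the two-sided t-test on the slope.
#' A zero-residual-variance fit (identical values within both groups)
#' returns the mean-difference beta with `p = 1` and a warning.
#'
#' @param phenotype_values Numeric vector (missing allowed).
#' @param carrier_flags Logical vector aligned with `phenotype_values`.
#' @return List with `beta`, `p`, `n_carriers`, `n_noncarriers`.
#' @export
carrier_regression <- function(phenotype_values, carrier_flags) {
  ok <- !is.na(phenotype_values) & !is.na(carrier_flags)
  y <- phenotype_values[ok]
  x <- carrier_flags[ok]
  if (!any(x) || all(x)) {
    stop("need at least one carrier and one noncarrier with non-missing ",
         "phenotype")
  }
  fit <- stats::lm(y ~ x)
  # summary.lm warns separately on an exact fit; the p = 1 convention below
  # already covers that case
  sm <- suppressWarnings(summary(fit))$coefficients
  beta <- unname(sm["xTRUE", "Estimate"])
  p <- unname(sm["xTRUE", "Pr(>|t|)"])
  if (is.nan(p)) {
    warning("degenerate fit (zero residual variance); p set to 1")
    p <- 1
  }
  list(beta = beta, p = p, n_carriers = sum(x), n_noncarriers = sum(!x))
}

#' Scan candidate genes for carrier-phenotype associations within cases
#'
#' For each candidate gene, each SNV set in which it has qualifying
#' variants, and each quantitative phenotype, regresses the phenotype on
#' carrier status among case samples only. Cells whose preconditions fail
#' (no carrier or no noncarrier case with a non-missing phenotype) are
#' skipped and logged.
#'
#' @param candidate_genes Genes to scan (e.g. survivors of
#'   [evidence_filter()]).
#' @param gene_sets Membership data frame from [build_gene_sets()].
#' @param genotypes Sample x variant allele-count matrix.
#' @param phenotypes Data frame with `sample_id` and one numeric column per
#'   phenotype, or a numeric-only data frame in genotype row order.
#' @param case_mask Logical vector, one per genotype row: `TRUE` for cases.
#' @return Data frame (`gene`, `set`, `phenotype`, `beta`, `p`,
#'   `n_carriers`), with the skipped cells in attribute `skipped` and the
#'   number of tests in attribute `n_tests`.
#' @export
phenotype_scan <- function(candidate_genes, gene_sets, genotypes, phenotypes,
                           case_mask) {
  stopifnot(is.logical(case_mask), length(case_mask) == nrow(genotypes))
  ph <- phenotypes
  if ("sample_id" %in% names(ph)) {
    idx <- match(rownames(genotypes), ph$sample_id)
    if (anyNA(idx)) {
      stop("phenotype table lacks sample(s): ",
           paste(utils::head(rownames(genotypes)[is.na(idx)], 3),
                 collapse = ", "))
    }
    ph <- ph[idx, setdiff(names(ph), "sample_id"), drop = FALSE]
  }
  numeric_ph <- names(ph)[vapply(ph, is.numeric, logical(1L))]
  gs <- gene_sets[gene_sets$gene %in% candidate_genes, , drop = FALSE]
  cells <- unique(gs[, c("gene", "set")])
  cells <- cells[order(match(cells$gene, candidate_genes), cells$set), ,
                 drop = FALSE]
  case_geno <- genotypes[case_mask, , drop = FALSE]
  case_ph <- ph[case_mask, , drop = FALSE]

  rows <- list()
  skipped <- list()
  for (i in seq_len(nrow(cells))) {
    ids <- gs$variant_id[gs$gene == cells$gene[i] & gs$set == cells$set[i]]
    carrier <- carrier_status(case_geno, ids)
    for (pn in numeric_ph) {
      y <- case_ph[[pn]]
      ok <- !is.na(y) & !is.na(carrier)
      if (!any(carrier[ok]) || !any(!carrier[ok])) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          gene = cells$gene[i], set = cells$set[i], phenotype = pn,
          reason = if (!any(carrier[ok])) "no carrier with phenotype"
                   else "no noncarrier with phenotype",
          stringsAsFactors = FALSE)
        next
      }
      fit <- suppressWarnings(carrier_regression(y, carrier))
      rows[[length(rows) + 1L]] <- data.frame(
        gene = cells$gene[i], set = cells$set[i], phenotype = pn,
        beta = fit$beta, p = fit$p, n_carriers = fit$n_carriers,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), set = character(),
               phenotype = character(), beta = numeric(), p = numeric(),
               n_carriers = integer(), stringsAsFactors = FALSE)
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(gene = character(), set = character(),
               phenotype = character(), reason = character(),
               stringsAsFactors = FALSE)
  attr(out, "n_tests") <- nrow(out)
  out
}

#' Keep genes with any significant phenotype association
#'
#' @param results Scan results from [phenotype_scan()].
#' @param alpha Strict significance bound (default 0.05).
#' @return Character vector of surviving genes (first-appearance order).
#' @export
any_significant_filter <- function(results, alpha = 0.05) {
  unique(results$gene[results$p < alpha])
}

LIPID_TRAITS <- c("TC", "LDL_C", "TG", "HDL_C", "ApoA1", "ApoB", "ApoE",
                  "NHDL_C")

#' Lipid-pattern filter
#'
#' Keeps genes with at least one lipid-trait row that is significant and in
#' the configured direction (positive association by default), and reports
#' which traits drove inclusion.
#'
#' @param results Scan results from [phenotype_scan()].
#' @param traits Lipid phenotype names to consider.
#' @param direction `"positive"` (beta > 0) or `"negative"` (beta < 0).
#' @param alpha Strict significance bound.
#' @return Data frame (`gene`, `traits`) with traits comma-joined, one row
#'   per surviving gene.
#' @export
lipid_filter <- function(results, traits = LIPID_TRAITS,
                         direction = c("positive", "negative"),
                         alpha = 0.05) {
  direction <- match.arg(direction)
  hit <- results$phenotype %in% traits & results$p < alpha &
    (if (direction == "positive") results$beta > 0 else results$beta < 0)
  hits <- results[hit, , drop = FALSE]
  genes <- unique(hits$gene)
  data.frame(
    gene = genes,
    traits = vapply(genes, function(g) {
      paste(sort(unique(hits$phenotype[hits$gene == g])), collapse = ",")
    }, character(1L)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Thrombosis-pattern filter on coagulation times
#'
#' A gene is thrombosis-direction when, in at least one SNV set, both its
#' prothrombin-time and activated-partial-thromboplastin-time rows are
#' significant with negative betas (shortened clotting times). Genes whose
#' PT and APTT rows are both significant but positive are reported
#' separately as bleeding-direction — prolonged clotting carries no
#' thrombotic risk.
#'
#' @param results Scan results from [phenotype_scan()].
#' @param pt,aptt Phenotype names of the two coagulation times.
#' @param alpha Strict significance bound.
#' @return List with character vectors `thrombosis` and `bleeding`.
#' @export
thrombosis_filter <- function(results, pt = "PT", aptt = "APTT",
                              alpha = 0.05) {
  cells <- unique(results[, c("gene", "set")])
  thrombosis <- character()
  bleeding <- character()
  for (i in seq_len(nrow(cells))) {
    sub <- results[results$gene == cells$gene[i] &
                   results$set == cells$set[i], , drop = FALSE]
    r_pt <- sub[sub$phenotype == pt, , drop = FALSE]
    r_ap <- sub[sub$phenotype == aptt, , drop = FALSE]
    if (nrow(r_pt) != 1L || nrow(r_ap) != 1L) next
    both_sig <- r_pt$p < alpha && r_ap$p < alpha
    if (!both_sig) next
    if (r_pt$beta < 0 && r_ap$beta < 0) {
      thrombosis <- c(thrombosis, cells$gene[i])
    } else if (r_pt$beta > 0 && r_ap$beta > 0) {
      bleeding <- c(bleeding, cells$gene[i])
    }
  }
  list(thrombosis = unique(thrombosis), bleeding = unique(bleeding))
}

#' Inflammation-pattern filter
#'
#' Keeps genes where, within one SNV set, the anchor acute-phase marker
#' (CRP or fibrinogen) rises significantly in carriers together with the
#' leukocyte signature observed in the case cohort: higher white-cell
#' count, higher neutrophil percentage and lower monocyte percentage (all
#' strict `p < alpha`, signs as stated). Genes missing any required
#' phenotype row are skipped and logged.
#'
#' @param results Scan results from [phenotype_scan()].
#' @param anchor `"CRP"` or `"fibrinogen"` (any phenotype name present in
#'   the scan is accepted).
#' @param wbc,neutrophil,monocyte Phenotype names of the leukocyte rows.
#' @param alpha Strict significance bound.
#' @return Character vector of surviving genes, with skipped cells in
#'   attribute `skipped`.
#' @export
inflammation_filter <- function(results, anchor = c("CRP", "fibrinogen"),
                                wbc = "WBC", neutrophil = "neutrophil_pct",
                                monocyte = "monocyte_pct", alpha = 0.05) {
  anchor <- if (length(anchor) > 1L) match.arg(anchor) else anchor
  need <- c(anchor, wbc, neutrophil, monocyte)
  cells <- unique(results[, c("gene", "set")])
  kept <- character()
  skipped <- list()
  for (i in seq_len(nrow(cells))) {
    sub <- results[results$gene == cells$gene[i] &
                   results$set == cells$set[i], , drop = FALSE]
    row_of <- function(pn) sub[sub$phenotype == pn, , drop = FALSE]
    rows <- lapply(need, row_of)
    if (any(vapply(rows, nrow, integer(1L)) != 1L)) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        gene = cells$gene[i], set = cells$set[i],
        reason = "missing required phenotype row", stringsAsFactors = FALSE)
      next
    }
    sig <- vapply(rows, function(r) r$p < alpha, logical(1L))
    signs <- vapply(rows, function(r) r$beta, numeric(1L))
    if (all(sig) && signs[1] > 0 && signs[2] > 0 && signs[3] > 0 &&
        signs[4] < 0) {
      kept <- c(kept, cells$gene[i])
    }
  }
  out <- unique(kept)
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(gene = character(), set = character(), reason = character(),
               stringsAsFactors = FALSE)
  out
}

#' Case-versus-control cohort comparison
#'
#' Summarises every quantitative phenotype as mean (SD) per arm with a
#' two-sided Wilcoxon rank-sum p-value (exact when both arms have at most
#' 25 observations and no ties; tie-corrected normal approximation
#' otherwise), and every categorical flag as a percentage per arm with a
#' two-sided Fisher exact p-value.
#'
#' @param phenotypes Data frame with `sample_id` plus phenotype columns;
#'   logical or 0/1 columns listed in `categorical` are treated as flags.
#' @param labels Named character vector ("case"/"control") keyed by sample
#'   id, or unnamed in phenotype row order.
#' @param categorical Column names to treat as categorical flags.
#' @return Data frame: `phenotype`, `type`, `case_mean`/`case_sd` (for
#'   flags, the case percentage and `NA`), the control equivalents, `p`
#'   and `test`. All-missing phenotypes are omitted with a message.
#' @export
cohort_compare <- function(phenotypes, labels, categorical = character()) {
  ph <- phenotypes
  if ("sample_id" %in% names(ph)) {
    if (!is.null(names(labels))) {
      labels <- labels[ph$sample_id]
    }
    ph <- ph[, setdiff(names(ph), "sample_id"), drop = FALSE]
  }
  is_case <- labels == "case"
  if (sum(is_case) < 2L || sum(!is_case) < 2L) {
    stop("need at least two samples per arm")
  }
  rows <- list()
  for (pn in names(ph)) {
    x <- ph[[pn]]
    if (all(is.na(x))) {
      message("phenotype ", pn, " is all-missing; omitted")
      next
    }
    if (pn %in% categorical) {
      xx <- as.logical(x)
      a <- sum(xx & is_case, na.rm = TRUE)
      b <- sum(!xx & is_case, na.rm = TRUE)
      cc <- sum(xx & !is_case, na.rm = TRUE)
      d <- sum(!xx & !is_case, na.rm = TRUE)
      p <- suppressWarnings(fisher_two_sided(a, b, cc, d))
      rows[[length(rows) + 1L]] <- data.frame(
        phenotype = pn, type = "categorical",
        case_mean = 100 * a / (a + b), case_sd = NA_real_,
        control_mean = 100 * cc / (cc + d), control_sd = NA_real_,
        p = p, test = "fisher", stringsAsFactors = FALSE)
    } else {
      xc <- x[is_case & !is.na(x)]
      xk <- x[!is_case & !is.na(x)]
      exact <- length(xc) <= 25L && length(xk) <= 25L &&
        !any(duplicated(c(xc, xk)))
      p <- suppressWarnings(
        stats::wilcox.test(xc, xk, exact = exact, correct = TRUE)$p.value)
      rows[[length(rows) + 1L]] <- data.frame(
        phenotype = pn, type = "quantitative",
        case_mean = mean(xc), case_sd = stats::sd(xc),
        control_mean = mean(xk), control_sd = stats::sd(xk),
        p = p, test = if (exact) "wilcoxon_exact" else "wilcoxon_normal",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
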