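#' Per-sample carrier status over a set of qualifying variants
#'
#' A sample is a carrier when it has at least one minor allele at at least
#' one qualifying variant. Samples with missing genotypes at every
#' qualifying variant get `NA` and are excluded from downstream counts.
#'
#' @param genotypes Sample x variant allele-count matrix (0/1/2, `NA`
#'   missing) with variant ids as column names.
#' @param variant_ids Qualifying variant ids (must be columns of
#'   `genotypes`).
#' @return Logical vector, one entry per sample.
#' @export
carrier_status <- function(genotypes, variant_ids) {
  if (length(variant_ids) == 0L) {
    stop("empty qualifying variant list")
  }
  missing_ids <- setdiff(variant_ids, colnames(genotypes))
  if (length(missing_ids)) {
    stop("variant ids absent from genotype matrix: ",
         paste(utils::head(missing_ids, 3), collapse = ", "))
  }
  g <- genotypes[, variant_ids, drop = FALSE]
  n_obs <- rowSums(!is.na(g))
  carrier <- rowSums(g >= 1L, na.rm = TRUE) >= 1L
  carrier[n_obs == 0L] <- NA
  carrier
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Conditions on both margins: the p-value is the sum, over all tables with
#' the observed margins whose hypergeometric point probability does not
#' exceed that of the observed table (ties included), of those
#' probabilities.
#'
#' @param a,b,c,d Cell counts; rows are carrier/noncarrier, columns
#'   case/control (any orientation — the test is transpose-invariant).
#' @return A p-value in (0, 1]. Degenerate margins give 1 with a warning.
#' @export
fisher_two_sided <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (anyNA(cells) || any(cells < 0)) stop("cell counts must be >= 0")
  m <- a + b
  n <- c + d
  k <- a + c
  if (m == 0 || n == 0 || k == 0 || k == m + n) {
    warning("degenerate 2x2 margins; p = 1")
    return(1)
  }
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- probs[support == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Odds ratio of a 2x2 table
#'
#' Default estimator is the cross-product ratio `(a*d)/(b*c)`; when any
#' cell is zero the Haldane-Anscombe correction (0.5 added to every cell)
#' is applied so the estimate is finite. `correction = "none"` returns the
#' raw cross-product (possibly infinite); `"cmle"` returns the conditional
#' maximum-likelihood estimate from the noncentral hypergeometric model.
#'
#' @param a,b,c,d Cell counts (carrier cases, noncarrier cases, carrier
#'   controls, noncarrier controls).
#' @param correction One of `"haldane"`, `"none"`, `"cmle"`.
#' @return Odds ratio (>= 0, finite under the default correction).
#' @export
odds_ratio <- function(a, b, c, d, correction = c("haldane", "none", "cmle")) {
  correction <- match.arg(correction)
  if (any(c(a, b, c, d) < 0)) stop("cell counts must be >= 0")
  switch(correction,
    haldane = {
      if (any(c(a, b, c, d) == 0)) {
        ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
      } else (a * d) / (b * c)
    },
    none = (a * d) / (b * c),
    cmle = unname(stats::fisher.test(matrix(c(a, b, c, d), 2L,
                                            byrow = TRUE))$estimate)
  )
}

#' Collapsed minor allele frequency
#'
#' Default (`mode = "allele"`): total minor-allele count across the
#' qualifying variants and all non-missing samples, divided by the total
#' number of non-missing allele slots (two per sample per variant).
#' `mode = "carrier"` returns the carrier fraction instead.
#'
#' @inheritParams carrier_status
#' @param mode `"allele"` or `"carrier"`.
#' @return Frequency in \[0, 1\].
#' @export
collapsed_maf <- function(genotypes, variant_ids,
                          mode = c("allele", "carrier")) {
  mode <- match.arg(mode)
  if (length(variant_ids) == 0L) stop("empty qualifying variant list")
  g <- genotypes[, variant_ids, drop = FALSE]
  if (all(is.na(g))) stop("all genotypes missing; cMAF undefined")
  if (mode == "allele") {
    sum(g, na.rm = TRUE) / (2 * sum(!is.na(g)))
  } else {
    carrier <- carrier_status(genotypes, variant_ids)
    mean(carrier, na.rm = TRUE)
  }
}

#' Per-gene, per-set collapsing burden scan
#'
#' For every (gene, SNV set) cell with at least one qualifying variant,
#' collapses the cell's variants to per-sample carrier status (CAST-style
#' dominant coding), cross-tabulates carriers against the case/control
#' label, and computes the collapsed MAF, odds ratio and two-sided Fisher
#' exact p-value.
#'
#' @param gene_sets Gene-set membership data frame from
#'   [build_gene_sets()].
#' @param genotypes Sample x variant allele-count matrix.
#' @param labels Character vector ("case"/"control"), one per sample, in
#'   genotype row order.
#' @param or_correction Zero-cell handling for [odds_ratio()].
#' @param cmaf_mode Definition used by [collapsed_maf()].
#' @param coding `"carrier"` tests the carrier 2x2 table; `"allele"` tests
#'   the minor-allele count table (alleles as Bernoulli trials).
#' @return Data frame of class `gene_burden` with one row per (gene, set):
#'   carrier/noncarrier counts per arm, `cmaf`, `or_estimate`, `p`,
#'   `n_variants`; ordered by gene then set. The number of tests performed
#'   is attached as attribute `n_tests` (no multiple-testing correction is
#'   applied at this stage).
#' @export
burden_scan <- function(gene_sets, genotypes, labels,
                        or_correction = "haldane",
                        cmaf_mode = "allele",
                        coding = c("carrier", "allele")) {
  coding <- match.arg(coding)
  if (nrow(gene_sets) == 0L) {
    stop("gene_sets is empty")
  }
  is_case <- labels == "case"
  if (!any(is_case) || all(is_case)) {
    stop("labels must define at least one case and one control")
  }
  key <- paste(gene_sets$gene, gene_sets$set, sep = "\r")
  ids_by_cell <- split(gene_sets$variant_id, key)
  cell_keys <- sort(names(ids_by_cell))
  nc <- length(cell_keys)
  a <- b <- cc <- d <- nvar <- integer(nc)
  cmaf <- or <- p <- numeric(nc)
  col_idx <- match(gene_sets$variant_id, colnames(genotypes))
  idx_by_cell <- split(col_idx, key)
  for (i in seq_len(nc)) {
    ids <- idx_by_cell[[cell_keys[i]]]
    g <- genotypes[, ids, drop = FALSE]
    if (coding == "carrier") {
      n_obs <- rowSums(!is.na(g))
      carrier <- rowSums(g >= 1L, na.rm = TRUE) >= 1L
      carrier[n_obs == 0L] <- NA
      a[i] <- sum(carrier & is_case, na.rm = TRUE)
      b[i] <- sum(!carrier & is_case, na.rm = TRUE)
      cc[i] <- sum(carrier & !is_case, na.rm = TRUE)
      d[i] <- sum(!carrier & !is_case, na.rm = TRUE)
    } else {
      a[i] <- sum(g[is_case, ], na.rm = TRUE)
      b[i] <- 2L * sum(!is.na(g[is_case, ])) - a[i]
      cc[i] <- sum(g[!is_case, ], na.rm = TRUE)
      d[i] <- 2L * sum(!is.na(g[!is_case, ])) - cc[i]
    }
    p[i] <- if ((a[i] + cc[i]) == 0L) 1 else
      fisher_two_sided(a[i], b[i], cc[i], d[i])
    or[i] <- odds_ratio(a[i], b[i], cc[i], d[i], correction = or_correction)
    cmaf[i] <- if (cmaf_mode == "allele") {
      sum(g, na.rm = TRUE) / (2 * sum(!is.na(g)))
    } else {
      collapsed_maf(genotypes, colnames(genotypes)[ids], mode = "carrier")
    }
    nvar[i] <- length(ids)
  }
  parts <- strsplit(cell_keys, "\r", fixed = TRUE)
  out <- data.frame(
    gene = vapply(parts, `[`, "", 1L),
    set = vapply(parts, `[`, "", 2L),
    n_carrier_cases = a, n_noncarrier_cases = b,
    n_carrier_controls = cc, n_noncarrier_controls = d,
    cmaf = cmaf, or_estimate = or, p = p, n_variants = nvar,
    stringsAsFactors = FALSE)
  attr(out, "n_tests") <- nrow(out)
  class(out) <- c("gene_burden", "data.frame")
  out
}

#' Screen burden results on p-value and odds ratio
#'
#' Keeps rows with `p < p_max` and `or_estimate > or_min` (both strict),
#' and reports the deduplicated gene list: a gene survives when any of its
#' set-level rows survives.
#'
#' @param results Data frame from [burden_scan()] (or any data frame with
#'   `gene`, `or_estimate`, `p`).
#' @param p_max Strict p-value ceiling (default 0.05).
#' @param or_min Strict odds-ratio floor (default 3.5).
#' @return List with `rows` (the surviving result rows) and `genes` (unique
#'   surviving genes, in first-appearance order).
#' @export
threshold_screen <- function(results, p_max = 0.05, or_min = 3.5) {
  keep <- results$p < p_max & results$or_estimate > or_min
  rows <- results[keep, , drop = FALSE]
  list(rows = rows, genes = unique(rows$gene))
}
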