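new_evidence_tables <- function(glgc, cardiogram, mgi, gwas_catalog) {
  fold <- function(df) {
    df$gene <- toupper(df$gene)
    df
  }
  structure(list(
    glgc = fold(glgc),
    cardiogram = toupper(cardiogram$gene),
    mgi = fold(mgi),
    gwas_catalog = toupper(gwas_catalog$gene)
  ), class = "evidence_tables")
}

MGI_CATEGORIES <- c("cardiovascular", "adipose", "metabolism",
                    "endocrine/exocrine", "liver")

#' Load gene-evidence tables
#'
#' Reads the four TSV evidence sources: `glgc.tsv` (columns `gene`, `tc_p`,
#' `tg_p`, `ldl_p`, `hdl_p` — per-trait lipid association p-values, `NA`
#' when absent), `cardiogram.tsv` (`gene` — CAD-associated genes),
#' `mgi.tsv` (`gene`, `category` — mouse phenotype categories among
#' cardiovascular, adipose, metabolism, endocrine/exocrine, liver) and
#' `gwas_catalog.tsv` (`gene`). Gene symbols are matched case-insensitively
#' (stored upper-cased); a duplicated gene row wins last, with a warning.
#'
#' The package ships miniature synthetic fixtures of all four sources under
#' `system.file("extdata", "synthetic_evidence", package = "rarecascade")`;
#' point the paths at full database exports for real analyses.
#'
#' @param dir Directory containing the four files, or `NULL` when `paths`
#'   is given.
#' @param paths Named character vector/list overriding individual file
#'   paths (`glgc`, `cardiogram`, `mgi`, `gwas_catalog`).
#' @return An object of class `evidence_tables`.
#' @export
load_evidence <- function(dir = NULL, paths = NULL) {
  files <- c(glgc = "glgc.tsv", cardiogram = "cardiogram.tsv",
             mgi = "mgi.tsv", gwas_catalog = "gwas_catalog.tsv")
  p <- if (!is.null(dir)) stats::setNames(file.path(dir, files), names(files))
       else character(0)
  if (!is.null(paths)) p[names(paths)] <- unlist(paths)
  missing_src <- setdiff(names(files), names(p))
  if (length(missing_src)) {
    stop("no path for evidence source(s): ",
         paste(missing_src, collapse = ", "))
  }
  for (f in p) if (!file.exists(f)) stop("no such evidence file: ", f)

  check_cols <- function(df, need, file) {
    missing_cols <- setdiff(need, names(df))
    if (length(missing_cols)) {
      stop("malformed evidence header in ", file, ": missing column(s) ",
           paste(missing_cols, collapse = ", "))
    }
    df
  }
  dedupe <- function(df, file) {
    if (anyDuplicated(toupper(df$gene))) {
      warning("duplicate gene rows in ", file, "; keeping the last")
      df <- df[!duplicated(toupper(df$gene), fromLast = TRUE), , drop = FALSE]
    }
    df
  }
  glgc <- dedupe(check_cols(read_tsv(p[["glgc"]]),
                            c("gene", "tc_p", "tg_p", "ldl_p", "hdl_p"),
                            p[["glgc"]]), p[["glgc"]])
  cardiogram <- dedupe(check_cols(read_tsv(p[["cardiogram"]]), "gene",
                                  p[["cardiogram"]]), p[["cardiogram"]])
  mgi <- check_cols(read_tsv(p[["mgi"]]), c("gene", "category"), p[["mgi"]])
  bad <- setdiff(unique(mgi$category), MGI_CATEGORIES)
  if (length(bad)) {
    stop("unknown MGI category in ", p[["mgi"]], ": ",
         paste(bad, collapse = ", "))
  }
  gwas <- dedupe(check_cols(read_tsv(p[["gwas_catalog"]]), "gene",
                            p[["gwas_catalog"]]), p[["gwas_catalog"]])
  new_evidence_tables(glgc, cardiogram, mgi, gwas)
}

#' Filter screened genes on database evidence
#'
#' Keeps genes with evidence in at least one of the required sources
#' (by default the GLGC lipid associations, the CAD GWAS consortium list,
#' and the mouse phenotype categories — the GWAS-catalog flag is recorded
#' as annotation only). GLGC evidence means any of the four lipid-trait
#' p-values is present; MGI evidence means any of the five categories.
#'
#' @param genes Character vector of gene symbols (e.g. from
#'   [threshold_screen()]).
#' @param evidence An `evidence_tables` object from [load_evidence()].
#' @param require Sources whose union a gene must hit to survive.
#' @return Data frame, order-preserving subset of `genes`, with per-source
#'   logical provenance flags (`glgc`, `cardiogram`, `mgi`,
#'   `gwas_catalog`), the matched `mgi_categories` (comma-joined), and
#'   `all_four` marking genes present in every source.
#' @export
evidence_filter <- function(genes, evidence,
                            require = c("glgc", "cardiogram", "mgi")) {
  stopifnot(inherits(evidence, "evidence_tables"))
  require <- match.arg(require, c("glgc", "cardiogram", "mgi",
                                  "gwas_catalog"), several.ok = TRUE)
  key <- toupper(genes)
  glgc_hit <- vapply(key, function(g) {
    row <- evidence$glgc[evidence$glgc$gene == g, , drop = FALSE]
    nrow(row) > 0 && any(!is.na(unlist(row[c("tc_p", "tg_p", "ldl_p",
                                             "hdl_p")])))
  }, logical(1L))
  mgi_cats <- vapply(key, function(g) {
    paste(sort(unique(evidence$mgi$category[evidence$mgi$gene == g])),
          collapse = ",")
  }, character(1L))
  flags <- data.frame(
    gene = genes,
    glgc = unname(glgc_hit),
    cardiogram = key %in% evidence$cardiogram,
    mgi = nzchar(mgi_cats),
    gwas_catalog = key %in% evidence$gwas_catalog,
    mgi_categories = unname(mgi_cats),
    stringsAsFactors = FALSE)
  flags$all_four <- flags$glgc & flags$cardiogram & flags$mgi &
    flags$gwas_catalog
  keep <- rowSums(as.matrix(flags[require])) > 0
  out <- flags[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
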