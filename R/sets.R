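SET_LABELS <- c("nonsynonymous", "polyphen", "broad", "strict", "disruptive")

DELETERIOUS_CALLS <- c("deleterious", "possibly_damaging",
                       "probably_damaging")

is_deleterious_call <- function(x) {
  !is.na(x) & x %in% DELETERIOUS_CALLS
}

# vectorised membership over an annotation data frame; returns a logical
# matrix with one column per set label
classify_matrix <- function(annotations) {
  cls <- annotations$functional_class
  known <- c(FUNCTIONAL_CLASSES, "other")
  bad <- setdiff(unique(cls), known)
  if (length(bad)) {
    stop("unknown functional_class: ", paste(bad, collapse = ", "))
  }
  del <- vapply(PREDICTORS, function(p) is_deleterious_call(annotations[[p]]),
                logical(nrow(annotations)))
  if (is.null(dim(del))) {
    del <- matrix(del, nrow = 1L, dimnames = list(NULL, PREDICTORS))
  }
  n_del <- rowSums(del)
  missense <- cls == "missense"
  disruptive <- cls %in% DISRUPTIVE_CLASSES
  cbind(
    nonsynonymous = missense | disruptive,
    polyphen = disruptive | (missense & del[, "polyphen_humdiv"]),
    broad = disruptive | (missense & n_del >= 1L),
    strict = disruptive | (missense & n_del == length(PREDICTORS)),
    disruptive = disruptive
  )
}

#' Classify one annotated variant into qualifying SNV sets
#'
#' The five sets: *nonsynonymous* (missense, nonsense, splice, frameshift
#' indel); *polyphen* (disruptive variants, plus missense called possibly
#' or probably damaging by PolyPhen-2 HumDiv); *broad* (disruptive, plus
#' missense called deleterious by at least one of the five predictors);
#' *strict* (disruptive, plus missense called deleterious by all five —
#' a missing call counts as not deleterious); *disruptive* (nonsense,
#' splice-site, frameshift indel only). Synonymous variants belong to no
#' set; predictor calls are ignored for non-missense classes.
#'
#' @param a A one-row data frame or named list with `functional_class` and
#'   the five predictor columns
#'   (`r paste(PREDICTORS, collapse = ", ")`).
#' @return Character vector of set labels the variant belongs to (possibly
#'   empty).
#' @export
classify_variant <- function(a) {
  df <- as.data.frame(as.list(a)[c("functional_class", PREDICTORS)],
                      stringsAsFactors = FALSE)
  m <- classify_matrix(df)
  SET_LABELS[m[1, SET_LABELS]]
}

#' Group qualifying variants by gene and SNV set
#'
#' Restricts annotations to QC-retained variants that are rare
#' (MAF strictly below `maf_threshold`), classifies each into the five
#' sets, and returns the long-format gene-set membership.
#'
#' @param annotations Annotation data frame (`variant_id`, `gene`,
#'   `functional_class`, five predictor columns, `maf`).
#' @param retained_ids Character vector of QC-retained variant ids.
#' @param maf_threshold Strict upper bound on MAF (default 0.05).
#' @param maf_override Optional named numeric vector of MAFs (e.g. from a
#'   reference panel) used instead of the annotation `maf` column.
#' @return Data frame (`gene`, `set`, `variant_id`), one row per
#'   qualifying variant per set it belongs to, ordered by gene then set.
#' @export
build_gene_sets <- function(annotations, retained_ids, maf_threshold = 0.05,
                            maf_override = NULL) {
  if (anyDuplicated(annotations$variant_id)) {
    stop("duplicate variant_id in annotations")
  }
  if (!all(retained_ids %in% annotations$variant_id)) {
    stop("retained_ids contains ids absent from annotations")
  }
  maf <- annotations$maf
  if (!is.null(maf_override)) {
    maf <- unname(maf_override[annotations$variant_id])
  }
  keep <- annotations$variant_id %in% retained_ids &
    !is.na(maf) & maf < maf_threshold
  ann <- annotations[keep, , drop = FALSE]
  if (nrow(ann) == 0L) {
    return(data.frame(gene = character(), set = character(),
                      variant_id = character(), stringsAsFactors = FALSE))
  }
  m <- classify_matrix(ann)
  out <- do.call(rbind, lapply(SET_LABELS, function(s) {
    idx <- which(m[, s])
    data.frame(gene = ann$gene[idx], set = rep(s, length(idx)),
               variant_id = ann$variant_id[idx], stringsAsFactors = FALSE)
  }))
  out[order(out$gene, out$set, out$variant_id), , drop = FALSE]
}
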