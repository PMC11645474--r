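#' Variant container
#'
#' A columnar set of bi-allelic called sites: per-variant metadata and
#' aligned per-sample matrices. This is the object [read_vcf()] returns and
#' [apply_qc()] filters.
#'
#' @param meta Data frame with one row per variant: `variant_id`, `chrom`,
#'   `pos` (1-based), `ref`, `alt`, `mq` (site mapping quality) and strand
#'   counts `sb_ref_fwd`, `sb_ref_rev`, `sb_alt_fwd`, `sb_alt_rev`.
#' @param genotypes Sample x variant matrix of minor-allele counts
#'   (0/1/2, `NA` for missing).
#' @param depth,ad_ref,ad_alt Sample x variant matrices of total read
#'   depth and ref/alt allele depths.
#' @return An object of class `variant_set`.
#' @export
variant_set <- function(meta, genotypes, depth, ad_ref, ad_alt) {
  stopifnot(is.data.frame(meta), nrow(meta) == ncol(genotypes))
  need <- c("variant_id", "chrom", "pos", "ref", "alt", "mq",
            "sb_ref_fwd", "sb_ref_rev", "sb_alt_fwd", "sb_alt_rev")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols)) {
    stop("variant_set meta lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(meta$variant_id)) stop("duplicate variant_id")
  if (any(meta$pos < 1)) stop("positions must be >= 1 (1-based)")
  colnames(genotypes) <- meta$variant_id
  colnames(depth) <- meta$variant_id
  colnames(ad_ref) <- meta$variant_id
  colnames(ad_alt) <- meta$variant_id
  structure(list(meta = meta, genotypes = genotypes, depth = depth,
                 ad_ref = ad_ref, ad_alt = ad_alt),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat("variant_set:", nrow(x$meta), "variants x", nrow(x$genotypes),
      "samples\n")
  invisible(x)
}

# subset a variant_set by variant index or id
subset_variants <- function(vs, keep) {
  if (is.character(keep)) keep <- match(keep, vs$meta$variant_id)
  variant_set(vs$meta[keep, , drop = FALSE],
              vs$genotypes[, keep, drop = FALSE],
              vs$depth[, keep, drop = FALSE],
              vs$ad_ref[, keep, drop = FALSE],
              vs$ad_alt[, keep, drop = FALSE])
}

#' Write a variant set as VCF v4.2
#'
#' One bi-allelic record per variant with FORMAT fields GT, DP, AD, INFO
#' fields MQ and SB (four comma-separated strand counts:
#' ref-fwd, ref-rev, alt-fwd, alt-rev).
#'
#' @param vs A [variant_set()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(vs, path) {
  stopifnot(inherits(vs, "variant_set"))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=rarecascade",
    paste0("##INFO=<ID=MQ,Number=1,Type=Float,",
           "Description=\"Site mapping quality\">"),
    paste0("##INFO=<ID=SB,Number=4,Type=Integer,Description=\"Strand ",
           "counts: ref-fwd,ref-rev,alt-fwd,alt-rev\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
           "Description=\"Allele depths\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(vs$genotypes)), collapse = "\t"))
  m <- vs$meta
  nv <- nrow(m)
  if (nv == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", nrow(vs$genotypes), nv)
  ok <- !is.na(vs$genotypes)
  gt[ok] <- gt_code[as.character(vs$genotypes[ok])]
  field <- matrix(paste0(gt, ":", vs$depth, ":", vs$ad_ref, ",", vs$ad_alt),
                  nrow(vs$genotypes), nv)
  info <- sprintf("MQ=%g;SB=%d,%d,%d,%d", m$mq,
                  as.integer(m$sb_ref_fwd), as.integer(m$sb_ref_rev),
                  as.integer(m$sb_alt_fwd), as.integer(m$sb_alt_rev))
  body <- paste(m$chrom, m$pos, m$variant_id, m$ref, m$alt, ".", "PASS",
                info, "GT:DP:AD",
                apply(field, 2, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a multi-sample VCF into a variant set
#'
#' Parses VCF v4.2 via the vcfR reader. Multi-allelic records are split
#' into one bi-allelic record per alternate allele: the genotype counts
#' that allele, AD keeps the reference depth and that allele's depth, and
#' the split records get ids suffixed `_alt<k>`. Missing genotypes (`./.`)
#' are preserved as `NA`; non-diploid genotypes are an error.
#'
#' @param path Path to a VCF file.
#' @return A [variant_set()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  nv <- nrow(fix)
  samples <- colnames(vcf@gt)[-1]
  ns <- length(samples)
  empty <- function() matrix(NA_integer_, ns, 0L,
                             dimnames = list(samples, NULL))
  if (nv == 0L) {
    meta <- data.frame(variant_id = character(), chrom = character(),
                       pos = integer(), ref = character(), alt = character(),
                       mq = numeric(), sb_ref_fwd = integer(),
                       sb_ref_rev = integer(), sb_alt_fwd = integer(),
                       sb_alt_rev = integer(), stringsAsFactors = FALSE)
    return(variant_set(meta, empty(), empty(), empty(), empty()))
  }

  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  dp_raw <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
  ad_raw <- vcfR::extract.gt(vcf, element = "AD")
  mq <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "MQ")))
  sb_raw <- vcfR::extract.info(vcf, "SB")

  parse_sb <- function(x) {
    if (is.na(x)) return(rep(NA_integer_, 4L))
    as.integer(strsplit(x, ",", fixed = TRUE)[[1]])
  }
  sb <- t(vapply(sb_raw, parse_sb, integer(4L)))

  out_meta <- vector("list", nv)
  out_gt <- out_dp <- out_adr <- out_ada <- vector("list", nv)
  for (i in seq_len(nv)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    n_alt <- length(alts)
    gts <- gt_raw[i, ]
    alleles <- strsplit(gts, "[/|]")
    bad <- !is.na(gts) & lengths(alleles) != 2L
    if (any(bad)) {
      stop("non-diploid genotype at ", fix[i, "CHROM"], ":", fix[i, "POS"],
           " (", gts[which(bad)[1]], ")")
    }
    ad_parts <- lapply(ad_raw[i, ], function(x) {
      if (is.na(x)) return(rep(NA_integer_, n_alt + 1L))
      as.integer(strsplit(x, ",", fixed = TRUE)[[1]])
    })
    vid <- fix[i, "ID"]
    if (is.na(vid) || vid == ".") {
      vid <- paste0(fix[i, "CHROM"], ":", fix[i, "POS"])
    }
    rows <- vector("list", n_alt)
    gmat <- matrix(NA_integer_, ns, n_alt)
    amat <- matrix(NA_integer_, ns, n_alt)
    for (k in seq_len(n_alt)) {
      cnt <- vapply(alleles, function(al) {
        if (is.null(al) || anyNA(al) || any(al == ".")) return(NA_integer_)
        sum(al == as.character(k))
      }, integer(1L))
      gmat[, k] <- cnt
      amat[, k] <- vapply(ad_parts, function(x) x[k + 1L], integer(1L))
      rows[[k]] <- data.frame(
        variant_id = if (n_alt == 1L) vid else paste0(vid, "_alt", k),
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alts[k],
        mq = mq[i],
        sb_ref_fwd = sb[i, 1], sb_ref_rev = sb[i, 2],
        sb_alt_fwd = sb[i, 3], sb_alt_rev = sb[i, 4],
        stringsAsFactors = FALSE)
    }
    out_meta[[i]] <- do.call(rbind, rows)
    out_gt[[i]] <- gmat
    out_dp[[i]] <- matrix(as.integer(dp_raw[i, ]), ns, n_alt)
    out_adr[[i]] <- matrix(vapply(ad_parts, function(x) x[1L], integer(1L)),
                           ns, n_alt)
    out_ada[[i]] <- amat
  }
  meta <- do.call(rbind, out_meta)
  rownames(meta) <- NULL
  bind <- function(l) {
    m <- do.call(cbind, l)
    rownames(m) <- samples
    m
  }
  variant_set(meta, bind(out_gt), bind(out_dp), bind(out_adr), bind(out_ada))
}
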