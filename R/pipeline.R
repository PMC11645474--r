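#' Fraction of screened patients free of conventional risk factors
#'
#' @param n_included Patients with none of the defined conventional risk
#'   factors who entered the study.
#' @param n_screened Patients screened.
#' @return Percentage (0-100).
#' @export
screened_fraction <- function(n_included, n_screened) {
  n_included <- assert_count(n_included, "n_included")
  n_screened <- assert_count(n_screened, "n_screened", min = 1L)
  if (n_included > n_screened) stop_config("n_included > n_screened")
  100 * n_included / n_screened
}

#' Default pipeline configuration
#'
#' A fully resolved configuration for [run_pipeline()] running on a
#' simulated cohort with one planted lipid gene (G0001: LDL-C carrier shift
#' of +73.87 mg/dL) and one planted inflammation gene (G0002: fibrinogen
#' +9.94 g/L, WBC +4.91 x10^9/L, neutrophils +16.9 points, monocytes
#' -5.17 points), both with carrier probability 0.12 in cases versus 0.01
#' in controls. Every threshold of the cascade is a named key and can be
#' overridden.
#'
#' @param out_dir Directory the pipeline writes its stage outputs to.
#' @param seed Integer seed governing all randomness.
#' @return Named list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(out_dir = tempfile("cascade_"),
                                    seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    simulate = list(
      n_cases = 92L, n_controls = 102L, n_genes = 200L,
      variants_per_gene = 8L,
      planted_burden_genes = data.frame(
        gene = c("G0001", "G0002"),
        case_prob = c(0.12, 0.12),
        control_prob = c(0.01, 0.01),
        stringsAsFactors = FALSE),
      planted_phenotype_effects = data.frame(
        gene = c("G0001", "G0002", "G0002", "G0002", "G0002"),
        phenotype = c("LDL_C", "fibrinogen", "WBC", "neutrophil_pct",
                      "monocyte_pct"),
        shift = c(73.87, 9.94, 4.91, 16.9, -5.17),
        stringsAsFactors = FALSE)),
    inputs = NULL,
    qc = list(),
    maf_threshold = 0.05,
    p_max = 0.05,
    or_min = 3.5,
    alpha = 0.05,
    or_correction = "haldane",
    cmaf_mode = "allele",
    coding = "carrier",
    evidence_require = c("glgc", "cardiogram", "mgi"),
    lipid_direction = "positive",
    inflammation_anchors = c("CRP", "fibrinogen")
  ), class = "pipeline_config")
}

# accept a list, a pipeline_config, or a YAML file path
resolve_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("no such config file: ", config)
    config <- yaml::read_yaml(config)
    for (key in c("planted_burden_genes", "planted_phenotype_effects")) {
      if (!is.null(config$simulate[[key]])) {
        config$simulate[[key]] <-
          do.call(rbind, lapply(config$simulate[[key]], as.data.frame))
      }
    }
  }
  base <- default_pipeline_config()
  if (!is.null(config$simulate)) base$simulate <- config$simulate
  for (key in setdiff(names(config), "simulate")) base[[key]] <- config[[key]]
  base
}

#' Run the full gene-discovery cascade
#'
#' Executes, in order: cohort simulation (or ingestion of the configured
#' input files), site-level QC, qualifying-set construction, the per-gene
#' collapsing burden test, the p/odds-ratio screen, database evidence
#' mapping, the case-only carrier-phenotype scan with its significance
#' filter, and the lipid / thrombosis / inflammation pathway-pattern
#' filters. Every intermediate is written to `out_dir` as TSV (the retained
#' variants as VCF) and the run is deterministic given the seed.
#'
#' @param config A list, `pipeline_config`, or path to a YAML file; see
#'   [default_pipeline_config()] for the keys. When `config$inputs` is set
#'   (paths `vcf`, `annotations`, `phenotypes`, `labels`, `evidence_dir`)
#'   those files are ingested instead of simulating.
#' @return A `cascade_report`: the stage-count ledger (`stage_counts`),
#'   stage output paths (`stage_tables`), per-stage gene lists (`genes`),
#'   key result tables, the resolved configuration and the seed.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  cfg <- resolve_config(config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  t0 <- Sys.time()
  say <- function(...) message("[cascade] ", ...)

  if (is.null(cfg$inputs)) {
    say("simulating cohort (seed ", cfg$seed, ")")
    sim_args <- cfg$simulate
    sim_args$seed <- cfg$seed
    sc <- do.call(sim_config, sim_args)
    cohort <- simulate_cohort(sc)
    cohort_dir <- file.path(out_dir, "cohort")
    write_cohort(cohort, cohort_dir)
    evidence <- simulate_evidence(cohort, seed = cfg$seed + 4L)
    ev_dir <- file.path(cohort_dir, "evidence")
    write_evidence(evidence, ev_dir)
    variants <- cohort$variants
    annotations <- cohort$annotations
    phenotypes <- cohort$phenotypes
    labels <- cohort$labels
  } else {
    inp <- cfg$inputs
    for (f in c("vcf", "annotations", "phenotypes", "labels")) {
      if (is.null(inp[[f]]) || !file.exists(inp[[f]])) {
        stop("stage ingest: missing input '", f, "'")
      }
    }
    variants <- read_vcf(inp$vcf)
    annotations <- read_tsv(inp$annotations)
    phenotypes <- read_tsv(inp$phenotypes)
    lab <- read_tsv(inp$labels)
    labels <- stats::setNames(lab$status, lab$sample_id)
    evidence <- load_evidence(inp$evidence_dir)
    bad <- setdiff(rownames(variants$genotypes), phenotypes$sample_id)
    bad <- union(bad, setdiff(rownames(variants$genotypes), names(labels)))
    if (length(bad)) {
      stop("stage ingest: samples absent from phenotype/label tables: ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  labels <- labels[rownames(variants$genotypes)]
  control_mask <- labels == "control"
  case_mask <- labels == "case"
  genes_of <- function(ids) {
    unique(annotations$gene[annotations$variant_id %in% ids])
  }

  ledger <- list()
  note <- function(stage, genes_in, genes_out) {
    ledger[[length(ledger) + 1L]] <<- data.frame(
      stage = stage, genes_in = length(genes_in),
      genes_out = length(genes_out), stringsAsFactors = FALSE)
    say(stage, ": ", length(genes_in), " -> ", length(genes_out), " genes")
  }
  emit <- function(df, name) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    write_tsv(df, path)
    paths[[name]] <<- path
    path
  }

  # --- QC ------------------------------------------------------------
  th <- do.call(qc_thresholds, cfg$qc)
  qc <- apply_qc(variants, th, control_mask)
  genes_pre <- genes_of(variants$meta$variant_id)
  genes_qc <- genes_of(qc$retained$meta$variant_id)
  note("qc", genes_pre, genes_qc)
  write_vcf(qc$retained, file.path(out_dir, "qc_retained.vcf"))
  paths[["qc_retained_vcf"]] <- file.path(out_dir, "qc_retained.vcf")
  emit(qc$log, "qc_log")

  # --- qualifying sets ------------------------------------------------
  gene_sets <- build_gene_sets(annotations, qc$retained$meta$variant_id,
                               maf_threshold = cfg$maf_threshold)
  genes_sets <- unique(gene_sets$gene)
  note("sets", genes_qc, genes_sets)
  emit(gene_sets, "gene_sets")

  # --- burden test + screen -------------------------------------------
  burden <- burden_scan(gene_sets, variants$genotypes, labels,
                        or_correction = cfg$or_correction,
                        cmaf_mode = cfg$cmaf_mode, coding = cfg$coding)
  note("burden", genes_sets, unique(burden$gene))
  emit(burden, "burden")
  screen <- threshold_screen(burden, p_max = cfg$p_max, or_min = cfg$or_min)
  note("screen", unique(burden$gene), screen$genes)
  emit(screen$rows, "screen")

  # --- evidence mapping -----------------------------------------------
  ev <- evidence_filter(screen$genes, evidence, require = cfg$evidence_require)
  note("evidence", screen$genes, ev$gene)
  emit(ev, "evidence")

  # --- carrier-phenotype scan -----------------------------------------
  scan <- phenotype_scan(ev$gene, gene_sets, variants$genotypes, phenotypes,
                         case_mask)
  sig_genes <- any_significant_filter(scan, alpha = cfg$alpha)
  note("phenotype_significant", ev$gene, sig_genes)
  emit(scan, "phenotype_scan")
  scan_sig <- scan[scan$gene %in% sig_genes, , drop = FALSE]

  # --- pathway-pattern filters ----------------------------------------
  lipid <- lipid_filter(scan_sig, direction = cfg$lipid_direction,
                        alpha = cfg$alpha)
  thromb <- thrombosis_filter(scan_sig, alpha = cfg$alpha)
  inflam_by_anchor <- lapply(cfg$inflammation_anchors, function(anch) {
    inflammation_filter(scan_sig, anchor = anch, alpha = cfg$alpha)
  })
  names(inflam_by_anchor) <- cfg$inflammation_anchors
  inflam_genes <- unique(unlist(lapply(inflam_by_anchor, as.character)))
  pathway_genes <- unique(c(lipid$gene, thromb$thrombosis, inflam_genes))
  note("pathway", sig_genes, pathway_genes)
  emit(lipid, "lipid_genes")
  emit(data.frame(gene = thromb$thrombosis, stringsAsFactors = FALSE),
       "thrombosis_genes")
  emit(data.frame(gene = thromb$bleeding, stringsAsFactors = FALSE),
       "bleeding_genes")
  inflam_df <- do.call(rbind, lapply(names(inflam_by_anchor), function(anch) {
    g <- as.character(inflam_by_anchor[[anch]])
    if (!length(g)) return(NULL)
    data.frame(anchor = anch, gene = g, stringsAsFactors = FALSE)
  }))
  if (is.null(inflam_df)) {
    inflam_df <- data.frame(anchor = character(), gene = character(),
                            stringsAsFactors = FALSE)
  }
  emit(inflam_df, "inflammation_genes")

  # --- cohort comparison ----------------------------------------------
  compare <- cohort_compare(phenotypes, labels)
  emit(compare, "cohort_comparison")

  stage_counts <- do.call(rbind, ledger)
  emit(stage_counts, "stage_counts")

  summary_path <- file.path(out_dir, "run_summary.txt")
  writeLines(c(
    paste0("seed\t", cfg$seed),
    paste0("n_burden_tests\t", attr(burden, "n_tests")),
    paste0("n_phenotype_tests\t", attr(scan, "n_tests")),
    paste0(stage_counts$stage, "\t", stage_counts$genes_in, "\t",
           stage_counts$genes_out),
    paste0("elapsed_s\t",
           round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2))
  ), summary_path)
  paths[["run_summary"]] <- summary_path

  structure(list(
    stage_counts = stage_counts,
    stage_tables = paths,
    genes = list(qc = genes_qc, sets = genes_sets, screen = screen$genes,
                 evidence = ev$gene, significant = sig_genes,
                 lipid = lipid$gene, thrombosis = thromb$thrombosis,
                 bleeding = thromb$bleeding, inflammation = inflam_genes),
    burden = burden, screen = screen, evidence = ev, phenotype_scan = scan,
    lipid = lipid, inflammation = inflam_by_anchor,
    cohort_comparison = compare,
    config_echo = cfg, seed = cfg$seed
  ), class = "cascade_report")
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("cascade_report (seed ", x$seed, ")\n", sep = "")
  print(x$stage_counts, row.names = FALSE)
  cat("final pathway genes:\n")
  cat("  lipid:", paste(x$genes$lipid, collapse = ", "), "\n")
  cat("  thrombosis:", paste(x$genes$thrombosis, collapse = ", "), "\n")
  cat("  inflammation:", paste(x$genes$inflammation, collapse = ", "), "\n")
  invisible(x)
}

#' Write evidence tables as TSV
#'
#' Inverse of [load_evidence()]; used by the simulator and pipeline.
#'
#' @param evidence An `evidence_tables` object.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_evidence <- function(evidence, dir) {
  stopifnot(inherits(evidence, "evidence_tables"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(evidence$glgc, file.path(dir, "glgc.tsv"))
  write_tsv(data.frame(gene = evidence$cardiogram),
            file.path(dir, "cardiogram.tsv"))
  write_tsv(evidence$mgi, file.path(dir, "mgi.tsv"))
  write_tsv(data.frame(gene = evidence$gwas_catalog),
            file.path(dir, "gwas_catalog.tsv"))
  invisible(dir)
}

#' Simulate a cohort and write it to disk
#'
#' Thin wrapper combining [simulate_cohort()], [simulate_evidence()] and
#' [write_cohort()]: the file-producing counterpart of [run_pipeline()]'s
#' simulation stage.
#'
#' @param config A [sim_config()], or a list of `sim_config` arguments, or
#'   a YAML file path with those keys.
#' @param out_dir Output directory.
#' @return Invisibly, the named vector of written paths.
#' @export
simulate_command <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
    for (key in c("planted_burden_genes", "planted_phenotype_effects")) {
      if (!is.null(config[[key]])) {
        config[[key]] <- do.call(rbind, lapply(config[[key]], as.data.frame))
      }
    }
  }
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  cohort <- simulate_cohort(config)
  paths <- write_cohort(cohort, out_dir)
  evidence <- simulate_evidence(cohort, seed = config$seed + 4L)
  write_evidence(evidence, file.path(out_dir, "evidence"))
  invisible(paths)
}
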