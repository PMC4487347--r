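#' Configure an end-to-end pipeline run
#'
#' Collects the file paths, focus and thresholds for [run_pipeline()]. The
#' reference directory must contain `genes.genepred` and the seven evidence
#' TSVs (see [read_evidence_tables()]). The primary (scored) variant set is
#' the MuTect call-stats file when given, otherwise the first target VCF.
#' Input files are checked by the stage that consumes them, so a failure is
#' reported against the stage it belongs to.
#'
#' @param ref_dir Reference directory.
#' @param vep Path to the VEP default-format output for the coding variants.
#' @param out_dir Output directory for the stage TSVs and the report.
#' @param control_vcfs Character vector of control-sample VCF paths; with
#'   two or more, their annotated coding sets are intersected into a
#'   pseudo-germline set.
#' @param target_vcfs Character vector of target-sample VCF paths.
#' @param mutect Optional MuTect call-stats path.
#' @param focus A [focus_config()].
#' @param thresholds A [filter_thresholds()].
#' @param damage_mode Passed to [result_table()].
#' @param normalize_chrom Passed to the variant readers.
#' @return A list of class `eva_run_config`.
#' @export
run_config <- function(ref_dir, vep, out_dir,
                       control_vcfs = character(),
                       target_vcfs = character(),
                       mutect = NULL,
                       focus = leukemia_focus(),
                       thresholds = filter_thresholds(),
                       damage_mode = "all",
                       normalize_chrom = "none") {
  stopifnot(inherits(focus, "eva_focus"), inherits(thresholds, "eva_thresholds"))
  if (!dir.exists(ref_dir)) {
    abort(paste0("reference directory not found: ", ref_dir))
  }
  if (is.null(mutect) && length(target_vcfs) == 0L) {
    abort("need a primary variant set: pass mutect or at least one target VCF")
  }
  structure(
    list(
      ref_dir = ref_dir, vep = vep, out_dir = out_dir,
      control_vcfs = control_vcfs, target_vcfs = target_vcfs,
      mutect = mutect, focus = focus, thresholds = thresholds,
      damage_mode = damage_mode, normalize_chrom = normalize_chrom
    ),
    class = "eva_run_config"
  )
}

eva_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("stage ", name, " failed: ", conditionMessage(e)))
  })
}

#' Run the full annotation, scoring and reporting pipeline
#'
#' Executes refdata loading, variant reading, gene annotation, coding
#' selection, (with two or more controls) pseudo-germline intersection,
#' pileup export, VEP-output enrichment, scoring/ranking, filtering and
#' report rendering. Every stage materializes its output as a TSV under
#' `config$out_dir`, so intermediate results are inspectable and the stages
#' are independently reusable; per-stage input/output counts are logged as
#' messages. A stage failure raises an error naming the stage.
#'
#' @param config An [run_config()] object.
#' @param dry_run Validate the configuration and input files, touch nothing,
#'   return `TRUE` invisibly.
#' @return Invisibly, a list with `scored` (ranked [rank_variants()] tibble),
#'   `table` (filtered [result_table()]), `heatmap` ([heatmap_matrix()]),
#'   `germline` (intersection tibble or `NULL`) and `paths` of the written
#'   files.
#' @export
run_pipeline <- function(config, dry_run = FALSE) {
  stopifnot(inherits(config, "eva_run_config"))
  inputs <- c(
    file.path(config$ref_dir, "genes.genepred"),
    file.path(config$ref_dir, evidence_files),
    config$vep, config$control_vcfs, config$target_vcfs, config$mutect
  )
  if (dry_run) {
    missing <- inputs[!file.exists(inputs)]
    if (length(missing) > 0L) {
      abort(paste0("missing input file(s): ", paste(missing, collapse = ", ")))
    }
    return(invisible(TRUE))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  log <- function(...) message("evanno: ", sprintf(...))

  models <- eva_stage("refdata", read_gene_models(
    file.path(config$ref_dir, "genes.genepred")
  ))
  evidence <- eva_stage("refdata", read_evidence_tables(
    config$ref_dir, config$focus$mesh_term
  ))
  log(
    "stage refdata: %d transcripts (%d genes), evidence for %d genes",
    nrow(models), length(unique(models$gene_symbol)), nrow(evidence)
  )

  primary <- eva_stage("read", {
    if (!is.null(config$mutect)) {
      read_mutect(config$mutect, sample_id = "primary",
        normalize_chrom = config$normalize_chrom
      )
    } else {
      read_vcf(config$target_vcfs[1L],
        origin = "germline_called",
        normalize_chrom = config$normalize_chrom
      )
    }
  })
  log("stage read: %d primary variants", nrow(primary))

  annotated <- eva_stage("annotate", annotate_variants(primary, models))
  p <- file.path(config$out_dir, "annotated.tsv")
  write_variants_tsv(annotated, p)
  paths["annotated"] <- p
  log(
    "stage annotate: %d variants, %d mapped, %d intergenic",
    nrow(annotated), sum(!annotated$intergenic), sum(annotated$intergenic)
  )

  coding <- eva_stage("coding", find_coding(annotated, models))
  p <- file.path(config$out_dir, "coding.tsv")
  write_variants_tsv(coding, p)
  paths["coding"] <- p
  log("stage coding: %d coding variants", nrow(coding))

  germline <- NULL
  if (length(config$control_vcfs) >= 2L) {
    germline <- eva_stage("intersect", {
      sets <- purrr::map(config$control_vcfs, function(f) {
        v <- read_vcf(f, normalize_chrom = config$normalize_chrom)
        find_coding(annotate_variants(v, models), models)
      })
      intersect_variants(sets)
    })
    p <- file.path(config$out_dir, "intersect.tsv")
    write_variants_tsv(germline, p)
    paths["intersect"] <- p
    log(
      "stage intersect: %d pseudo-germline variants shared by %d controls",
      nrow(germline), length(config$control_vcfs)
    )
  }

  p <- file.path(config$out_dir, "coding.pileup")
  eva_stage("to-pileup", write_pileup(coding, p))
  paths["pileup"] <- p
  log("stage to-pileup: wrote %d lines", nrow(coding))

  enriched <- eva_stage("enrich", {
    vep <- read_vep(config$vep)
    enrich_variants(vep, coding, evidence, config$focus)
  })
  p <- file.path(config$out_dir, "enriched.tsv")
  write_variants_tsv(enriched, p)
  paths["enriched"] <- p
  recon <- attr(enriched, "reconciliation")
  log(
    "stage enrich: %d joined (%d annotations unmatched, %d variants unmatched)",
    recon[["n_joined"]], recon[["n_unmatched_annotations"]],
    recon[["n_unmatched_variants"]]
  )

  scored <- eva_stage(
    "score",
    rank_variants(score_variants(enriched, config$focus))
  )
  p <- file.path(config$out_dir, "scored.tsv")
  write_variants_tsv(scored, p)
  paths["scored"] <- p
  log("stage score: %d ranked variants", nrow(scored))

  out <- eva_stage("report", {
    table <- result_table(scored, config$focus, config$thresholds,
      damage_mode = config$damage_mode
    )
    hm <- heatmap_matrix(table, evidence)
    files <- render_report(table, hm, config$out_dir)
    hm_path <- file.path(config$out_dir, "heatmap.tsv")
    hm_df <- if (nrow(hm) > 0L) {
      m <- unclass(hm)
      attr(m, "not_found") <- NULL
      tibble::as_tibble(m, rownames = "gene")
    } else {
      tibble::tibble(gene = character())
    }
    readr::write_tsv(hm_df, hm_path, progress = FALSE)
    list(table = table, heatmap = hm, files = c(files, heatmap = hm_path))
  })
  paths <- c(paths, out$files)
  log(
    "stage report: %d variants retained, heatmap over %d genes",
    nrow(out$table), nrow(out$heatmap)
  )

  invisible(list(
    scored = scored, table = out$table, heatmap = out$heatmap,
    germline = germline, paths = paths
  ))
}
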