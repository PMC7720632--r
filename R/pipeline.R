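#' Full pipeline configuration
#'
#' Bundles the per-stage parameters with a single global seed from which
#' all stage seeds are derived (see [derive_seed()]), so the entire run is
#' reproducible from the configuration alone.
#'
#' @param sim a [simulation_config()] (used when no input files are given).
#' @param cv_threshold replicate CV threshold (default 0.15).
#' @param trim trim fraction (default 0.05).
#' @param trim_mode `"winsorize"` or `"discard"`.
#' @param batch_column batch factor for correction (default scan_batch).
#' @param screen_alpha univariate screen threshold (default 0.05).
#' @param be a [be_config()].
#' @param enr an [enr_config()].
#' @param weight_source `"refit"` (default; required for synthetic
#'   cohorts) or `"published"` for the published index weights.
#' @param min_frac minimum group fraction for cutpoint searches.
#' @param endpoint `"OS"` (default) or `"PFS"` as the selection endpoint.
#' @param seed global integer seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            cv_threshold = 0.15, trim = 0.05,
                            trim_mode = "winsorize",
                            batch_column = "scan_batch",
                            screen_alpha = 0.05,
                            be = be_config(), enr = enr_config(),
                            weight_source = c("refit", "published"),
                            min_frac = 0.10, endpoint = c("OS", "PFS"),
                            seed = 1L) {
  stopifnot(cv_threshold > 0, cv_threshold < 1, trim > 0, trim < 0.5,
            screen_alpha > 0, screen_alpha < 1)
  structure(list(sim = sim, cv_threshold = cv_threshold, trim = trim,
                 trim_mode = trim_mode, batch_column = batch_column,
                 screen_alpha = screen_alpha, be = be, enr = enr,
                 weight_source = match.arg(weight_source),
                 min_frac = min_frac, endpoint = match.arg(endpoint),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.surv_from_clinical <- function(clinical, endpoint = "OS") {
  if (endpoint == "OS")
    surv_data(clinical$os_months, clinical$os_event, clinical$patient_id)
  else
    surv_data(clinical$pfs_months, clinical$pfs_event, clinical$patient_id)
}

#' Run the complete analysis pipeline
#'
#' Simulate (or accept) a cohort, pre-process the spot table to a
#' batch-corrected log2 expression matrix, run both selection arms
#' (Cox screen + backward-elimination consensus; elastic net), intersect
#' them into the signature panel, compute the signature score and its
#' ternary coding, refit the combined index weights by multivariate Cox,
#' build the combined index, and stratify/evaluate against MIPI alone.
#'
#' @param config a [pipeline_config()].
#' @param cohort optional pre-built cohort (as from [generate_cohort()] or
#'   assembled from [read_spot_table()]/[read_clinical()]/
#'   [read_annotation()] as a list with `spots`, `clinical`,
#'   `annotation`); when NULL one is simulated from `config$sim` with the
#'   stage-derived seed.
#' @param output_dir optional directory; when given, all artifacts plus a
#'   run manifest are written there.
#' @param include_timestamp add a wall-clock field to the manifest
#'   (default FALSE so identical runs yield byte-identical manifests).
#' @return List of class `pipeline_result` with elements `cohort`,
#'   `preprocess`, `screen`, `be`, `coxbe_proteins`, `enr`, `panel`,
#'   `scores`, `multivariate`, `evaluation`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL,
                         output_dir = NULL, include_timestamp = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character()

  ## 1. cohort ------------------------------------------------------------
  if (is.null(cohort)) {
    sim_cfg <- config$sim
    sim_cfg$rng_seed <- derive_seed(config$seed, "simulate")
    cohort <- generate_cohort(sim_cfg)
    log <- c(log, sprintf("simulated cohort (seed %d)", sim_cfg$rng_seed))
  }
  clinical <- cohort$clinical
  surv <- .surv_from_clinical(clinical, config$endpoint)

  ## 2. preprocess --------------------------------------------------------
  prep <- preprocess_cohort(cohort$spots, cv_threshold = config$cv_threshold,
                            trim = config$trim, trim_mode = config$trim_mode,
                            batch_column = config$batch_column)
  x <- prep$x
  keep <- rownames(x)
  surv_x <- surv[match(keep, clinical$patient_id), , drop = FALSE]
  clin_x <- clinical[match(keep, clinical$patient_id), , drop = FALSE]
  log <- c(log, prep$log)

  ## 3. selection ---------------------------------------------------------
  screen <- suppressWarnings(cox_screen(x, surv_x, alpha = config$screen_alpha))
  candidates <- screen$analyte_id[screen$pass]
  log <- c(log, sprintf("screen: %d/%d analytes pass p < %g",
                        length(candidates), nrow(screen),
                        config$screen_alpha))
  be_cfg <- config$be
  be_cfg$rng_seed <- derive_seed(config$seed, "backward_elimination")
  be <- suppressWarnings(backward_eliminate(x, surv_x, candidates, be_cfg,
                                            annotation = cohort$annotation))
  # consensus at the target-protein level: clones of one protein are
  # interchangeable across runs, so the stability filter acts on proteins
  cand_prot <- cohort$annotation$protein_id[match(candidates,
                                                  cohort$annotation$analyte_id)]
  coxbe_analytes <- candidates[cand_prot %in% be$consensus_proteins]
  coxbe_prot <- dedupe_clones(coxbe_analytes, screen, cohort$annotation)
  log <- c(log, sprintf(
    "Cox-BE arm: %d consensus analytes / %d consensus proteins",
    length(be$consensus), nrow(coxbe_prot)))
  enr_cfg <- config$enr
  enr_cfg$rng_seed <- derive_seed(config$seed, "elastic_net")
  enr <- suppressWarnings(enr_select(x, surv_x, enr_cfg, screen = screen,
                                     annotation = cohort$annotation))
  enr_prot <- if (!is.null(enr$selected_proteins)) enr$selected_proteins
              else dedupe_clones(intersect(enr$selected_analytes,
                                           screen$analyte_id),
                                 screen, cohort$annotation)
  log <- c(log, sprintf("ENR arm: alpha %.1f, %d analytes -> %d proteins",
                        enr$chosen_alpha, length(enr$selected_analytes),
                        nrow(enr_prot)))
  panel <- suppressWarnings(
    intersect_panels(coxbe_prot, enr_prot, screen, cohort$annotation))
  log <- c(log, sprintf("intersected signature panel: %d proteins",
                        nrow(panel)))

  ## 4. scoring -----------------------------------------------------------
  scores <- NULL
  multi <- NULL
  evaluation <- NULL
  if (nrow(panel) >= 1L) {
    ris <- compute_ris(x, panel, surv = surv_x, min_frac = config$min_frac)
    scores <- data.frame(patient_id = keep,
                         mipi_score = clin_x$mipi_score,
                         mipi_category = mipi_category(clin_x$mipi_score),
                         s_continuous = ris$s_continuous,
                         s_ternary = ris$s_ternary)
    multi <- tryCatch(
      fit_multivariate(clin_x$mipi_score, ris$s_ternary, surv_x),
      error = function(e) {
        log <<- c(log, paste("multivariate fit failed:",
                             conditionMessage(e)))
        NULL
      })
    w <- if (config$weight_source == "refit" && !is.null(multi))
      multi$weights else index_weights()
    scores$mipi_ris <- compute_mipi_ris(scores$mipi_score,
                                        scores$s_ternary, w)

    ## 5. evaluation ------------------------------------------------------
    pfs <- .surv_from_clinical(clin_x, "PFS")
    evaluation <- tryCatch(
      compare_indices(list(MIPI = scores$mipi_score,
                           MIPI_ris = scores$mipi_ris),
                      surv_x, pfs = pfs,
                      cutpoints = list(MIPI = c(5.7, 6.2)),
                      min_frac = config$min_frac),
      error = function(e) {
        log <<- c(log, paste("evaluation skipped:", conditionMessage(e)))
        NULL
      })
  } else {
    log <- c(log, "empty panel: scoring and evaluation skipped")
  }

  result <- list(cohort = cohort, preprocess = prep, screen = screen,
                 be = be, coxbe_proteins = coxbe_prot, enr = enr,
                 panel = panel, scores = scores, multivariate = multi,
                 evaluation = evaluation, log = log)
  class(result) <- "pipeline_result"
  if (!is.null(output_dir))
    result$manifest <- write_pipeline_artifacts(result, config, output_dir,
                                                include_timestamp)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("mclris pipeline result\n")
  for (l in x$log) cat(" -", l, "\n")
  invisible(x)
}

#' Write pipeline artifacts and the run manifest
#'
#' Artifacts: spot table (TSV), clinical table (CSV), annotation (CSV),
#' expression matrix (TSV), QC report (CSV), screen table (CSV), BE run
#' log (CSV), ENR path (CSV), panel (JSON), per-patient scores (CSV),
#' index weights (JSON), evaluation table (CSV), processing log, and
#' `manifest.json` (version, seed, configuration snapshot, MD5 checksum
#' per artifact). With `include_timestamp = FALSE` (default) rerunning an
#' identical configuration reproduces the manifest byte for byte.
#'
#' @param result a `pipeline_result`.
#' @param config the [pipeline_config()] used.
#' @param output_dir directory (created if needed).
#' @param include_timestamp add wall-clock time to the manifest.
#' @return The manifest (invisibly also written as JSON).
#' @export
write_pipeline_artifacts <- function(result, config, output_dir,
                                     include_timestamp = FALSE) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(output_dir, f)
  write_spot_table(result$cohort$spots, p("spots.tsv"))
  write_clinical(result$cohort$clinical, p("clinical.csv"))
  write_annotation(result$cohort$annotation, p("annotation.csv"))
  write_expression_matrix(result$preprocess$x, p("expression.tsv"))
  data.table::fwrite(result$preprocess$qc, p("qc_report.csv"))
  data.table::fwrite(as.data.frame(result$screen), p("screen.csv"))
  if (!is.null(result$be$runs))
    data.table::fwrite(result$be$runs, p("be_runs.csv"))
  data.table::fwrite(result$enr$path, p("enr_path.csv"))
  jsonlite::write_json(
    list(panel = result$panel,
         weights = if (!is.null(result$multivariate))
           unclass(result$multivariate$weights) else unclass(index_weights())),
    p("panel.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(result$scores))
    data.table::fwrite(result$scores, p("scores.csv"), na = "")
  if (!is.null(result$evaluation)) {
    ev <- result$evaluation
    attr(ev, "stratification") <- NULL
    data.table::fwrite(ev, p("evaluation.csv"), na = "")
  }
  log_lines <- result$log
  if (include_timestamp)
    log_lines <- c(log_lines, paste("finished:", format(Sys.time())))
  writeLines(log_lines, p("pipeline.log"))

  files <- sort(setdiff(list.files(output_dir), "manifest.json"))
  files <- setdiff(files, "pipeline.log") # log may carry timestamps
  sums <- tools::md5sum(file.path(output_dir, files))
  manifest <- list(
    package = "mclris",
    version = as.character(packageVersion("mclris")),
    seed = config$seed,
    config = .config_snapshot(config),
    checksums = as.list(setNames(unname(sums), files)))
  if (include_timestamp) manifest$timestamp <- format(Sys.time())
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest
}

.config_snapshot <- function(config) {
  strip <- function(z) {
    if (is.list(z)) lapply(unclass(z), strip) else z
  }
  strip(config)
}
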