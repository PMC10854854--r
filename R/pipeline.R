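.configSections <- list(
  seed = NULL,
  input = c("mode", "tic_dir", "cohort_csv", "patients", "times",
            "times_csv", "schema", "noise_sd"),
  curve_fit = c("smoothing", "window_size", "washout_cap_s"),
  classifier = c("folds", "threshold", "lambda"),
  survival = c("censor_horizon_days"),
  output = c("dir"),
  max_fail_fraction = NULL
)

#' Read and validate a pipeline configuration
#'
#' YAML configuration for [runPipeline()]. Unknown keys are rejected so
#' typos do not silently fall back to defaults.
#'
#' @param path YAML path.
#' @return Validated configuration list (class \code{"pipelineConfig"})
#'   with defaults filled in.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  validatePipelineConfig(cfg, source = path)
}

#' @rdname readPipelineConfig
#' @param cfg Configuration list (as parsed from YAML).
#' @param source Label used in error messages.
#' @export
validatePipelineConfig <- function(cfg, source = "config") {
  unknown <- setdiff(names(cfg), names(.configSections))
  if (length(unknown))
    stop(sprintf("%s: unknown keys: %s", source,
                 paste(unknown, collapse = ", ")))
  for (sec in names(.configSections)) {
    allowed <- .configSections[[sec]]
    if (!is.null(allowed) && !is.null(cfg[[sec]])) {
      bad <- setdiff(names(cfg[[sec]]), allowed)
      if (length(bad))
        stop(sprintf("%s: unknown keys in '%s': %s", source, sec,
                     paste(bad, collapse = ", ")))
    }
  }
  cfg$seed <- as.integer(cfg$seed %||% 42L)
  cfg$input <- cfg$input %||% list()
  cfg$input$mode <- cfg$input$mode %||% "synthetic"
  if (!cfg$input$mode %in% c("synthetic", "tic_csv", "nifti"))
    stop(sprintf("%s: input mode must be synthetic, tic_csv or nifti",
                 source))
  cfg$input$noise_sd <- cfg$input$noise_sd %||% 3
  cf <- cfg$curve_fit %||% list()
  cfg$curve_fit <- fitConfig(
    smoothing = cf$smoothing,
    windowSize = cf$window_size %||% 5L,
    washoutCapS = cf$washout_cap_s %||% Inf)
  cl <- cfg$classifier %||% list()
  cfg$classifier <- list(folds = as.integer(cl$folds %||% 5L),
                         threshold = cl$threshold %||% 0.5,
                         lambda = cl$lambda %||% 1e-3)
  sv <- cfg$survival %||% list()
  cfg$survival <- list(censor_horizon_days =
                         sv$censor_horizon_days %||% 1095)
  cfg$output <- cfg$output %||% list()
  cfg$max_fail_fraction <- cfg$max_fail_fraction %||% 0.2
  class(cfg) <- "pipelineConfig"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Assemble the cohort table plus one lazy curve getter per patient, so a
## corrupt input file fails only its own patient inside the fitting loop.
collectCurves <- function(cfg) {
  mode <- cfg$input$mode
  if (mode == "synthetic") {
    coh <- generateCohort(noiseSd = cfg$input$noise_sd, seed = cfg$seed)
    cohort <- coh$records[, c("patient_id", "survival_days", "event",
                              "phenotype_visual")]
    getters <- lapply(coh$curves, function(cc)
      function() list(tumor = cc$tumor, pancreas = cc$pancreas))
    return(list(cohort = cohort, getters = getters))
  }
  if (mode == "tic_csv") {
    cohort <- readCohortCSV(cfg$input$cohort_csv)
    getters <- lapply(cohort$patient_id, function(id) {
      force(id)
      function() lapply(c(tumor = "tumor", pancreas = "pancreas"),
        function(roi) {
          p <- file.path(cfg$input$tic_dir, sprintf("%s_%s.csv", id, roi))
          if (!file.exists(p)) stop(sprintf("missing TIC CSV: %s", p))
          readTICCSV(p)
        })
    })
    names(getters) <- cohort$patient_id
    return(list(cohort = cohort, getters = getters))
  }
  ## nifti mode: per-patient series + label map, shared time grid
  cohort <- readCohortCSV(cfg$input$cohort_csv)
  times <- if (!is.null(cfg$input$times)) as.numeric(cfg$input$times)
           else utils::read.csv(cfg$input$times_csv)$time_s
  schema <- if (!is.null(cfg$input$schema))
    readLabelSchema(cfg$input$schema) else defaultLabelSchema()
  pats <- cfg$input$patients
  ids <- vapply(pats, function(p) p$id, character(1))
  getters <- lapply(pats, function(p) {
    force(p)
    function() {
      series <- readDynamicSeries(unlist(p$series), times)
      labels <- readLabelMap(p$labels)
      list(tumor = extractTIC(series, labels, schema, "tumor"),
           pancreas = extractTIC(series, labels, schema, "pancreas",
                                 exclude = character(0)))
    }
  })
  names(getters) <- ids
  cohort <- cohort[match(ids, cohort$patient_id), ]
  list(cohort = cohort, getters = getters)
}

#' Run the end-to-end perfusion phenotyping pipeline
#'
#' For every patient: obtain tumor and pancreas time-intensity curves
#' (synthetic cohort, per-patient TIC CSVs, or NIfTI series + label maps),
#' fit the trilinear model to both, and compute the three perfusion
#' features. Patients whose curves fail fitting are excluded from cohort
#' statistics and enumerated in the report. The cohort then gets a
#' stratified cross-validated logistic phenotype model, Mann-Whitney
#' feature tests, and Kaplan-Meier / log-rank survival comparisons for
#' both the visual and the predicted phenotype split. All artifacts are
#' written to the output directory together with a manifest recording the
#' seed and configuration hash.
#'
#' @param config A \code{"pipelineConfig"} (see [readPipelineConfig()]) or
#'   a path to a YAML configuration.
#' @param outputDir Output directory (overrides the configuration).
#' @return Invisibly, a list with \code{features}, \code{failures},
#'   \code{model}, \code{featureTests}, \code{survival}, \code{manifest}.
#' @export
runPipeline <- function(config, outputDir = NULL) {
  cfgPath <- NA_character_
  if (is.character(config)) {
    cfgPath <- config
    config <- readPipelineConfig(config)
  }
  stopifnot(inherits(config, "pipelineConfig"))
  outDir <- outputDir %||% config$output$dir %||% "."
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  inp <- collectCurves(config)
  cohort <- inp$cohort

  rows <- list(); diagRows <- list(); failures <- list()
  for (id in cohort$patient_id) {
    res <- tryCatch({
      cc <- inp$getters[[id]]()
      ft <- fitCurve(cc$tumor, config$curve_fit)
      fp <- fitCurve(cc$pancreas, config$curve_fit)
      feat <- computeFeatures(ft, fp)
      rows[[id]] <- data.frame(
        patient_id = id,
        tumor_slope_hu_s = tumorSlope(feat),
        tumor_peak_hu = tumorPeak(feat),
        delta_peak_hu = deltaPeak(feat),
        visual_phenotype =
          cohort$phenotype_visual[cohort$patient_id == id])
      diagRows[[id]] <- cbind(
        data.frame(patient_id = id, roi = c("tumor", "pancreas")),
        rbind(trilinearAsRow(ft), trilinearAsRow(fp)))
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) failures[[id]] <- res
  }
  failFrac <- length(failures) / nrow(cohort)
  if (failFrac > config$max_fail_fraction)
    stop(sprintf("%.0f%% of patients failed curve fitting (limit %.0f%%)",
                 100 * failFrac, 100 * config$max_fail_fraction))
  features <- do.call(rbind, rows)
  rownames(features) <- NULL
  diagnostics <- do.call(rbind, diagRows)
  rownames(diagnostics) <- NULL

  x <- features[, c("tumor_slope_hu_s", "tumor_peak_hu", "delta_peak_hu")]
  colnames(x) <- c("tumor_slope", "tumor_peak", "delta_peak")
  model <- crossvalClassify(x, features$visual_phenotype,
                            folds = config$classifier$folds,
                            seed = config$seed,
                            lambda = config$classifier$lambda,
                            threshold = config$classifier$threshold)
  features$predicted_phenotype <- predictedPhenotype(model)

  featureTests <- lapply(colnames(x), function(f)
    featureGroupTest(x, features$visual_phenotype, f))
  names(featureTests) <- colnames(x)

  ## survival comparisons on the fitted subset
  sub <- cohort[match(features$patient_id, cohort$patient_id), ]
  survivalReport <- lapply(
    c(visual = "visual_phenotype", predicted = "predicted_phenotype"),
    function(col) {
      lab <- features[[col]]
      a <- lab == 0L; b <- lab == 1L
      if (!any(a) || !any(b)) return(NULL)
      lr <- logrankTest(sub$survival_days[a], sub$event[a],
                        sub$survival_days[b], sub$event[b])
      list(
        logrank = lr,
        km_hypovascular = kmEstimate(sub$survival_days[a], sub$event[a]),
        km_isovascular = kmEstimate(sub$survival_days[b], sub$event[b]))
    })

  ## write artifacts
  writeFeatureCSV(features, file.path(outDir, "features.csv"))
  sub$phenotype_predicted <- features$predicted_phenotype
  writeCohortCSV(sub, file.path(outDir, "cohort.csv"))
  utils::write.csv(diagnostics, file.path(outDir, "fit_diagnostics.csv"),
                   row.names = FALSE, quote = FALSE)
  for (split in names(survivalReport)) {
    sr <- survivalReport[[split]]
    if (is.null(sr)) next
    for (g in c("km_hypovascular", "km_isovascular"))
      utils::write.csv(sr[[g]]$table,
        file.path(outDir, sprintf("%s_%s.csv", g, split)),
        row.names = FALSE, quote = FALSE)
  }
  report <- list(
    n_patients = nrow(cohort),
    n_fitted = nrow(features),
    failed_patients = failures,
    fold_auc = model@foldAUC,
    mean_auc = model@meanAUC,
    pooled_auc = model@pooledAUC,
    coefficients = as.list(coef(model)),
    feature_tests = lapply(featureTests, function(tst)
      tst[c("feature", "mean0", "sd0", "n0", "mean1", "sd1", "n1",
            "U", "p", "method")]),
    survival = lapply(survivalReport, function(sr) {
      if (is.null(sr)) return(NULL)
      list(chisq = sr$logrank$chisq, p = sr$logrank$p,
           median_hypovascular = sr$km_hypovascular$median,
           median_isovascular = sr$km_isovascular$median)
    })
  )
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  manifest <- list(
    package = "ctperfusion",
    version = as.character(utils::packageVersion("ctperfusion")),
    seed = config$seed,
    input_mode = config$input$mode,
    config_path = cfgPath,
    config_md5 = if (!is.na(cfgPath)) unname(tools::md5sum(cfgPath))
                 else NA_character_,
    n_failed = length(failures)
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")

  invisible(list(features = features, failures = failures, model = model,
                 featureTests = featureTests, survival = survivalReport,
                 manifest = manifest))
}
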