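# Top-level pipeline: extraction -> per-method selection -> report.

#' Extract features for every lesion of a manifest
#'
#' Reads each image/mask pair and extracts the ten features.  Lesions whose
#' extraction fails (e.g. a lesion touching the bottom edge has no
#' posterior region) are excluded with a warning naming the lesion and the
#' reason; the number of exclusions is attached as attribute `n_failed`.
#'
#' @param manifest A [load_manifest()] result (or equivalent `data.frame`).
#' @param config A [feature_config()].
#' @param quiet Suppress per-lesion progress messages.
#' @return Labelled feature table (`data.frame` with `lesion_id`, `label`,
#'   ten feature columns), ready for [cross_validate()] /
#'   [forward_select()].
#' @export
extract_features_table <- function(manifest, config = feature_config(),
                                   quiet = TRUE) {
  rows <- list()
  n_failed <- 0L
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$lesion_id[i]
    res <- tryCatch({
      image <- read_grey_image(manifest$image_path[i])
      mask <- read_mask(manifest$mask_path[i], dim = dim(image))
      fv <- extract_features(image, mask, config)
      cbind(data.frame(lesion_id = id, label = manifest$label[i],
                       stringsAsFactors = FALSE),
            as.data.frame(as.list(fv)))
    }, error = function(e) {
      warning(sprintf("lesion '%s' excluded: %s", id, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (is.null(res)) n_failed <- n_failed + 1L else rows[[length(rows) + 1L]] <- res
    if (!quiet) message(sprintf("[extract] %s (%d/%d)", id, i, nrow(manifest)))
  }
  out <- do.call(rbind, rows)
  attr(out, "n_failed") <- n_failed
  out
}

#' Write a feature table to CSV
#'
#' Columns: `lesion_id`, the ten features in canonical order, and `label`
#' when present.
#'
#' @param table Feature table (see [extract_features_table()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  cols <- c("lesion_id", intersect(feature_names(), names(table)),
            intersect("label", names(table)))
  utils::write.csv(table[cols], path, row.names = FALSE)
  invisible(path)
}

#' Write a selection trace to CSV
#'
#' Columns `step,features,auc,sensitivity,specificity`, one row per
#' retained selection step (sensitivity/specificity as proportions at the
#' Youden-optimal cutoff).
#'
#' @param trace A [forward_select()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_selection_trace <- function(trace, path) {
  utils::write.csv(trace$steps, path, row.names = FALSE)
  invisible(path)
}

#' Run the full classification pipeline
#'
#' Extracts features for every lesion of the manifest, runs greedy forward
#' selection for each requested classifier, and writes `features.csv`, one
#' `trace_<method>.csv` per method, and `report.json` summarizing for each
#' method the selected subset and its AUC, sensitivity, and specificity
#' with 95% CIs.  Fully reproducible from (manifest, config, seed).
#'
#' @inheritParams extract_features_table
#' @param methods Classifier methods to run (see [classifier_spec()]).
#' @param k Number of CV folds.
#' @param seed Integer seed driving fold assignment and stochastic fits.
#' @param out_dir Output directory (created if missing); `NULL` to skip
#'   writing files.
#' @return The report (named list, one entry per method; attributes
#'   `n_lesions` and `n_failed`), invisibly when `out_dir` is given.
#' @export
run_pipeline <- function(manifest, config = feature_config(),
                         methods = CLASSIFIER_METHODS, k = 10, seed = 1,
                         out_dir = NULL, quiet = TRUE) {
  table <- extract_features_table(manifest, config, quiet = quiet)
  if (!quiet)
    message(sprintf("[extract] %d lesions, %d excluded", nrow(table),
                    attr(table, "n_failed")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_feature_table(table, file.path(out_dir, "features.csv"))
  }
  report <- list()
  for (m in methods) {
    if (!quiet) message(sprintf("[select] method %s", m))
    trace <- forward_select(table, classifier_spec(m, seed = seed),
                            k = k, seed = seed)
    roc <- trace$cv$roc
    report[[m]] <- list(
      method = m,
      selected_features = trace$selected_subset,
      auc = roc$auc,
      auc_ci95 = unname(roc$auc_ci95),
      sensitivity = roc$best_sensitivity$value,
      sensitivity_ci95 = roc$best_sensitivity$ci95,
      specificity = roc$best_specificity$value,
      specificity_ci95 = roc$best_specificity$ci95,
      steps = trace$steps)
    if (!is.null(out_dir))
      write_selection_trace(trace, file.path(out_dir,
                                             paste0("trace_", m, ".csv")))
  }
  attr(report, "n_lesions") <- nrow(table)
  attr(report, "n_failed") <- attr(table, "n_failed")
  if (!is.null(out_dir)) {
    out <- lapply(report, function(r) {
      r$steps <- NULL
      r
    })
    jsonlite::write_json(list(n_lesions = nrow(table),
                              n_failed = attr(table, "n_failed"),
                              methods = out),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(report))
  }
  report
}
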