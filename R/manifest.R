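# Dataset manifests and cohort composition summaries.

#' Load and validate a dataset manifest
#'
#' Reads a CSV with header `lesion_id,image_path,mask_path,label`
#' (optionally `histotype`).  Labels are trimmed and matched
#' case-insensitively against benign/malignant.  Relative paths are
#' resolved against the manifest's directory.  All problems are reported
#' together with their row numbers.
#'
#' @param path Path to the manifest CSV.
#' @param check_files Verify that the referenced image/mask files exist.
#' @return Object of class `dataset_manifest` (a validated `data.frame`).
#' @export
load_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lesion_id", "image_path", "mask_path", "label")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop("manifest lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  errs <- character(0)
  dup <- m$lesion_id[duplicated(m$lesion_id)]
  for (d in unique(dup)) {
    rows <- which(m$lesion_id == d)
    errs <- c(errs, sprintf("duplicate lesion_id '%s' in rows %s", d,
                            paste(rows, collapse = ", ")))
  }
  lab <- tolower(trimws(m$label))
  bad <- which(!lab %in% c("benign", "malignant"))
  for (i in bad)
    errs <- c(errs, sprintf("row %d: unknown label '%s'", i, m$label[i]))
  m$label <- lab
  base <- dirname(path)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  m$image_path <- resolve(m$image_path)
  m$mask_path <- resolve(m$mask_path)
  if (check_files) {
    for (i in seq_len(nrow(m))) {
      for (col in c("image_path", "mask_path")) {
        if (!file.exists(m[[col]][i]))
          errs <- c(errs, sprintf("row %d: missing file '%s'", i, m[[col]][i]))
      }
    }
  }
  if (length(errs))
    stop("invalid manifest:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  structure(m, class = c("dataset_manifest", "data.frame"))
}

#' Histopathological composition of a cohort
#'
#' Per-class histotype counts and percentages, the standard opening
#' demographics table of a clinical series.  Percentages are
#' `100 * count / class_total` rounded
#' half-up to one decimal; rows are sorted by descending count within each
#' class.
#'
#' @param manifest A `data.frame` with columns `label` and `histotype`
#'   (e.g. a [load_manifest()] result).
#' @return Object of class `composition_summary`: `data.frame` with columns
#'   `label`, `histotype`, `n`, `percentage`.
#' @export
summarize_composition <- function(manifest) {
  if (is.null(manifest$histotype) || all(is.na(manifest$histotype)) ||
      all(!nzchar(manifest$histotype)))
    stop("no histotype data in manifest", call. = FALSE)
  lab <- tolower(trimws(manifest$label))
  out <- NULL
  for (cls in c("benign", "malignant")) {
    sub <- manifest$histotype[lab == cls]
    sub <- sub[!is.na(sub) & nzchar(sub)]
    if (length(sub) == 0L) next
    tab <- sort(table(sub), decreasing = TRUE)
    out <- rbind(out, data.frame(
      label = cls,
      histotype = names(tab),
      n = as.integer(tab),
      percentage = round_half_up(100 * as.integer(tab) / length(sub), 1),
      stringsAsFactors = FALSE))
  }
  structure(out, class = c("composition_summary", "data.frame"))
}

#' Example cohort composition table
#'
#' The bundled per-lesion histotype listing of a 206-lesion consecutive
#' biopsy-proven series (144 benign, 62 malignant) used in the package
#' examples, expanded from the count table shipped in
#' `inst/extdata/example_cohort_composition.csv`.
#'
#' @return `data.frame` with columns `lesion_id`, `label`, `histotype`
#'   (one row per lesion).
#' @export
example_cohort_histotypes <- function() {
  counts <- utils::read.csv(system.file("extdata",
                                        "example_cohort_composition.csv",
                                        package = "usradiomics"),
                            stringsAsFactors = FALSE)
  rows <- counts[rep(seq_len(nrow(counts)), counts$n), c("label", "histotype")]
  rows$lesion_id <- sprintf("%s%03d",
                            ifelse(rows$label == "benign", "B", "M"),
                            stats::ave(seq_len(nrow(rows)), rows$label,
                                       FUN = seq_along))
  rownames(rows) <- NULL
  rows[c("lesion_id", "label", "histotype")]
}
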