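# ROC analysis: empirical curve, AUC with DeLong CI, Youden operating point.

#' ROC analysis of malignancy scores
#'
#' Builds the empirical ROC curve over all observed score thresholds
#' (classification rule: score >= threshold is called malignant).  The AUC
#' is the Mann-Whitney statistic (ties counted 1/2) with a 95% DeLong
#' confidence interval (via \pkg{pROC}).  The operating point maximizes
#' Youden's J = sensitivity + specificity - 1 over the observed scores
#' (plus the `Inf` sentinel); ties are resolved towards higher specificity,
#' then towards the higher threshold.  Sensitivity and specificity at the
#' chosen cutoff carry exact Clopper-Pearson 95% CIs.
#'
#' @param scores Numeric malignancy scores, one per lesion (higher = more
#'   suspicious).
#' @param labels Class labels: factor/character (`"benign"`/`"malignant"`),
#'   logical, or 0/1 numeric (1 = malignant).
#' @return Object of class `roc_result`: list with `thresholds` (descending,
#'   starting at `Inf`), `sens_spec_points` (matrix of sensitivity and
#'   specificity per threshold), `auc`, `auc_ci95` (`c(lo, hi)`),
#'   `best_cutoff`, `best_sensitivity`, `best_specificity` (each a list with
#'   `value` and `ci95`), and the class counts `n_pos`, `n_neg`.
#' @export
#' @examples
#' compute_roc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
compute_roc <- function(scores, labels) {
  lab <- normalize_labels(labels)
  if (length(scores) != length(lab))
    stop("scores and labels lengths differ", call. = FALSE)
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  if (length(unique(lab)) < 2L)
    stop("degenerate labels: both classes must be present", call. = FALSE)
  pos <- scores[lab == "malignant"]
  neg <- scores[lab == "benign"]
  r <- pROC::roc(response = lab, predictor = scores,
                 levels = c("benign", "malignant"), direction = "<",
                 quiet = TRUE)
  auc <- as.numeric(r$auc)
  # a degenerate [auc, auc] interval is acceptable for perfect separation
  ci <- tryCatch(suppressWarnings(
    as.numeric(pROC::ci.auc(r, method = "delong"))),
    error = function(e) c(auc, auc, auc))
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg < t), numeric(1))
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)
  if (length(best) > 1L) best <- best[spec[best] >= max(spec[best]) - 1e-12]
  best <- best[1L]  # thresholds descend, so the first is the largest cutoff
  x_se <- sum(pos >= thr[best]); x_sp <- sum(neg < thr[best])
  structure(list(
    thresholds = thr,
    sens_spec_points = cbind(sensitivity = sens, specificity = spec),
    auc = auc,
    auc_ci95 = c(lo = ci[1L], hi = ci[3L]),
    best_cutoff = thr[best],
    best_sensitivity = list(value = sens[best],
                            ci95 = as.numeric(stats::binom.test(
                              x_se, length(pos))$conf.int)),
    best_specificity = list(value = spec[best],
                            ci95 = as.numeric(stats::binom.test(
                              x_sp, length(neg))$conf.int)),
    n_pos = length(pos), n_neg = length(neg)),
    class = "roc_result")
}

# Coerce assorted label encodings to a benign/malignant factor.
normalize_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    lab <- tolower(trimws(labels))
    bad <- !lab %in% c("benign", "malignant")
    if (any(bad))
      stop("unknown label(s): ", paste(unique(labels[bad]), collapse = ", "),
           call. = FALSE)
  } else if (is.logical(labels) || is.numeric(labels)) {
    if (is.numeric(labels) && !all(labels %in% c(0, 1)))
      stop("numeric labels must be 0/1", call. = FALSE)
    lab <- ifelse(as.logical(labels), "malignant", "benign")
  } else {
    stop("unsupported label type", call. = FALSE)
  }
  factor(lab, levels = c("benign", "malignant"))
}

#' Plot an ROC curve
#'
#' @param roc A `roc_result` from [compute_roc()].
#' @param ... Passed to [graphics::plot()].
#' @return `roc`, invisibly.
#' @export
plot_roc <- function(roc, ...) {
  pts <- roc$sens_spec_points
  graphics::plot(1 - pts[, "specificity"], pts[, "sensitivity"],
                 type = "s", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "1 - specificity", ylab = "Sensitivity", ...)
  graphics::abline(0, 1, lty = 3, col = "grey")
  graphics::legend("bottomright", bty = "n",
                   legend = sprintf("AUC = %.3f (95%% CI %.3f-%.3f)",
                                    roc$auc, roc$auc_ci95[1L],
                                    roc$auc_ci95[2L]))
  invisible(roc)
}
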