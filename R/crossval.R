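# Stratified k-fold cross-validation and greedy forward feature selection.

# Stratified fold assignment keyed by sorted lesion_id.  Classes are dealt
# round-robin with a rotating offset so overall fold sizes differ by <= 1.
make_folds <- function(lesion_id, labels, k, seed) {
  n <- length(lesion_id)
  fold <- integer(n)
  with_seed(seed, {
    offset <- 0L
    for (cls in levels(labels)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
      offset <- (offset + length(idx)) %% k
    }
  })
  fold
}

# Validate a labelled feature table and return it sorted by lesion_id with
# canonical label factor.
prepare_table <- function(table, features) {
  stopifnot(is.data.frame(table))
  need <- c("lesion_id", "label", features)
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("feature table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(table$lesion_id))
    stop("duplicate lesion_id in feature table", call. = FALSE)
  if (anyNA(table[features]))
    stop("missing feature values", call. = FALSE)
  table <- table[order(table$lesion_id), , drop = FALSE]
  table$label <- normalize_labels(table$label)
  table
}

#' Stratified k-fold cross-validation of one classifier
#'
#' Splits the lesions into `k` label-stratified folds (assignment keyed by
#' sorted `lesion_id`, so it is invariant to row order), trains the
#' classifier on each set of k-1 folds and scores the held-out lesions.
#' Scale-sensitive methods (MLP, LDA, SVM) are fed features z-scored with
#' training-fold statistics only.  The pooled out-of-fold scores (every
#' lesion scored exactly once) feed a single ROC analysis.
#'
#' @param table `data.frame` with columns `lesion_id`, `label`, and the
#'   feature columns (see [features_from_cases()]).
#' @param spec A [classifier_spec()].
#' @param features Character vector of feature columns to use (default: all
#'   canonical features present).
#' @param k Number of folds.
#' @param seed Integer seed for the fold assignment.
#' @return Object of class `cv_result`: list with `pooled_scores` (named by
#'   `lesion_id`), `fold_assignment`, `labels`, and `roc`
#'   (see [compute_roc()]).
#' @export
cross_validate <- function(table, spec,
                           features = intersect(feature_names(), names(table)),
                           k = 10, seed = 1) {
  table <- prepare_table(table, features)
  if (min(table(table$label)) < k)
    stop("insufficient class size: each class needs >= k lesions",
         call. = FALSE)
  cls <- build_classifier(spec)
  fold <- make_folds(table$lesion_id, table$label, k, seed)
  x <- table[features]
  y <- table$label
  scores <- rep(NA_real_, nrow(table))
  for (f in seq_len(k)) {
    tr <- fold != f
    xtr <- x[tr, , drop = FALSE]; xte <- x[!tr, , drop = FALSE]
    if (cls$needs_scaling) {
      mu <- vapply(xtr, mean, numeric(1))
      sd <- vapply(xtr, stats::sd, numeric(1))
      sd[!is.finite(sd) | sd == 0] <- 1
      xtr <- as.data.frame(scale(xtr, center = mu, scale = sd))
      xte <- as.data.frame(scale(xte, center = mu, scale = sd))
    }
    scorer <- cls$fit(xtr, y[tr], seed = spec$seed + f)
    scores[!tr] <- scorer(xte)
  }
  names(scores) <- table$lesion_id
  fold_assignment <- stats::setNames(fold, table$lesion_id)
  structure(list(pooled_scores = scores,
                 fold_assignment = fold_assignment,
                 labels = stats::setNames(y, table$lesion_id),
                 roc = compute_roc(scores, y)),
            class = "cv_result")
}

#' Greedy forward feature selection driven by cross-validated AUC
#'
#' Bottom-up selection: every feature is first evaluated alone by pooled
#' k-fold CV AUC and the best is kept; each later step evaluates adding
#' every remaining feature and keeps the best candidate only if its AUC
#' strictly exceeds the current one, stopping otherwise (or when all
#' features are included).  Ties are broken by the canonical feature order
#' ([feature_names()]).  Each retained step records the subset, its AUC,
#' and the sensitivity/specificity at the Youden-optimal cutoff.
#'
#' @inheritParams cross_validate
#' @return Object of class `selection_trace`: list with `steps`
#'   (`data.frame` of `step`, `features` (comma-joined), `auc`,
#'   `sensitivity`, `specificity`), `selected_subset` (character vector),
#'   and `cv` (the [cross_validate()] result of the final subset).
#' @export
forward_select <- function(table, spec,
                           features = intersect(feature_names(), names(table)),
                           k = 10, seed = 1) {
  table <- prepare_table(table, features)
  selected <- character(0)
  current_auc <- -Inf
  steps <- list()
  best_cv <- NULL
  repeat {
    remaining <- setdiff(features, selected)
    if (length(remaining) == 0L) break
    cand_auc <- rep(-Inf, length(remaining))
    cand_cv <- vector("list", length(remaining))
    for (i in seq_along(remaining)) {
      cv <- cross_validate(table, spec, c(selected, remaining[i]),
                           k = k, seed = seed)
      cand_auc[i] <- cv$roc$auc
      cand_cv[[i]] <- cv
    }
    best <- which.max(cand_auc)  # first max: canonical-order tie-break
    if (cand_auc[best] <= current_auc) break
    selected <- c(selected, remaining[best])
    current_auc <- cand_auc[best]
    best_cv <- cand_cv[[best]]
    steps[[length(steps) + 1L]] <- data.frame(
      step = length(steps) + 1L,
      features = paste(selected, collapse = ","),
      auc = current_auc,
      sensitivity = best_cv$roc$best_sensitivity$value,
      specificity = best_cv$roc$best_specificity$value,
      stringsAsFactors = FALSE)
  }
  structure(list(steps = do.call(rbind, steps),
                 selected_subset = selected,
                 cv = best_cv),
            class = "selection_trace")
}
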