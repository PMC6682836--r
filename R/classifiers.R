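# The five benign/malignant classifiers behind a uniform score interface.

CLASSIFIER_METHODS <- c("dt", "rf", "mlp", "lda", "svm")

#' Classifier specification
#'
#' @param method One of `"dt"` (CART decision tree), `"rf"` (random
#'   forest), `"mlp"` (single-hidden-layer perceptron), `"lda"` (linear
#'   discriminant analysis), `"svm"` (RBF-kernel support vector machine).
#'   Case-insensitive.
#' @param hyperparameters Named list overriding the documented defaults
#'   (see [build_classifier()]).
#' @param seed Integer seed fixed for stochastic methods (RF, MLP weight
#'   initialization).
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(method, hyperparameters = list(), seed = 1) {
  m <- tolower(trimws(method))
  if (length(m) != 1L || !m %in% CLASSIFIER_METHODS)
    stop("unknown classifier: ", method, call. = FALSE)
  structure(list(method = m, hyperparameters = hyperparameters,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Build a trained-model factory for a classifier specification
#'
#' Returns a factory closure `function(x, y, seed)` fitting the model on a
#' numeric feature data.frame `x` and label factor `y` (levels
#' `benign`, `malignant`) and returning a scorer `function(newx)` that
#' emits a continuous malignancy score in \[0, 1\].
#'
#' Defaults: DT = CART with Gini splits, no depth limit (`rpart`,
#' `cp = 0.01`, `maxdepth = 30`); RF = 100 trees, `floor(sqrt(p))` features
#' per split; MLP = one hidden layer of 8 logistic units, up to 500
#' iterations; LDA = pooled-covariance linear discriminant scoring by class
#' posterior; SVM = RBF kernel, `C = 1`,
#' `gamma = 1 / (p * var(as.vector(x)))`, scored by the logistic of the
#' decision value.  Scale-sensitive methods (MLP, LDA, SVM) expect
#' standardized features; [cross_validate()] standardizes with
#' training-fold statistics.
#'
#' @param spec A [classifier_spec()].
#' @return List with `fit` (the factory) and `needs_scaling` (logical).
#' @export
build_classifier <- function(spec) {
  stopifnot(inherits(spec, "classifier_spec"))
  hp <- spec$hyperparameters
  hp_get <- function(name, default) if (!is.null(hp[[name]])) hp[[name]] else default
  fit <- switch(spec$method,
    dt = function(x, y, seed = spec$seed) {
      d <- cbind(x, .y = y)
      m <- rpart::rpart(.y ~ ., data = d, method = "class",
                        parms = list(split = "gini"),
                        control = rpart::rpart.control(
                          cp = hp_get("cp", 0.01),
                          maxdepth = hp_get("maxdepth", 30)))
      function(newx) unname(predict(m, newx, type = "prob")[, "malignant"])
    },
    rf = function(x, y, seed = spec$seed) {
      m <- with_seed(seed,
        randomForest::randomForest(x, y,
                                   ntree = hp_get("ntree", 100),
                                   mtry = hp_get("mtry",
                                                 max(1L, floor(sqrt(ncol(x)))))))
      function(newx) unname(predict(m, newx, type = "prob")[, "malignant"])
    },
    mlp = function(x, y, seed = spec$seed) {
      d <- cbind(x, .y = y)
      m <- with_seed(seed,
        nnet::nnet(.y ~ ., data = d, size = hp_get("size", 8),
                   maxit = hp_get("maxit", 500),
                   decay = hp_get("decay", 1e-4), trace = FALSE))
      # single logistic output = probability of the second level (malignant)
      function(newx) as.numeric(predict(m, newx, type = "raw"))
    },
    lda = function(x, y, seed = spec$seed) {
      m <- MASS::lda(x, grouping = y)
      function(newx) unname(predict(m, newx)$posterior[, "malignant"])
    },
    svm = function(x, y, seed = spec$seed) {
      v <- stats::var(as.vector(as.matrix(x)))
      g <- hp_get("gamma",
                  if (is.finite(v) && v > 0) 1 / (ncol(x) * v) else 1 / ncol(x))
      m <- e1071::svm(as.matrix(x), y, kernel = "radial",
                      cost = hp_get("cost", 1), gamma = g, scale = FALSE)
      function(newx) {
        p <- predict(m, as.matrix(newx), decision.values = TRUE)
        d <- drop(attr(p, "decision.values"))
        # decision value is signed towards the first class of the colname
        first <- strsplit(colnames(attr(p, "decision.values"))[1L], "/")[[1L]][1L]
        if (identical(first, "malignant")) stats::plogis(d)
        else stats::plogis(-d)
      }
    })
  list(fit = fit, needs_scaling = spec$method %in% c("mlp", "lda", "svm"))
}
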