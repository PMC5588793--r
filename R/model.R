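#' Classifier configuration
#'
#' A cost-sensitive support vector machine on composition features. The
#' kernel and its hyperparameters are explicit configuration: the defaults
#' are an RBF kernel with `gamma = 1/(dim * mean feature variance)` (the
#' variance-aware "scale" convention, appropriate for percentage-scale
#' composition vectors, which are never standardized), `cost = 10`, and a
#' misclassification-cost
#' ratio equal to the class imbalance (`n_neg / n_pos`) so the minority
#' ERRP class is not swamped. Set `tune = TRUE` to grid-search `cost` and
#' `gamma` by internal cross-validation on the training data (never on
#' held-out examples).
#'
#' @param scheme feature scheme the model consumes (one of
#'   [FEATURE_SCHEMES]).
#' @param kernel `"radial"` or `"linear"`.
#' @param cost SVM regularisation constant C.
#' @param gamma RBF width; `NULL` = `1/(dim * mean feature variance)`,
#'   computed on the training matrix.
#' @param cost_ratio weight of a positive-class error relative to a
#'   negative-class error; `NULL` = `n_neg/n_pos` computed at fit time.
#' @param threshold decision threshold on the margin score (default 0;
#'   scores `>=` threshold are called positive).
#' @param n split size for the SAAC schemes.
#' @param lambda,w pseudo amino acid composition parameters.
#' @param tune logical; grid-search `cost`/`gamma` at fit time.
#' @param tune_cost,tune_gamma grids used when `tune = TRUE`.
#' @return A list of class `svm_config`.
#' @export
svm_config <- function(scheme = "SAAC3", kernel = c("radial", "linear"),
                       cost = 10, gamma = NULL, cost_ratio = NULL,
                       threshold = 0, n = 25L, lambda = 1L, w = 0.05,
                       tune = FALSE,
                       tune_cost = 2^seq(-5, 15, by = 4),
                       tune_gamma = 2^seq(-15, 3, by = 4)) {
  scheme <- match.arg(scheme, FEATURE_SCHEMES)
  kernel <- match.arg(kernel)
  if (!is.finite(threshold)) config_error("threshold must be finite")
  structure(list(scheme = scheme, kernel = kernel, cost = cost,
                 gamma = gamma, cost_ratio = cost_ratio,
                 threshold = threshold, n = as.integer(n),
                 lambda = as.integer(lambda), w = w, tune = tune,
                 tune_cost = tune_cost, tune_gamma = tune_gamma),
            class = "svm_config")
}

check_xy <- function(X, y, config) {
  dim_expected <- scheme_dimension(config$scheme, config$lambda)
  if (ncol(X) != dim_expected) {
    input_error(sprintf("feature matrix has %d columns; scheme %s expects %d",
                        ncol(X), config$scheme, dim_expected))
  }
  y <- factor(as.character(y), levels = c("positive", "negative"))
  if (anyNA(y)) input_error("labels must be 'positive' or 'negative'")
  if (nlevels(droplevels(y)) < 2L) {
    input_error("training data must contain both classes")
  }
  if (length(y) != nrow(X)) input_error("X and y sizes differ")
  y
}

#' Train the classifier
#'
#' @param X numeric feature matrix (rows = sequences), e.g. from
#'   [encode_batch()].
#' @param y labels, `"positive"` / `"negative"`, one per row.
#' @param config an [svm_config()].
#' @return An object of class `erpred_model`.
#' @export
train_model <- function(X, y, config = svm_config()) {
  y <- check_xy(X, y, config)
  n_pos <- sum(y == "positive"); n_neg <- sum(y == "negative")
  cost_ratio <- config$cost_ratio %||% (n_neg / n_pos)
  gamma <- config$gamma %||% default_gamma(X)
  cost <- config$cost
  wts <- c(positive = cost_ratio, negative = 1)
  if (isTRUE(config$tune)) {
    grid <- expand.grid(cost = config$tune_cost,
                        gamma = if (config$kernel == "radial")
                          config$tune_gamma else 1 / ncol(X))
    acc <- vapply(seq_len(nrow(grid)), function(i) {
      m <- e1071::svm(X, y, kernel = config$kernel, cost = grid$cost[i],
                      gamma = grid$gamma[i], class.weights = wts,
                      scale = FALSE, cross = 3)
      m$tot.accuracy
    }, numeric(1))
    best <- which.max(acc)
    cost <- grid$cost[best]; gamma <- grid$gamma[best]
  }
  fit <- e1071::svm(X, y, kernel = config$kernel, cost = cost, gamma = gamma,
                    class.weights = wts, scale = FALSE)
  # libsvm orients decision values toward the first class it encounters;
  # record the sign that makes higher scores mean "positive"
  dv <- attr(stats::predict(fit, X[1, , drop = FALSE], decision.values = TRUE),
             "decision.values")
  sign_flip <- if (colnames(dv)[1L] == "negative/positive") -1 else 1
  structure(list(config = config, fit = fit, sign_flip = sign_flip,
                 cost = cost, gamma = gamma, cost_ratio = cost_ratio,
                 threshold = config$threshold,
                 n_train = c(positive = n_pos, negative = n_neg),
                 train_checksum = matrix_checksum(X),
                 version = 1L),
            class = "erpred_model")
}

# variance-aware RBF width: 1 / (dim * mean per-feature variance)
default_gamma <- function(X) {
  v <- mean(apply(X, 2, stats::var))
  if (!is.finite(v) || v <= 0) return(1 / ncol(X))
  1 / (ncol(X) * v)
}

matrix_checksum <- function(X) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(list(dim(X), round(unname(X), 9)), f, version = 2)
  unname(tools::md5sum(f))
}

#' @export
print.erpred_model <- function(x, ...) {
  cat(sprintf(
    "<erpred_model> scheme=%s kernel=%s cost=%g gamma=%g cost_ratio=%.3g threshold=%g\n",
    x$config$scheme, x$config$kernel, x$cost, x$gamma, x$cost_ratio,
    x$threshold))
  cat(sprintf("  trained on %d positive / %d negative examples\n",
              x$n_train["positive"], x$n_train["negative"]))
  invisible(x)
}

#' Score and classify feature vectors
#'
#' Returns the raw margin score of every row (higher = more ERRP-like) and
#' the thresholded label: positive iff `score >= threshold`.
#'
#' @param model an `erpred_model`.
#' @param X feature matrix with the model's scheme dimension.
#' @param threshold decision threshold; defaults to the model's stored one.
#' @return `data.frame` with columns `id` (row names of `X`, or row index),
#'   `score`, `label`.
#' @export
predict_model <- function(model, X, threshold = NULL) {
  if (!inherits(model, "erpred_model")) input_error("not an erpred_model")
  dim_expected <- scheme_dimension(model$config$scheme, model$config$lambda)
  if (ncol(X) != dim_expected) {
    input_error(sprintf(
      "feature matrix has %d columns; model scheme %s expects %d",
      ncol(X), model$config$scheme, dim_expected))
  }
  threshold <- threshold %||% model$threshold
  if (nrow(X) == 0L) {
    return(data.frame(id = character(), score = numeric(),
                      label = character(), stringsAsFactors = FALSE))
  }
  pr <- stats::predict(model$fit, X, decision.values = TRUE)
  score <- model$sign_flip * as.numeric(attr(pr, "decision.values"))
  data.frame(id = rownames(X) %||% as.character(seq_len(nrow(X))),
             score = score,
             label = ifelse(score >= threshold, "positive", "negative"),
             stringsAsFactors = FALSE)
}

#' Save / load a trained model
#'
#' The model file is a self-describing container: scheme, split size,
#' kernel and hyperparameters, cost ratio, a checksum of the training
#' matrix, and the decision threshold. `load_model(save_model(m))`
#' reproduces identical predictions.
#'
#' @param model an `erpred_model`.
#' @param path file path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   model.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "erpred_model")) input_error("not an erpred_model")
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) input_error(sprintf("model file not found: %s", path))
  model <- tryCatch(readRDS(path), error = function(e) {
    input_error(sprintf("cannot read model file '%s': %s", path,
                        conditionMessage(e)))
  })
  if (!inherits(model, "erpred_model") || is.null(model$version)) {
    input_error(sprintf("'%s' is not an erpred model file", path))
  }
  if (model$version != 1L) {
    input_error(sprintf("unsupported model file version %s", model$version))
  }
  model
}
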