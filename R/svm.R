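#' Classifier configuration
#'
#' Hyperparameters and bookkeeping shared by all classifiers in the package.
#' Defaults are a linear-kernel SVM with regularization cost 1 and
#' Platt-style sigmoid probability calibration; stacking (CombC) uses 5
#' internal out-of-fold partitions. All randomness downstream (fold
#' partitions, stacking splits) flows from `seed`.
#'
#' @param seed Integer seed controlling every stochastic choice.
#' @param kernel SVM kernel, passed to [e1071::svm()] (default "linear").
#' @param cost Regularization parameter C (default 1).
#' @param stacking_folds Internal out-of-fold partitions for meta-feature
#'   generation in CombC (default 5).
#' @param fit_log Optional environment; when supplied, every fit of a
#'   standardizer or classifier appends a record of the document ids it was
#'   fitted on (instrumentation for leakage audits).
#' @return An object of class `fw_config`.
#' @export
fw_config <- function(seed = 1L, kernel = "linear", cost = 1,
                      stacking_folds = 5L, fit_log = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            is.numeric(cost), cost > 0,
            is.numeric(stacking_folds), stacking_folds >= 2L)
  if (!is.null(fit_log)) stopifnot(is.environment(fit_log))
  structure(list(seed = as.integer(seed), kernel = kernel, cost = cost,
                 stacking_folds = as.integer(stacking_folds),
                 fit_log = fit_log),
            class = "fw_config")
}

# Record a fit event (component name, fold context, training doc ids)
# into the instrumentation log, if one is attached.
log_fit <- function(config, component, doc_ids) {
  env <- config$fit_log
  if (is.null(env)) return(invisible(NULL))
  if (is.null(env$records)) env$records <- list()
  env$records[[length(env$records) + 1L]] <-
    list(component = component, context = env$context, doc_ids = doc_ids)
  invisible(NULL)
}

# Platt's sigmoid calibration: fit P(y=1|f) = 1/(1+exp(A f + B)) by
# regularized maximum likelihood (Newton iteration with backtracking,
# using Platt's soft targets so separable data cannot blow up the fit).
platt_fit <- function(f, y, max_iter = 100L) {
  stopifnot(length(f) == length(y), all(y %in% c(0L, 1L)))
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  hi <- (n1 + 1) / (n1 + 2); lo <- 1 / (n0 + 2)
  t <- ifelse(y == 1L, hi, lo)
  A <- 0; B <- log((n0 + 1) / (n1 + 1))
  sigma <- 1e-12; min_step <- 1e-10
  fval <- function(A, B) {
    fApB <- A * f + B
    sum(ifelse(fApB >= 0,
               t * fApB + log1p(exp(-fApB)),
               (t - 1) * fApB + log1p(exp(fApB))))
  }
  fv <- fval(A, B)
  for (it in seq_len(max_iter)) {
    fApB <- A * f + B
    p <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)),
                1 / (1 + exp(fApB)))
    q <- 1 - p
    d1 <- t - p
    d2 <- p * q
    g1 <- sum(f * d1); g2 <- sum(d1)
    if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
    h11 <- sum(f * f * d2) + sigma
    h22 <- sum(d2) + sigma
    h21 <- sum(f * d2)
    det <- h11 * h22 - h21 * h21
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    step <- 1
    while (step >= min_step) {
      nA <- A + step * dA; nB <- B + step * dB
      nf <- fval(nA, nB)
      if (nf < fv + 1e-4 * step * gd) {
        A <- nA; B <- nB; fv <- nf
        break
      }
      step <- step / 2
    }
    if (step < min_step) break
  }
  list(A = A, B = B)
}

platt_predict <- function(model, f) {
  fApB <- model$A * f + model$B
  ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)), 1 / (1 + exp(fApB)))
}

#' Train a base SVM classifier on one feature block
#'
#' Pipeline: train-fit standardization -> maximum-margin classifier
#' ([e1071::svm()]) -> Platt-style sigmoid calibration of decision values
#' into relevant-class probabilities. For linear kernels, columns that are
#' constant in the (standardized) training block are dropped before the SVM
#' call: centered constant columns are identically zero in every support
#' vector and contribute nothing to any linear decision value, so the
#' reduction is prediction-exact and keeps the sparse 2048-column d_IMG
#' block fast. Training is deterministic given the inputs and config.
#'
#' @param x Numeric feature matrix, rows = training documents (rownames used
#'   as doc ids for fit logging).
#' @param y Integer 0/1 labels (1 = relevant); both classes must be present.
#' @param config An [fw_config()].
#' @param component Component name recorded in the fit log.
#' @return An object of class `fw_base_model`.
#' @export
train_base <- function(x, y, config = fw_config(), component = "base") {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class; cannot fit a classifier",
         call. = FALSE)
  std <- fit_standardizer(x)
  xs <- apply_standardizer(std, x)
  keep <- if (identical(config$kernel, "linear")) which(!std$constant)
          else seq_len(ncol(xs))
  if (length(keep) == 0L)
    stop("all features are constant in the training data", call. = FALSE)
  fit <- e1071::svm(x = xs[, keep, drop = FALSE],
                    y = factor(y, levels = c(0L, 1L)),
                    kernel = config$kernel, cost = config$cost,
                    scale = FALSE)
  dv <- predict(fit, xs[, keep, drop = FALSE], decision.values = TRUE)
  f <- attr(dv, "decision.values")[, 1L]
  # libsvm orients decision values toward the first label it encounters;
  # flip so positive decision values favor the relevant class (1)
  flip <- if (startsWith(colnames(attr(dv, "decision.values"))[1L], "1")) 1
          else -1
  platt <- platt_fit(flip * f, y)
  log_fit(config, component, rownames(x))
  structure(list(std = std, keep = keep, fit = fit, flip = flip,
                 platt = platt, kernel = config$kernel),
            class = "fw_base_model")
}

#' Predict with a base classifier
#'
#' @param model An `fw_base_model` from [train_base()].
#' @param x Feature matrix with the same columns as at training.
#' @return A data.frame with columns `label` (0/1, 1 = relevant; equals
#'   `prob >= 0.5`) and `prob` (calibrated relevant-class probability);
#'   rownames are the doc ids of `x`.
#' @export
predict_base <- function(model, x) {
  stopifnot(inherits(model, "fw_base_model"))
  x <- as.matrix(x)
  xs <- apply_standardizer(model$std, x)
  dv <- predict(model$fit, xs[, model$keep, drop = FALSE],
                decision.values = TRUE)
  f <- model$flip * attr(dv, "decision.values")[, 1L]
  prob <- platt_predict(model$platt, f)
  data.frame(label = as.integer(prob >= 0.5), prob = prob,
             row.names = rownames(x))
}
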