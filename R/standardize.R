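#' Fit a feature standardizer
#'
#' Learns per-column means and standard deviations from a training matrix so
#' features can be rescaled to mean 0 and standard deviation 1. Fitting is
#' confined to training rows; [apply_standardizer()] reuses the stored
#' statistics on any matrix (no test-set leakage). Columns that are constant
#' in training have their sd clamped to 1, so they transform to all-zero
#' rather than dividing by zero.
#'
#' The standard deviation is the population form (divisor n), so a
#' two-point column `c(1, 3)` transforms exactly to `c(-1, 1)`.
#'
#' @param train Numeric matrix (rows = training documents).
#' @return An object of class `fw_standardizer` with `mean`, `sd` (clamped)
#'   and `constant` (logical per column).
#' @export
fit_standardizer <- function(train) {
  train <- as.matrix(train)
  if (nrow(train) < 2L)
    stop("standardizer needs at least 2 training rows", call. = FALSE)
  mu <- colMeans(train)
  sdv <- sqrt(colMeans(sweep(train, 2L, mu, "-")^2))
  constant <- !is.finite(sdv) | sdv < .Machine$double.eps^0.5
  sdv[constant] <- 1
  structure(list(mean = mu, sd = sdv, constant = constant),
            class = "fw_standardizer")
}

#' Apply a fitted standardizer
#'
#' @param model An `fw_standardizer` from [fit_standardizer()].
#' @param x Numeric matrix with the same columns as the training matrix.
#' @return The rescaled matrix.
#' @export
apply_standardizer <- function(model, x) {
  stopifnot(inherits(model, "fw_standardizer"))
  x <- as.matrix(x)
  if (ncol(x) != length(model$mean))
    stop("standardizer fitted on ", length(model$mean),
         " columns, got ", ncol(x), call. = FALSE)
  sweep(sweep(x, 2L, model$mean, "-"), 2L, model$sd, "/")
}
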