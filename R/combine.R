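# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin over k folds, so every fold keeps (up to rounding) the corpus
# class balance and every training set contains both classes.
make_folds <- function(y, k, seed) {
  y <- as.integer(y)
  n <- length(y)
  if (any(tabulate(y + 1L, 2L) < k))
    stop("cannot stratify: a class has fewer than ", k, " members",
         call. = FALSE)
  folds <- integer(n)
  set.seed(as.integer(seed))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

fw_schemes <- c("img", "cap", "ta", "combv", "combc")

meta_feature_names <- c("L_IMG", "P_IMG", "L_CAP", "P_CAP", "L_TA", "P_TA")

# Assemble the 6-dim meta-feature block <L_IMG,P_IMG,L_CAP,P_CAP,L_TA,P_TA>
# from per-modality base outputs (order fixed).
meta_features <- function(img, cap, ta) {
  m <- cbind(img$label, img$prob, cap$label, cap$prob, ta$label, ta$prob)
  colnames(m) <- meta_feature_names
  rownames(m) <- rownames(img)
  m
}

#' Train a classification scheme
#'
#' Trains one of the five document classifiers on the given training rows of
#' a representation set:
#' * `"img"`, `"cap"`, `"ta"` - a base SVM on the single block d_IMG, d_CAP
#'   or d_TA;
#' * `"combv"` - integration via concatenated vectors: the blocks are
#'   concatenated into d_ALL, standardized (train-fit), and classified by a
#'   single SVM;
#' * `"combc"` - integration via meta-classification (stacking): base SVMs
#'   are trained separately per block; meta-features for the training
#'   documents are produced by internal stratified out-of-fold prediction
#'   (so the meta-classifier never sees in-sample base outputs); the
#'   meta-SVM is trained on the 6-dim `<L_IMG,P_IMG,L_CAP,P_CAP,L_TA,P_TA>`
#'   vectors; base classifiers refit on the full training set supply
#'   meta-features at prediction time.
#'
#' @param reps An `fw_reps` from [build_representations()].
#' @param scheme One of `"img"`, `"cap"`, `"ta"`, `"combv"`, `"combc"`.
#' @param train_idx Integer row indices of the training documents (default
#'   all labeled rows).
#' @param config An [fw_config()].
#' @return An object of class `fw_model`.
#' @export
train_scheme <- function(reps, scheme = fw_schemes,
                         train_idx = NULL, config = fw_config()) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(reps, "fw_reps"))
  if (is.null(train_idx)) train_idx <- which(!is.na(reps$labels))
  y <- rep_y(reps, train_idx)

  if (scheme %in% c("img", "cap", "ta")) {
    x <- rep_block(reps, scheme, train_idx)
    model <- list(base = train_base(x, y, config, component = scheme))
  } else if (scheme == "combv") {
    model <- list(base = train_base(rep_all(reps, train_idx), y, config,
                                    component = "combv"))
  } else {
    blocks <- c("img", "cap", "ta")
    inner <- make_folds(y, config$stacking_folds,
                        seed = config$seed + 104729L)
    oof <- matrix(NA_real_, length(train_idx), 6L,
                  dimnames = list(reps$doc_ids[train_idx],
                                  meta_feature_names))
    for (j in seq_len(config$stacking_folds)) {
      tr <- inner != j; ho <- inner == j
      preds <- lapply(blocks, function(b) {
        fit <- train_base(rep_block(reps, b, train_idx[tr]), y[tr], config,
                          component = paste0("combc_oof_", b))
        predict_base(fit, rep_block(reps, b, train_idx[ho]))
      })
      oof[ho, ] <- meta_features(preds[[1L]], preds[[2L]], preds[[3L]])
    }
    bases <- lapply(stats::setNames(blocks, blocks), function(b)
      train_base(rep_block(reps, b, train_idx), y, config,
                 component = paste0("combc_base_", b)))
    meta <- train_base(oof, y, config, component = "combc_meta")
    model <- list(bases = bases, meta = meta)
  }
  structure(c(model, list(scheme = scheme, config = config)),
            class = "fw_model")
}

#' Predict with a trained scheme
#'
#' @param model An `fw_model` from [train_scheme()].
#' @param reps Representation set to predict on (built with the same
#'   taxonomy and embedding table as at training).
#' @param idx Row indices to predict (default all rows).
#' @return Data frame with columns `doc_id`, `label` (0/1, 1 = relevant)
#'   and `prob` (relevant-class probability).
#' @export
predict_scheme <- function(model, reps, idx = NULL) {
  stopifnot(inherits(model, "fw_model"), inherits(reps, "fw_reps"))
  if (is.null(idx)) idx <- seq_along(reps$doc_ids)
  if (model$scheme %in% c("img", "cap", "ta")) {
    out <- predict_base(model$base, rep_block(reps, model$scheme, idx))
  } else if (model$scheme == "combv") {
    out <- predict_base(model$base, rep_all(reps, idx))
  } else {
    preds <- lapply(c("img", "cap", "ta"), function(b)
      predict_base(model$bases[[b]], rep_block(reps, b, idx)))
    out <- predict_base(model$meta,
                        meta_features(preds[[1L]], preds[[2L]], preds[[3L]]))
  }
  data.frame(doc_id = reps$doc_ids[idx], label = out$label, prob = out$prob,
             row.names = NULL)
}

#' @rdname train_scheme
#' @export
train_combv <- function(reps, train_idx = NULL, config = fw_config()) {
  train_scheme(reps, "combv", train_idx, config)
}

#' @rdname train_scheme
#' @export
train_combc <- function(reps, train_idx = NULL, config = fw_config()) {
  train_scheme(reps, "combc", train_idx, config)
}

#' @rdname predict_scheme
#' @param ... Passed to [predict_scheme()].
#' @export
predict_combv <- function(model, reps, ...) {
  stopifnot(identical(model$scheme, "combv"))
  predict_scheme(model, reps, ...)
}

#' @rdname predict_scheme
#' @export
predict_combc <- function(model, reps, ...) {
  stopifnot(identical(model$scheme, "combc"))
  predict_scheme(model, reps, ...)
}
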