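#' Confusion counts
#'
#' @param pred Integer 0/1 predicted labels (1 = relevant).
#' @param gold Integer 0/1 gold labels, same length.
#' @return Named integer vector `c(tp, fp, fn, tn)`.
#' @export
confusion_counts <- function(pred, gold) {
  stopifnot(length(pred) == length(gold),
            all(pred %in% c(0L, 1L)), all(gold %in% c(0L, 1L)))
  c(tp = sum(pred == 1L & gold == 1L),
    fp = sum(pred == 1L & gold == 0L),
    fn = sum(pred == 0L & gold == 1L),
    tn = sum(pred == 0L & gold == 0L))
}

#' Precision, recall and F-score
#'
#' Standard relevance-retrieval measures: precision = TP/(TP+FP), recall =
#' TP/(TP+FN), F = 2PR/(P+R). When a denominator is zero the measure is
#' undefined; it is reported as 0 with a warning (so degenerate folds do not
#' crash aggregate reporting).
#'
#' @param counts Named vector with `tp`, `fp`, `fn` (and optionally `tn`),
#'   as from [confusion_counts()].
#' @return Named numeric vector `c(precision, recall, f_score)`.
#' @export
metrics <- function(counts) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]; fn <- counts[["fn"]]
  if (tp + fp > 0) p <- tp / (tp + fp)
  else { warning("precision undefined (no predicted positives); using 0",
                 call. = FALSE); p <- 0 }
  if (tp + fn > 0) r <- tp / (tp + fn)
  else { warning("recall undefined (no gold positives); using 0",
                 call. = FALSE); r <- 0 }
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f_score = f)
}

#' Cross-validation plan
#'
#' Repeated stratified k-fold cross-validation: `rounds` complete rounds of
#' `folds`-fold CV, each round using a distinct stratified partition of the
#' corpus (default: five rounds of 5-fold CV, i.e. 25 train/test
#' evaluations). Each round's partition is driven by its own seed derived
#' deterministically from `seed`.
#'
#' @param rounds Number of complete CV rounds (default 5).
#' @param folds Number of folds per round (default 5).
#' @param seed Base seed; round r uses seed `seed + 1000 * (r - 1)`.
#' @return An object of class `fw_cv_plan`.
#' @export
make_cv_plan <- function(rounds = 5L, folds = 5L, seed = 1L) {
  stopifnot(rounds >= 1L, folds >= 2L)
  structure(list(rounds = as.integer(rounds), folds = as.integer(folds),
                 seeds = as.integer(seed) + 1000L * (seq_len(rounds) - 1L)),
            class = "fw_cv_plan")
}

#' Run cross-validated evaluation of a scheme
#'
#' For every (round, fold) of the plan: all fitted components (standardizer,
#' base classifiers, stacking, meta-classifier) are trained on the training
#' folds only, the held-out fold is predicted, and precision, recall,
#' F-score and accuracy are recorded. With the default 5x5 plan this yields
#' 25 rows per scheme. Identical seeds and inputs reproduce the identical
#' score table.
#'
#' @param reps An `fw_reps` over a fully labeled corpus.
#' @param scheme Scheme name, see [train_scheme()].
#' @param plan An [make_cv_plan()] object.
#' @param config An [fw_config()]; its `fit_log`, when set, receives every
#'   fit event annotated with the (round, fold) context for leakage audits.
#' @param keep_predictions Attach per-document predictions as attribute
#'   `"predictions"`?
#' @return A data.frame (class `fw_scores`) with columns `scheme`, `round`,
#'   `fold`, `tp`, `fp`, `fn`, `tn`, `precision`, `recall`, `f_score`,
#'   `accuracy`.
#' @export
run_cv <- function(reps, scheme, plan = make_cv_plan(),
                   config = fw_config(), keep_predictions = FALSE) {
  stopifnot(inherits(reps, "fw_reps"), inherits(plan, "fw_cv_plan"))
  y <- rep_y(reps)
  n <- length(y)
  rows <- list()
  preds_acc <- list()
  for (r in seq_len(plan$rounds)) {
    folds <- make_folds(y, plan$folds, seed = plan$seeds[r])
    for (k in seq_len(plan$folds)) {
      if (!is.null(config$fit_log))
        config$fit_log$context <- c(round = r, fold = k)
      tr <- which(folds != k); te <- which(folds == k)
      model <- train_scheme(reps, scheme, train_idx = tr, config = config)
      pred <- predict_scheme(model, reps, idx = te)
      cc <- confusion_counts(pred$label, y[te])
      m <- suppressWarnings(metrics(cc))
      rows[[length(rows) + 1L]] <- data.frame(
        scheme = scheme, round = r, fold = k,
        tp = cc[["tp"]], fp = cc[["fp"]], fn = cc[["fn"]], tn = cc[["tn"]],
        precision = m[["precision"]], recall = m[["recall"]],
        f_score = m[["f_score"]],
        accuracy = (cc[["tp"]] + cc[["tn"]]) / length(te)
      )
      if (keep_predictions)
        preds_acc[[length(preds_acc) + 1L]] <-
          cbind(data.frame(scheme = scheme, round = r, fold = k), pred,
                gold = y[te])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (keep_predictions)
    attr(out, "predictions") <- do.call(rbind, preds_acc)
  class(out) <- c("fw_scores", class(out))
  out
}

#' Summarize a score table
#'
#' Mean and standard deviation per scheme of precision, recall, F-score and
#' accuracy over all (round, fold) evaluations, mirroring the usual
#' mean (sd) benchmark layout.
#'
#' @param scores An `fw_scores` table (rows from one or more schemes may be
#'   rbind-ed together).
#' @return A data.frame with one row per scheme.
#' @export
score_summary <- function(scores) {
  measures <- c("precision", "recall", "f_score", "accuracy")
  out <- do.call(rbind, lapply(split(scores, scores$scheme), function(s) {
    row <- data.frame(scheme = s$scheme[1L], n_evals = nrow(s))
    for (m in measures) {
      row[[paste0(m, "_mean")]] <- mean(s[[m]])
      row[[paste0(m, "_sd")]] <- stats::sd(s[[m]])
    }
    row
  }))
  rownames(out) <- NULL
  out
}

# Welch two-sample t statistic with the degenerate cases guarded:
# identical constant samples give t = 0, p = 1; zero-variance separation
# gives t = +/-Inf, p = 0.
welch_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 2L, n2 >= 2L)
  m1 <- mean(x); m2 <- mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  se2 <- v1 / n1 + v2 / n2
  if (se2 <= 0) {
    if (m1 == m2) return(list(t = 0, df = n1 + n2 - 2, p = 1))
    return(list(t = sign(m1 - m2) * Inf, df = n1 + n2 - 2, p = 0))
  }
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Compare two systems' cross-validation scores
#'
#' Welch (unequal-variance) two-sample t-test on the per-fold scores of two
#' systems evaluated under the same CV plan. A positive t statistic means
#' system `a` scored higher on average. `level = "round"` pools each round's
#' folds into a round mean before testing.
#'
#' @param a,b `fw_scores` tables for the two systems, with equal numbers of
#'   evaluations.
#' @param measure Score column to compare (default `"f_score"`).
#' @param level `"fold"` (default; test over all round x fold scores) or
#'   `"round"` (test over per-round means).
#' @return List with `t`, `df`, `p`, and the two mean scores.
#' @export
compare_systems <- function(a, b, measure = "f_score",
                            level = c("fold", "round")) {
  level <- match.arg(level)
  stopifnot(measure %in% names(a), measure %in% names(b))
  if (nrow(a) != nrow(b))
    stop("score tables have different numbers of evaluations (",
         nrow(a), " vs ", nrow(b), ")", call. = FALSE)
  pick <- function(s) {
    if (level == "fold") s[[measure]]
    else as.numeric(tapply(s[[measure]], s$round, mean))
  }
  x <- pick(a); y <- pick(b)
  res <- welch_t(x, y)
  c(res, list(mean_a = mean(x), mean_b = mean(y), measure = measure,
              level = level))
}

align_preds <- function(p, gold_ids) {
  stopifnot(is.data.frame(p), all(c("doc_id", "label") %in% names(p)))
  i <- match(gold_ids, p$doc_id)
  if (anyNA(i))
    stop("predictions are missing documents: '",
         gold_ids[is.na(i)][1L], "'", call. = FALSE)
  p$label[i]
}

#' Complementarity of two classifiers on the relevant class
#'
#' Among gold-relevant documents, counts how many are correctly identified
#' by classifier A only, by B only, by both, and by neither — the pairwise
#' error-overlap analysis showing whether two information sources capture
#' distinct documents.
#'
#' @param preds_a,preds_b Data frames with columns `doc_id` and `label`
#'   (0/1) covering the same documents.
#' @param gold Data frame with columns `doc_id` and `gold` (0/1 or
#'   "relevant"/"irrelevant").
#' @return List with counts `a_only`, `b_only`, `both`, `neither` and the
#'   corresponding doc-id vectors `a_only_ids`, `b_only_ids`.
#' @export
complementarity <- function(preds_a, preds_b, gold) {
  g <- normalize_gold(gold)
  rel <- g$doc_id[g$gold == 1L]
  a <- align_preds(preds_a, rel) == 1L
  b <- align_preds(preds_b, rel) == 1L
  list(a_only = sum(a & !b), b_only = sum(!a & b),
       both = sum(a & b), neither = sum(!a & !b),
       a_only_ids = rel[a & !b], b_only_ids = rel[!a & b])
}

#' Three-way complementarity region counts
#'
#' Venn-style region counts over gold-relevant documents for three
#' classifiers: each region is the set of relevant documents correctly
#' identified by exactly that combination of classifiers. Region counts sum
#' to the number of relevant documents identified by at least one
#' classifier, plus `none`.
#'
#' @param preds_a,preds_b,preds_c Prediction data frames as in
#'   [complementarity()].
#' @inheritParams complementarity
#' @return Named list of counts: `a_only`, `b_only`, `c_only`, `ab`, `ac`,
#'   `bc`, `abc`, `none`.
#' @export
complementarity3 <- function(preds_a, preds_b, preds_c, gold) {
  g <- normalize_gold(gold)
  rel <- g$doc_id[g$gold == 1L]
  a <- align_preds(preds_a, rel) == 1L
  b <- align_preds(preds_b, rel) == 1L
  c_ <- align_preds(preds_c, rel) == 1L
  list(a_only = sum(a & !b & !c_), b_only = sum(!a & b & !c_),
       c_only = sum(!a & !b & c_),
       ab = sum(a & b & !c_), ac = sum(a & !b & c_), bc = sum(!a & b & c_),
       abc = sum(a & b & c_), none = sum(!a & !b & !c_))
}

normalize_gold <- function(gold) {
  stopifnot(is.data.frame(gold), all(c("doc_id", "gold") %in% names(gold)))
  g <- gold
  if (is.character(g$gold)) g$gold <- as.integer(g$gold == "relevant")
  stopifnot(all(g$gold %in% c(0L, 1L)))
  g
}
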