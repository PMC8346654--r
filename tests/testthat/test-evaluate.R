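test_that("precision/recall/F match their definitions and guard zeros", {
  m <- metrics(c(tp = 8, fp = 2, fn = 2, tn = 8))
  expect_equal(unname(m), c(0.8, 0.8, 0.8))
  expect_warning(m0 <- metrics(c(tp = 0, fp = 0, fn = 5, tn = 0)),
                 "precision undefined")
  expect_equal(unname(m0), c(0, 0, 0))
})

test_that("metrics agree with brute-force recomputation on random counts", {
  set.seed(91)
  for (i in 1:50) {
    pred <- rbinom(60, 1, 0.5)
    gold <- rbinom(60, 1, 0.5)
    cc <- confusion_counts(pred, gold)
    expect_identical(sum(cc), 60L)
    # independent recomputation straight from the prediction vectors
    p_ref <- sum(pred & gold) / sum(pred)
    r_ref <- sum(pred & gold) / sum(gold)
    f_ref <- 2 * p_ref * r_ref / (p_ref + r_ref)
    if (!is.finite(p_ref) || !is.finite(r_ref)) next
    m <- suppressWarnings(metrics(cc))
    expect_equal(unname(m["precision"]), p_ref, tolerance = 1e-12)
    expect_equal(unname(m["recall"]), r_ref, tolerance = 1e-12)
    expect_equal(unname(m["f_score"]),
                 if (is.finite(f_ref)) f_ref else 0, tolerance = 1e-12)
  }
})

test_that("stratified folds partition each round and keep both classes", {
  y <- rep(c(0L, 1L), c(40L, 24L))
  folds <- make_folds(y, 5L, seed = 3L)
  expect_identical(sort(unique(folds)), 1:5)
  for (k in 1:5) {
    expect_true(all(table(y[folds != k]) > 0))
    # stratification keeps near-balanced fold sizes per class
    expect_lte(abs(sum(folds == k & y == 1L) - 24 / 5), 1)
  }
  expect_error(make_folds(rep(c(0L, 1L), c(60L, 3L)), 5L, seed = 1L),
               "stratify")
})

test_that("cross-validation yields rounds x folds rows covering every doc", {
  reps <- fix_separable_reps(n = 30L)
  plan <- make_cv_plan(rounds = 2L, folds = 5L, seed = 7L)
  st <- run_cv(reps, "cap", plan, fw_config(seed = 1),
               keep_predictions = TRUE)
  expect_identical(nrow(st), 10L)
  sizes <- st$tp + st$fp + st$fn + st$tn
  expect_true(all(tapply(sizes, st$round, sum) == 30))
  preds <- attr(st, "predictions")
  for (r in 1:2) {
    tested <- preds$doc_id[preds$round == r]
    expect_identical(sort(tested), sort(reps$doc_ids))  # exactly once
  }
  # distinct partitions across rounds
  f1 <- preds$fold[preds$round == 1][order(preds$doc_id[preds$round == 1])]
  f2 <- preds$fold[preds$round == 2][order(preds$doc_id[preds$round == 2])]
  expect_false(identical(f1, f2))
})

test_that("identical seeds reproduce the identical score table", {
  reps <- fix_separable_reps(n = 24L, seed = 19L)
  plan <- make_cv_plan(rounds = 2L, folds = 4L, seed = 5L)
  s1 <- run_cv(reps, "combv", plan, fw_config(seed = 2))
  s2 <- run_cv(reps, "combv", plan, fw_config(seed = 2))
  expect_identical(s1, s2)
})

test_that("score summaries report mean and sd per scheme", {
  st <- data.frame(scheme = "x", round = rep(1:2, each = 2), fold = 1:2,
                   tp = 1, fp = 1, fn = 1, tn = 1,
                   precision = c(0.5, 0.7, 0.6, 0.8),
                   recall = c(0.4, 0.6, 0.5, 0.7),
                   f_score = c(0.44, 0.65, 0.55, 0.75),
                   accuracy = c(0.5, 0.65, 0.55, 0.75))
  sm <- score_summary(st)
  expect_equal(sm$precision_mean, 0.65)
  expect_equal(sm$f_score_sd, sd(c(0.44, 0.65, 0.55, 0.75)))
})

test_that("system comparison matches Welch's t-test and guards degeneracy", {
  mk <- function(f) data.frame(scheme = "s", round = rep(1:5, each = 5),
                               f_score = f)
  set.seed(13)
  for (i in 1:20) {
    a <- mk(runif(25, 0.6, 0.9))
    b <- mk(runif(25, 0.5, 0.8))
    res <- compare_systems(a, b)
    ref <- t.test(a$f_score, b$f_score)  # independent oracle
    expect_equal(res$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(res$p, ref$p.value, tolerance = 1e-10)
    # symmetry up to sign
    expect_equal(compare_systems(b, a)$t, -res$t, tolerance = 1e-12)
  }
  same <- mk(rep(0.7, 25))
  expect_equal(compare_systems(same, same)[c("t", "p")], list(t = 0, p = 1))
  res <- compare_systems(mk(rep(0.9, 25)), mk(rep(0.5, 25)))
  expect_identical(res$t, Inf)
  expect_identical(res$p, 0)
  expect_error(compare_systems(mk(rep(0.5, 25)), mk(rep(0.5, 25))[1:10, ]),
               "different numbers")
})

test_that("round-level comparison pools fold scores by round", {
  a <- data.frame(scheme = "a", round = rep(1:5, each = 5),
                  f_score = rep(c(0.8, 0.9, 0.85, 0.7, 0.75), each = 5))
  b <- data.frame(scheme = "b", round = rep(1:5, each = 5),
                  f_score = rep(c(0.6, 0.7, 0.65, 0.5, 0.55), each = 5))
  res <- compare_systems(a, b, level = "round")
  ref <- t.test(c(0.8, 0.9, 0.85, 0.7, 0.75), c(0.6, 0.7, 0.65, 0.5, 0.55))
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-10)
})

test_that("pairwise complementarity counts exclusive correct-relevant sets", {
  gold <- data.frame(doc_id = c("1", "2", "3", "4"),
                     gold = c(1L, 1L, 1L, 0L))
  pa <- data.frame(doc_id = c("1", "2", "3", "4"),
                   label = c(1L, 1L, 0L, 1L))
  pb <- data.frame(doc_id = c("1", "2", "3", "4"),
                   label = c(0L, 1L, 1L, 0L))
  res <- complementarity(pa, pb, gold)
  expect_identical(res$a_only, 1L)
  expect_identical(res$b_only, 1L)
  expect_identical(res$both, 1L)
  expect_identical(res$a_only_ids, "1")
  expect_identical(res$b_only_ids, "3")
  # identical predictions leave both exclusive sets empty
  same <- complementarity(pa, pa, gold)
  expect_identical(same$a_only + same$b_only, 0L)
  expect_error(complementarity(pa[1:2, ], pb, gold), "missing documents")
})

test_that("three-way regions sum to the relevant docs caught by any system", {
  set.seed(44)
  ids <- sprintf("d%02d", 1:40)
  gold <- data.frame(doc_id = ids, gold = rbinom(40, 1, 0.5))
  mk <- function() data.frame(doc_id = ids, label = rbinom(40, 1, 0.6))
  pa <- mk(); pb <- mk(); pc <- mk()
  res <- complementarity3(pa, pb, pc, gold)
  caught_any <- sum(vapply(which(gold$gold == 1L), function(i)
    any(pa$label[i] == 1L, pb$label[i] == 1L, pc$label[i] == 1L),
    logical(1L)))
  expect_identical(
    res$a_only + res$b_only + res$c_only + res$ab + res$ac + res$bc +
      res$abc,
    caught_any)
  expect_identical(res$none, sum(gold$gold == 1L) - caught_any)
  # pairwise calls agree with the three-way regions
  pw <- complementarity(pa, pb, gold)
  expect_identical(pw$a_only, res$a_only + res$ac)
  expect_identical(pw$b_only, res$b_only + res$bc)
})
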