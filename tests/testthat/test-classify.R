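test_that("standardizer rescales to mean 0 / sd 1 and guards constants", {
  m <- fit_standardizer(matrix(c(1, 3), ncol = 1))
  expect_equal(unname(m$mean), 2)
  expect_equal(unname(m$sd), 1)  # population sd of {1,3}
  expect_equal(as.numeric(apply_standardizer(m, matrix(c(1, 3)))),
               c(-1, 1))

  cm <- fit_standardizer(matrix(5, nrow = 3))
  expect_true(cm$constant)
  expect_equal(as.numeric(apply_standardizer(cm, matrix(5, nrow = 3))),
               c(0, 0, 0))
  expect_error(fit_standardizer(matrix(1, nrow = 1)), "at least 2")
})

test_that("standardized training columns recompute to mean 0 / sd 1", {
  set.seed(21)
  x <- matrix(rnorm(500, mean = 3, sd = 7), 50, 10)
  z <- apply_standardizer(fit_standardizer(x), x)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  expect_true(all(abs(colMeans(z)) < 1e-9))
  expect_true(all(abs(apply(z, 2, pop_sd) - 1) < 1e-9))
})

test_that("base SVM separates a separable toy set with calibrated labels", {
  set.seed(5)
  x <- rbind(matrix(rnorm(20, -3, 0.3), 10, 2),
             matrix(rnorm(20, 3, 0.3), 10, 2))
  rownames(x) <- paste0("p", 1:20)
  y <- rep(c(0L, 1L), each = 10L)
  fit <- train_base(x, y, fw_config(seed = 1))
  pred <- predict_base(fit, x)
  expect_identical(pred$label, y)
  expect_true(all(pred$prob >= 0 & pred$prob <= 1))
  expect_identical(pred$label, as.integer(pred$prob >= 0.5))
  expect_error(train_base(x, rep(1L, 20L)), "single class")
})

test_that("flipping all training labels flips predictions on a symmetric set", {
  set.seed(6)
  x <- rbind(matrix(rnorm(40, -2, 0.5), 20, 2),
             matrix(rnorm(40, 2, 0.5), 20, 2))
  rownames(x) <- paste0("p", 1:40)
  y <- rep(c(0L, 1L), each = 20L)
  p1 <- predict_base(train_base(x, y, fw_config(seed = 1)), x)
  p2 <- predict_base(train_base(x, 1L - y, fw_config(seed = 1)), x)
  expect_identical(p2$label, 1L - p1$label)
})

test_that("d_ALL concatenates to 2048 + dim + dim columns", {
  cfg <- synth_config(n_docs = 6L, seed = 2L)
  corp <- generate_corpus(cfg)
  reps <- build_representations(corp$documents, generate_embeddings(cfg),
                                warn = FALSE)
  expect_identical(ncol(rep_all(reps)), 2048L + 200L + 200L)  # 2448
  small <- build_representations(
    corp$documents,
    generate_embeddings(synth_config(n_docs = 6L, seed = 2L,
                                     embedding_dim = 16L)),
    warn = FALSE)
  expect_identical(ncol(rep_all(small)), 2048L + 16L + 16L)
})

test_that("standardizer and block widths are enforced at prediction", {
  m <- fit_standardizer(matrix(rnorm(20), 10, 2))
  expect_error(apply_standardizer(m, matrix(rnorm(30), 10, 3)),
               "fitted on 2")
})

test_that("meta-features are the 6-tuple <L,P> per modality in fixed order", {
  reps <- fix_separable_reps(n = 30L)
  model <- train_combc(reps, config = fw_config(seed = 3))
  expect_identical(names(model$meta$std$mean),
                   c("L_IMG", "P_IMG", "L_CAP", "P_CAP", "L_TA", "P_TA"))
  expect_length(model$meta$std$mean, 6L)
})

test_that("perfect base classifiers give a perfect meta-classifier", {
  reps <- fix_separable_reps(n = 30L)
  y <- as.integer(reps$labels == "relevant")
  cfg <- fw_config(seed = 3)
  for (s in c("img", "cap", "ta")) {
    p <- predict_scheme(train_scheme(reps, s, config = cfg), reps)
    expect_identical(p$label, y)
  }
  pc <- predict_combc(train_combc(reps, config = cfg), reps)
  expect_identical(pc$label, y)
  pv <- predict_combv(train_combv(reps, config = cfg), reps)
  expect_identical(pv$label, y)
})

test_that("training is deterministic given the seed", {
  reps <- fix_separable_reps(n = 24L, seed = 12L)
  cfg <- fw_config(seed = 9)
  for (s in c("combv", "combc")) {
    p1 <- predict_scheme(train_scheme(reps, s, config = cfg), reps)
    p2 <- predict_scheme(train_scheme(reps, s, config = cfg), reps)
    expect_identical(p1, p2)
  }
})

test_that("CombV with zeroed text blocks degrades to the image classifier", {
  reps <- fix_separable_reps(n = 30L)
  ablated <- reps
  ablated$cap[] <- 0
  ablated$ta[] <- 0
  cfg <- fw_config(seed = 4)
  p_img <- predict_scheme(train_scheme(reps, "img", config = cfg), reps)
  p_ablv <- predict_combv(train_combv(ablated, config = cfg), ablated)
  # constant text columns are dropped by standardization, so CombV reduces
  # to exactly the image-block model
  expect_identical(p_ablv$label, p_img$label)
  expect_equal(p_ablv$prob, p_img$prob, tolerance = 1e-8)
})

test_that("stacking meta-features are produced out-of-fold", {
  # On a corpus where base classifiers overfit (high-dimensional IMG block,
  # weak signal), in-sample base accuracy is perfect while out-of-fold
  # meta-features are not: the log proves the meta-classifier never saw
  # in-fold base predictions of its own training rows.
  cfg <- synth_config(n_docs = 40L, seed = 33L, caption_signal = 0,
                      ta_signal = 0)
  corp <- generate_corpus(cfg)
  reps <- build_representations(corp$documents, generate_embeddings(cfg),
                                warn = FALSE)
  log <- new.env()
  model <- train_combc(reps, config = fw_config(seed = 2, fit_log = log))
  comps <- vapply(log$records, `[[`, character(1L), "component")
  oof <- log$records[grepl("^combc_oof_", comps)]
  expect_gt(length(oof), 0L)
  n_train <- length(reps$doc_ids)
  for (rec in oof)
    expect_lt(length(rec$doc_ids), n_train)
})
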