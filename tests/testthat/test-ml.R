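test_that("stratified folds partition the data evenly and reproducibly", {
  labels <- rep(c("control", "stroke"), c(60, 40))
  f <- make_folds(labels, K = 10, seed = 1)
  expect_setequal(unique(f), 1:10)
  expect_true(all(table(f) == 10))           # n = 100, K = 10 -> ten folds of 10
  ## stratification: every fold sees both classes
  expect_true(all(table(f, labels) > 0))
  expect_identical(f, make_folds(labels, K = 10, seed = 1))
  expect_false(identical(f, make_folds(labels, K = 10, seed = 2)))
  expect_error(make_folds(labels[1:5], K = 10), "exceeds")
})

test_that("min-max scaling is fit on train only and extends affinely", {
  sc <- minmax_scale(matrix(c(2, 4, 6), ncol = 1), matrix(8, ncol = 1))
  expect_equal(as.vector(sc$train), c(0, 0.5, 1))
  expect_equal(as.vector(sc$test), 1.5)      # no clipping
  ## idempotent on already-[0,1] data
  u <- matrix(c(0, 0.25, 1), ncol = 1)
  expect_equal(minmax_scale(u)$train, u, ignore_attr = TRUE)
  expect_warning(s2 <- minmax_scale(matrix(c(3, 3, 3), ncol = 1)), "constant")
  expect_equal(as.vector(s2$train), c(0, 0, 0))
})

test_that("binary metrics follow their definitions with stroke positive", {
  truth <- rep(c("stroke", "stroke", "control", "control"), c(40, 10, 45, 5))
  pred <- rep(c("stroke", "control", "control", "stroke"), c(40, 10, 45, 5))
  m <- compute_metrics(truth, pred)
  expect_equal(unname(m), c(0.85, 40 / 45, 0.80, 0.842105), tolerance = 1e-6)
  expect_equal(m[["f1"]],
               2 * m[["precision"]] * m[["recall"]] /
                 (m[["precision"]] + m[["recall"]]))
  expect_equal(unname(compute_metrics(truth, truth)), c(1, 1, 1, 1))
  expect_warning(m0 <- compute_metrics(truth, rep("control", 100)),
                 "no predicted positives")
  expect_equal(unname(m0), c(0.5, 0, 0, 0))
})

## small, well-separated training set shared by the model tests
make_sep_data <- function(n = 80, seed = 3) {
  set.seed(seed)
  y <- factor(rep(c("control", "stroke"), each = n / 2),
              levels = c("control", "stroke"))
  x <- matrix(rnorm(n * 12), n, 12,
              dimnames = list(NULL, apm_parameter_names()))
  x[y == "stroke", 1:3] <- x[y == "stroke", 1:3] + 3
  list(x = x, y = y)
}

test_that("models are configured exactly as specified", {
  d <- make_sep_data()
  ## decision tree: depth never exceeds 4
  dt <- fit_classifier(model_spec("DT"), d$x, d$y)
  nodes <- as.numeric(rownames(dt$fit$frame))
  expect_lte(max(floor(log2(nodes))), 4)   # node depth = floor(log2(id))
  ## random forest: exactly 100 trees
  rf <- fit_classifier(model_spec("RF"), d$x, d$y)
  expect_equal(rf$fit$ntree, 100)
  ## DNN: 12-8-1 architecture has 269 trainable weights
  spec <- model_spec("DNN", epochs = 1L)
  dnn <- fit_classifier(spec, d$x, d$y)
  expect_equal(propriokit:::mlp_n_params(dnn$fit), 269)
  expect_error(model_spec("GBM"), "unknown model")
  ## LR converges within its iteration cap on separated-ish data
  lr <- fit_classifier(model_spec("LR"), d$x, d$y)
  expect_lte(lr$fit$iterations, 100)
})

test_that("all six models separate an easy problem and predict sanely", {
  d <- make_sep_data(n = 120)
  for (nm in c("LR", "DT", "RF", "RFT", "SVM", "DNN")) {
    spec <- if (nm == "RFT") model_spec(nm, seed = 5, n_iter = 4L) else
      model_spec(nm, seed = 5)
    fit <- fit_classifier(spec, d$x, d$y)
    lab <- predict(fit, d$x, type = "label")
    expect_gt(mean(lab == d$y), 0.9)
    sc <- predict(fit, d$x, type = "score")
    expect_length(sc, nrow(d$x))
    expect_gt(mean(sc[d$y == "stroke"]), mean(sc[d$y == "control"]))
  }
})

test_that("random-forest tuning is seeded and contains the default", {
  d <- make_sep_data(n = 60, seed = 9)
  t1 <- tune_random_forest(d$x, d$y, seed = 4, n_iter = 5, inner_k = 3)
  t2 <- tune_random_forest(d$x, d$y, seed = 4, n_iter = 5, inner_k = 3)
  expect_identical(t1$best, t2$best)
  ## the default forest is candidate 1; the argmax can never score below it
  expect_gte(t1$score, t1$candidates$score[1])
  ## a one-point space returns that point
  t3 <- tune_random_forest(d$x, d$y, seed = 4, n_iter = 1, inner_k = 3)
  expect_equal(t3$best$num_trees, 100L)
  expect_equal(t3$best$min_bucket, 1L)
})

test_that("mean ROC interpolation behaves at the extremes", {
  lab <- rep(c("control", "stroke"), each = 20)
  perfect <- as.numeric(lab == "stroke")
  r <- mean_roc(list(perfect), list(lab))
  expect_equal(r$auc, 1)
  ## identical folds average to the single-fold curve
  set.seed(2)
  sc <- rnorm(40) + 1.2 * (lab == "stroke")
  r1 <- mean_roc(list(sc), list(lab))
  r3 <- mean_roc(list(sc, sc, sc), list(lab, lab, lab))
  expect_equal(r3$auc, r1$auc)
  expect_equal(r3$tpr, r1$tpr)
  ## label-independent scores give chance AUC
  set.seed(7)
  lab2 <- rep(c("control", "stroke"), each = 5000)
  r0 <- mean_roc(list(rnorm(10000)), list(lab2))
  expect_equal(r0$auc, 0.5, tolerance = 0.04)
  expect_error(mean_roc(list(1:5), list(rep("stroke", 5))), "one class")
})

test_that("feature importance is a percentage and isolates signal", {
  set.seed(12)
  n <- 300
  y <- factor(rep(c("control", "stroke"), each = n / 2),
              levels = c("control", "stroke"))
  x <- cbind(signal = as.numeric(y == "stroke") + rnorm(n, 0, 0.01),
             noise = rnorm(n))
  rf <- fit_classifier(model_spec("RF"), x, y)
  imp <- feature_importance(rf)
  expect_equal(sum(imp), 100, tolerance = 1e-6)
  expect_gt(imp[["signal"]], 90)
  lr <- fit_classifier(model_spec("LR"), x, y)
  imp_lr <- feature_importance(lr, x, y, R = 10, seed = 1)
  expect_equal(sum(imp_lr), 100, tolerance = 1e-6)
  expect_lt(imp_lr[["noise"]], 5)
  dnn <- fit_classifier(model_spec("DNN", epochs = 1L), x, y)
  expect_error(feature_importance(dnn), "not supported")
})

test_that("the experiment harness aggregates folds without leakage", {
  d <- make_sep_data(n = 90, seed = 21)
  specs <- list(model_spec("LR"), model_spec("DT"))
  ex <- suppressWarnings(
    run_experiment(d$x, d$y, specs = specs, K = 3, seed = 2))
  expect_true(ex$leak_ok)
  tab <- summary(ex)
  expect_true(all(tab$accuracy >= 0 & tab$accuracy <= 1))
  expect_true(all(tab$auc >= 0 & tab$auc <= 1))
  for (m in ex$models) {
    expect_equal(nrow(m$fold_metrics), 3)
    expect_equal(sum(m$importance), 100, tolerance = 1e-6)
    ok <- m$fold_metrics[, "precision"] + m$fold_metrics[, "recall"] > 0
    expect_equal(m$fold_metrics[ok, "f1"],
                 2 * m$fold_metrics[ok, "precision"] * m$fold_metrics[ok, "recall"] /
                   (m$fold_metrics[ok, "precision"] + m$fold_metrics[ok, "recall"]))
  }
  ## determinism
  ex2 <- suppressWarnings(
    run_experiment(d$x, d$y, specs = specs, K = 3, seed = 2))
  expect_equal(summary(ex), summary(ex2))
  ## missing values are refused, as is an unknown model
  xna <- d$x; xna[1, 1] <- NA
  expect_error(run_experiment(xna, d$y, specs = specs, K = 3, seed = 2),
               "imputation")
})
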