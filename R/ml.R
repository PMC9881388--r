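## Cross-validated classifier comparison: six models classifying sessions
## as stroke vs control from the 12 z-scored APM parameters.
##
## Models and their fixed settings follow the published recipes: LR with
## L2 regularization (tol 1e-4, max 100 iterations), decision tree (Gini,
## depth 4, min leaf 1), random forest (100 trees, min split 2, min leaf
## 1), tuned random forest (search over five hyperparameters with inner
## CV), RBF-kernel SVM (tol 1e-3), and a 12-8-1 sigmoid-output MLP
## trained with RMSprop (batch 10, 100 epochs, binary cross-entropy).

APM_MODEL_NAMES <- c("LR", "DT", "RF", "RFT", "SVM", "DNN")

#' Stratified K-fold assignment
#'
#' Disjoint, exhaustive, near-equal folds, stratified by label so every
#' fold sees both classes; deterministic for a fixed seed.
#'
#' @param labels Class labels (vector or factor).
#' @param K Number of folds (default 10).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..K`.
#' @export
make_folds <- function(labels, K = 10L, seed = 1L) {
  n <- length(labels)
  if (K > n) stop(sprintf("K = %d exceeds n = %d", K, n), call. = FALSE)
  if (K < 1L) stop("K must be at least 1", call. = FALSE)
  folds <- integer(n)
  with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(sample.int(K), length(idx))
    }
  })
  folds
}

#' Min-max scaling fitted on the training fold only
#'
#' Each training column is mapped affinely so its minimum becomes 0 and
#' its maximum 1; the same affine map (no clipping) is applied to the
#' test fold.  A constant training feature maps to 0 with a warning.
#'
#' @param train,test Numeric matrices/data frames with identical columns.
#' @return List with scaled `train`, `test`, and the fitted `min`,
#'   `range` vectors.
#' @export
minmax_scale <- function(train, test = NULL) {
  train <- as.matrix(train)
  mins <- apply(train, 2, min)
  maxs <- apply(train, 2, max)
  rng <- maxs - mins
  flat <- rng == 0
  if (any(flat)) {
    warning(sprintf("constant training feature(s) mapped to 0: %s",
                    paste(colnames(train)[flat], collapse = ", ")),
            call. = FALSE)
    rng[flat] <- 1
  }
  scale_mat <- function(m) {
    m <- as.matrix(m)
    out <- sweep(sweep(m, 2, mins), 2, rng, "/")
    out[, flat] <- 0
    out
  }
  list(train = scale_mat(train),
       test = if (is.null(test)) NULL else scale_mat(test),
       min = mins, range = rng)
}

#' Specify one classifier
#'
#' Fills in the fixed hyperparameters for the named model; entries in
#' `...` override defaults (e.g. `lambda` for the LR regularization
#' strength, `cost` for the SVM, `n_iter`/`inner_k` for the tuned random
#' forest search).
#'
#' @param name One of `"LR"`, `"DT"`, `"RF"`, `"RFT"`, `"SVM"`, `"DNN"`.
#' @param seed Integer seed for any stochastic element of the fit.
#' @param ... Hyperparameter overrides.
#' @return Object of class `apm_model_spec`.
#' @export
model_spec <- function(name, seed = 1L, ...) {
  name <- toupper(name)
  if (!name %in% APM_MODEL_NAMES) {
    stop(sprintf("unknown model '%s'; expected one of %s", name,
                 paste(APM_MODEL_NAMES, collapse = ", ")), call. = FALSE)
  }
  hyper <- switch(name,
    LR = list(lambda = 1, tol = 1e-4, max_iter = 100L),
    DT = list(criterion = "gini", max_depth = 4L, min_leaf = 1L, min_split = 2L),
    RF = list(n_trees = 100L, min_split = 2L, min_leaf = 1L),
    RFT = list(n_iter = 50L, inner_k = 3L),
    SVM = list(kernel = "radial", cost = 1, tolerance = 1e-3, cachesize = 200),
    DNN = list(units = c(12L, 8L, 1L), batch_size = 10L, epochs = 100L,
               lr = 0.001, rho = 0.9, eps = 1e-7))
  dots <- list(...)
  hyper[names(dots)] <- dots
  structure(list(name = name, hyper = hyper, seed = as.integer(seed)),
            class = "apm_model_spec")
}

#' Default specification list for the six compared models
#'
#' @param seed Base seed propagated to each spec.
#' @return Named list of `apm_model_spec`s.
#' @export
default_model_specs <- function(seed = 1L) {
  specs <- lapply(APM_MODEL_NAMES, model_spec, seed = seed)
  names(specs) <- APM_MODEL_NAMES
  specs
}

## ----- L2-penalised logistic regression (IRLS/Newton) -------------------

fit_lr_ridge <- function(x, y01, lambda = 1, tol = 1e-4, max_iter = 100L) {
  X <- cbind(1, as.matrix(x))
  p <- ncol(X)
  pen <- c(0, rep(lambda, p - 1L))   # intercept unpenalised
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X, X * w) + diag(pen, p)
    g <- crossprod(X, y01 - mu) - pen * beta
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(beta = as.vector(beta), iterations = it)
}

predict_lr_ridge <- function(fit, x) {
  as.vector(stats::plogis(cbind(1, as.matrix(x)) %*% fit$beta))
}

## ----- small MLP with RMSprop -------------------------------------------

mlp_init <- function(n_in, units = c(12L, 8L, 1L)) {
  sizes <- c(n_in, units)
  w <- list(); b <- list()
  for (i in seq_along(units)) {
    w[[i]] <- matrix(stats::rnorm(sizes[i] * sizes[i + 1], 0,
                                  sqrt(2 / sizes[i])),
                     nrow = sizes[i])
    b[[i]] <- numeric(sizes[i + 1])
  }
  list(w = w, b = b)
}

mlp_forward <- function(net, x) {
  a1 <- x %*% net$w[[1]]
  h1 <- pmax(sweep(a1, 2, net$b[[1]], "+"), 0)
  a2 <- h1 %*% net$w[[2]]
  h2 <- pmax(sweep(a2, 2, net$b[[2]], "+"), 0)
  a3 <- sweep(h2 %*% net$w[[3]], 2, net$b[[3]], "+")
  p <- stats::plogis(a3)
  list(h1 = h1, h2 = h2, p = p)
}

mlp_n_params <- function(net) {
  sum(vapply(net$w, length, 1)) + sum(vapply(net$b, length, 1))
}

mlp_train <- function(x, y01, units = c(12L, 8L, 1L), epochs = 100L,
                      batch_size = 10L, lr = 0.001, rho = 0.9, eps = 1e-7,
                      seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  with_seed(seed, {
    net <- mlp_init(ncol(x), units)
    cache <- list(w = lapply(net$w, function(m) m * 0),
                  b = lapply(net$b, function(v) v * 0))
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + batch_size - 1L, n)]
        xb <- x[idx, , drop = FALSE]
        yb <- y01[idx]
        m <- length(idx)
        f <- mlp_forward(net, xb)
        ## BCE gradient at the sigmoid pre-activation
        d3 <- (f$p - yb) / m                       # m x 1
        gW3 <- crossprod(f$h2, d3); gb3 <- colSums(d3)
        d2 <- (d3 %*% t(net$w[[3]])) * (f$h2 > 0)
        gW2 <- crossprod(f$h1, d2); gb2 <- colSums(d2)
        d1 <- (d2 %*% t(net$w[[2]])) * (f$h1 > 0)
        gW1 <- crossprod(xb, d1); gb1 <- colSums(d1)
        gw <- list(gW1, gW2, gW3); gb <- list(gb1, gb2, gb3)
        for (l in 1:3) {
          cache$w[[l]] <- rho * cache$w[[l]] + (1 - rho) * gw[[l]]^2
          cache$b[[l]] <- rho * cache$b[[l]] + (1 - rho) * gb[[l]]^2
          net$w[[l]] <- net$w[[l]] - lr * gw[[l]] / sqrt(cache$w[[l]] + eps)
          net$b[[l]] <- net$b[[l]] - lr * gb[[l]] / sqrt(cache$b[[l]] + eps)
        }
      }
    }
    net
  })
}

## ----- tuned random forest ----------------------------------------------

#' Randomized hyperparameter search for the random forest
#'
#' Searches the five forest hyperparameters (number of trees, maximum
#' tree depth, features per split, minimum node size to split, minimum
#' leaf size) by seeded random sampling with internal cross-validation on
#' the training fold only.  The default forest configuration is always a
#' candidate, so the tuned inner-CV score can never fall below it.
#'
#' @param x,y Training features and labels (factor).
#' @param seed Integer seed.
#' @param n_iter Number of sampled combinations (default 50).
#' @param inner_k Inner CV folds (default 3).
#' @return List with `best` (named hyperparameter list), `score` (inner
#'   CV accuracy), and the evaluated `candidates` data frame.
#' @export
tune_random_forest <- function(x, y, seed = 1L, n_iter = 50L, inner_k = 3L) {
  x <- as.matrix(x)
  p <- ncol(x)
  default <- list(num_trees = 100L, max_depth = 0L,
                  mtry = max(1L, floor(sqrt(p))),
                  min_node_size = 2L, min_bucket = 1L)
  cands <- with_seed(seed, {
    cand <- vector("list", n_iter)
    cand[[1]] <- default
    for (i in seq_len(n_iter - 1L)) {
      cand[[i + 1L]] <- list(
        num_trees = sample(c(50L, 100L, 200L, 300L, 500L), 1),
        max_depth = sample(c(0L, 2L, 3L, 4L, 6L, 8L, 10L), 1),
        mtry = sample.int(p, 1),
        min_node_size = sample(c(2L, 5L, 10L), 1),
        min_bucket = sample(c(1L, 2L, 4L), 1))
    }
    cand
  })
  folds <- make_folds(y, K = inner_k, seed = seed + 1L)
  scores <- vapply(seq_along(cands), function(i) {
    h <- cands[[i]]
    acc <- vapply(seq_len(inner_k), function(k) {
      tr <- folds != k; te <- !tr
      fit <- ranger::ranger(x = x[tr, , drop = FALSE], y = y[tr],
                            num.trees = h$num_trees,
                            max.depth = if (h$max_depth == 0L) NULL else h$max_depth,
                            mtry = h$mtry, min.node.size = h$min_node_size,
                            min.bucket = h$min_bucket,
                            seed = seed + 100L + i, num.threads = 1L,
                            verbose = FALSE)
      mean(predict(fit, data = x[te, , drop = FALSE],
                   num.threads = 1L)$predictions == y[te])
    }, 1)
    mean(acc)
  }, 1)
  best <- which.max(scores)   # ties resolve to the earliest (default first)
  tab <- cbind(do.call(rbind, lapply(cands, as.data.frame)), score = scores)
  list(best = cands[[best]], score = scores[best], candidates = tab)
}

## ----- fit / predict dispatch -------------------------------------------

#' Build and fit a classifier from a model specification
#'
#' @param spec An [model_spec()] object (or model name).
#' @param x Training feature matrix (rows = sessions).
#' @param y Training labels; coerced to a factor with levels
#'   `control`, `stroke`.
#' @return Object of class `apm_fit` wrapping the underlying model.
#' @export
fit_classifier <- function(spec, x, y) {
  if (is.character(spec)) spec <- model_spec(spec)
  x <- as.matrix(x)
  y <- factor(y, levels = c("control", "stroke"))
  if (any(is.na(x))) stop("missing feature values; imputation is out of scope",
                          call. = FALSE)
  y01 <- as.numeric(y == "stroke")
  h <- spec$hyper
  fit <- switch(spec$name,
    LR = fit_lr_ridge(x, y01, lambda = h$lambda, tol = h$tol,
                      max_iter = h$max_iter),
    DT = {
      d <- data.frame(.y = y, x, check.names = FALSE)
      rpart::rpart(.y ~ ., data = d, method = "class",
                   parms = list(split = "gini"),
                   control = rpart::rpart.control(
                     maxdepth = h$max_depth, minbucket = h$min_leaf,
                     minsplit = h$min_split, cp = 0, xval = 0))
    },
    RF = with_seed(spec$seed,
      randomForest::randomForest(x = x, y = y, ntree = h$n_trees,
                                 nodesize = h$min_leaf)),
    RFT = {
      tuned <- tune_random_forest(x, y, seed = spec$seed,
                                  n_iter = h$n_iter, inner_k = h$inner_k)
      b <- tuned$best
      fit <- ranger::ranger(x = x, y = y, num.trees = b$num_trees,
                            max.depth = if (b$max_depth == 0L) NULL else b$max_depth,
                            mtry = b$mtry, min.node.size = b$min_node_size,
                            min.bucket = b$min_bucket,
                            probability = TRUE, importance = "impurity",
                            seed = spec$seed, num.threads = 1L,
                            verbose = FALSE)
      list(forest = fit, tuned = tuned)
    },
    SVM = with_seed(spec$seed,
      e1071::svm(x = x, y = y, kernel = h$kernel, cost = h$cost,
                 tolerance = h$tolerance, cachesize = h$cachesize,
                 probability = TRUE)),
    DNN = mlp_train(x, y01, units = h$units, epochs = h$epochs,
                    batch_size = h$batch_size, lr = h$lr, rho = h$rho,
                    eps = h$eps, seed = spec$seed))
  structure(list(spec = spec, fit = fit, features = colnames(x)),
            class = "apm_fit")
}

#' Predict from a fitted classifier
#'
#' @param object An `apm_fit` object.
#' @param x Feature matrix to score.
#' @param type `"score"` for a continuous stroke-leaning score
#'   (probability for LR/DT/RF/RFT/DNN, decision value for SVM) or
#'   `"label"` for the hard class.
#' @param ... Unused.
#' @return Numeric vector (`"score"`) or factor (`"label"`).
#' @export
predict.apm_fit <- function(object, x, type = c("score", "label"), ...) {
  type <- match.arg(type)
  x <- as.matrix(x)
  score <- switch(object$spec$name,
    LR = predict_lr_ridge(object$fit, x),
    DT = {
      d <- as.data.frame(x, check.names = FALSE)
      unname(predict(object$fit, newdata = d, type = "prob")[, "stroke"])
    },
    RF = unname(predict(object$fit, newdata = x, type = "prob")[, "stroke"]),
    RFT = unname(predict(object$fit$forest, data = x,
                         num.threads = 1L)$predictions[, "stroke"]),
    SVM = {
      pr <- predict(object$fit, newdata = x, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      ## orient the decision value so larger means stroke
      if (grepl("^stroke", colnames(dv)[1])) as.vector(dv) else -as.vector(dv)
    },
    DNN = as.vector(mlp_forward(object$fit, x)$p))
  if (type == "score") return(score)
  thr <- if (object$spec$name == "SVM") 0 else 0.5
  factor(ifelse(score > thr, "stroke", "control"),
         levels = c("control", "stroke"))
}

## stroke-class probability (for log-loss based importance)
predict_prob <- function(object, x) {
  x <- as.matrix(x)
  if (object$spec$name == "SVM") {
    pr <- predict(object$fit, newdata = x, probability = TRUE)
    unname(attr(pr, "probabilities")[, "stroke"])
  } else {
    predict(object, x, type = "score")
  }
}

## ----- metrics, ROC, importance -----------------------------------------

#' Binary classification metrics with stroke as the positive class
#'
#' @param truth,pred Label vectors of equal length.
#' @param positive Positive class (default `"stroke"`).
#' @return Named vector: `accuracy`, `precision`, `recall`, `f1`.
#' @export
compute_metrics <- function(truth, pred, positive = "stroke") {
  stopifnot(length(truth) == length(pred))
  truth_pos <- truth == positive
  pred_pos <- pred == positive
  tp <- sum(truth_pos & pred_pos)
  fp <- sum(!truth_pos & pred_pos)
  fn <- sum(truth_pos & !pred_pos)
  accuracy <- mean(truth == pred)
  if (tp + fp == 0) {
    warning("no predicted positives; precision reported as 0", call. = FALSE)
    precision <- 0
  } else precision <- tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(accuracy = accuracy, precision = precision, recall = recall, f1 = f1)
}

## ROC points for one fold: returns fpr/tpr step coordinates
roc_points <- function(scores, labels, positive = "stroke") {
  pos <- labels == positive
  if (!any(pos) || all(pos)) {
    stop("a fold contains one class only; use stratified folds", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
  ## collapse score ties to their final counts (keep last index per tie)
  keep <- rev(!duplicated(rev(scores[ord])))
  tpr <- c(0, tp[keep] / sum(pos))
  fpr <- c(0, fp[keep] / sum(!pos))
  list(fpr = fpr, tpr = tpr)
}

#' Mean ROC curve over folds
#'
#' Each fold's ROC is linearly interpolated onto a common 101-point FPR
#' grid; TPRs are averaged pointwise and the AUC is the trapezoidal area
#' of the mean curve, anchored at (0,0) and (1,1).
#'
#' @param scores_list List of per-fold continuous scores.
#' @param labels_list List of matching label vectors.
#' @param positive Positive class.
#' @param grid_n Grid resolution (default 101).
#' @return List with `fpr` (grid), `tpr` (mean curve), `auc`.
#' @export
mean_roc <- function(scores_list, labels_list, positive = "stroke",
                     grid_n = 101L) {
  grid <- seq(0, 1, length.out = grid_n)
  curves <- Map(function(s, l) {
    r <- roc_points(s, l, positive)
    ## max TPR at duplicated FPR, then linear interpolation
    agg <- tapply(r$tpr, r$fpr, max)
    fx <- as.numeric(names(agg)); fy <- as.vector(agg)
    if (fx[length(fx)] < 1) { fx <- c(fx, 1); fy <- c(fy, 1) }
    stats::approx(fx, fy, xout = grid, rule = 2)$y
  }, scores_list, labels_list)
  tpr <- colMeans(do.call(rbind, curves))
  auc <- sum(diff(grid) * (tpr[-1] + tpr[-grid_n]) / 2)
  list(fpr = grid, tpr = tpr, auc = auc)
}

#' Per-feature importance of a fitted classifier, as percentages
#'
#' Tree models report mean impurity-decrease importances; LR and SVM use
#' seeded permutation importance (mean log-loss increase over `R`
#' permutations of each feature, floored at 0).  Values are normalized to
#' sum to 100.  The DNN has no supported importance and raises an error.
#'
#' @param object Fitted `apm_fit`.
#' @param x,y Data on which permutation importance is evaluated
#'   (training fold); ignored for tree models.
#' @param R Permutations per feature (default 20).
#' @param seed Integer seed for the permutations.
#' @return Named numeric vector summing to 100.
#' @export
feature_importance <- function(object, x = NULL, y = NULL, R = 20L, seed = 1L) {
  name <- object$spec$name
  feats <- object$features
  raw <- switch(name,
    DT = {
      vi <- object$fit$variable.importance
      out <- stats::setNames(numeric(length(feats)), feats)
      out[names(vi)] <- vi
      out
    },
    RF = {
      im <- randomForest::importance(object$fit)[, "MeanDecreaseGini"]
      stats::setNames(as.vector(im), rownames(randomForest::importance(object$fit)))[feats]
    },
    RFT = object$fit$forest$variable.importance[feats],
    LR = ,
    SVM = {
      if (is.null(x) || is.null(y)) {
        stop("permutation importance needs `x` and `y`", call. = FALSE)
      }
      permutation_importance(object, as.matrix(x), y, R = R, seed = seed)
    },
    DNN = stop("feature importance is not supported for the DNN model",
               call. = FALSE))
  raw <- pmax(raw, 0)
  tot <- sum(raw)
  if (tot == 0) {
    warning("all importances zero; returning zeros", call. = FALSE)
    return(stats::setNames(numeric(length(feats)), feats))
  }
  100 * raw / tot
}

log_loss <- function(y01, p) {
  p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  -mean(y01 * log(p) + (1 - y01) * log(1 - p))
}

permutation_importance <- function(object, x, y, R = 20L, seed = 1L) {
  y01 <- as.numeric(y == "stroke")
  base <- log_loss(y01, predict_prob(object, x))
  n <- nrow(x)
  with_seed(seed, {
    imp <- vapply(seq_len(ncol(x)), function(j) {
      d <- vapply(seq_len(R), function(r) {
        xp <- x
        xp[, j] <- xp[sample.int(n), j]
        log_loss(y01, predict_prob(object, xp)) - base
      }, 1)
      mean(d)
    }, 1)
  })
  stats::setNames(imp, colnames(x))
}

## ----- the experiment ----------------------------------------------------

#' Run the cross-validated classifier comparison
#'
#' For each fold: min-max scaling is fitted on the training fold and
#' applied to both folds, every model is fitted on the scaled training
#' data, and metrics/scores are collected on the test fold.  Feature
#' importances are computed on the training fold and averaged across
#' folds (not defined for the DNN).  A leakage check verifies the raw
#' test rows are untouched by the fold body.
#'
#' @param features Numeric feature table (rows = sessions, no missing
#'   values).
#' @param labels Labels coerced to factor `control`/`stroke`.
#' @param specs List of [model_spec()]s (default all six).
#' @param K Number of folds (default 10).
#' @param seed Integer seed controlling folds and model randomness.
#' @param importance Compute per-fold feature importances (default TRUE).
#' @return Object of class `apm_experiment`: per-model list with fold
#'   metrics, mean/SD metrics, mean ROC + AUC, and importance table.
#' @export
run_experiment <- function(features, labels, specs = default_model_specs(),
                           K = 10L, seed = 1L, importance = TRUE) {
  x <- as.matrix(features)
  if (any(is.na(x))) stop("missing feature values; imputation is out of scope",
                          call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- factor(labels, levels = c("control", "stroke"))
  stopifnot(nrow(x) == length(y))
  folds <- make_folds(y, K = K, seed = seed)

  per_model <- lapply(specs, function(s) {
    list(metrics = matrix(NA_real_, K, 4,
                          dimnames = list(NULL, c("accuracy", "precision",
                                                  "recall", "f1"))),
         scores = vector("list", K), labels = vector("list", K),
         importance = NULL)
  })
  names(per_model) <- vapply(specs, `[[`, "", "name")
  imp_acc <- lapply(specs, function(s) NULL)
  names(imp_acc) <- names(per_model)
  leak_ok <- TRUE

  for (k in seq_len(K)) {
    te <- folds == k; tr <- !te
    before <- sum(x[te, , drop = FALSE]) + sum(x[te, , drop = FALSE]^2)
    sc <- minmax_scale(x[tr, , drop = FALSE], x[te, , drop = FALSE])
    for (s in specs) {
      fit <- local({
        s2 <- s; s2$seed <- s$seed + 1000L * k
        fit_classifier(s2, sc$train, y[tr])
      })
      pred <- predict(fit, sc$test, type = "label")
      per_model[[s$name]]$metrics[k, ] <-
        suppressWarnings(compute_metrics(y[te], pred))
      per_model[[s$name]]$scores[[k]] <- predict(fit, sc$test, type = "score")
      per_model[[s$name]]$labels[[k]] <- y[te]
      if (importance && s$name != "DNN") {
        im <- feature_importance(fit, sc$train, y[tr],
                                 seed = s$seed + 1000L * k)
        imp_acc[[s$name]] <- rbind(imp_acc[[s$name]], im)
      }
    }
    after <- sum(x[te, , drop = FALSE]) + sum(x[te, , drop = FALSE]^2)
    leak_ok <- leak_ok && identical(before, after)
  }

  results <- lapply(names(per_model), function(nm) {
    pm <- per_model[[nm]]
    roc <- mean_roc(pm$scores, pm$labels)
    imp <- if (!is.null(imp_acc[[nm]])) {
      v <- colMeans(imp_acc[[nm]])
      100 * v / sum(v)
    } else NULL
    list(name = nm, fold_metrics = pm$metrics,
         mean_metrics = colMeans(pm$metrics),
         sd_metrics = apply(pm$metrics, 2, stats::sd),
         roc = roc, auc = roc$auc, importance = imp)
  })
  names(results) <- names(per_model)
  structure(list(models = results, K = K, seed = seed, folds = folds,
                 leak_ok = leak_ok, n = nrow(x),
                 features = colnames(x)),
            class = "apm_experiment")
}

#' @export
print.apm_experiment <- function(x, ...) {
  cat(sprintf("APM classifier comparison: %d sessions, %d-fold CV\n", x$n, x$K))
  tab <- summary(x)
  print(tab, digits = 3)
  invisible(x)
}

#' @export
summary.apm_experiment <- function(object, ...) {
  tab <- do.call(rbind, lapply(object$models, function(m) {
    data.frame(model = m$name,
               accuracy = m$mean_metrics[["accuracy"]],
               precision = m$mean_metrics[["precision"]],
               recall = m$mean_metrics[["recall"]],
               f1 = m$mean_metrics[["f1"]],
               auc = m$auc)
  }))
  rownames(tab) <- NULL
  tab
}

#' Plot mean ROC curves of an experiment
#'
#' @param x An `apm_experiment`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.apm_experiment <- function(x, ...) {
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 2, col = "grey",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = "Mean cross-validated ROC", ...)
  cols <- grDevices::hcl.colors(length(x$models), "Dark 3")
  for (i in seq_along(x$models)) {
    m <- x$models[[i]]
    graphics::lines(m$roc$fpr, m$roc$tpr, col = cols[i], lwd = 2)
  }
  graphics::legend("bottomright",
                   legend = sprintf("%s (AUC %.3f)",
                                    vapply(x$models, `[[`, "", "name"),
                                    vapply(x$models, `[[`, 1, "auc")),
                   col = cols, lwd = 2, bty = "n")
  invisible(x)
}
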