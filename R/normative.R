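## Normative (healthy-control) modelling of the 12 APM parameters.
##
## Per parameter: a Box-Cox power transform maps the control marginal
## towards normality; a first linear regression models the transformed
## mean as a function of age, sex, handedness and robotic platform; a
## second regression on the same design models the residual standard
## deviation.  A participant's z-score is the first-stage residual
## divided by the second-stage predicted SD.

#' Box-Cox profile log-likelihood fit
#'
#' Chooses the power `lambda` maximizing the Box-Cox profile
#' log-likelihood on `values + offset`, searching `lambda` in `[-3, 3]`.
#' If the profile at `lambda = 1` is within numerical tolerance of the
#' maximum, `lambda = 1` (an affine, shape-preserving transform) is
#' preferred.  When any shifted value is non-positive and no offset was
#' supplied, the offset `-min(values) + 0.1 * IQR(values)` is applied.
#'
#' @param values Numeric control values (n >= 30 recommended).
#' @param offset Shift added before transforming; `NULL` selects it
#'   automatically as above (0 for all-positive data).
#' @param interval Search interval for `lambda`.
#' @return List with `lambda` and `offset`.
#' @export
fit_boxcox <- function(values, offset = NULL, interval = c(-3, 3)) {
  values <- values[is.finite(values)]
  if (length(values) < 2L || stats::sd(values) == 0) {
    stop("cannot fit a Box-Cox transform to constant input", call. = FALSE)
  }
  if (is.null(offset)) {
    offset <- if (min(values) <= 0) {
      -min(values) + 0.1 * stats::IQR(values)
    } else 0
  }
  x <- values + offset
  if (min(x) <= 0) stop("offset leaves non-positive values", call. = FALSE)
  ll <- function(lambda) boxcox_loglik(x, lambda)
  opt <- stats::optimize(ll, interval = interval, maximum = TRUE, tol = 1e-6)
  lambda <- opt$maximum
  if (ll(1) >= opt$objective - 1e-8) lambda <- 1
  list(lambda = lambda, offset = offset)
}

boxcox_loglik <- function(x, lambda) {
  n <- length(x)
  tx <- boxcox_apply(x, lambda)
  s2 <- stats::var(tx) * (n - 1) / n
  -n / 2 * log(s2) + (lambda - 1) * sum(log(x))
}

#' Apply a Box-Cox transform
#'
#' @param x Positive values (already shifted by any offset).
#' @param lambda Power parameter; `lambda = 0` is the log transform.
#' @return Transformed values.
#' @export
boxcox_apply <- function(x, lambda) {
  if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
}

#' Skew/kurtosis normality diagnostics
#'
#' Population-moment skewness (`mu3 / sigma^3`) and kurtosis
#' (`mu4 / sigma^4`) with the close-to-normal acceptance bands
#' `|skew| <= 0.8` and `2.4 <= kurtosis <= 3.6` used to decide whether a
#' transformed parameter distribution supports parametric z-scoring.
#'
#' @param x Numeric vector, `n >= 4`, non-constant.
#' @return List with `skew_stat`, `kurtosis_stat`, `valid`.
#' @export
check_distribution <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 4L) stop("need at least 4 values", call. = FALSE)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) stop("zero variance: diagnostics undefined", call. = FALSE)
  skew <- mean((x - m)^3) / s2^1.5
  kurt <- mean((x - m)^4) / s2^2
  list(skew_stat = skew, kurtosis_stat = kurt,
       valid = abs(skew) <= 0.8 && kurt >= 2.4 && kurt <= 3.6)
}

## Covariate design: intercept + centred age (+ age^2) + sex + handedness
## + platform.  Age is centred at 50 years so the linear and quadratic
## terms are nearly orthogonal.
normative_design <- function(meta, quadratic_age = TRUE) {
  sex <- factor(meta$sex, levels = c("F", "M"))
  hand <- factor(meta$handedness, levels = c("R", "L", "A"))
  plat <- factor(meta$platform, levels = c("exoskeleton", "endpoint"))
  agec <- meta$age - 50
  X <- cbind("(Intercept)" = 1, age = agec)
  if (quadratic_age) X <- cbind(X, age2 = agec^2)
  X <- cbind(X,
             sexM = as.numeric(sex == "M"),
             handL = as.numeric(hand == "L"),
             handA = as.numeric(hand == "A"),
             platform_endpoint = as.numeric(plat == "endpoint"))
  X
}

## Drop all-zero columns (e.g. a factor level absent from a training
## fold), then fail loudly if the remaining design is rank deficient.
prune_design <- function(X) {
  zero <- colSums(abs(X)) == 0
  if (any(zero)) {
    warning(sprintf("dropping empty design terms: %s",
                    paste(colnames(X)[zero], collapse = ", ")), call. = FALSE)
    X <- X[, !zero, drop = FALSE]
  }
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop(sprintf("rank-deficient normative design; collinear terms: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  X
}

#' Fit the normative z-score model on healthy controls
#'
#' For each of the 12 APM parameters: select a Box-Cox offset and power
#' on the control marginal, regress the transformed values on the
#' covariate design (mean model), regress `|residual| * sqrt(pi/2)` on
#' the same design (SD model, half-normal mean correction), and store
#' skew/kurtosis diagnostics of the resulting z-scores.  Predicted SDs
#' are floored at 10% of the overall residual SD.
#'
#' @param params Parameter table (one row per session) as produced by
#'   [compute_parameters()].
#' @param meta Participant table aligned with `params`; rows with
#'   `group != "control"` are dropped with a message.
#' @param quadratic_age Include a quadratic age term (default `TRUE`).
#' @param parameters Which parameter columns to model.
#' @return An object of class `apm_normative`.
#' @export
fit_normative <- function(params, meta, quadratic_age = TRUE,
                          parameters = apm_parameter_names()) {
  stopifnot(nrow(params) == nrow(meta))
  if (!is.null(meta$group) && any(meta$group != "control")) {
    keep <- meta$group == "control"
    message(sprintf("fit_normative: using %d control of %d rows",
                    sum(keep), length(keep)))
    params <- params[keep, , drop = FALSE]
    meta <- meta[keep, , drop = FALSE]
  }
  if (nrow(params) < 30L) {
    stop("need at least 30 control sessions to fit a normative model",
         call. = FALSE)
  }
  miss <- setdiff(parameters, names(params))
  if (length(miss)) {
    stop(sprintf("missing parameter columns: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  X <- prune_design(normative_design(meta, quadratic_age))

  models <- lapply(parameters, function(p) {
    v <- params[[p]]
    ## signed parameters always get the positivity shift; others only
    ## when the control sample itself strays to or below zero
    offset <- if (p %in% c("shift_x", "shift_y")) {
      -min(v) + 0.1 * stats::IQR(v)
    } else if (min(v) <= 0) NULL else 0
    bc <- fit_boxcox(v, offset = offset)
    tx <- boxcox_apply(v + bc$offset, bc$lambda)
    fit1 <- stats::lm.fit(X, tx)
    r <- fit1$residuals
    fit2 <- stats::lm.fit(X, abs(r) * sqrt(pi / 2))
    sd_floor <- 0.1 * stats::sd(r)
    s <- pmax(X %*% fit2$coefficients, sd_floor)
    z <- r / s
    diag <- check_distribution(z)
    list(parameter = p, boxcox_lambda = bc$lambda, boxcox_offset = bc$offset,
         mean_coeffs = fit1$coefficients, sd_coeffs = fit2$coefficients,
         sd_floor = sd_floor,
         clamp_floor = 0.5 * min(v + bc$offset),
         skew_stat = diag$skew_stat, kurtosis_stat = diag$kurtosis_stat,
         valid = diag$valid)
  })
  names(models) <- parameters
  invalid <- parameters[!vapply(models, `[[`, TRUE, "valid")]
  if (length(invalid)) {
    warning(sprintf("normality diagnostics failed for: %s",
                    paste(invalid, collapse = ", ")), call. = FALSE)
  }
  structure(list(models = models, terms = colnames(X),
                 quadratic_age = quadratic_age, n = nrow(params),
                 parameters = parameters),
            class = "apm_normative")
}

#' @export
print.apm_normative <- function(x, ...) {
  cat(sprintf("Normative APM model: %d parameters fitted on %d control sessions\n",
              length(x$models), x$n))
  cat("Design terms:", paste(x$terms, collapse = ", "), "\n")
  nv <- sum(!vapply(x$models, `[[`, TRUE, "valid"))
  if (nv) cat(sprintf("%d parameter(s) fail the skew/kurtosis criteria\n", nv))
  invisible(x)
}

#' @export
summary.apm_normative <- function(object, ...) {
  tab <- do.call(rbind, lapply(object$models, function(m) {
    data.frame(parameter = m$parameter, lambda = m$boxcox_lambda,
               offset = m$boxcox_offset, skew = m$skew_stat,
               kurtosis = m$kurtosis_stat, valid = m$valid)
  }))
  rownames(tab) <- NULL
  structure(list(table = tab, n = object$n, terms = object$terms),
            class = "summary.apm_normative")
}

#' @export
print.summary.apm_normative <- function(x, ...) {
  cat(sprintf("Normative APM model (%d control sessions)\n", x$n))
  print(x$table, digits = 3)
  invisible(x)
}

#' @export
coef.apm_normative <- function(object, which = c("mean", "sd"), ...) {
  which <- match.arg(which)
  t(vapply(object$models,
           function(m) m[[paste0(which, "_coeffs")]],
           numeric(length(object$terms))))
}

#' Standardize sessions against a fitted normative model
#'
#' Applies the frozen Box-Cox + dual-regression chain: `z = (boxcox(value
#' + offset) - predicted mean) / predicted SD`.  Values whose shifted
#' argument is non-positive (outside the training support) are clamped to
#' half the smallest shifted training value, with a warning.
#'
#' @param object Fitted `apm_normative` model.
#' @param params Parameter table for the sessions to score.
#' @param meta Covariate table aligned with `params`.
#' @param ... Unused.
#' @return Data frame of z-scores (one column per parameter).
#' @export
predict.apm_normative <- function(object, params, meta, ...) {
  stopifnot(nrow(params) == nrow(meta))
  X <- normative_design(meta, object$quadratic_age)
  X <- X[, object$terms, drop = FALSE]
  out <- lapply(object$models, function(m) {
    x <- params[[m$parameter]] + m$boxcox_offset
    bad <- x <= 0
    if (any(bad)) {
      warning(sprintf("%s: %d value(s) at or below the transform support; clamped",
                      m$parameter, sum(bad)), call. = FALSE)
      x[bad] <- m$clamp_floor
    }
    tx <- boxcox_apply(x, m$boxcox_lambda)
    mu <- as.vector(X %*% m$mean_coeffs)
    s <- pmax(as.vector(X %*% m$sd_coeffs), m$sd_floor)
    (tx - mu) / s
  })
  res <- as.data.frame(out)
  names(res) <- names(object$models)
  if (!is.null(params$participant_id)) {
    res <- cbind(participant_id = params$participant_id, res)
  }
  res
}

#' Z-score a cohort (convenience wrapper)
#'
#' @inheritParams predict.apm_normative
#' @param model Fitted `apm_normative` model.
#' @return Data frame of z-scores.
#' @export
zscore <- function(params, meta, model) predict(model, params, meta)

## numeric z matrix from a zscore() result
zscore_matrix <- function(z, parameters = apm_parameter_names()) {
  as.matrix(z[, parameters, drop = FALSE])
}

#' Serialize a normative (and optional task-score) model to JSON
#'
#' @param model Fitted `apm_normative`.
#' @param task_model Optional fitted `apm_taskscore` appended to the file.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_normative_json <- function(model, path, task_model = NULL) {
  obj <- list(
    type = "apm_normative",
    n = model$n, terms = model$terms, quadratic_age = model$quadratic_age,
    parameters = lapply(model$models, function(m) {
      list(boxcox_lambda = m$boxcox_lambda, boxcox_offset = m$boxcox_offset,
           mean_coeffs = as.list(stats::setNames(m$mean_coeffs, model$terms)),
           sd_coeffs = as.list(stats::setNames(m$sd_coeffs, model$terms)),
           sd_floor = m$sd_floor, clamp_floor = m$clamp_floor,
           skew_stat = m$skew_stat, kurtosis_stat = m$kurtosis_stat,
           valid = m$valid)
    }))
  if (!is.null(task_model)) {
    obj$task_score <- list(
      sidedness = as.list(task_model$sidedness),
      rss_boxcox_lambda = task_model$lambda,
      rss_boxcox_offset = task_model$offset,
      rss_mean = task_model$mean, rss_sd = task_model$sd,
      outlier_ids = task_model$outlier_ids,
      iterations = task_model$iterations)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
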