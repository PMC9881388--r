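## Composite task score.
##
## One-sided parameters (where only one direction of deviation marks poor
## performance) are re-expressed as zeta scores; the Euclidean norm over
## all z/zeta scores (the RSS distance) is Box-Cox transformed,
## standardized against controls, and folded one-sided again so that 0 is
## best performance, > 1.96 marks impairment and > 3.29 a control outlier
## (normally 1 in 1000).

#' Default sidedness map for the 12 APM parameters
#'
#' Dispersion and magnitude parameters (variability, absolute error, the
#' resultant shift) are one-sided with large values bad; the signed
#' shifts and the workspace gain ratios are abnormal in either direction
#' and stay two-sided.
#'
#' @return Named character vector over the 12 parameters with values
#'   `"two_sided"`, `"one_sided_high_bad"` or `"one_sided_low_bad"`.
#' @export
default_sidedness <- function() {
  s <- c(var_x = "one_sided_high_bad", var_y = "one_sided_high_bad",
         var_xy = "one_sided_high_bad",
         ce_x = "two_sided", ce_y = "two_sided", ce_xy = "two_sided",
         shift_x = "two_sided", shift_y = "two_sided",
         shift_xy = "one_sided_high_bad",
         ae_x = "one_sided_high_bad", ae_y = "one_sided_high_bad",
         ae_xy = "one_sided_high_bad")
  s[apm_parameter_names()]
}

check_sidedness <- function(sidedness, parameters = apm_parameter_names()) {
  if (!setequal(names(sidedness), parameters)) {
    stop("sidedness map must cover each of the 12 parameters exactly once",
         call. = FALSE)
  }
  ok <- sidedness %in% c("two_sided", "one_sided_high_bad", "one_sided_low_bad")
  if (!all(ok)) {
    stop(sprintf("unknown sidedness value(s): %s",
                 paste(unique(sidedness[!ok]), collapse = ", ")), call. = FALSE)
  }
  sidedness[parameters]
}

#' One-sided zeta transform of a z-score
#'
#' `zeta = sqrt(2) * erfcinv(erfc(+/- z / sqrt(2)) / 2)`: the one-sided
#' tail probability of `+/- z` is halved and mapped back through the
#' normal quantile, so that a standard-normal z yields
#' `P(zeta > c) = 2 * (1 - pnorm(c))`.  Strictly increasing in `+/- z`,
#' positive, and 0.67449 at `z = 0`.
#'
#' @param z Numeric vector of z-scores.
#' @param sign `"plus"` when poor performance is positive, `"minus"` when
#'   poor performance is negative.
#' @return Zeta scores, same length as `z`.
#' @export
zeta_transform <- function(z, sign = c("plus", "minus")) {
  sign <- match.arg(sign)
  x <- if (sign == "plus") z else -z
  ## upper-tail probability, kept away from 0/1 so the quantile stays finite
  p <- stats::pnorm(x, lower.tail = FALSE)
  p <- pmin(pmax(p, 1e-300), 1 - 1e-16)
  stats::qnorm(p / 2, lower.tail = FALSE)
}

#' Root-sum-square distance over z and zeta scores
#'
#' Two-sided parameters contribute their squared z-scores; one-sided
#' parameters their squared zeta scores (with the sign dictated by the
#' sidedness map).
#'
#' @param z Matrix or data frame of z-scores (columns = parameters), or a
#'   single named vector.
#' @param sidedness Sidedness map (default [default_sidedness()]).
#' @return Non-negative numeric vector, one RSS distance per row.
#' @export
rss_distance <- function(z, sidedness = default_sidedness()) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1, dimnames = list(NULL, names(z)))
  z <- as.data.frame(z)
  cols <- intersect(names(sidedness), colnames(z))
  if (!length(cols)) {
    stop("no z-score columns match the sidedness map", call. = FALSE)
  }
  sidedness <- sidedness[cols]
  ok <- sidedness %in% c("two_sided", "one_sided_high_bad", "one_sided_low_bad")
  if (!all(ok)) {
    stop(sprintf("unknown sidedness value(s): %s",
                 paste(unique(sidedness[!ok]), collapse = ", ")), call. = FALSE)
  }
  zm <- as.matrix(z[, cols, drop = FALSE])
  if (any(!is.finite(zm))) stop("non-finite z-scores", call. = FALSE)
  acc <- 0
  for (p in names(sidedness)) {
    v <- switch(sidedness[[p]],
                two_sided = zm[, p],
                one_sided_high_bad = zeta_transform(zm[, p], "plus"),
                one_sided_low_bad = zeta_transform(zm[, p], "minus"))
    acc <- acc + v^2
  }
  unname(sqrt(acc))
}

#' Fit the composite task-score model on control z-scores
#'
#' Computes control RSS distances, Box-Cox transforms them, standardizes
#' with the control mean/SD, folds one-sided (poor performance positive),
#' then removes controls scoring above the 1-in-1000 bound (3.29) and
#' refits, iterating to a fixed point (at most `max_iter` rounds).
#'
#' @param z Control z-score table ([zscore()] output or plain matrix).
#' @param sidedness Sidedness map.
#' @param outlier_threshold Control-outlier bound (default 3.29).
#' @param max_iter Maximum removal/refit rounds (default 5).
#' @return An object of class `apm_taskscore`.
#' @export
fit_task_score <- function(z, sidedness = default_sidedness(),
                           outlier_threshold = 3.29, max_iter = 5L) {
  sidedness <- check_sidedness(sidedness)
  z <- as.data.frame(z)
  miss <- setdiff(names(sidedness), colnames(z))
  if (length(miss)) {
    stop(sprintf("z-score table lacks columns: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  ids <- if (!is.null(z$participant_id)) as.character(z$participant_id)
         else as.character(seq_len(nrow(z)))
  rss <- rss_distance(z, sidedness)
  if (stats::sd(rss) == 0) {
    stop("degenerate control cohort: all RSS distances equal", call. = FALSE)
  }
  keep <- rep(TRUE, length(rss))
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    bc <- fit_boxcox(rss[keep])
    t <- boxcox_apply(rss[keep] + bc$offset, bc$lambda)
    m <- mean(t); s <- stats::sd(t)
    if (s == 0) stop("degenerate control cohort: zero transformed spread",
                     call. = FALSE)
    scores <- zeta_transform((t - m) / s, "plus")
    new_out <- scores > outlier_threshold
    if (!any(new_out) || iterations >= max_iter) break
    keep[keep][new_out] <- FALSE
  }
  structure(list(sidedness = sidedness, lambda = bc$lambda, offset = bc$offset,
                 mean = m, sd = s,
                 outlier_ids = ids[!keep], iterations = iterations,
                 outlier_threshold = outlier_threshold,
                 n = sum(keep),
                 clamp_floor = 0.5 * min(rss[keep] + bc$offset)),
            class = "apm_taskscore")
}

#' @export
print.apm_taskscore <- function(x, ...) {
  cat(sprintf("APM task-score model: %d retained controls, lambda = %.3f\n",
              x$n, x$lambda))
  cat(sprintf("%d control outlier(s) removed in %d iteration(s) at threshold %.2f\n",
              length(x$outlier_ids), x$iterations, x$outlier_threshold))
  invisible(x)
}

#' Compute task scores with a fitted model
#'
#' Applies the frozen chain RSS -> Box-Cox -> control standardization ->
#' one-sided fold.  Scores are non-negative and strictly increasing in
#' the RSS distance.
#'
#' @param object Fitted `apm_taskscore` model.
#' @param z Z-score table (or matrix) for the sessions to score.
#' @param ... Unused.
#' @return Numeric vector of task scores.
#' @export
predict.apm_taskscore <- function(object, z, ...) {
  rss <- rss_distance(z, object$sidedness)
  x <- rss + object$offset
  bad <- x <= 0
  if (any(bad)) {
    warning(sprintf("%d RSS value(s) at or below the transform support; clamped",
                    sum(bad)), call. = FALSE)
    x[bad] <- object$clamp_floor
  }
  t <- boxcox_apply(x, object$lambda)
  zeta_transform((t - object$mean) / object$sd, "plus")
}

#' Task scores for a cohort (convenience wrapper)
#'
#' @param z Z-score table.
#' @param model Fitted `apm_taskscore`.
#' @return Numeric vector of task scores.
#' @export
task_score <- function(z, model) predict(model, z)
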