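## 95% cut-off score technique.
##
## A session is impaired on a one-sided parameter when its zeta score
## exceeds the threshold, on a two-sided parameter when |z| does, and
## overall when the composite task score does (strict inequality; the
## default 1.96 is the two-sided 95% normal bound).

#' Classify impairment against the control cut-off
#'
#' @param z Z-score table or matrix for the sessions to classify.
#' @param scores Task scores for the same sessions ([task_score()]).
#' @param sidedness Sidedness map used for the per-parameter rule.
#' @param threshold Cut-off (default 1.96); impairment requires a score
#'   strictly above it.
#' @return Data frame of logicals: one column per parameter plus
#'   `overall`.
#' @export
classify_impairment <- function(z, scores, sidedness = default_sidedness(),
                                threshold = 1.96) {
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  sidedness <- check_sidedness(sidedness)
  z <- as.data.frame(z)
  flags <- lapply(names(sidedness), function(p) {
    v <- z[[p]]
    if (sidedness[[p]] == "two_sided") {
      abs(v) > threshold
    } else {
      sgn <- if (sidedness[[p]] == "one_sided_high_bad") "plus" else "minus"
      zeta_transform(v, sgn) > threshold
    }
  })
  names(flags) <- names(sidedness)
  out <- as.data.frame(flags)
  out$overall <- scores > threshold
  if (!is.null(z$participant_id)) {
    out <- cbind(participant_id = z$participant_id, out)
  }
  out
}

#' Cross-validated impairment rates among stroke participants
#'
#' Stratified K-fold split of the cohort; for each fold the normative and
#' task-score models are refitted on the training-fold controls and
#' impairment is classified among the test-fold stroke sessions.  Returns
#' the mean and SD of the per-fold rates for every parameter and the
#' overall task score.  `K = 1` degenerates to whole-sample fitting and
#' classification.
#'
#' @param params Parameter table for the full cohort.
#' @param meta Participant table (`group` column with both levels).
#' @param K Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @param sidedness Sidedness map.
#' @param threshold Impairment cut-off (default 1.96).
#' @param quadratic_age Passed to [fit_normative()].
#' @return List with `rates` (data frame: parameter, mean_rate, sd_rate)
#'   and `folds` (per-fold rate matrix).
#' @export
impairment_rates_cv <- function(params, meta, K = 10L, seed = 1L,
                                sidedness = default_sidedness(),
                                threshold = 1.96, quadratic_age = TRUE) {
  stopifnot(nrow(params) == nrow(meta))
  if (!all(c("control", "stroke") %in% meta$group)) {
    stop("cohort must contain both control and stroke sessions", call. = FALSE)
  }
  n <- nrow(meta)
  folds <- if (K == 1L) rep(1L, n) else make_folds(meta$group, K = K, seed = seed)
  rate_names <- c(names(check_sidedness(sidedness)), "overall")
  per_fold <- matrix(NA_real_, nrow = K, ncol = length(rate_names),
                     dimnames = list(NULL, rate_names))
  for (k in seq_len(K)) {
    test <- if (K == 1L) folds == 1L else folds == k
    train <- if (K == 1L) rep(TRUE, n) else !test
    tr_ctrl <- train & meta$group == "control"
    te_strk <- test & meta$group == "stroke"
    if (!any(te_strk)) {
      stop(sprintf("fold %d contains no stroke sessions; use stratified folds or smaller K", k),
           call. = FALSE)
    }
    nm <- fit_normative(params[tr_ctrl, , drop = FALSE],
                        meta[tr_ctrl, , drop = FALSE],
                        quadratic_age = quadratic_age)
    z_ctrl <- predict(nm, params[tr_ctrl, , drop = FALSE],
                      meta[tr_ctrl, , drop = FALSE])
    ts <- fit_task_score(z_ctrl, sidedness)
    z_te <- predict(nm, params[te_strk, , drop = FALSE],
                    meta[te_strk, , drop = FALSE])
    sc <- predict(ts, z_te)
    imp <- classify_impairment(z_te, sc, sidedness, threshold)
    per_fold[k, ] <- colMeans(imp[, rate_names, drop = FALSE])
  }
  rates <- data.frame(parameter = rate_names,
                      mean_rate = colMeans(per_fold),
                      sd_rate = apply(per_fold, 2, stats::sd))
  rownames(rates) <- NULL
  list(rates = rates, folds = per_fold, K = K, threshold = threshold)
}
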