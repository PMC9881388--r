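## Synthetic cohorts for the arm-position-matching (APM) task.
##
## The generator emulates the behavioural structure the downstream analysis
## assumes: the robot places the passive hand exactly on a target of a 2x2
## (20 cm) or 3x3 (10 cm) grid; the participant mirror-matches with the
## active hand.  A participant's matching behaviour is an affine distortion
## of the ideal mirror (per-axis gain about the active workspace centroid
## plus a constant offset) with independent per-trial Gaussian noise.

#' Cohort configuration for the synthetic APM generator
#'
#' Builds the configuration object consumed by [generate_cohort()].  The
#' defaults emulate a large cross-sectional study: 465 control sessions
#' (healthy controls tested once per arm, two sessions sharing covariates)
#' and 429 stroke sessions, with ages, sex ratios and handedness mixes
#' typical of such cohorts, and a stroke group that is a mixture of
#' unimpaired-like and impaired matching behaviour (default impaired
#' fraction 0.44).
#'
#' Control latent traits depend on covariates so that the normative
#' regressions are identifiable: trial noise (and hence absolute error)
#' grows log-linearly with age, with small multiplicative sex, handedness
#' and platform offsets; the contraction/expansion gain drifts slightly
#' below 1 with age.  All trait parameters are per-axis and configurable.
#'
#' @param n_control,n_stroke Number of participant sessions per group.
#' @param protocol_mix Named probabilities for `"9-target"`/`"4-target"`.
#' @param platform_mix Named probabilities for `"exoskeleton"`/`"endpoint"`.
#' @param dual_arm_controls If `TRUE`, control sessions come in pairs (one
#'   per passive arm) sharing covariates but with independent traits.
#' @param control,stroke Named lists overriding entries of the default
#'   group configurations (see Details in the package vignette).
#' @return An object of class `apm_cohort_config` (a named list).
#' @export
cohort_config <- function(n_control = 465L, n_stroke = 429L,
                          protocol_mix = c("9-target" = 0.6, "4-target" = 0.4),
                          platform_mix = c(exoskeleton = 0.7, endpoint = 0.3),
                          dual_arm_controls = TRUE,
                          control = list(), stroke = list()) {
  ctrl <- list(
    age_mean = 51, age_sd = 16, age_range = c(20, 88),
    p_male = 0.525,
    handedness_probs = c(R = 0.933, L = 0.062, A = 0.005),
    sigma_base = c(x = 0.9, y = 1.1),       # cm, trial-noise SD at age 50
    sigma_log_sd = 0.25,                    # between-participant spread
    sigma_age_slope = 0.008,                # per year, on log sigma
    sigma_male_mult = 1.05,
    sigma_left_mult = 1.03,
    sigma_endpoint_mult = 1.08,
    ce_log_sd = c(x = 0.08, y = 0.08),
    ce_age_slope = -0.0008,                 # per year, on log gain
    shift_mean = c(x = 0.5, y = 0.5),       # cm
    shift_sd = c(x = 1.2, y = 1.2)          # cm
  )
  strk <- list(
    age_mean = 63, age_sd = 14, age_range = c(18, 92),
    p_male = 0.653,
    handedness_probs = c(R = 0.916, L = 0.077, A = 0.007),
    impaired_fraction = 0.44,
    unimpaired_sigma_mult = 1.15,
    impaired_sigma_mult_log_mean = c(x = log(2.2), y = log(2.2)),
    impaired_sigma_mult_log_sd = c(x = 0.4, y = 0.4),
    impaired_ce_log_mean = c(x = -0.08, y = -0.08),
    impaired_ce_log_sd = c(x = 0.12, y = 0.12),
    impaired_extra_shift_sd = c(x = 1.5, y = 1.5)
  )
  ctrl[names(control)] <- control
  strk[names(stroke)] <- stroke

  cfg <- list(n_control = as.integer(n_control), n_stroke = as.integer(n_stroke),
              protocol_mix = protocol_mix, platform_mix = platform_mix,
              dual_arm_controls = isTRUE(dual_arm_controls),
              control = ctrl, stroke = strk)
  class(cfg) <- "apm_cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_control < 0L) stop_config("n_control", "must be non-negative")
  if (cfg$n_stroke < 0L) stop_config("n_stroke", "must be non-negative")
  if (cfg$n_control + cfg$n_stroke <= 0L) stop_config("n_control", "cohort is empty")
  if (any(cfg$protocol_mix < 0) || sum(cfg$protocol_mix) <= 0)
    stop_config("protocol_mix", "must be non-negative with positive sum")
  if (any(cfg$platform_mix < 0) || sum(cfg$platform_mix) <= 0)
    stop_config("platform_mix", "must be non-negative with positive sum")
  ctrl <- cfg$control
  if (any(ctrl$sigma_base <= 0)) stop_config("control$sigma_base", "must be positive")
  if (ctrl$sigma_log_sd < 0) stop_config("control$sigma_log_sd", "must be non-negative")
  if (any(ctrl$shift_sd < 0)) stop_config("control$shift_sd", "must be non-negative")
  if (any(ctrl$ce_log_sd < 0)) stop_config("control$ce_log_sd", "must be non-negative")
  if (diff(ctrl$age_range) < 0) stop_config("control$age_range", "must be increasing")
  strk <- cfg$stroke
  if (strk$impaired_fraction < 0 || strk$impaired_fraction > 1)
    stop_config("stroke$impaired_fraction", "must be in [0, 1]")
  if (any(strk$impaired_sigma_mult_log_sd < 0))
    stop_config("stroke$impaired_sigma_mult_log_sd", "must be non-negative")
  if (any(strk$impaired_extra_shift_sd < 0))
    stop_config("stroke$impaired_extra_shift_sd", "must be non-negative")
  invisible(cfg)
}

#' Default population configuration
#'
#' Convenience wrapper returning [cohort_config()] with its defaults: 465
#' control and 429 stroke sessions, control ages spanning 20-88 years
#' (mean 51), stroke ages 18-92 (mean 63), and a stroke impaired fraction
#' of 0.44.
#'
#' @return An `apm_cohort_config` object.
#' @export
default_population_config <- function() cohort_config()

## Passive-hand target grid in a global frame with the body midline at x = 0.
## The passive workspace is centred 20 cm lateral of the midline on the
## passive side, 30 cm in front; targets are ordered by (y, x) ascending.
target_grid <- function(protocol, passive_arm) {
  if (protocol == "9-target") {
    off <- c(-10, 0, 10)
  } else if (protocol == "4-target") {
    off <- c(-10, 10)   # 20 cm spacing
  } else {
    stop_config("protocol", sprintf("unknown protocol '%s'", protocol))
  }
  xc <- if (passive_arm == "left") -20 else 20
  g <- expand.grid(x = off, y = off, KEEP.OUT.ATTRS = FALSE)
  g <- g[order(g$y, g$x), ]
  data.frame(target_id = seq_len(nrow(g)),
             target_x = xc + g$x, target_y = 30 + g$y)
}

## target_id sequence tracing the border polygon (perimeter order)
border_order <- function(protocol) {
  if (protocol == "9-target") c(1L, 2L, 3L, 6L, 9L, 8L, 7L, 4L) else c(1L, 2L, 4L, 3L)
}

#' Simulate the trials of one participant session
#'
#' The robot places the passive hand exactly on the target.  The active
#' hand's matched position is the mirror image of the target distorted by
#' per-axis gains about the active workspace centroid, a constant offset,
#' and independent Gaussian trial noise.  Target order within each of the
#' six blocks is a seeded permutation.
#'
#' @param meta One-row data frame (or list) with `participant_id`,
#'   `protocol` and `passive_arm`.
#' @param traits Named list/vector with `sigma_x`, `sigma_y` (cm, > 0 or 0),
#'   `ce_x`, `ce_y` (gains > 0), `shift_x`, `shift_y` (cm).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return Data frame of trial records (6 blocks x 4 or 9 targets).
#' @export
generate_participant_trials <- function(meta, traits, seed = NULL) {
  traits <- as.list(traits)
  for (f in c("sigma_x", "sigma_y")) {
    if (traits[[f]] < 0) stop_config(f, "must be non-negative")
  }
  for (f in c("ce_x", "ce_y")) {
    if (traits[[f]] <= 0) stop_config(f, "must be positive")
  }
  with_seed(seed, {
    grid <- target_grid(meta$protocol, meta$passive_arm)
    nt <- nrow(grid)
    order_mat <- vapply(seq_len(6L), function(b) sample.int(nt), integer(nt))
    idx <- as.vector(order_mat)             # trial order within blocks
    tx <- grid$target_x[idx]; ty <- grid$target_y[idx]
    n <- length(idx)
    ## ideal active position mirrors the target about the midline (x = 0)
    ax0 <- -tx; ay0 <- ty
    cx <- mean(-grid$target_x); cy <- mean(grid$target_y)   # active centroid
    ax <- cx + traits$ce_x * (ax0 - cx) + traits$shift_x + rnorm(n, 0, traits$sigma_x)
    ay <- cy + traits$ce_y * (ay0 - cy) + traits$shift_y + rnorm(n, 0, traits$sigma_y)
    data.frame(participant_id = rep(meta$participant_id, n),
               block = rep(seq_len(6L), each = nt),
               target_id = grid$target_id[idx],
               target_x = tx, target_y = ty,
               passive_x = tx, passive_y = ty,
               active_x = ax, active_y = ay)
  })
}

## truncated-normal ages
draw_ages <- function(n, mean, sd, range) {
  if (n == 0L) return(numeric(0))
  a <- rnorm(n, mean, sd)
  bad <- which(a < range[1] | a > range[2])
  while (length(bad)) {
    a[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[a[bad] < range[1] | a[bad] > range[2]]
  }
  round(a, 1)
}

## control-model latent traits given covariates (vectorised over rows)
draw_baseline_traits <- function(meta, ctrl) {
  n <- nrow(meta)
  agec <- meta$age - 50
  covlog <- ctrl$sigma_age_slope * agec +
    log(ctrl$sigma_male_mult) * (meta$sex == "M") +
    log(ctrl$sigma_left_mult) * (meta$handedness != "R") +
    log(ctrl$sigma_endpoint_mult) * (meta$platform == "endpoint")
  data.frame(
    sigma_x = exp(log(ctrl$sigma_base[["x"]]) + covlog + rnorm(n, 0, ctrl$sigma_log_sd)),
    sigma_y = exp(log(ctrl$sigma_base[["y"]]) + covlog + rnorm(n, 0, ctrl$sigma_log_sd)),
    ce_x = exp(ctrl$ce_age_slope * agec + rnorm(n, 0, ctrl$ce_log_sd[["x"]])),
    ce_y = exp(ctrl$ce_age_slope * agec + rnorm(n, 0, ctrl$ce_log_sd[["y"]])),
    shift_x = rnorm(n, ctrl$shift_mean[["x"]], ctrl$shift_sd[["x"]]),
    shift_y = rnorm(n, ctrl$shift_mean[["y"]], ctrl$shift_sd[["y"]]),
    impaired = rep(FALSE, n)
  )
}

draw_categorical <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

## Vectorised trial simulation for a whole table of sessions; one rnorm
## call per axis per (protocol, passive_arm) stratum.
generate_trials_batch <- function(meta, traits) {
  combos <- unique(meta[, c("protocol", "passive_arm")])
  out <- vector("list", nrow(combos))
  for (k in seq_len(nrow(combos))) {
    rows <- which(meta$protocol == combos$protocol[k] &
                    meta$passive_arm == combos$passive_arm[k])
    grid <- target_grid(combos$protocol[k], combos$passive_arm[k])
    nt <- nrow(grid); np <- length(rows); ntr <- 6L * nt
    perm <- vapply(seq_len(np * 6L), function(i) sample.int(nt), integer(nt))
    idx <- as.vector(perm)
    n <- np * ntr
    tx <- grid$target_x[idx]; ty <- grid$target_y[idx]
    cx <- mean(-grid$target_x); cy <- mean(grid$target_y)
    sx <- rep(traits$sigma_x[rows], each = ntr)
    sy <- rep(traits$sigma_y[rows], each = ntr)
    gx <- rep(traits$ce_x[rows], each = ntr)
    gy <- rep(traits$ce_y[rows], each = ntr)
    ox <- rep(traits$shift_x[rows], each = ntr)
    oy <- rep(traits$shift_y[rows], each = ntr)
    ax <- cx + gx * (-tx - cx) + ox + rnorm(n, 0, sx)
    ay <- cy + gy * (ty - cy) + oy + rnorm(n, 0, sy)
    out[[k]] <- data.frame(
      participant_id = rep(meta$participant_id[rows], each = ntr),
      block = rep(rep(seq_len(6L), each = nt), np),
      target_id = grid$target_id[idx],
      target_x = tx, target_y = ty,
      passive_x = tx, passive_y = ty,
      active_x = ax, active_y = ay)
  }
  trials <- do.call(rbind, out)
  trials <- trials[order(match(trials$participant_id, meta$participant_id),
                         trials$block), ]
  rownames(trials) <- NULL
  trials
}

#' Generate a seeded synthetic APM cohort
#'
#' Draws participant metadata and latent matching traits per group, then
#' simulates the full trial tables.  Control sessions optionally come in
#' dual-arm pairs sharing covariates; a configurable fraction of the
#' stroke group carries inflated traits (noise, workspace gain, shift).
#' Fully deterministic for a fixed `(config, seed)` pair.
#'
#' @param config An [cohort_config()] object.
#' @param seed Integer seed.
#' @return A list with data frames `participants` (one row per session)
#'   and `trials` (one row per trial).
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  validate_cohort_config(config)
  with_seed(seed, {
    parts <- list(); traits <- list()

    ## --- controls -------------------------------------------------------
    nc <- config$n_control
    if (nc > 0L) {
      ni <- if (config$dual_arm_controls) ceiling(nc / 2) else nc
      base <- data.frame(
        age = draw_ages(ni, config$control$age_mean, config$control$age_sd,
                        config$control$age_range),
        sex = draw_categorical(ni, c(M = config$control$p_male,
                                     F = 1 - config$control$p_male)),
        handedness = draw_categorical(ni, config$control$handedness_probs),
        platform = draw_categorical(ni, config$platform_mix),
        protocol = draw_categorical(ni, config$protocol_mix)
      )
      if (config$dual_arm_controls) {
        base <- base[rep(seq_len(ni), each = 2L), ]
        base$passive_arm <- rep(c("left", "right"), ni)
        suffix <- rep(c("a", "b"), ni)
        base$participant_id <- sprintf("C%04d%s", rep(seq_len(ni), each = 2L), suffix)
        base <- base[seq_len(nc), ]
      } else {
        base$passive_arm <- draw_categorical(ni, c(left = 0.5, right = 0.5))
        base$participant_id <- sprintf("C%04d", seq_len(ni))
      }
      base$group <- "control"
      rownames(base) <- NULL
      tr <- draw_baseline_traits(base, config$control)
      parts$control <- base; traits$control <- tr
    }

    ## --- stroke ---------------------------------------------------------
    ns <- config$n_stroke
    if (ns > 0L) {
      strk <- config$stroke
      base <- data.frame(
        age = draw_ages(ns, strk$age_mean, strk$age_sd, strk$age_range),
        sex = draw_categorical(ns, c(M = strk$p_male, F = 1 - strk$p_male)),
        handedness = draw_categorical(ns, strk$handedness_probs),
        platform = draw_categorical(ns, config$platform_mix),
        protocol = draw_categorical(ns, config$protocol_mix),
        passive_arm = draw_categorical(ns, c(left = 0.5, right = 0.5)),
        participant_id = sprintf("S%04d", seq_len(ns)),
        group = "stroke"
      )
      tr <- draw_baseline_traits(base, config$control)
      imp <- runif(ns) < strk$impaired_fraction
      tr$impaired <- imp
      n_imp <- sum(imp)
      if (n_imp > 0L) {
        tr$sigma_x[imp] <- tr$sigma_x[imp] *
          exp(rnorm(n_imp, strk$impaired_sigma_mult_log_mean[["x"]],
                    strk$impaired_sigma_mult_log_sd[["x"]]))
        tr$sigma_y[imp] <- tr$sigma_y[imp] *
          exp(rnorm(n_imp, strk$impaired_sigma_mult_log_mean[["y"]],
                    strk$impaired_sigma_mult_log_sd[["y"]]))
        tr$ce_x[imp] <- tr$ce_x[imp] *
          exp(rnorm(n_imp, strk$impaired_ce_log_mean[["x"]],
                    strk$impaired_ce_log_sd[["x"]]))
        tr$ce_y[imp] <- tr$ce_y[imp] *
          exp(rnorm(n_imp, strk$impaired_ce_log_mean[["y"]],
                    strk$impaired_ce_log_sd[["y"]]))
        tr$shift_x[imp] <- tr$shift_x[imp] +
          rnorm(n_imp, 0, strk$impaired_extra_shift_sd[["x"]])
        tr$shift_y[imp] <- tr$shift_y[imp] +
          rnorm(n_imp, 0, strk$impaired_extra_shift_sd[["y"]])
      }
      if (any(!imp)) {
        m <- strk$unimpaired_sigma_mult
        tr$sigma_x[!imp] <- tr$sigma_x[!imp] * m
        tr$sigma_y[!imp] <- tr$sigma_y[!imp] * m
      }
      parts$stroke <- base; traits$stroke <- tr
    }

    meta <- do.call(rbind, lapply(parts, function(p) {
      p[, c("participant_id", "group", "age", "sex", "handedness",
            "platform", "passive_arm", "protocol")]
    }))
    rownames(meta) <- NULL
    trt <- do.call(rbind, unname(traits))
    rownames(trt) <- NULL
    meta$impaired <- trt$impaired

    trials <- generate_trials_batch(meta, trt)
    list(participants = meta, trials = trials, traits = cbind(
      participant_id = meta$participant_id, trt))
  })
}
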