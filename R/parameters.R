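## The 12 arm-position-matching parameters.
##
## All computations happen in the passive-hand frame after reflecting the
## active hand about the body midline (x = 0).  The matching error of a
## trial is defined as (mirrored active - target); its sign convention is
## therefore "positive x = matched position farther from the midline on
## the passive side is negative x" and is carried through Shift.

#' Mirror active-hand positions into the passive-hand frame
#'
#' Reflects each trial's active-hand final position about the body
#' midline (x = 0) so matched and target positions live in a common
#' frame; y is unchanged.  Verifies trial completeness (six blocks, one
#' trial per target per block).
#'
#' @param trials Trial records for one participant session.
#' @param meta Ignored except for error messages; kept for interface
#'   symmetry with the generator.
#' @return The trials with `matched_x`, `matched_y`, `err_x`, `err_y`
#'   columns appended.
#' @export
mirror_active_positions <- function(trials, meta = NULL) {
  check_trials_complete(trials)
  trials$matched_x <- -trials$active_x
  trials$matched_y <- trials$active_y
  trials$err_x <- trials$matched_x - trials$target_x
  trials$err_y <- trials$matched_y - trials$target_y
  trials
}

check_trials_complete <- function(trials) {
  tid <- sort(unique(trials$target_id))
  nt <- length(tid)
  if (!nt %in% c(4L, 9L)) {
    stop(sprintf("expected 4 or 9 targets, found %d", nt), call. = FALSE)
  }
  full <- expand.grid(block = seq_len(6L), target_id = tid)
  key <- paste(trials$block, trials$target_id)
  fkey <- paste(full$block, full$target_id)
  missing <- setdiff(fkey, key)
  if (length(missing)) {
    stop(sprintf("missing trials for (block, target): %s",
                 paste(missing, collapse = "; ")), call. = FALSE)
  }
  if (anyDuplicated(key)) {
    stop(sprintf("duplicated trials for (block, target): %s",
                 paste(unique(key[duplicated(key)]), collapse = "; ")),
         call. = FALSE)
  }
  invisible(trials)
}

#' Trial-to-trial variability of the matched position
#'
#' Per-target sample standard deviation (n-1 denominator) of the matched
#' position across the six blocks, averaged over targets; the combined
#' value is the resultant `sqrt(var_x^2 + var_y^2)`.
#'
#' @param matched Output of [mirror_active_positions()].
#' @return Named numeric vector `var_x`, `var_y`, `var_xy` (cm).
#' @export
compute_variability <- function(matched) {
  g <- factor(matched$target_id)
  cnt <- tabulate(g)
  if (any(cnt < 2L)) stop("need at least 2 trials per target", call. = FALSE)
  sd_by <- function(v) tapply(v, g, stats::sd)
  var_x <- mean(sd_by(matched$matched_x))
  var_y <- mean(sd_by(matched$matched_y))
  c(var_x = var_x, var_y = var_y, var_xy = sqrt(var_x^2 + var_y^2))
}

## per-target mean matched and target positions, one row per target,
## ordered by target_id
target_means <- function(matched) {
  g <- factor(matched$target_id)
  data.frame(target_id = as.integer(levels(g)),
             tx = as.vector(tapply(matched$target_x, g, mean)),
             ty = as.vector(tapply(matched$target_y, g, mean)),
             mx = as.vector(tapply(matched$matched_x, g, mean)),
             my = as.vector(tapply(matched$matched_y, g, mean)))
}

shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Spatial contraction/expansion ratio of the matched workspace
#'
#' `ce_x` is the x-range of the per-target mean matched positions (the
#' difference between the mean x of the left-column and right-column
#' targets) divided by the same range of the targets themselves; `ce_y`
#' analogously for the top/bottom rows.  `ce_xy` is the area of the
#' polygon spanned by the mean matched positions of the border targets
#' (shoelace formula) divided by the target polygon area.
#'
#' @param matched Output of [mirror_active_positions()].
#' @param protocol `"9-target"` or `"4-target"` (inferred from the target
#'   count when `NULL`).
#' @return Named numeric vector `ce_x`, `ce_y`, `ce_xy` (dimensionless).
#' @export
compute_contraction_expansion <- function(matched, protocol = NULL) {
  tm <- target_means(matched)
  if (is.null(protocol)) {
    protocol <- if (nrow(tm) == 9L) "9-target" else "4-target"
  }
  xs <- sort(unique(tm$tx)); ys <- sort(unique(tm$ty))
  left <- tm$tx == xs[1]; right <- tm$tx == xs[length(xs)]
  bottom <- tm$ty == ys[1]; top <- tm$ty == ys[length(ys)]
  rng_tx <- abs(mean(tm$tx[right]) - mean(tm$tx[left]))
  rng_ty <- abs(mean(tm$ty[top]) - mean(tm$ty[bottom]))
  if (rng_tx <= 0 || rng_ty <= 0) {
    stop("degenerate protocol: zero passive target range", call. = FALSE)
  }
  ce_x <- abs(mean(tm$mx[right]) - mean(tm$mx[left])) / rng_tx
  ce_y <- abs(mean(tm$my[top]) - mean(tm$my[bottom])) / rng_ty
  b <- match(border_order(protocol), tm$target_id)
  a_active <- shoelace_area(tm$mx[b], tm$my[b])
  a_passive <- shoelace_area(tm$tx[b], tm$ty[b])
  c(ce_x = ce_x, ce_y = ce_y, ce_xy = a_active / a_passive)
}

#' Systematic spatial shift of the matched workspace
#'
#' Mean matching error (mirrored active minus target) per target,
#' averaged over targets; components are signed, the resultant
#' `shift_xy = sqrt(shift_x^2 + shift_y^2)` is not.
#'
#' @inheritParams compute_variability
#' @return Named numeric vector `shift_x`, `shift_y`, `shift_xy` (cm).
#' @export
compute_shift <- function(matched) {
  g <- factor(matched$target_id)
  shift_x <- mean(tapply(matched$err_x, g, mean))
  shift_y <- mean(tapply(matched$err_y, g, mean))
  c(shift_x = shift_x, shift_y = shift_y,
    shift_xy = sqrt(shift_x^2 + shift_y^2))
}

#' Mean absolute matching error
#'
#' Mean over all trials (not per target first) of the absolute matching
#' error per axis; `ae_xy = sqrt(ae_x^2 + ae_y^2)`.
#'
#' @inheritParams compute_variability
#' @return Named numeric vector `ae_x`, `ae_y`, `ae_xy` (cm).
#' @export
compute_absolute_error <- function(matched) {
  ae_x <- mean(abs(matched$err_x))
  ae_y <- mean(abs(matched$err_y))
  c(ae_x = ae_x, ae_y = ae_y, ae_xy = sqrt(ae_x^2 + ae_y^2))
}

#' Compute the full 12-parameter vector for one session
#'
#' @param trials Trial records of a single participant session.
#' @param meta Optional metadata row (unused in the computation).
#' @return Named numeric vector with the 12 entries of
#'   [apm_parameter_names()].
#' @export
compute_parameter_vector <- function(trials, meta = NULL) {
  m <- mirror_active_positions(trials, meta)
  c(compute_variability(m),
    compute_contraction_expansion(m),
    compute_shift(m),
    compute_absolute_error(m))
}

#' Compute APM parameters for every session in a trial table
#'
#' Vectorised equivalent of applying [compute_parameter_vector()] per
#' participant session; suitable for cohorts of tens of thousands of
#' sessions.
#'
#' @param trials Trial table covering one or more sessions.
#' @param meta Optional participant table (checked for id coverage).
#' @return Data frame with `participant_id` plus the 12 parameter columns.
#' @export
compute_parameters <- function(trials, meta = NULL) {
  pid <- factor(trials$participant_id, levels = unique(trials$participant_id))
  mx <- -trials$active_x
  my <- trials$active_y
  ex <- mx - trials$target_x
  ey <- my - trials$target_y

  gt <- interaction(pid, trials$target_id, drop = TRUE, lex.order = TRUE)
  gti <- as.integer(gt)   # integer codes keep rowsum rows in level order
  n_g <- as.vector(rowsum(rep(1, length(gt)), gti))
  if (any(n_g < 2L)) stop("need at least 2 trials per target", call. = FALSE)
  gsum <- function(v) as.vector(rowsum(v, gti))
  mean_g <- function(v) gsum(v) / n_g
  sd_g <- function(v) {
    m <- mean_g(v)
    sqrt(pmax(gsum(v^2) / n_g - m^2, 0) * n_g / (n_g - 1))
  }
  ## group -> participant map (groups are pid-major in lex order)
  g_pid <- factor(sub("\\..*$", "", levels(gt)), levels = levels(pid))
  n_t <- as.vector(table(g_pid))
  psum <- function(v) as.vector(rowsum(v, as.integer(g_pid)))
  pmean_over_targets <- function(v) psum(v) / n_t

  var_x <- pmean_over_targets(sd_g(mx))
  var_y <- pmean_over_targets(sd_g(my))

  mtx <- mean_g(trials$target_x); mty <- mean_g(trials$target_y)
  mmx <- mean_g(mx); mmy <- mean_g(my)
  shift_x <- pmean_over_targets(mean_g(ex))
  shift_y <- pmean_over_targets(mean_g(ey))

  n_p <- as.vector(table(pid))
  ae_x <- as.vector(rowsum(abs(ex), as.integer(pid))) / n_p
  ae_y <- as.vector(rowsum(abs(ey), as.integer(pid))) / n_p

  ## contraction/expansion needs target geometry; do it per session on the
  ## per-target mean table (cheap: one row per participant-target)
  tmtab <- data.frame(pid = g_pid, target_id = as.integer(sub("^.*\\.", "", levels(gt))),
                      tx = mtx, ty = mty, mx = mmx, my = mmy)
  ce <- t(vapply(split(tmtab, tmtab$pid), function(d) {
    d <- d[order(d$target_id), ]
    protocol <- if (nrow(d) == 9L) "9-target" else "4-target"
    xs <- sort(unique(d$tx)); ys <- sort(unique(d$ty))
    left <- d$tx == xs[1]; right <- d$tx == xs[length(xs)]
    bottom <- d$ty == ys[1]; top <- d$ty == ys[length(ys)]
    rngx <- abs(mean(d$tx[right]) - mean(d$tx[left]))
    rngy <- abs(mean(d$ty[top]) - mean(d$ty[bottom]))
    if (rngx <= 0 || rngy <= 0) stop("degenerate protocol: zero passive target range",
                                     call. = FALSE)
    b <- match(border_order(protocol), d$target_id)
    c(abs(mean(d$mx[right]) - mean(d$mx[left])) / rngx,
      abs(mean(d$my[top]) - mean(d$my[bottom])) / rngy,
      shoelace_area(d$mx[b], d$my[b]) / shoelace_area(d$tx[b], d$ty[b]))
  }, numeric(3)))

  out <- data.frame(participant_id = levels(pid),
                    var_x = var_x, var_y = var_y,
                    var_xy = sqrt(var_x^2 + var_y^2),
                    ce_x = ce[, 1], ce_y = ce[, 2], ce_xy = ce[, 3],
                    shift_x = shift_x, shift_y = shift_y,
                    shift_xy = sqrt(shift_x^2 + shift_y^2),
                    ae_x = ae_x, ae_y = ae_y,
                    ae_xy = sqrt(ae_x^2 + ae_y^2))
  rownames(out) <- NULL
  if (!is.null(meta)) {
    missing <- setdiff(meta$participant_id, out$participant_id)
    if (length(missing)) {
      stop(sprintf("no trials for participants: %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    out <- out[match(meta$participant_id, out$participant_id), ]
    rownames(out) <- NULL
  }
  out
}
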