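## Independent, deliberately naive oracles used to cross-check the
## vectorised implementations.  Everything here is straight-line code
## with explicit loops; keep it that way.

## naive recomputation of the 12 parameters from raw trials
naive_parameter_vector <- function(trials) {
  mx <- -trials$active_x
  my <- trials$active_y
  tx <- trials$target_x
  ty <- trials$target_y
  tids <- sort(unique(trials$target_id))

  sds_x <- c(); sds_y <- c()
  mean_ex <- c(); mean_ey <- c()
  mmx <- c(); mmy <- c(); mtx <- c(); mty <- c()
  for (tid in tids) {
    i <- trials$target_id == tid
    sds_x <- c(sds_x, sd(mx[i]))
    sds_y <- c(sds_y, sd(my[i]))
    mean_ex <- c(mean_ex, mean(mx[i] - tx[i]))
    mean_ey <- c(mean_ey, mean(my[i] - ty[i]))
    mmx <- c(mmx, mean(mx[i])); mmy <- c(mmy, mean(my[i]))
    mtx <- c(mtx, mean(tx[i])); mty <- c(mty, mean(ty[i]))
  }
  var_x <- mean(sds_x); var_y <- mean(sds_y)
  shift_x <- mean(mean_ex); shift_y <- mean(mean_ey)
  ae_x <- mean(abs(mx - tx)); ae_y <- mean(abs(my - ty))

  xs <- sort(unique(mtx)); ys <- sort(unique(mty))
  left <- mtx == min(xs); right <- mtx == max(xs)
  bot <- mty == min(ys); top <- mty == max(ys)
  ce_x <- abs(mean(mmx[right]) - mean(mmx[left])) /
    abs(mean(mtx[right]) - mean(mtx[left]))
  ce_y <- abs(mean(mmy[top]) - mean(mmy[bot])) /
    abs(mean(mty[top]) - mean(mty[bot]))

  ## border polygon by angle about the target centroid
  border <- !(abs(mtx - mean(xs)) < 1e-9 & abs(mty - mean(ys)) < 1e-9)
  ang <- atan2(mty[border] - mean(mty), mtx[border] - mean(mtx))
  ord <- order(ang)
  poly_area <- function(x, y) {
    n <- length(x); a <- 0
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      a <- a + x[i] * y[j] - x[j] * y[i]
    }
    abs(a) / 2
  }
  ce_xy <- poly_area(mmx[border][ord], mmy[border][ord]) /
    poly_area(mtx[border][ord], mty[border][ord])

  c(var_x = var_x, var_y = var_y, var_xy = sqrt(var_x^2 + var_y^2),
    ce_x = ce_x, ce_y = ce_y, ce_xy = ce_xy,
    shift_x = shift_x, shift_y = shift_y,
    shift_xy = sqrt(shift_x^2 + shift_y^2),
    ae_x = ae_x, ae_y = ae_y, ae_xy = sqrt(ae_x^2 + ae_y^2))
}

## literal complementary-error-function route for the zeta transform
oracle_erfc <- function(x) 2 * pnorm(-x * sqrt(2))
oracle_erfcinv <- function(y) {
  uniroot(function(x) oracle_erfc(x) - y, c(-40, 40), tol = 1e-12)$root
}
oracle_zeta <- function(z, sign = "plus") {
  s <- if (sign == "plus") 1 else -1
  sqrt(2) * oracle_erfcinv(0.5 * oracle_erfc(s * z / sqrt(2)))
}

inv_boxcox <- function(t, lambda, offset = 0) {
  x <- if (abs(lambda) < 1e-12) exp(t) else (lambda * t + 1)^(1 / lambda)
  x - offset
}

## small helper: one-session metadata for trial generation
session_meta <- function(protocol = "9-target", passive_arm = "left",
                         id = "P001") {
  list(participant_id = id, protocol = protocol, passive_arm = passive_arm)
}

perfect_traits <- function() {
  list(sigma_x = 0, sigma_y = 0, ce_x = 1, ce_y = 1, shift_x = 0, shift_y = 0)
}

## a fully noise-controlled cohort configuration (no covariate effects)
flat_config <- function(n_control = 200L, n_stroke = 0L, sigma = c(1, 1),
                        control = list(), stroke = list()) {
  base <- list(sigma_base = c(x = sigma[1], y = sigma[2]),
               sigma_log_sd = 0, sigma_age_slope = 0,
               sigma_male_mult = 1, sigma_left_mult = 1,
               sigma_endpoint_mult = 1,
               ce_log_sd = c(x = 0, y = 0), ce_age_slope = 0,
               shift_mean = c(x = 0, y = 0), shift_sd = c(x = 0, y = 0))
  base[names(control)] <- control
  cohort_config(n_control = n_control, n_stroke = n_stroke,
                control = base, stroke = stroke)
}

## z-score table of iid standard normal draws
normal_z <- function(n, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n * 12), n, 12,
              dimnames = list(NULL, apm_parameter_names()))
  as.data.frame(m)
}
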