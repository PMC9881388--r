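test_that("Box-Cox fit normalises skewed data and matches the profile oracle", {
  set.seed(42)
  x <- rnorm(5000, 10, 1)
  bc <- fit_boxcox(x)
  tx <- boxcox_apply(x + bc$offset, bc$lambda)
  expect_lt(abs(check_distribution(tx)$skew_stat), 0.2)

  y <- exp(rnorm(5000, 1, 0.6))   # log-normal
  bcy <- fit_boxcox(y)
  ty <- boxcox_apply(y + bcy$offset, bcy$lambda)
  expect_lte(abs(check_distribution(ty)$skew_stat), 0.8)
  expect_lt(abs(bcy$lambda), 0.1)  # near the log transform

  ## independent profile-likelihood oracle (MASS grid search)
  skip_if_not_installed("MASS")
  prof <- MASS::boxcox(y ~ 1, lambda = seq(-1, 1, 0.005), plotit = FALSE)
  expect_lt(abs(bcy$lambda - prof$x[which.max(prof$y)]), 0.02)

  expect_error(fit_boxcox(rep(2, 100)), "constant")
})

test_that("lambda = 1 is an affine identity and is preferred on ties", {
  x <- c(1.5, 2, 4, 8)
  expect_equal(boxcox_apply(x, 1), x - 1)
  expect_equal(boxcox_apply(x, 0), log(x))
  ## exactly normal data: profile is maximised arbitrarily close to
  ## affine; the tie-break picks lambda = 1 when indistinguishable
  set.seed(1)
  z <- rnorm(2000, 50, 1)  # tiny CV: profile nearly flat
  bc <- fit_boxcox(z)
  tx <- boxcox_apply(z + bc$offset, bc$lambda)
  expect_gt(cor(tx, z), 0.9999)
})

test_that("moment diagnostics match closed forms", {
  set.seed(3)
  g <- rnorm(1e5)
  d <- check_distribution(g)
  expect_lt(abs(d$skew_stat), 0.05)
  expect_lt(abs(d$kurtosis_stat - 3), 0.1)
  expect_true(d$valid)

  two_point <- rep(c(-1, 1), 50)
  d2 <- check_distribution(two_point)
  expect_equal(d2$skew_stat, 0)
  expect_equal(d2$kurtosis_stat, 1)
  expect_false(d2$valid)

  ex <- rexp(2e5)
  d3 <- check_distribution(ex)
  expect_equal(d3$skew_stat, 2, tolerance = 0.1)
  expect_false(d3$valid)

  expect_error(check_distribution(c(1, 1, 1, 1)), "variance")
  expect_error(check_distribution(c(1, 2, 3)), "at least 4")
})

test_that("zero covariate effects yield negligible fitted slopes", {
  co <- generate_cohort(flat_config(n_control = 2000,
                                    control = list(sigma_log_sd = 0.25,
                                                   shift_sd = c(x = 1, y = 1))),
                        seed = 31)
  p <- compute_parameters(co$trials, co$participants)
  nm <- fit_normative(p, co$participants)
  ## compare with an lm oracle on the same transformed response
  m <- nm$models$var_y
  tx <- boxcox_apply(p$var_y + m$boxcox_offset, m$boxcox_lambda)
  X <- propriokit:::normative_design(co$participants)
  ofit <- lm(tx ~ X - 1)
  expect_equal(unname(m$mean_coeffs), unname(coef(ofit)), tolerance = 1e-8)
  se <- summary(ofit)$coefficients[, "Std. Error"]
  expect_lt(abs(m$mean_coeffs[["age"]]), 2 * se[["Xage"]])
  expect_lt(abs(m$mean_coeffs[["sexM"]]), 2 * se[["XsexM"]])
})

test_that("an injected age effect on variability is recovered", {
  co <- generate_cohort(
    flat_config(n_control = 5000,
                control = list(sigma_log_sd = 0.2,
                               sigma_age_slope = 0.008,
                               shift_sd = c(x = 1, y = 1))),
    seed = 32)
  p <- compute_parameters(co$trials, co$participants)
  nm <- fit_normative(p, co$participants)
  m <- nm$models$var_y
  ## model-implied median var_y ratio between ages 70 and 30 vs the
  ## generative ratio exp(0.008 * 40); lambda-free comparison
  mu_at <- function(age) {
    X <- propriokit:::normative_design(
      data.frame(age = age, sex = "F", handedness = "R",
                 platform = "exoskeleton"))
    as.vector(X[, nm$terms] %*% m$mean_coeffs)
  }
  ratio <- inv_boxcox(mu_at(70), m$boxcox_lambda, m$boxcox_offset) /
    inv_boxcox(mu_at(30), m$boxcox_lambda, m$boxcox_offset)
  expect_equal(log(ratio), 0.008 * 40, tolerance = 0.1)
})

test_that("z-scores are zero at the predicted mean and unit at mean + SD", {
  co <- generate_cohort(cohort_config(n_control = 400, n_stroke = 0), seed = 33)
  p <- compute_parameters(co$trials, co$participants)
  nm <- fit_normative(p, co$participants)
  meta1 <- co$participants[5, ]
  X <- propriokit:::normative_design(meta1)[, nm$terms, drop = FALSE]
  p1 <- p[5, ]
  for (pname in c("var_y", "ce_x", "shift_x")) {
    m <- nm$models[[pname]]
    mu <- as.vector(X %*% m$mean_coeffs)
    s <- max(as.vector(X %*% m$sd_coeffs), m$sd_floor)
    p_at <- p1
    p_at[[pname]] <- inv_boxcox(mu, m$boxcox_lambda, m$boxcox_offset)
    z <- suppressWarnings(predict(nm, p_at, meta1))
    expect_equal(z[[pname]], 0, tolerance = 1e-8)
    ## one modelled SD above the mean (in transformed space) maps to z = 1
    p_at[[pname]] <- inv_boxcox(mu + s, m$boxcox_lambda, m$boxcox_offset)
    z1 <- suppressWarnings(predict(nm, p_at, meta1))
    expect_equal(z1[[pname]], 1, tolerance = 1e-8)
  }
})

test_that("z is strictly increasing in the raw parameter value", {
  co <- generate_cohort(cohort_config(n_control = 200, n_stroke = 0), seed = 34)
  p <- compute_parameters(co$trials, co$participants)
  nm <- fit_normative(p, co$participants)
  meta1 <- co$participants[1, ]
  vals <- seq(0.3, 4, length.out = 15)
  z <- vapply(vals, function(v) {
    pp <- p[1, ]; pp$var_x <- v
    suppressWarnings(predict(nm, pp, meta1))$var_x
  }, 1)
  expect_true(all(diff(z) > 0))
})

test_that("refitting on reconstructed values is a fixed point", {
  co <- generate_cohort(cohort_config(n_control = 300, n_stroke = 0), seed = 35)
  p <- compute_parameters(co$trials, co$participants)
  nm <- fit_normative(p, co$participants)
  z <- predict(nm, p, co$participants)
  ## invert the chain back to raw values, then refit
  X <- propriokit:::normative_design(co$participants)[, nm$terms, drop = FALSE]
  p2 <- p
  for (pname in apm_parameter_names()) {
    m <- nm$models[[pname]]
    mu <- as.vector(X %*% m$mean_coeffs)
    s <- pmax(as.vector(X %*% m$sd_coeffs), m$sd_floor)
    p2[[pname]] <- inv_boxcox(mu + z[[pname]] * s, m$boxcox_lambda,
                              m$boxcox_offset)
  }
  expect_equal(p2[, apm_parameter_names()], p[, apm_parameter_names()],
               tolerance = 1e-6)
  nm2 <- fit_normative(p2, co$participants)
  expect_equal(coef(nm2), coef(nm), tolerance = 1e-6)
})

test_that("degenerate designs fail loudly, absent levels are dropped quietly", {
  co <- generate_cohort(cohort_config(n_control = 120, n_stroke = 0), seed = 36)
  p <- compute_parameters(co$trials, co$participants)
  meta <- co$participants
  ## absent handedness level: dropped with a warning, model still fits
  meta$handedness <- "R"
  meta$platform <- "exoskeleton"
  expect_warning(nm <- fit_normative(p, meta), "dropping empty design terms")
  expect_false("handL" %in% nm$terms)
  ## genuine collinearity: handedness L coincides with endpoint platform
  meta2 <- co$participants
  meta2$handedness <- ifelse(meta2$platform == "endpoint", "L", "R")
  expect_error(suppressWarnings(fit_normative(p, meta2)), "collinear")
})

test_that("out-of-support values are clamped with a warning", {
  co <- generate_cohort(cohort_config(n_control = 200, n_stroke = 0), seed = 37)
  p <- compute_parameters(co$trials, co$participants)
  nm <- fit_normative(p, co$participants)
  bad <- p[1, ]
  bad$shift_x <- min(p$shift_x) - 50    # far outside the training support
  expect_warning(z <- predict(nm, bad, co$participants[1, ]), "clamped")
  expect_true(is.finite(z$shift_x) && z$shift_x < -2)
})
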