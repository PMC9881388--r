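random_session <- function(seed, protocol = "9-target") {
  set.seed(seed)
  traits <- list(sigma_x = runif(1, 0.3, 3), sigma_y = runif(1, 0.3, 3),
                 ce_x = runif(1, 0.5, 1.4), ce_y = runif(1, 0.5, 1.4),
                 shift_x = rnorm(1, 0, 3), shift_y = rnorm(1, 0, 3))
  arm <- sample(c("left", "right"), 1)
  generate_participant_trials(session_meta(protocol, arm), traits,
                              seed = seed + 1)
}

test_that("mirroring reflects about the midline and is an involution", {
  tr <- random_session(1)
  m <- mirror_active_positions(tr)
  expect_equal(m$matched_x, -tr$active_x)
  expect_equal(m$matched_y, tr$active_y)
  expect_equal(-m$matched_x, tr$active_x)  # double mirror = identity
  ## perfect matcher: mirrored positions equal targets
  mp <- mirror_active_positions(
    generate_participant_trials(session_meta(), perfect_traits(), seed = 2))
  expect_equal(mp$matched_x, mp$target_x)
  expect_equal(mp$matched_y, mp$target_y)
})

test_that("incomplete trial sets are rejected with the absent pairs named", {
  tr <- random_session(3)
  expect_error(mirror_active_positions(tr[-c(1, 2), ]), "missing trials")
  dup <- rbind(tr, tr[1, ])
  expect_error(mirror_active_positions(dup), "duplicated")
  one_block <- tr[tr$block == 1, ]
  expect_error(compute_variability(
    transform(one_block, matched_x = -active_x, matched_y = active_y)),
    "at least 2 trials")
})

test_that("perfect matching yields zero errors and unit ratios", {
  tr <- generate_participant_trials(session_meta("4-target"), perfect_traits(),
                                    seed = 7)
  pv <- compute_parameter_vector(tr)
  expect_equal(unname(pv[c("var_x", "var_y", "var_xy")]), c(0, 0, 0))
  expect_equal(unname(pv[c("ce_x", "ce_y", "ce_xy")]), c(1, 1, 1))
  expect_equal(unname(pv[c("shift_x", "shift_y", "shift_xy")]), c(0, 0, 0))
  expect_equal(unname(pv[c("ae_x", "ae_y", "ae_xy")]), c(0, 0, 0))
})

test_that("noise-free gains scale the ratios; area scales as the product", {
  tr <- generate_participant_trials(
    session_meta(), list(sigma_x = 0, sigma_y = 0, ce_x = 0.5, ce_y = 1,
                         shift_x = 0, shift_y = 0), seed = 8)
  m <- mirror_active_positions(tr)
  ce <- compute_contraction_expansion(m)
  expect_equal(unname(ce), c(0.5, 1, 0.5))
  ## gains (0.8, 0.7): border polygon area ratio = 0.8 * 0.7
  tr2 <- generate_participant_trials(
    session_meta(), list(sigma_x = 0, sigma_y = 0, ce_x = 0.8, ce_y = 0.7,
                         shift_x = 0, shift_y = 0), seed = 8)
  ce2 <- compute_contraction_expansion(mirror_active_positions(tr2))
  expect_equal(unname(ce2[["ce_xy"]]), 0.56, tolerance = 1e-12)
  ## centroid-preserving gain leaves the mean error zero
  sh <- compute_shift(mirror_active_positions(tr2))
  expect_equal(unname(sh), c(0, 0, 0))
})

test_that("constant offsets propagate to shift and absolute error", {
  ## matched position = target + (3, -4) on every trial
  tr <- generate_participant_trials(session_meta(), perfect_traits(), seed = 9)
  tr$active_x <- -(tr$target_x + 3)   # mirrored x = target_x + 3
  tr$active_y <- tr$target_y - 4
  m <- mirror_active_positions(tr)
  expect_equal(unname(compute_shift(m)), c(3, -4, 5))
  expect_equal(unname(compute_absolute_error(m)), c(3, 4, 5))
  ## x-only 5 cm offset
  tr$active_x <- -(tr$target_x + 5); tr$active_y <- tr$target_y
  expect_equal(unname(compute_absolute_error(mirror_active_positions(tr))),
               c(5, 0, 5))
})

test_that("resultant identities and block permutation invariance hold", {
  for (s in 1:5) {
    tr <- random_session(s * 13, protocol = if (s %% 2) "9-target" else "4-target")
    pv <- compute_parameter_vector(tr)
    expect_equal(pv[["var_xy"]], sqrt(pv[["var_x"]]^2 + pv[["var_y"]]^2),
                 tolerance = 1e-9)
    expect_equal(pv[["shift_xy"]], sqrt(pv[["shift_x"]]^2 + pv[["shift_y"]]^2),
                 tolerance = 1e-9)
    expect_equal(pv[["ae_xy"]], sqrt(pv[["ae_x"]]^2 + pv[["ae_y"]]^2),
                 tolerance = 1e-9)
    ## |shift| <= ae componentwise (balanced design)
    expect_lte(abs(pv[["shift_x"]]), pv[["ae_x"]] + 1e-12)
    ## permuting block labels changes nothing
    perm <- tr
    perm$block <- c(3L, 1L, 6L, 2L, 5L, 4L)[perm$block]
    perm <- perm[order(perm$block), ]
    expect_equal(compute_parameter_vector(perm), pv)
  }
})

test_that("translation of active positions moves shift and not variability", {
  tr <- random_session(77)
  pv <- compute_parameter_vector(tr)
  tr2 <- tr
  tr2$active_x <- tr$active_x + 2.5   # mirrored x shifts by -2.5
  tr2$active_y <- tr$active_y - 1.5
  pv2 <- compute_parameter_vector(tr2)
  expect_equal(pv2[["shift_x"]], pv[["shift_x"]] - 2.5)
  expect_equal(pv2[["shift_y"]], pv[["shift_y"]] - 1.5)
  expect_equal(pv2[c("var_x", "var_y", "var_xy")],
               pv[c("var_x", "var_y", "var_xy")])
  expect_equal(pv2[c("ce_x", "ce_y", "ce_xy")], pv[c("ce_x", "ce_y", "ce_xy")])
})

test_that("vectorised computation equals the naive oracle", {
  for (s in c(2, 31, 54)) {
    tr <- random_session(s, protocol = if (s %% 2) "9-target" else "4-target")
    expect_equal(compute_parameter_vector(tr), naive_parameter_vector(tr),
                 tolerance = 1e-9)
  }
  ## and the cohort-level table agrees with the per-session path
  co <- generate_cohort(cohort_config(n_control = 15, n_stroke = 10), seed = 5)
  tab <- compute_parameters(co$trials, co$participants)
  i <- 11
  pid <- tab$participant_id[i]
  pv <- compute_parameter_vector(co$trials[co$trials$participant_id == pid, ])
  expect_equal(unlist(tab[i, apm_parameter_names()]),
               pv[apm_parameter_names()], tolerance = 1e-9,
               ignore_attr = TRUE)
})
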