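test_that("the Gaussian NLL matches its closed forms", {
  d <- laisk_fixture("full")[1:9, ]
  p <- attr(laisk_fixture("full"), "params")
  d <- dplyr::mutate(d, a_net = fvcb_anet(cc, light, p))  # zero residuals
  expect_equal(laisk_nll(d, p, sigma = 0.07),
               9 / 2 * log(2 * pi * 0.07^2), tolerance = 1e-10)
  # doubling all residuals quadruples the SSE term
  d1 <- dplyr::mutate(d, a_net = a_net + 0.1)
  d2 <- dplyr::mutate(d, a_net = a_net + 0.2)
  base <- laisk_nll(d, p, sigma = 0.07)
  expect_equal(laisk_nll(d2, p, sigma = 0.07) - base,
               4 * (laisk_nll(d1, p, sigma = 0.07) - base), tolerance = 1e-9)
  # non-finite predictions are penalised, never NaN
  bad <- update(p, gamma_star = 1e6)
  expect_true(is.finite(laisk_nll(d, bad)))
})

test_that("NLL is invariant to observation order", {
  set.seed(71)
  d <- laisk_fixture("full", noise_sd = 0.07)
  p <- attr(d, "params")
  shuffled <- d[sample(nrow(d)), ]
  expect_lt(abs(laisk_nll(d, p) - laisk_nll(shuffled, p)), 1e-12)
})

test_that("profiled and fixed-sigma objectives share an argmin", {
  set.seed(72)
  d <- laisk_fixture("full", noise_sd = 0.07)
  set.seed(73)
  f_prof <- fit_laisk_fvcb(d, sigma = NULL)
  set.seed(73)
  f_fix <- fit_laisk_fvcb(d, sigma = 0.07)
  expect_equal(f_prof$gamma_star, f_fix$gamma_star, tolerance = 1e-4)
  expect_equal(f_prof$d_l, f_fix$d_l, tolerance = 1e-4)
})

test_that("noise-free fits recover the generating parameters", {
  d <- laisk_fixture("full")
  fit <- fit_laisk_fvcb(d)
  expect_true(fit$converged)
  expect_equal(fit$gamma_star, 1.67, tolerance = 1e-4)
  expect_equal(fit$d_l, 1.0, tolerance = 1e-4)
  expect_lt(fit$rmse, 1e-6)
})

test_that("noise-free recovery holds across random true values", {
  set.seed(81)
  worst <- 0
  for (k in 1:50) {
    gs <- runif(1, 1, 8); dl <- runif(1, 0.3, 2)
    p <- update(six_degree_params(), gamma_star = gs, d_l = dl,
                vcmax = runif(1, 30, 80), jmax = runif(1, 40, 90))
    d <- laisk_fixture("full", params = p)
    fit <- fit_laisk_fvcb(d, params = six_degree_params(), n_restarts = 2)
    worst <- max(worst, abs(fit$gamma_star - gs) / gs, abs(fit$d_l - dl) / dl)
  }
  expect_lt(worst, 1e-3)
})

test_that("fitted curves share the intersection (gamma_star, -d_l)", {
  set.seed(91)
  d <- laisk_fixture("full", noise_sd = 0.07)
  fit <- fit_laisk_fvcb(d)
  xing <- predicted_intersection(fit)
  expect_equal(xing$height, -fit$d_l)
  a <- fvcb_anet(rep(fit$gamma_star, 3), c(300, 150, 80), fit$estimate)
  expect_true(all(abs(a + fit$d_l) < 1e-10))
})

test_that("under-determined designs are rejected", {
  one_light <- laisk_fixture("full", lights = 300)
  expect_error(fit_laisk_fvcb(one_light), "single light")
  tiny <- laisk_fixture("full", lights = c(300, 150))[c(1, 2, 10, 11), ]
  expect_error(fit_laisk_fvcb(tiny), "fewer observations")
})

test_that("vcmax is flagged unidentified on purely RuBP-limited data", {
  # e = 0: with the exact minimum, vcmax has no leverage anywhere on the
  # RuBP-limited branch (a positive e weakly identifies it via the
  # co-limitation sag)
  p0 <- update(six_degree_params(), e_smooth = 0)
  d <- laisk_fixture("full", params = p0)
  fit <- fit_laisk_fvcb(d, params = p0)
  expect_true(fit$vcmax_unidentified)
  expect_false(is.na(fit$gamma_star))
})

test_that("the estimator is consistent under measurement noise", {
  base <- laisk_fixture("wide_include")
  mc <- laisk_mc(base, n_reps = 1000, sigma = 0.07, estimators = "fvcb", seed = 7)
  s <- tidy(mc)
  se_gamma <- s$sd_gamma / sqrt(s$n_valid)
  expect_lt(abs(s$mean_gamma - 1.67), 3 * se_gamma)
})

test_that("the intercellular basis with finite gm goes through the flux balance", {
  p <- update(six_degree_params(), gm = 2)
  cc <- seq(1.6, 9.2, by = 1.2)
  d <- simulate_anet(c(300, 150, 80), cc, p)
  # convert the generated cc grid to the ci scale: ci = cc + a/gm
  d_ci <- tibble::tibble(light = d$light, ci = d$cc + d$a_net / 2, a_net = d$a_net)
  d_ci <- d_ci[d_ci$ci > 0, ]
  fit <- fit_laisk_fvcb(d_ci, params = p, basis = "ci", n_restarts = 1)
  expect_equal(fit$gamma_star, p$gamma_star, tolerance = 1e-3)
  expect_equal(fit$d_l, p$d_l, tolerance = 1e-3)
})
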