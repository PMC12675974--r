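make_lines_data <- function(lines, cc = 1:3) {
  # lines: named list light -> c(slope, intercept); points exactly on lines
  purrr::map_dfr(names(lines), function(l) {
    tibble::tibble(light = as.numeric(l), cc = cc,
                   a_net = lines[[l]][1] * cc + lines[[l]][2])
  })
}

test_that("per-light OLS lines reproduce closed-form fits", {
  d <- tibble::tibble(light = rep(c(100, 50), each = 3), cc = rep(1:3, 2),
                      a_net = c(1, 2, 3, 1, 1.9, 3.1))
  fit <- fit_laisk_linear(d)
  lines <- tidy(fit, "lines")
  expect_equal(lines$slope[lines$light == 100], 1)
  expect_equal(lines$intercept[lines$light == 100], 0)
  expect_equal(lines$slope[lines$light == 50], 1.05)
  expect_equal(lines$intercept[lines$light == 50], -0.1)
  # flat line through zero
  d0 <- tibble::tibble(light = rep(c(2, 1), each = 2), cc = c(1, 3, 1, 2),
                       a_net = c(0, 0, 1, 2))
  l0 <- tidy(fit_laisk_linear(d0), "lines")
  expect_equal(l0$slope[l0$light == 2], 0)
})

test_that("degenerate designs error", {
  one_light <- tibble::tibble(light = 100, cc = 1:3, a_net = 1:3)
  expect_error(fit_laisk_linear(one_light), "two light")
  same_cc <- tibble::tibble(light = rep(c(1, 2), each = 2), cc = rep(2, 4),
                            a_net = c(1, 2, 3, 4))
  expect_error(fit_laisk_linear(same_cc), "identical")
})

test_that("line intersections solve the 2x2 system", {
  x <- line_intersection(2, -2, 1, -1)
  expect_equal(x$gamma, 1); expect_equal(x$height, 0)
  x <- line_intersection(1, -2, 3, -4)
  expect_equal(x$gamma, 1); expect_equal(x$height, -1)
  expect_true(line_intersection(1, 0, 1, 5)$excluded)
})

test_that("intersection coordinates satisfy both line equations", {
  set.seed(52)
  for (k in 1:200) {
    m <- runif(2, -3, 3); b <- runif(2, -3, 3)
    x <- line_intersection(m[1], b[1], m[2], b[2])
    if (x$excluded) next
    expect_lt(abs(m[1] * x$gamma + b[1] - x$height), 1e-10)
    expect_lt(abs(m[2] * x$gamma + b[2] - x$height), 1e-10)
  }
})

test_that("lines through a common point give zero dispersion", {
  d <- make_lines_data(list(`300` = c(2, -2), `150` = c(1, -1), `80` = c(0.5, -0.5)))
  fit <- fit_laisk_linear(d)
  expect_equal(fit$gamma_star, 1, tolerance = 1e-10)
  expect_equal(fit$height, 0, tolerance = 1e-10)
  expect_equal(fit$gamma_sd, 0, tolerance = 1e-10)
  expect_equal(fit$n_pairs, 3L)
})

test_that("near-parallel pairs are excluded with a warning, not fatal", {
  d <- make_lines_data(list(`300` = c(2, 1), `150` = c(2, 3), `80` = c(1, 0)))
  expect_warning(fit <- fit_laisk_linear(d), "near-parallel")
  expect_equal(fit$n_pairs, 2L)
  expect_equal(sum(tidy(fit)$excluded), 1L)
})

test_that("the estimate is invariant to curve ordering", {
  d <- laisk_fixture("wide_include")
  f1 <- fit_laisk_linear(d)
  f2 <- fit_laisk_linear(d[rev(seq_len(nrow(d))), ])
  expect_equal(f1$gamma_star, f2$gamma_star, tolerance = 1e-12)
  expect_equal(f1$d_l, f2$d_l, tolerance = 1e-12)
})

test_that("RuBP-limitation lemma: intersections coincide at (-a/b, -d_l)", {
  set.seed(62)
  for (k in 1:20) {
    gs <- runif(1, 0.8, 4); dl <- runif(1, 0.3, 2)
    p <- rubp_params(gamma_star = gs, d_l = dl)
    cc <- sort(runif(5, gs + 0.5, gs + 9))
    d <- simulate_anet(c(300, 150, 80), cc, p)
    # confirm strict Wj limitation of the generator
    expect_true(all(wj_rate(d$cc, d$light, p) < wc_rate(d$cc, p)))
    fit <- fit_laisk_linear(d)
    xs <- tidy(fit)
    # all pairwise intersections identical
    expect_lt(max(xs$gamma_star) - min(xs$gamma_star), 1e-8)
    expect_lt(max(xs$height) - min(xs$height), 1e-8)
    # brute-force oracle: OLS of g(c) = (c - gs) / (4 (c + 2 gs))
    g <- (cc - gs) / (4 * (cc + 2 * gs))
    ab <- coef(lm(g ~ cc))
    expect_equal(fit$gamma_star, -ab[[1]] / ab[[2]], tolerance = 1e-8)
    expect_equal(fit$height, -dl, tolerance = 1e-8)
    expect_equal(fit$d_l, dl, tolerance = 1e-8)
  }
})

test_that("implausible negative d_l is flagged", {
  # lines crossing above zero: positive intersection height
  d <- make_lines_data(list(`300` = c(2, 1), `150` = c(1, 2)))
  fit <- fit_laisk_linear(d)
  expect_lt(fit$d_l, 0)
  expect_true(glance(fit)$implausible_dl)
})
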