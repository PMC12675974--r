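test_that("electron transport solves the light-response quadratic", {
  p <- toy_params(jmax = 100, alpha = 0.3, theta = 0.9)
  expect_identical(electron_transport(0, p), 0)
  # frozen from the polyroot oracle on 0.9 J^2 - 130 J + 3000
  j <- electron_transport(100, p)
  expect_equal(j, 28.831946245, tolerance = 1e-9)
  # the root satisfies the quadratic it came from
  expect_lt(abs(0.9 * j^2 - (0.3 * 100 + 100) * j + 0.3 * 100 * 100), 1e-8)
  # theta -> 0 limit: alpha I Jmax / (alpha I + Jmax)
  p0 <- update(p, theta = 1e-8)
  expect_equal(electron_transport(100, p0), 23.0769230769, tolerance = 1e-6)
})

test_that("electron transport is bounded and monotone in light", {
  set.seed(11)
  for (k in 1:50) {
    p <- random_params()
    light <- sort(runif(20, 0, 2000))
    j <- electron_transport(light, p)
    expect_true(all(j <= pmin(p$alpha * light, p$jmax) + 1e-9))
    expect_true(all(diff(j) >= -1e-9))
  }
})

test_that("effective Km handles oxygen inhibition", {
  expect_equal(effective_km(toy_params(o2 = 0)), 40)
  expect_equal(effective_km(toy_params(kc = 40, ko = 24800, o2 = 21000)),
               73.8709677419, tolerance = 1e-9)
  expect_equal(effective_km(toy_params(ko = 1e12)), 40, tolerance = 1e-6)
})

test_that("apparent vcmax follows the activation Michaelis term", {
  p <- toy_params(vcmax = 50)
  expect_equal(apparent_vcmax(c(1, 5, 30), p), c(50, 50, 50))  # ka = 0
  p1 <- update(p, ka = 2)
  expect_equal(apparent_vcmax(2, p1), 25)  # half saturation at cc = ka
  expect_equal(apparent_vcmax(5, update(p, ka = 1)), 41.6666666667, tolerance = 1e-9)
})

test_that("Rubisco-limited rate saturates at vcmax", {
  p <- toy_params(vcmax = 50, kc = 40, ko = 24800, o2 = 21000)
  km <- effective_km(p)
  expect_equal(wc_rate(km, p), 25)          # half saturation at Km
  expect_equal(wc_rate(1e9, p), 50, tolerance = 1e-5)
  expect_equal(wc_rate(5, p), 3.16973415133, tolerance = 1e-9)
})

test_that("RuBP-limited rate has the electron-transport stoichiometry", {
  p <- toy_params(jmax = 100, alpha = 0.3, theta = 0.9, gamma_star = 1.67)
  j <- electron_transport(100, p)
  expect_equal(wj_rate(2 * 1.67, 100, p), j / 8, tolerance = 1e-12)
  expect_equal(wj_rate(1e9, 100, p), j / 4, tolerance = 1e-5)
  expect_equal(wj_rate(5, 100, p), 4.32133486885, tolerance = 1e-8)
})

test_that("co-limitation with e = 0 is the exact minimum", {
  expect_identical(colimit_vc(3, 5, 0), 3)
  expect_identical(colimit_vc(4, 4, 0), 4)
  set.seed(21)
  wc <- runif(200, 0, 30); wj <- runif(200, 0, 30)
  expect_equal(colimit_vc(wc, wj, 0), pmin(wc, wj), tolerance = 1e-12)
})

test_that("co-limitation root matches the quadratic and decreases with e", {
  # frozen from the polyroot oracle on Vc^2 - 8.5 Vc + 15
  expect_equal(colimit_vc(3, 5, 0.5), 2.5, tolerance = 1e-12)
  vc <- colimit_vc(3, 5, 0.5)
  expect_lt(abs(vc^2 - vc * 8.5 + 15), 1e-10)
  e_grid <- seq(0, 2, by = 0.1)
  vals <- colimit_vc(3, 5, e_grid)
  expect_true(all(diff(vals) <= 1e-12))
  expect_true(all(vals <= pmin(3, 5) + 1e-12) && all(vals >= 0))
})

test_that("net assimilation composes the sub-rates", {
  p <- toy_params()
  expect_equal(fvcb_anet(5, 100, p), 1.11104294479, tolerance = 1e-9)
  expect_error(fvcb_anet(0, 100, p), "cc")
  expect_error(fvcb_anet(-1, 100, p), "cc")
})

test_that("every curve passes through (gamma_star, -d_l)", {
  set.seed(31)
  for (k in 1:1000) {
    p <- random_params()
    light <- runif(1, 20, 1500)
    expect_equal(fvcb_anet(p$gamma_star, light, p), -p$d_l, tolerance = 1e-12)
  }
})

test_that("net assimilation increases with cc above the compensation region", {
  set.seed(41)
  for (k in 1:25) {
    p <- update(random_params(), ka = 0)
    cc <- seq(p$gamma_star / 2 + 1e-6, 50, length.out = 200)
    a <- fvcb_anet(cc, 400, p)
    expect_true(all(diff(a) > 0))
  }
})

test_that("cc_from_ci solves the mesophyll flux balance", {
  p <- toy_params()
  expect_identical(cc_from_ci(5, 100, p), 5)  # infinite gm
  p2 <- update(p, gm = 2)
  cc <- cc_from_ci(5, 100, p2)
  expect_lt(abs(fvcb_anet(cc, 100, p2) - 2 * (5 - cc)), 1e-10)
  # independent bisection oracle on a fine grid
  f <- function(x) fvcb_anet(x, 100, p2) - 2 * (5 - x)
  grid <- seq(1e-6, 15, length.out = 40001)
  fg <- f(grid)
  i <- which(fg[-1] * fg[-length(fg)] <= 0)[1]
  expect_lt(abs(cc - grid[i]), diff(grid)[1] * 2)
  expect_lt(cc, 5)  # positive flux means a drawdown
})

test_that("cc approaches ci monotonically as gm grows", {
  p <- toy_params()
  gms <- c(0.5, 1, 2, 5, 20, 100, 1e4)
  ccs <- vapply(gms, function(g) cc_from_ci(5, 100, update(p, gm = g)), numeric(1))
  expect_true(all(diff(ccs) > 0))
  expect_true(all(ccs <= 5))
  expect_equal(ccs[length(ccs)], 5, tolerance = 1e-3)
  # zero net flux means no gradient: at ci = gamma_star with d_l = 0
  p0 <- update(p, d_l = 0, gm = 2)
  expect_equal(cc_from_ci(p0$gamma_star, 100, p0), p0$gamma_star, tolerance = 1e-9)
})
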