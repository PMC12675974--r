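#' Intersection of two fitted regression lines
#'
#' Solves `m1 x + b1 = m2 x + b2` for the abscissa (the pairwise
#' `gamma_star` estimate) and the common ordinate (the intersection
#' height, whose negation is the pairwise `d_l` estimate). Near-parallel
#' lines carry no intersection information and are flagged instead of
#' producing a wild estimate.
#'
#' @param m1,b1,m2,b2 Slopes (flux Pa-1) and intercepts (flux).
#' @param parallel_tol Minimum slope difference below which the pair is
#'   excluded.
#' @return A list with `gamma` (Pa), `height` (flux) and `excluded`.
#' @examples
#' line_intersection(2, -2, 1, -1)  # both lines pass through (1, 0)
#' @export
line_intersection <- function(m1, b1, m2, b2, parallel_tol = 1e-8) {
  if (abs(m1 - m2) < parallel_tol) {
    return(list(gamma = NA_real_, height = NA_real_, excluded = TRUE))
  }
  gamma <- (b1 - b2) / (m2 - m1)
  list(gamma = gamma, height = m1 * gamma + b1, excluded = FALSE)
}

#' Classical linear-intersection Laisk estimator
#'
#' Fits an ordinary least-squares line of `a_net` on CO2 partial pressure
#' separately for each irradiance, computes every pairwise intersection,
#' and averages the intersection coordinates: the mean abscissa is the
#' `gamma_star` estimate and the negated mean height is the `d_l`
#' estimate. Pairs of near-parallel lines are excluded with a warning
#' (the degenerate case has no defined intersection).
#'
#' A negative `d_l` (lines crossing at positive assimilation) is
#' physiologically implausible but can and does occur when the measured
#' CO2 range excludes the expected compensation point; the estimate is
#' returned as-is and flagged.
#'
#' @param data A tibble with columns `light`, `a_net` and `cc` (or `ci`
#'   with `basis = "ci"`): at least two light levels with two or more
#'   distinct CO2 values each.
#' @param basis CO2 basis of the abscissa, `"cc"` (chloroplastic,
#'   default) or `"ci"` (intercellular; the estimate is then the apparent
#'   compensation point Ci*).
#' @param parallel_tol Slope-difference tolerance of
#'   [line_intersection()].
#' @return An object of class `laisk_linear` with elements `lines`
#'   (per-light OLS fits), `intersections` (one row per pair),
#'   `gamma_star`, `d_l`, `height`, dispersion SDs and `n_pairs`.
#'   Use [tidy()], [glance()], [autoplot()].
#' @examples
#' fit <- fit_laisk_linear(laisk_fixture("narrow_include"))
#' glance(fit)
#' @export
fit_laisk_linear <- function(data, basis = c("cc", "ci"), parallel_tol = 1e-8) {
  basis <- match.arg(basis)
  co2 <- laisk_co2(data, basis)
  d <- tibble(light = data$light, co2 = co2, a_net = data$a_net)
  if (length(unique(d$light)) < 2) abort("fit_laisk_linear: need at least two light levels")

  lines <- purrr::map_dfr(split(d, d$light), function(g) {
    if (length(unique(g$co2)) < 2) {
      abort(sprintf("fit_laisk_linear: all CO2 values identical at light %g", g$light[1]))
    }
    m <- lm(a_net ~ co2, data = g)
    sst <- sum((g$a_net - mean(g$a_net))^2)
    r2 <- if (sst > 0) 1 - sum(residuals(m)^2) / sst else 1
    tibble(light = g$light[1], slope = coef(m)[[2]], intercept = coef(m)[[1]],
           n_points = nrow(g), r2 = r2)
  }) %>%
    arrange(dplyr::desc(.data$light))

  prs <- combn(seq_len(nrow(lines)), 2)
  intersections <- purrr::map_dfr(seq_len(ncol(prs)), function(k) {
    i <- prs[1, k]; j <- prs[2, k]
    xing <- line_intersection(lines$slope[i], lines$intercept[i],
                              lines$slope[j], lines$intercept[j], parallel_tol)
    tibble(light_i = lines$light[i], light_j = lines$light[j],
           gamma_star = xing$gamma, height = xing$height,
           d_l = -xing$height, excluded = xing$excluded)
  })
  if (any(intersections$excluded)) {
    warn(sprintf("fit_laisk_linear: %d near-parallel line pair(s) excluded",
                 sum(intersections$excluded)))
  }
  kept <- intersections %>% filter(!.data$excluded)
  if (nrow(kept) < 1) abort("fit_laisk_linear: no usable line pairs (all near-parallel)")

  out <- list(
    lines = lines,
    intersections = intersections,
    gamma_star = mean(kept$gamma_star),
    height = mean(kept$height),
    d_l = -mean(kept$height),
    gamma_sd = sd(kept$gamma_star),
    dl_sd = sd(kept$height),
    n_pairs = nrow(kept),
    basis = basis,
    data = d
  )
  class(out) <- "laisk_linear"
  out
}

#' @export
print.laisk_linear <- function(x, ...) {
  cat("<laisk_linear> classical Laisk estimate\n")
  cat(sprintf("  gamma* = %.4g Pa, D_L = %.4g umol m-2 s-1 (%d pairs)\n",
              x$gamma_star, x$d_l, x$n_pairs))
  if (is.finite(x$d_l) && x$d_l < 0) {
    cat("  note: D_L < 0 is physiologically implausible\n")
  }
  invisible(x)
}

#' @describeIn fit_laisk_linear One row per pairwise intersection
#'   (`type = "intersections"`) or per fitted line (`type = "lines"`).
#' @param x,object A `laisk_linear` object.
#' @param type Which component to tidy.
#' @param ... Unused.
#' @export
tidy.laisk_linear <- function(x, type = c("intersections", "lines"), ...) {
  type <- match.arg(type)
  if (type == "lines") x$lines else x$intersections
}

#' @describeIn fit_laisk_linear One-row summary with the averaged
#'   estimates, their pairwise dispersion and an implausibility flag.
#' @export
glance.laisk_linear <- function(x, ...) {
  tibble(gamma_star = x$gamma_star, d_l = x$d_l,
         gamma_sd = x$gamma_sd, dl_sd = x$dl_sd,
         n_pairs = x$n_pairs, implausible_dl = x$d_l < 0)
}

#' @describeIn fit_laisk_linear Data, per-light regression lines and
#'   their pairwise intersections.
#' @export
autoplot.laisk_linear <- function(object, ...) {
  xlab <- if (object$basis == "cc") expression(C[c] ~ (Pa)) else expression(C[i] ~ (Pa))
  kept <- object$intersections %>% filter(!.data$excluded)
  ggplot(object$data, aes(x = .data$co2, y = .data$a_net,
                          colour = factor(.data$light))) +
    geom_point() +
    geom_abline(data = object$lines,
                aes(slope = .data$slope, intercept = .data$intercept,
                    colour = factor(.data$light))) +
    geom_point(data = kept, aes(x = .data$gamma_star, y = .data$height),
               inherit.aes = FALSE, shape = 8, size = 3) +
    labs(x = xlab, y = expression(A[net] ~ (mu * mol ~ m^-2 ~ s^-1)),
         colour = "light") +
    theme_minimal()
}
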