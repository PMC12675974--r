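#' Noise-free design curves for the bias simulations
#'
#' Builds the simulated measurement design used to quantify the linear
#' estimator's bias: at leaf temperature `t`, the reference compensation
#' point is set from the Brooks-Farquhar polynomial, `vcmax`/`jmax` are
#' rescaled by MMRT and the Rubisco constants by Arrhenius
#' ([photo_params_at()]), and noise-free curves are evaluated at
#' chloroplastic CO2 values placed at fixed offsets above the reference
#' point. By construction all curves pass exactly through
#' `(gamma_star_ref, -d_l)`.
#'
#' @param t Leaf temperature (degrees C).
#' @param lights Irradiances (umol photons m-2 s-1).
#' @param offsets Positive offsets of the sampled CO2 values above the
#'   reference compensation point (Pa); default 2.1, 4.6 and 7.2 Pa.
#' @param params A 25 C [photo_params()] set.
#' @param tm A [temp_model()].
#' @return A tibble `light`, `cc`, `a_net` with the temperature-adjusted
#'   `params` and `gamma_ref` attached as attributes.
#' @examples
#' design_bias_curves(15)
#' @export
design_bias_curves <- function(t, lights = c(300, 150, 80),
                               offsets = c(2.1, 4.6, 7.2),
                               params = photo_params(), tm = temp_model()) {
  if (length(offsets) < 2 || any(offsets <= 0) || any(duplicated(offsets))) {
    abort("design_bias_curves: `offsets` must be >= 2 distinct positive values")
  }
  pt <- photo_params_at(t, params, tm)
  out <- simulate_anet(lights, pt$gamma_star + offsets, pt)
  attr(out, "gamma_ref") <- pt$gamma_star
  attr(out, "temp") <- t
  attr(out, "basis") <- "cc"
  out
}

# Per-curve limitation state over the sampled points: Rubisco-limited
# ("wc"), RuBP-regeneration-limited ("wj") or "mixed".
curve_limitation <- function(data, params) {
  data %>%
    group_by(.data$light) %>%
    summarise(limitation = {
      wc <- wc_rate(.data$cc, params)
      wj <- wj_rate(.data$cc, .data$light, params)
      lim <- ifelse(wc < wj, "wc", "wj")
      if (all(lim == "wc")) "wc" else if (all(lim == "wj")) "wj" else "mixed"
    }, .groups = "drop") %>%
    arrange(dplyr::desc(.data$light))
}

.estimate_for_bias <- function(data, estimator, params) {
  if (estimator == "linear") {
    f <- fit_laisk_linear(data)
    c(gamma = f$gamma_star, dl = f$d_l)
  } else {
    f <- fit_laisk_fvcb(data, params = params, n_restarts = 2,
                        start = c(gamma_star = params$gamma_star, d_l = params$d_l))
    c(gamma = f$gamma_star, dl = f$d_l)
  }
}

#' Temperature sweep of Laisk-estimator bias
#'
#' For each temperature, generates the noise-free three-point design of
#' [design_bias_curves()], runs the requested estimator and records the
#' bias `eps_gamma = gamma_est - gamma_ref` and
#' `eps_dl = dl_est - dl_ref`. With the linear estimator this reproduces
#' the characteristic bias pattern of fitting straight lines to curved
#' responses: `d_l` strongly underestimated (even negative) at low
#' temperature when the top light is Rubisco-limited, and `gamma_star`
#' underestimated at warmer temperatures where all curves are
#' RuBP-regeneration-limited.
#'
#' @param t Temperatures (degrees C).
#' @param estimator `"linear"` (default) or `"fvcb"` (which recovers the
#'   reference values to optimizer tolerance, since generator and fitter
#'   share the model).
#' @inheritParams design_bias_curves
#' @return A tibble with one row per temperature: reference and
#'   estimated values, `eps_gamma`, `eps_dl`, a `limitation` list-column
#'   (per-curve states from the forward model) and `failed`.
#' @examples
#' sweep_temperature(t = c(10, 25))
#' @export
sweep_temperature <- function(t = seq(5, 40, by = 5), lights = c(300, 150, 80),
                              offsets = c(2.1, 4.6, 7.2),
                              params = photo_params(), tm = temp_model(),
                              estimator = c("linear", "fvcb")) {
  estimator <- match.arg(estimator)
  purrr::map_dfr(t, function(ti) {
    curves <- design_bias_curves(ti, lights, offsets, params, tm)
    pt <- attr(curves, "params")
    lim <- curve_limitation(curves, pt)
    est <- tryCatch(.estimate_for_bias(curves, estimator, pt),
                    error = function(e) c(gamma = NA_real_, dl = NA_real_))
    tibble(t = ti, gamma_ref = pt$gamma_star, dl_ref = pt$d_l,
           gamma_est = est[["gamma"]], dl_est = est[["dl"]],
           eps_gamma = est[["gamma"]] - pt$gamma_star,
           eps_dl = est[["dl"]] - pt$d_l,
           limitation = list(lim),
           failed = !is.finite(est[["gamma"]]))
  })
}

# CO2 windows for the range-sensitivity sweep, relative to gamma_ref.
# include: lower edge 0.5 Pa below gamma_ref, first upper edge 0.5 Pa
# above it, extended in 0.5 Pa steps to a 10 Pa span.
# exclude: lower edge 3.0 Pa above gamma_ref, first upper edge 1.0 Pa
# beyond the start, extended in 0.5 Pa steps to a 10.5 Pa span.
# cap = "span" treats the maxima as range spans; cap = "absolute" treats
# them as offsets of the upper edge above gamma_ref.
.range_offsets <- function(mode, cap) {
  if (mode == "include") {
    lower <- -0.5
    uppers <- if (cap == "span") seq(0.5, lower + 10, by = 0.5) else seq(0.5, 10, by = 0.5)
  } else {
    lower <- 3.0
    uppers <- if (cap == "span") seq(4.0, lower + 10.5, by = 0.5) else seq(4.0, 10.5, by = 0.5)
  }
  list(lower = lower, uppers = uppers)
}

#' CO2-range sensitivity of Laisk-estimator bias
#'
#' Sweeps the width of the measured CO2 window at each temperature,
#' either including the reference compensation point (window starting
#' 0.5 Pa below it) or excluding it (window starting 3.0 Pa above it),
#' generates noise-free curves on `n_points` evenly spaced CO2 values in
#' the window, and records the linear estimator's bias per cell.
#'
#' @inheritParams sweep_temperature
#' @param mode `"include"` or `"exclude"`: whether the window brackets
#'   the reference compensation point.
#' @param n_points CO2 points per curve within each window.
#' @param cap Whether the documented maxima (10 Pa include, 10.5 Pa
#'   exclude) cap the window span (default) or the upper edge's offset
#'   above the reference point.
#' @return A tibble with one row per (temperature, window):  `span`,
#'   window edges, `eps_gamma`, `eps_dl`, `failed`.
#' @examples
#' sweep_cc_range(t = 25, mode = "include")
#' @export
sweep_cc_range <- function(t = seq(5, 40, by = 5), mode = c("include", "exclude"),
                           lights = c(300, 150, 80), n_points = 3,
                           params = photo_params(), tm = temp_model(),
                           estimator = c("linear", "fvcb"),
                           cap = c("span", "absolute")) {
  mode <- match.arg(mode)
  cap <- match.arg(cap)
  estimator <- match.arg(estimator)
  stopifnot(n_points >= 2)
  off <- .range_offsets(mode, cap)
  grid <- tidyr::expand_grid(t = t, upper = off$uppers)
  purrr::map_dfr(seq_len(nrow(grid)), function(k) {
    ti <- grid$t[k]
    pt <- photo_params_at(ti, params, tm)
    lo <- pt$gamma_star + off$lower
    hi <- pt$gamma_star + grid$upper[k]
    cc <- seq(max(lo, 1e-3), hi, length.out = n_points)
    curves <- simulate_anet(lights, cc, pt)
    est <- tryCatch(.estimate_for_bias(curves, estimator, pt),
                    error = function(e) c(gamma = NA_real_, dl = NA_real_))
    tibble(t = ti, mode = mode, span = grid$upper[k] - off$lower,
           cc_lower = lo, cc_upper = hi,
           gamma_ref = pt$gamma_star, dl_ref = pt$d_l,
           eps_gamma = est[["gamma"]] - pt$gamma_star,
           eps_dl = est[["dl"]] - pt$d_l,
           failed = !is.finite(est[["gamma"]]))
  })
}

#' Plot a temperature sweep of estimator bias
#'
#' @param sweep Output of [sweep_temperature()].
#' @return A ggplot: bias in `gamma_star` and `d_l` against temperature.
#' @export
plot_temperature_sweep <- function(sweep) {
  long <- sweep %>%
    dplyr::select("t", "eps_gamma", "eps_dl") %>%
    tidyr::pivot_longer(c("eps_gamma", "eps_dl"),
                        names_to = "quantity", values_to = "bias")
  ggplot(long, aes(x = .data$t, y = .data$bias)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "red") +
    geom_line() + geom_point() +
    facet_wrap(~quantity, scales = "free_y",
               labeller = ggplot2::as_labeller(c(
                 eps_gamma = "bias in gamma* (Pa)",
                 eps_dl = "bias in D_L (umol m-2 s-1)"))) +
    labs(x = "leaf temperature (°C)", y = "estimator bias") +
    theme_minimal()
}

#' Plot CO2-range sensitivity of estimator bias
#'
#' @param sweep Output of [sweep_cc_range()] (one or both modes, row-bound).
#' @return A ggplot: bias against window span, coloured by temperature.
#' @export
plot_range_sensitivity <- function(sweep) {
  long <- sweep %>%
    dplyr::select("t", "mode", "span", "eps_gamma", "eps_dl") %>%
    tidyr::pivot_longer(c("eps_gamma", "eps_dl"),
                        names_to = "quantity", values_to = "bias")
  ggplot(long, aes(x = .data$span, y = .data$bias,
                   colour = factor(.data$t), group = .data$t)) +
    geom_hline(yintercept = 0, linetype = 2) +
    geom_line() +
    facet_grid(.data$quantity ~ .data$mode, scales = "free_y") +
    labs(x = "CO2 range span (Pa)", y = "estimator bias",
         colour = "temperature (°C)") +
    theme_minimal()
}
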