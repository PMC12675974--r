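#' Simulate net assimilation over a light x CO2 grid
#'
#' Evaluates the forward FvCB model on the full crossing of the supplied
#' irradiances and chloroplastic CO2 partial pressures, optionally adding
#' Gaussian gas-analyser noise via the Box-Muller transform.
#'
#' @param lights Irradiances (umol photons m-2 s-1).
#' @param cc Chloroplastic CO2 partial pressures (Pa).
#' @param params A [photo_params()] object.
#' @param noise_sd Measurement noise standard deviation
#'   (umol CO2 m-2 s-1); 0 gives noise-free curves. Uses the current RNG
#'   state, so wrap in `withr::with_seed()` / `set.seed()` for
#'   reproducibility.
#' @return A tibble with columns `light`, `cc`, `a_net`, one row per grid
#'   point, ordered by decreasing light then increasing `cc`. The
#'   generating `params` are attached as an attribute.
#' @examples
#' simulate_anet(c(300, 150, 80), seq(1.2, 9.2, by = 2), six_degree_params())
#' @export
simulate_anet <- function(lights, cc, params, noise_sd = 0) {
  stopifnot(length(lights) >= 1, length(cc) >= 1, all(cc > 0), noise_sd >= 0)
  out <- tidyr::expand_grid(light = sort(lights, decreasing = TRUE), cc = sort(cc))
  out$a_net <- fvcb_anet(out$cc, out$light, params)
  if (noise_sd > 0) out <- perturb_anet(out, noise_sd)
  attr(out, "params") <- params
  out
}

#' Named CO2 ranges of the 6 C experiment
#'
#' The four analysis subsets of the 6 C measurements, defined by whether
#' the expected compensation point (about 1.5 Pa at 6 C) lies inside the
#' range and by the span: narrow/wide including it (1.2-3.6, 1.2-6.6 Pa)
#' and narrow/wide excluding it (3.6-6.6, 3.6-9.2 Pa), plus the full
#' 1.2-9.2 Pa range.
#'
#' @format A named list of `c(lower, upper)` pairs in Pa.
#' @export
laisk_cc_ranges <- list(
  full = c(1.2, 9.2),
  narrow_include = c(1.2, 3.6),
  wide_include = c(1.2, 6.6),
  narrow_exclude = c(3.6, 6.6),
  wide_exclude = c(3.6, 9.2)
)

#' Synthetic 6 C Laisk dataset
#'
#' Generates the synthetic analogue of the 6 C gas-exchange experiment:
#' three light-response curves (300/150/80 umol photons m-2 s-1) over a
#' regular chloroplastic CO2 grid spanning 1.2-9.2 Pa, produced by the
#' forward FvCB model with true `gamma_star` 1.67 Pa and `d_l` 1.0
#' umol m-2 s-1 (see [six_degree_params()]). The `range` argument slices
#' the full grid to one of the four analysis subsets of
#' [laisk_cc_ranges].
#'
#' The default grid has 9 evenly spaced points (1 Pa apart), so each
#' subset retains at least three points per curve.
#'
#' @param range One of `"full"`, `"narrow_include"`, `"wide_include"`,
#'   `"narrow_exclude"`, `"wide_exclude"`.
#' @param lights Irradiances (umol photons m-2 s-1).
#' @param n_points Number of CO2 grid points over the full 1.2-9.2 Pa
#'   span before slicing.
#' @param noise_sd Gaussian measurement noise SD (umol CO2 m-2 s-1).
#' @param params Generating [photo_params()].
#' @param temp Leaf temperature recorded in the `temp` attribute (C).
#' @return A tibble with columns `light`, `cc`, `a_net` and attributes
#'   `params`, `temp`, `basis` (`"cc"`) and `range`.
#' @examples
#' laisk_fixture("narrow_include")
#' @export
laisk_fixture <- function(range = "full", lights = c(300, 150, 80),
                          n_points = 9, noise_sd = 0,
                          params = six_degree_params(), temp = 6) {
  if (!range %in% names(laisk_cc_ranges)) {
    abort(paste0("unknown fixture range \"", range, "\"; use one of: ",
                 paste(names(laisk_cc_ranges), collapse = ", ")))
  }
  full <- laisk_cc_ranges$full
  cc <- seq(full[1], full[2], length.out = n_points)
  bounds <- laisk_cc_ranges[[range]]
  cc <- cc[cc >= bounds[1] - 1e-9 & cc <= bounds[2] + 1e-9]
  if (length(cc) < 2) abort("fixture range retains fewer than 2 CO2 points")
  out <- simulate_anet(lights, cc, params, noise_sd = noise_sd)
  attr(out, "temp") <- temp
  attr(out, "basis") <- "cc"
  attr(out, "range") <- range
  out
}

#' Restrict a gas-exchange table to a CO2 window
#'
#' @param data A tibble with a `cc` (or `ci`) column.
#' @param lower,upper Window bounds in Pa (inclusive).
#' @param basis Which CO2 column to filter on.
#' @return The filtered tibble (attributes preserved).
#' @export
slice_cc_range <- function(data, lower, upper, basis = c("cc", "ci")) {
  basis <- match.arg(basis)
  keep <- laisk_co2(data, basis) >= lower - 1e-9 & laisk_co2(data, basis) <= upper + 1e-9
  out <- data[keep, , drop = FALSE]
  for (a in c("params", "temp", "basis", "range")) attr(out, a) <- attr(data, a)
  out
}
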