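#' Potential electron transport rate from the light response
#'
#' Smaller root of the non-rectangular hyperbola
#' `theta J^2 - (alpha I + Jmax) J + alpha I Jmax = 0`, the standard light
#' response of whole-chain electron transport.
#'
#' @param light Photon flux density I (umol photons m-2 s-1), vectorised.
#' @param params A [photo_params()] object (uses `alpha`, `jmax`, `theta`).
#' @return Electron transport rate J (umol e- m-2 s-1), satisfying
#'   `0 <= J <= min(alpha * light, jmax)`.
#' @examples
#' electron_transport(100, photo_params(jmax = 100, alpha = 0.3, theta = 0.9))
#' @export
electron_transport <- function(light, params) {
  stopifnot(all(light >= 0))
  b <- params$alpha * light + params$jmax
  disc <- b^2 - 4 * params$theta * params$alpha * light * params$jmax
  if (any(disc < -1e-8 * b^2)) abort("electron_transport: negative discriminant")
  (b - sqrt(pmax(disc, 0))) / (2 * params$theta)
}

#' Effective Michaelis-Menten constant for CO2
#'
#' `Km = Kc (1 + O2 / Ko)`: the CO2 constant inflated by competitive
#' inhibition by oxygen.
#'
#' @inheritParams electron_transport
#' @return Effective Km (Pa).
#' @export
effective_km <- function(params) {
  params$kc * (1 + params$o2 / params$ko)
}

#' Apparent maximum carboxylation rate
#'
#' `V'cmax = Vcmax * cc / (cc + Ka)`, the maximum carboxylation rate
#' reduced by incomplete CO2 activation of Rubisco. With the default
#' `ka = 0` the activation term is disabled and `V'cmax = Vcmax`.
#'
#' @param cc Chloroplastic CO2 partial pressure (Pa), vectorised.
#' @inheritParams electron_transport
#' @return Apparent Vcmax (umol m-2 s-1).
#' @export
apparent_vcmax <- function(cc, params) {
  stopifnot(all(cc > 0))
  params$vcmax * cc / (cc + params$ka)
}

#' Rubisco-limited carboxylation rate
#'
#' `Wc = V'cmax * cc / (cc + Km)` with `V'cmax` from [apparent_vcmax()]
#' and `Km` from [effective_km()].
#'
#' @inheritParams apparent_vcmax
#' @return Wc (umol m-2 s-1).
#' @export
wc_rate <- function(cc, params) {
  apparent_vcmax(cc, params) * cc / (cc + effective_km(params))
}

#' RuBP-regeneration-limited carboxylation rate
#'
#' `Wj = J cc / (4 (cc + 2 gamma_star))` with J from
#' [electron_transport()]. The factor 4 converts electron transport into
#' RuBP-regeneration capacity under the NADPH-limited stoichiometry.
#'
#' @inheritParams apparent_vcmax
#' @param light Photon flux density (umol photons m-2 s-1), vectorised.
#' @return Wj (umol m-2 s-1).
#' @export
wj_rate <- function(cc, light, params) {
  stopifnot(all(cc > 0))
  electron_transport(light, params) * cc / (4 * (cc + 2 * params$gamma_star))
}

#' Smoothly co-limited carboxylation rate
#'
#' Smaller root of `Vc^2 - Vc (Wc + Wj + e) + Wc Wj = 0`. With `e = 0`
#' this is exactly `min(Wc, Wj)`; `e > 0` smooths the transition between
#' the Rubisco- and RuBP-regeneration-limited regimes into a hyperbola.
#'
#' @param wc,wj Limiting carboxylation rates (umol m-2 s-1), vectorised.
#' @param e_smooth Co-limitation factor (flux units, >= 0).
#' @return Vc (umol m-2 s-1), with `0 <= Vc <= min(wc, wj)`.
#' @examples
#' colimit_vc(3, 5, 0)    # exactly min(3, 5)
#' colimit_vc(3, 5, 0.5)
#' @export
colimit_vc <- function(wc, wj, e_smooth) {
  stopifnot(all(wc >= 0), all(wj >= 0), all(e_smooth >= 0))
  s <- wc + wj + e_smooth
  disc <- s^2 - 4 * wc * wj
  # disc >= (wc - wj)^2 for e >= 0; clamp tiny negative rounding
  if (any(disc < -1e-10 * pmax(s^2, 1))) abort("colimit_vc: negative radicand")
  (s - sqrt(pmax(disc, 0))) / 2
}

#' Net assimilation from the FvCB forward model
#'
#' `A_net = Vc (1 - gamma_star / cc) - d_l` with Vc the smoothly
#' co-limited minimum of the Rubisco-limited ([wc_rate()]) and
#' RuBP-regeneration-limited ([wj_rate()]) carboxylation rates. At
#' `cc = gamma_star` the carboxylation term vanishes, so every light
#' response passes through `(gamma_star, -d_l)`.
#'
#' @inheritParams wj_rate
#' @return Net assimilation rate (umol CO2 m-2 s-1), vectorised over
#'   `cc` and `light`.
#' @examples
#' p <- photo_params(vcmax = 50, jmax = 100, alpha = 0.3, theta = 0.9,
#'                   gamma_star = 1.67, d_l = 1, e_smooth = 0, o2 = 21000)
#' fvcb_anet(cc = c(1.67, 5), light = 100, params = p)
#' @export
fvcb_anet <- function(cc, light, params) {
  if (any(cc <= 0)) abort("fvcb_anet: `cc` must be > 0")
  vc <- colimit_vc(wc_rate(cc, params), wj_rate(cc, light, params), params$e_smooth)
  vc * (1 - params$gamma_star / cc) - params$d_l
}

#' Chloroplastic CO2 from intercellular CO2
#'
#' Solves the mesophyll flux balance `A_net(cc) = gm (ci - cc)` for the
#' chloroplastic partial pressure by bracketed root finding on
#' `[1e-6, ci + 10]` Pa. With infinite `gm` the two pressures coincide
#' and `ci` is returned unchanged.
#'
#' @param ci Intercellular CO2 partial pressure (Pa), vectorised.
#' @inheritParams wj_rate
#' @return Chloroplastic CO2 partial pressure (Pa); the flux-balance
#'   residual at the root is below 1e-10 umol m-2 s-1.
#' @export
cc_from_ci <- function(ci, light, params) {
  if (any(ci <= 0)) abort("cc_from_ci: `ci` must be > 0")
  if (!is.finite(params$gm)) return(ci)
  n <- max(length(ci), length(light))
  ci <- rep_len(ci, n); light <- rep_len(light, n)
  vapply(seq_len(n), function(i) {
    f <- function(x) fvcb_anet(x, light[i], params) - params$gm * (ci[i] - x)
    lo <- 1e-6; hi <- ci[i] + 10
    flo <- f(lo); fhi <- f(hi)
    if (is.na(flo) || is.na(fhi) || flo * fhi > 0) {
      abort(sprintf(
        "cc_from_ci: no sign change on [%g, %g] for ci = %g, light = %g (f = %g, %g)",
        lo, hi, ci[i], light[i], flo, fhi))
    }
    r <- uniroot(f, c(lo, hi), tol = 1e-12)
    # polish so the flux residual, not just the bracket, is tight
    if (abs(r$f.root) > 1e-10) r <- uniroot(f, c(lo, hi), tol = .Machine$double.eps^0.9)
    r$root
  }, numeric(1))
}

# Predict A_net for a gas-exchange table on either CO2 basis.
fvcb_predict <- function(data, params, basis = c("cc", "ci")) {
  basis <- match.arg(basis)
  co2 <- laisk_co2(data, basis)
  if (basis == "ci" && is.finite(params$gm)) {
    cc <- cc_from_ci(co2, data$light, params)
  } else {
    cc <- co2
  }
  fvcb_anet(cc, data$light, params)
}

# Column accessor shared by the estimators: chloroplastic basis expects
# a `cc` column, intercellular basis a `ci` column.
laisk_co2 <- function(data, basis = c("cc", "ci")) {
  basis <- match.arg(basis)
  if (is.null(data[[basis]])) {
    abort(paste0("expected a `", basis, "` column for basis = \"", basis, "\""))
  }
  data[[basis]]
}
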