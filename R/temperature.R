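#' Temperature-response model for the photosynthetic parameters
#'
#' Collects the coefficients used to move a 25 C parameter set to another
#' leaf temperature: the Brooks-Farquhar quadratic for the reference CO2
#' compensation point, macromolecular rate theory (MMRT) parameters for
#' Vcmax and Jmax, and Arrhenius activation energies for the Rubisco
#' Michaelis constants Kc and Ko.
#'
#' The MMRT parameters are placeholders chosen to give realistic
#' temperature optima (about 40 C for Vcmax, 35 C for Jmax) and a
#' roughly five-fold drop between 25 C and 5 C; only `dh` and `dcp`
#' affect the normalised scaling (`ds` cancels when `t0` equals the
#' reference temperature).
#'
#' @param t_ref Reference temperature (degrees C, fixed at 25).
#' @param gamma_poly Coefficients `(a0, a1, a2)` of the Brooks-Farquhar
#'   polynomial `a0 + a1 (t - 25) + a2 (t - 25)^2` in Pa.
#' @param mmrt_vcmax,mmrt_jmax Lists with elements `dh` (activation
#'   enthalpy at `t0`, J mol-1), `ds` (activation entropy at `t0`,
#'   J mol-1 K-1), `dcp` (activation heat capacity, J mol-1 K-1,
#'   negative for an interior optimum) and `t0` (K).
#' @param ea_kc,ea_ko Arrhenius activation energies for Kc and Ko
#'   (J mol-1).
#' @return An object of class `temp_model`.
#' @examples
#' gamma_star_ref(15)  # 2.17 Pa with the default coefficients
#' @export
temp_model <- function(t_ref = 25,
                       gamma_poly = c(3.69, 0.188, 0.0036),
                       mmrt_vcmax = list(dh = 50000, ds = 0, dcp = -2500, t0 = 298.15),
                       mmrt_jmax = list(dh = 20000, ds = 0, dcp = -2000, t0 = 298.15),
                       ea_kc = 79430, ea_ko = 36380) {
  stopifnot(length(gamma_poly) == 3, all(is.finite(gamma_poly)))
  structure(list(t_ref = t_ref, gamma_poly = gamma_poly,
                 mmrt_vcmax = mmrt_vcmax, mmrt_jmax = mmrt_jmax,
                 ea_kc = ea_kc, ea_ko = ea_ko),
            class = "temp_model")
}

#' Reference CO2 compensation point at a given temperature
#'
#' Brooks-Farquhar quadratic `a0 + a1 (t - 25) + a2 (t - 25)^2`, used to
#' position the simulated measurement CO2 ranges relative to the true
#' compensation point at each temperature.
#'
#' @param t Leaf temperature (degrees C), vectorised; sensible on
#'   0-45 C.
#' @param tm A [temp_model()].
#' @return Reference gamma-star (Pa).
#' @export
gamma_star_ref <- function(t, tm = temp_model()) {
  stopifnot(all(t >= 0), all(t <= 45))
  a <- tm$gamma_poly
  a[1] + a[2] * (t - 25) + a[3] * (t - 25)^2
}

#' Macromolecular rate theory (MMRT) temperature scaling
#'
#' Scales a rate known at the reference temperature using
#' `ln k(T) = ln k(T_ref) - dG(T)/(R T) + dG(T_ref)/(R T_ref)` with the
#' activation free energy
#' `dG(T) = dh + dcp (T - t0) - T (ds + dcp ln(T / t0))`. A negative
#' activation heat capacity `dcp` produces a single interior temperature
#' optimum; `dcp = 0` recovers a monotone Arrhenius-like response.
#'
#' @param t Leaf temperature (degrees C), vectorised.
#' @param k_ref Rate at the reference temperature.
#' @param pars List with `dh`, `ds`, `dcp` (J mol-1 or J mol-1 K-1) and
#'   `t0` (K); see [temp_model()].
#' @param t_ref Reference temperature (degrees C).
#' @return The rate at `t`, same units as `k_ref`.
#' @export
mmrt_scale <- function(t, k_ref, pars, t_ref = 25) {
  lnk <- function(tk) {
    dg <- pars$dh + pars$dcp * (tk - pars$t0) - tk * (pars$ds + pars$dcp * log(tk / pars$t0))
    -dg / (.R_GAS * tk)
  }
  k_ref * exp(lnk(t + .C_TO_K) - lnk(t_ref + .C_TO_K))
}

#' Arrhenius temperature scaling
#'
#' `k(T) = k_ref exp(Ea (T - T_ref) / (R T T_ref))` with temperatures in
#' Kelvin; used for the Rubisco Michaelis constants Kc and Ko.
#'
#' @param t Leaf temperature (degrees C), vectorised.
#' @param k_ref Value at the reference temperature.
#' @param ea Activation energy (J mol-1).
#' @param t_ref Reference temperature (degrees C).
#' @return The value at `t`, same units as `k_ref`.
#' @export
arrhenius_scale <- function(t, k_ref, ea, t_ref = 25) {
  tk <- t + .C_TO_K
  tr <- t_ref + .C_TO_K
  k_ref * exp(ea * (tk - tr) / (.R_GAS * tk * tr))
}

#' Rescale a 25 C parameter set to another leaf temperature
#'
#' Applies [mmrt_scale()] to `vcmax` and `jmax`, [arrhenius_scale()] to
#' `kc` and `ko`, and sets `gamma_star` to [gamma_star_ref()] at `t`.
#' `alpha`, `theta`, `d_l`, `o2`, `ka`, `e_smooth` and `gm` are kept
#' unchanged.
#'
#' @param t Leaf temperature (degrees C).
#' @param params A [photo_params()] set valid at `tm$t_ref`.
#' @param tm A [temp_model()].
#' @return A `photo_params` object at temperature `t`.
#' @examples
#' photo_params_at(6, photo_params())
#' @export
photo_params_at <- function(t, params = photo_params(), tm = temp_model()) {
  update(params,
         vcmax = mmrt_scale(t, params$vcmax, tm$mmrt_vcmax, tm$t_ref),
         jmax = mmrt_scale(t, params$jmax, tm$mmrt_jmax, tm$t_ref),
         kc = arrhenius_scale(t, params$kc, tm$ea_kc, tm$t_ref),
         ko = arrhenius_scale(t, params$ko, tm$ea_ko, tm$t_ref),
         gamma_star = gamma_star_ref(t, tm))
}
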