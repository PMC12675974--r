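#' Photosynthetic parameter set for one leaf at one temperature
#'
#' Bundles the kinetic and biophysical constants of the FvCB model of C3
#' photosynthesis. All CO2/O2 quantities are partial pressures in Pa; all
#' rates are fluxes in umol m-2 s-1. The defaults describe a
#' high-capacity C3 leaf (sunflower-like) at 25 degrees C; use
#' [photo_params_at()] to rescale a 25 C set to another leaf temperature,
#' or supply values measured at the temperature of interest directly.
#'
#' @param vcmax Maximum Rubisco carboxylation rate (umol CO2 m-2 s-1).
#' @param jmax Maximum electron transport rate (umol e- m-2 s-1).
#' @param alpha Quantum yield of electron transport (mol e- / mol photons).
#' @param theta Curvature of the light response of electron transport,
#'   strictly inside (0, 1).
#' @param gamma_star Photorespiratory CO2 compensation point (Pa). At
#'   `cc = gamma_star` the carboxylation term vanishes and net assimilation
#'   equals `-d_l` at any irradiance.
#' @param d_l Total non-photorespiratory CO2 release in the light, a.k.a.
#'   day respiration R_day / R_L (umol CO2 m-2 s-1, >= 0).
#' @param kc,ko Michaelis-Menten constants of Rubisco for CO2 and O2 (Pa).
#'   Defaults are literature-typical 25 C values; they are placeholders,
#'   not measurements.
#' @param ka Michaelis-Menten constant for CO2 activation of Rubisco (Pa).
#'   The default 0 disables the activation term, recovering the standard
#'   Rubisco-limited rate.
#' @param o2 Oxygen partial pressure (Pa); 21000 Pa is ambient.
#' @param e_smooth Co-limitation smoothing factor (flux units). 0 gives
#'   the abrupt `min(Wc, Wj)` transition; larger values smooth it into a
#'   hyperbola. Default 0.5.
#' @param gm Mesophyll conductance (umol m-2 s-1 Pa-1). `Inf` means the
#'   chloroplastic and intercellular CO2 partial pressures coincide.
#'
#' @return An object of class `photo_params`: a validated named list.
#' @seealso [fvcb_anet()], [photo_params_at()], [six_degree_params()]
#' @examples
#' p <- photo_params(vcmax = 50, jmax = 100, gamma_star = 1.67, d_l = 1)
#' fvcb_anet(cc = 5, light = 100, params = p)
#' @export
photo_params <- function(vcmax = 150, jmax = 180, alpha = 0.26, theta = 0.9,
                         gamma_star = 3.69, d_l = 1.0,
                         kc = 40.4, ko = 24800, ka = 0, o2 = 21000,
                         e_smooth = 0.5, gm = Inf) {
  p <- list(vcmax = vcmax, jmax = jmax, alpha = alpha, theta = theta,
            gamma_star = gamma_star, d_l = d_l, kc = kc, ko = ko, ka = ka,
            o2 = o2, e_smooth = e_smooth, gm = gm)
  validate_photo_params(p)
}

validate_photo_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)
  for (nm in names(p)) {
    if (!num1(p[[nm]])) abort(paste0("photo_params: `", nm, "` must be a single number"))
  }
  finite_fields <- setdiff(names(p), "gm")
  bad <- finite_fields[!vapply(p[finite_fields], is.finite, logical(1))]
  if (length(bad)) abort(paste0("photo_params: non-finite value for ", paste(bad, collapse = ", ")))
  if (p$theta <= 0 || p$theta >= 1) abort("photo_params: `theta` must lie strictly in (0, 1)")
  pos <- c("vcmax", "jmax", "alpha", "gamma_star", "kc", "ko")
  bad <- pos[vapply(pos, function(nm) p[[nm]] <= 0, logical(1))]
  if (length(bad)) abort(paste0("photo_params: must be > 0: ", paste(bad, collapse = ", ")))
  nonneg <- c("d_l", "ka", "o2", "e_smooth")
  bad <- nonneg[vapply(nonneg, function(nm) p[[nm]] < 0, logical(1))]
  if (length(bad)) abort(paste0("photo_params: must be >= 0: ", paste(bad, collapse = ", ")))
  if (p$gm <= 0) abort("photo_params: `gm` must be > 0 (or Inf)")
  structure(p, class = "photo_params")
}

#' Update fields of a photosynthetic parameter set
#'
#' @param object A [photo_params()] object.
#' @param ... Named fields to replace, e.g. `gamma_star = 2`.
#' @return A revalidated `photo_params` object.
#' @examples
#' update(photo_params(), d_l = 0.5)
#' @export
update.photo_params <- function(object, ...) {
  dots <- list(...)
  unknown <- setdiff(names(dots), names(object))
  if (length(unknown)) abort(paste0("unknown photo_params field(s): ", paste(unknown, collapse = ", ")))
  validate_photo_params(modifyList(unclass(object), dots))
}

#' @export
print.photo_params <- function(x, ...) {
  cat("<photo_params>\n")
  cat(sprintf("  Vcmax %.6g, Jmax %.6g umol m-2 s-1; alpha %.3g, theta %.3g\n",
              x$vcmax, x$jmax, x$alpha, x$theta))
  cat(sprintf("  gamma* %.6g Pa, D_L %.6g umol m-2 s-1\n", x$gamma_star, x$d_l))
  cat(sprintf("  Kc %.6g Pa, Ko %.6g Pa, Ka %.6g Pa, O2 %.6g Pa\n", x$kc, x$ko, x$ka, x$o2))
  cat(sprintf("  e %.3g, gm %s\n", x$e_smooth,
              if (is.finite(x$gm)) sprintf("%.6g umol m-2 s-1 Pa-1", x$gm) else "Inf"))
  invisible(x)
}

#' @export
as.data.frame.photo_params <- function(x, ...) as.data.frame(unclass(x))

#' Leaf parameters emulating the 6 degree C sunflower experiment
#'
#' A [photo_params()] set describing a cold (6 C) high-capacity C3 leaf,
#' used as the default generator for the 6 C synthetic fixtures: true
#' `gamma_star` 1.67 Pa and `d_l` 1.0 umol m-2 s-1, with Rubisco kinetic
#' constants rescaled from their 25 C defaults by the Arrhenius
#' activation energies of [temp_model()]. At these values all three
#' standard Laisk irradiances (300/150/80 umol photons m-2 s-1) are
#' RuBP-regeneration limited across 1.2-9.2 Pa.
#'
#' @param temp Leaf temperature in degrees C (default 6).
#' @param tm A [temp_model()] providing the Arrhenius activation energies.
#' @return A `photo_params` object at `temp`.
#' @examples
#' six_degree_params()
#' @export
six_degree_params <- function(temp = 6, tm = temp_model()) {
  photo_params(
    vcmax = 50, jmax = 60, alpha = 0.26, theta = 0.9,
    gamma_star = 1.67, d_l = 1.0,
    kc = arrhenius_scale(temp, 40.4, tm$ea_kc, t_ref = tm$t_ref),
    ko = arrhenius_scale(temp, 24800, tm$ea_ko, t_ref = tm$t_ref),
    ka = 0, o2 = 21000, e_smooth = 0.5, gm = Inf
  )
}
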