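# laiskfit

Estimation of the photorespiratory CO₂ compensation point (Γ\*) and the
rate of CO₂ release in the light (D_L, a.k.a. day respiration R_day or
R_L) from leaf gas-exchange measurements with the **Laisk method** — and
a model-based refinement of it that avoids the systematic bias of the
classical straight-line analysis.

## The scientific problem

In the Laisk method, net assimilation (A_net) is measured against low
CO₂ partial pressures at several sub-saturating irradiances. All of a
leaf's A_net–C_c response curves pass through the single point
(Γ\*, −D_L): at the compensation point the carboxylation term vanishes
at any light level. The classical analysis fits a straight line per
irradiance and reads Γ\* and D_L off the averaged pairwise
intersections (slopes *m*, intercepts *b*):

    Γ*_ij = (b_i − b_j) / (m_j − m_i),   D_L_ij = −(m_i Γ*_ij + b_i)

But photosynthetic theory says the A_net–C_c response is curved. In the
Farquhar–von Caemmerer–Berry (FvCB) model,

    A_net = V_c (1 − Γ*/C_c) − D_L,

with the carboxylation rate V_c the (smoothly co-limited) minimum of
the Rubisco-limited rate W_c = V′cmax·C_c/(C_c + K_m) and the
RuBP-regeneration-limited rate W_j = J·C_c / (4(C_c + 2Γ\*)), where J is
the non-rectangular-hyperbola light response of electron transport.
Fitting straight lines to these curved responses biases Γ\* and D_L —
severely at low temperature, or when the measured CO₂ range excludes
the expected compensation point, where the "estimates" can even go
negative. `laiskfit` implements:

- the forward FvCB model (`fvcb_anet()`), with smooth co-limitation,
  optional Rubisco CO₂-activation, and mesophyll-conductance coupling
  between intercellular and chloroplastic CO₂ (`cc_from_ci()`);
- the classical linear estimator (`fit_laisk_linear()`);
- the refined estimator (`fit_laisk_fvcb()`): a joint
  maximum-likelihood fit of the FvCB model to all light curves with a
  derivative-free Nelder–Mead search, which respects the curvature and
  returns consistent Γ\*/D_L regardless of the CO₂ range;
- temperature machinery (`gamma_star_ref()`, `mmrt_scale()`,
  `arrhenius_scale()`, `photo_params_at()`);
- simulation studies quantifying the linear method's bias across 5–40 °C
  and CO₂-range choices (`sweep_temperature()`, `sweep_cc_range()`), and
  Monte Carlo propagation of gas-analyser noise (`laisk_mc()`).

All estimator inputs are plain tables (`light`, `cc` or `ci`, `a_net`),
all outputs are tibbles or broom-style objects (`tidy()`, `glance()`,
`autoplot()`), so everything chains with the pipe.

## Worked example

A synthetic 6 °C sunflower-like dataset ships with the package: three
light curves (300/150/80 µmol photons m⁻² s⁻¹) over 1.2–9.2 Pa with
Gaussian analyser noise (SD 0.07 µmol m⁻² s⁻¹), generated from true
Γ\* = 1.67 Pa and D_L = 1.0 µmol m⁻² s⁻¹:

```r
library(laiskfit)
curves <- read_gas_exchange(
  system.file("extdata", "sunflower_6C_synthetic.csv", package = "laiskfit"))

glance(fit_laisk_linear(curves))
#> # A tibble: 1 × 6
#>   gamma_star   d_l gamma_sd dl_sd n_pairs implausible_dl
#>        <dbl> <dbl>    <dbl> <dbl>   <int> <lgl>
#> 1       1.12 0.954    0.145 0.102       3 FALSE

set.seed(1)
fit_laisk_fvcb(curves)
#> <laisk_fvcb> FvCB-model Laisk estimate
#>   gamma* = 1.705 Pa, D_L = 0.9954 umol m-2 s-1
#>   free: vcmax, jmax, gamma_star, d_l; NLL = -31.1046, RMSE = 0.0765, converged: TRUE
```

The linear analysis over the full range underestimates Γ\* by a third
(1.12 vs 1.67 Pa) because the fitted lines chase the curvature; the
FvCB fit lands on 1.705 Pa with an RMSE at the noise level. The bias is
far worse when the measured range excludes the expected compensation
point — under noise, the linear estimator then scatters into
physiologically impossible territory while the model-based fit stays
put:

```r
mc <- laisk_mc(laisk_fixture("wide_exclude"), n_reps = 200, seed = 7)
tidy(mc)
#> # A tibble: 2 × 7
#>   method mean_gamma sd_gamma mean_dl  sd_dl n_valid n_failed
#>   <chr>       <dbl>    <dbl>   <dbl>  <dbl>   <int>    <int>
#> 1 fvcb         1.76   0.0862   0.970 0.0665     197        3
#> 2 linear      -1.67   0.488    0.838 0.236      200        0
```

`autoplot()` methods draw the curves, fitted lines and intersection
points; `plot_temperature_sweep()` and `plot_range_sensitivity()` chart
the bias sweeps. See the methods vignette
(`vignettes/laisk-method.Rmd`) for the model, the synthetic designs and
all numerical choices.

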