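# Parameter set used by the worked single-point examples: e = 0 so the
# co-limitation reduces to an exact minimum.
toy_params <- function(...) {
  p <- photo_params(vcmax = 50, jmax = 100, alpha = 0.3, theta = 0.9,
                    gamma_star = 1.67, d_l = 1, kc = 40, ko = 24800,
                    ka = 0, o2 = 21000, e_smooth = 0, gm = Inf)
  if (length(list(...))) p <- update(p, ...)
  p
}

# Random but physiologically sane parameter draw for property loops.
random_params <- function() {
  photo_params(
    vcmax = runif(1, 10, 200), jmax = runif(1, 20, 300),
    alpha = runif(1, 0.1, 0.4), theta = runif(1, 0.5, 0.99),
    gamma_star = runif(1, 0.5, 8), d_l = runif(1, 0, 3),
    kc = runif(1, 5, 80), ko = runif(1, 5000, 40000),
    ka = 0, o2 = runif(1, 0, 25000), e_smooth = runif(1, 0, 1)
  )
}

# Strictly RuBP-regeneration-limited generator: huge Rubisco capacity
# and e = 0 make A_net = J(I) g(cc) - d_l exactly.
rubp_params <- function(gamma_star = 1.67, d_l = 1) {
  toy_params(vcmax = 5000, gamma_star = gamma_star, d_l = d_l)
}
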