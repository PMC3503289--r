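# Random kinetic truths that keep fixed-bed conversion data informative on
# the default residence-time grid: Vmax is scaled so the longest time gives
# deep but numerically incomplete conversion (otherwise every observation
# saturates and the linearization has nothing to fit).
draw_informative_kinetics <- function(t_max = 120) {
  Km <- 10^stats::runif(1, -1, 1.5)
  S0 <- 10^stats::runif(1, 0, 2)
  Vmax <- stats::runif(1, 0.05, 0.9) * (S0 + Km * log(1e6)) / t_max
  list(k = mm_kinetics(Km = Km, Vmax = Vmax), S0 = S0, Km = Km, Vmax = Vmax)
}

default_t_grid <- c(5, 10, 20, 40, 60, 90, 120)

noiseless_series <- function(S0, k, t = default_t_grid) {
  conversion_series(S0, t, predict_outlet(S0, t, k))
}

# L-infinity distance between an axisymmetric field and the first-order
# closed-form radial profile evaluated at its cell centres
linf_vs_first_order <- function(field, phi) {
  rad <- sqrt(field$mesh$r_dot^2 + field$mesh$z_dot^2)
  max(abs(field$Cs - first_order_profile(phi, rad)))
}
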