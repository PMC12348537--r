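# shared fixtures: the skin parameter set and derived quantities
skin <- tissue_properties(rho = 1180, c = 2291, k = 0.58, Q_met = 33800)
blood_std <- blood_properties(rho_b = 1060, omega_b = 0.5,
                              unit_mode = "mass_flux", T_b = 38)
W_std <- perfusion_coefficient(blood_std) # 1808.5 W m^-3 K^-1
D0_mm2 <- thermal_diffusivity(skin) * 1e6 # ~0.21455 mm^2/s
tau_q_2mm <- relaxation_time_from_diameter(2, D0_mm2) # ~1.165 s

# gaussian ball of excess energy E0 (J) with width sigma (m), as a function
# of a radial node matrix -- used for solver impulse/warm-start fixtures
gauss_ball <- function(E0, sigma, rho_c) {
  function(nodes) {
    E0 / rho_c * (2 * pi * sigma^2)^(-1.5) * exp(-nodes[, 1]^2 / (2 * sigma^2))
  }
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
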