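# bioheatwave

Non-Fourier (telegraph-type) Pennes bioheat modelling of laser-heated
tissue, for researchers in biomedical thermal modelling and laser
thermotherapy planning who need finite-propagation-speed temperature
predictions with a built-in cross-validation path.

## The model

The classical Pennes bioheat equation

ρc ∂T/∂t = k ∇²T + W (T_b − T) + Q_met + Q_ext

assumes Fourier conduction and hence an unphysical infinite heat
propagation speed.  Introducing a finite thermal relaxation time τ_q
(the Cattaneo–Vernotte flux law) gives the hyperbolic form this package
implements:

ρc τ_q ∂²T/∂t² + (ρc + W τ_q) ∂T/∂t = k ∇²T − W (T − T_b) + Q_met + Q_ext

Dividing by H = ρc + W τ_q maps it onto the telegraph equation
τ T_tt + T_t = D ∇²T + μT with τ = ρc τ_q/H, D = k/H, μ = −W/H.
Thermal fronts travel at √(D/τ), which decreases with increasing τ_q.
The relaxation time itself is estimated from the heated target diameter
d (mm) and tissue diffusivity D₀ (mm²/s) as **τ_q = d²/(16 D₀)**.

The package provides:

* the exact causal point-impulse kernel of the telegraph form
  (modified-Bessel I₁ inside the thermal wave cone, identically zero
  outside it) with an energy-matched amplitude calibration, plus the
  classical parabolic kernel as its τ_q → 0 limit;
* an explicit finite-difference solver of the hyperbolic PDE (cartesian
  1/2/3-D and spherically symmetric radial geometry) for independent
  cross-validation, with CFL-safe automatic time stepping;
* verification oracles: pointwise PDE residuals, manufactured
  solutions, field-comparison metrics, front-speed diagnostics, and a
  residual-minimization lock of the kernel reading;
* a skin-tissue parameter fixture, eight named scenarios,
  threshold-exceedance maps (50/60/70 °C damage thresholds), CSV / VTK /
  JSON export, and a small CLI.

## Worked example

```r
library(bioheatwave)

p <- table1_parameters()           # skin: rho 1180, c 2291, k 0.58 ...
round_tau_q(relaxation_time_from_diameter(2, thermal_diffusivity(p$tissue) * 1e6))
#> [1] 1.16

map_to_telegraph(p$tissue, p$blood, 1.16)
#> Telegraph coefficients
#>   tau_q = 1.16 s  tau = 1.1591 s  D = 2.1438e-07 m^2/s  mu = -0.000668459 1/s
#>   eps = 0.862738 1/s  alpha = 1.84954e-07 m^2/s^2  kappa = -0.000576705 1/s^2  disc = 0.74201 1/s^2
#>   front speed sqrt(alpha) = 0.430062 mm/s

cross_validate_impulse()$report
#> Field comparison over 1176 points (mask: exclude r <= 2dx, |r - front| <= 2dx, boundary margin 5dx; times 40,50)
#>   L2 rel 0.0005167  Linf rel 0.002222  peak rel diff 0.00225  peak offset 0 mm
```

A 2 mm skin target gives τ_q = 1.16 s (1.16525 s unrounded); the
telegraph mapping barely perturbs τ (1.1591 s) because perfusion is a
weak sink, and the resulting thermal front creeps at 0.43 mm/s — the
finite-speed behaviour the Fourier model cannot represent.  The
cross-validation line shows the closed-form kernel and the independent
finite-difference solver agreeing to 0.05 % (masked L2) on a 30 mm
radial domain, with the peak in the same cell.

From the shell:

```sh
Rscript inst/cli/bioheatwave tau --diameter-mm 2
# 1.16
# unrounded: 1.165250 s
Rscript inst/cli/bioheatwave scenario --id comsol60 --out out/
Rscript inst/cli/bioheatwave validate --out out/
```

Note that absolute peak temperatures of the analytic maps are a
calibration choice (the impulse amplitude is defined only up to
proportionality, and point deposition uses a fixed 1 mm³ reference
volume); run reports record the calibration so results are auditable.
See the methods vignette (`vignettes/nonfourier-bioheat.Rmd`) for the
model derivation, kernel selection, stability analysis and limitations.

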