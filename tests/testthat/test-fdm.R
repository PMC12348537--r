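test_that("stable timestep follows the damped-wave CFL", {
  co <- map_to_telegraph(skin, blood_std, 1.16)
  # hand arithmetic: 0.9 * 5e-4 / (sqrt(1.8495e-7) * sqrt(3)) = 0.604 s
  expect_rel(stable_timestep(co, 5e-4, 3), 0.604, 1e-3)
  # halving dx exactly halves the hyperbolic bound
  expect_equal(stable_timestep(co, 2.5e-4, 3), stable_timestep(co, 5e-4, 3) / 2)
  # tau_q = 0 returns the parabolic bound
  co0 <- map_to_telegraph(skin, blood_std, 0)
  expect_equal(stable_timestep(co0, 5e-4, 3),
               0.9 * (5e-4)^2 / (2 * 3 * co0$D))
  expect_error(stable_timestep(co, -1, 3), "dx")
})

test_that("source fields honor the exposure window and conserve power", {
  g <- bh_grid(0.5, 10, geometry = "radial")
  src <- laser_source(1e7, t_on = 1, t_off = 5)
  expect_identical(source_field(src, g, 0.5), numeric(prod(g$n)))
  expect_identical(source_field(src, g, 5), numeric(prod(g$n)))
  # point deposition: sum Q V_cell = P0 V_ref independent of dx
  for (dx in c(0.5, 0.25)) {
    gi <- bh_grid(dx, 10, geometry = "radial")
    Q <- source_field(src, gi, 2)
    expect_rel(sum(Q * cell_volumes(gi)), 1e7 * 1e-9, 1e-12)
  }
  # gaussian deposition vs quadrature of the truncated profile at
  # dx = spot_d / 8
  gs <- laser_source(1e7, profile = "gaussian", spot_d = 2, t_on = 0,
                     t_off = 10)
  gg <- bh_grid(2 / 8, 30, geometry = "radial")
  disc <- sum(source_field(gs, gg, 1) * cell_volumes(gg))
  w <- 1e-3
  quad <- stats::integrate(function(r) 4 * pi * r^2 * 1e7 * exp(-2 * r^2 / w^2),
                           0, 3 * w, rel.tol = 1e-10)$value
  expect_rel(disc, quad, 0.01)
})

test_that("zero sources stay in equilibrium", {
  g <- bh_grid(1, 10, geometry = "radial")
  scn <- bioheat_scenario(skin, blood_std, relaxation_spec(tau_q = 1.16),
                          laser_source(0, t_off = 1), g,
                          times = c(0, 5, 10), baseline_T0 = 37,
                          solver = "fdm")
  fld <- fdm_solve(scn)
  expect_true(all(fld$values == 37))
})

test_that("uniform heating matches the damped-ODE closed form", {
  # negligible conduction, no perfusion, constant uniform Q:
  # rho c tau_q T'' + rho c T' = Q with T(0)=T0, T'(0)=0 has
  # dT = (Q/(rho c)) (t - tau_q (1 - exp(-t/tau_q)))
  tis0 <- tissue_properties(rho = 1180, c = 2291, k = 1e-12)
  bl0 <- blood_properties(omega_b = 0)
  rc <- tis0$rho * tis0$c
  g <- bh_grid(1, 10, dim = 1)
  Q0 <- 1e6
  tq <- 1.16
  scn <- bioheat_scenario(tis0, bl0, relaxation_spec(tau_q = tq),
                          laser_source(0, t_off = 5), g,
                          times = c(1, 2, 3.48), baseline_T0 = 40,
                          solver = "fdm")
  fld <- fdm_solve(scn, fdm_config(dt = tq / 200,
                                   forcing = function(co, t) rep(Q0, nrow(co)),
                                   max_undershoot = 1))
  mid <- which.min(abs(grid_nodes(g)[, 1]))
  for (i in seq_along(fld$times)) {
    t <- fld$times[i]
    exact <- Q0 / rc * (t - tq * (1 - exp(-t / tq)))
    expect_rel(fld$values[i, mid] - 40, exact, 1e-3)
  }
})

test_that("cooling phase: peak decays after shutoff", {
  g <- bh_grid(0.25, 30, geometry = "radial")
  src <- laser_source(1e7, profile = "gaussian", spot_d = 2, t_on = 0,
                      t_off = 10)
  # parabolic: maximum principle, strictly decreasing max after t_off
  scnp <- bioheat_scenario(skin, blood_std, relaxation_spec(tau_q = 0), src,
                           g, times = seq(10, 30, 2.5), baseline_T0 = 37,
                           solver = "fdm")
  lg <- attr(fdm_solve(scnp), "log")
  expect_true(all(diff(lg$max_T) < 0))
  # hyperbolic: peak after t_off + 5 tau below the shutoff peak
  tq <- 1.16
  tau <- map_to_telegraph(skin, blood_std, tq)$tau
  scnh <- bioheat_scenario(skin, blood_std, relaxation_spec(tau_q = tq), src,
                           g, times = c(10, 10 + 5 * tau, 30),
                           baseline_T0 = 37, solver = "fdm")
  fh <- fdm_solve(scnh)
  expect_lt(max(fh$values[2, ]), max(fh$values[1, ]))
  expect_lte(attr(fh, "undershoot_frac"), 0.01)
  # t_off = end time is identical to a no-cooling run
  src2 <- laser_source(1e7, profile = "gaussian", spot_d = 2, t_on = 0,
                       t_off = 10)
  scn_a <- bioheat_scenario(skin, blood_std, relaxation_spec(tau_q = tq),
                            src2, g, times = c(5, 10), baseline_T0 = 37,
                            solver = "fdm")
  src3 <- laser_source(1e7, profile = "gaussian", spot_d = 2, t_on = 0,
                       t_off = 50)
  scn_b <- bioheat_scenario(skin, blood_std, relaxation_spec(tau_q = tq),
                            src3, g, times = c(5, 10), baseline_T0 = 37,
                            solver = "fdm")
  expect_equal(fdm_solve(scn_a)$values, fdm_solve(scn_b)$values)
})

test_that("parabolic impulse conserves energy without perfusion", {
  rc <- skin$rho * skin$c
  bl0 <- blood_properties(omega_b = 0)
  g <- bh_grid(1, 60, geometry = "radial")
  scn <- suppressWarnings(
    bioheat_scenario(skin, bl0, relaxation_spec(tau_q = 0),
                     laser_source(0, t_off = 1), g,
                     times = c(0, 100, 300), baseline_T0 = 37,
                     solver = "fdm"))
  fld <- fdm_solve(scn, fdm_config(initial_excess = gauss_ball(1, 3e-3, rc)))
  E0 <- field_energy(fld, skin, 1)
  for (i in 2:3) expect_rel(field_energy(fld, skin, i), E0, 0.01)
})

test_that("perfusion makes the excess energy decay exponentially", {
  rc <- skin$rho * skin$c
  g <- bh_grid(1, 200, geometry = "radial")
  tmax <- 3 * rc / W_std # ~4485 s
  scn <- suppressWarnings(
    bioheat_scenario(skin, blood_std, relaxation_spec(tau_q = 0),
                     laser_source(0, t_off = 1), g,
                     times = c(0, tmax / 3, tmax), baseline_T0 = 37,
                     solver = "fdm"))
  fld <- fdm_solve(scn, fdm_config(initial_excess = gauss_ball(1, 5e-3, rc)))
  E0 <- field_energy(fld, skin, 1)
  for (i in 2:3) {
    expect_rel(field_energy(fld, skin, i) / E0,
               exp(-(W_std / rc) * fld$times[i]), 0.02)
  }
})

test_that("hyperbolic runs approach the parabolic run linearly in tau_q", {
  rc <- skin$rho * skin$c
  g <- bh_grid(0.25, 30, geometry = "radial")
  ic <- gauss_ball(0.01, 1e-3, rc)
  run <- function(tq) {
    scn <- bioheat_scenario(skin, blood_std, relaxation_spec(tau_q = tq),
                            laser_source(0, t_off = 1), g, times = 20,
                            baseline_T0 = 37, solver = "fdm")
    fdm_solve(scn, fdm_config(initial_excess = ic, dt = 0.04,
                              max_undershoot = 1))$values[1, ]
  }
  up <- run(0)
  l2 <- sapply(c(1.16, 0.58, 0.29), function(tq) {
    sqrt(mean((run(tq) - up)^2)) / sqrt(mean((up - 37)^2))
  })
  expect_true(all(diff(l2) < 0))
  # approximately linear: successive halvings shrink the difference by
  # roughly a factor two
  expect_true(all(l2[2:3] / l2[1:2] > 0.3 & l2[2:3] / l2[1:2] < 0.7))
})

test_that("instability and bad steps are rejected before/while marching", {
  g <- bh_grid(1, 10, geometry = "radial")
  scn <- bioheat_scenario(skin, blood_std, relaxation_spec(tau_q = 1.16),
                          laser_source(0, t_off = 1), g, times = 10,
                          baseline_T0 = 37, solver = "fdm")
  co <- map_to_telegraph(skin, blood_std, 1.16)
  dt_bad <- 2 * stable_timestep(co, g$spacing, 3)
  expect_error(fdm_solve(scn, fdm_config(dt = dt_bad)), "stability bound")
})

test_that("a 3-D cartesian parabolic run matches the free-space kernel", {
  rc <- skin$rho * skin$c
  bl0 <- blood_properties(omega_b = 0)
  g <- bh_grid(1, 15, dim = 3)
  sigma <- 2e-3
  E0 <- 1
  scn <- bioheat_scenario(skin, bl0, relaxation_spec(tau_q = 0),
                          laser_source(0, t_off = 1), g, times = 60,
                          baseline_T0 = 37, solver = "fdm")
  ic <- function(nodes) {
    r2 <- rowSums(nodes^2)
    E0 / rc * (2 * pi * sigma^2)^(-1.5) * exp(-r2 / (2 * sigma^2))
  }
  fld <- fdm_solve(scn, fdm_config(initial_excess = ic))
  nodes <- grid_nodes(g)
  r <- sqrt(rowSums(nodes^2))
  # exact solution for a gaussian ball: a gaussian with variance
  # sigma^2 + 2 D0 t
  D0 <- thermal_diffusivity(skin)
  s2t <- sigma^2 + 2 * D0 * 60
  exact <- E0 / rc * (2 * pi * s2t)^(-1.5) * exp(-r^2 / (2 * s2t))
  keep <- r < 10e-3
  err <- sqrt(mean((fld$values[1, keep] - 37 - exact[keep])^2)) /
    sqrt(mean(exact[keep]^2))
  expect_lt(err, 0.02)
})
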