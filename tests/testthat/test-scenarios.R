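test_that("the skin parameter fixture carries the canonical values", {
  p <- table1_parameters()
  expect_equal(p$tissue$rho, 1180)
  expect_equal(p$tissue$c, 2291)
  expect_equal(p$tissue$k, 0.58)
  expect_equal(p$tissue$Q_met, 33800)
  expect_equal(p$blood$rho_b, 1060)
  expect_equal(p$blood$omega_b, 0.5)
  expect_identical(p$blood$unit_mode, "mass_flux")
  expect_equal(p$blood$T_b, 38)
  expect_true(p$blood$c_b_is_default)
  expect_equal(p$defaults$P0, 1e7)
  expect_equal(p$defaults$tau_q_range, c(0.01, 10.44))
  expect_equal(p$defaults$exposure_range, c(0.01, 120))
})

test_that("the scenario catalogue matches its literal parameter matrix", {
  entries <- scenario_catalog()
  expect_identical(names(entries),
                   c("fig1", "fig2", "fig3", "fig4", "fig5", "fig6",
                     "comsol60", "comsol120"))
  want <- data.frame(
    id = c("fig1", "fig2", "fig3", "fig4", "fig5", "fig6"),
    t = c(30, 0.007, 0.007, 0.01, 0.01, 0.01),
    tau_q = c(0, 1.16, 2.61, 2.61, 0.01, 1.16),
    z_mm = c(0, 0, 0, 0, 0, 1))
  for (i in seq_len(nrow(want))) {
    scn <- entries[[want$id[i]]]$scenario
    expect_equal(scn$relax$tau_q, want$tau_q[i], label = want$id[i])
    expect_identical(scn$relax$origin, "explicit")
    expect_equal(scn$times, want$t[i], label = want$id[i])
    expect_equal(scn$sources[[1]]$t_off, want$t[i])
    expect_equal(scn$sources[[1]]$center[3], want$z_mm[i] * 1e-3)
    expect_equal(scn$baseline_T0, 40)
    expect_identical(scn$solver, "analytic")
    expect_equal(scn$sources[[1]]$P0, 1e7)
  }
  for (expo in c(60, 120)) {
    scn <- entries[[paste0("comsol", expo)]]$scenario
    expect_identical(scn$solver, "fdm")
    expect_equal(scn$sources[[1]]$t_off - scn$sources[[1]]$t_on, expo)
    expect_identical(scn$sources[[1]]$profile, "gaussian")
    expect_equal(scn$sources[[1]]$spot_d, 2)
    expect_equal(scn$grid$extents[1], 30e-3)
    expect_equal(scn$baseline_T0, 37)
    expect_equal(scn$relax$tau_q, 1.16)
  }
})

test_that("threshold exceedance reproduces a geometric oracle", {
  # synthetic field: baseline + 10 K inside a 2 mm ball
  g <- bh_grid(0.125, 4, dim = 3)
  nodes <- grid_nodes(g)
  r <- sqrt(rowSums(nodes^2))
  vals <- matrix(37 + 10 * (r <= 2e-3), 1)
  fld <- thermal_field(g, 1, vals, 37)
  th <- threshold_exceedance(fld, c(30, 42, 60))
  # below the minimum: the whole domain
  expect_equal(th[[1]]$volume_mm3, sum(cell_volumes(g)) / 1e-9)
  # above the maximum: nothing
  expect_equal(th[[3]]$volume_mm3, 0)
  expect_true(is.na(th[[3]]$max_lateral_mm))
  # baseline + 5 K threshold: the ball volume (4/3) pi 2^3 within the
  # voxelization slack of one cell volume per surface cell
  vol <- th[[2]]$volume_mm3
  exact <- 4 / 3 * pi * 8
  n_surf <- sum(abs(r - 2e-3) < g$spacing)
  expect_lt(abs(vol - exact), n_surf * (0.125)^3)
  expect_rel(th[[2]]$max_lateral_mm, 2, 0.1)
})

test_that("catalogue scenarios run end to end through both solvers", {
  entries <- scenario_catalog()
  f1 <- evaluate_field(entries$fig1$scenario)
  expect_true(all(is.finite(f1$values)))
  expect_gt(max(f1$values), 40) # heating above baseline
  f2 <- evaluate_field(entries$fig2$scenario)
  # the parabolic fig1 field is positive everywhere (infinite speed);
  # the hyperbolic fig2 field is baseline outside the causal front
  expect_true(all(f1$values > 40))
  co <- map_to_telegraph(skin, blood_std, 1.16)
  nodes <- abs(grid_nodes(entries$fig2$scenario$grid)[, 1])
  outside <- nodes > front_radius(co, 0.007) * 1.05
  expect_true(all(f2$values[1, outside] == 40))
  f60 <- fdm_solve(entries$comsol60$scenario)
  expect_gt(max(f60$values), 37.5)
  expect_lte(attr(f60, "undershoot_frac"), 0.01)
})

test_that("run reports record the audit fields", {
  entries <- scenario_catalog()
  fld <- evaluate_field(entries$fig2$scenario)
  rep <- run_report(entries$fig2$scenario, fld)
  expect_identical(rep$branch, "telegraph")
  expect_identical(rep$interpretation_id, "causal_I1")
  expect_identical(rep$calibration, "energy_matched")
  expect_identical(rep$unit_mode, "mass_flux")
  expect_true(rep$c_b_is_default)
  expect_equal(rep$c_b, 3617)
  expect_gt(rep$front_radius_mm, 0)
  f60 <- fdm_solve(entries$comsol60$scenario)
  rep60 <- run_report(entries$comsol60$scenario, f60)
  expect_true(is.finite(rep60$dt_s) && rep60$dt_s > 0)
  expect_true(is.finite(rep60$cfl) && rep60$cfl <= 1)
})

test_that("the command line interface runs its subcommands", {
  # relaxation-time estimate prints the two-decimal value
  out <- capture.output(status <- cli_main(c("tau", "--diameter-mm", "2")))
  expect_identical(status, 0L)
  expect_identical(out[1], "1.16")
  expect_match(out[2], "unrounded: 1.165250")

  od <- withr::local_tempdir()
  out <- capture.output(
    status <- cli_main(c("scenario", "--id", "fig1", "--out", od)))
  expect_identical(status, 0L)
  rep <- jsonlite::fromJSON(file.path(od, "fig1_report.json"))
  expect_identical(rep$solver, "analytic")
  expect_identical(rep$branch, "parabolic")
  expect_true(file.exists(file.path(od, "fig1_field.csv")))

  # determinism: identical runs give byte-identical CSV output
  od2 <- withr::local_tempdir()
  capture.output(cli_main(c("scenario", "--id", "fig2", "--out", od2)))
  od3 <- withr::local_tempdir()
  capture.output(cli_main(c("scenario", "--id", "fig2", "--out", od3)))
  expect_identical(readLines(file.path(od2, "fig2_field.csv")),
                   readLines(file.path(od3, "fig2_field.csv")))

  # config errors exit with status 2
  expect_identical(suppressMessages(
    cli_main(c("scenario", "--id", "nope", "--out", od))), 2L)
  expect_identical(suppressMessages(cli_main(c("tau"))), 2L)

  # run a user config end to end
  scn <- scenario_catalog()$fig2$scenario
  cfg <- withr::local_tempfile(fileext = ".json")
  write_scenario(scn, cfg)
  od4 <- withr::local_tempdir()
  out <- capture.output(
    status <- cli_main(c("run", "--config", cfg, "--out", od4)))
  expect_identical(status, 0L)
  expect_true(file.exists(file.path(od4, "run_report.json")))
})

test_that("the validate subcommand writes a passing comparison report", {
  od <- withr::local_tempdir()
  out <- capture.output(status <- cli_main(c("validate", "--out", od)))
  expect_identical(status, 0L)
  rep <- jsonlite::fromJSON(file.path(od, "validation_report.json"))
  expect_lt(rep$comparison$l2_rel, 0.05)
  expect_identical(rep$selected_interpretation, "causal_I1")
})
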