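# Config documents use interface units throughout: mm, s, degrees C,
# W m^-3.  JSON is the canonical format (bit-faithful numeric round trip);
# YAML is accepted on read.

#' Convert a scenario to a plain config list
#' @param scenario A [bioheat_scenario()].
#' @return Nested list mirroring the config document schema.
#' @export
as_scenario_config <- function(scenario) {
  stopifnot(inherits(scenario, "bioheat_scenario"))
  ts <- scenario$tissue; bl <- scenario$blood; rx <- scenario$relax
  g <- scenario$grid
  list(
    tissue = list(rho = ts$rho, c = ts$c, k = ts$k, Q_met = ts$Q_met),
    blood = list(rho_b = bl$rho_b, c_b = bl$c_b, omega_b = bl$omega_b,
                 unit_mode = bl$unit_mode, T_b = bl$T_b,
                 c_b_is_default = bl$c_b_is_default),
    relaxation = c(list(tau_q = rx$tau_q, origin = rx$origin),
                   if (!is.null(rx$d)) list(d = rx$d)),
    sources = lapply(scenario$sources, function(s) {
      c(list(P0 = s$P0, center = s$center / .MM, profile = s$profile,
             t_on = s$t_on, t_off = s$t_off, alpha_abs = s$alpha_abs),
        if (!is.null(s$spot_d)) list(spot_d = s$spot_d))
    }),
    grid = list(spacing = g$spacing / .MM, extents = g$extents / .MM,
                dim = g$dim, geometry = g$geometry),
    times = scenario$times,
    baseline_T0 = scenario$baseline_T0,
    solver = scenario$solver,
    analytic_mode = scenario$analytic_mode,
    amplitude_calibration = scenario$amplitude_calibration,
    user_scale = scenario$user_scale
  )
}

#' Build a scenario from a config list
#' @param config Nested list as produced by [as_scenario_config()] (or
#'   parsed from a JSON/YAML document).
#' @return A [bioheat_scenario()].
#' @export
as_bioheat_scenario <- function(config) {
  req <- c("tissue", "blood", "relaxation", "sources", "grid", "times")
  miss <- setdiff(req, names(config))
  if (length(miss)) {
    stop("as_bioheat_scenario: missing config sections: ",
         paste(miss, collapse = ", "))
  }
  ts <- config$tissue
  tissue <- tissue_properties(ts$rho, ts$c, ts$k,
                              if (is.null(ts$Q_met)) 0 else ts$Q_met)
  bl <- config$blood
  blood <- if (is.null(bl$c_b) || isTRUE(bl$c_b_is_default)) {
    blood_properties(rho_b = bl$rho_b, omega_b = bl$omega_b,
                     unit_mode = bl$unit_mode, T_b = bl$T_b)
  } else {
    blood_properties(rho_b = bl$rho_b, c_b = bl$c_b, omega_b = bl$omega_b,
                     unit_mode = bl$unit_mode, T_b = bl$T_b)
  }
  rx <- config$relaxation
  relax <- if (identical(rx$origin, "from_diameter")) {
    relaxation_spec(d = rx$d, tissue = tissue)
  } else {
    relaxation_spec(tau_q = rx$tau_q)
  }
  sources <- lapply(config$sources, function(s) {
    laser_source(P0 = s$P0,
                 center = if (is.null(s$center)) c(0, 0, 0) else s$center,
                 profile = s$profile,
                 spot_d = s$spot_d,
                 t_on = s$t_on, t_off = s$t_off,
                 alpha_abs = if (is.null(s$alpha_abs)) 0 else s$alpha_abs)
  })
  g <- config$grid
  grid <- bh_grid(spacing = g$spacing, extents = g$extents,
                  dim = if (is.null(g$dim)) length(g$extents) else g$dim,
                  geometry = if (is.null(g$geometry)) "cartesian" else g$geometry)
  bioheat_scenario(tissue, blood, relax, sources, grid,
                   times = as.numeric(config$times),
                   baseline_T0 = if (is.null(config$baseline_T0)) 40 else config$baseline_T0,
                   solver = if (is.null(config$solver)) "analytic" else config$solver,
                   analytic_mode = if (is.null(config$analytic_mode)) "impulse" else config$analytic_mode,
                   amplitude_calibration = if (is.null(config$amplitude_calibration)) "energy_matched" else config$amplitude_calibration,
                   user_scale = config$user_scale)
}

#' Read a scenario config file (JSON or YAML)
#' @param path File path; format chosen by extension (`.json` vs
#'   `.yaml`/`.yml`).
#' @return A [bioheat_scenario()].
#' @export
read_scenario <- function(path) {
  ext <- tolower(tools::file_ext(path))
  config <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                       simplifyMatrix = FALSE)
  }
  as_bioheat_scenario(config)
}

#' Write a scenario config file (JSON)
#' @param scenario A [bioheat_scenario()].
#' @param path Output path.
#' @export
write_scenario <- function(scenario, path) {
  cfg <- as_scenario_config(scenario)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Export a thermal field as long-form CSV
#'
#' Columns `x_mm,y_mm,z_mm,t_s,T_C`; absent axes report 0.  Radial grids
#' export the radius as `x_mm`.
#'
#' @param field A [thermal_field()].
#' @param path Output path.
#' @export
write_field_csv <- function(field, path) {
  stopifnot(inherits(field, "thermal_field"))
  nodes <- grid_nodes(field$grid)
  xyz <- matrix(0, nrow(nodes), 3)
  xyz[, seq_len(ncol(nodes))] <- nodes
  nt <- length(field$times)
  df <- data.frame(
    x_mm = rep(xyz[, 1] / .MM, nt),
    y_mm = rep(xyz[, 2] / .MM, nt),
    z_mm = rep(xyz[, 3] / .MM, nt),
    t_s = rep(field$times, each = nrow(nodes)),
    T_C = as.numeric(t(field$values)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a 3-D field snapshot as a legacy VTK structured-points file
#' @param field A [thermal_field()] on a 3-D cartesian grid.
#' @param path Output path.
#' @param time_index Field row to export (default last).
#' @export
write_field_vtk <- function(field, path, time_index = length(field$times)) {
  stopifnot(inherits(field, "thermal_field"))
  g <- field$grid
  if (g$geometry != "cartesian" || g$dim != 3) {
    stop("write_field_vtk: 3-D cartesian grids only")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "bioheatwave temperature field",
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", g$n[1], g$n[2], g$n[3]),
               sprintf("ORIGIN %g %g %g", -g$extents[1], -g$extents[2],
                       -g$extents[3]),
               sprintf("SPACING %g %g %g", g$spacing, g$spacing, g$spacing),
               sprintf("POINT_DATA %d", prod(g$n)),
               "SCALARS T_C double 1",
               "LOOKUP_TABLE default"), con)
  writeLines(format(field$values[time_index, ], digits = 10,
                    scientific = FALSE, trim = TRUE), con)
  invisible(path)
}

#' Assemble a run report
#'
#' Records everything needed to audit a run: solver and branch, the blood
#' specific heat in force and whether it is the package default, the
#' perfusion unit mode, the kernel interpretation and amplitude
#' calibration, time step and CFL number (FDM), peak temperature and
#' location, and the causal front radius at the final time (hyperbolic).
#'
#' @param scenario The [bioheat_scenario()] that was run.
#' @param field The resulting [thermal_field()].
#' @return Named list (serializable with [write_run_report()]).
#' @export
run_report <- function(scenario, field) {
  stopifnot(inherits(scenario, "bioheat_scenario"),
            inherits(field, "thermal_field"))
  ex <- field$values - field$baseline_T0
  ipk <- arrayInd(which.max(ex), dim(ex))
  nodes <- grid_nodes(field$grid)
  peak_xyz <- rep(0, 3)
  peak_xyz[seq_len(ncol(nodes))] <- nodes[ipk[2], ]
  tau_q <- scenario$relax$tau_q
  branch <- if (tau_q == 0) "parabolic" else "telegraph"
  fr <- if (branch == "telegraph") {
    coeffs <- map_to_telegraph(scenario$tissue, scenario$blood, tau_q)
    front_radius(coeffs, max(field$times)) / .MM
  } else {
    NULL
  }
  sols <- attr(field, "solutions")
  list(solver = scenario$solver,
       branch = branch,
       tau_q_s = tau_q,
       baseline_T0_C = scenario$baseline_T0,
       c_b = scenario$blood$c_b,
       c_b_is_default = scenario$blood$c_b_is_default,
       unit_mode = scenario$blood$unit_mode,
       interpretation_id = if (!is.null(sols)) {
         sols[[1]]$interpretation_id
       } else if (branch == "telegraph") "causal_I1" else "parabolic_gaussian",
       calibration = scenario$amplitude_calibration,
       amplitude_scale = if (!is.null(sols)) sols[[1]]$amplitude_scale else NULL,
       dt_s = attr(field, "dt"),
       cfl = attr(field, "cfl"),
       undershoot_frac = attr(field, "undershoot_frac"),
       peak_T_C = max(field$values),
       peak_time_s = field$times[ipk[1]],
       peak_location_mm = peak_xyz / .MM,
       front_radius_mm = fr,
       times_s = range(field$times))
}

#' Write a run report (or any report list) as JSON
#' @param report Named list.
#' @param path Output path.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
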