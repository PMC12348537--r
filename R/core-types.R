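#' Tissue thermal properties
#'
#' Bulk thermal properties of the (homogeneous, isotropic) tissue.
#'
#' @param rho Mass density, kg m^-3.
#' @param c Specific heat capacity, J kg^-1 K^-1.
#' @param k Thermal conductivity, W m^-1 K^-1.
#' @param Q_met Metabolic heat generation rate, W m^-3 (>= 0).
#' @return An object of class `tissue_properties`.
#' @examples
#' skin <- tissue_properties(rho = 1180, c = 2291, k = 0.58, Q_met = 33800)
#' thermal_diffusivity(skin)
#' @export
tissue_properties <- function(rho, c, k, Q_met = 0) {
  vals <- list(rho = rho, c = c, k = k, Q_met = Q_met)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("tissue_properties: '", nm, "' must be a finite scalar")
    }
  }
  if (vals$rho <= 0 || vals$c <= 0 || vals$k <= 0 || vals$Q_met < 0) {
    stop("tissue_properties: require rho > 0, c > 0, k > 0, Q_met >= 0")
  }
  if (!is.finite(vals$rho * vals$c)) stop("tissue_properties: rho*c overflows")
  vals <- lapply(vals, as.numeric)
  structure(vals, class = "tissue_properties")
}

#' Blood properties and perfusion
#'
#' The perfusion rate `omega_b` is stored together with its unit convention.
#' Published parameter tables quote perfusion either as a volumetric mass
#' flux (kg m^-3 s^-1) or as a rate (s^-1); the two feed differently into
#' the volumetric heat-exchange coefficient, see [perfusion_coefficient()].
#'
#' @param rho_b Blood density, kg m^-3.
#' @param c_b Blood specific heat, J kg^-1 K^-1.  The skin parameter table
#'   shipped with this package does not pin this value; the default 3617 is
#'   a standard literature value and is flagged in run reports.
#' @param omega_b Perfusion rate, in the units given by `unit_mode`.
#' @param unit_mode `"mass_flux"` (kg m^-3 s^-1) or `"rate"` (s^-1).
#' @param T_b Arterial blood temperature, degrees C.
#' @return An object of class `blood_properties`.
#' @export
blood_properties <- function(rho_b = 1060, c_b = 3617, omega_b = 0.5,
                             unit_mode = c("mass_flux", "rate"), T_b = 38) {
  unit_mode <- match.arg(unit_mode)
  c_b_is_default <- missing(c_b)
  vals <- list(rho_b = rho_b, c_b = c_b, omega_b = omega_b,
               unit_mode = unit_mode, T_b = T_b,
               c_b_is_default = c_b_is_default)
  num <- vals[c("rho_b", "c_b", "omega_b", "T_b")]
  for (nm in names(num)) {
    v <- num[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("blood_properties: '", nm, "' must be a finite scalar")
    }
  }
  if (vals$rho_b <= 0 || vals$c_b <= 0 || vals$omega_b < 0) {
    stop("blood_properties: require rho_b > 0, c_b > 0, omega_b >= 0")
  }
  for (nm in names(num)) vals[[nm]] <- as.numeric(vals[[nm]])
  structure(vals, class = "blood_properties")
}

#' Thermal relaxation time specification
#'
#' Either an explicit relaxation time `tau_q`, or one derived from a target
#' diameter via \eqn{\tau_q = d^2 / (16 D)} with `d` in mm and the tissue
#' diffusivity `D` in mm^2 s^-1 (see [relaxation_time_from_diameter()]).
#'
#' @param tau_q Thermal relaxation time, s (>= 0).  May be omitted when `d`
#'   and `tissue` are supplied.
#' @param d Target diameter, mm; triggers `origin = "from_diameter"`.
#' @param tissue A [tissue_properties()] object (required with `d`).
#' @return An object of class `relaxation_spec` with fields `tau_q`,
#'   `origin` and (when derived) `d`.
#' @examples
#' skin <- tissue_properties(1180, 2291, 0.58, 33800)
#' relaxation_spec(d = 2, tissue = skin)$tau_q # ~1.165 s
#' @export
relaxation_spec <- function(tau_q = NULL, d = NULL, tissue = NULL) {
  if (!is.null(d)) {
    if (is.null(tissue)) stop("relaxation_spec: 'tissue' needed with 'd'")
    D_mm2 <- thermal_diffusivity(tissue) * 1e6
    derived <- relaxation_time_from_diameter(d, D_mm2)
    if (!is.null(tau_q) &&
        abs(tau_q - derived) > 1e-6 * max(derived, .Machine$double.eps)) {
      stop("relaxation_spec: supplied tau_q disagrees with d^2/(16 D) ",
           "beyond 1 part in 1e6 (", format(derived), " s expected)")
    }
    out <- list(tau_q = derived, origin = "from_diameter", d = as.numeric(d))
  } else {
    if (is.null(tau_q)) stop("relaxation_spec: give tau_q or d")
    if (!is.numeric(tau_q) || length(tau_q) != 1L || !is.finite(tau_q) ||
        tau_q < 0) {
      stop("relaxation_spec: tau_q must be a finite scalar >= 0")
    }
    out <- list(tau_q = as.numeric(tau_q), origin = "explicit", d = NULL)
  }
  structure(out, class = "relaxation_spec")
}

#' Volumetric laser heating source
#'
#' A localized volumetric heating term with a rectangular exposure window.
#' The `point` profile is an idealized Dirac deposition (implemented with a
#' fixed 1 mm^3 reference volume so deposited power is mesh-independent);
#' the `gaussian` profile is a beam-like spot, full width `spot_d` at 1/e^2
#' of irradiance.  `alpha_abs` is carried as metadata: at the sub-millimetre
#' depths considered by the analytic branch, exp(-alpha_abs * x) is taken
#' as 1.
#'
#' @param P0 Volumetric heating strength (laser power density), W m^-3.
#' @param center Source location, mm (3-vector, recycled to length 3).
#' @param profile `"point"` or `"gaussian"`.
#' @param spot_d Gaussian spot diameter (1/e^2 full width), mm; required
#'   for `profile = "gaussian"`.
#' @param t_on,t_off Exposure window, s (`t_on < t_off`).
#' @param alpha_abs Absorption coefficient, m^-1 (metadata only).
#' @return An object of class `laser_source`; `center` is stored in m.
#' @export
laser_source <- function(P0, center = c(0, 0, 0), profile = c("point", "gaussian"),
                         spot_d = NULL, t_on = 0, t_off = 1, alpha_abs = 0) {
  profile <- match.arg(profile)
  if (!is.numeric(P0) || length(P0) != 1L || !is.finite(P0) || P0 < 0) {
    stop("laser_source: P0 must be a finite scalar >= 0")
  }
  if (!(t_on < t_off)) stop("laser_source: need t_on < t_off")
  center <- rep_len(as.numeric(center), 3L)
  if (identical(profile, "gaussian")) {
    if (is.null(spot_d) || !is.finite(spot_d) || spot_d <= 0) {
      stop("laser_source: gaussian profile needs spot_d > 0 (mm)")
    }
  }
  structure(list(P0 = as.numeric(P0), center = center * .MM,
                 profile = profile,
                 spot_d = if (is.null(spot_d)) NULL else as.numeric(spot_d),
                 t_on = as.numeric(t_on), t_off = as.numeric(t_off),
                 alpha_abs = as.numeric(alpha_abs)),
            class = "laser_source")
}

#' Computational grid
#'
#' Node-centered uniform grid with a node at the origin.  The x axis is the
#' beam direction.  `geometry = "radial"` is a spherically symmetric 1-D
#' grid over r in `[0, extent]` (r^2-weighted Laplacian in the solver);
#' cartesian grids span `[-extent, +extent]` per axis.
#'
#' @param spacing Node spacing, mm (> 0).
#' @param extents Half-width per axis (cartesian) or outer radius (radial),
#'   mm; recycled to `dim`.
#' @param dim Number of axes (1, 2 or 3); forced to 1 for radial geometry.
#' @param geometry `"cartesian"` or `"radial"`.
#' @return An object of class `bh_grid` (internal storage in m).
#' @export
bh_grid <- function(spacing, extents, dim = length(extents),
                    geometry = c("cartesian", "radial")) {
  geometry <- match.arg(geometry)
  if (geometry == "radial") dim <- 1L
  dim <- as.integer(dim)
  if (!dim %in% 1:3) stop("bh_grid: dim must be 1, 2 or 3")
  extents <- rep_len(as.numeric(extents), dim)
  if (!is.finite(spacing) || spacing <= 0) stop("bh_grid: spacing must be > 0")
  if (any(extents < spacing)) stop("bh_grid: extents must be >= spacing")
  sp <- spacing * .MM
  ex <- extents * .MM
  n <- if (geometry == "radial") {
    as.integer(floor(ex[1] / sp) + 1L)
  } else {
    as.integer(floor(2 * ex / sp) + 1L)
  }
  structure(list(spacing = sp, extents = ex, dim = dim, geometry = geometry,
                 n = n),
            class = "bh_grid")
}

#' Axis coordinates of a grid (m)
#' @param grid A [bh_grid()].
#' @return List of numeric vectors, one per axis.
#' @export
grid_axes <- function(grid) {
  stopifnot(inherits(grid, "bh_grid"))
  if (grid$geometry == "radial") {
    return(list(r = seq(0, by = grid$spacing, length.out = grid$n[1])))
  }
  lapply(seq_len(grid$dim), function(j) {
    -grid$extents[j] + grid$spacing * (seq_len(grid$n[j]) - 1)
  })
}

#' Node coordinate matrix of a grid (m)
#'
#' Rows are nodes in column-major (first axis fastest) order; columns are
#' axes.  Radial grids return a one-column matrix of radii.
#' @param grid A [bh_grid()].
#' @export
grid_nodes <- function(grid) {
  ax <- grid_axes(grid)
  if (length(ax) == 1L) return(matrix(ax[[1]], ncol = 1))
  as.matrix(do.call(expand.grid, ax))
}

#' Per-node cell volumes (m^3)
#'
#' Cartesian: spacing^dim (unit transverse measure for dim < 3).  Radial:
#' spherical shell volumes 4 pi r^2 dr, with a half-spacing ball at r = 0.
#' @param grid A [bh_grid()].
#' @export
cell_volumes <- function(grid) {
  dx <- grid$spacing
  if (grid$geometry == "radial") {
    r <- grid_axes(grid)[[1]]
    v <- 4 * pi * r^2 * dx
    v[1] <- 4 / 3 * pi * (dx / 2)^3
    return(v)
  }
  rep(dx^grid$dim, prod(grid$n))
}

#' Gridded thermal field
#'
#' Absolute temperature over (time, node), degrees C, with its baseline.
#'
#' @param grid A [bh_grid()].
#' @param times Strictly increasing sample times, s.
#' @param values Numeric matrix, `length(times)` rows by `prod(grid$n)`
#'   columns (node order as in [grid_nodes()]).
#' @param baseline_T0 Baseline temperature, degrees C.
#' @export
thermal_field <- function(grid, times, values, baseline_T0) {
  stopifnot(inherits(grid, "bh_grid"))
  times <- as.numeric(times)
  if (length(times) < 1L || any(diff(times) <= 0)) {
    stop("thermal_field: times must be strictly increasing")
  }
  values <- as.matrix(values)
  if (nrow(values) != length(times) || ncol(values) != prod(grid$n)) {
    stop("thermal_field: values must be length(times) x prod(grid$n)")
  }
  if (!all(is.finite(values))) stop("thermal_field: non-finite values")
  structure(list(grid = grid, times = times, values = values,
                 baseline_T0 = baseline_T0),
            class = "thermal_field")
}

#' Simulation scenario
#'
#' Bundles tissue, blood, relaxation, sources, grid, output times and solver
#' choices into a single runnable description.
#'
#' @param tissue,blood,relax,grid Component objects; see
#'   [tissue_properties()], [blood_properties()], [relaxation_spec()],
#'   [bh_grid()].
#' @param sources A [laser_source()] or list of them (superposed).
#' @param baseline_T0 Baseline temperature, degrees C.
#' @param times Output times, s.  Times outside `[0, 120]` s (the validated
#'   exposure range) trigger a warning.
#' @param solver `"analytic"` or `"fdm"`.
#' @param analytic_mode `"impulse"` (each source is an energy impulse
#'   E0 = P0 (t_off - t_on) V_ref released at t_on) or `"paper_direct"`
#'   (kernel evaluated at the elapsed exposure time, reproducing the
#'   morphology of exposure-time temperature maps).
#' @param amplitude_calibration `"energy_matched"` (default) or
#'   `"user_scale"`.
#' @param user_scale Amplitude scale, K, for `"user_scale"` calibration.
#' @return An object of class `bioheat_scenario`.
#' @export
bioheat_scenario <- function(tissue, blood, relax, sources, grid, times,
                             baseline_T0 = 40,
                             solver = c("analytic", "fdm"),
                             analytic_mode = c("impulse", "paper_direct"),
                             amplitude_calibration = c("energy_matched",
                                                       "user_scale"),
                             user_scale = NULL) {
  solver <- match.arg(solver)
  analytic_mode <- match.arg(analytic_mode)
  amplitude_calibration <- match.arg(amplitude_calibration)
  stopifnot(inherits(tissue, "tissue_properties"),
            inherits(blood, "blood_properties"),
            inherits(relax, "relaxation_spec"),
            inherits(grid, "bh_grid"))
  if (inherits(sources, "laser_source")) sources <- list(sources)
  if (length(sources) < 1L) stop("bioheat_scenario: at least one source")
  for (s in sources) {
    stopifnot(inherits(s, "laser_source"))
    ctr <- s$center[seq_len(grid$dim)]
    lim <- if (grid$geometry == "radial") c(0, grid$extents[1]) else NULL
    inside <- if (grid$geometry == "radial") {
      abs(ctr[1]) <= grid$extents[1]
    } else {
      all(abs(ctr) <= grid$extents)
    }
    if (!inside) stop("bioheat_scenario: source center outside grid extents")
  }
  times <- sort(as.numeric(times))
  if (any(times < 0 | times > 120)) {
    warning("bioheat_scenario: output times outside the validated ",
            "exposure range [0, 120] s", call. = FALSE)
  }
  if (amplitude_calibration == "user_scale" &&
      (is.null(user_scale) || user_scale <= 0)) {
    stop("bioheat_scenario: user_scale > 0 required")
  }
  structure(list(tissue = tissue, blood = blood, relax = relax,
                 sources = sources, grid = grid, times = times,
                 baseline_T0 = as.numeric(baseline_T0), solver = solver,
                 analytic_mode = analytic_mode,
                 amplitude_calibration = amplitude_calibration,
                 user_scale = user_scale),
            class = "bioheat_scenario")
}

#' @export
print.telegraph_coefficients <- function(x, ...) {
  cat("Telegraph coefficients",
      if (isTRUE(x$degenerate)) "(degenerate: parabolic branch)" else "",
      "\n")
  cat(sprintf("  tau_q = %g s  tau = %g s  D = %g m^2/s  mu = %g 1/s\n",
              x$tau_q, x$tau, x$D, x$mu))
  if (!isTRUE(x$degenerate)) {
    cat(sprintf("  eps = %g 1/s  alpha = %g m^2/s^2  kappa = %g 1/s^2  disc = %g 1/s^2\n",
                x$eps, x$alpha, x$kappa, x$disc))
    cat(sprintf("  front speed sqrt(alpha) = %g mm/s\n", sqrt(x$alpha) / .MM))
  }
  invisible(x)
}

#' @export
print.bioheat_scenario <- function(x, ...) {
  cat("Bioheat scenario:", x$solver, "solver,",
      length(x$sources), "source(s), tau_q =", x$relax$tau_q, "s\n")
  cat("  grid:", x$grid$geometry, paste(x$grid$n, collapse = "x"),
      "nodes, spacing", x$grid$spacing / .MM, "mm; baseline",
      x$baseline_T0, "degC\n")
  cat("  times:", paste(utils::head(x$times, 6), collapse = ", "),
      if (length(x$times) > 6) "...", "s\n")
  invisible(x)
}
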