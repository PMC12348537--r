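#' Finite-difference solver configuration
#'
#' Controls for [fdm_solve()].  The scheme is explicit, second order,
#' central in time and space; the outer boundary is Dirichlet at the
#' scenario baseline; the initial state is `T = baseline_T0` with
#' `dT/dt = 0` unless an initial excess field is supplied.
#'
#' @param dt Time step, s, or `NULL` for the stable step from
#'   [stable_timestep()].
#' @param include_Tb_inflow Keep the arterial inflow term
#'   `W (T_b - baseline)` (the analytic branch drops it; default off).
#' @param include_Qmet Keep the metabolic heat source (default off, the
#'   analytic-branch approximation).
#' @param include_source_rate_term Add the Cattaneo source-rate term
#'   `tau_q dQ/dt` (exact flux-law expansion; default off).  Its switch-on
#'   transient is smoothed over one time step.
#' @param initial_excess Optional initial temperature excess over baseline:
#'   a numeric vector over grid nodes, or a function of the node coordinate
#'   matrix returning one.  Used for warm starts.  Displacement initial
#'   data on a damped-wave equation carries a physical negative trailing
#'   lobe, so the undershoot guard is logged but not enforced for such
#'   runs.
#' @param initial_rate Optional initial temperature rate dT/dt, K/s (same
#'   forms as `initial_excess`); hyperbolic runs only.  An impulsive point
#'   release of energy E0 corresponds to a rate
#'   `E0 / (rho c tau_q) * delta` -- this is the Green's-function initial
#'   condition and stays non-negative.
#' @param forcing Optional extra volumetric source: function of
#'   `(coords, t)` returning W m^-3 per node (used by manufactured-solution
#'   verification).
#' @param max_undershoot Largest tolerated undershoot below baseline near
#'   the wavefront, as a fraction of the peak excess (hyperbolic runs only;
#'   exceeding it aborts the run).
#' @return An object of class `fdm_config`.
#' @export
fdm_config <- function(dt = NULL, include_Tb_inflow = FALSE,
                       include_Qmet = FALSE,
                       include_source_rate_term = FALSE,
                       initial_excess = NULL, initial_rate = NULL,
                       forcing = NULL, max_undershoot = 0.01) {
  structure(list(dt = dt, include_Tb_inflow = include_Tb_inflow,
                 include_Qmet = include_Qmet,
                 include_source_rate_term = include_source_rate_term,
                 initial_excess = initial_excess, initial_rate = initial_rate,
                 forcing = forcing, max_undershoot = max_undershoot),
            class = "fdm_config")
}

#' Stable explicit time step
#'
#' Hyperbolic branch: the damped-wave CFL bound
#' `dt = 0.9 dx / (sqrt(alpha) sqrt(dim))` with wave speed
#' `sqrt(alpha) = sqrt(D/tau)` (von Neumann analysis of the central-central
#' scheme shows the wave bound governs for all tau > 0), additionally capped
#' at `tau` so the damping term is resolved.  Parabolic branch (tau_q = 0):
#' the forward-Euler diffusion bound `dt = 0.9 dx^2 / (2 dim D)`.
#'
#' @param coeffs A `telegraph_coefficients` object.
#' @param dx Node spacing, m (> 0).
#' @param dim Spatial dimension (1, 2 or 3); for radial geometry use 1.
#' @return Time step, s.
#' @export
stable_timestep <- function(coeffs, dx, dim) {
  stopifnot(inherits(coeffs, "telegraph_coefficients"))
  if (!is.finite(dx) || dx <= 0) stop("stable_timestep: dx must be > 0")
  if (!dim %in% 1:3) stop("stable_timestep: dim must be 1, 2 or 3")
  if (!is.finite(coeffs$D) || coeffs$D <= 0) {
    stop("stable_timestep: degenerate coefficients (D <= 0)")
  }
  if (isTRUE(coeffs$degenerate)) {
    return(0.9 * dx^2 / (2 * dim * coeffs$D))
  }
  dt_h <- 0.9 * dx / (sqrt(coeffs$alpha) * sqrt(dim))
  min(dt_h, coeffs$tau)
}

#' Discretized volumetric source field
#'
#' Deposits a [laser_source()] on a grid at time `t`.  Outside the exposure
#' window `[t_on, t_off)` the field is zero.  Point profile: the total
#' power `P0 * V_ref` (V_ref = 1 mm^3) is deposited on the node nearest the
#' center, so deposited power is independent of the spacing.  Gaussian
#' profile: `Q(r) = P0 exp(-2 r^2 / (spot_d/2)^2)` truncated at three spot
#' radii.
#'
#' @param source A [laser_source()].
#' @param grid A [bh_grid()].
#' @param t Time, s (>= 0).
#' @return Numeric vector of W m^-3 per node.
#' @export
source_field <- function(source, grid, t) {
  stopifnot(inherits(source, "laser_source"), inherits(grid, "bh_grid"))
  if (t < 0) stop("source_field: t must be >= 0")
  nnode <- prod(grid$n)
  Q <- numeric(nnode)
  if (t < source$t_on || t >= source$t_off) return(Q)
  nodes <- grid_nodes(grid)
  ctr <- source$center
  if (grid$dim < 3 && any(abs(ctr[(grid$dim + 1):3]) > 0) &&
      source$profile == "point") {
    stop("source_field: point source center must lie on the grid")
  }
  d2 <- rep(0, nnode)
  for (j in seq_len(ncol(nodes))) d2 <- d2 + (nodes[, j] - ctr[j])^2
  if (source$profile == "point") {
    i0 <- which.min(d2)
    if (sqrt(d2[i0]) > grid$spacing) {
      stop("source_field: source center outside the grid")
    }
    Q[i0] <- source$P0 * .V_REF / cell_volumes(grid)[i0]
  } else {
    w <- source$spot_d / 2 * .MM # 1/e^2 radius, m
    r2 <- d2
    Q <- source$P0 * exp(-2 * r2 / w^2)
    Q[r2 > (3 * w)^2] <- 0
  }
  Q
}

# second-order Laplacians with homogeneous Dirichlet boundaries, operating
# on the excess variable u = T - baseline.

.lap_cart1 <- function(u, dx) {
  n <- length(u)
  (c(u[-1], 0) + c(0, u[-n]) - 2 * u) / dx^2
}

.lap_cart <- function(u, dx) {
  # u: array of dim 1..3 (vector for 1-D)
  d <- dim(u)
  if (is.null(d)) return(.lap_cart1(u, dx))
  L <- array(0, d)
  nd <- length(d)
  for (ax in seq_len(nd)) {
    up <- array(0, d); dn <- array(0, d)
    n <- d[ax]
    ito <- lapply(d, seq_len); ifrom <- lapply(d, seq_len)
    ito[[ax]] <- seq_len(n - 1); ifrom[[ax]] <- 2:n
    if (nd == 2) {
      up[ito[[1]], ito[[2]]] <- u[ifrom[[1]], ifrom[[2]]]
      dn[ifrom[[1]], ifrom[[2]]] <- u[ito[[1]], ito[[2]]]
    } else {
      up[ito[[1]], ito[[2]], ito[[3]]] <- u[ifrom[[1]], ifrom[[2]], ifrom[[3]]]
      dn[ifrom[[1]], ifrom[[2]], ifrom[[3]]] <- u[ito[[1]], ito[[2]], ito[[3]]]
    }
    L <- L + up + dn - 2 * u
  }
  L / dx^2
}

.lap_radial <- function(u, r, dx) {
  n <- length(u)
  L <- numeric(n)
  if (n >= 3) {
    i <- 2:(n - 1)
    rp <- (r[i] + dx / 2)^2
    rm <- (r[i] - dx / 2)^2
    up <- u[i + 1]
    um <- u[i - 1]
    L[i] <- (rp * (up - u[i]) - rm * (u[i] - um)) / (r[i]^2 * dx^2)
  }
  L[1] <- 6 * (u[2] - u[1]) / dx^2 # r = 0: lap = 3 u''(0)
  L[n] <- 0 # Dirichlet boundary node held at baseline
  L
}

#' Explicit finite-difference solution of the hyperbolic bioheat PDE
#'
#' Time-marches
#' \deqn{\rho c \tau_q T_{tt} + (\rho c + W \tau_q) T_t =
#'   k \nabla^2 T - W (T - T_{b,eff}) + Q_{met,eff} + Q_{ext}}
#' with a central-time/central-space scheme (forward Euler diffusion when
#' `tau_q = 0`), Dirichlet baseline on the outer boundary and a ghost time
#' level implementing `dT/dt = 0` at the start.  Supports cartesian grids
#' (1/2/3-D) and the spherically symmetric radial geometry.  Cooling phases
#' need no special handling: after `t_off` the source field vanishes and
#' the march continues.
#'
#' @param scenario A [bioheat_scenario()] with `solver = "fdm"`.
#' @param config An [fdm_config()].
#' @return A [thermal_field()] sampled at `scenario$times`, with attributes
#'   `dt`, `cfl`, `undershoot_frac` and a per-sample `log` data frame.
#' @export
fdm_solve <- function(scenario, config = fdm_config()) {
  stopifnot(inherits(scenario, "bioheat_scenario"),
            inherits(config, "fdm_config"))
  if (scenario$solver != "fdm") stop("fdm_solve: scenario$solver must be 'fdm'")
  grid <- scenario$grid
  tissue <- scenario$tissue
  W <- perfusion_coefficient(scenario$blood)
  tau_q <- scenario$relax$tau_q
  rc <- tissue$rho * tissue$c
  coeffs <- .telegraph_from_W(tissue, W, tau_q)
  dx <- grid$spacing
  # the radial mode discretizes the full 3-D operator (its center-node
  # stencil has the 3-D eigenvalue bound), so its CFL dimension is 3
  dim_eff <- if (grid$geometry == "radial") 3L else grid$dim
  dt_stab <- stable_timestep(coeffs, dx, dim_eff)
  dt <- if (is.null(config$dt)) dt_stab else config$dt
  if (dt > dt_stab * (1 + 1e-12)) {
    stop("fdm_solve: dt = ", format(dt), " s violates the stability bound ",
         format(dt_stab), " s")
  }
  cfl <- if (coeffs$degenerate) {
    2 * dim_eff * coeffs$D * dt / dx^2
  } else {
    sqrt(coeffs$alpha) * sqrt(dim_eff) * dt / dx
  }

  nodes <- grid_nodes(grid)
  nnode <- nrow(nodes)
  r_ax <- if (grid$geometry == "radial") grid_axes(grid)[[1]] else NULL

  lap <- function(uv) {
    if (grid$geometry == "radial") return(.lap_radial(uv, r_ax, dx))
    if (grid$dim == 1) return(.lap_cart1(uv, dx))
    L <- .lap_cart(array(uv, grid$n), dx)
    as.numeric(L)
  }
  # boundary mask (excess pinned to 0 there)
  bmask <- if (grid$geometry == "radial") {
    seq_len(nnode) == nnode
  } else {
    on_edge <- rep(FALSE, nnode)
    for (j in seq_len(grid$dim)) {
      on_edge <- on_edge | abs(abs(nodes[, j]) -
                                 max(abs(grid_axes(grid)[[j]]))) < dx / 2
    }
    on_edge
  }

  inflow <- if (config$include_Tb_inflow) {
    W * (scenario$blood$T_b - scenario$baseline_T0)
  } else 0
  qmet <- if (config$include_Qmet) tissue$Q_met else 0

  laser_Q <- function(t) {
    Q <- rep(0, nnode)
    for (src in scenario$sources) Q <- Q + source_field(src, grid, t)
    Q
  }
  total_Q <- function(t) {
    Qx <- laser_Q(t)
    Q <- Qx + inflow + qmet
    if (!is.null(config$forcing)) Q <- Q + config$forcing(nodes, t)
    if (config$include_source_rate_term && tau_q > 0) {
      # Cattaneo source-rate term, one-step forward difference (the
      # switch-on jump is thereby smoothed over one dt)
      Q <- Q + tau_q * (laser_Q(t + dt) - Qx) / dt
    }
    Q
  }

  u <- rep(0, nnode)
  if (!is.null(config$initial_excess)) {
    u <- if (is.function(config$initial_excess)) {
      config$initial_excess(nodes)
    } else {
      as.numeric(config$initial_excess)
    }
    if (length(u) != nnode) stop("fdm_solve: initial_excess length mismatch")
  }
  u[bmask] <- 0

  out_times <- scenario$times
  t_end <- max(out_times)
  nt_out <- length(out_times)
  out <- matrix(NA_real_, nt_out, nnode)
  log_rows <- vector("list", nt_out)

  peak <- max(u, 0)
  trough <- min(u, 0)
  sample_count <- 0L

  record <- function(tprev, tcur, uprev, ucur) {
    # linear interpolation of any requested output times in (tprev, tcur]
    hit <- which(out_times > tprev - 1e-12 & out_times <= tcur + 1e-12 &
                   is.na(out[, 1]))
    for (io in hit) {
      w <- if (tcur > tprev) (out_times[io] - tprev) / (tcur - tprev) else 1
      w <- min(max(w, 0), 1)
      ui <- (1 - w) * uprev + w * ucur
      out[io, ] <<- scenario$baseline_T0 + ui
      log_rows[[io]] <<- data.frame(time = out_times[io],
                                    max_T = scenario$baseline_T0 + max(ui),
                                    min_T = scenario$baseline_T0 + min(ui))
    }
  }

  rhs <- function(uv, t) {
    tissue$k * lap(uv) - W * uv + total_Q(t)
  }

  t <- 0
  record(-Inf, 0, u, u)
  if (t_end > 0) {
    if (coeffs$degenerate) {
      # forward Euler parabolic update
      while (t < t_end - 1e-12) {
        un <- u + dt / rc * rhs(u, t)
        un[bmask] <- 0
        if (max(abs(un)) > 1e4) {
          stop("fdm_solve: numerical instability detected (|T - T0| > 1e4 K ",
               "at t = ", format(t + dt), " s, dt = ", format(dt), " s)")
        }
        record(t, t + dt, u, un)
        u <- un
        t <- t + dt
        peak <- max(peak, max(un))
      }
    } else {
      a <- rc * tau_q
      b <- rc + W * tau_q
      A <- a / dt^2
      B <- b / (2 * dt)
      v0 <- rep(0, nnode)
      if (!is.null(config$initial_rate)) {
        v0 <- if (is.function(config$initial_rate)) {
          config$initial_rate(nodes)
        } else {
          as.numeric(config$initial_rate)
        }
        if (length(v0) != nnode) stop("fdm_solve: initial_rate length mismatch")
      }
      # ghost start implementing dT/dt = v0 at t = 0:
      # T1 = T0 + dt v0 + dt^2/(2a) (RHS0 - b v0)
      u_prev <- u
      un <- u + dt * v0 + dt^2 / (2 * a) * (rhs(u, 0) - b * v0)
      un[bmask] <- 0
      record(0, dt, u, un)
      peak <- max(peak, max(un)); trough <- min(trough, min(un))
      u_prev <- u; u <- un; t <- dt
      while (t < t_end - 1e-12) {
        un <- (rhs(u, t) + A * (2 * u - u_prev) + B * u_prev) / (A + B)
        un[bmask] <- 0
        if (max(abs(un)) > 1e4) {
          stop("fdm_solve: numerical instability detected (|T - T0| > 1e4 K ",
               "at t = ", format(t + dt), " s, dt = ", format(dt), " s, ",
               "CFL = ", format(cfl), ")")
        }
        record(t, t + dt, u, un)
        u_prev <- u; u <- un; t <- t + dt
        peak <- max(peak, max(un)); trough <- min(trough, min(un))
      }
      if (is.null(config$initial_excess) &&
          peak > 0 && -trough > config$max_undershoot * peak) {
        stop("fdm_solve: wavefront undershoot ", format(-trough / peak),
             " of peak excess exceeds the tolerated ",
             format(config$max_undershoot))
      }
    }
  }
  if (anyNA(out[, 1])) {
    # any outputs beyond the marched range get the final state
    miss <- which(is.na(out[, 1]))
    for (io in miss) {
      out[io, ] <- scenario$baseline_T0 + u
      log_rows[[io]] <- data.frame(time = out_times[io],
                                   max_T = scenario$baseline_T0 + max(u),
                                   min_T = scenario$baseline_T0 + min(u))
    }
  }
  fld <- thermal_field(grid, out_times, out, scenario$baseline_T0)
  attr(fld, "dt") <- dt
  attr(fld, "cfl") <- cfl
  attr(fld, "undershoot_frac") <- if (peak > 0) max(0, -trough) / peak else 0
  attr(fld, "log") <- do.call(rbind, log_rows)
  attr(fld, "coeffs") <- coeffs
  fld
}

#' Total excess thermal energy of a field snapshot
#'
#' `integral of rho c (T - baseline) dV` over the grid, J (per unit
#' transverse measure for reduced-dimension cartesian grids).
#'
#' @param field A [thermal_field()].
#' @param tissue A [tissue_properties()].
#' @param time_index Row of the field to integrate (default last).
#' @export
field_energy <- function(field, tissue, time_index = length(field$times)) {
  stopifnot(inherits(field, "thermal_field"))
  v <- cell_volumes(field$grid)
  sum((field$values[time_index, ] - field$baseline_T0) * v) *
    tissue$rho * tissue$c
}
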