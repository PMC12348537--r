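#' Tissue thermal diffusivity
#'
#' \eqn{D_0 = k / (\rho c)}, m^2 s^-1.
#' @param tissue A [tissue_properties()] object.
#' @return Diffusivity in m^2 s^-1 (multiply by 1e6 for mm^2 s^-1).
#' @export
thermal_diffusivity <- function(tissue) {
  stopifnot(inherits(tissue, "tissue_properties"))
  tissue$k / (tissue$rho * tissue$c)
}

#' Thermal relaxation time from target diameter
#'
#' \eqn{\tau_q = d^2 / (16 D)} with `d` in millimetres and the diffusivity
#' in mm^2 s^-1.  The estimate scales quadratically in the diameter:
#' tau_q(s d) = s^2 tau_q(d).
#'
#' @param d Target diameter, mm (>= 0).
#' @param diffusivity_mm2_s Tissue diffusivity, mm^2 s^-1 (> 0).
#' @return Relaxation time, s.
#' @examples
#' skin <- tissue_properties(1180, 2291, 0.58)
#' relaxation_time_from_diameter(2, thermal_diffusivity(skin) * 1e6)
#' @export
relaxation_time_from_diameter <- function(d, diffusivity_mm2_s) {
  if (!is.numeric(diffusivity_mm2_s) || any(!is.finite(diffusivity_mm2_s)) ||
      any(diffusivity_mm2_s <= 0)) {
    stop("relaxation_time_from_diameter: diffusivity must be > 0 ",
         "(invalid tissue parameters)")
  }
  if (any(d < 0)) stop("relaxation_time_from_diameter: d must be >= 0")
  d^2 / (16 * diffusivity_mm2_s)
}

#' Round a relaxation time for reporting
#'
#' Relaxation times are quoted to two decimal places, rounding first at the
#' millisecond precision of the underlying parameter table and then
#' half-to-even at centiseconds.  Under this convention the skin-tissue
#' 2 mm estimate 1.16525... s is reported as 1.16 s.
#' @param tau_q Relaxation time(s), s.
#' @return Value rounded to two decimals.
#' @export
round_tau_q <- function(tau_q) {
  y <- round(tau_q, 3) * 100
  lo <- floor(y)
  near_half <- abs(y - lo - 0.5) < 1e-6
  out <- ifelse(near_half, ifelse(lo %% 2 == 0, lo, lo + 1), round(y))
  out / 100
}

#' Volumetric perfusion heat-exchange coefficient
#'
#' The Pennes perfusion term is `W * (T_b - T)` with `W` in W m^-3 K^-1.
#' Perfusion quoted as a volumetric mass flux (kg m^-3 s^-1) already carries
#' the blood density, so `W = c_b * omega_b`; quoted as a rate (s^-1) it
#' needs it, `W = rho_b * c_b * omega_b`.  Both conventions appear in the
#' literature and the stored `unit_mode` disambiguates them.
#'
#' @param blood A [blood_properties()] object.
#' @return W, W m^-3 K^-1 (>= 0).
#' @examples
#' perfusion_coefficient(blood_properties(omega_b = 0.5)) # 1808.5
#' @export
perfusion_coefficient <- function(blood) {
  stopifnot(inherits(blood, "blood_properties"))
  switch(blood$unit_mode,
         mass_flux = blood$c_b * blood$omega_b,
         rate = blood$rho_b * blood$c_b * blood$omega_b,
         stop("perfusion_coefficient: unknown unit_mode '",
              blood$unit_mode, "'"))
}

# telegraph coefficients from tissue, perfusion coefficient W and tau_q.
# H = rho c + W tau_q is the common denominator of the coefficient mapping.
.telegraph_from_W <- function(tissue, W, tau_q) {
  rc <- tissue$rho * tissue$c
  H <- rc + W * tau_q
  tau <- rc * tau_q / H
  D <- tissue$k / H
  mu <- -W / H
  if (tau_q == 0) {
    out <- list(tau = 0, D = D, mu = mu,
                eps = NA_real_, alpha = NA_real_, kappa = NA_real_,
                disc = NA_real_, tau_q = 0, H = H, W = W, rho_c = rc,
                degenerate = TRUE)
    return(structure(out, class = "telegraph_coefficients"))
  }
  eps <- 1 / tau
  alpha <- D / tau
  kappa <- mu / tau
  disc <- eps^2 + 4 * kappa
  if (!is.finite(disc) || disc <= 0) {
    stop("map_to_telegraph: oscillatory regime unsupported (eps^2 + 4*kappa ",
         "<= 0); physiological parameter sets do not reach this regime")
  }
  structure(list(tau = tau, D = D, mu = mu, eps = eps, alpha = alpha,
                 kappa = kappa, disc = disc, tau_q = tau_q, H = H, W = W,
                 rho_c = rc, degenerate = FALSE),
            class = "telegraph_coefficients")
}

#' Map bioheat parameters onto telegraph-equation coefficients
#'
#' Dividing the hyperbolic bioheat PDE
#' \deqn{\rho c \tau_q T_{tt} + (\rho c + W \tau_q) T_t =
#'       k \nabla^2 T - W (T - T_b) + Q}
#' by \eqn{H = \rho c + W \tau_q} puts it in telegraph form
#' \eqn{\tau T_{tt} + T_t = D \nabla^2 T + \mu T} with
#' \eqn{\tau = \rho c \tau_q / H}, \eqn{D = k / H}, \eqn{\mu = -W / H}.
#' The derived quantities \eqn{\epsilon = 1/\tau}, \eqn{\alpha = D/\tau}
#' (squared front speed), \eqn{\kappa = \mu/\tau} and the discriminant
#' \eqn{\epsilon^2 + 4\kappa} parameterize the closed-form kernel.
#'
#' @param tissue A [tissue_properties()] object.
#' @param blood A [blood_properties()] object.
#' @param tau_q Thermal relaxation time, s (>= 0).
#' @return A `telegraph_coefficients` object.  `tau_q = 0` yields a
#'   degenerate (parabolic-branch) object in which `eps`, `alpha`, `kappa`
#'   and `disc` are `NA`; requesting telegraph-only quantities then fails.
#' @export
map_to_telegraph <- function(tissue, blood, tau_q) {
  stopifnot(inherits(tissue, "tissue_properties"),
            inherits(blood, "blood_properties"))
  if (!is.numeric(tau_q) || length(tau_q) != 1L || !is.finite(tau_q) ||
      tau_q < 0) {
    stop("map_to_telegraph: tau_q must be a finite scalar >= 0")
  }
  .telegraph_from_W(tissue, perfusion_coefficient(blood), tau_q)
}
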