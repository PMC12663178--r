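#' Physical and geometric parameters of the Goldman uptake model
#'
#' All values in SI units. Defaults describe the reference experiment: PI at
#' c0 = 60 nM (6e-5 mol/m^3), divalent dye (z = 2) crossing membranes held at
#' 125 mV, PI diffusion constant 1e-12 m^2/s through 50 nm pores, a quasi-2D
#' chamber of depth 2 um populated by rod-shaped cells (length 2 um, radius
#' 0.5 um) at planar density 0.275/um^2 occupying volume fraction beta = 0.41,
#' bubble radius R_max = 29.7 um, observation time 600 s, and permeability-
#' intensity conversion k1 = 0.011 m/AU.
#'
#' `phi_override` / `kappa_override` replace the values otherwise derived from
#' the formulas (dimensionless potential phi = z e0 dPhi_m / kB T; kappa from
#' the cell-geometry expression) — useful for sensitivity analyses, since the
#' derived values are authoritative here.
#'
#' @param c0 Initial PI concentration, mol/m^3.
#' @param dPhi_m Transmembrane potential, V.
#' @param z Dye valence.
#' @param T Temperature, K.
#' @param D PI diffusion constant, m^2/s.
#' @param L Pore path length, m.
#' @param h0 Chamber depth, m.
#' @param a_cell Cell length, m.
#' @param r_e Cell radius, m.
#' @param rho Planar cell density, 1/m^2.
#' @param beta Cell volume fraction of the chamber (0 < beta < 1).
#' @param R_max Maximum bubble radius, m.
#' @param T_obs Observation time, s.
#' @param k1 Permeability-intensity factor, m/AU.
#' @param phi_override,kappa_override Optional replacements for the derived
#'   dimensionless potential and volume-to-surface ratio (m).
#' @return An object of class `goldman_params`.
#' @export
goldman_params <- function(c0 = 6e-5, dPhi_m = 0.125, z = 2, T = 300,
                           D = 1e-12, L = 50e-9, h0 = 2e-6,
                           a_cell = 2e-6, r_e = 0.5e-6, rho = 0.275e12,
                           beta = 0.41, R_max = 29.7e-6, T_obs = 600,
                           k1 = 0.011,
                           phi_override = NULL, kappa_override = NULL) {
  p <- list(c0 = c0, dPhi_m = dPhi_m, z = z, T = T, D = D, L = L, h0 = h0,
            a_cell = a_cell, r_e = r_e, rho = rho, beta = beta,
            R_max = R_max, T_obs = T_obs, k1 = k1,
            phi_override = phi_override, kappa_override = kappa_override)
  for (nm in setdiff(names(p), c("phi_override", "kappa_override"))) {
    check_positive(p[[nm]], nm)
  }
  if (beta >= 1) stop("`beta` must be in (0, 1)", call. = FALSE)
  structure(p, class = "goldman_params")
}

E0_CHARGE <- 1.602176634e-19  # C
KB_BOLTZ <- 1.380649e-23      # J/K

#' Derive the dimensionless constants of the Goldman model
#'
#' Computes, from first principles:
#' * `p0 = D/L`, the characteristic membrane permeability (m/s);
#' * `phi = z e0 dPhi_m / (kB T)`, the dimensionless transmembrane potential;
#' * `alpha_m = exp(-phi)`, the Boltzmann factor suppressing outward flux;
#' * `kappa = V_out/(N_e A_e)`, the ratio of extracellular volume to total
#'   cell surface area, from the cylinder-cell geometry:
#'   `a r_e (1/(pi r_e^2) - rho) / (2 rho (r_e + a))` (m);
#' * `alpha = p0 T_obs phi / kappa`, the flux scaling factor;
#' * `theta = k T_obs`, the dimensionless resealing rate.
#'
#' @param params A [goldman_params()].
#' @param k Fitted uptake rate constant, 1/s.
#' @return List of class `goldman_constants` with elements `p0`, `phi`,
#'   `alpha_m`, `kappa`, `alpha`, `theta`, and the `k` used.
#' @export
#' @examples
#' derive_constants(goldman_params(), k = 0.0046)$p0 # 2e-5 m/s
derive_constants <- function(params, k = 0.0046) {
  stopifnot(inherits(params, "goldman_params"))
  check_positive(k, "k")
  p0 <- params$D / params$L
  phi <- params$phi_override %||%
    (params$z * E0_CHARGE * params$dPhi_m / (KB_BOLTZ * params$T))
  kappa <- params$kappa_override %||%
    (params$a_cell * params$r_e * (1 / (pi * params$r_e^2) - params$rho) /
       (2 * params$rho * (params$r_e + params$a_cell)))
  if (kappa <= 0) stop("derived kappa is non-positive: rho exceeds close packing", call. = FALSE)
  structure(list(p0 = p0, phi = phi, alpha_m = exp(-phi), kappa = kappa,
                 alpha = p0 * params$T_obs * phi / kappa,
                 theta = k * params$T_obs, k = k),
            class = "goldman_constants")
}

#' @export
print.goldman_constants <- function(x, ...) {
  cat(sprintf(paste0("Goldman model constants:\n",
                     "  p0      = %.4g m/s   (characteristic permeability)\n",
                     "  phi     = %.4g       (dimensionless potential)\n",
                     "  alpha_m = %.4g       (exp(-phi))\n",
                     "  kappa   = %.4g m     (V_out / total cell area)\n",
                     "  alpha   = %.4g       (flux scaling)\n",
                     "  theta   = %.4g       (k * T_obs)\n"),
              x$p0, x$phi, x$alpha_m, x$kappa, x$alpha, x$theta))
  invisible(x)
}

#' Spatiotemporal membrane permeability
#'
#' Permeability is proportional to the instantaneous uptake rate,
#' P(gamma, t) = k1 dI/dt = k k1 I_final(gamma) exp(-k t): maximal at the
#' collapse (t = 0) and decaying exponentially as pores reseal, with the same
#' rate constant k as the uptake itself.
#'
#' @param gamma Normalized distances (> 0).
#' @param t_s Times since cavitation, s (>= 0).
#' @param k Uptake/resealing rate constant, 1/s.
#' @param k1 Permeability-intensity factor, m/AU.
#' @param law A [radial_law()] giving I_final(gamma).
#' @return Permeability in m/s (vector recycling over `gamma`/`t_s`).
#' @export
permeability_field <- function(gamma, t_s, k, k1, law = radial_law()) {
  if (any(gamma <= 0)) stop("`gamma` must be strictly positive", call. = FALSE)
  if (any(t_s < 0)) stop("`t_s` must be non-negative", call. = FALSE)
  k * k1 * predict(law, gamma) * exp(-k * t_s)
}

#' Membrane damage fraction
#'
#' The pore area fraction S_p of a cell's membrane follows from relative
#' permeability: P/p0 = n pi r_p^2 = S_p, giving
#' S_p(gamma, t) = (k k1 / p0) I_final(gamma) exp(-k t). Evaluated with the
#' physical constants this raw expression exceeds 1, so by default it is
#' normalized so that a plateau intensity of `I_100` (2500 AU) at t = 0 maps
#' to S_p = 1 — cells above that intensity are counted as totally damaged —
#' and capped to \[0, 1\]. Set `normalize = FALSE` for the raw expression.
#'
#' @param gamma Normalized distances (> 0).
#' @param t_s Times since cavitation, s.
#' @param k Rate constant, 1/s.
#' @param k1 Permeability-intensity factor, m/AU.
#' @param law A [radial_law()].
#' @param p0 Characteristic permeability, m/s.
#' @param I_100 Intensity corresponding to total damage, AU.
#' @param normalize Normalize and cap to \[0, 1\] (default) or return the raw
#'   expression.
#' @return Damage fraction (dimensionless).
#' @export
damage_fraction <- function(gamma, t_s, k, k1, law = radial_law(),
                            p0 = 2e-5, I_100 = 2500, normalize = TRUE) {
  if (any(gamma <= 0)) stop("`gamma` must be strictly positive", call. = FALSE)
  raw <- (k * k1 / p0) * predict(law, gamma) * exp(-k * t_s)
  if (!normalize) return(raw)
  pmin(raw / ((k * k1 / p0) * I_100), 1)
}

# dimensionless relative permeability P/p0 at dimensionless time t_dimless
rel_permeability_dimless <- function(gamma, t_dimless, consts, k1, law) {
  (consts$k * k1 / consts$p0) * predict(law, gamma) * exp(-consts$theta * t_dimless)
}

#' Closed-form solution of the Goldman uptake system
#'
#' With the outward Boltzmann factor alpha_m negligible (phi of order 10),
#' the external-concentration equation separates and integrates to
#' c1(gamma, t) = exp\[(phi k1 / kappa) I_final(gamma) (exp(-theta t) - 1)\],
#' with c2 = 1 - c1 by dye conservation. Time is dimensionless (t / T_obs).
#'
#' @param gamma Normalized distances (> 0).
#' @param t_dimless Dimensionless times (t / T_obs, >= 0).
#' @param consts A [derive_constants()] result.
#' @param k1 Permeability-intensity factor, m/AU.
#' @param law A [radial_law()].
#' @return List with vectors `c1`, `c2`.
#' @export
solve_goldman_analytic <- function(gamma, t_dimless, consts, k1,
                                   law = radial_law()) {
  if (any(gamma <= 0)) stop("`gamma` must be strictly positive", call. = FALSE)
  if (any(t_dimless < 0)) stop("`t_dimless` must be non-negative", call. = FALSE)
  coefx <- consts$phi * k1 / consts$kappa
  c1 <- exp(coefx * predict(law, gamma) * (exp(-consts$theta * t_dimless) - 1))
  list(c1 = c1, c2 = 1 - c1)
}

#' Linearized internal concentration
#'
#' First-order expansion of the closed-form c2 for small exponent
#' x = (phi k1 / kappa) I_final(gamma):
#' c2(gamma, t) = x (1 - exp(-theta t)), which shares the normalized time
#' course of the fluorescence saturation curve — the basis for reading
#' intensity as internal concentration. Warns when the exponent exceeds 0.1,
#' outside the expansion's validity.
#'
#' @inheritParams solve_goldman_analytic
#' @return Vector of linearized c2 values.
#' @export
c2_linearized <- function(gamma, t_dimless, consts, k1, law = radial_law()) {
  if (any(gamma <= 0)) stop("`gamma` must be strictly positive", call. = FALSE)
  x <- (consts$phi * k1 / consts$kappa) * predict(law, gamma)
  if (any(x > 0.1)) {
    warning("linearization exponent exceeds 0.1; expansion may be inaccurate")
  }
  x * (1 - exp(-consts$theta * t_dimless))
}

#' Numerically integrate the Goldman uptake system
#'
#' Integrates, independently for each gamma (radial symmetry decouples the
#' field), the modified Goldman flux equation in dimensionless time:
#' dc1/dt = alpha P(gamma, t) (c2 alpha_m - c1) / (1 - alpha_m), with
#' c1(0) = 1, c2(0) = 0. By default dye conservation c2 = 1 - c1 is
#' substituted into the flux, making conservation exact; with
#' `conserve = FALSE` the literal two-equation system including the chamber
#' continuity factor (beta - 1)/beta is integrated instead (that coupling
#' conserves total dye only for beta = 1/2, so conservation is then reported,
#' not enforced). An adaptive stiff-capable integrator (lsoda) is used.
#'
#' @param params A [goldman_params()].
#' @param k Uptake rate constant, 1/s.
#' @param gamma Vector of normalized distances (> 0).
#' @param t_dimless Dimensionless time grid (will be solved from 0).
#' @param law A [radial_law()].
#' @param alpha_m Override for the Boltzmann factor (e.g. 0 to match the
#'   analytic solution); default from [derive_constants()].
#' @param conserve Substitute c2 = 1 - c1 (default `TRUE`).
#' @param rtol,atol Solver tolerances.
#' @return List with matrices `c1`, `c2` (`length(gamma)` x
#'   `length(t_dimless)`) and the grids.
#' @export
solve_goldman_numeric <- function(params, k, gamma, t_dimless,
                                  law = radial_law(), alpha_m = NULL,
                                  conserve = TRUE, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "goldman_params"))
  if (!length(gamma) || !length(t_dimless)) stop("empty grid", call. = FALSE)
  if (any(gamma <= 0)) stop("`gamma` must be strictly positive", call. = FALSE)
  consts <- derive_constants(params, k)
  am <- alpha_m %||% consts$alpha_m
  times <- sort(unique(c(0, t_dimless)))
  c1 <- matrix(NA_real_, length(gamma), length(t_dimless))
  c2 <- matrix(NA_real_, length(gamma), length(t_dimless))
  pick <- match(t_dimless, times)
  for (gi in seq_along(gamma)) {
    p_of_t <- function(t) rel_permeability_dimless(gamma[gi], t, consts, params$k1, law)
    deriv <- if (conserve) {
      function(t, y, parms) {
        list(consts$alpha * p_of_t(t) * ((1 - y[1]) * am - y[1]) / (1 - am))
      }
    } else {
      function(t, y, parms) {
        d1 <- consts$alpha * p_of_t(t) * (y[2] * am - y[1]) / (1 - am)
        list(c(d1, (params$beta - 1) / params$beta * d1))
      }
    }
    y0 <- if (conserve) c(c1 = 1) else c(c1 = 1, c2 = 0)
    sol <- tryCatch(
      deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                   method = "lsoda", rtol = rtol, atol = atol),
      warning = function(w) stop(sprintf("ODE solver failed at gamma index %d: %s",
                                         gi, conditionMessage(w)), call. = FALSE))
    c1[gi, ] <- pmin(pmax(sol[pick, "c1"], 0), 1)  # clip atol-level overshoot
    c2[gi, ] <- if (conserve) 1 - c1[gi, ] else sol[pick, "c2"]
  }
  list(gamma = gamma, t_dimless = t_dimless, c1 = c1, c2 = c2)
}

#' Calibrate the intensity-concentration factor k2
#'
#' Matching the linearized Goldman solution to the fluorescence saturation
#' curve requires (phi k1 k2 c0) / kappa = 1, so
#' k2 = kappa / (phi k1 c0) in AU m^3/mol; intensity then follows from the
#' internal concentration as I = c2 c0 k2.
#'
#' @param params A [goldman_params()].
#' @param consts A [derive_constants()] result (defaults derived from
#'   `params`).
#' @return k2 in AU m^3/mol.
#' @export
calibrate_k2 <- function(params, consts = derive_constants(params)) {
  consts$kappa / (consts$phi * params$k1 * params$c0)
}

#' Transmembrane potential from the phenomenological constants
#'
#' Inverts the k2 calibration into the potential relation
#' dPhi_m = kappa kB T / (z e0 c0 k1 k2): the membrane potential is tied to
#' the dye's uptake phenomenology and is inversely proportional to the dye
#' concentration.
#'
#' @param params A [goldman_params()] (supplies kappa via its geometry, plus
#'   T, z, c0).
#' @param k1 Permeability-intensity factor, m/AU.
#' @param k2 Intensity-concentration factor, AU m^3/mol.
#' @return Transmembrane potential, V.
#' @export
transmembrane_potential <- function(params, k1 = params$k1,
                                    k2 = calibrate_k2(params)) {
  stopifnot(inherits(params, "goldman_params"))
  consts <- derive_constants(params)
  consts$kappa * KB_BOLTZ * params$T /
    (params$z * E0_CHARGE * params$c0 * k1 * k2)
}

#' Compute the spatiotemporal field map
#'
#' Evaluates, on a gamma x time grid, the model fields: fluorescence
#' I(gamma, t) = I_final(gamma)(1 - exp(-k t)), relative permeability P/p0,
#' damage fraction S_p, and the external/internal dye concentrations c1, c2
#' (analytic closed form by default, or the numeric integrator).
#'
#' @param params A [goldman_params()].
#' @param k Uptake rate constant, 1/s.
#' @param law A [radial_law()].
#' @param gamma Gamma grid (> 0).
#' @param t_s Time grid, seconds since cavitation.
#' @param I_100 Total-damage intensity for the S_p normalization, AU.
#' @param method `"analytic"` or `"numeric"` concentration solver.
#' @return A tibble of class `field_map`, long format: `gamma`, `t_s`, `I`,
#'   `P_over_p0`, `S_p`, `c1`, `c2`.
#' @export
compute_field_map <- function(params = goldman_params(), k = 0.0046,
                              law = radial_law(),
                              gamma = seq(0.14, 3, length.out = 60),
                              t_s = seq(0, params$T_obs, length.out = 121),
                              I_100 = 2500,
                              method = c("analytic", "numeric")) {
  method <- match.arg(method)
  if (!length(gamma) || !length(t_s)) stop("empty grid", call. = FALSE)
  consts <- derive_constants(params, k)
  grid <- expand.grid(t_s = t_s, gamma = gamma)[, c("gamma", "t_s")]
  td <- grid$t_s / params$T_obs
  if (method == "analytic") {
    conc <- solve_goldman_analytic(grid$gamma, td, consts, params$k1, law)
    c1 <- conc$c1; c2 <- conc$c2
  } else {
    sol <- solve_goldman_numeric(params, k, gamma, t_s / params$T_obs, law = law)
    c1 <- as.vector(t(sol$c1)); c2 <- as.vector(t(sol$c2))
  }
  out <- tibble::tibble(
    gamma = grid$gamma, t_s = grid$t_s,
    I = predict(law, grid$gamma) * (1 - exp(-k * grid$t_s)),
    P_over_p0 = permeability_field(grid$gamma, grid$t_s, k, params$k1, law) / consts$p0,
    S_p = damage_fraction(grid$gamma, grid$t_s, k, params$k1, law,
                          p0 = consts$p0, I_100 = I_100),
    c1 = c1, c2 = c2
  )
  class(out) <- c("field_map", class(out))
  attr(out, "params") <- params
  attr(out, "k") <- k
  out
}
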