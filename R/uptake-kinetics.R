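#' Fit diagnostics: R-squared, RMSE, residuals
#'
#' R^2 = 1 - SS_res/SS_tot with SS_res = sum((y - Y)^2) and
#' SS_tot = sum((y - mean(y))^2); RMSE is the root mean squared residual;
#' residuals are observed minus predicted. When the observations have zero
#' variance R^2 is undefined and returned as `NA`.
#'
#' @param observed,predicted Equal-length numeric vectors (length >= 2).
#' @return List with `r_squared`, `rmse`, `residuals`.
#' @export
#' @examples
#' goodness(c(1, 2, 3), c(1, 2, 4)) # R^2 = 0.5, RMSE = sqrt(1/3)
goodness <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("lengths differ", call. = FALSE)
  if (length(observed) < 2) stop("need at least 2 points", call. = FALSE)
  res <- observed - predicted
  ss_res <- sum(res^2)
  ss_tot <- sum((observed - mean(observed))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot
  list(r_squared = r2, rmse = sqrt(mean(res^2)), residuals = res)
}

#' Fit the first-order saturation curve to one trace
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' I(t) = I_final (1 - exp(-k t)) with the conventional starting point
#' (I_final = max of the data, k = 0.01 1/s) and bounds I_final >= 0, k > 0.
#' The time axis is measured from the cavitation event, so the acquisition
#' delay before the first frame is part of `time_s`. Traces carrying no
#' kinetic information (all-zero, or saturated before the first frame so that
#' k is unidentifiable) are flagged `converged = FALSE` and excluded from
#' population summaries downstream.
#'
#' @param intensity Numeric vector, AU per frame.
#' @param time_s Frame times in seconds from cavitation (length >= 3).
#' @param start_k Starting value for k, 1/s.
#' @return List with `I_final`, `k`, `r_squared`, `rmse`, `residuals`,
#'   `converged`.
#' @export
fit_saturation <- function(intensity, time_s, start_k = 0.01) {
  if (length(intensity) != length(time_s)) stop("trace and time axis lengths differ", call. = FALSE)
  if (length(time_s) < 3) stop("need at least 3 frames", call. = FALSE)
  failed <- list(I_final = NA_real_, k = NA_real_, r_squared = NA_real_,
                 rmse = NA_real_, residuals = rep(NA_real_, length(time_s)),
                 converged = FALSE)
  if (all(intensity == 0)) return(failed)
  df <- data.frame(t = time_s, y = intensity)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ If * (1 - exp(-k * t)), data = df,
                      start = list(If = max(intensity), k = start_k),
                      lower = c(0, .Machine$double.xmin),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(failed)
  cf <- stats::coef(fit)
  pred <- cf[["If"]] * (1 - exp(-cf[["k"]] * time_s))
  g <- goodness(intensity, pred)
  # k unidentifiable when the curve is already saturated at the first frame
  informative <- (1 - exp(-cf[["k"]] * time_s[1])) < 0.999
  list(I_final = unname(cf[["If"]]), k = unname(cf[["k"]]),
       r_squared = g$r_squared, rmse = g$rmse, residuals = g$residuals,
       converged = informative && cf[["k"]] > 0)
}

#' Fit saturation kinetics for every cell in a trace set
#'
#' @param traces A [trace_set()].
#' @param start_k Starting value for k, 1/s.
#' @return Tibble with the cell metadata columns plus `I_final`, `k`,
#'   `r_squared`, `rmse`, `converged`.
#' @export
fit_uptake <- function(traces, start_k = 0.01) {
  stopifnot(inherits(traces, "trace_set"))
  n <- n_cells(traces)
  out <- matrix(NA_real_, n, 4,
                dimnames = list(NULL, c("I_final", "k", "r_squared", "rmse")))
  conv <- logical(n)
  for (i in seq_len(n)) {
    f <- fit_saturation(traces$intensities[i, ], traces$time_s, start_k)
    out[i, ] <- c(f$I_final, f$k, f$r_squared, f$rmse)
    conv[i] <- f$converged
  }
  fits <- tibble::as_tibble(cbind(traces$cells, tibble::as_tibble(out)))
  fits$converged <- conv
  fits
}

#' Population summary of the uptake rate constant
#'
#' Summarizes converged per-cell fits with a single-pass 3-sigma outlier
#' exclusion: mean and sd are computed, values beyond `n_sigma` standard
#' deviations from that mean are dropped, and the statistics are recomputed
#' once on the retained set. The characteristic saturation time is
#' tau_char = 1/mean_k.
#'
#' @param fits Tibble from [fit_uptake()] (needs `k` and `converged`).
#' @param n_sigma Exclusion threshold in initial standard deviations.
#' @return List with `mean_k`, `sd_k`, `n_used`, `n_excluded`, `tau_char`.
#' @export
population_k_stats <- function(fits, n_sigma = 3) {
  k <- fits$k[fits$converged]
  if (length(k) < 2) stop("need at least 2 converged fits", call. = FALSE)
  m0 <- mean(k); s0 <- stats::sd(k)
  keep <- if (s0 == 0) rep(TRUE, length(k)) else abs(k - m0) <= n_sigma * s0
  if (!any(keep)) stop("all rate constants excluded as outliers", call. = FALSE)
  kk <- k[keep]
  mean_k <- mean(kk)
  list(mean_k = mean_k,
       sd_k = if (length(kk) > 1) stats::sd(kk) else 0,
       n_used = length(kk), n_excluded = sum(!keep),
       tau_char = 1 / mean_k)
}

#' Initial uptake rate versus final intensity
#'
#' Under first-order kinetics the initial slope of each cell's trace is
#' dI/dt at t = 0 = k * I_final, so a zero-intercept regression of initial
#' rate on I_final estimates the population rate constant. The initial rate
#' is taken from the fitted model's analytic derivative (k * I_final), which
#' is robust to frame noise; the slope returned is
#' sum(rate * I_final) / sum(I_final^2), the I_final^2-weighted mean of k.
#'
#' @param fits Tibble from [fit_uptake()] with `I_final`, `k`, `converged`.
#' @return List with `slope` (1/s), `n`, and `r_squared` of the regression.
#' @export
initial_rate_vs_final <- function(fits) {
  ok <- fits$converged
  i_final <- fits$I_final[ok]
  k <- fits$k[ok]
  if (length(k) < 1) stop("no converged fits", call. = FALSE)
  if (all(i_final == 0)) stop("all final intensities are zero; slope undefined", call. = FALSE)
  rate <- k * i_final
  slope <- sum(rate * i_final) / sum(i_final^2)
  r2 <- if (length(k) >= 2) goodness(rate, slope * i_final)$r_squared else NA_real_
  list(slope = slope, n = length(k), r_squared = r2)
}

#' Fit the radial final-intensity law
#'
#' Ordinary least squares of I_final = a + b/gamma, linear in the regressor
#' 1/gamma and solved in closed form (unweighted). Requires at least 2 cells
#' spanning distinct gamma values (two exact points are interpolated exactly).
#'
#' @param gamma Normalized distances (> 0).
#' @param i_final Plateau intensities, AU.
#' @return A [radial_law()] with fields `a_AU`, `b_AU` plus diagnostics
#'   `r_squared`, `rmse`, `n`.
#' @export
fit_radial_law <- function(gamma, i_final) {
  if (length(gamma) != length(i_final)) stop("lengths differ", call. = FALSE)
  ok <- is.finite(gamma) & is.finite(i_final)
  gamma <- gamma[ok]; i_final <- i_final[ok]
  if (length(gamma) < 2) stop("need at least 2 cells", call. = FALSE)
  if (any(gamma <= 0)) stop("`gamma` must be strictly positive", call. = FALSE)
  x <- 1 / gamma
  if (stats::sd(x) == 0) stop("all gamma equal: radial fit is rank deficient", call. = FALSE)
  fit <- stats::lm(i_final ~ x)
  cf <- stats::coef(fit)
  law <- radial_law(unname(cf[1]), unname(cf[2]))
  g <- goodness(i_final, unname(stats::fitted(fit)))
  law$r_squared <- g$r_squared
  law$rmse <- g$rmse
  law$n <- length(gamma)
  law
}
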