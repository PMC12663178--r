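#' Radial final-intensity law
#'
#' The plateau fluorescence of a cell decreases with its normalized distance
#' gamma from the cavitation center as I_final(gamma) = a + b/gamma. The
#' inverse-distance form reflects the collapse energy spreading over annuli of
#' area proportional to gamma in the quasi-2D cell layer. The defaults are the
#' coefficients fitted to the single-event dataset the model was built on
#' (a = 321 AU, b = 228 AU).
#'
#' @param a_AU Intercept, AU: plateau intensity far from the cavitation center.
#' @param b_AU Coefficient of 1/gamma, AU.
#' @return An object of class `radial_law`.
#' @seealso [fit_radial_law()] to estimate the coefficients from data.
#' @export
#' @examples
#' law <- radial_law()
#' predict(law, gamma = 1) # 549 AU
radial_law <- function(a_AU = 321, b_AU = 228) {
  if (!is.numeric(a_AU) || length(a_AU) != 1L || !is.finite(a_AU)) stop("`a_AU` must be a finite number")
  if (!is.numeric(b_AU) || length(b_AU) != 1L || !is.finite(b_AU)) stop("`b_AU` must be a finite number")
  structure(list(a_AU = a_AU, b_AU = b_AU), class = "radial_law")
}

#' Evaluate a radial law
#'
#' @param object A [radial_law()].
#' @param gamma Normalized distances (> 0).
#' @param ... Unused.
#' @return I_final(gamma) = a + b/gamma, AU.
#' @export
predict.radial_law <- function(object, gamma, ...) {
  if (any(gamma <= 0)) stop("`gamma` must be strictly positive", call. = FALSE)
  object$a_AU + object$b_AU / gamma
}

#' @export
print.radial_law <- function(x, ...) {
  cat(sprintf("Radial final-intensity law: I_final(gamma) = %.4g + %.4g / gamma [AU]\n",
              x$a_AU, x$b_AU))
  if (!is.null(x$r_squared)) {
    cat(sprintf("  fit: n = %d, R^2 = %.4f, RMSE = %.4g AU\n", x$n, x$r_squared, x$rmse))
  }
  invisible(x)
}
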