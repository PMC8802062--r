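#' Fit an Arrhenius model to rate constants
#'
#' Temperature dependence of a rate constant, `k = k0 exp(-Ea / (R T))`, is
#' estimated by ordinary least squares of `ln k` on `1/T`: the slope is
#' `-Ea/R` and the intercept `ln k0`, with R the ideal gas constant
#' (8.314 J mol^-1 K^-1). With exactly two temperatures the fit is an exact
#' interpolation and R-squared is 1 by construction.
#'
#' Duplicate temperatures are collapsed to their geometric-mean rate with a
#' warning (the regression is on `ln k`, so this is the least-squares
#' resolution).
#'
#' @param temp_k absolute temperatures, Kelvin. Celsius values can be
#'   converted with [celsius_to_kelvin()].
#' @param k rate constants at those temperatures, day^-1, all positive.
#' @return an `arrhenius_fit` with fields `ea` (J/mol), `ea_kj` (kJ/mol),
#'   `k0` (day^-1), `r2`, `n_temps`, `temp_range`.
#' @examples
#' f <- fit_arrhenius(celsius_to_kelvin(c(20, 30, 40)),
#'                    c(0.032, 0.066, 0.157))
#' f$ea_kj
#' @export
fit_arrhenius <- function(temp_k, k) {
  if (length(temp_k) != length(k)) {
    stop("temp_k and k must have equal length", call. = FALSE)
  }
  if (any(!is.finite(k)) || any(k <= 0)) {
    stop("rate constants must be positive", call. = FALSE)
  }
  if (any(temp_k <= 0)) stop("temperatures must be in Kelvin (> 0)",
                             call. = FALSE)
  if (anyDuplicated(temp_k)) {
    warning("duplicate temperatures collapsed to geometric-mean rates",
            call. = FALSE)
    lk <- tapply(log(k), temp_k, mean)
    temp_k <- as.numeric(names(lk))
    k <- exp(as.numeric(lk))
  }
  if (length(temp_k) < 2L) {
    stop("at least 2 distinct temperatures are required", call. = FALSE)
  }
  x <- 1 / temp_k
  y <- log(k)
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  ea <- -slope * R_GAS
  k0 <- exp(unname(stats::coef(fit)[1]))
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (length(y) == 2L || ss_tot == 0) 1 else {
    1 - sum(stats::residuals(fit)^2) / ss_tot
  }
  structure(list(ea = ea, ea_kj = ea / 1000, k0 = k0, r2 = r2,
                 n_temps = length(temp_k),
                 temp_range = range(temp_k), R = R_GAS),
            class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf(
    "Arrhenius fit: Ea = %.2f kJ/mol, k0 = %.4g /day, R2 = %.3f (%d temperatures, %.1f-%.1f K)\n",
    x$ea_kj, x$k0, x$r2, x$n_temps, x$temp_range[1], x$temp_range[2]))
  invisible(x)
}

#' Evaluate an Arrhenius fit at a temperature
#'
#' `k(T) = k0 exp(-Ea / (R T))`. Evaluating outside the fitted temperature
#' range extrapolates and raises a warning.
#'
#' @param fit an [fit_arrhenius()] result.
#' @param temp_k absolute temperature(s), Kelvin.
#' @return rate constant(s), day^-1.
#' @export
interpolate_k <- function(fit, temp_k) {
  stopifnot(inherits(fit, "arrhenius_fit"))
  if (any(temp_k <= 0)) stop("temperature must be positive Kelvin",
                             call. = FALSE)
  if (any(temp_k < fit$temp_range[1] - 1e-9 |
          temp_k > fit$temp_range[2] + 1e-9)) {
    warning("temperature outside the fitted range; Arrhenius extrapolation",
            call. = FALSE)
  }
  fit$k0 * exp(-fit$ea / (R_GAS * temp_k))
}

.new_q10 <- function(q10, t1_k, source) {
  structure(list(q10 = q10, t1_k = t1_k, t2_k = t1_k + 10, source = source),
            class = "q10_value")
}

#' @export
print.q10_value <- function(x, ...) {
  cat(sprintf("Q10 = %.4g (%.2f K -> %.2f K, %s)\n",
              x$q10, x$t1_k, x$t2_k, x$source))
  invisible(x)
}

#' Q10 from a pair of rate constants
#'
#' `Q10 = k2 / k1`, the factor by which the rate changes over a 10-degree
#' temperature increase from `T1` to `T2 = T1 + 10`.
#'
#' @param k1 rate at the lower temperature `t1_k`, day^-1.
#' @param k2 rate at `t1_k + 10`, day^-1.
#' @param t1_k lower absolute temperature, Kelvin.
#' @return a `q10_value`.
#' @examples
#' q10_from_rates(0.032, 0.066, celsius_to_kelvin(20))$q10   # 2.0625
#' @export
q10_from_rates <- function(k1, k2, t1_k) {
  if (any(c(k1, k2) <= 0)) stop("rates must be positive", call. = FALSE)
  .new_q10(k2 / k1, t1_k, "rate_ratio")
}

#' Q10 from an activation energy
#'
#' `Q10 = exp((Ea / R) (1/T1 - 1/T2))` with `T2 = T1 + 10`. When `Ea` comes
#' from a two-point Arrhenius fit on `(T1, T2)` this reproduces the rate
#' ratio `k2/k1` exactly.
#'
#' @param ea activation energy, J/mol.
#' @param t1_k lower absolute temperature, Kelvin (> 0).
#' @return a `q10_value`.
#' @export
q10_from_ea <- function(ea, t1_k) {
  if (t1_k <= 0) stop("temperature must be positive Kelvin", call. = FALSE)
  t2 <- t1_k + 10
  .new_q10(exp((ea / R_GAS) * (1 / t1_k - 1 / t2)), t1_k, "from_ea")
}
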