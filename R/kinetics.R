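#' Construct a color-attribute time series
#'
#' One attribute's measurements over storage days at a single temperature x
#' relative-humidity condition. Replicate and pseudo-replicate readings at the
#' same day are kept as separate observations and pooled by the fitters.
#'
#' @param day storage day of each observation (>= 0).
#' @param value attribute value of each observation.
#' @param attribute one of `"L"`, `"C"`, `"h"`.
#' @param temp_c storage temperature, degrees Celsius.
#' @param rh_pct relative humidity, percent.
#' @param cultivar,year optional labels.
#' @param replicate optional replicate labels (recycled).
#' @return a `color_series` data.frame with attributes describing the
#'   condition.
#' @examples
#' s <- color_series(c(0, 100, 200), c(79, 74, 69), "h", 20, 30)
#' fit_zero_order(s)
#' @export
color_series <- function(day, value, attribute, temp_c = NA_real_,
                         rh_pct = NA_real_, cultivar = NA_character_,
                         year = NA_character_, replicate = NULL) {
  attribute <- match.arg(attribute, c("L", "C", "h"))
  keep <- is.finite(day) & is.finite(value)
  day <- day[keep]; value <- value[keep]
  if (any(day < 0)) stop("storage days must be nonnegative", call. = FALSE)
  if (length(unique(day)) < 3L) {
    stop("a color series needs at least 3 distinct time points",
         call. = FALSE)
  }
  if (is.null(replicate)) replicate <- rep("1", length(day))
  out <- data.frame(day = day, value = value,
                    replicate = rep_len(as.character(replicate), length(day)))
  attr(out, "attribute") <- attribute
  attr(out, "temp_c") <- temp_c
  attr(out, "rh_pct") <- rh_pct
  attr(out, "cultivar") <- cultivar
  attr(out, "year") <- year
  class(out) <- c("color_series", "data.frame")
  out
}

#' @export
print.color_series <- function(x, ...) {
  cat(sprintf("color series: %s, %s degC / %s%% RH, %d obs over days %g-%g\n",
              attr(x, "attribute"), attr(x, "temp_c"), attr(x, "rh_pct"),
              nrow(x), min(x$day), max(x$day)))
  invisible(x)
}

.new_kinetic_fit <- function(order, k, slope_sign, P0, adj_r2, residual_sd,
                             n_obs, series, method = "ols",
                             increasing = FALSE) {
  structure(list(order = order, k = k, slope_sign = slope_sign, P0 = P0,
                 adj_r2 = adj_r2, residual_sd = residual_sd, n_obs = n_obs,
                 attribute = attr(series, "attribute"),
                 temp_c = attr(series, "temp_c"),
                 rh_pct = attr(series, "rh_pct"),
                 cultivar = attr(series, "cultivar"),
                 year = attr(series, "year"),
                 method = method, increasing = increasing),
            class = "kinetic_fit")
}

.adj_r2 <- function(obs, fitted, n_par = 2L) {
  n <- length(obs)
  ss_res <- sum((obs - fitted)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) return(if (ss_res == 0) 1 else -Inf)
  r2 <- 1 - ss_res / ss_tot
  1 - (1 - r2) * (n - 1) / (n - n_par)
}

#' Fit a zero-order (linear) decay model
#'
#' Ordinary least squares of the attribute on storage day, `P = P0 - k t`.
#' The rate constant is reported as a magnitude (`k >= 0`); an increasing
#' trend is flagged via the `increasing` field and `slope_sign`, with a
#' warning.
#'
#' @param series a [color_series()].
#' @return a `kinetic_fit` with fields `order` (0), `k`, `slope_sign`, `P0`,
#'   `adj_r2`, `residual_sd`, `n_obs`.
#' @export
fit_zero_order <- function(series) {
  stopifnot(inherits(series, "color_series"))
  fit <- stats::lm(value ~ day, data = series)
  slope <- unname(stats::coef(fit)[2])
  P0 <- unname(stats::coef(fit)[1])
  increasing <- slope > 0
  if (increasing) {
    warning("attribute increases with storage day; k reported as magnitude",
            call. = FALSE)
  }
  fitted <- P0 + slope * series$day
  n <- nrow(series)
  res_sd <- if (n > 2) sqrt(sum((series$value - fitted)^2) / (n - 2)) else 0
  .new_kinetic_fit(order = 0L, k = abs(slope),
                   slope_sign = if (slope == 0) 0 else sign(slope),
                   P0 = P0, adj_r2 = .adj_r2(series$value, fitted),
                   residual_sd = res_sd, n_obs = n, series = series)
}

#' Fit a first-order (exponential) decay model
#'
#' Nonlinear least squares of `P = P0 exp(-k t)` on the original scale
#' (Levenberg-Marquardt), started from a log-linear OLS of `ln P` on day.
#' The adjusted R-squared is computed on the untransformed scale so linear
#' and exponential fits are comparable. If the optimizer fails to converge a
#' fit error is signalled (condition class `pecan_fit_error`) carrying the
#' log-linear fallback estimate in its `fallback` field.
#'
#' @param series a [color_series()]; all values must be positive.
#' @return a `kinetic_fit` with `order = 1`.
#' @export
fit_first_order <- function(series) {
  stopifnot(inherits(series, "color_series"))
  if (any(series$value <= 0)) {
    stop("first-order fitting requires strictly positive attribute values",
         call. = FALSE)
  }
  ll <- stats::lm(log(value) ~ day, data = series)
  k_start <- -unname(stats::coef(ll)[2])
  P0_start <- exp(unname(stats::coef(ll)[1]))
  fb <- list(k = abs(k_start), P0 = P0_start)
  nls_fit <- tryCatch(
    minpack.lm::nlsLM(value ~ P0 * exp(-k * day), data = series,
                      start = list(P0 = P0_start, k = k_start),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
    error = function(e) e)
  if (inherits(nls_fit, "error")) {
    cond <- structure(
      class = c("pecan_fit_error", "error", "condition"),
      list(message = paste0("first-order fit did not converge: ",
                            conditionMessage(nls_fit)),
           call = sys.call(-1), fallback = fb))
    stop(cond)
  }
  cf <- stats::coef(nls_fit)
  k <- unname(cf["k"]); P0 <- unname(cf["P0"])
  increasing <- k < 0
  if (increasing) {
    warning("attribute increases with storage day; k reported as magnitude",
            call. = FALSE)
  }
  fitted <- P0 * exp(-k * series$day)
  n <- nrow(series)
  res_sd <- if (n > 2) sqrt(sum((series$value - fitted)^2) / (n - 2)) else 0
  .new_kinetic_fit(order = 1L, k = abs(k),
                   slope_sign = if (k == 0) 0 else -sign(k),
                   P0 = P0, adj_r2 = .adj_r2(series$value, fitted),
                   residual_sd = res_sd, n_obs = n, series = series,
                   method = "nls", increasing = increasing)
}

#' Fit a series with the appropriate reaction order
#'
#' `by_attribute` applies the orders established for pecan color: zero order
#' for hue, first order for lightness and chroma. `by_fit` fits both models
#' and keeps the one with the higher adjusted R-squared (ties go to zero
#' order, the simpler model).
#'
#' @param series a [color_series()].
#' @param mode `"by_attribute"` (default) or `"by_fit"`.
#' @return a `kinetic_fit`.
#' @export
select_order <- function(series, mode = c("by_attribute", "by_fit")) {
  mode <- match.arg(mode)
  if (mode == "by_attribute") {
    if (attr(series, "attribute") == "h") {
      return(fit_zero_order(series))
    }
    return(fit_first_order(series))
  }
  f0 <- fit_zero_order(series)
  f1 <- tryCatch(fit_first_order(series), error = function(e) NULL)
  if (is.null(f1) || f0$adj_r2 >= f1$adj_r2) f0 else f1
}

#' Evaluate a fitted decay model
#'
#' Zero-order predictions are floored at 0 (color attributes cannot be
#' negative); first-order predictions are positive by construction.
#'
#' @param object a `kinetic_fit`.
#' @param t storage days (>= 0), vectorized.
#' @param ... unused.
#' @return predicted attribute value(s).
#' @export
predict.kinetic_fit <- function(object, t, ...) {
  if (any(t < 0)) stop("storage days must be nonnegative", call. = FALSE)
  signed <- if (object$slope_sign == 0) 0 else object$slope_sign * object$k
  if (object$order == 0L) {
    pmax(object$P0 + signed * t, 0)
  } else {
    object$P0 * exp(if (object$increasing) object$k * t else -object$k * t)
  }
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf(
    "%s-order kinetic fit (%s): k = %.4g /day, P0 = %.4g, adj R2 = %.3f, n = %d\n",
    if (x$order == 0L) "zero" else "first", x$attribute, x$k, x$P0,
    x$adj_r2, x$n_obs))
  if (isTRUE(x$increasing)) cat("  note: attribute increased over storage\n")
  invisible(x)
}

#' @export
coef.kinetic_fit <- function(object, ...) {
  c(P0 = object$P0, k = object$k)
}

#' Tabulate kinetic fits
#'
#' @param fits a list of `kinetic_fit` objects.
#' @return data.frame with one row per fit: cultivar, year, temp_c, rh_pct,
#'   attribute, order, k, P0, adj_r2, residual_sd, n_obs.
#' @export
fit_table <- function(fits) {
  if (inherits(fits, "kinetic_fit")) fits <- list(fits)
  do.call(rbind, lapply(fits, function(f) {
    data.frame(cultivar = f$cultivar, year = f$year, temp_c = f$temp_c,
               rh_pct = f$rh_pct, attribute = f$attribute, order = f$order,
               k = f$k, P0 = f$P0, adj_r2 = f$adj_r2,
               residual_sd = f$residual_sd, n_obs = f$n_obs,
               stringsAsFactors = FALSE)
  }))
}
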