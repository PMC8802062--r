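#' Storage days to reach a target value, zero-order kinetics
#'
#' Inverts the linear decay law: `S = (initial - final) / k`. Used for hue,
#' which declines linearly with storage time.
#'
#' @param initial,final attribute values (initial >= final).
#' @param k zero-order rate constant, day^-1 (> 0).
#' @return storage days.
#' @examples
#' storage_days_zero_order(73, 60, 0.05)   # 260
#' @export
storage_days_zero_order <- function(initial, final, k) {
  if (any(k <= 0)) stop("rate constant must be positive", call. = FALSE)
  if (any(final > initial)) {
    stop("final value exceeds initial; color lightening is outside the model",
         call. = FALSE)
  }
  (initial - final) / k
}

#' Storage days to reach a target value, first-order kinetics
#'
#' Inverts the exponential decay law: `S = ln(initial / final) / k`. Used for
#' lightness (and chroma), which decay exponentially; lightness-based
#' prediction is the recommended mode at high humidity (>= 75% RH) where the
#' change in L dominates the change in hue.
#'
#' @param initial,final positive attribute values (initial >= final).
#' @param k first-order rate constant, day^-1 (> 0).
#' @return storage days.
#' @export
storage_days_first_order <- function(initial, final, k) {
  if (any(k <= 0)) stop("rate constant must be positive", call. = FALSE)
  if (any(final <= 0)) stop("attribute values must be positive",
                            call. = FALSE)
  if (any(final > initial)) {
    stop("final value exceeds initial; color lightening is outside the model",
         call. = FALSE)
  }
  log(initial / final) / k
}

#' Rescale a storage duration to a higher temperature with Q10
#'
#' Dividing a storage duration by the Q10 of the relevant 10-degree
#' transition gives the duration at the temperature 10 degrees higher:
#' `S(T+10) = S(T) / Q10`. Supplying a vector of Q10 values chains
#' transitions (division by their product), e.g. 20 -> 40 degC.
#'
#' @param s storage days at the lower temperature (>= 0).
#' @param q10 Q10 value(s) (> 0), one per 10-degree step.
#' @return storage days at the higher temperature.
#' @examples
#' rescale_days_q10(270, 2.50)        # 108
#' rescale_days_q10(270, c(2.5, 3))   # 36, 20 degrees warmer
#' @export
rescale_days_q10 <- function(s, q10) {
  if (any(s < 0)) stop("storage days must be nonnegative", call. = FALSE)
  if (any(q10 <= 0)) stop("Q10 must be positive", call. = FALSE)
  s / prod(q10)
}

.resolve_hue <- function(grade_or_value, scale, role) {
  if (is.list(grade_or_value) || length(grade_or_value) == 3L) {
    v <- unlist(grade_or_value)
    return(list(value = v[3], grade = classify_grade(hue = v[3],
                                                     scale = scale)))
  }
  g <- as.integer(grade_or_value)
  if (g < 1L || g > 6L) stop("grade must be between 1 and 6", call. = FALSE)
  entry <- scale[g, , drop = FALSE]
  value <- if (role == "initial") {
    grade_initial_hue(g, min(g + 1L, 6L), scale = scale)
  } else {
    entry$h
  }
  list(value = value, grade = entry)
}

#' Predict storage days to reach a target color grade
#'
#' The computation behind the published color-prediction tool: given a
#' cultivar, storage temperature and relative humidity, an initial color
#' (USDA grade number or measured LCh triple) and a darker target grade, the
#' number of storage days required is predicted from the reference rate
#' constants.
#'
#' Three routes to the rate constant are available:
#' * `"lookup"` — exact match in the rate table (on-grid temperatures
#'   20/30/40 degC only).
#' * `"arrhenius"` — a two-point Arrhenius fit through the grid rates at the
#'   temperatures bracketing the request (the nearest pair when outside the
#'   grid), evaluated at the requested temperature; this passes through the
#'   grid rates, so on-grid requests reproduce the lookup. Required for
#'   off-grid temperatures.
#' * `"q10"` — predict at the nearest cooler grid temperature by lookup and
#'   rescale with the reference Q10 value(s) for the intervening 10-degree
#'   transitions.
#'
#' The initial hue for a lot given as grade `g` is the mean of the hues of
#' grades `g` and `g + 1` (the interval such a lot spans); a measured LCh
#' triple overrides it. With `attribute = "L"` the first-order law is
#' inverted on the grade lightness coordinates instead — the recommended
#' indicator at >= 75% RH.
#'
#' Relative humidity must be one of the study levels (30/50/75/80%); no
#' humidity interpolation model exists. Temperatures outside 20-40 degC are
#' extrapolations and are flagged in `notes`.
#'
#' @param cultivar one of the reference cultivars (Desirable, Pawnee,
#'   Stuart).
#' @param temp_c storage temperature, degC.
#' @param rh_pct relative humidity, percent (one of 30, 50, 75, 80).
#' @param initial USDA grade number (1-6) or measured `c(L, C, h)`.
#' @param target target USDA grade number (darker than `initial`) or target
#'   `c(L, C, h)`.
#' @param method `"lookup"`, `"arrhenius"` or `"q10"`.
#' @param attribute `"h"` (zero-order, default) or `"L"` (first-order).
#' @param rates a [reference_rates()] table.
#' @param q10s a [reference_q10()] table (used by `method = "q10"`).
#' @param scale a [pecan_scale()].
#' @return a `prediction_result`: list with `days`, `days_ceiling`, `method`,
#'   `attribute`, `initial_value`, `final_value`, `k`, `cultivar`, `temp_c`,
#'   `rh_pct` and `notes` (character vector of warnings such as
#'   extrapolation flags).
#' @examples
#' p <- predict_storage_days("Stuart", 20, 30, initial = 2, target = 4)
#' p$days   # about 302
#' @export
predict_storage_days <- function(cultivar, temp_c, rh_pct, initial = 2,
                                 target = 4,
                                 method = c("lookup", "arrhenius", "q10"),
                                 attribute = c("h", "L"),
                                 rates = reference_rates(),
                                 q10s = reference_q10(),
                                 scale = pecan_scale()) {
  method <- match.arg(method)
  attribute <- match.arg(attribute)
  notes <- character()
  if (!rh_pct %in% unique(rates$rh_pct)) {
    stop(sprintf(
      "RH %s%% is not a study level (%s); no humidity model is available",
      rh_pct, paste(sort(unique(rates$rh_pct)), collapse = ", ")),
      call. = FALSE)
  }
  if (!cultivar %in% unique(rates$cultivar)) {
    stop(sprintf("unknown cultivar '%s'; valid: %s", cultivar,
                 paste(unique(rates$cultivar), collapse = ", ")),
         call. = FALSE)
  }
  if (temp_c < 20 || temp_c > 40) {
    notes <- c(notes,
               sprintf("temperature %g degC outside the studied 20-40 range",
                       temp_c))
  }

  same_grade <- length(initial) == 1L && length(target) == 1L &&
    as.integer(initial) == as.integer(target)
  if (attribute == "h") {
    ini <- .resolve_hue(initial, scale, "initial")
    fin <- .resolve_hue(target, scale, "final")
  } else {
    grade_of <- function(x, role) {
      if (length(x) == 3L) {
        list(value = unlist(x)[1], grade = NULL)
      } else {
        g <- as.integer(x)
        if (g < 1L || g > 6L) stop("grade must be between 1 and 6",
                                   call. = FALSE)
        val <- if (role == "initial") {
          mean(scale$L_lch[c(g, min(g + 1L, 6L))])
        } else {
          scale$L_lch[g]
        }
        list(value = val, grade = scale[g, , drop = FALSE])
      }
    }
    ini <- grade_of(initial, "initial")
    fin <- grade_of(target, "final")
  }
  if (same_grade) fin$value <- ini$value  # already at the target grade
  if (fin$value > ini$value) {
    stop("target color is lighter than the initial color", call. = FALSE)
  }

  grid <- rates[rates$cultivar == cultivar & rates$rh_pct == rh_pct &
                  rates$attribute == attribute, , drop = FALSE]
  on_grid <- temp_c %in% grid$temp_c

  if (method == "lookup") {
    if (!on_grid) {
      stop(sprintf(
        "temperature %g degC is off the reference grid (%s); use method = 'arrhenius'",
        temp_c, paste(sort(grid$temp_c), collapse = ", ")), call. = FALSE)
    }
    k <- lookup_rate(cultivar, temp_c, rh_pct, attribute, rates)$k
  } else if (method == "arrhenius") {
    # rate pair at the temperatures bracketing the request (nearest pair
    # outside the grid): the two-point Arrhenius fit passes through the
    # grid rates, so on-grid requests reproduce the lookup exactly
    ord <- order(grid$temp_c)
    gt <- grid$temp_c[ord]; gk <- grid$k[ord]
    lo <- max(which(gt <= temp_c), 1L)
    lo <- min(lo, length(gt) - 1L)
    af <- fit_arrhenius(celsius_to_kelvin(gt[c(lo, lo + 1L)]),
                        gk[c(lo, lo + 1L)])
    k <- withCallingHandlers(
      interpolate_k(af, celsius_to_kelvin(temp_c)),
      warning = function(w) {
        notes <<- c(notes, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  } else { # q10
    base_temps <- sort(grid$temp_c)
    steps <- (temp_c - base_temps) / 10
    ok <- which(steps == floor(steps) & steps >= 1)
    if (!length(ok)) {
      stop("method 'q10' needs a grid temperature 10 or 20 degC below the target",
           call. = FALSE)
    }
    base_t <- max(base_temps[ok])
    k_base <- lookup_rate(cultivar, base_t, rh_pct, attribute, rates)$k
    s_base <- if (attribute == "h") {
      storage_days_zero_order(ini$value, fin$value, k_base)
    } else {
      storage_days_first_order(ini$value, fin$value, k_base)
    }
    q <- numeric(0)
    for (t0 in seq(base_t, temp_c - 10, by = 10)) {
      tr <- sprintf("%d-%d", t0, t0 + 10)
      row <- q10s[q10s$transition == tr & q10s$rh_pct == rh_pct, ,
                  drop = FALSE]
      if (nrow(row) != 1L) {
        stop(sprintf("no reference Q10 for transition %s at %s%% RH",
                     tr, rh_pct), call. = FALSE)
      }
      q <- c(q, row$q10)
    }
    s <- rescale_days_q10(s_base, q)
    return(structure(list(
      days = s, days_ceiling = ceiling(s), method = "q10_rescaled",
      attribute = attribute, initial_value = ini$value,
      final_value = fin$value, k = k_base / prod(q), cultivar = cultivar,
      temp_c = temp_c, rh_pct = rh_pct, q10 = q,
      notes = notes), class = "prediction_result"))
  }

  s <- if (attribute == "h") {
    storage_days_zero_order(ini$value, fin$value, k)
  } else {
    storage_days_first_order(ini$value, fin$value, k)
  }
  structure(list(
    days = s, days_ceiling = ceiling(s),
    method = if (method == "lookup") "lookup" else "arrhenius_interpolated",
    attribute = attribute, initial_value = ini$value, final_value = fin$value,
    k = k, cultivar = cultivar, temp_c = temp_c, rh_pct = rh_pct,
    notes = notes), class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf(
    "%s at %g degC / %g%% RH: %s %.4g -> %.4g in %.1f days (%.0f whole days, %s, k = %.4g /day)\n",
    x$cultivar, x$temp_c, x$rh_pct, x$attribute, x$initial_value,
    x$final_value, x$days, x$days_ceiling, x$method, x$k))
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Days to reach each successive color grade
#'
#' Cumulative storage days for a lot to darken from its initial grade through
#' every darker grade on the scale, at one condition — a textual rendering of
#' the color-timeline illustration of the prediction tool.
#'
#' @inheritParams predict_storage_days
#' @param to_grade last grade to include (default 6).
#' @return data.frame with columns `grade_number`, `name`, `hue`, `days`
#'   (monotone nondecreasing), starting at the initial grade with 0 days.
#' @examples
#' grade_timeline("Stuart", 20, 30, initial = 2)
#' @export
grade_timeline <- function(cultivar, temp_c, rh_pct, initial = 2,
                           to_grade = 6,
                           method = c("lookup", "arrhenius", "q10"),
                           rates = reference_rates(),
                           q10s = reference_q10(),
                           scale = pecan_scale()) {
  method <- match.arg(method)
  g0 <- if (length(initial) == 3L) {
    classify_grade(hue = unlist(initial)[3], scale = scale)$grade_number
  } else {
    as.integer(initial)
  }
  if (to_grade < g0) stop("to_grade must not be lighter than the initial grade",
                          call. = FALSE)
  grades <- g0:to_grade
  days <- vapply(grades, function(g) {
    if (g == g0) return(0)
    predict_storage_days(cultivar, temp_c, rh_pct, initial = initial,
                         target = g, method = method, rates = rates,
                         q10s = q10s, scale = scale)$days
  }, numeric(1))
  data.frame(grade_number = grades, name = scale$name[grades],
             hue = scale$h[grades], days = days, stringsAsFactors = FALSE)
}
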