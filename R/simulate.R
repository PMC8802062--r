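#' Storage-experiment design for simulation
#'
#' Encodes the study layout: 3 temperatures x 4 relative humidities, 3
#' cultivars grown in 2 crop years, duplicate storage chambers per condition
#' and 3 pseudo-replicate color readings per sample, with 5 sampling
#' occasions plus a day-0 baseline. Sampling days default to six evenly
#' spaced occasions from 0 to the condition's terminal day in the packaged
#' storage matrix (15-450 days depending on condition), rounded to whole
#' days.
#'
#' @param temperatures storage temperatures, degC.
#' @param rh_levels relative humidities, percent.
#' @param cultivars,years labels.
#' @param replicates storage chambers per condition.
#' @param pseudo_replicates color readings per chamber and occasion.
#' @param n_occasions sampling occasions including the day-0 baseline.
#' @param terminal_days data.frame like [storage_design()] giving the last
#'   sampling day per condition.
#' @return a `simulation_design` list; `sampling_days` is a list keyed
#'   `"<temp>_<rh>"`.
#' @export
simulation_design <- function(temperatures = c(20, 30, 40),
                              rh_levels = c(30, 50, 75, 80),
                              cultivars = c("Desirable", "Pawnee", "Stuart"),
                              years = c("2018", "2019"),
                              replicates = 2, pseudo_replicates = 3,
                              n_occasions = 6,
                              terminal_days = storage_design()) {
  stopifnot(replicates >= 1, pseudo_replicates >= 1, n_occasions >= 3)
  sampling_days <- list()
  for (tc in temperatures) {
    for (rh in rh_levels) {
      row <- terminal_days[terminal_days$temp_c == tc &
                             terminal_days$rh_pct == rh, , drop = FALSE]
      if (nrow(row) != 1L) {
        stop(sprintf("no terminal day for %g degC / %g%% RH", tc, rh),
             call. = FALSE)
      }
      days <- round(seq(0, row$terminal_day, length.out = n_occasions))
      sampling_days[[sprintf("%g_%g", tc, rh)]] <- days
    }
  }
  structure(list(temperatures = temperatures, rh_levels = rh_levels,
                 cultivars = cultivars, years = years,
                 replicates = replicates,
                 pseudo_replicates = pseudo_replicates,
                 sampling_days = sampling_days),
            class = "simulation_design")
}

#' Generative parameters for the simulator
#'
#' The "truth" a simulated experiment is drawn from. Per attribute: the decay
#' order (zero for hue, first for lightness and chroma), a baseline value
#' `P0` (a fresh cream-grade lot: hue ~79 degrees, L ~72, C ~27), a
#' measurement noise SD, and per-RH Arrhenius parameters `(k0, Ea)`. By
#' default the Arrhenius parameters are derived from the packaged reference
#' rates: for each RH and attribute an Arrhenius curve is fitted through the
#' cross-cultivar mean rate at each grid temperature, so simulated rates have
#' the magnitudes observed in stored pecans (hue k roughly 0.03-1.3 per day
#' across 20-40 degC). Cultivar rate multipliers (geometric-mean deviation of
#' each cultivar's hue rates from the cross-cultivar geometric mean) and a
#' small per-cultivar baseline shift provide between-cultivar spread.
#'
#' @param rates a [reference_rates()] table used to seed default magnitudes.
#' @param noise_sd named numeric: measurement SD per attribute, in attribute
#'   units (hue in degrees).
#' @param p0 named numeric: baseline value per attribute.
#' @param cultivar_p0_shift named numeric: additive baseline shift per
#'   cultivar (applied to every attribute).
#' @return a `true_parameters` list with elements `attributes` (per-attribute
#'   list of `order`, `p0`, `noise_sd`, `arrhenius` data.frame of
#'   `rh_pct`, `k0`, `ea`), `cultivar_multipliers`, `cultivar_p0_shift`.
#' @export
true_parameters <- function(rates = reference_rates(),
                            noise_sd = c(h = 1.5, L = 1.0, C = 1.0),
                            p0 = c(h = 79, L = 72, C = 27),
                            cultivar_p0_shift = c(Desirable = -1,
                                                  Pawnee = 0,
                                                  Stuart = 1)) {
  stopifnot(all(noise_sd >= 0), all(p0 > 0))
  attrs <- list()
  for (a in c("h", "L", "C")) {
    sub <- rates[rates$attribute == a, , drop = FALSE]
    arr <- list()
    for (rh in sort(unique(sub$rh_pct))) {
      cell <- sub[sub$rh_pct == rh, , drop = FALSE]
      km <- tapply(cell$k, cell$temp_c, mean)
      af <- fit_arrhenius(celsius_to_kelvin(as.numeric(names(km))),
                          as.numeric(km))
      arr[[length(arr) + 1L]] <- data.frame(rh_pct = rh, k0 = af$k0,
                                            ea = af$ea)
    }
    attrs[[a]] <- list(order = if (a == "h") 0L else 1L,
                       p0 = unname(p0[a]), noise_sd = unname(noise_sd[a]),
                       arrhenius = do.call(rbind, arr))
  }
  hue <- rates[rates$attribute == "h", , drop = FALSE]
  lk <- stats::aggregate(log(hue$k),
                         by = list(cultivar = hue$cultivar), FUN = mean)
  mult <- exp(lk$x - mean(lk$x))
  names(mult) <- lk$cultivar
  structure(list(attributes = attrs, cultivar_multipliers = mult,
                 cultivar_p0_shift = cultivar_p0_shift),
            class = "true_parameters")
}

#' True rate constant implied by the generative parameters
#'
#' `k = multiplier * k0 * exp(-Ea / (R T))` for one cultivar, RH, attribute
#' and temperature.
#'
#' @param truth a [true_parameters()] object.
#' @param cultivar,rh_pct,attribute,temp_c condition.
#' @return rate constant, day^-1.
#' @export
true_k <- function(truth, cultivar, rh_pct, attribute, temp_c) {
  at <- truth$attributes[[attribute]]
  row <- at$arrhenius[at$arrhenius$rh_pct == rh_pct, , drop = FALSE]
  if (nrow(row) != 1L) stop("no generative parameters for RH ", rh_pct,
                            call. = FALSE)
  mult <- truth$cultivar_multipliers[[cultivar]]
  if (is.null(mult)) mult <- 1
  mult * row$k0 * exp(-row$ea / (R_GAS * celsius_to_kelvin(temp_c)))
}

.decay_mean <- function(order, p0, k, day) {
  if (order == 0L) pmax(p0 - k * day, 0) else p0 * exp(-k * day)
}

#' Simulate a storage experiment
#'
#' Draws a complete long-format dataset under the study design: per condition
#' the rate constant follows the generative Arrhenius law, hue declines
#' linearly and lightness/chroma exponentially, and independent Gaussian
#' measurement noise is added to every pseudo-replicate reading. Values are
#' clipped to physical ranges (nonnegative; hue below 360). Deterministic
#' given `seed`.
#'
#' @param design a [simulation_design()].
#' @param truth a [true_parameters()] object.
#' @param seed integer seed for the noise draws.
#' @return a `simulated_dataset` data.frame with columns `cultivar`, `year`,
#'   `temperature_C`, `rh_pct`, `day`, `replicate`, `pseudo_replicate`, `L`,
#'   `C`, `h`, and the generative `truth` (plus `design` and `seed`) attached
#'   as attributes for recovery scoring.
#' @examples
#' d <- simulate_experiment(seed = 1)
#' nrow(d)   # 2592
#' @export
simulate_experiment <- function(design = simulation_design(),
                                truth = true_parameters(), seed = 1) {
  stopifnot(inherits(design, "simulation_design"),
            inherits(truth, "true_parameters"))
  set.seed(as.integer(seed))
  blocks <- list()
  for (cv in design$cultivars) for (yr in design$years) {
    for (tc in design$temperatures) for (rh in design$rh_levels) {
      days <- design$sampling_days[[sprintf("%g_%g", tc, rh)]]
      g <- expand.grid(pseudo_replicate = seq_len(design$pseudo_replicates),
                       replicate = seq_len(design$replicates),
                       day = days, KEEP.OUT.ATTRS = FALSE)
      n <- nrow(g)
      vals <- list()
      for (a in c("L", "C", "h")) {
        at <- truth$attributes[[a]]
        k <- true_k(truth, cv, rh, a, tc)
        p0 <- at$p0 + truth$cultivar_p0_shift[[cv]]
        mu <- .decay_mean(at$order, p0, k, g$day)
        v <- mu + stats::rnorm(n, 0, at$noise_sd)
        v <- pmax(v, 0)
        if (a == "h") v <- pmin(v, 360 - 1e-9)
        vals[[a]] <- v
      }
      blocks[[length(blocks) + 1L]] <- data.frame(
        cultivar = cv, year = yr, temperature_C = tc, rh_pct = rh,
        day = g$day, replicate = g$replicate,
        pseudo_replicate = g$pseudo_replicate,
        L = vals$L, C = vals$C, h = vals$h, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  attr(out, "truth") <- truth
  attr(out, "design") <- design
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("simulated_dataset", "data.frame")
  out
}

#' Recover generative parameters from a simulated dataset
#'
#' The acceptance surface for the whole pipeline: pools years, replicates and
#' pseudo-replicates into one series per cultivar x temperature x RH x
#' attribute, fits the decay model ([select_order()]), then fits an Arrhenius
#' curve per cultivar x RH x attribute across temperatures, and scores every
#' estimate against the embedded truth. Readings clipped to zero (possible
#' for nearly fully faded lightness/chroma under noise) are treated as
#' censored and dropped before first-order fitting. Fit failures are
#' summarized, not raised.
#'
#' @param data a [simulate_experiment()] result (truth attached).
#' @param mode order-selection mode passed to [select_order()].
#' @return a `recovery_report`: list with `k_table` (per-condition true and
#'   estimated rate, relative error), `ea_table` (per cultivar x RH x
#'   attribute), `summary` (median/RMS relative errors and bias), `n_failed`.
#' @export
recover_parameters <- function(data, mode = c("by_attribute", "by_fit")) {
  mode <- match.arg(mode)
  truth <- attr(data, "truth")
  if (is.null(truth)) stop("dataset carries no embedded truth", call. = FALSE)
  k_rows <- list(); failed <- 0L
  for (cv in unique(data$cultivar)) for (rh in unique(data$rh_pct)) {
    for (tc in unique(data$temperature_C)) for (a in c("L", "C", "h")) {
      sub <- data[data$cultivar == cv & data$rh_pct == rh &
                    data$temperature_C == tc, , drop = FALSE]
      v <- sub[[a]]
      keep <- if (truth$attributes[[a]]$order == 1L) v > 0 else is.finite(v)
      fit <- tryCatch({
        s <- color_series(sub$day[keep], v[keep], a, tc, rh, cv)
        suppressWarnings(select_order(s, mode))
      }, error = function(e) NULL)
      if (is.null(fit)) { failed <- failed + 1L; next }
      kt <- true_k(truth, cv, rh, a, tc)
      k_rows[[length(k_rows) + 1L]] <- data.frame(
        cultivar = cv, rh_pct = rh, temp_c = tc, attribute = a,
        order = fit$order, k_true = kt, k_hat = fit$k,
        rel_err = (fit$k - kt) / kt, stringsAsFactors = FALSE)
    }
  }
  k_table <- do.call(rbind, k_rows)
  ea_rows <- list()
  for (cv in unique(k_table$cultivar)) for (rh in unique(k_table$rh_pct)) {
    for (a in c("L", "C", "h")) {
      sub <- k_table[k_table$cultivar == cv & k_table$rh_pct == rh &
                       k_table$attribute == a, , drop = FALSE]
      if (nrow(sub) < 2L || any(sub$k_hat <= 0)) { failed <- failed + 1L; next }
      af <- tryCatch(fit_arrhenius(celsius_to_kelvin(sub$temp_c), sub$k_hat),
                     error = function(e) NULL)
      if (is.null(af)) { failed <- failed + 1L; next }
      at <- truth$attributes[[a]]
      ea_true <- at$arrhenius$ea[at$arrhenius$rh_pct == rh]
      ea_rows[[length(ea_rows) + 1L]] <- data.frame(
        cultivar = cv, rh_pct = rh, attribute = a, ea_true = ea_true,
        ea_hat = af$ea, rel_err = (af$ea - ea_true) / ea_true,
        stringsAsFactors = FALSE)
    }
  }
  ea_table <- do.call(rbind, ea_rows)
  summary <- c(
    k_median_rel_err = stats::median(abs(k_table$rel_err)),
    k_rel_rmse = sqrt(mean(k_table$rel_err^2)),
    k_bias = mean(k_table$rel_err),
    ea_median_rel_err = stats::median(abs(ea_table$rel_err)),
    ea_rel_rmse = sqrt(mean(ea_table$rel_err^2)))
  structure(list(k_table = k_table, ea_table = ea_table, summary = summary,
                 n_failed = failed),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(
    "parameter recovery: %d rate constants, %d Arrhenius fits, %d failures\n",
    nrow(x$k_table), nrow(x$ea_table), x$n_failed))
  cat(sprintf("  k:  median |rel err| = %.3f, rel RMSE = %.3f, bias = %+.3f\n",
              x$summary["k_median_rel_err"], x$summary["k_rel_rmse"],
              x$summary["k_bias"]))
  cat(sprintf("  Ea: median |rel err| = %.3f, rel RMSE = %.3f\n",
              x$summary["ea_median_rel_err"], x$summary["ea_rel_rmse"]))
  invisible(x)
}
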