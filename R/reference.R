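#' Published reference rate constants
#'
#' The packaged per-condition rate constants for three cultivars (Desirable,
#' Pawnee, Stuart) at 20/30/40 degC and 30/50/75/80% RH, for each color
#' attribute (L, C, h), together with the published per-(cultivar, RH,
#' attribute) activation energies. Rate constants are magnitudes (day^-1);
#' all attributes decline during storage.
#'
#' @param path optional alternative CSV with the same columns.
#' @return data.frame with columns `cultivar`, `temp_c`, `rh_pct`,
#'   `attribute`, `k`, `k_sd`, `adj_r2`, `ea_kj_mol`, `ea_sd`.
#' @export
reference_rates <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table4_rates.csv", package = "pecancolor",
                        mustWork = TRUE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("cultivar", "temp_c", "rh_pct", "attribute", "k")
  miss <- setdiff(needed, names(df))
  if (length(miss)) {
    stop("rate table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$k < 0)) stop("rate constants must be nonnegative", call. = FALSE)
  df
}

#' Published reference Q10 coefficients (hue)
#'
#' Mean Q10 of the hue rate constant over the three cultivars for each
#' relative humidity and each 10-degree transition (20->30, 30->40 degC).
#'
#' @param path optional alternative CSV with the same columns.
#' @return data.frame with columns `transition`, `rh_pct`, `q10`, `q10_sd`.
#' @export
reference_q10 <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table5_q10.csv", package = "pecancolor",
                        mustWork = TRUE)
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Storage-duration matrix of the study design
#'
#' Terminal storage day for every temperature x relative-humidity condition;
#' warmer and more humid conditions were followed for shorter times (15-450
#' days). Used as the default sampling horizon by [simulation_design()].
#'
#' @param path optional alternative CSV with the same columns.
#' @return data.frame with columns `temp_c`, `rh_pct`, `terminal_day`.
#' @export
storage_design <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table2_storage_days.csv",
                        package = "pecancolor", mustWork = TRUE)
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Look up a reference rate constant
#'
#' Exact-match lookup in a reference rate table; unknown keys produce an
#' error listing the valid values.
#'
#' @param cultivar,temp_c,rh_pct,attribute lookup key.
#' @param rates a [reference_rates()] table.
#' @return the matched one-row data.frame.
#' @export
lookup_rate <- function(cultivar, temp_c, rh_pct, attribute = "h",
                        rates = reference_rates()) {
  hit <- rates[rates$cultivar == cultivar & rates$temp_c == temp_c &
                 rates$rh_pct == rh_pct & rates$attribute == attribute, ,
               drop = FALSE]
  if (nrow(hit) != 1L) {
    stop(sprintf(
      paste0("no reference rate for (%s, %s degC, %s%% RH, %s); valid ",
             "cultivars: %s; temperatures: %s; RH: %s; attributes: %s"),
      cultivar, temp_c, rh_pct, attribute,
      paste(unique(rates$cultivar), collapse = ", "),
      paste(sort(unique(rates$temp_c)), collapse = ", "),
      paste(sort(unique(rates$rh_pct)), collapse = ", "),
      paste(unique(rates$attribute), collapse = ", ")), call. = FALSE)
  }
  hit
}

#' Cross-cultivar Q10 table from a rate table
#'
#' Recomputes the hue Q10 summary from per-condition rate constants: for each
#' RH and each 10-degree transition, the rate ratio is taken per cultivar and
#' the unweighted mean (and SD) over cultivars is reported.
#'
#' @param rates a [reference_rates()]-shaped table.
#' @param attribute color attribute (default `"h"`).
#' @return data.frame with columns `transition`, `rh_pct`, `q10`, `q10_sd`,
#'   `n_cultivars`.
#' @export
q10_table <- function(rates = reference_rates(), attribute = "h") {
  rates <- rates[rates$attribute == attribute, , drop = FALSE]
  temps <- sort(unique(rates$temp_c))
  out <- list()
  for (i in seq_len(length(temps) - 1L)) {
    t1 <- temps[i]; t2 <- temps[i + 1L]
    for (rh in sort(unique(rates$rh_pct))) {
      k1 <- rates[rates$temp_c == t1 & rates$rh_pct == rh, ]
      k2 <- rates[rates$temp_c == t2 & rates$rh_pct == rh, ]
      k2 <- k2[match(k1$cultivar, k2$cultivar), ]
      ratio <- k2$k / k1$k
      out[[length(out) + 1L]] <- data.frame(
        transition = sprintf("%d-%d", t1, t2), rh_pct = rh,
        q10 = mean(ratio), q10_sd = stats::sd(ratio),
        n_cultivars = length(ratio), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
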