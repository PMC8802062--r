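#' Read long-format color measurements
#'
#' Reads a comma-separated file with header columns `cultivar`, `year`,
#' `temperature_C`, `rh_pct`, `day`, `replicate` and one column per color
#' attribute (`L`, `C`, `h`; any subset), the format written by
#' [write_measurements()]. Rows are grouped into one [color_series()] per
#' cultivar x year x temperature x RH x attribute; replicate and
#' pseudo-replicate readings are pooled as observations. Blank attribute
#' cells are skipped for that attribute only. Malformed rows (unparsable
#' numbers, hue outside \[0, 360), negative days) are collected and reported
#' together in a single error.
#'
#' @param path file path.
#' @return named list of `color_series` (possibly empty, with a warning for
#'   an empty file); names are `cultivar_year_temp_rh_attribute`.
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("cultivar", "year", "temperature_C", "rh_pct", "day",
                "replicate")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("missing required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  attrs <- intersect(c("L", "C", "h"), names(df))
  if (!length(attrs)) {
    stop("no attribute columns (L, C, h) found", call. = FALSE)
  }
  if (nrow(df) == 0L) {
    warning("empty measurement file: ", path, call. = FALSE)
    return(list())
  }
  problems <- character()
  num <- function(col) {
    x <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.na(df[[col]]) & nzchar(trimws(df[[col]])) & is.na(x))
    if (length(bad)) {
      problems <<- c(problems, sprintf("row %d: unparsable %s '%s'",
                                       bad + 1L, col, df[[col]][bad]))
    }
    x
  }
  day <- num("day")
  bad_day <- which(!is.na(day) & day < 0)
  if (length(bad_day)) {
    problems <- c(problems, sprintf("row %d: negative day", bad_day + 1L))
  }
  vals <- lapply(attrs, num)
  names(vals) <- attrs
  if ("h" %in% attrs) {
    bad_h <- which(!is.na(vals$h) & (vals$h < 0 | vals$h >= 360))
    if (length(bad_h)) {
      problems <- c(problems,
                    sprintf("row %d: hue outside [0, 360)", bad_h + 1L))
    }
  }
  if (length(problems)) {
    stop("invalid rows in ", path, ":\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  key <- interaction(df$cultivar, df$year, df$temperature_C, df$rh_pct,
                     sep = "_", drop = TRUE)
  out <- list()
  for (kk in levels(key)) {
    idx <- key == kk
    for (a in attrs) {
      v <- vals[[a]][idx]
      keep <- !is.na(v)
      if (sum(keep) == 0L) next
      s <- color_series(day[idx][keep], v[keep], a,
                        temp_c = as.numeric(df$temperature_C[idx][1]),
                        rh_pct = as.numeric(df$rh_pct[idx][1]),
                        cultivar = df$cultivar[idx][1],
                        year = df$year[idx][1],
                        replicate = df$replicate[idx][keep])
      out[[paste(kk, a, sep = "_")]] <- s
    }
  }
  out
}

#' Write a measurement dataset
#'
#' Writes a (simulated or assembled) long-format dataset as the CSV dialect
#' read by [read_measurements()]: comma-separated, UTF-8, '.' decimal, no
#' degree symbols.
#'
#' @param data data.frame with the long-format columns.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fit every series in a measurement set
#'
#' Lightness/chroma readings clipped at zero are treated as censored and
#' dropped before the exponential fit; series that cannot be fitted (too few
#' distinct days, optimizer failure) are omitted from the table rather than
#' raising.
#'
#' @param series a list of [color_series()] (from [read_measurements()]) or
#'   a long-format data.frame / [simulate_experiment()] result.
#' @param mode order-selection mode, see [select_order()].
#' @param pool_years pool crop years into one series per condition
#'   (default FALSE: one fit per cultivar x year x condition x attribute).
#' @return data.frame of fits, one row per series (see [fit_table()]).
#' @export
fit_all <- function(series, mode = c("by_attribute", "by_fit"),
                    pool_years = FALSE) {
  mode <- match.arg(mode)
  if (is.data.frame(series)) {
    tmp <- tempfile(fileext = ".csv")
    on.exit(unlink(tmp))
    if (pool_years) {
      series <- within(as.data.frame(series), year <- "pooled")
    }
    write_measurements(series, tmp)
    series <- read_measurements(tmp)
  }
  fits <- lapply(series, function(s) {
    if (attr(s, "attribute") != "h" && any(s$value <= 0)) {
      # readings clipped at zero are censored; drop before exponential fits
      keep <- s$value > 0
      s <- tryCatch(
        color_series(s$day[keep], s$value[keep], attr(s, "attribute"),
                     attr(s, "temp_c"), attr(s, "rh_pct"),
                     attr(s, "cultivar"), attr(s, "year"),
                     s$replicate[keep]),
        error = function(e) NULL)
      if (is.null(s)) return(NULL)
    }
    tryCatch(suppressWarnings(select_order(s, mode)),
             error = function(e) NULL)
  })
  fit_table(Filter(Negate(is.null), fits))
}

#' Write a results table
#'
#' Deterministic column order; `csv` and `json` write full precision, the
#' `text` report rounds rate constants to 3 decimals and activation energies
#' (kJ/mol) to 2, the precision of the published tables.
#'
#' @param results data.frame (e.g. from [fit_all()] or [q10_table()]).
#' @param path output path.
#' @param format one of `"csv"`, `"json"`, `"text"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("csv", "json", "text")) {
  format <- match.arg(format)
  results <- as.data.frame(results)
  if (format == "csv") {
    utils::write.csv(results, path, row.names = FALSE)
  } else if (format == "json") {
    jsonlite::write_json(results, path, dataframe = "rows", digits = NA,
                         pretty = TRUE)
  } else {
    disp <- results
    for (cl in intersect(c("k", "k_hat", "k_true", "k_sd"), names(disp))) {
      disp[[cl]] <- sprintf("%.3f", disp[[cl]])
    }
    for (cl in intersect(c("ea_kj_mol", "ea_kj"), names(disp))) {
      disp[[cl]] <- sprintf("%.2f", disp[[cl]])
    }
    writeLines(c(paste(names(disp), collapse = "\t"),
                 apply(disp, 1, paste, collapse = "\t")), path)
  }
  invisible(path)
}
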