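#' The digitized USDA six-grade pecan color scale
#'
#' Loads the packaged digitization of the USDA pecan color rating scale:
#' six grades from light cream (grade 1, hue ~88 degrees) to dark reddish
#' brown (grade 6, hue ~37 degrees), each with Munsell notation and sRGB,
#' CIELAB and LCh coordinates. Munsell hue/value/chroma are carried as
#' annotation only; no renotation math is performed.
#'
#' Grade boundaries used for classification are the hue midpoints between
#' consecutive grades.
#'
#' @param path optional path to an alternative scale file with the same
#'   columns; defaults to the packaged scale.
#' @return a `grade_scale`: a data.frame with one row per grade (columns
#'   `grade_number`, `name`, `munsell_hue`, `munsell_value`, `munsell_chroma`,
#'   `r`, `g`, `b`, `L_lab`, `a`, `b_lab`, `L_lch`, `C`, `h`) and a
#'   `boundaries` attribute of 5 decreasing hue values.
#' @examples
#' sc <- pecan_scale()
#' sc$h                     # 88 79 67 60 49 37
#' attr(sc, "boundaries")
#' @export
pecan_scale <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table3_scale.csv", package = "pecancolor",
                        mustWork = TRUE)
  }
  sc <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_grade_scale(sc)
}

#' Construct and validate a grade scale
#'
#' @param df data.frame with the columns documented in [pecan_scale()].
#' @return validated `grade_scale` object with hue boundaries attached.
#' @export
as_grade_scale <- function(df) {
  needed <- c("grade_number", "name", "r", "g", "b",
              "L_lab", "a", "b_lab", "L_lch", "C", "h")
  miss <- setdiff(needed, names(df))
  if (length(miss)) {
    stop("grade scale is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- df[order(df$grade_number), , drop = FALSE]
  if (nrow(df) != 6L || !identical(as.integer(df$grade_number), 1:6)) {
    stop("grade scale must contain exactly grades 1 through 6", call. = FALSE)
  }
  if (any(diff(df$h) >= 0)) {
    stop("grade hue must be strictly decreasing with grade number",
         call. = FALSE)
  }
  bounds <- (df$h[-6] + df$h[-1]) / 2
  stopifnot(all(diff(bounds) < 0), all(bounds < df$h[-6] & bounds > df$h[-1]))
  attr(df, "boundaries") <- bounds
  class(df) <- c("grade_scale", "data.frame")
  df
}

#' @export
print.grade_scale <- function(x, ...) {
  cat("USDA pecan color scale (6 grades, hue", max(x$h), "->", min(x$h),
      "deg)\n")
  print.data.frame(x, row.names = FALSE)
  cat("hue boundaries:", paste(round(attr(x, "boundaries"), 2),
                               collapse = ", "), "\n")
  invisible(x)
}

#' Classify a color into a USDA grade
#'
#' Assigns the grade whose hue interval contains the color's hue angle.
#' Intervals are delimited by the midpoints between consecutive grade hues,
#' open-ended at grades 1 and 6. A hue exactly on a boundary classifies to
#' the darker (higher-numbered) grade — conservative for quality grading.
#'
#' @param lch length-3 `c(L, C, h)` vector, an n x 3 matrix, or a bare
#'   numeric vector of hue angles via `hue =`.
#' @param scale a [pecan_scale()] object.
#' @param hue alternative to `lch`: hue angle(s) in degrees.
#' @return one-row (or n-row) data.frame slice of the scale: the matched
#'   grade entries.
#' @examples
#' classify_grade(hue = 60)$name   # "Light brown"
#' classify_grade(c(81, 28, 88))$grade_number
#' @export
classify_grade <- function(lch = NULL, scale = pecan_scale(), hue = NULL) {
  if (is.null(hue)) {
    if (is.null(lch)) stop("supply either lch or hue", call. = FALSE)
    x <- if (is.null(dim(lch))) matrix(lch, nrow = 1) else as.matrix(lch)
    hue <- x[, 3]
  }
  bounds <- attr(scale, "boundaries")
  idx <- vapply(hue, function(h) 1L + sum(h <= bounds), integer(1))
  out <- scale[idx, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}

#' Representative starting hue for a graded lot
#'
#' A lot judged to be a given grade spans the hue interval between that
#' grade's coordinate and the next darker grade's; the representative initial
#' hue is the arithmetic mean of the two. A cream lot (grade 2, 79 degrees,
#' bounded below by golden at 67 degrees) starts at 73 degrees.
#'
#' @param grade_from,grade_adjacent grade numbers (1-6); must be equal or
#'   adjacent on the scale.
#' @param scale a [pecan_scale()] object.
#' @return hue angle in degrees.
#' @examples
#' grade_initial_hue(3, 2)   # 73
#' @export
grade_initial_hue <- function(grade_from, grade_adjacent, scale = pecan_scale()) {
  g1 <- as.integer(grade_from); g2 <- as.integer(grade_adjacent)
  if (any(c(g1, g2) < 1L) || any(c(g1, g2) > 6L)) {
    stop("grades must be between 1 and 6", call. = FALSE)
  }
  if (abs(g1 - g2) > 1L) {
    stop("grades must be adjacent on the scale", call. = FALSE)
  }
  mean(scale$h[c(g1, g2)])
}
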