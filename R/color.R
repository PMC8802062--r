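#' pecancolor: kinetics and prediction of pecan nutmeat color degradation
#'
#' Models the loss of pecan nutmeat color during storage as chemical kinetics:
#' hue angle declines linearly with storage time (zero order) while lightness
#' and chroma decay exponentially (first order). Rate constants fitted per
#' temperature x relative-humidity condition feed an Arrhenius analysis
#' (activation energy, Q10) and a shelf-life predictor that reports the days
#' required to darken from one USDA color grade to another.
#'
#' @section Main entry points:
#' * [pecan_scale()], [classify_grade()] — the digitized USDA 6-grade scale.
#' * [fit_zero_order()], [fit_first_order()], [select_order()] — decay fits.
#' * [fit_arrhenius()], [q10_from_rates()], [q10_from_ea()] — temperature
#'   dependence of the rate constants.
#' * [predict_storage_days()], [grade_timeline()] — shelf-life prediction from
#'   the packaged reference rate tables.
#' * [simulate_experiment()], [recover_parameters()] — synthetic
#'   storage-experiment data and a parameter-recovery harness.
#'
#' @keywords internal
"_PACKAGE"

# Ideal gas constant, J mol^-1 K^-1
R_GAS <- 8.314

# D65/2-degree reference white (CIE XYZ, Y normalized to 1)
.d65 <- c(0.95047, 1.0, 1.08883)

# sRGB (IEC 61966-2-1) linear RGB -> XYZ matrix, D65
.rgb2xyz <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041), nrow = 3, byrow = TRUE)
.xyz2rgb <- solve(.rgb2xyz)

#' Convert Celsius to Kelvin
#'
#' @param temp_c temperature in degrees Celsius.
#' @return temperature in Kelvin (`temp_c + 273.15`).
#' @export
celsius_to_kelvin <- function(temp_c) temp_c + 273.15

#' Round half away from zero
#'
#' Display rounding used for color coordinates: 0.5 always rounds up in
#' magnitude (base `round()` rounds half to even), matching the integer
#' coordinates of the packaged grade scale.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  trunc(x * m + 0.5 * sign(x)) / m
}

.as_rgb_matrix <- function(rgb) {
  if (is.null(dim(rgb))) rgb <- matrix(rgb, nrow = 1)
  rgb <- as.matrix(rgb)
  if (ncol(rgb) != 3) stop("RGB input must have 3 channels", call. = FALSE)
  if (any(!is.finite(rgb)) || any(rgb < 0) || any(rgb > 255)) {
    stop("RGB channels must lie in [0, 255]", call. = FALSE)
  }
  rgb
}

.as_lab_matrix <- function(lab) {
  if (is.null(dim(lab))) lab <- matrix(lab, nrow = 1)
  lab <- as.matrix(lab)
  if (ncol(lab) != 3) stop("Lab input must have 3 components", call. = FALSE)
  if (any(!is.finite(lab)) || any(lab[, 1] < 0) || any(lab[, 1] > 100)) {
    stop("Lab lightness must lie in [0, 100]", call. = FALSE)
  }
  lab
}

#' Convert sRGB to CIELAB
#'
#' Standard sRGB gamma expansion, linear RGB to XYZ with the sRGB/D65 matrix,
#' then XYZ to CIE 1976 L*a*b* under the D65/2-degree white point. Values are
#' returned unrounded; use [round_half_up()] for integer display.
#'
#' @param rgb length-3 vector `c(r, g, b)` or an n x 3 matrix of 8-bit sRGB
#'   channel values in \[0, 255\].
#' @return named vector (or matrix) with components `L`, `a`, `b`.
#' @examples
#' srgb_to_lab(c(223, 200, 150))           # pale cream, L ~ 81
#' round_half_up(srgb_to_lab(c(105, 61, 52)))
#' @export
srgb_to_lab <- function(rgb) {
  x <- .as_rgb_matrix(rgb)
  v <- x / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  xyz <- lin %*% t(.rgb2xyz)
  r <- sweep(xyz, 2, .d65, "/")
  eps <- (6 / 29)^3
  f <- ifelse(r > eps, r^(1 / 3), r / (3 * (6 / 29)^2) + 4 / 29)
  out <- cbind(L = 116 * f[, 2] - 16,
               a = 500 * (f[, 1] - f[, 2]),
               b = 200 * (f[, 2] - f[, 3]))
  if (is.null(dim(rgb))) drop(out) else out
}

#' Convert CIELAB to sRGB
#'
#' Inverse of [srgb_to_lab()]. Out-of-gamut channels are clipped to
#' \[0, 255\]; when clipping occurs the result carries the attribute
#' `out_of_gamut = TRUE`.
#'
#' @param lab length-3 vector `c(L, a, b)` or an n x 3 matrix.
#' @param round round channels half-up to integers (default `TRUE`).
#' @return vector (or matrix) with components `r`, `g`, `b` in \[0, 255\],
#'   with an `out_of_gamut` logical attribute.
#' @examples
#' lab_to_srgb(srgb_to_lab(c(202, 171, 128)))
#' @export
lab_to_srgb <- function(lab, round = TRUE) {
  x <- .as_lab_matrix(lab)
  fy <- (x[, 1] + 16) / 116
  fx <- fy + x[, 2] / 500
  fz <- fy - x[, 3] / 200
  finv <- function(f) ifelse(f > 6 / 29, f^3, 3 * (6 / 29)^2 * (f - 4 / 29))
  xyz <- cbind(finv(fx), finv(fy), finv(fz))
  xyz <- sweep(xyz, 2, .d65, "*")
  lin <- xyz %*% t(.xyz2rgb)
  v <- ifelse(lin <= 0.0031308, 12.92 * lin, 1.055 * lin^(1 / 2.4) - 0.055)
  chan <- v * 255
  oog <- any(chan < -0.5 | chan > 255.5)
  chan <- pmin(pmax(chan, 0), 255)
  if (round) chan <- round_half_up(chan)
  colnames(chan) <- c("r", "g", "b")
  out <- if (is.null(dim(lab))) drop(chan) else chan
  attr(out, "out_of_gamut") <- oog
  out
}

#' Convert CIELAB to cylindrical LCh
#'
#' `C = sqrt(a^2 + b^2)`; `h = atan2(b, a)` in degrees wrapped to \[0, 360).
#' When chroma is zero the hue angle is undefined and is reported as 0 by
#' convention.
#'
#' @param lab length-3 vector `c(L, a, b)` or an n x 3 matrix.
#' @return vector (or matrix) with components `L`, `C`, `h`.
#' @examples
#' lab_to_lch(c(81, 1, 28))
#' @export
lab_to_lch <- function(lab) {
  x <- .as_lab_matrix(lab)
  C <- sqrt(x[, 2]^2 + x[, 3]^2)
  h <- (atan2(x[, 3], x[, 2]) * 180 / pi) %% 360
  h[C == 0] <- 0
  out <- cbind(L = x[, 1], C = C, h = h)
  if (is.null(dim(lab))) drop(out) else out
}

#' Convert LCh to CIELAB
#'
#' Inverse of [lab_to_lch()]: `a = C cos(h)`, `b = C sin(h)`.
#'
#' @param lch length-3 vector `c(L, C, h)` or an n x 3 matrix; `C >= 0`,
#'   `h` in degrees.
#' @return vector (or matrix) with components `L`, `a`, `b`.
#' @export
lch_to_lab <- function(lch) {
  if (is.null(dim(lch))) x <- matrix(lch, nrow = 1) else x <- as.matrix(lch)
  if (ncol(x) != 3) stop("LCh input must have 3 components", call. = FALSE)
  if (any(x[, 2] < 0)) stop("Chroma must be nonnegative", call. = FALSE)
  hr <- x[, 3] * pi / 180
  out <- cbind(L = x[, 1], a = x[, 2] * cos(hr), b = x[, 2] * sin(hr))
  if (is.null(dim(lch))) drop(out) else out
}

#' Convert sRGB directly to LCh
#'
#' Composition of [srgb_to_lab()] and [lab_to_lch()].
#' @inheritParams srgb_to_lab
#' @return vector (or matrix) with components `L`, `C`, `h`.
#' @export
srgb_to_lch <- function(rgb) lab_to_lch(srgb_to_lab(rgb))

#' Signed hue difference from baseline
#'
#' Difference `current - baseline` in degrees, taken on the shortest arc so
#' the result lies in (-180, 180]. Declining (darkening) hue gives negative
#' values. Over the hue range seen in pecans (about 30-90 degrees) this is
#' plain subtraction; the wrap only matters for robustness.
#'
#' @param current,baseline hue angles in degrees (vectors recycle).
#' @return signed difference in degrees.
#' @examples
#' delta_hue(60, 79)   # -19
#' @export
delta_hue <- function(current, baseline) {
  d <- (current - baseline) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Total color difference (CIE76)
#'
#' Euclidean distance between two colors in CIELAB.
#'
#' @param lab1,lab2 length-3 Lab vectors or n x 3 matrices (rows paired).
#' @return nonnegative distance(s).
#' @export
delta_e <- function(lab1, lab2) {
  a <- if (is.null(dim(lab1))) matrix(lab1, nrow = 1) else as.matrix(lab1)
  b <- if (is.null(dim(lab2))) matrix(lab2, nrow = 1) else as.matrix(lab2)
  d <- sqrt(rowSums((a - b)^2))
  if (is.null(dim(lab1)) && is.null(dim(lab2))) drop(d) else d
}
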