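scale <- pecan_scale()

test_that("sRGB -> Lab -> LCh reproduces every published grade row within a unit", {
  rgb <- as.matrix(scale[, c("r", "g", "b")])
  lab <- round_half_up(srgb_to_lab(rgb))
  expect_true(all(abs(lab[, "L"] - scale$L_lab) <= 1))
  expect_true(all(abs(lab[, "a"] - scale$a) <= 1))
  expect_true(all(abs(lab[, "b"] - scale$b_lab) <= 1))
  lch <- round_half_up(srgb_to_lch(rgb))
  expect_true(all(abs(lch[, "L"] - scale$L_lch) <= 1))
  expect_true(all(abs(lch[, "C"] - scale$C) <= 1))
  expect_true(all(abs(lch[, "h"] - scale$h) <= 1))
})

test_that("white maps to L = 100, a = b = 0 and black to the origin", {
  expect_equal(unname(srgb_to_lab(c(255, 255, 255))), c(100, 0, 0),
               tolerance = 1e-6)
  expect_equal(unname(srgb_to_lab(c(0, 0, 0))), c(0, 0, 0), tolerance = 1e-9)
  expect_equal(as.vector(lab_to_srgb(c(100, 0, 0))), c(255, 255, 255))
  expect_equal(as.vector(lab_to_srgb(c(0, 0, 0))), c(0, 0, 0))
})

test_that("cylindrical transform matches closed-form arithmetic", {
  # sqrt(1 + 28^2) and atan2(28, 1) in degrees, frozen
  lch <- lab_to_lch(c(81, 1, 28))
  expect_equal(unname(lch), c(81, 28.01785, 87.95459), tolerance = 1e-6)
  # C cos(h), C sin(h) for (41, 24, 49 deg), frozen
  lab <- lch_to_lab(c(41, 24, 49))
  expect_equal(unname(lab), c(41, 15.74542, 18.11303), tolerance = 1e-6)
})

test_that("zero chroma reports hue 0 by convention and round-trips", {
  expect_equal(unname(lab_to_lch(c(50, 0, 0))), c(50, 0, 0))
  expect_equal(unname(lch_to_lab(c(50, 0, 0))), c(50, 0, 0))
})

test_that("lab_to_lch / lch_to_lab invert each other for positive chroma", {
  set.seed(11)
  for (i in 1:25) {
    lab <- c(runif(1, 5, 95), runif(1, -40, 40), runif(1, -40, 40))
    if (lab[2] == 0 && lab[3] == 0) next
    expect_equal(unname(lch_to_lab(lab_to_lch(lab))), unname(lab),
                 tolerance = 1e-9)
  }
})

test_that("Lab -> sRGB -> Lab round trip stays within one Lab unit in gamut", {
  rgb <- as.matrix(scale[, c("r", "g", "b")])
  back <- lab_to_srgb(srgb_to_lab(rgb), round = TRUE)
  expect_true(all(abs(back - rgb) <= 1))
  lab <- srgb_to_lab(c(202, 171, 128))
  lab2 <- srgb_to_lab(lab_to_srgb(lab))
  expect_true(all(abs(lab2 - lab) <= 1))
})

test_that("out-of-range channels and out-of-gamut colors are handled", {
  expect_error(srgb_to_lab(c(-1, 0, 0)), "0, 255")
  expect_error(srgb_to_lab(c(0, 0, 300)), "0, 255")
  res <- lab_to_srgb(c(50, 120, -120))
  expect_true(attr(res, "out_of_gamut"))
  expect_true(all(res >= 0 & res <= 255))
})

test_that("delta_hue is signed shortest-arc difference", {
  expect_equal(delta_hue(60, 79), -19)
  expect_equal(delta_hue(73, 73), 0)
  expect_equal(delta_hue(1, 359), 2)
  expect_equal(delta_hue(359, 1), -2)
})

test_that("delta_e is a metric on random in-gamut colors", {
  expect_equal(delta_e(c(81, 1, 28), c(72, 5, 27)), sqrt(98),
               tolerance = 1e-12)
  set.seed(7)
  for (i in 1:30) {
    x <- srgb_to_lab(runif(3, 0, 255))
    y <- srgb_to_lab(runif(3, 0, 255))
    z <- srgb_to_lab(runif(3, 0, 255))
    expect_equal(delta_e(x, y), delta_e(y, x))
    expect_gte(delta_e(x, y) + delta_e(y, z), delta_e(x, z) - 1e-12)
    expect_equal(delta_e(x, x), 0)
  }
})

test_that("grade hues decrease strictly and entries classify to themselves", {
  expect_true(all(diff(scale$h) < 0))
  expect_equal(scale$h, c(88, 79, 67, 60, 49, 37))
  for (i in 1:6) {
    got <- classify_grade(unlist(scale[i, c("L_lch", "C", "h")]),
                          scale = scale)
    expect_identical(got$grade_number, scale$grade_number[i])
  }
})

test_that("classification uses midpoint boundaries with darker tie-break", {
  expect_identical(classify_grade(hue = 60)$name, "Light brown")
  expect_identical(classify_grade(hue = 88)$name, "Light cream")
  # 73 is the exact midpoint of 79 and 67: darker grade wins
  expect_identical(classify_grade(hue = 73)$name, "Golden")
  expect_identical(classify_grade(hue = 0)$grade_number, 6L)
  expect_identical(classify_grade(hue = 170)$grade_number, 1L)
})

test_that("representative initial hue averages adjacent grade hues", {
  expect_equal(grade_initial_hue(3, 2), 73)
  expect_equal(grade_initial_hue(2, 3), 73)
  expect_equal(grade_initial_hue(4, 3), 63.5)
  expect_equal(grade_initial_hue(4, 4), 60)
  expect_error(grade_initial_hue(2, 5), "adjacent")
})

test_that("a malformed scale is rejected", {
  bad <- as.data.frame(scale)
  bad$h[1] <- 50  # no longer decreasing
  expect_error(as_grade_scale(bad), "decreasing")
  expect_error(as_grade_scale(as.data.frame(scale)[-2, ]), "1 through 6")
})
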