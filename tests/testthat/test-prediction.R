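rates <- reference_rates()
q10s <- reference_q10()

test_that("zero-order storage-day inversion is exact arithmetic", {
  expect_equal(storage_days_zero_order(73, 60, 0.05), 260)
  expect_equal(storage_days_zero_order(73, 73, 0.05), 0)
  expect_equal(storage_days_zero_order(73, 60, 0.043), 13 / 0.043)
  expect_error(storage_days_zero_order(73, 60, 0), "positive")
  expect_error(storage_days_zero_order(60, 73, 0.05), "lightening")
})

test_that("zero-order inversion is homogeneous and linear in the hue gap", {
  set.seed(9)
  for (i in 1:20) {
    k <- runif(1, 0.01, 1); gap <- runif(1, 1, 40)
    expect_equal(storage_days_zero_order(73, 73 - gap, 2 * k),
                 storage_days_zero_order(73, 73 - gap, k) / 2,
                 tolerance = 1e-12)
    expect_equal(storage_days_zero_order(73, 73 - 2 * gap, k),
                 2 * storage_days_zero_order(73, 73 - gap, k),
                 tolerance = 1e-12)
  }
})

test_that("first-order storage-day inversion matches the half-life identity", {
  expect_equal(storage_days_first_order(70, 70, 0.01), 0)
  expect_equal(storage_days_first_order(70, 35, log(2) / 100), 100,
               tolerance = 1e-12)
  expect_equal(storage_days_first_order(72, 52, 0.01), 32.54224,
               tolerance = 1e-6)
  expect_error(storage_days_first_order(72, 0, 0.01), "positive")
  expect_error(storage_days_first_order(52, 72, 0.01), "lightening")
})

test_that("Q10 rescaling divides and composes", {
  expect_equal(rescale_days_q10(270, 2.50), 108)
  expect_equal(rescale_days_q10(270, 1), 270)
  expect_equal(rescale_days_q10(270, c(2.5, 3)), 36)
  set.seed(4)
  for (i in 1:20) {
    s <- runif(1, 10, 500); qa <- runif(1, 1, 5); qb <- runif(1, 1, 5)
    expect_equal(rescale_days_q10(rescale_days_q10(s, qa), qb),
                 s / (qa * qb), tolerance = 1e-12)
  }
  expect_error(rescale_days_q10(100, 0), "positive")
})

test_that("the reference rate table is complete and nonnegative", {
  grid <- expand.grid(cultivar = c("Desirable", "Pawnee", "Stuart"),
                      temp_c = c(20, 30, 40), rh_pct = c(30, 50, 75, 80),
                      attribute = c("L", "C", "h"))
  expect_identical(nrow(rates), nrow(grid))  # 108 rows
  key_have <- with(rates, paste(cultivar, temp_c, rh_pct, attribute))
  key_want <- with(grid, paste(cultivar, temp_c, rh_pct, attribute))
  expect_setequal(key_have, key_want)
  expect_true(all(rates$k >= 0))
  # round trip file -> memory -> file is lossless
  tmp <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(rates, tmp, row.names = FALSE, quote = FALSE)
  expect_identical(reference_rates(tmp), rates)
})

test_that("rate lookup errors list the valid keys", {
  expect_equal(lookup_rate("Stuart", 20, 30, "h")$k, 0.043)
  expect_error(lookup_rate("Elliott", 20, 30, "h"), "Desirable")
  expect_error(lookup_rate("Stuart", 25, 30, "h"), "20, 30, 40")
})

test_that("grade-2 lookup prediction reproduces the published worked numbers", {
  p <- predict_storage_days("Stuart", 20, 30, initial = 2, target = 4)
  expect_equal(p$initial_value, 73)
  expect_equal(p$final_value, 60)
  expect_equal(p$days, 13 / 0.043, tolerance = 1e-12)
  expect_identical(p$method, "lookup")
  expect_identical(p$days_ceiling, 303)
  # target equal to the initial grade: zero days
  p0 <- predict_storage_days("Stuart", 20, 30, initial = 2, target = 2)
  expect_equal(p0$days, 0)
})

test_that("lookup equals Arrhenius interpolation at grid temperatures", {
  for (cv in c("Desirable", "Pawnee", "Stuart")) {
    for (rh in c(30, 50, 75, 80)) {
      for (tc in c(20, 30, 40)) {
        p1 <- predict_storage_days(cv, tc, rh, 2, 4, method = "lookup")
        p2 <- predict_storage_days(cv, tc, rh, 2, 4, method = "arrhenius")
        expect_equal(p2$days, p1$days, tolerance = 1e-9)
      }
    }
  }
})

test_that("Q10-route prediction divides the cooler-grid prediction", {
  p20 <- predict_storage_days("Desirable", 20, 30, 2, 4)
  p30 <- predict_storage_days("Desirable", 30, 30, 2, 4, method = "q10")
  q <- q10s$q10[q10s$transition == "20-30" & q10s$rh_pct == 30]
  expect_equal(p30$days, p20$days / q, tolerance = 1e-12)
  # a 40 degC request starts from the nearest cooler grid temperature (30)
  p40 <- predict_storage_days("Desirable", 40, 30, 2, 4, method = "q10")
  p30lk <- predict_storage_days("Desirable", 30, 30, 2, 4)
  q2 <- q10s$q10[q10s$transition == "30-40" & q10s$rh_pct == 30]
  expect_equal(p40$days, p30lk$days / q2, tolerance = 1e-12)
  # a request 20 degrees above the lowest grid point chains two rescalings
  rates25 <- rates[rates$temp_c == 20, ]
  p40chain <- predict_storage_days("Desirable", 40, 30, 2, 4,
                                   method = "q10", rates = rates25)
  expect_equal(p40chain$days, p20$days / (q * q2), tolerance = 1e-12)
})

test_that("off-grid requests route or fail as documented", {
  expect_error(predict_storage_days("Stuart", 25, 30, 2, 4,
                                    method = "lookup"), "arrhenius")
  p <- predict_storage_days("Stuart", 25, 30, 2, 4, method = "arrhenius")
  p20 <- predict_storage_days("Stuart", 20, 30, 2, 4)
  p30 <- predict_storage_days("Stuart", 30, 30, 2, 4)
  expect_true(p$days < p20$days && p$days > p30$days)
  expect_error(predict_storage_days("Stuart", 20, 60, 2, 4), "humidity")
  expect_error(predict_storage_days("Stuart", 20, 30, 4, 2), "lighter")
  p45 <- suppressWarnings(
    predict_storage_days("Stuart", 45, 30, 2, 4, method = "arrhenius"))
  expect_true(any(grepl("outside", p45$notes)))
})

test_that("a measured LCh triple overrides the grade-average initial hue", {
  p <- predict_storage_days("Stuart", 20, 30, initial = c(70, 25, 70),
                            target = 4)
  expect_equal(p$initial_value, 70)
  expect_equal(p$days, 10 / 0.043, tolerance = 1e-12)
})

test_that("lightness-based first-order prediction inverts the exponential law", {
  p <- predict_storage_days("Stuart", 20, 75, 2, 4, attribute = "L")
  k <- lookup_rate("Stuart", 20, 75, "L")$k
  ini <- mean(c(72, 62)); fin <- 52
  expect_equal(p$days, log(ini / fin) / k, tolerance = 1e-12)
})

test_that("the grade timeline is cumulative, monotone and prefix-stable", {
  tl <- grade_timeline("Stuart", 20, 30, initial = 2)
  expect_identical(tl$grade_number, 2:6)
  expect_equal(tl$days[1], 0)
  expect_true(all(diff(tl$days) > 0))
  expect_equal(tl$days[tl$grade_number == 4], 13 / 0.043, tolerance = 1e-12)
  expect_equal(tl$days[tl$grade_number == 5], 24 / 0.043, tolerance = 1e-12)
  # restricting the target yields a prefix
  tl4 <- grade_timeline("Stuart", 20, 30, initial = 2, to_grade = 4)
  expect_equal(tl4, tl[1:3, ], ignore_attr = TRUE)
})
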