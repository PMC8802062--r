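test_that("the default design mirrors the study layout", {
  d <- simulation_design()
  expect_length(d$sampling_days, 12)
  for (days in d$sampling_days) {
    expect_length(days, 6)
    expect_equal(days[1], 0)
    expect_true(all(diff(days) > 0))
  }
  expect_equal(d$sampling_days[["20_30"]][6], 450)
  expect_equal(d$sampling_days[["40_80"]][6], 15)
})

test_that("simulation is deterministic under a fixed seed", {
  a <- simulate_experiment(seed = 123)
  b <- simulate_experiment(seed = 123)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c_ <- simulate_experiment(seed = 124)
  expect_false(identical(a$h, c_$h))
})

test_that("the default design yields the full record count", {
  d <- simulate_experiment(seed = 1)
  # 3 cultivars x 2 years x 12 conditions x 6 occasions x 2 reps x 3 pseudo
  expect_identical(nrow(d), 2592L)
  cells <- unique(d[, c("cultivar", "year", "temperature_C", "rh_pct")])
  expect_identical(nrow(cells), 72L)
  expect_true(all(d$L >= 0 & d$C >= 0 & d$h >= 0 & d$h < 360))
})

test_that("noiseless records lie exactly on their decay curves", {
  truth <- noiseless_truth()
  d <- simulate_experiment(small_design(), truth, seed = 1)
  for (cv in unique(d$cultivar)) {
    sub <- d[d$cultivar == cv & d$temperature_C == 30 & d$rh_pct == 50, ]
    k_h <- true_k(truth, cv, 50, "h", 30)
    p0 <- truth$attributes$h$p0 + truth$cultivar_p0_shift[[cv]]
    expect_equal(sub$h, pmax(p0 - k_h * sub$day, 0), tolerance = 1e-12)
    k_L <- true_k(truth, cv, 50, "L", 30)
    p0L <- truth$attributes$L$p0 + truth$cultivar_p0_shift[[cv]]
    expect_equal(sub$L, p0L * exp(-k_L * sub$day), tolerance = 1e-12)
  }
})

test_that("day-0 means match the configured baselines under noise", {
  d <- simulate_experiment(seed = 2024)
  truth <- attr(d, "truth")
  for (a in c("h", "L", "C")) {
    base <- d[d$day == 0, ]
    shift <- truth$cultivar_p0_shift[base$cultivar]
    centered <- base[[a]] - shift
    n <- length(centered)
    sd_a <- truth$attributes[[a]]$noise_sd
    expect_lt(abs(mean(centered) - truth$attributes[[a]]$p0),
              4 * sd_a / sqrt(n))
  }
})

test_that("noiseless hue is nonincreasing in time and in temperature", {
  d <- simulate_experiment(simulation_design(years = "2018",
                                             replicates = 1,
                                             pseudo_replicates = 1),
                           noiseless_truth(), seed = 1)
  for (cv in unique(d$cultivar)) for (rh in unique(d$rh_pct)) {
    for (tc in unique(d$temperature_C)) {
      tr <- d[d$cultivar == cv & d$rh_pct == rh & d$temperature_C == tc, ]
      tr <- tr[order(tr$day), ]
      expect_true(all(diff(tr$h) <= 0))
    }
    # at a common day (day 0 aside), warmer runs are at least as dark
    k20 <- true_k(attr(d, "truth"), cv, rh, "h", 20)
    k30 <- true_k(attr(d, "truth"), cv, rh, "h", 30)
    k40 <- true_k(attr(d, "truth"), cv, rh, "h", 40)
    expect_true(k20 < k30 && k30 < k40)
  }
})

test_that("noiseless parameter recovery is exact to optimizer precision", {
  d <- simulate_experiment(truth = noiseless_truth(), seed = 1)
  rec <- recover_parameters(d)
  expect_identical(rec$n_failed, 0L)
  expect_identical(nrow(rec$k_table), 108L)
  expect_lt(max(abs(rec$k_table$rel_err)), 1e-5)
  expect_lt(max(abs(rec$ea_table$rel_err)), 1e-5)
})

test_that("by_fit order selection identifies the generative order everywhere", {
  d <- simulate_experiment(small_design(), noiseless_truth(), seed = 1)
  rec <- recover_parameters(d, mode = "by_fit")
  expect_true(all(rec$k_table$order[rec$k_table$attribute == "h"] == 0L))
  expect_true(all(rec$k_table$order[rec$k_table$attribute != "h"] == 1L))
})

test_that("seeded noisy recovery keeps the median k error under 15 percent", {
  d <- simulate_experiment(seed = 7)
  rec <- recover_parameters(d)
  expect_lt(rec$summary[["k_median_rel_err"]], 0.15)
})

test_that("the full pipeline recovers time-to-target-hue on noiseless data", {
  truth <- noiseless_truth()
  d <- simulate_experiment(small_design(), truth, seed = 1)
  cv <- "Stuart"; tc <- 20; rh <- 30
  sub <- d[d$cultivar == cv & d$temperature_C == tc & d$rh_pct == rh, ]
  s <- color_series(sub$day, sub$h, "h", tc, rh, cv)
  f <- select_order(s)
  s_hat <- storage_days_zero_order(73, 60, f$k)
  s_true <- storage_days_zero_order(73, 60, true_k(truth, cv, rh, "h", tc))
  expect_lt(abs(s_hat - s_true) / s_true, 0.05)
})
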