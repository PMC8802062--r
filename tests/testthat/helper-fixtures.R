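# Fixtures built in code: exact decay series and small simulated datasets.

make_line_series <- function(P0 = 79, k = 0.05, days = seq(0, 450, 50),
                             attribute = "h", sd = 0) {
  v <- P0 - k * days
  if (sd > 0) v <- v + rnorm(length(days), 0, sd)
  color_series(days, v, attribute, temp_c = 20, rh_pct = 30)
}

make_exp_series <- function(P0 = 70, k = 0.02, days = seq(0, 300, 30),
                            attribute = "L", sd = 0) {
  v <- P0 * exp(-k * days)
  if (sd > 0) v <- v + rnorm(length(days), 0, sd)
  color_series(days, v, attribute, temp_c = 20, rh_pct = 30)
}

noiseless_truth <- function() {
  true_parameters(noise_sd = c(h = 0, L = 0, C = 0))
}

# small design: fewer cells so simulation-heavy tests stay fast
small_design <- function() {
  simulation_design(cultivars = c("Desirable", "Stuart"), years = "2018")
}
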