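make_exp_ts <- function(mu, t = 0:20, x0 = 0.1) {
  cultivation_ts(tibble::tibble(
    strain = "S", replicate = 1L, time_h = t, cdw = x0 * exp(mu * t),
    co2 = 1, phosphate = 5 * pmax(0, 1 - t / max(t))))
}

test_that("growth-rate fit is exact on noise-free exponentials", {
  for (mu in c(0.01, 0.05, 0.21, 0.5, 1)) {
    fit <- estimate_growth_rate(make_exp_ts(mu), window = c(0, 20))
    expect_equal(fit$mu, mu, tolerance = 1e-10)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  }
  # constant cdw -> mu 0
  flat <- cultivation_ts(tibble::tibble(strain = "S", replicate = 1L,
                                        time_h = 0:9, cdw = 2, co2 = 1))
  expect_equal(estimate_growth_rate(flat, window = c(0, 9))$mu, 0)
})

test_that("auto window recovers the preset rates from noisy series", {
  expect_equal(glance(estimate_growth_rate(fx_ts0("M145")))$mu, 0.21,
               tolerance = 1e-9)
  expect_equal(glance(estimate_growth_rate(fx_ts0("M1152")))$mu, 0.15,
               tolerance = 1e-9)
  noisy <- make_timeseries(toy_config(seed = 7, noise_sd = 0.02), "M1152")
  expect_equal(glance(estimate_growth_rate(noisy))$mu, 0.15,
               tolerance = 0.01)
})

test_that("depletion detection interpolates the first downward crossing", {
  lin <- cultivation_ts(tibble::tibble(
    strain = "S", replicate = 1L, time_h = seq(0, 40, 5), cdw = 1,
    co2 = 1, phosphate = pmax(0, 5 * (1 - seq(0, 40, 5) / 35))))
  expect_equal(detect_depletion(lin, "phosphate", 0), 35)
  # never depleted
  lin$glucose <- 40
  expect_true(is.na(detect_depletion(lin, "glucose", 0)))
  # shift equivariance
  shifted <- lin
  shifted$time_h <- shifted$time_h + 7
  expect_equal(detect_depletion(shifted, "phosphate", 0), 42)
  # chatter: first crossing wins, with a warning
  chat <- lin
  chat$phosphate[7:9] <- c(0, 0.4, 0)
  expect_warning(d <- detect_depletion(chat, "phosphate", 0),
                 "re-crosses")
  expect_lt(d, 31)
  # synthetic preset series land on the planted times
  expect_equal(detect_depletion(fx_ts0("M145"), "phosphate", 0), 35)
  noisy1152 <- make_timeseries(toy_config(seed = 5, noise_sd = 0.02), "M1152")
  expect_equal(detect_depletion(noisy1152, "phosphate", 0), 47,
               tolerance = 1 / 47)
})

test_that("interval specific rates use the log-mean biomass", {
  ts <- cultivation_ts(tibble::tibble(
    strain = "S", replicate = 1L, time_h = c(0, 2), cdw = 1, co2 = 1,
    glucose = c(10, 8)))
  q <- specific_rates(ts)
  expect_equal(q$q[q$compound == "glucose"], -1)
  # mass conservation on generator output: q_substrate / n = -mu exactly
  sr <- specific_rates(fx_ts0("M145"))
  pre <- sr$t_end <= 35
  q_glc <- sr$q[pre & sr$compound == "glucose"]
  mu <- sr$q[pre & sr$compound == "biomass"]
  expect_equal(q_glc / 0.8, -mu, tolerance = 1e-9)
  # uptake ratio: equal rates -> 1; generator plants the strain contrast
  r145 <- uptake_ratio(specific_rates(fx_ts0("M145")), "glucose", "glutamate")
  r1152 <- uptake_ratio(specific_rates(fx_ts0("M1152")), "glucose",
                        "glutamate")
  i <- 10   # a pre-switch interval in both strains
  expect_lt(r1152$ratio[i], r145$ratio[i])
})

test_that("production comparison aligns by time since depletion", {
  tsA <- fx_ts0("M145")
  expect_equal(as.numeric(production_comparison(tsA, tsA, "germA")), 0)
  # alt titer exactly 0.08x the reference at aligned time -> 92%
  expect_equal(as.numeric(production_comparison(
    tsA, make_timeseries(toy_config(seed = 1, noise_sd = 0), "M1152"),
    "germA")), 92, tolerance = 1e-9)
  # scale invariance under common unit change
  tsB <- make_timeseries(toy_config(seed = 1, noise_sd = 0), "M1146")
  scale2 <- function(ts) { ts$germA <- ts$germA * 1000; ts }
  expect_equal(as.numeric(production_comparison(scale2(tsA), scale2(tsB),
                                                "germA")),
               as.numeric(production_comparison(tsA, tsB, "germA")),
               tolerance = 1e-9)
  # rate-based variant agrees for linear post-switch accumulation
  expect_equal(as.numeric(production_comparison(tsA, tsB, "germA",
                                                method = "rate")),
               27, tolerance = 0.5)
  expect_error(production_comparison(tsA, tsB, "nope"),
               class = "switchflux_usage_error")
})

test_that("long-format TSV round trip preserves the time series", {
  ts <- fx_ts0("M145")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_cultivation_tsv(ts, f)
  back <- read_cultivation_tsv(f)
  expect_equal(as.data.frame(back)[names(as.data.frame(ts))],
               as.data.frame(ts))
})
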