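test_that("min-max normalization honours anchors and channel defaults", {
  t <- seq(0, 40, 0.1)
  tr <- ca_trace(t, rep(c(100, 500, 900), length.out = length(t)),
                 channel = "cyto", Fmin = 100, Fmax = 900)
  nt <- normalize_trace(tr)
  expect_equal(range(nt$F), c(0, 1))
  # ER channel without per-cell calibration: floor defaults to 7.655% of Fmax
  er <- ca_trace(t, rep(0.07655 * 800, length(t)), channel = "er", Fmax = 800)
  expect_equal(normalize_trace(er)$F[1], 0, tolerance = 1e-12)
  cy <- ca_trace(t, rep(0, length(t)), channel = "cyto", Fmax = 900)
  expect_equal(normalize_trace(cy)$F[1], 0)
  expect_error(normalize_trace(ca_trace(t, t, channel = "cyto")),
               "Fmax is required")
  expect_error(ca_trace(t, t, channel = "cyto", Fmin = 5, Fmax = 5),
               "calibration error")
})

test_that("normalization is invariant under joint positive affine transforms", {
  set.seed(21)
  t <- seq(0, 60, 0.2)
  F <- 200 + 300 * runif(length(t))
  base <- normalize_trace(ca_trace(t, F, channel = "cyto",
                                   Fmin = 200, Fmax = 500))
  for (i in 1:10) {
    a <- runif(1, 0.1, 50); b <- runif(1, -100, 100)
    tr2 <- normalize_trace(ca_trace(t, a * F + b, channel = "cyto",
                                    Fmin = a * 200 + b, Fmax = a * 500 + b))
    expect_equal(tr2$F, base$F, tolerance = 1e-10)
  }
})

test_that("oscillation detection recovers the generated spike train", {
  # flat trace with sub-threshold noise: no events
  set.seed(22)
  t <- seq(0, 120, 0.1)
  flat <- ca_trace(t, 0.2 + rnorm(length(t), 0, 0.01), channel = "cyto",
                   Fmin = 0, Fmax = 1)
  expect_equal(detect_oscillations(flat)$event_count, 0)
  # noiseless generated train: exact count and 5/min
  tr <- gen_dual_trace(osc_freq_per_min = 5, noise_sd = 0, seed = 1)
  rep0 <- detect_oscillations(normalize_trace(tr$cyto))
  expect_equal(rep0$event_count, tr$truth$spike_count)
  expect_equal(rep0$event_count, 10)
  expect_equal(rep0$frequency_per_min, 5)
  # the same train at the generator's noise level
  trn <- gen_dual_trace(osc_freq_per_min = 5, noise_sd = 0.02, seed = 2)
  expect_equal(detect_oscillations(normalize_trace(trn$cyto))$event_count, 10)
  # too-short traces are refused
  expect_error(
    detect_oscillations(ca_trace(seq(0, 10, 0.1), rnorm(101), "cyto", 0, 1)),
    "insufficient data")
})

test_that("spike counts are recovered across seeds at SNR >= 5", {
  for (seed in 1:8) {
    tr <- gen_dual_trace(osc_freq_per_min = 5, cyto_amp = 0.8,
                         noise_sd = 0.1, seed = seed)   # SNR 8
    got <- detect_oscillations(normalize_trace(tr$cyto))$event_count
    expect_equal(got, tr$truth$spike_count)
  }
})

test_that("the upper ER level is the 95th percentile envelope", {
  t <- seq(0, 100, by = 0.01)
  # constant trace
  const <- ca_trace(t, rep(0.8, length(t)), channel = "er", Fmin = 0, Fmax = 1)
  expect_equal(upper_er_level(const), 0.8)
  # dense sawtooth between 0.5 and 0.9: analytic 95th percentile 0.88
  saw <- ca_trace(t, 0.5 + 0.4 * ((t * 0.2) %% 1), channel = "er",
                  Fmin = 0, Fmax = 1)
  expect_equal(upper_er_level(saw), 0.88, tolerance = 0.01)
  # window selection and emptiness
  dep <- ca_trace(t, ifelse(t < 50, 0.9, 0.2), channel = "er", Fmin = 0, Fmax = 1)
  expect_equal(upper_er_level(dep, window = c(60, 90)), 0.2)
  expect_error(upper_er_level(dep, window = c(200, 300)), "empty window")
  # monotone under pointwise increase
  up <- ca_trace(t, saw$F + 0.05, channel = "er", Fmin = 0, Fmax = 1)
  expect_gt(upper_er_level(up), upper_er_level(saw))
})

test_that("Hill dose-response fitting recovers the caffeine EC50", {
  doses <- c(0.03, 0.1, 0.3, 1, 3, 10)
  # noiseless self-consistency
  y <- doses^1.5 / (doses^1.5 + 1)
  f0 <- caffeine_dose_response(doses, y)
  expect_equal(f0$EC50, 1, tolerance = 1e-6)
  expect_equal(f0$hill, 1.5, tolerance = 1e-5)
  expect_true(f0$ec50_in_range)
  # response at the EC50 is halfway between floor and ceiling
  expect_equal(y[doses == 1], 0.5)
  # noisy recovery at the generator conditions
  d <- gen_dose_response(EC50 = 1, hill = 1.5, noise_sd = 0.05, seed = 31)
  f1 <- caffeine_dose_response(d$dose_mM, d$response)
  expect_lt(abs(f1$EC50 - 1), 0.2)
  # insufficient span is refused
  expect_error(caffeine_dose_response(c(1, 2, 3, 4), c(0.1, 0.2, 0.3, 0.4)),
               "log units")
})

test_that("per-cell summaries follow the linear-interpolation convention", {
  s <- summarize_cells(1:5)
  expect_equal(unlist(s[c("min", "q1", "median", "q3", "max")]),
               c(min = 1, q1 = 2, median = 3, q3 = 4, max = 5))
  # frozen hand computation
  s2 <- summarize_cells(c(2, 4, 4, 4, 5, 5, 7, 9))
  expect_equal(s2$mean, 5)
  expect_equal(s2$sd, 2.138, tolerance = 1e-3)
  expect_equal(s2$sem, 0.756, tolerance = 1e-3)
  # single value: five numbers collapse, SEM undefined
  s3 <- summarize_cells(42)
  expect_equal(unlist(s3[c("min", "q1", "median", "q3", "max", "mean")]),
               c(min = 42, q1 = 42, median = 42, q3 = 42, max = 42, mean = 42))
  expect_true(is.na(s3$sem))
})
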