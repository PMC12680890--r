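quiet_params <- function(...) acoustic_params(noise_std = 0, count_cv = 0, ...)

record <- function(strain = "WB06", wort = 12, yeast = 0.4) {
  tibble::tibble(
    strain = factor(strain, ys_strains()), wort_wt_pct = wort, yeast_wt_pct = yeast
  )
}

test_that("echo 2 arrives at t1 + 2d/c inside its gating window", {
  cfg <- fast_config()
  p <- quiet_params()
  x <- synth_ascan(record(yeast = 0), params = p, config = cfg)
  rate <- attr(x, "sampling_rate")
  win <- echo_windows()[2, ]
  ia <- round(win$a * rate / 1e9) + 1
  ib <- round(win$b * rate / 1e9) + 1
  t_peak <- (ia + which.max(abs(x[ia:ib])) - 2) * (1e9 / rate)
  t2_expected <- p$echo1_time_t1 + 2 * 0.0375 / p$base_velocity_c0 * 1e9
  expect_gt(t_peak, win$a)
  expect_lt(t_peak, win$b)
  # peak within one toneburst period of the echo centre
  expect_lt(abs(t_peak - t2_expected), 1e9 / p$toneburst_frequency_f0)
})

test_that("every echo peak lands within one period of its centre across the design", {
  cfg <- fast_config()
  p <- quiet_params()
  geo <- vessel_geometry()
  win <- echo_windows()
  grid <- tidyr::expand_grid(strain = ys_strains(), wort = c(10, 14), yeast = c(0, 1))
  for (k in seq_len(nrow(grid))) {
    rec <- record(grid$strain[k], grid$wort[k], grid$yeast[k])
    x <- synth_ascan(rec, p, geo, cfg)
    ep <- sonoyeast:::echo_parameters(rec$strain, rec$wort_wt_pct, rec$yeast_wt_pct, p, geo)
    rate <- attr(x, "sampling_rate")
    for (i in 1:3) {
      ia <- round(win$a[i] * rate / 1e9) + 1
      ib <- round(win$b[i] * rate / 1e9) + 1
      t_peak <- (ia + which.max(abs(x[ia:ib])) - 2) * (1e9 / rate)
      expect_lt(abs(t_peak - ep$t[i]), 1e9 / p$toneburst_frequency_f0)
    }
  }
})

test_that("higher yeast concentration attenuates the sample echoes", {
  cfg <- fast_config()
  p <- quiet_params()
  x_lo <- synth_ascan(record(yeast = 0.2), p, config = cfg)
  x_hi <- synth_ascan(record(yeast = 0.8), p, config = cfg)
  rate <- attr(x_lo, "sampling_rate")
  peak_in <- function(x, w) {
    ia <- round(w$a * rate / 1e9) + 1; ib <- round(w$b * rate / 1e9) + 1
    max(abs(x[ia:ib]))
  }
  win <- echo_windows()
  expect_lt(peak_in(x_hi, win[2, ]), peak_in(x_lo, win[2, ]))
  expect_lt(peak_in(x_hi, win[3, ]), peak_in(x_lo, win[3, ]))
  # echo 1 never enters the sample: unchanged
  expect_equal(peak_in(x_hi, win[1, ]), peak_in(x_lo, win[1, ]), tolerance = 1e-12)
})

test_that("zero excitation with zero noise gives the zero waveform", {
  x <- synth_ascan(record(), quiet_params(excitation_amplitude_A0 = 1e-300),
                   config = fast_config())
  expect_lt(max(abs(x)), 1e-280)
})

test_that("misconfigured echo timing raises a gating error", {
  expect_error(
    synth_ascan(record(), quiet_params(echo1_time_t1 = 5000), config = fast_config()),
    "outside its gating window"
  )
})

test_that("a measurement is a 50-shot schedule spanning the acquisition interval", {
  cfg <- fast_config()
  m <- simulate_measurement(record(), acoustic_params(noise_std = 0.01), config = cfg)
  expect_equal(ncol(m), 50)
  ts <- attr(m, "timestamps")
  expect_equal(ts[length(ts)], 24.5)
  expect_equal(diff(ts), rep(0.5, 49))
  # deterministic echo parameters within a measurement, independent noise per shot
  expect_false(identical(m[, 1], m[, 2]))
})

test_that("a single-shot measurement equals synth_ascan under the same seed", {
  cfg <- fast_config(signals_per_measurement = 1)
  p <- acoustic_params()
  m <- withr::with_seed(11, simulate_measurement(record(), p, config = cfg))
  x <- withr::with_seed(11, synth_ascan(record(), p, config = cfg))
  expect_identical(as.numeric(m[, 1]), as.numeric(x))
})

test_that("identical seeds give bit-identical simulated feature sets", {
  d <- yeast_design(1)[c(1, 40), ]
  f1 <- simulate_features(d, config = fast_config(), seed = 5)
  f2 <- simulate_features(d, config = fast_config(), seed = 5)
  expect_identical(f1, f2)
  f3 <- simulate_features(d, config = fast_config(), seed = 6)
  expect_false(identical(f1$a_max_2, f3$a_max_2))
})
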