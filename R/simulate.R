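# echo arrival times (ns), velocity (m/s), attenuation (Np/m), amplitudes
# for one sample record; shared by synth_ascan and the tests
echo_parameters <- function(strain, wort_wt_pct, yeast_wt_pct,
                            params, geometry) {
  strain <- as.character(strain)
  d_m <- geometry$sample_diameter_d / 1000
  c_ms <- params$base_velocity_c0 +
    params$velocity_wort_slope * (wort_wt_pct - 12) +
    params$velocity_yeast_slope[[strain]] * yeast_wt_pct
  alpha <- params$base_attenuation_alpha0[[as.character(wort_wt_pct)]] +
    params$attenuation_slope_k_alpha[[strain]] * yeast_wt_pct
  t1 <- params$echo1_time_t1
  t2 <- t1 + 2 * d_m / c_ms * 1e9
  t3 <- t2 + params$echo3_reverb_delay
  A0 <- params$excitation_amplitude_A0
  list(
    t = c(t1, t2, t3),
    A = c(
      A0 * params$echo1_gain_r1,
      A0 * params$echo2_gain_g2[[strain]] * exp(-2 * alpha * d_m),
      A0 * params$echo3_gain_g3 * exp(-4 * alpha * d_m)
    ),
    velocity = c_ms,
    attenuation = alpha
  )
}

#' Synthesize one pulse-echo A-scan
#'
#' Generates the three-echo waveform
#' `x0(t) = sum_i A_i exp(-(t - t_i)^2 / (2 sigma^2)) sin(2 pi f0 (t - t_i))`
#' plus i.i.d. Gaussian recording noise. Echo arrivals follow the sample's
#' sound velocity (echo 2 at `t1 + 2d/c`), echo amplitudes the exponential
#' attenuation over the 2d and 4d sample paths; see [acoustic_params()].
#' Each echo centre is checked against its fixed gating window and an error
#' is raised if a parameter combination pushes it outside.
#'
#' @param record One-row design tibble (or list) with `strain`,
#'   `wort_wt_pct`, `yeast_wt_pct`.
#' @param params [acoustic_params()].
#' @param geometry [vessel_geometry()].
#' @param config [sim_config()].
#' @return Numeric waveform vector with attributes `sampling_rate` (Hz) and
#'   `t0_offset` (ns, always 0 here).
#' @export
synth_ascan <- function(record, params = acoustic_params(),
                        geometry = vessel_geometry(), config = sim_config()) {
  ep <- echo_parameters(record$strain, record$wort_wt_pct, record$yeast_wt_pct,
                        params, geometry)
  win <- echo_windows()
  off <- which(ep$t < win$a | ep$t > win$b)
  if (length(off) > 0) {
    stop("echo ", off[1], " centre at ", round(ep$t[off[1]]),
         " ns falls outside its gating window [", win$a[off[1]], ", ",
         win$b[off[1]], "] ns; check acoustic parameters", call. = FALSE)
  }
  if (config$sampling_rate < 10 * params$toneburst_frequency_f0) {
    stop("sampling rate must be at least 10x the toneburst frequency", call. = FALSE)
  }
  n <- floor(config$record_length * config$sampling_rate / 1e9)
  t_ns <- (seq_len(n) - 1) * (1e9 / config$sampling_rate)
  x <- numeric(n)
  f0_per_ns <- params$toneburst_frequency_f0 / 1e9
  for (i in 1:3) {
    dt <- t_ns - ep$t[i]
    x <- x + ep$A[i] * exp(-dt^2 / (2 * params$toneburst_sigma^2)) *
      sin(2 * pi * f0_per_ns * dt)
  }
  if (params$noise_std > 0) {
    x <- x + stats::rnorm(n, 0, params$noise_std)
  }
  structure(x, sampling_rate = config$sampling_rate, t0_offset = 0)
}

#' Simulate one measurement (a burst of repeated A-scans)
#'
#' The acoustic parameters are deterministic within a measurement; only the
#' recording noise differs between the repeated shots. Acquisition
#' timestamps `(k - 1) * signal_interval` are attached; the default 50-shot,
#' 0.5 s schedule spans 25.0 s of acquisition.
#'
#' @inheritParams synth_ascan
#' @return Numeric matrix, samples x `signals_per_measurement`, with
#'   attributes `sampling_rate`, `timestamps` (s), `measurement_id`.
#' @export
simulate_measurement <- function(record, params = acoustic_params(),
                                 geometry = vessel_geometry(),
                                 config = sim_config()) {
  k <- config$signals_per_measurement
  sigs <- vapply(
    seq_len(k),
    function(i) as.numeric(synth_ascan(record, params, geometry, config)),
    numeric(floor(config$record_length * config$sampling_rate / 1e9))
  )
  structure(sigs,
    sampling_rate = config$sampling_rate,
    timestamps = (seq_len(k) - 1) * config$signal_interval,
    measurement_id = if ("measurement_id" %in% names(record)) record$measurement_id else NA_character_
  )
}

#' Simulate a design and extract the echo-feature table
#'
#' The main generative entry point: for every measurement of `design`, draw
#' cell-count labels, synthesize the repeated A-scans, run the
#' signal-processing pipeline (zero-phase bandpass, block averaging,
#' envelope, echo gating), and return one feature row per averaged signal
#' (10 rows per measurement under the defaults). Waveforms are generated and
#' processed one measurement at a time, so memory stays bounded for the full
#' 162-measurement design even at 1 GHz sampling.
#'
#' @param design Tibble from [yeast_design()].
#' @param params [acoustic_params()].
#' @param geometry [vessel_geometry()].
#' @param config [sim_config()].
#' @param pipeline [pipeline_config()].
#' @param seed Integer root seed; per-measurement noise and the label draws
#'   use deterministic substreams so results are reproducible end to end.
#' @return Tibble with the design columns, cell-count labels, `signal_block`
#'   (index of the averaged signal within the measurement), and the nine
#'   feature columns [ys_feature_cols()].
#' @examples
#' feats <- simulate_features(yeast_design(1)[1:2, ],
#'                            config = sim_config(sampling_rate = 1e8), seed = 1)
#' @export
simulate_features <- function(design, params = acoustic_params(),
                              geometry = vessel_geometry(),
                              config = sim_config(),
                              pipeline = pipeline_config(),
                              seed = 1) {
  design <- add_cell_counts(design, params, seed = seed)
  rows <- purrr::map(seq_len(nrow(design)), function(i) {
    rec <- design[i, ]
    m <- withr::with_seed(
      substream_seed(seed, "simulate", i),
      simulate_measurement(rec, params, geometry, config)
    )
    feats <- extract_features(m, pipeline)
    dplyr::bind_cols(rec[rep(1, nrow(feats)), ], feats)
  })
  dplyr::bind_rows(rows)
}

#' Collapse per-signal feature rows to one row per measurement
#'
#' Averages the feature rows of each measurement (the 10 averaged signals
#' under the defaults) into a single row, keeping the labels.
#'
#' @param features Tibble from [simulate_features()].
#' @return Tibble with one row per `measurement_id`.
#' @export
collapse_features <- function(features) {
  features |>
    dplyr::group_by(dplyr::across(dplyr::any_of(c(
      "measurement_id", "strain", "wort_wt_pct", "yeast_wt_pct", "replicate",
      "true_cell_count", "measured_cell_count"
    )))) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(ys_feature_cols()), mean),
      .groups = "drop"
    )
}
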