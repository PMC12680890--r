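#' Yeast strain codes
#'
#' The three *Saccharomyces* strains covered by the measurement design, in
#' the canonical order used everywhere in the package (one-hot encodings,
#' confusion matrices, per-strain parameter tables): top-fermenting
#' *S. cerevisiae*, *S. cerevisiae* var. *diastaticus* (WB-06), and the
#' lager strain *S. pastorianus* W 34/70.
#'
#' @return Character vector of the three strain codes.
#' @export
ys_strains <- function() c("S_CEREVISIAE", "WB06", "W3470")

#' Display labels for the strain codes
#' @return Named character vector mapping codes to display labels.
#' @export
ys_strain_labels <- function() {
  c(S_CEREVISIAE = "S. cerevisiae", WB06 = "WB-06", W3470 = "W 34/70")
}

#' Wort extract concentrations of the measurement design
#' @return Numeric vector, wt% extract.
#' @export
ys_worts <- function() c(10, 12, 14)

#' Yeast concentration levels of the gradient design
#' @return Numeric vector, wt% dry yeast.
#' @export
ys_levels <- function() seq(0, 1, by = 0.2)

#' Names of the nine echo-derived features, in canonical order
#'
#' Per echo i = 1..3: envelope maximum `a_max_i`, its time `t_max_i` (ns),
#' and the summed rectified signal `a_sum_i`.
#'
#' @return Character vector of length 9.
#' @export
ys_feature_cols <- function() {
  as.vector(vapply(1:3, function(i) {
    paste0(c("a_max_", "t_max_", "a_sum_"), i)
  }, character(3)))
}

#' Measurement vessel geometry
#'
#' The pulse-echo cell: a buffer rod (acoustic delay line) above the sample
#' chamber, with a parallel reflector behind it. The sample diameter sets the
#' acoustic path: the echo off the reflector traverses the sample twice
#' (path 2d), the following reverberation accumulates a 4d attenuation path.
#'
#' @param sample_diameter_d Sample chamber diameter, mm.
#' @param buffer_rod_diameter_db Buffer rod diameter, mm.
#' @return A list of class `ys_geometry`.
#' @export
vessel_geometry <- function(sample_diameter_d = 37.5, buffer_rod_diameter_db = 17) {
  stopifnot(sample_diameter_d > 0, buffer_rod_diameter_db > 0)
  structure(
    list(
      sample_diameter_d = sample_diameter_d,
      buffer_rod_diameter_db = buffer_rod_diameter_db
    ),
    class = "ys_geometry"
  )
}

#' Acoustic and label-model parameters of the A-scan simulator
#'
#' Parameterizes the three-echo generative model. Echo amplitudes follow
#' `A1 = A0 * r1`, `A2 = A0 * g2[strain] * exp(-2 * alpha * d)`, and
#' `A3 = A0 * g3 * exp(-4 * alpha * d)` with attenuation
#' `alpha = alpha0[wort] + k_alpha[strain] * yeast_wt_pct` (Np/m) and sample
#' diameter `d` in metres. Sound velocity shifts with medium composition,
#' `c = c0 + velocity_wort_slope * (wort - 12) + velocity_yeast_slope[strain] *
#' yeast_wt_pct`, which moves the echo-2 arrival `t2 = t1 + 2 d / c`.
#' The cell-count label model is linear in the yeast mass fraction,
#' `true_count = count_slope[strain] * yeast_wt_pct`, with a multiplicative
#' Gaussian counting error of coefficient of variation `count_cv` standing in
#' for manual hemocytometer counts.
#'
#' Defaults put every echo centre inside its fixed gating window and give the
#' three strains distinct attenuation slopes, velocity slopes, and interface
#' gains so strain identity is recoverable from the echo features.
#'
#' @param excitation_amplitude_A0 Excitation amplitude, arbitrary units.
#' @param echo1_gain_r1 Reflection gain of the buffer-rod/sample interface.
#' @param echo2_gain_g2 Named per-strain transmission/reflection gain of the
#'   reflector echo; gains must lie in (0, 1].
#' @param echo3_gain_g3 Gain of the second reverberation.
#' @param base_attenuation_alpha0 Named per-wort base attenuation, Np/m.
#' @param attenuation_slope_k_alpha Named per-strain attenuation increase per
#'   wt% yeast, Np/m.
#' @param base_velocity_c0 Sound velocity in 12 wt% wort with no yeast, m/s.
#' @param velocity_wort_slope Velocity change per wt% extract, m/s.
#' @param velocity_yeast_slope Named per-strain velocity change per wt% yeast, m/s.
#' @param echo1_time_t1 Arrival of the buffer-rod interface echo, ns.
#' @param echo3_reverb_delay Delay between echo 2 and echo 3, ns.
#' @param toneburst_frequency_f0 Transducer centre frequency, Hz.
#' @param toneburst_sigma Gaussian envelope width of the emitted burst, ns.
#' @param noise_std Standard deviation of additive recording noise, same
#'   units as `excitation_amplitude_A0`.
#' @param count_slope Named per-strain cells/mL at 1.0 wt% yeast.
#' @param count_cv Coefficient of variation of the counting error.
#' @return A list of class `ys_params`.
#' @export
acoustic_params <- function(excitation_amplitude_A0 = 1,
                            echo1_gain_r1 = 0.25,
                            echo2_gain_g2 = c(S_CEREVISIAE = 0.50, WB06 = 0.55, W3470 = 0.60),
                            echo3_gain_g3 = 0.35,
                            base_attenuation_alpha0 = c(`10` = 6, `12` = 7, `14` = 8),
                            attenuation_slope_k_alpha = c(S_CEREVISIAE = 9, WB06 = 12, W3470 = 6),
                            base_velocity_c0 = 1500,
                            velocity_wort_slope = 4,
                            velocity_yeast_slope = c(S_CEREVISIAE = 8, WB06 = 12, W3470 = 5),
                            echo1_time_t1 = 12500,
                            echo3_reverb_delay = 12000,
                            toneburst_frequency_f0 = 2e6,
                            toneburst_sigma = 500,
                            noise_std = 0.01,
                            count_slope = c(S_CEREVISIAE = 245e6, WB06 = 315e6, W3470 = 165e6),
                            count_cv = 0.05) {
  p <- structure(as.list(environment()), class = "ys_params")
  stopifnot(
    all(c(echo1_gain_r1, echo2_gain_g2, echo3_gain_g3) > 0),
    all(c(echo1_gain_r1, echo2_gain_g2, echo3_gain_g3) <= 1),
    all(base_attenuation_alpha0 >= 0), all(attenuation_slope_k_alpha >= 0),
    base_velocity_c0 > 0, toneburst_frequency_f0 > 0, toneburst_sigma > 0,
    noise_std >= 0, all(count_slope >= 0), count_cv >= 0
  )
  for (nm in c("echo2_gain_g2", "attenuation_slope_k_alpha",
               "velocity_yeast_slope", "count_slope")) {
    if (!all(ys_strains() %in% names(p[[nm]]))) {
      stop("`", nm, "` must be named for every strain code", call. = FALSE)
    }
  }
  if (!all(as.character(ys_worts()) %in% names(p$base_attenuation_alpha0))) {
    stop("`base_attenuation_alpha0` must be named for worts 10, 12, 14", call. = FALSE)
  }
  p
}

#' Acquisition configuration of the simulated oscilloscope
#'
#' One measurement records `signals_per_measurement` A-scans at fixed
#' `signal_interval` spacing; the default 50-shot schedule spans 24.5 s of
#' timestamps (25.0 s total acquisition). The production sampling rate is
#' 1 GHz; all time quantities are specified in ns and converted per rate, so
#' coarser rates (e.g. 100 MHz) yield the same echo structure with fewer
#' samples.
#'
#' @param sampling_rate Samples per second, Hz.
#' @param record_length Record duration, ns; must cover the last gating
#'   window (>= 77,000 ns).
#' @param signals_per_measurement Number of A-scans per measurement.
#' @param signal_interval Time between consecutive A-scans, s.
#' @return A list of class `ys_sim_config`.
#' @export
sim_config <- function(sampling_rate = 1e9,
                       record_length = 80000,
                       signals_per_measurement = 50,
                       signal_interval = 0.5) {
  stopifnot(
    sampling_rate > 0,
    record_length >= 77000,
    signals_per_measurement >= 1,
    signal_interval > 0
  )
  structure(as.list(environment()), class = "ys_sim_config")
}

#' Default echo gating windows
#'
#' The fixed time intervals, in ns, inside which the three echoes are
#' characterized: buffer-rod interface echo E1, reflector echo E2 (sample
#' path 2d), and the reverberation E3 (attenuation path 4d).
#'
#' @return A tibble with columns `echo`, `a`, `b` (ns).
#' @export
echo_windows <- function() {
  tibble::tibble(
    echo = 1:3,
    a = c(10000, 60000, 72000),
    b = c(15000, 65000, 77000)
  )
}

#' Signal-processing pipeline configuration
#'
#' @param passband Bandpass edges, Hz (default 1.5-2.5 MHz around the 2 MHz
#'   transducer).
#' @param filter_order Effective magnitude order of the zero-phase bandpass;
#'   realized as a half-order Butterworth applied forward and backward, so it
#'   must be even.
#' @param average_block Number of consecutive signals averaged into one.
#' @param envelope_window Moving-maximum window for envelope detection, ns
#'   (1000 ns = 1000 samples at 1 GHz).
#' @param echo_windows Echo gating windows, as [echo_windows()].
#' @return A list of class `ys_pipeline_config`.
#' @export
pipeline_config <- function(passband = c(1.5e6, 2.5e6),
                            filter_order = 8,
                            average_block = 5,
                            envelope_window = 1000,
                            echo_windows = sonoyeast::echo_windows()) {
  stopifnot(
    length(passband) == 2, passband[1] > 0, passband[1] < passband[2],
    filter_order >= 2, filter_order %% 2 == 0,
    average_block >= 1,
    envelope_window > 0,
    all(echo_windows$a < echo_windows$b)
  )
  structure(
    list(
      passband = passband, filter_order = filter_order,
      average_block = average_block, envelope_window = envelope_window,
      echo_windows = echo_windows
    ),
    class = "ys_pipeline_config"
  )
}

# deterministic 32-bit substream seed for a named stage + index
substream_seed <- function(seed, stage, index = 0L) {
  offset <- switch(stage,
    simulate = 101L, counts = 211L, split = 307L, init = 401L, valsplit = 503L,
    stop("unknown seed stage: ", stage)
  )
  as.integer((as.numeric(seed) * 48271 + offset * 99991 + index * 1009) %% 2147483646) + 1L
}
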