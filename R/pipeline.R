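# Butterworth bandpass as second-order sections, designed in zero-pole-gain
# form. Transfer-function coefficients of a narrow-band design (1.5-2.5 MHz
# at 1 GHz is a normalized band of 0.003-0.005) are numerically unusable, so
# the design stays in poles/zeros throughout: analytic Butterworth prototype
# poles, lowpass->bandpass transform and bilinear mapping via the signal
# package, then conjugate pole pairs become biquads. A Butterworth bandpass
# has all zeros at z = +/-1, so every section gets numerator (z^2 - 1) and an
# equal share of the overall gain.
butter_bandpass_sos <- function(order_half, passband, sampling_rate) {
  if (passband[2] >= sampling_rate / 2) {
    stop("passband infeasible: upper edge must be below the Nyquist frequency",
         call. = FALSE)
  }
  W <- passband / (sampling_rate / 2)
  T <- 2
  warped <- 2 / T * tan(pi * W / T)
  n <- order_half
  pole <- exp(1i * pi * (2 * seq_len(n) + n - 1) / (2 * n))
  if (n %% 2 == 1) pole[(n + 1) / 2] <- -1
  zpg <- signal::Zpg(zero = numeric(0), pole = pole, gain = 1)
  zpg <- signal::sftrans(zpg, W = warped, stop = FALSE)
  zpg <- signal::bilinear(zpg, T = T)
  p <- zpg$pole[Im(zpg$pole) > 0]      # one representative per conjugate pair
  g_section <- abs(Re(zpg$gain))^(1 / length(p))
  lapply(p, function(pk) {
    list(b = g_section * c(1, 0, -1), a = c(1, -2 * Re(pk), Mod(pk)^2))
  })
}

# complex frequency response of the sos cascade at frequencies f (Hz)
sos_response <- function(sos, f, sampling_rate) {
  z <- exp(1i * 2 * pi * f / sampling_rate)
  H <- rep(1 + 0i, length(z))
  for (s in sos) {
    H <- H * (s$b[1] * z^2 + s$b[2] * z + s$b[3]) /
      (s$a[1] * z^2 + s$a[2] * z + s$a[3])
  }
  H
}

#' Zero-phase bandpass filtering
#'
#' Applies the configured Butterworth bandpass forward and backward
#' (`signal::filtfilt` per second-order section), giving an effective
#' magnitude order of `filter_order` and exactly zero phase: echo timing is
#' preserved, which is essential because two of the nine features are echo
#' arrival times. The bandpass zero at DC removes any baseline offset.
#'
#' @param x Numeric waveform vector (or samples-by-signals matrix) with a
#'   `sampling_rate` attribute, as produced by [synth_ascan()] /
#'   [simulate_measurement()]; alternatively supply `sampling_rate`.
#' @param pipeline [pipeline_config()].
#' @param sampling_rate Sampling rate in Hz, if `x` carries no attribute.
#' @return Filtered object of the same shape, attributes preserved.
#' @export
bandpass_zero_phase <- function(x, pipeline = pipeline_config(),
                                sampling_rate = attr(x, "sampling_rate")) {
  if (is.null(sampling_rate)) stop("sampling_rate is required", call. = FALSE)
  sos <- butter_bandpass_sos(pipeline$filter_order / 2, pipeline$passband,
                             sampling_rate)
  filt1 <- function(v) {
    for (s in sos) v <- signal::filtfilt(s$b, s$a, v)
    v
  }
  y <- if (is.matrix(x)) apply(x, 2, filt1) else filt1(as.numeric(x))
  attributes(y) <- utils::modifyList(attributes(x) %||% list(),
                                     list(dim = dim(y)))
  y
}

#' Block-average consecutive signals
#'
#' Averages every `block` consecutive signals sample-wise (non-overlapping
#' blocks, order preserved) to raise signal-to-noise; residual noise falls as
#' `1/sqrt(block)`. 50 recorded signals with the default block of 5 become
#' 10 averaged signals.
#'
#' @param signals Samples-by-signals numeric matrix.
#' @param block Block size; the number of signals must be divisible by it.
#' @return Samples-by-(n/block) matrix, attributes preserved.
#' @export
block_average <- function(signals, block = 5) {
  stopifnot(is.matrix(signals), block >= 1)
  k <- ncol(signals)
  if (k %% block != 0) {
    stop("number of signals (", k, ") is not divisible by the block size (",
         block, "); partial blocks are not averaged", call. = FALSE)
  }
  out <- vapply(
    seq_len(k / block),
    function(j) rowMeans(signals[, ((j - 1) * block + 1):(j * block), drop = FALSE]),
    numeric(nrow(signals))
  )
  a <- attributes(signals)
  a$dim <- dim(out)
  a$timestamps <- NULL
  attributes(out) <- a
  out
}

# moving maximum over a centred window of half-width `half` samples, with
# shrinking windows at the edges; O(n) two-pass block algorithm (padding with
# -Inf, per-block prefix/suffix cumulative maxima)
moving_max <- function(v, half) {
  n <- length(v)
  if (half <= 0) return(v)
  W <- 2 * half + 1
  padded <- c(rep(-Inf, half), v, rep(-Inf, half))
  m <- length(padded)
  nblock <- ceiling(m / W)
  padded <- c(padded, rep(-Inf, nblock * W - m))
  mat <- matrix(padded, nrow = W)
  left <- apply(mat, 2, cummax)                       # prefix max per block
  right <- apply(mat[W:1, , drop = FALSE], 2, cummax)[W:1, , drop = FALSE]
  j <- seq_len(n)                                     # window [j, j + W - 1] in padded
  pmax(as.vector(right)[j], as.vector(left)[j + W - 1])
}

#' Moving-window envelope of a waveform
#'
#' Estimates the envelope `e(t)` as the maximum of `|x|` over a centred
#' moving window (default 1000 ns, i.e. 1000 samples at 1 GHz), extracting
#' the upper contour of the waveform; edge windows shrink to the available
#' samples. This is the gate-friendly envelope the feature definitions
#' expect, not a Hilbert-transform instantaneous amplitude.
#'
#' @inheritParams bandpass_zero_phase
#' @return Numeric vector `e(t)`, same length as `x`, with `e >= |x|`
#'   everywhere.
#' @export
envelope <- function(x, pipeline = pipeline_config(),
                     sampling_rate = attr(x, "sampling_rate")) {
  if (is.null(sampling_rate)) stop("sampling_rate is required", call. = FALSE)
  w_samples <- round(pipeline$envelope_window * sampling_rate / 1e9)
  if (w_samples < 1) {
    stop("envelope window is below one sample at this sampling rate", call. = FALSE)
  }
  moving_max(abs(as.numeric(x)), floor(w_samples / 2))
}

# ns -> 1-based sample index at a given rate
ns_to_index <- function(t_ns, sampling_rate) round(t_ns * sampling_rate / 1e9) + 1

#' Echo features of one gated window
#'
#' Within the gate `[a, b]`: the envelope maximum `A_max`, the time of that
#' maximum `t_max` (ns; earliest sample on ties), and the sum of `|x|` over
#' the window samples `A_sum` (computed on the filtered signal, not the
#' envelope; endpoints inclusive; not normalized by window length).
#'
#' @param x Filtered (and typically block-averaged) waveform vector.
#' @param env Envelope of `x` from [envelope()].
#' @param window One row of [echo_windows()] (fields `a`, `b`, ns).
#' @param sampling_rate Hz.
#' @return Named list `a_max`, `t_max`, `a_sum`.
#' @export
extract_echo_features <- function(x, env, window,
                                  sampling_rate = attr(x, "sampling_rate")) {
  if (is.null(sampling_rate)) stop("sampling_rate is required", call. = FALSE)
  ia <- ns_to_index(window$a, sampling_rate)
  ib <- ns_to_index(window$b, sampling_rate)
  if (ia < 1 || ib > length(x)) {
    stop("echo window [", window$a, ", ", window$b,
         "] ns lies outside the recorded samples (truncated acquisition?)",
         call. = FALSE)
  }
  seg <- env[ia:ib]
  imax <- which.max(seg)                     # earliest index on exact ties
  list(
    a_max = seg[imax],
    t_max = (ia + imax - 2) * (1e9 / sampling_rate),
    a_sum = sum(abs(x[ia:ib]))
  )
}

#' Full feature extraction for one measurement
#'
#' Filters every recorded signal ([bandpass_zero_phase()]), block-averages
#' them ([block_average()]), then per averaged signal computes the envelope
#' and the three features of each of the three echo gates: nine features per
#' averaged signal, 10 rows for a default 50-signal measurement.
#'
#' @param signals Samples-by-signals matrix from [simulate_measurement()]
#'   (or real data with a `sampling_rate` attribute).
#' @param pipeline [pipeline_config()].
#' @param sampling_rate Hz, if `signals` carries no attribute.
#' @return Tibble with `signal_block` and the nine columns
#'   [ys_feature_cols()].
#' @export
extract_features <- function(signals, pipeline = pipeline_config(),
                             sampling_rate = attr(signals, "sampling_rate")) {
  if (is.null(sampling_rate)) stop("sampling_rate is required", call. = FALSE)
  filtered <- bandpass_zero_phase(signals, pipeline, sampling_rate)
  averaged <- block_average(filtered, pipeline$average_block)
  win <- pipeline$echo_windows
  purrr::map_dfr(seq_len(ncol(averaged)), function(j) {
    x <- averaged[, j]
    e <- envelope(x, pipeline, sampling_rate)
    row <- list(signal_block = j)
    for (i in seq_len(nrow(win))) {
      f <- extract_echo_features(x, e, win[i, ], sampling_rate)
      row[[paste0("a_max_", win$echo[i])]] <- f$a_max
      row[[paste0("t_max_", win$echo[i])]] <- f$t_max
      row[[paste0("a_sum_", win$echo[i])]] <- f$a_sum
    }
    tibble::as_tibble(row)
  })
}
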