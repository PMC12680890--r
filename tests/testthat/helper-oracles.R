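# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities with plain loops so they stay independent of the
# package's vectorized implementations.

# moving maximum over a centred window of half-width `half`, shrinking at edges
naive_moving_max <- function(v, half) {
  n <- length(v)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - half)
    hi <- min(n, i + half)
    m <- -Inf
    for (j in lo:hi) if (v[j] > m) m <- v[j]
    out[i] <- m
  }
  out
}

# per-window echo features by exhaustive scan
naive_echo_features <- function(x, env, a_ns, b_ns, rate) {
  ia <- round(a_ns * rate / 1e9) + 1
  ib <- round(b_ns * rate / 1e9) + 1
  best <- -Inf; best_i <- ia; s <- 0
  for (i in ia:ib) {
    if (env[i] > best) { best <- env[i]; best_i <- i }
    s <- s + abs(x[i])
  }
  list(a_max = best, t_max = (best_i - 1) * (1e9 / rate), a_sum = s)
}

# central finite-difference gradient of a scalar function of a vector
fd_gradient <- function(fn, par, h = 1e-6) {
  vapply(seq_along(par), function(i) {
    e <- numeric(length(par)); e[i] <- h
    (fn(par + e) - fn(par - e)) / (2 * h)
  }, numeric(1))
}

# Gaussian-windowed toneburst placed at t0_ns, at `rate` Hz, n samples
make_toneburst <- function(n, rate, t0_ns, f0 = 2e6, sigma_ns = 500, A = 1) {
  t_ns <- (seq_len(n) - 1) * (1e9 / rate)
  dt <- t_ns - t0_ns
  A * exp(-dt^2 / (2 * sigma_ns^2)) * sin(2 * pi * (f0 / 1e9) * dt)
}

# a coarse acquisition configuration used throughout the tests
fast_config <- function(...) sim_config(sampling_rate = 1e8, ...)

# synthetic tabular feature set with a learnable structure, for model-layer
# tests that do not need the waveform simulator
fake_features <- function(n_rep = 2, seed = 42, sd_noise = 0.01) {
  design <- yeast_design(n_rep)
  design <- add_cell_counts(design, acoustic_params(count_cv = 0.02), seed = seed)
  withr::with_seed(seed, {
    rows <- design[rep(seq_len(nrow(design)), each = 2), ]
    k_str <- c(S_CEREVISIAE = 1, WB06 = 2, W3470 = 3)[as.character(rows$strain)]
    u <- rows$yeast_wt_pct * k_str
    v <- (rows$wort_wt_pct - 12) / 2
    n <- nrow(rows)
    feat <- sapply(1:9, function(j) {
      sin(j) * u + cos(j) * v + 0.3 * cos(2 * j) * u^2 + stats::rnorm(n, 0, sd_noise)
    })
    colnames(feat) <- ys_feature_cols()
    dplyr::bind_cols(rows, tibble::as_tibble(feat))
  })
}
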