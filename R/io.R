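#' Write / read an extracted feature table as CSV
#'
#' One row per averaged signal: measurement labels plus the nine
#' echo-derived feature columns.
#'
#' @param features Tibble from [simulate_features()].
#' @param path CSV path.
#' @return `path` (write) or the feature tibble with `strain` restored as a
#'   factor (read).
#' @export
write_features_csv <- function(features, path) {
  readr::write_csv(features, path)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE) |>
    dplyr::mutate(strain = factor(.data$strain, levels = ys_strains()))
}

#' Serialize a trained approach model to JSON
#'
#' Stores shapes, flattened weights, the scaler, the input schema, the
#' network configuration and the training trace in a portable, diffable
#' form.
#'
#' @param model A `ys_model`.
#' @param path JSON path.
#' @return `path` (write) or the reconstructed `ys_model` (read).
#' @export
write_model_json <- function(model, path) {
  cfg <- model$net$config
  obj <- list(
    schema = model$schema,
    scaler = list(mean = as.list(model$scaler$mean),
                  sd = as.list(model$scaler$sd),
                  columns = model$scaler$columns),
    config = unclass(cfg),
    weights = lapply(model$net$weights, function(w) {
      if (is.matrix(w)) list(dim = dim(w), values = as.numeric(w))
      else list(dim = length(w), values = as.numeric(w))
    }),
    trace = as.list(model$net$trace),
    best_iteration = model$net$best_iteration,
    stopped_iteration = model$net$stopped_iteration,
    optimizer = model$net$optimizer
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- lapply(obj$weights, function(x) {
    if (length(x$dim) == 2) matrix(x$values, x$dim[1], x$dim[2]) else as.numeric(x$values)
  })
  cfg <- obj$config
  cfg$hidden <- as.numeric(cfg$hidden)
  class(cfg) <- "ys_net_config"
  net <- structure(
    list(weights = structure(w, class = "ys_weights"), config = cfg,
         trace = tibble::as_tibble(obj$trace),
         best_iteration = obj$best_iteration,
         stopped_iteration = obj$stopped_iteration,
         optimizer = obj$optimizer),
    class = "ys_mlp"
  )
  scaler <- structure(
    list(mean = unlist(obj$scaler$mean), sd = unlist(obj$scaler$sd),
         columns = obj$scaler$columns),
    class = "ys_scaler"
  )
  schema <- obj$schema
  ys_model(net, scaler, schema)
}

#' Write a split plan manifest as JSON
#'
#' @param split A `ys_split` from [make_split()].
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_split_json <- function(split, path) {
  jsonlite::write_json(unclass(split), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Export / import simulated waveforms
#'
#' Stores the raw A-scans of a run as one long Feather table (columns:
#' `measurement_id`, `signal`, `sample`, `amplitude`) together with a CSV
#' index of per-measurement metadata. Intended for small runs and external
#' inspection; the feature pipeline itself streams measurements in memory
#' and does not need these files.
#'
#' @param design Design tibble (with cell-count labels if available).
#' @param waveforms Named list (by `measurement_id`) of samples-by-signals
#'   matrices from [simulate_measurement()].
#' @param dir Output directory, created if missing.
#' @return `dir` (write) or a list `index`, `waveforms` (read).
#' @export
write_waveforms <- function(design, waveforms, dir) {
  if (!requireNamespace("arrow", quietly = TRUE)) {
    stop("the arrow package is required to write waveform containers", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  long <- purrr::imap_dfr(waveforms, function(m, id) {
    tibble::tibble(
      measurement_id = id,
      signal = rep(seq_len(ncol(m)), each = nrow(m)),
      sample = rep(seq_len(nrow(m)), ncol(m)),
      amplitude = as.numeric(m),
      sampling_rate = attr(m, "sampling_rate")
    )
  })
  arrow::write_feather(long, file.path(dir, "waveforms.feather"))
  readr::write_csv(design, file.path(dir, "index.csv"))
  invisible(dir)
}

#' @rdname write_waveforms
#' @export
read_waveforms <- function(dir) {
  if (!requireNamespace("arrow", quietly = TRUE)) {
    stop("the arrow package is required to read waveform containers", call. = FALSE)
  }
  long <- tibble::as_tibble(arrow::read_feather(file.path(dir, "waveforms.feather")))
  index <- readr::read_csv(file.path(dir, "index.csv"), show_col_types = FALSE)
  waveforms <- lapply(split(long, long$measurement_id), function(d) {
    m <- matrix(d$amplitude, nrow = max(d$sample))
    attr(m, "sampling_rate") <- d$sampling_rate[1]
    m
  })
  list(index = index, waveforms = waveforms)
}
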