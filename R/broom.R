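#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the evaluation metrics of an approach run
#'
#' One row per model, partition (per-fold, cross-validation mean, test) and
#' metric, in long format.
#'
#' @param x A `ys_run` from [run_approach()].
#' @param ... Unused.
#' @return Tibble with `model`, `partition`, `metric`, `value`.
#' @method tidy ys_run
#' @export
tidy.ys_run <- function(x, ...) {
  long <- function(tbl, partition) {
    tbl |>
      dplyr::select(-dplyr::any_of("n")) |>
      tidyr::pivot_longer(-dplyr::any_of(c("model", "fold")),
                          names_to = "metric", values_to = "value") |>
      dplyr::mutate(partition = partition, .after = "model")
  }
  dplyr::bind_rows(
    long(x$fold_metrics, "cv_fold"),
    long(x$cv_mean, "cv_mean"),
    long(x$test_metrics, "test")
  )
}

#' One-row summary of an approach run (test-set metrics)
#'
#' @param x A `ys_run`.
#' @param ... Unused.
#' @return Tibble, one row per model, with the test metrics.
#' @method glance ys_run
#' @export
glance.ys_run <- function(x, ...) {
  dplyr::mutate(x$test_metrics, approach = x$approach, .before = 1)
}

#' Tidy a trained network's training trace
#'
#' @param x A `ys_mlp` from [train_mlp()].
#' @param ... Unused.
#' @return The trace tibble: `iteration`, `train_loss`, `val_loss`.
#' @method tidy ys_mlp
#' @export
tidy.ys_mlp <- function(x, ...) x$trace

#' One-row training summary of a network
#'
#' @param x A `ys_mlp`.
#' @param ... Unused.
#' @return Tibble: iterations run, best-validation iteration, final losses.
#' @method glance ys_mlp
#' @export
glance.ys_mlp <- function(x, ...) {
  tibble::tibble(
    task = x$config$task,
    iterations = x$stopped_iteration,
    best_iteration = x$best_iteration,
    train_loss = x$trace$train_loss[nrow(x$trace)],
    val_loss = min(x$trace$val_loss)
  )
}
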