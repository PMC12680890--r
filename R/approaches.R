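ys_model <- function(net, scaler, schema) {
  structure(list(net = net, scaler = scaler, schema = schema), class = "ys_model")
}

#' @export
print.ys_model <- function(x, ...) {
  cat("<ys_model> approach ", x$schema$approach, " (", x$schema$task, "), ",
      length(x$schema$columns), " inputs\n", sep = "")
  invisible(x)
}

# fit one network on the given feature rows (already restricted to the
# approach's scope); handles assembly, scaling, and target units
fit_model_rows <- function(features, approach, rows, seed) {
  asm <- assemble_approach(features[rows, ], approach)
  scaler <- fit_scaler(asm$x)
  x_std <- apply_scaler(asm$x, scaler)
  cfg <- net_config(
    input_width = ncol(asm$x),
    task = asm$schema$task,
    seed = seed
  )
  y <- if (cfg$task == "regression") asm$y / 1e6 else asm$y
  ys_model(train_mlp(x_std, y, cfg), scaler, asm$schema)
}

#' Predict from a trained approach model
#'
#' Assembles the model's input columns from a feature tibble, applies the
#' stored standardization, and runs the network forward. Regression
#' predictions are returned in cells/mL; classification returns the argmax
#' class (earliest class on exact probability ties) or the softmax
#' probability matrix.
#'
#' @param object A fitted model from [run_approach()]'s `models` list.
#' @param features Feature tibble with the columns the approach needs.
#' @param type `"response"` (default: cells/mL or class labels) or `"prob"`
#'   (classification probabilities).
#' @param ... Unused.
#' @return Numeric vector, factor, or probability matrix.
#' @export
predict.ys_model <- function(object, features, type = c("response", "prob"), ...) {
  type <- match.arg(type)
  asm <- assemble_approach(features, object$schema$approach)
  if (!identical(colnames(asm$x), object$schema$columns)) {
    stop("feature columns do not match the model schema", call. = FALSE)
  }
  x <- apply_scaler(asm$x, object$scaler)
  if (object$schema$task == "regression") {
    mlp_forward(object$net$weights, x, "regression") * 1e6
  } else {
    p <- mlp_forward(object$net$weights, x, "classification")
    colnames(p) <- ys_strains()
    if (type == "prob") p else {
      factor(ys_strains()[apply(p, 1, which.max)], levels = ys_strains())
    }
  }
}

eval_rows <- function(model, features, rows) {
  task <- model$schema$task
  if (task == "regression") {
    pred <- predict(model, features[rows, ])
    list(
      metrics = regression_metrics(features$measured_cell_count[rows], pred),
      predictions = tibble::tibble(
        measurement_id = features$measurement_id[rows],
        strain = features$strain[rows],
        measured = features$measured_cell_count[rows],
        predicted = pred
      )
    )
  } else {
    pred <- predict(model, features[rows, ])
    truth <- factor(as.character(features$strain[rows]), ys_strains())
    cm <- confusion_matrix(truth, pred)
    cls <- classification_metrics(cm)
    list(
      metrics = tibble::tibble(accuracy = cls$accuracy, n = sum(cm)),
      per_class = cls$per_class,
      confusion = cm,
      predictions = tibble::tibble(
        measurement_id = features$measurement_id[rows],
        truth = truth, predicted = pred
      )
    )
  }
}

#' Fivefold cross-validation and test evaluation of one model job
#'
#' For each fold, retrains the network (scaler refitted on the fold's
#' training rows, so no fold leaks into its own standardization), scores the
#' held-out fold, and aggregates fold metrics by their unweighted mean; a
#' final model trained on the full training partition is scored on the test
#' partition. For classification, out-of-fold predictions are also pooled
#' into one cross-validation confusion matrix.
#'
#' @param features Feature tibble.
#' @param approach Approach id 1-5 (for approach 1, `features` must already
#'   be one strain).
#' @param split [make_split()] plan whose row indices refer to `features`.
#' @param seed Seed for initialization and inner validation splits.
#' @param scope_rows Row indices defining the job's scope (default all rows).
#' @return List: `fold_metrics` (5 rows), `cv_mean` (1 row), `test_metrics`,
#'   `model` (the final trained `ys_model`), `predictions` (test-set parity
#'   data), and for classification `cv_confusion`, `test_confusion`,
#'   `per_class` metrics for both.
#' @export
crossval_report <- function(features, approach, split, seed = 1,
                            scope_rows = seq_len(nrow(features))) {
  g_train <- intersect(split$train_rows, scope_rows)
  g_test <- intersect(split$test_rows, scope_rows)
  fold_of <- stats::setNames(split$fold, split$train_rows)[as.character(g_train)]
  n_folds <- max(split$fold)
  fold_res <- purrr::map(seq_len(n_folds), function(f) {
    tr <- g_train[fold_of != f]
    va <- g_train[fold_of == f]
    m <- fit_model_rows(features, approach, tr, seed = seed + f)
    ev <- eval_rows(m, features, va)
    ev$metrics$fold <- f
    ev
  })
  fold_metrics <- dplyr::bind_rows(purrr::map(fold_res, "metrics"))
  cv_mean <- dplyr::summarise(
    fold_metrics,
    dplyr::across(-dplyr::any_of(c("fold", "n")), mean),
    n = sum(.data$n)
  )
  final <- fit_model_rows(features, approach, g_train, seed = seed)
  test_ev <- eval_rows(final, features, g_test)
  out <- list(
    fold_metrics = fold_metrics,
    cv_mean = cv_mean,
    test_metrics = test_ev$metrics,
    model = final,
    predictions = test_ev$predictions
  )
  if (final$schema$task == "classification") {
    cv_pred <- dplyr::bind_rows(purrr::map(fold_res, "predictions"))
    out$cv_confusion <- confusion_matrix(cv_pred$truth, cv_pred$predicted)
    out$cv_per_class <- classification_metrics(out$cv_confusion)$per_class
    out$test_confusion <- test_ev$confusion
    out$test_per_class <- test_ev$per_class
  }
  out
}

#' Run one modeling approach end to end
#'
#' Executes assembly, standardization, training (fivefold cross-validation
#' plus a final model), and evaluation for one of the five approaches on an
#' extracted feature table. Approach 1 expands into three strain-specific
#' jobs sharing the global split; approaches 2-4 fit one regression network
#' each; approach 5 fits the softmax strain classifier.
#'
#' @param features Feature tibble from [simulate_features()].
#' @param approach Approach id 1-5.
#' @param seed Root seed (split, initialization, inner validation).
#' @param split Optional [make_split()] plan to share across approaches;
#'   computed from `seed` when missing.
#' @return Object of class `ys_run` with `models` (1 or 3), `fold_metrics`,
#'   `cv_mean`, `test_metrics`, test-set `predictions`, confusion matrices
#'   for approach 5, the `split`, and the `seed`.
#' @export
run_approach <- function(features, approach, seed = 1, split = NULL) {
  stopifnot(approach %in% 1:5)
  split <- split %||% make_split(features, seed = seed)
  jobs <- if (approach == 1) {
    lapply(ys_strains(), function(s) {
      list(label = s, rows = which(as.character(features$strain) == s))
    })
  } else {
    list(list(label = paste0("approach_", approach),
              rows = seq_len(nrow(features))))
  }
  reports <- purrr::map(jobs, function(j) {
    crossval_report(features, approach, split, seed = seed, scope_rows = j$rows)
  })
  names(reports) <- purrr::map_chr(jobs, "label")
  bind_labeled <- function(field) {
    dplyr::bind_rows(purrr::imap(reports, function(r, nm) {
      dplyr::mutate(r[[field]], model = nm, .before = 1)
    }))
  }
  out <- list(
    approach = approach,
    task = reports[[1]]$model$schema$task,
    models = purrr::map(reports, "model"),
    fold_metrics = bind_labeled("fold_metrics"),
    cv_mean = bind_labeled("cv_mean"),
    test_metrics = bind_labeled("test_metrics"),
    predictions = bind_labeled("predictions"),
    split = split,
    seed = seed
  )
  if (approach == 5) {
    out$cv_confusion <- reports[[1]]$cv_confusion
    out$test_confusion <- reports[[1]]$test_confusion
    out$cv_per_class <- reports[[1]]$cv_per_class
    out$test_per_class <- reports[[1]]$test_per_class
  }
  structure(out, class = "ys_run")
}

#' @export
print.ys_run <- function(x, ...) {
  cat("<ys_run> approach ", x$approach, " (", x$task, "), ",
      length(x$models), " model(s)\n", sep = "")
  print(x$test_metrics)
  invisible(x)
}

#' Run all five approaches on one shared dataset and split
#'
#' @param features Feature tibble.
#' @param seed Root seed; one shared group-aware split is derived from it.
#' @param approaches Subset of 1:5 to run (default all; seven trained
#'   networks in total).
#' @return Named list of [run_approach()] results, class `ys_run_set`.
#' @export
run_all <- function(features, seed = 1, approaches = 1:5) {
  split <- make_split(features, seed = seed)
  out <- purrr::map(approaches, function(a) {
    run_approach(features, a, seed = seed, split = split)
  })
  names(out) <- paste0("approach_", approaches)
  structure(out, class = "ys_run_set")
}
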