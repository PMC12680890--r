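#' One-hot encoding of strain identity
#'
#' `S_CEREVISIAE -> (1, 0, 0)`, `WB06 -> (0, 1, 0)`, `W3470 -> (0, 0, 1)`.
#' Unknown labels are an error, never a silent zero vector.
#'
#' @param strain Vector of strain codes or factor over [ys_strains()].
#' @return Numeric matrix, `length(strain)` x 3, columns named
#'   `strain_<code>`.
#' @export
one_hot_strain <- function(strain) {
  strain <- as.character(strain)
  bad <- setdiff(unique(strain), ys_strains())
  if (length(bad) > 0) {
    stop("unknown strain code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  m <- outer(strain, ys_strains(), "==") * 1
  colnames(m) <- paste0("strain_", ys_strains())
  m
}

#' Ordinal encoding of wort extract concentration
#'
#' Maps the ordered levels 10, 12, 14 wt% to -1, 0, +1.
#'
#' @param wort_wt_pct Vector over \{10, 12, 14\}.
#' @return Numeric vector in \{-1, 0, 1\}.
#' @export
ordinal_wort <- function(wort_wt_pct) {
  if (!all(wort_wt_pct %in% ys_worts())) {
    stop("wort concentration must be one of 10, 12, 14 wt%", call. = FALSE)
  }
  (wort_wt_pct - 12) / 2
}

#' Assemble the model matrix for one modeling approach
#'
#' The five approaches share the nine echo-derived features and differ in
#' covariates and target:
#' \describe{
#'   \item{1}{per-strain regression, 9 features (rows must be one strain)}
#'   \item{2}{combined regression, 9 features}
#'   \item{3}{combined regression, 9 features + one-hot strain (12 columns)}
#'   \item{4}{combined regression, 9 + one-hot strain + ordinal wort (13)}
#'   \item{5}{strain classification, 9 features, target = strain}
#' }
#'
#' @param features Feature tibble from [simulate_features()] (or read from
#'   CSV) with the nine feature columns plus `strain`, `wort_wt_pct`,
#'   `measured_cell_count`, `measurement_id`.
#' @param approach Integer 1-5.
#' @return List with `x` (numeric matrix), `y` (cells/mL for regression, a
#'   factor for classification), `group_id` (measurement ids, for
#'   leakage-free splitting), and `schema` (approach, task, column names,
#'   which columns are standardized).
#' @export
assemble_approach <- function(features, approach) {
  stopifnot(approach %in% 1:5)
  us <- as.matrix(features[, ys_feature_cols()])
  storage.mode(us) <- "double"
  x <- switch(as.character(approach),
    `1` = ,
    `2` = ,
    `5` = us,
    `3` = cbind(us, one_hot_strain(features$strain)),
    `4` = cbind(us, one_hot_strain(features$strain),
                wort_ordinal = ordinal_wort(features$wort_wt_pct))
  )
  if (approach == 1 && length(unique(features$strain)) > 1) {
    stop("approach 1 is strain-specific: filter the rows to a single strain first",
         call. = FALSE)
  }
  task <- if (approach == 5) "classification" else "regression"
  y <- if (task == "classification") {
    factor(as.character(features$strain), levels = ys_strains())
  } else {
    features$measured_cell_count
  }
  list(
    x = x, y = y,
    group_id = features$measurement_id,
    schema = list(
      approach = approach, task = task,
      columns = colnames(x),
      scaled_columns = ys_feature_cols()
    )
  )
}

#' Fit a standardizing scaler on training rows
#'
#' Means and standard deviations of the nine echo-derived feature columns
#' only; encoded covariate columns pass through unscaled. Fit on training
#' rows only, never on test rows. A constant column gets standard deviation
#' 1 (with a warning) and is thereby centred to zeros.
#'
#' @param x Model matrix (training rows only).
#' @param columns Columns to standardize (default the nine features).
#' @return List of class `ys_scaler` with `mean`, `sd`, `columns`.
#' @export
fit_scaler <- function(x, columns = ys_feature_cols()) {
  columns <- intersect(columns, colnames(x))
  mu <- colMeans(x[, columns, drop = FALSE])
  sd <- apply(x[, columns, drop = FALSE], 2, stats::sd)
  if (any(sd == 0)) {
    warning("constant feature column(s) ",
            paste(columns[sd == 0], collapse = ", "),
            ": standard deviation set to 1", call. = FALSE)
    sd[sd == 0] <- 1
  }
  structure(list(mean = mu, sd = sd, columns = columns), class = "ys_scaler")
}

#' Apply a fitted scaler
#'
#' @param x Model matrix.
#' @param scaler From [fit_scaler()].
#' @return `x` with the scaler's columns standardized; all other columns
#'   (one-hot, ordinal) untouched.
#' @export
apply_scaler <- function(x, scaler) {
  stopifnot(inherits(scaler, "ys_scaler"))
  x[, scaler$columns] <- sweep(
    sweep(x[, scaler$columns, drop = FALSE], 2, scaler$mean, "-"),
    2, scaler$sd, "/"
  )
  x
}

#' Train/test split with fivefold cross-validation plan
#'
#' Randomly partitions the data 80:20 into training and test and assigns the
#' training part to five cross-validation folds. By default the split is
#' group-aware — all rows of one physical measurement stay on the same side
#' and in the same fold, so near-duplicate repeated signals never leak across
#' partitions — and stratified by strain. `group_aware = FALSE` reproduces a
#' literal row-level random split.
#'
#' @param features Feature tibble (needs `measurement_id` and `strain`).
#' @param seed Integer seed; the same seed always yields the same plan.
#' @param group_aware Split by measurement (default) or by row.
#' @param test_fraction Held-out fraction (default 0.2).
#' @param n_folds Number of CV folds over the training rows (default 5).
#' @return List of class `ys_split`: integer row indices `train_rows`,
#'   `test_rows`, integer `fold` (one entry per training row, 1..n_folds),
#'   plus `seed` and `policy`.
#' @export
make_split <- function(features, seed = 1, group_aware = TRUE,
                       test_fraction = 0.2, n_folds = 5) {
  unit <- if (group_aware) features$measurement_id else seq_len(nrow(features))
  strain_of <- tapply(as.character(features$strain), unit, function(s) s[1])
  units <- names(strain_of)
  if (group_aware && length(units) < 10) {
    stop("need at least 10 measurement groups for a group-aware split", call. = FALSE)
  }
  withr::with_seed(substream_seed(seed, "split"), {
    test_units <- character(0)
    fold_of <- stats::setNames(integer(0), character(0))
    for (s in unique(strain_of)) {
      u <- sample(units[strain_of == s])
      n_test <- round(test_fraction * length(u))
      test_units <- c(test_units, u[seq_len(n_test)])
      train_u <- u[-seq_len(n_test)]
      if (length(train_u) < n_folds) {
        stop("too few units to form ", n_folds, " non-empty folds", call. = FALSE)
      }
      fold_of <- c(fold_of, stats::setNames(
        rep_len(seq_len(n_folds), length(train_u)), train_u
      ))
    }
  })
  test_rows <- which(unit %in% test_units)
  train_rows <- setdiff(seq_len(nrow(features)), test_rows)
  structure(
    list(
      train_rows = train_rows,
      test_rows = test_rows,
      fold = unname(fold_of[as.character(unit[train_rows])]),
      seed = seed,
      policy = if (group_aware) "group" else "row"
    ),
    class = "ys_split"
  )
}
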