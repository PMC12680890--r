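#' Enumerate the full concentration-gradient measurement design
#'
#' Three strains x three wort extract concentrations (10/12/14 wt%) x six
#' yeast levels (0.0-1.0 wt% in 0.2 steps) x `replicates` biological
#' replicates, in deterministic order (strain, wort, level, replicate
#' ascending). With three replicates this is the full 162-measurement study
#' design.
#'
#' @param replicates Number of biological replicates (>= 0).
#' @return A tibble with one row per physical measurement: `measurement_id`,
#'   `strain` (factor over [ys_strains()]), `wort_wt_pct`, `yeast_wt_pct`,
#'   `replicate`.
#' @examples
#' yeast_design(3)  # 162 rows
#' @export
yeast_design <- function(replicates = 3) {
  stopifnot(length(replicates) == 1, replicates >= 0, replicates == round(replicates))
  grid <- tidyr::expand_grid(
    strain = factor(ys_strains(), levels = ys_strains()),
    wort_wt_pct = ys_worts(),
    yeast_wt_pct = ys_levels(),
    replicate = seq_len(replicates)
  )
  dplyr::mutate(grid,
    measurement_id = sprintf(
      "%s_w%02d_y%03.0f_r%d",
      strain, wort_wt_pct, 100 * yeast_wt_pct, replicate
    ),
    .before = 1
  )
}

#' Cell-count label model for one suspension
#'
#' The true count is linear in the yeast mass fraction,
#' `count_slope[strain] * yeast_wt_pct`; the measured count emulates a manual
#' hemocytometer determination with multiplicative Gaussian error of
#' coefficient of variation `count_cv`, truncated at zero. A blank suspension
#' (0 wt% yeast) measures exactly zero.
#'
#' @param strain Strain code, one of [ys_strains()].
#' @param yeast_wt_pct Yeast mass fraction, wt% (>= 0).
#' @param params [acoustic_params()] list (uses `count_slope`, `count_cv`).
#' @return A list with `true_count` and `measured_count`, cells/mL.
#' @export
cell_count_from_fraction <- function(strain, yeast_wt_pct, params = acoustic_params()) {
  strain <- as.character(strain)
  if (!strain %in% ys_strains()) {
    stop("unknown strain code: ", strain, call. = FALSE)
  }
  stopifnot(yeast_wt_pct >= 0)
  true_count <- params$count_slope[[strain]] * yeast_wt_pct
  if (yeast_wt_pct == 0) {
    return(list(true_count = 0, measured_count = 0))
  }
  eps <- stats::rnorm(1, 0, params$count_cv)
  list(true_count = true_count, measured_count = max(0, true_count * (1 + eps)))
}

#' Attach cell-count labels to a measurement design
#'
#' Draws one hemocytometer-style measured count per design row via
#' [cell_count_from_fraction()], reproducibly for a given seed.
#'
#' @param design Tibble from [yeast_design()].
#' @param params [acoustic_params()].
#' @param seed Integer seed for the counting-error draws.
#' @return `design` with `true_cell_count` and `measured_cell_count` columns.
#' @export
add_cell_counts <- function(design, params = acoustic_params(), seed = 1) {
  withr::with_seed(substream_seed(seed, "counts"), {
    counts <- purrr::map2(
      as.character(design$strain), design$yeast_wt_pct,
      function(s, y) cell_count_from_fraction(s, y, params)
    )
  })
  dplyr::mutate(design,
    true_cell_count = purrr::map_dbl(counts, "true_count"),
    measured_cell_count = purrr::map_dbl(counts, "measured_count")
  )
}
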