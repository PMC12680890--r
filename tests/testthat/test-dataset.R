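test_that("strain one-hot encoding follows the fixed class order", {
  expect_equal(unname(one_hot_strain("S_CEREVISIAE")[1, ]), c(1, 0, 0))
  expect_equal(unname(one_hot_strain("WB06")[1, ]), c(0, 1, 0))
  expect_equal(unname(one_hot_strain("W3470")[1, ]), c(0, 0, 1))
  m <- one_hot_strain(c("WB06", "W3470", "WB06"))
  expect_equal(rowSums(m), rep(1, 3))
  expect_error(one_hot_strain("LAGER"), "unknown strain")
})

test_that("wort encoding is the ordered map 10/12/14 -> -1/0/+1", {
  expect_equal(ordinal_wort(10), -1)
  expect_equal(ordinal_wort(12), 0)
  expect_equal(ordinal_wort(14), 1)
  expect_true(all(diff(ordinal_wort(c(10, 12, 14))) > 0))
  expect_error(ordinal_wort(11), "10, 12, 14")
})

test_that("assembled matrices have the approach-specific widths and targets", {
  f <- fake_features(1)
  expect_equal(ncol(assemble_approach(f, 2)$x), 9)
  expect_equal(ncol(assemble_approach(f, 3)$x), 12)
  expect_equal(ncol(assemble_approach(f, 4)$x), 13)
  a2 <- assemble_approach(f, 2)
  a5 <- assemble_approach(f, 5)
  expect_identical(a2$x, a5$x)                 # same inputs, different target
  expect_type(a2$y, "double")
  expect_s3_class(a5$y, "factor")
  expect_error(assemble_approach(f, 1), "single strain")
  f_one <- dplyr::filter(f, strain == "WB06")
  expect_equal(ncol(assemble_approach(f_one, 1)$x), 9)
  # column order: ultrasound block, one-hot block, ordinal scalar
  expect_identical(colnames(assemble_approach(f, 4)$x),
                   c(ys_feature_cols(), paste0("strain_", ys_strains()), "wort_ordinal"))
})

test_that("the scaler standardizes only the ultrasound block, on training data", {
  f <- fake_features(1)
  x <- assemble_approach(f, 4)$x
  sc <- fit_scaler(x)
  xs <- apply_scaler(x, sc)
  expect_equal(unname(colMeans(xs[, ys_feature_cols()])), rep(0, 9),
               tolerance = 1e-10)
  expect_equal(unname(apply(xs[, ys_feature_cols()], 2, sd)), rep(1, 9),
               tolerance = 1e-10)
  expect_identical(xs[, 10:13], x[, 10:13])    # encoded columns pass through
  # affine maps do not compose to the identity: double application re-centres
  expect_false(isTRUE(all.equal(apply_scaler(xs, sc), xs)))
})

test_that("constant feature columns are centred with a warning, not divided by zero", {
  f <- fake_features(1)
  x <- assemble_approach(f, 2)$x
  x[, "a_sum_3"] <- 7
  expect_warning(sc <- fit_scaler(x), "constant")
  xs <- apply_scaler(x, sc)
  expect_equal(unname(xs[, "a_sum_3"]), rep(0, nrow(x)))
})

test_that("the group-aware split partitions rows without measurement leakage", {
  f <- fake_features(2)
  sp <- make_split(f, seed = 3)
  expect_setequal(c(sp$train_rows, sp$test_rows), seq_len(nrow(f)))
  expect_length(intersect(sp$train_rows, sp$test_rows), 0)
  gid <- f$measurement_id
  expect_length(intersect(gid[sp$train_rows], gid[sp$test_rows]), 0)
  # folds partition the training rows; no measurement straddles two folds
  expect_length(sp$fold, length(sp$train_rows))
  expect_setequal(unique(sp$fold), 1:5)
  per_group_folds <- tapply(sp$fold, gid[sp$train_rows], function(x) length(unique(x)))
  expect_true(all(per_group_folds == 1))
  # close to the 80:20 target at group granularity
  n_groups <- length(unique(gid))
  n_test_groups <- length(unique(gid[sp$test_rows]))
  expect_equal(n_test_groups / n_groups, 0.2, tolerance = 0.05)
  expect_identical(sp, make_split(f, seed = 3))
  expect_false(identical(sp$test_rows, make_split(f, seed = 4)$test_rows))
})

test_that("row-level splitting and small-design errors behave as specified", {
  f <- fake_features(2)
  sp <- make_split(f, seed = 1, group_aware = FALSE)
  expect_equal(length(sp$test_rows) / nrow(f), 0.2, tolerance = 0.05)
  expect_equal(sp$policy, "row")
  expect_error(make_split(f[1:8, ], seed = 1), "at least 10")
})
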