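feats <- fake_features(2)

test_that("approach 1 expands into three strain-specific models", {
  r1 <- run_approach(feats, 1, seed = 2)
  expect_length(r1$models, 3)
  expect_setequal(names(r1$models), ys_strains())
  expect_equal(nrow(r1$fold_metrics), 15)       # 5 folds x 3 models
  expect_equal(nrow(r1$test_metrics), 3)
  # strain-specific recovery on the synthetic fixture
  expect_true(all(r1$test_metrics$r2 > 0.9))
})

test_that("cross-validation reports five folds, their mean, and a test row", {
  sp <- make_split(feats, seed = 2)
  rep4 <- crossval_report(feats, 4, sp, seed = 2)
  expect_equal(nrow(rep4$fold_metrics), 5)
  expect_equal(sort(rep4$fold_metrics$fold), 1:5)
  expect_equal(rep4$cv_mean$r2, mean(rep4$fold_metrics$r2))
  expect_equal(rep4$cv_mean$rmse, mean(rep4$fold_metrics$rmse))
  expect_equal(nrow(rep4$test_metrics), 1)
  expect_equal(nrow(rep4$predictions), length(intersect(sp$test_rows, seq_len(nrow(feats)))))
})

test_that("runs are deterministic per seed and structured per approach", {
  ra <- run_approach(feats, 3, seed = 9)
  rb <- run_approach(feats, 3, seed = 9)
  expect_equal(ra$test_metrics, rb$test_metrics)
  expect_identical(ra$models[[1]]$net$weights, rb$models[[1]]$net$weights)
  runs <- run_all(feats, seed = 9, approaches = c(2, 4))
  expect_named(runs, c("approach_2", "approach_4"))
  # all approaches share one split
  expect_identical(runs$approach_2$split$test_rows, runs$approach_4$split$test_rows)
})

test_that("the classifier run carries CV and test confusion matrices", {
  r5 <- run_approach(feats, 5, seed = 2)
  expect_s3_class(r5$cv_confusion, "ys_confusion")
  expect_s3_class(r5$test_confusion, "ys_confusion")
  expect_equal(sum(r5$test_confusion), length(r5$split$test_rows))
  expect_equal(sum(r5$cv_confusion), length(r5$split$train_rows))
  expect_equal(nrow(r5$test_per_class), 3)
  expect_equal(r5$test_metrics$accuracy,
               100 * sum(diag(r5$test_confusion)) / sum(r5$test_confusion))
})

test_that("model predictions are a row-wise map honoring the schema", {
  sp <- make_split(feats, seed = 1)
  m <- sonoyeast:::fit_model_rows(feats, 4, sp$train_rows, seed = 1)
  idx <- sp$test_rows[1:20]
  p <- predict(m, feats[idx, ])
  perm <- sample(length(idx))
  expect_equal(predict(m, feats[idx[perm], ]), p[perm])
  m5 <- sonoyeast:::fit_model_rows(feats, 5, sp$train_rows, seed = 1)
  probs <- predict(m5, feats[idx, ], type = "prob")
  expect_equal(rowSums(probs), rep(1, 20), tolerance = 1e-12)
  bad <- dplyr::rename(feats[idx, ], wrong = a_max_1)
  expect_error(predict(m, bad))
})

test_that("tidy and glance expose the metrics in broom shape", {
  r <- run_approach(feats, 2, seed = 3)
  td <- tidy(r)
  expect_setequal(unique(td$partition), c("cv_fold", "cv_mean", "test"))
  expect_true(all(c("model", "metric", "value") %in% names(td)))
  gl <- glance(r)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$approach, 2)
  net <- r$models[[1]]$net
  expect_s3_class(tidy(net), "tbl_df")
  expect_equal(glance(net)$iterations, net$stopped_iteration)
})

test_that("autoplot produces parity and confusion graphics", {
  r2 <- run_approach(feats, 2, seed = 3)
  expect_s3_class(ggplot2::autoplot(r2), "ggplot")
  r5 <- run_approach(feats, 5, seed = 3)
  expect_s3_class(ggplot2::autoplot(r5), "ggplot")
  expect_s3_class(plot_confusion(r5$cv_confusion, percent = FALSE), "ggplot")
})
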