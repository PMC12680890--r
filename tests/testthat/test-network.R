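test_that("Glorot initialization respects the fan-in/fan-out bound, deterministically", {
  cfg <- net_config(9, "regression", seed = 4)
  w <- init_glorot(cfg)
  expect_lte(max(abs(w$W1)), sqrt(6 / (9 + 5)))
  expect_lte(max(abs(w$W2)), sqrt(6 / (5 + 3)))
  expect_lte(max(abs(w$W3)), sqrt(6 / (3 + 1)))
  expect_equal(w$b1, numeric(5))
  expect_equal(w$b2, numeric(3))
  expect_identical(init_glorot(cfg), w)
  expect_false(identical(init_glorot(cfg, seed = 5), w))
})

test_that("the forward pass reduces to the affine/softmax limits", {
  cfg <- net_config(9, "classification", seed = 1)
  w0 <- init_glorot(cfg)
  for (nm in c("W1", "W2", "W3")) w0[[nm]][] <- 0
  x <- matrix(rnorm(45), 5, 9)
  p <- mlp_forward(w0, x, "classification")
  expect_equal(unname(p), matrix(1 / 3, 5, 3))     # softmax of zero logits
  cfg_r <- net_config(9, "regression", seed = 1)
  wr <- init_glorot(cfg_r)
  for (nm in c("W1", "W2", "W3")) wr[[nm]][] <- 0
  wr$b3 <- 2.5
  expect_equal(mlp_forward(wr, x, "regression"), rep(2.5, 5))
  # probability rows always sum to one
  w <- init_glorot(cfg)
  expect_equal(rowSums(mlp_forward(w, x, "classification")), rep(1, 5),
               tolerance = 1e-12)
  expect_error(mlp_forward(w, x[, 1:5]), "input width")
})

test_that("losses hit their analytic anchors", {
  cfg <- net_config(4, "regression", seed = 2)
  w <- init_glorot(cfg)
  x <- matrix(rnorm(40), 10, 4)
  y_fit <- mlp_forward(w, x, "regression")
  expect_equal(mlp_loss(w, x, y_fit, 0, "regression"), 0)
  expect_gt(mlp_loss(w, x, y_fit, 0.001, "regression"), 0)  # additive penalty
  cfg_c <- net_config(4, "classification", seed = 2)
  wc <- init_glorot(cfg_c)
  for (nm in c("W1", "W2", "W3")) wc[[nm]][] <- 0
  ymat <- one_hot_strain(sample(ys_strains(), 10, replace = TRUE))
  expect_equal(mlp_loss(wc, x, ymat, 0, "classification"), log(3))
})

test_that("the analytic gradient matches central finite differences", {
  withr::with_seed(8, {
    for (task in c("regression", "classification")) {
      cfg <- net_config(6, task, seed = sample(1e6, 1))
      w <- init_glorot(cfg)
      x <- matrix(rnorm(8 * 6), 8, 6)
      y <- if (task == "regression") rnorm(8) else
        one_hot_strain(sample(ys_strains(), 8, replace = TRUE))
      lam <- 0.001
      par <- sonoyeast:::flatten_weights(w)
      fn <- function(p) mlp_loss(sonoyeast:::unflatten_weights(p, cfg), x, y, lam, task)
      g <- sonoyeast:::flatten_weights(mlp_gradient(w, x, y, lam, task))
      fd <- fd_gradient(fn, par)
      expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-5)
      # penalty part is linear in lambda
      g2 <- sonoyeast:::flatten_weights(mlp_gradient(w, x, y, 2 * lam, task))
      g0 <- sonoyeast:::flatten_weights(mlp_gradient(w, x, y, 0, task))
      expect_equal(g2 - g0, 2 * (g - g0), tolerance = 1e-12)
    }
  })
})

test_that("the gradient vanishes at a zero-loss regression optimum", {
  cfg <- net_config(3, "regression", seed = 3)
  w <- init_glorot(cfg)
  x <- matrix(rnorm(15), 5, 3)
  y <- mlp_forward(w, x, "regression")
  g <- sonoyeast:::flatten_weights(mlp_gradient(w, x, y, 0, "regression"))
  expect_equal(g, rep(0, length(g)), tolerance = 1e-12)
})

test_that("training recovers a representable noiseless linear target", {
  withr::with_seed(21, {
    x <- matrix(rnorm(200 * 5), 200, 5)
    y <- x %*% c(1, -2, 0.5, 0, 1.5) + 0.3
  })
  cfg <- net_config(5, "regression", l2_lambda = 0, patience = 50,
                    max_iterations = 2000, seed = 2)
  fit <- train_mlp(x, as.numeric(y), cfg)
  mse <- mean((mlp_forward(fit$weights, x) - y)^2)
  expect_lt(mse, 1e-4 * stats::var(as.numeric(y)))
  expect_identical(train_mlp(x, as.numeric(y), cfg)$weights, fit$weights)
})

test_that("training loss never ends above its initial value and L2 shrinks weights", {
  withr::with_seed(13, {
    x <- matrix(rnorm(150 * 4), 150, 4)
    y <- sin(x[, 1]) + x[, 2]^2 + rnorm(150, 0, 0.1)
  })
  cfg0 <- net_config(4, "regression", l2_lambda = 0, seed = 6)
  fit0 <- train_mlp(x, y, cfg0)
  init_loss <- mlp_loss(init_glorot(cfg0), x, y, 0, "regression")
  expect_lte(fit0$trace$train_loss[nrow(fit0$trace)], init_loss)
  cfgL <- net_config(4, "regression", l2_lambda = 0.1, seed = 6)
  fitL <- train_mlp(x, y, cfgL)
  wnorm <- function(w) sum(w$W1^2) + sum(w$W2^2) + sum(w$W3^2)
  expect_lt(wnorm(fitL$weights), wnorm(fit0$weights))
})

test_that("early stopping fires within a couple of iterations on a flat problem", {
  x <- matrix(0, 40, 2)
  y <- rep(3, 40)
  cfg <- net_config(2, "regression", patience = 1, seed = 1)
  fit <- train_mlp(x, y, cfg)
  expect_lte(fit$stopped_iteration, 4)
  expect_lte(fit$best_iteration, fit$stopped_iteration)
})
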