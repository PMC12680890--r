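#' Configuration of the compact fully connected network
#'
#' Two hidden layers of five and three ReLU units, a linear single output for
#' regression or a three-way softmax for classification, L2 penalty on the
#' weights, full-batch L-BFGS optimization, and early stopping on an inner
#' validation split with a patience of six iterations (full-batch training
#' makes one optimizer iteration the natural "epoch").
#'
#' @param input_width Number of input neurons (9-13 depending on approach).
#' @param task `"regression"` or `"classification"`.
#' @param hidden Hidden layer widths.
#' @param n_classes Output classes (classification only).
#' @param l2_lambda L2 regularization strength on weights (biases excluded).
#' @param patience Early-stopping patience, in optimizer iterations.
#' @param max_iterations Iteration cap.
#' @param inner_validation_fraction Fraction of the training rows held out
#'   (before optimization) to score early stopping.
#' @param seed Seed for Glorot initialization and the inner validation split.
#' @return List of class `ys_net_config`.
#' @export
net_config <- function(input_width,
                       task = c("regression", "classification"),
                       hidden = c(5, 3),
                       n_classes = 3,
                       l2_lambda = 0.001,
                       patience = 6,
                       max_iterations = 500,
                       inner_validation_fraction = 0.1,
                       seed = 1) {
  task <- match.arg(task)
  stopifnot(input_width >= 1, all(hidden >= 1), l2_lambda >= 0, patience >= 1,
            max_iterations >= 1,
            inner_validation_fraction >= 0, inner_validation_fraction < 1)
  structure(
    list(
      input_width = input_width, task = task, hidden = hidden,
      n_classes = if (task == "classification") n_classes else 1L,
      l2_lambda = l2_lambda, patience = patience,
      max_iterations = max_iterations,
      inner_validation_fraction = inner_validation_fraction,
      seed = seed
    ),
    class = "ys_net_config"
  )
}

net_dims <- function(config) {
  c(config$input_width, config$hidden, config$n_classes)
}

#' Glorot (uniform) weight initialization
#'
#' Each weight is drawn from
#' `Uniform(-sqrt(6 / (fan_in + fan_out)), +sqrt(6 / (fan_in + fan_out)))`;
#' biases start at zero. Deterministic for a given seed.
#'
#' @param config [net_config()].
#' @param seed Seed (defaults to the config's).
#' @return List of class `ys_weights` with `W1`, `b1`, `W2`, `b2`, `W3`, `b3`.
#' @export
init_glorot <- function(config, seed = config$seed) {
  dims <- net_dims(config)
  withr::with_seed(substream_seed(seed, "init"), {
    w <- list()
    for (l in 1:3) {
      fan_in <- dims[l]; fan_out <- dims[l + 1]
      bound <- sqrt(6 / (fan_in + fan_out))
      w[[paste0("W", l)]] <- matrix(
        stats::runif(fan_in * fan_out, -bound, bound), fan_in, fan_out
      )
      w[[paste0("b", l)]] <- numeric(fan_out)
    }
  })
  structure(w, class = "ys_weights")
}

flatten_weights <- function(w) {
  unlist(lapply(c("W1", "b1", "W2", "b2", "W3", "b3"), function(nm) as.numeric(w[[nm]])),
         use.names = FALSE)
}

unflatten_weights <- function(par, config) {
  dims <- net_dims(config)
  w <- list()
  pos <- 0
  for (l in 1:3) {
    nw <- dims[l] * dims[l + 1]
    w[[paste0("W", l)]] <- matrix(par[pos + seq_len(nw)], dims[l], dims[l + 1])
    pos <- pos + nw
    w[[paste0("b", l)]] <- par[pos + seq_len(dims[l + 1])]
    pos <- pos + dims[l + 1]
  }
  structure(w, class = "ys_weights")
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

# forward pass keeping the intermediate activations for backprop
forward_cache <- function(w, x) {
  z1 <- sweep(x %*% w$W1, 2, w$b1, "+")
  h1 <- pmax(z1, 0)
  z2 <- sweep(h1 %*% w$W2, 2, w$b2, "+")
  h2 <- pmax(z2, 0)
  out <- sweep(h2 %*% w$W3, 2, w$b3, "+")
  list(z1 = z1, h1 = h1, z2 = z2, h2 = h2, out = out)
}

#' Forward pass of the network
#'
#' @param weights [init_glorot()] weights (or trained ones).
#' @param x Input matrix, rows = observations.
#' @param task `"regression"` (returns the linear outputs) or
#'   `"classification"` (returns softmax probabilities, rows summing to 1).
#' @return Numeric vector (regression) or probability matrix (classification).
#' @export
mlp_forward <- function(weights, x, task = "regression") {
  if (ncol(x) != nrow(weights$W1)) {
    stop("input width ", ncol(x), " does not match the network (",
         nrow(weights$W1), ")", call. = FALSE)
  }
  out <- forward_cache(weights, x)$out
  if (task == "classification") softmax_rows(out) else as.numeric(out)
}

# y: numeric vector (regression) or 0/1 indicator matrix (classification)
data_loss <- function(out, y, task) {
  if (task == "regression") {
    mean((as.numeric(out) - y)^2)
  } else {
    p <- softmax_rows(out)
    -mean(log(pmax(rowSums(p * y), 1e-300)))
  }
}

penalty <- function(w, lambda) {
  lambda * (sum(w$W1^2) + sum(w$W2^2) + sum(w$W3^2))
}

#' Penalized training loss
#'
#' Mean squared error (regression) or mean categorical cross-entropy of the
#' softmax probabilities (classification), plus `lambda * sum(W^2)` over the
#' weight matrices (biases are not penalized).
#'
#' @param weights Network weights.
#' @param x Input matrix.
#' @param y Numeric targets (regression) or 0/1 indicator matrix
#'   (classification).
#' @param lambda L2 strength.
#' @param task Task string.
#' @return Scalar loss.
#' @export
mlp_loss <- function(weights, x, y, lambda = 0, task = "regression") {
  data_loss(forward_cache(weights, x)$out, y, task) + penalty(weights, lambda)
}

#' Analytic gradient of the penalized loss
#'
#' Exact backpropagation through the two ReLU layers (subgradient 0 at 0)
#' and the linear / softmax output.
#'
#' @inheritParams mlp_loss
#' @return A `ys_weights`-shaped list of gradients.
#' @export
mlp_gradient <- function(weights, x, y, lambda = 0, task = "regression") {
  n <- nrow(x)
  cc <- forward_cache(weights, x)
  d_out <- if (task == "regression") {
    matrix(2 * (as.numeric(cc$out) - y) / n, ncol = 1)
  } else {
    (softmax_rows(cc$out) - y) / n
  }
  g <- list()
  g$W3 <- crossprod(cc$h2, d_out) + 2 * lambda * weights$W3
  g$b3 <- colSums(d_out)
  d2 <- (d_out %*% t(weights$W3)) * (cc$z2 > 0)
  g$W2 <- crossprod(cc$h1, d2) + 2 * lambda * weights$W2
  g$b2 <- colSums(d2)
  d1 <- (d2 %*% t(weights$W2)) * (cc$z1 > 0)
  g$W1 <- crossprod(x, d1) + 2 * lambda * weights$W1
  g$b1 <- colSums(d1)
  structure(g[c("W1", "b1", "W2", "b2", "W3", "b3")], class = "ys_weights")
}

# Strong-Wolfe line search (bracket + zoom, Nocedal & Wright Alg. 3.5/3.6)
# on phi(a) = fn(par + a * d); returns the accepted step with its value and
# gradient, or NULL on failure.
wolfe_search <- function(par, d, f0, g0, fn, gr, step0 = 1,
                         c1 = 1e-4, c2 = 0.9, max_eval = 25) {
  dphi0 <- sum(g0 * d)
  phi <- function(a) fn(par + a * d)
  dphi_g <- function(a) gr(par + a * d)
  a_prev <- 0; f_prev <- f0
  a <- step0
  zoom <- function(lo, flo, hi, fhi) {
    for (j in 1:max_eval) {
      a <- (lo + hi) / 2                      # bisection zoom
      fa <- phi(a)
      if (!is.finite(fa) || fa > f0 + c1 * a * dphi0 || fa >= flo) {
        hi <- a; fhi <- fa
      } else {
        ga <- dphi_g(a)
        da <- sum(ga * d)
        if (abs(da) <= -c2 * dphi0) {
          return(list(step = a, f = fa, g = ga))
        }
        if (da * (hi - lo) >= 0) { hi <- lo; fhi <- flo }
        lo <- a; flo <- fa
      }
      if (abs(hi - lo) < 1e-14) break
    }
    ga <- dphi_g(lo)
    if (is.finite(flo)) list(step = lo, f = flo, g = ga) else NULL
  }
  for (i in 1:max_eval) {
    fa <- phi(a)
    if (!is.finite(fa) || fa > f0 + c1 * a * dphi0 || (i > 1 && fa >= f_prev)) {
      return(zoom(a_prev, f_prev, a, fa))
    }
    ga <- dphi_g(a)
    da <- sum(ga * d)
    if (abs(da) <= -c2 * dphi0) {
      return(list(step = a, f = fa, g = ga))
    }
    if (da >= 0) {
      return(zoom(a, fa, a_prev, f_prev))
    }
    a_prev <- a; f_prev <- fa
    a <- min(2 * a, 1e10)
  }
  NULL
}

# Limited-memory BFGS (two-loop recursion, memory 10) with a strong-Wolfe
# line search and a per-iteration callback used for validation-scored early
# stopping. Curvature pairs with s'y below 1e-12 are skipped to keep the
# inverse-Hessian estimate positive definite.
lbfgs_optimize <- function(par, fn, gr, max_iterations, callback = NULL,
                           memory = 10, gtol = 1e-10) {
  f <- fn(par); g <- gr(par)
  if (!is.finite(f)) stop("non-finite loss at the initial point", call. = FALSE)
  S <- list(); Yv <- list(); rho <- numeric(0)
  for (iter in seq_len(max_iterations)) {
    # two-loop recursion
    q <- g
    k <- length(S)
    alpha_i <- numeric(k)
    if (k > 0) {
      for (i in k:1) {
        alpha_i[i] <- rho[i] * sum(S[[i]] * q)
        q <- q - alpha_i[i] * Yv[[i]]
      }
      gamma <- sum(S[[k]] * Yv[[k]]) / sum(Yv[[k]] * Yv[[k]])
      q <- gamma * q
      for (i in 1:k) {
        beta <- rho[i] * sum(Yv[[i]] * q)
        q <- q + (alpha_i[i] - beta) * S[[i]]
      }
    }
    d <- -q
    gd <- sum(g * d)
    if (gd >= 0) { d <- -g; gd <- -sum(g * g) }      # safeguard: descent reset
    step0 <- if (k == 0) min(1, 1 / max(1e-12, sqrt(sum(g^2)))) else 1
    ls <- wolfe_search(par, d, f, g, fn, gr, step0 = step0)
    if (is.null(ls) || !is.finite(ls$f) || ls$f > f) break   # line search failed
    par_new <- par + ls$step * d
    f_new <- ls$f
    g_new <- ls$g
    s <- par_new - par; yv <- g_new - g
    sy <- sum(s * yv)
    if (sy > 1e-12) {
      S <- c(S, list(s)); Yv <- c(Yv, list(yv)); rho <- c(rho, 1 / sy)
      if (length(S) > memory) { S <- S[-1]; Yv <- Yv[-1]; rho <- rho[-1] }
    }
    moved <- sqrt(sum(s^2))
    par <- par_new; f <- f_new; g <- g_new
    if (!is.null(callback) && !isTRUE(callback(par, f, iter))) {
      return(list(par = par, value = f, iterations = iter, converged = FALSE))
    }
    if (sqrt(sum(g^2)) < gtol || moved < 1e-14) {
      return(list(par = par, value = f, iterations = iter, converged = TRUE))
    }
  }
  list(par = par, value = f, iterations = max_iterations, converged = FALSE)
}

#' Train the compact network with full-batch L-BFGS and early stopping
#'
#' Holds out an inner validation subset of the training rows (default 10%,
#' drawn before optimization from the config seed), minimizes the penalized
#' loss on the remainder by full-batch L-BFGS, scores the validation loss
#' after every iteration, and stops when it has not improved for `patience`
#' consecutive iterations (or at the iteration cap). The returned weights
#' are those of the best-validation iteration.
#'
#' Inputs are expected already standardized (see [fit_scaler()]); regression
#' targets are expected in units of 1e6 cells/mL so the loss is well scaled.
#'
#' @param x Standardized input matrix (training rows).
#' @param y Numeric targets (regression) or factor (classification).
#' @param config [net_config()].
#' @return Object of class `ys_mlp`: `weights`, `config`, and a training
#'   `trace` (tibble of iteration, training loss, validation loss) plus
#'   `best_iteration` and `stopped_iteration`.
#' @export
train_mlp <- function(x, y, config) {
  stopifnot(nrow(x) >= 10, ncol(x) == config$input_width)
  task <- config$task
  if (task == "classification") {
    stopifnot(is.factor(y))
    ymat <- one_hot_strain(as.character(y))
  } else {
    ymat <- as.numeric(y)
  }
  n <- nrow(x)
  n_val <- max(1, round(config$inner_validation_fraction * n))
  val_idx <- withr::with_seed(
    substream_seed(config$seed, "valsplit"),
    sample(n, n_val)
  )
  xt <- x[-val_idx, , drop = FALSE]
  xv <- x[val_idx, , drop = FALSE]
  yt <- if (task == "classification") ymat[-val_idx, , drop = FALSE] else ymat[-val_idx]
  yv <- if (task == "classification") ymat[val_idx, , drop = FALSE] else ymat[val_idx]

  fn <- function(par) mlp_loss(unflatten_weights(par, config), xt, yt,
                               config$l2_lambda, task)
  gr <- function(par) flatten_weights(
    mlp_gradient(unflatten_weights(par, config), xt, yt, config$l2_lambda, task)
  )

  par0 <- flatten_weights(init_glorot(config))
  best <- list(val = Inf, par = par0, iter = 0L)
  bad_streak <- 0L
  trace <- vector("list", config$max_iterations)
  cb <- function(par, f, iter) {
    vloss <- data_loss(forward_cache(unflatten_weights(par, config), xv)$out, yv, task)
    trace[[iter]] <<- c(iteration = iter, train_loss = f, val_loss = vloss)
    if (vloss < best$val) {
      best <<- list(val = vloss, par = par, iter = iter)
      bad_streak <<- 0L
    } else {
      bad_streak <<- bad_streak + 1L
    }
    bad_streak < config$patience
  }
  res <- lbfgs_optimize(par0, fn, gr, config$max_iterations, callback = cb)
  if (!is.finite(res$value)) {
    stop("training diverged to a non-finite loss", call. = FALSE)
  }
  structure(
    list(
      weights = unflatten_weights(best$par, config),
      config = config,
      trace = tibble::as_tibble(do.call(rbind, trace[!vapply(trace, is.null, logical(1))])),
      best_iteration = best$iter,
      stopped_iteration = res$iterations,
      optimizer = list(method = "L-BFGS", memory = 10,
                       line_search = "strong Wolfe (bracket/zoom)",
                       c1 = 1e-4, c2 = 0.9, gtol = 1e-10)
    ),
    class = "ys_mlp"
  )
}

#' @export
print.ys_mlp <- function(x, ...) {
  cat("<ys_mlp> ", x$config$task, " network ",
      paste(net_dims(x$config), collapse = "-"),
      "; stopped at iteration ", x$stopped_iteration,
      " (best validation at ", x$best_iteration, ")\n", sep = "")
  invisible(x)
}
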