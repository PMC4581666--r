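# Three-layer feedforward network trained by full-batch backpropagation.
#
# Hidden and output units compute z_j = f(sum_i w_ij x_i - theta_j) and
# y_k = f(sum_j w_kj z_j - theta_k) with sigmoid f, so regression targets
# must be scaled into (0, 1) before training (see fit_target_scaler) and
# inverse-scaled at prediction time.

#' Create a multilayer perceptron with random weights
#'
#' Weights and thresholds are drawn from `U(-0.5, 0.5)` using the ambient
#' RNG stream (wrap in [withr::with_seed()] for reproducibility).
#'
#' @param n Input dimension.
#' @param q Hidden-layer size.
#' @param m Output dimension.
#' @return An object of class `mlp_model` with fields `w_in` (n x q),
#'   `theta_hidden` (q), `w_out` (q x m), `theta_out` (m).
#' @export
new_mlp <- function(n, q, m = 1L) {
  structure(
    list(
      w_in = matrix(stats::runif(n * q, -0.5, 0.5), nrow = n),
      theta_hidden = stats::runif(q, -0.5, 0.5),
      w_out = matrix(stats::runif(q * m, -0.5, 0.5), nrow = q),
      theta_out = stats::runif(m, -0.5, 0.5)
    ),
    class = "mlp_model"
  )
}

#' Forward pass of the multilayer perceptron
#'
#' @param model An `mlp_model`.
#' @param X N x n input matrix (or a single input vector).
#' @return A list with `z` (N x q hidden activations) and `y` (N x m
#'   outputs), all in (0, 1).
#' @export
forward_mlp <- function(model, X) {
  stopifnot(inherits(model, "mlp_model"))
  if (is.vector(X)) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X)
  if (ncol(X) != nrow(model$w_in)) {
    stop("input dimension ", ncol(X), " does not match network (",
         nrow(model$w_in), ")")
  }
  z <- sigmoid(sweep(X %*% model$w_in, 2L, model$theta_hidden))
  y <- sigmoid(sweep(z %*% model$w_out, 2L, model$theta_out))
  list(z = z, y = y)
}

# Analytic gradients of the mean-squared-error loss
# L = mean over (sample, output) of (y - t)^2.
mlp_gradients <- function(model, X, T_mat) {
  fw <- forward_mlp(model, X)
  N <- nrow(X)
  m <- ncol(T_mat)
  delta_y <- 2 * (fw$y - T_mat) * fw$y * (1 - fw$y) / (N * m)
  delta_z <- (delta_y %*% t(model$w_out)) * fw$z * (1 - fw$z)
  list(
    w_in = crossprod(X, delta_z),
    theta_hidden = -colSums(delta_z),
    w_out = crossprod(fw$z, delta_y),
    theta_out = -colSums(delta_y),
    loss = mean((fw$y - T_mat)^2)
  )
}

#' Train the perceptron by full-batch backpropagation
#'
#' Gradient descent on the mean squared error over all samples, with a
#' fixed learning rate; default 1000 iterations.
#'
#' @param X N x n input matrix.
#' @param T_scaled Targets already scaled into (0, 1): length-N vector or
#'   N x m matrix. Values on or outside \[0, 1\] are an error (scale with
#'   [scale_targets()] first).
#' @param q Hidden-layer size.
#' @param iterations Number of full-batch updates (default 1000).
#' @param learning_rate Step size (default 0.1).
#' @param seed Optional integer seed for the weight initialization.
#' @param track_loss If `TRUE`, record the loss after every iteration.
#' @return An `mlp_model`; with `track_loss`, the numeric vector of losses
#'   is attached as attribute `"loss"`.
#' @export
train_backprop <- function(X, T_scaled, q, iterations = 1000L,
                           learning_rate = 0.1, seed = NULL,
                           track_loss = FALSE) {
  X <- as.matrix(X)
  T_mat <- as.matrix(T_scaled)
  if (nrow(X) != nrow(T_mat)) stop("X and targets must have the same rows")
  if (iterations < 1L) stop("iterations must be >= 1")
  if (any(T_mat <= 0 | T_mat >= 1)) {
    stop("targets must lie strictly inside (0, 1); ",
         "scale them first, e.g. with scale_targets(fit_target_scaler(y))")
  }
  make <- function() new_mlp(ncol(X), q, ncol(T_mat))
  model <- if (is.null(seed)) make() else {
    withr::with_seed(as.integer(seed), make())
  }
  losses <- if (track_loss) numeric(iterations) else NULL
  for (it in seq_len(iterations)) {
    g <- mlp_gradients(model, X, T_mat)
    model$w_in <- model$w_in - learning_rate * g$w_in
    model$theta_hidden <- model$theta_hidden - learning_rate * g$theta_hidden
    model$w_out <- model$w_out - learning_rate * g$w_out
    model$theta_out <- model$theta_out - learning_rate * g$theta_out
    if (track_loss) {
      losses[it] <- mean((forward_mlp(model, X)$y - T_mat)^2)
    }
  }
  if (track_loss) attr(model, "loss") <- losses
  model
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("MLP: %d-%d-%d, sigmoid, backprop-trained\n",
              nrow(x$w_in), ncol(x$w_in), ncol(x$w_out)))
  invisible(x)
}

#' Affine target scaler into (0, 1)
#'
#' Maps the training-target range onto \[`lo`, `hi`\] (default
#' \[0.1, 0.9\], keeping sigmoid outputs away from saturation); the
#' inverse transform returns predictions to original units. Constant
#' targets map to the midpoint.
#'
#' @param y Training targets.
#' @param lo,hi Scaled range bounds, `0 < lo < hi < 1`.
#' @return An object of class `target_scaler`.
#' @export
fit_target_scaler <- function(y, lo = 0.1, hi = 0.9) {
  stopifnot(lo > 0, hi < 1, lo < hi)
  structure(list(min = min(y), max = max(y), lo = lo, hi = hi),
            class = "target_scaler")
}

#' @rdname fit_target_scaler
#' @param scaler A `target_scaler`.
#' @export
scale_targets <- function(y, scaler) {
  stopifnot(inherits(scaler, "target_scaler"))
  span <- scaler$max - scaler$min
  if (span == 0) return(rep((scaler$lo + scaler$hi) / 2, length(y)))
  scaler$lo + (y - scaler$min) / span * (scaler$hi - scaler$lo)
}

#' @rdname fit_target_scaler
#' @param y_scaled Values on the scaled (0, 1) range.
#' @export
inverse_scale_targets <- function(y_scaled, scaler) {
  stopifnot(inherits(scaler, "target_scaler"))
  span <- scaler$max - scaler$min
  if (span == 0) return(rep(scaler$min, length(y_scaled)))
  scaler$min + (y_scaled - scaler$lo) / (scaler$hi - scaler$lo) * span
}

#' Predict in original target units
#'
#' Forward pass followed by the inverse target scaling.
#'
#' @param model An `mlp_model`.
#' @param X Input matrix.
#' @param scaler The `target_scaler` fitted on the training targets, or
#'   `NULL` to return raw (0, 1) outputs.
#' @return Numeric predictions (vector for one output, matrix otherwise).
#' @export
predict_mlp <- function(model, X, scaler = NULL) {
  y <- forward_mlp(model, X)$y
  if (!is.null(scaler)) y <- inverse_scale_targets(y, scaler)
  if (is.matrix(y) && ncol(y) == 1L) drop(y) else y
}

#' Select the MLP hidden size on a validation split
#'
#' Mirrors [select_elm_hidden()]: trains per candidate size on an internal
#' split, keeps the lowest validation RMSE, refits on all data. Inputs are
#' standardized internally; targets are scaled to (0.1, 0.9).
#'
#' @param X,y Training data (y in original units, e.g. years).
#' @param grid Candidate hidden sizes (default the reference {3, 6, 10}).
#' @param iterations,learning_rate Backprop parameters.
#' @param seed Integer seed.
#' @param val_frac Validation fraction.
#' @return A list with `q`, the fitted `model`, the input `center`/`scale`,
#'   the target `scaler`, per-size validation RMSEs, and a `predict`
#'   closure mapping new X to years.
#' @export
select_mlp_hidden <- function(X, y, grid = c(3L, 6L, 10L),
                              iterations = 1000L, learning_rate = 0.1,
                              seed = 1L, val_frac = 0.25) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  center <- colMeans(X)
  scale <- apply(X, 2L, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  Xs <- sweep(sweep(X, 2L, center), 2L, scale, "/")
  scaler <- fit_target_scaler(y)
  ys <- scale_targets(y, scaler)

  n <- nrow(Xs)
  idx <- withr::with_seed(as.integer(seed), sample.int(n))
  n_val <- max(1L, floor(val_frac * n))
  val <- idx[seq_len(n_val)]
  tr <- idx[-seq_len(n_val)]
  rmses <- vapply(grid, function(q) {
    m <- train_backprop(Xs[tr, , drop = FALSE], ys[tr], q = q,
                        iterations = iterations,
                        learning_rate = learning_rate,
                        seed = stage_seed(seed, paste0("ann", q)))
    rmse(y[val], predict_mlp(m, Xs[val, , drop = FALSE], scaler))
  }, numeric(1))
  best <- grid[which.min(rmses)]
  model <- train_backprop(Xs, ys, q = best, iterations = iterations,
                          learning_rate = learning_rate,
                          seed = stage_seed(seed, "ann_final"))
  list(
    q = best, model = model, center = center, scale = scale,
    scaler = scaler, validation_rmse = stats::setNames(rmses, grid),
    predict = function(Xnew) {
      Xn <- sweep(sweep(as.matrix(Xnew), 2L, center), 2L, scale, "/")
      predict_mlp(model, Xn, scaler)
    }
  )
}
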