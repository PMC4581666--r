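# Extreme learning machine regression.
#
# A single-hidden-layer feedforward network whose hidden-node parameters
# (a_i, b_i) are drawn at random and never tuned; only the output weights
# beta are solved, in closed form, as beta = H+ T where H is the hidden
# output matrix and H+ its Moore-Penrose pseudoinverse computed by SVD.
# Hidden nodes are either additive-sigmoid, G(a, b, x) = sigmoid(a.x + b),
# or Gaussian RBF, G(a, b, x) = exp(-b ||x - a||^2) with b > 0.

#' Additive (sigmoid) hidden-node activation
#'
#' `G(a, b, x) = sigmoid(a . x + b)`.
#'
#' @param a Input-weight vector.
#' @param b Scalar bias.
#' @param x Input vector, same length as `a`.
#' @return Activation in (0, 1).
#' @export
activation_additive <- function(a, b, x) {
  if (length(a) != length(x)) stop("a and x must have the same length")
  sigmoid(sum(a * x) + b)
}

#' Gaussian RBF hidden-node activation
#'
#' `G(a, b, x) = exp(-b ||x - a||^2)` with impact factor `b > 0`. The
#' literal form `g(b ||x - a||)` (Gaussian applied to the scaled distance,
#' i.e. `exp(-(b ||x - a||)^2)`) is available with `variant = "scaled_distance"`.
#'
#' @param a Centre vector.
#' @param b Positive impact factor.
#' @param x Input vector.
#' @param variant `"standard"` (default) or `"scaled_distance"`.
#' @return Activation in (0, 1].
#' @export
activation_rbf <- function(a, b, x, variant = c("standard", "scaled_distance")) {
  variant <- match.arg(variant)
  if (!is.numeric(b) || length(b) != 1L || b <= 0) {
    stop("RBF impact factor b must be > 0")
  }
  if (length(a) != length(x)) stop("a and x must have the same length")
  d2 <- sum((x - a)^2)
  if (variant == "standard") exp(-b * d2) else exp(-(b^2) * d2)
}

#' Draw a random hidden layer
#'
#' Hidden parameters come from the ambient RNG stream: additive nodes use
#' `a ~ U(-1, 1)^n`, `b ~ U(-1, 1)`; RBF nodes draw centres uniformly over
#' the per-dimension training-input bounding box (`x_range`) and impact
#' factors `b ~ U(0.1, 2]`.
#'
#' @param L Number of hidden nodes (>= 1).
#' @param input_dim Input dimension n.
#' @param kind `"additive"` or `"rbf"`.
#' @param x_range Optional 2 x n matrix of per-dimension (min, max) bounds
#'   for RBF centres; defaults to \[-1, 1\] in every dimension.
#' @return A list of `L` hidden nodes, each a list `(kind, a, b)`.
#' @export
random_hidden_layer <- function(L, input_dim, kind = c("additive", "rbf"),
                                x_range = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(L) || length(L) != 1L || L < 1) stop("L must be >= 1")
  L <- as.integer(L)
  if (kind == "rbf" && is.null(x_range)) {
    x_range <- rbind(rep(-1, input_dim), rep(1, input_dim))
  }
  lapply(seq_len(L), function(i) {
    if (kind == "additive") {
      list(kind = "additive",
           a = stats::runif(input_dim, -1, 1),
           b = stats::runif(1L, -1, 1))
    } else {
      list(kind = "rbf",
           a = stats::runif(input_dim, x_range[1L, ], x_range[2L, ]),
           b = 2 - stats::runif(1L, 0, 1.9))  # U(0.1, 2]
    }
  })
}

#' Hidden-layer output matrix H
#'
#' `H[j, i] = G(a_i, b_i, x_j)`: the i-th column is the i-th hidden node's
#' output over all N input rows.
#'
#' @param nodes List of hidden nodes from [random_hidden_layer()].
#' @param X N x n input matrix.
#' @return N x L matrix.
#' @export
hidden_output_matrix <- function(nodes, X) {
  X <- as.matrix(X)
  n <- ncol(X)
  bad <- vapply(nodes, function(nd) length(nd$a) != n, logical(1))
  if (any(bad)) stop("hidden-node dimension does not match input dimension")
  kinds <- vapply(nodes, `[[`, character(1), "kind")
  H <- matrix(0, nrow = nrow(X), ncol = length(nodes))
  add <- which(kinds == "additive")
  if (length(add)) {
    A <- vapply(nodes[add], `[[`, numeric(n), "a")
    A <- matrix(A, nrow = n)
    b <- vapply(nodes[add], `[[`, numeric(1), "b")
    H[, add] <- sigmoid(sweep(X %*% A, 2L, b, "+"))
  }
  rbf <- which(kinds == "rbf")
  if (length(rbf)) {
    C <- matrix(vapply(nodes[rbf], `[[`, numeric(n), "a"), nrow = n)
    b <- vapply(nodes[rbf], `[[`, numeric(1), "b")
    d2 <- outer(rowSums(X^2), colSums(C^2), `+`) - 2 * X %*% C
    d2 <- pmax(d2, 0)
    H[, rbf] <- exp(-sweep(d2, 2L, b, "*"))
  }
  H
}

# Moore-Penrose pseudoinverse via SVD. Singular values below
# max(dim) * eps * sigma_max are treated as zero.
mp_pseudoinverse <- function(H) {
  s <- svd(H)
  if (length(s$d) == 0L || s$d[1L] == 0) {
    return(matrix(0, nrow = ncol(H), ncol = nrow(H)))
  }
  cutoff <- max(dim(H)) * .Machine$double.eps * s$d[1L]
  dinv <- ifelse(s$d > cutoff, 1 / s$d, 0)
  s$v %*% (dinv * t(s$u))
}

#' Solve ELM output weights
#'
#' `beta = H+ T`, the minimum-norm least-squares solution of `H beta = T`,
#' with the Moore-Penrose generalized inverse computed by SVD (singular
#' values below `max(N, L) * eps * sigma_max` are treated as zero).
#'
#' @param H N x L hidden output matrix.
#' @param T_mat N x m target matrix (a vector is treated as one column).
#' @return L x m output-weight matrix beta.
#' @export
solve_output_weights <- function(H, T_mat) {
  H <- as.matrix(H)
  T_mat <- as.matrix(T_mat)
  if (!all(is.finite(H)) || !all(is.finite(T_mat))) {
    stop("H and T must be finite")
  }
  if (nrow(H) != nrow(T_mat)) {
    stop("H and T must have the same number of rows")
  }
  mp_pseudoinverse(H) %*% T_mat
}

#' Train an extreme learning machine
#'
#' Single-pass batch learning: draw the random hidden layer, form the
#' hidden output matrix H on the (optionally standardized) inputs, and set
#' `beta = H+ T`. No iteration, no gradient descent.
#'
#' @param X N x n input matrix.
#' @param y Targets: length-N vector or N x m matrix.
#' @param L Number of hidden nodes.
#' @param kind Hidden-node kind, `"additive"` (default) or `"rbf"`.
#' @param seed Optional integer seed for the random hidden layer.
#' @param standardize Standardize inputs to zero mean / unit variance
#'   (fitted on the training data) before the hidden layer. Default `TRUE`.
#' @param nodes Optional pre-drawn hidden layer (overrides `L`, `kind`,
#'   `seed`); used e.g. for nested-capacity sweeps.
#' @return An object of class `elm_model`.
#' @export
train_elm <- function(X, y, L = 10L, kind = c("additive", "rbf"),
                      seed = NULL, standardize = TRUE, nodes = NULL) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  T_mat <- as.matrix(y)
  if (nrow(X) < 1L) stop("need at least one training sample")
  if (nrow(X) != nrow(T_mat)) stop("X and y must have the same rows")

  if (standardize) {
    center <- colMeans(X)
    scale <- apply(X, 2L, stats::sd)
    scale[!is.finite(scale) | scale == 0] <- 1
  } else {
    center <- rep(0, ncol(X))
    scale <- rep(1, ncol(X))
  }
  Xs <- sweep(sweep(X, 2L, center), 2L, scale, "/")

  if (is.null(nodes)) {
    x_range <- rbind(apply(Xs, 2L, min), apply(Xs, 2L, max))
    draw <- function() random_hidden_layer(L, ncol(X), kind, x_range = x_range)
    nodes <- if (is.null(seed)) draw() else {
      withr::with_seed(as.integer(seed), draw())
    }
  }

  H <- hidden_output_matrix(nodes, Xs)
  beta <- solve_output_weights(H, T_mat)
  structure(
    list(nodes = nodes, beta = beta, kind = kind,
         center = center, scale = scale,
         input_dim = ncol(X), output_dim = ncol(T_mat)),
    class = "elm_model"
  )
}

#' Predict with an ELM model
#'
#' `f(x) = sum_i beta_i G(a_i, b_i, x)`, i.e. `H(X) beta`.
#'
#' @param model An `elm_model`.
#' @param X New input matrix (N x n).
#' @return N x m matrix of outputs (dropped to a vector when m = 1).
#' @export
predict_elm <- function(model, X) {
  stopifnot(inherits(model, "elm_model"))
  X <- as.matrix(X)
  if (ncol(X) != model$input_dim) {
    stop("input dimension ", ncol(X), " does not match model (",
         model$input_dim, ")")
  }
  Xs <- sweep(sweep(X, 2L, model$center), 2L, model$scale, "/")
  out <- hidden_output_matrix(model$nodes, Xs) %*% model$beta
  if (ncol(out) == 1L) drop(out) else out
}

#' @export
predict.elm_model <- function(object, newdata, ...) predict_elm(object, newdata)

#' @export
print.elm_model <- function(x, ...) {
  cat(sprintf("ELM model: %d %s hidden nodes, %d -> %d\n",
              length(x$nodes), x$kind, x$input_dim, x$output_dim))
  invisible(x)
}

#' Select the ELM hidden-layer size on a validation split
#'
#' Trains one ELM per candidate size on the training part of an internal
#' split and keeps the size with the lowest validation RMSE. The default
#' grid is the reference configuration {3, 6, 10}.
#'
#' @param X,y Training data.
#' @param grid Candidate hidden sizes.
#' @param kind Node kind.
#' @param seed Integer seed (controls both the split and the hidden layers).
#' @param val_frac Fraction held out for validation.
#' @return A list with the chosen `L`, the refitted `model` on all data,
#'   and the per-size validation RMSEs.
#' @export
select_elm_hidden <- function(X, y, grid = c(3L, 6L, 10L),
                              kind = c("additive", "rbf"),
                              seed = 1L, val_frac = 0.25) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  idx <- withr::with_seed(as.integer(seed), sample.int(n))
  n_val <- max(1L, floor(val_frac * n))
  val <- idx[seq_len(n_val)]
  tr <- idx[-seq_len(n_val)]
  rmses <- vapply(grid, function(L) {
    m <- train_elm(X[tr, , drop = FALSE], y[tr], L = L, kind = kind,
                   seed = stage_seed(seed, paste0("elm", L)))
    rmse(y[val], predict_elm(m, X[val, , drop = FALSE]))
  }, numeric(1))
  best <- grid[which.min(rmses)]
  model <- train_elm(X, y, L = best, kind = kind,
                     seed = stage_seed(seed, "elm_final"))
  list(L = best, model = model, validation_rmse = stats::setNames(rmses, grid))
}
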