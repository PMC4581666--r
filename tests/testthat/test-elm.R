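test_that("additive activation is the sigmoid of a.x + b", {
  expect_identical(activation_additive(c(0, 0), 0, c(5, -3)), 0.5)
  expect_equal(activation_additive(c(1, 1), 0, c(log(3), 0)), 0.75,
               tolerance = 1e-12)
  expect_equal(activation_additive(1, 0, 1000), 1, tolerance = 1e-12)
  expect_equal(activation_additive(1, 0, -1000), 0, tolerance = 1e-12)
  expect_error(activation_additive(c(1, 2), 0, 1), "length")
})

test_that("RBF activation is a Gaussian of the distance", {
  expect_identical(activation_rbf(c(1, 2), 1, c(1, 2)), 1)
  expect_equal(activation_rbf(0, 1, 1), exp(-1), tolerance = 1e-12)
  # strictly decreasing in distance
  d <- seq(0, 3, by = 0.5)
  v <- vapply(d, function(x) activation_rbf(0, 0.7, x), numeric(1))
  expect_true(all(diff(v) < 0))
  expect_error(activation_rbf(0, 0, 1), "b must be > 0")
  expect_error(activation_rbf(0, -1, 1), "b must be > 0")
  # documented literal variant g(b * dist)
  expect_equal(activation_rbf(0, 2, 1, variant = "scaled_distance"),
               exp(-4), tolerance = 1e-12)
})

test_that("random hidden layers are reproducible and respect invariants", {
  n1 <- withr::with_seed(3, random_hidden_layer(10, 4))
  n2 <- withr::with_seed(3, random_hidden_layer(10, 4))
  expect_identical(n1, n2)
  rbf <- withr::with_seed(4, random_hidden_layer(50, 2, kind = "rbf"))
  expect_true(all(vapply(rbf, function(nd) nd$b > 0, logical(1))))
  expect_error(random_hidden_layer(0, 3), "L must be >= 1")
  # additive biases are centred on zero
  b <- withr::with_seed(5, vapply(random_hidden_layer(1e5, 1),
                                  `[[`, numeric(1), "b"))
  expect_lt(abs(mean(b)), 0.02)
})

test_that("the hidden output matrix matches an element-wise loop oracle", {
  X <- matrix(c(0.1, -0.4, 0.7, 0.2, -0.9, 0.5), nrow = 3)
  nodes <- withr::with_seed(6, c(random_hidden_layer(2, 2, "additive"),
                                 random_hidden_layer(2, 2, "rbf",
                                                     x_range = rbind(c(-1, -1), c(1, 1)))))
  H <- hidden_output_matrix(nodes, X)
  for (j in 1:3) {
    for (i in seq_along(nodes)) {
      nd <- nodes[[i]]
      expected <- if (nd$kind == "additive") {
        activation_additive(nd$a, nd$b, X[j, ])
      } else {
        activation_rbf(nd$a, nd$b, X[j, ])
      }
      expect_equal(H[j, i], expected, tolerance = 1e-12)
    }
  }
  # zero-parameter additive nodes output 0.5 everywhere
  zero <- list(list(kind = "additive", a = c(0, 0), b = 0))
  expect_true(all(hidden_output_matrix(zero, X) == 0.5))
  expect_error(hidden_output_matrix(nodes, cbind(X, 0)), "dimension")
})

test_that("output weights solve the least-squares system", {
  # identity H returns T itself
  T4 <- withr::with_seed(1, matrix(rnorm(8), 4))
  expect_equal(solve_output_weights(diag(4), T4), T4, tolerance = 1e-12)

  # full column rank: equals the normal-equations solution
  withr::with_seed(7, for (i in 1:5) {
    H <- matrix(rnorm(40), 10)
    T1 <- matrix(rnorm(20), 10)
    oracle <- solve(crossprod(H), crossprod(H, T1))
    expect_equal(solve_output_weights(H, T1), oracle, tolerance = 1e-8)
  })

  # rank deficiency: minimum-norm among constructed minimisers
  withr::with_seed(8, {
    H0 <- matrix(rnorm(18), 6)
    H <- cbind(H0, H0[, 1])  # duplicated column -> null space span
    tvec <- matrix(rnorm(6), 6)
    beta <- solve_output_weights(H, tvec)
    base_res <- sqrt(sum((H %*% beta - tvec)^2))
    null_dir <- c(1, 0, 0, -1)
    for (a in c(-2, -0.5, 0.5, 2)) {
      alt <- beta + a * null_dir
      expect_equal(sqrt(sum((H %*% alt - tvec)^2)), base_res,
                   tolerance = 1e-8)
      expect_lte(sqrt(sum(beta^2)), sqrt(sum(alt^2)) + 1e-10)
    }
  })

  expect_error(solve_output_weights(matrix(c(1, NA), 1), matrix(1)), "finite")
})

test_that("an ELM interpolates when L = N and fits smooth targets when overcomplete", {
  X <- withr::with_seed(9, matrix(runif(30 * 2, -1, 1), 30))
  y <- withr::with_seed(10, runif(30, 1, 18))
  m <- train_elm(X, y, L = 30, seed = 9)
  expect_lt(rmse(y, predict_elm(m, X)), 1e-6)

  # N = 1 is fit exactly for any L
  m1 <- train_elm(matrix(c(0.3, 0.4), 1), 7, L = 3, seed = 1)
  expect_equal(predict_elm(m1, matrix(c(0.3, 0.4), 1)), 7, tolerance = 1e-8)

  # smooth 1-D target, overcomplete basis
  Xs <- withr::with_seed(11, matrix(runif(200, 0, 2 * pi), 200))
  ys <- sin(Xs[, 1])
  ms <- train_elm(Xs, ys, L = 40, seed = 11)
  expect_gt(r_squared(ys, predict_elm(ms, Xs)), 0.99)
})

test_that("prediction is H beta and linear in beta", {
  X <- withr::with_seed(12, matrix(rnorm(12), 6))
  y <- withr::with_seed(13, rnorm(6))
  m <- train_elm(X, y, L = 4, seed = 12)
  Xs <- sweep(sweep(X, 2, m$center), 2, m$scale, "/")
  H <- hidden_output_matrix(m$nodes, Xs)
  expect_equal(predict_elm(m, X), drop(H %*% m$beta), tolerance = 1e-12)

  m0 <- m
  m0$beta <- m$beta * 0
  expect_equal(predict_elm(m0, X), rep(0, 6))
  m2 <- m
  m2$beta <- m$beta * 2
  expect_equal(predict_elm(m2, X), 2 * predict_elm(m, X), tolerance = 1e-12)

  # single hand-set additive node on two points
  hand <- structure(list(
    nodes = list(list(kind = "additive", a = 2, b = 1)),
    beta = matrix(3), kind = "additive", center = 0, scale = 1,
    input_dim = 1L, output_dim = 1L), class = "elm_model")
  xin <- matrix(c(0, 1), 2)
  expect_equal(predict_elm(hand, xin),
               3 * stats::plogis(2 * c(0, 1) + 1), tolerance = 1e-12)
  expect_error(predict_elm(m, cbind(X, 1)), "dimension")
})

test_that("pseudoinverse satisfies the Moore-Penrose identities", {
  withr::with_seed(14, for (i in 1:5) {
    H <- matrix(rnorm(24), 6)
    H <- cbind(H, H[, 2])  # make it rank-deficient
    Hp <- solve_output_weights(H, diag(6))
    expect_equal(H %*% Hp %*% H, H, tolerance = 1e-8)
    expect_equal(Hp %*% H %*% Hp, Hp, tolerance = 1e-8)
  })
})
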