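test_that("Karva decoding handles simple genes", {
  # "+ a b" computes a + b
  tree <- karva_decode(c("+", "x1", "x2", "x1", "x1"))
  X <- cbind(x1 = c(2, -1), x2 = c(3, 5))
  expect_equal(evaluate_tree(tree, X), c(5, 4))

  # a gene starting with a terminal is a single leaf, rest ignored
  leaf <- karva_decode(c("x2", "+", "x1", "x1", "x1"))
  expect_length(leaf$syms, 1L)
  expect_equal(evaluate_tree(leaf, X), c(3, 5))

  expect_error(karva_decode(c("+", "z9", "x1")), "alphabet")
})

test_that("decoding matches an independent recursive-descent oracle", {
  terminals <- c("x1", "x2", "x3", "?")
  X <- withr::with_seed(30, matrix(runif(60, -3, 3), 20,
                                   dimnames = list(NULL, terminals[1:3])))
  withr::with_seed(31, for (i in 1:20) {
    h <- 7L
    gene <- c(sample(c("+", "-", "*", "/", "Q", "L", "E", "P", terminals),
                     h, replace = TRUE),
              sample(terminals, h + 1L, replace = TRUE))
    const <- runif(1, -10, 10)
    mine <- evaluate_tree(karva_decode(gene), X, const)
    oracle <- oracle_eval(oracle_decode(gene), X, const)
    expect_equal(mine, oracle, tolerance = 1e-12)
  })
})

test_that("protected arithmetic is total", {
  X <- matrix(c(-3, 0, 2), 3, dimnames = list(NULL, "x1"))
  # 1 / 0 -> 1
  div <- karva_decode(c("/", "?", "x1", "x1", "x1"))
  expect_equal(evaluate_tree(div, X, constant = 1)[2], 1.0)
  # sqrt(x^2) = |x|
  sq <- karva_decode(c("Q", "*", "x1", "x1", "x1", "x1", "x1"))
  expect_equal(evaluate_tree(sq, X), c(3, 0, 2))
  # ln of 0 -> 0, ln of negative -> ln |.|
  ln <- karva_decode(c("L", "x1", "x1"))
  expect_equal(evaluate_tree(ln, X), c(log(3), 0, log(2)))
  # overflow clamps instead of Inf
  ee <- karva_decode(c("E", "E", "E", "x1", "x1", "x1", "x1"))
  v <- evaluate_tree(ee, X)
  expect_true(all(is.finite(v)) && all(abs(v) <= 1e12))
})

test_that("fitness is a bounded monotone transform of RMSE", {
  X <- matrix(1:10, 10, dimnames = list(NULL, "x1"))
  y <- as.numeric(1:10)
  perfect <- list(genes = list(c("x1", rep("x1", 15))), constants = 0)
  expect_equal(gep_fitness(perfect, X, y), 1000)

  # strictly decreasing in RMSE via shifted constants
  fits <- vapply(c(0, 1, 2, 5), function(shift) {
    ch <- list(genes = list(c("+", "x1", "?", rep("x1", 13))),
               constants = shift)
    gep_fitness(ch, X, y)
  }, numeric(1))
  expect_true(all(diff(fits) < 0))

  # an exact hand-built formula on data generated from that formula
  X2 <- withr::with_seed(32, matrix(runif(40), 20, 2,
                                    dimnames = list(NULL, c("x1", "x2"))))
  y2 <- X2[, 1] + X2[, 2]
  exact <- list(genes = list(c("+", "x1", "x2", rep("x1", 13))),
                constants = 0)
  expect_equal(gep_fitness(exact, X2, y2), 1000)
})

test_that("configuration bounds are enforced", {
  expect_error(gep_config(population_size = 1), "population_size")
  expect_error(gep_config(head_length = 4), "head_length")
  expect_error(gep_config(n_genes = 5), "n_genes")
  expect_error(gep_config(mutation_rate = 1.5), "mutation_rate")
  cfg <- gep_config()
  expect_identical(cfg$population_size, 512L)
  expect_identical(cfg$head_length, 7L)
  # chromosome length h + (h + 1) per gene, 2 genes -> 30 symbols
  expect_identical(2L * (cfg$head_length * 2L + 1L), 30L)
})

test_that("evolution respects elitism, determinism and population size", {
  X <- withr::with_seed(33, matrix(runif(60, -2, 2), 30, 2,
                                   dimnames = list(NULL, c("x1", "x2"))))
  y <- X[, 1] + X[, 2]
  cfg <- gep_config(population_size = 60, generations = 12, seed = 41)
  r1 <- evolve_gep(X, y, cfg)
  r2 <- evolve_gep(X, y, cfg)
  expect_identical(r1$best, r2$best)
  expect_identical(r1$history, r2$history)
  expect_length(r1$history, 13L)
  expect_true(all(diff(r1$history) >= 0))
  expect_true(chromosome_valid(r1$best, cfg$head_length, 2))
  expect_true(is.character(r1$expression) && nzchar(r1$expression))
  # predictions deterministic given chromosome + data
  expect_identical(predict_chromosome(r1$best, X),
                   predict_chromosome(r1$best, X))
})

test_that("zero variation rates leave the population unchanged", {
  X <- withr::with_seed(34, matrix(runif(20), 10, 2,
                                   dimnames = list(NULL, c("x1", "x2"))))
  y <- X[, 1]
  cfg <- gep_config(population_size = 30, generations = 1,
                    mutation_rate = 0, crossover_rate = 0,
                    inversion_rate = 0, seed = 42)
  r <- evolve_gep(X, y, cfg)
  # with elitism and no operators the best fitness cannot change
  expect_identical(r$history[1], r$history[2])
})

test_that("constant targets short-circuit to an exact solution", {
  X <- matrix(runif(10), 10, 1, dimnames = list(NULL, "x1"))
  expect_warning(r <- evolve_gep(X, rep(7, 10), gep_config(seed = 1)),
                 "constant")
  expect_equal(predict_chromosome(r$best, X), rep(7, 10))
  expect_equal(r$best_fitness, 1000)
})

test_that("infix export mirrors chromosome evaluation", {
  ch <- list(genes = list(c("*", "x1", "?", rep("x1", 13)),
                          c("Q", "x2", rep("x2", 14))),
             constants = c(2.5, 0))
  X <- matrix(c(3, 4), 1, 2, dimnames = list(NULL, c("x1", "x2")))
  expect_equal(predict_chromosome(ch, X), 3 * 2.5 + 2)
  expr <- chromosome_to_infix(ch)
  expect_match(expr, "x1")
  expect_match(expr, "sqrt")
})
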