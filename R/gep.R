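# Gene-expression-programming symbolic regression.
#
# Fixed-length chromosomes of 2-3 genes; each gene has a head (functions or
# terminals) of length h and a tail (terminals only) of length
# t = h * (max_arity - 1) + 1 = h + 1, and decodes breadth-first (Karva
# notation) into an expression tree. Gene outputs are linked by addition.
# Arithmetic is protected so every chromosome is a total function.
#
# Function set: + - * / (binary), Q = square root, L = natural log,
# E = e^x, P = a^x with a gene-local random constant a (all unary).
# Terminals: x1..xn (features) and "?" (the gene-local constant).

GEP_FUNCTIONS <- c("+", "-", "*", "/", "Q", "L", "E", "P")
GEP_ARITY <- c("+" = 2L, "-" = 2L, "*" = 2L, "/" = 2L,
               "Q" = 1L, "L" = 1L, "E" = 1L, "P" = 1L)
GEP_MAX_ARITY <- 2L
GEP_CLAMP <- 1e12
GEP_EPS <- 1e-12

gep_terminals <- function(n_features) c(paste0("x", seq_len(n_features)), "?")

#' GEP configuration
#'
#' Defaults follow the reference setup: population 512; head length 7 and
#' 2 genes (tail length h + 1 = 8, so the chromosome carries 30 symbols,
#' inside the reference 20-30 range); event rates given per thousand in
#' the reference table (mutation 91.46, crossover 30.56, inversion 108.53)
#' are normalized to the probabilities 0.09146, 0.03056 and 0.10853.
#' Mutation is applied per symbol, crossover per selected pair, inversion
#' per individual.
#'
#' @param population_size Number of chromosomes per generation (>= 2).
#' @param head_length Gene head length, 5..9.
#' @param n_genes Genes per chromosome, 2..3.
#' @param mutation_rate,crossover_rate,inversion_rate Probabilities in
#'   \[0, 1\].
#' @param generations Number of generations to evolve.
#' @param elitism_count Best individuals copied unchanged (>= 1).
#' @param const_range Range for gene-local random constants.
#' @param seed Integer seed.
#' @return An object of class `gep_config`.
#' @export
gep_config <- function(population_size = 512L, head_length = 7L,
                       n_genes = 2L, mutation_rate = 0.09146,
                       crossover_rate = 0.03056, inversion_rate = 0.10853,
                       generations = 50L, elitism_count = 1L,
                       const_range = c(-10, 10), seed = 1L) {
  cfg <- list(
    population_size = as.integer(population_size),
    head_length = as.integer(head_length),
    n_genes = as.integer(n_genes),
    mutation_rate = mutation_rate,
    crossover_rate = crossover_rate,
    inversion_rate = inversion_rate,
    generations = as.integer(generations),
    elitism_count = as.integer(elitism_count),
    const_range = const_range,
    seed = as.integer(seed)
  )
  errs <- character(0)
  if (cfg$population_size < 2L) errs <- c(errs, "population_size must be >= 2")
  if (!cfg$head_length %in% 5:9) errs <- c(errs, "head_length must be in 5..9")
  if (!cfg$n_genes %in% 2:3) errs <- c(errs, "n_genes must be 2 or 3")
  for (r in c("mutation_rate", "crossover_rate", "inversion_rate")) {
    if (!is.numeric(cfg[[r]]) || cfg[[r]] < 0 || cfg[[r]] > 1) {
      errs <- c(errs, paste0(r, " must be a probability in [0, 1]"))
    }
  }
  if (cfg$generations < 0L) errs <- c(errs, "generations must be >= 0")
  if (cfg$elitism_count < 1L) errs <- c(errs, "elitism_count must be >= 1")
  if (length(errs)) stop(paste(errs, collapse = "; "))
  structure(cfg, class = "gep_config")
}

gene_tail_length <- function(head_length) {
  head_length * (GEP_MAX_ARITY - 1L) + 1L
}

random_gene <- function(head_length, terminals) {
  tail_length <- gene_tail_length(head_length)
  head <- sample(c(GEP_FUNCTIONS, terminals), head_length, replace = TRUE)
  tail <- sample(terminals, tail_length, replace = TRUE)
  c(head, tail)
}

random_chromosome <- function(config, terminals) {
  list(
    genes = replicate(config$n_genes,
                      random_gene(config$head_length, terminals),
                      simplify = FALSE),
    constants = stats::runif(config$n_genes, config$const_range[1L],
                             config$const_range[2L]),
    fitness = NA_real_
  )
}

#' Check the head/tail validity of a chromosome
#'
#' Head positions may hold functions or terminals; tail positions must
#' hold terminals only; every symbol must come from the alphabet.
#'
#' @param chromosome A chromosome as produced by [evolve_gep()]'s
#'   population (list with `genes` and `constants`).
#' @param head_length Gene head length.
#' @param n_features Number of input features.
#' @return `TRUE` or `FALSE`.
#' @export
chromosome_valid <- function(chromosome, head_length, n_features) {
  terminals <- gep_terminals(n_features)
  tail_length <- gene_tail_length(head_length)
  all(vapply(chromosome$genes, function(g) {
    if (length(g) != head_length + tail_length) return(FALSE)
    head <- g[seq_len(head_length)]
    tail <- g[head_length + seq_len(tail_length)]
    all(head %in% c(GEP_FUNCTIONS, terminals)) && all(tail %in% terminals)
  }, logical(1)))
}

#' Decode a gene breadth-first (Karva notation) into an expression tree
#'
#' The first symbol is the root; each function node consumes its arity's
#' worth of symbols from the remaining string, level by level. Surplus
#' tail symbols are ignored. A gene whose first symbol is a terminal
#' decodes to a single leaf.
#'
#' @param gene Character vector of symbols.
#' @return A list with `syms` (symbols in BFS order) and `kids` (list of
#'   child indices per node; children always have larger indices than
#'   their parent).
#' @export
karva_decode <- function(gene) {
  bad <- !(gene %in% GEP_FUNCTIONS | grepl("^x[0-9]+$", gene) | gene == "?")
  if (any(bad)) {
    stop("symbol(s) outside the alphabet: ",
         paste(unique(gene[bad]), collapse = ", "))
  }
  syms <- gene[1L]
  kids <- list(integer(0))
  next_pos <- 2L
  node <- 1L
  while (node <= length(syms)) {
    ar <- if (syms[node] %in% GEP_FUNCTIONS) GEP_ARITY[[syms[node]]] else 0L
    if (ar > 0L) {
      if (next_pos + ar - 1L > length(gene)) {
        stop("gene too short to decode (invalid head/tail structure)")
      }
      child_idx <- length(syms) + seq_len(ar)
      syms <- c(syms, gene[next_pos:(next_pos + ar - 1L)])
      for (ci in child_idx) kids[[ci]] <- integer(0)
      kids[[node]] <- child_idx
      next_pos <- next_pos + ar
    }
    node <- node + 1L
  }
  list(syms = syms, kids = kids)
}

clamp_val <- function(v) {
  v[is.nan(v)] <- 0
  pmin(pmax(v, -GEP_CLAMP), GEP_CLAMP)
}

apply_op <- function(op, v1, v2 = NULL, constant = 0) {
  out <- switch(op,
    "+" = v1 + v2,
    "-" = v1 - v2,
    "*" = v1 * v2,
    "/" = ifelse(abs(v2) < GEP_EPS, 1.0, v1 / v2),
    "Q" = sqrt(abs(v1)),
    "L" = {
      av <- abs(v1)
      ifelse(av < GEP_EPS, 0, log(pmax(av, GEP_EPS)))
    },
    "E" = exp(pmin(v1, log(GEP_CLAMP))),
    "P" = {
      base <- abs(constant)
      if (base < GEP_EPS) {
        rep(0, length(v1))
      } else {
        exp(pmin(v1 * log(base), log(GEP_CLAMP)))
      }
    },
    stop("unknown operator: ", op)
  )
  clamp_val(out)
}

#' Evaluate a decoded expression tree on a data matrix
#'
#' Protected arithmetic: division by (near-)zero yields 1; square root and
#' log act on absolute values (log of 0 yields 0); `e^x` and `a^x` are
#' clamped; every node output is clamped to +-1e12, so evaluation is a
#' total function.
#'
#' @param tree Output of [karva_decode()].
#' @param X N x n feature matrix (terminal `xj` reads column j).
#' @param constant The gene-local constant bound to `?` and to `P`'s base.
#' @return Numeric vector of length N.
#' @export
evaluate_tree <- function(tree, X, constant = 0) {
  X <- as.matrix(X)
  N <- nrow(X)
  n_nodes <- length(tree$syms)
  vals <- vector("list", n_nodes)
  for (j in rev(seq_len(n_nodes))) {
    s <- tree$syms[j]
    if (s %in% GEP_FUNCTIONS) {
      ch <- tree$kids[[j]]
      if (GEP_ARITY[[s]] == 2L) {
        vals[[j]] <- apply_op(s, vals[[ch[1L]]], vals[[ch[2L]]],
                              constant = constant)
      } else {
        vals[[j]] <- apply_op(s, vals[[ch[1L]]], constant = constant)
      }
    } else if (s == "?") {
      vals[[j]] <- rep(constant, N)
    } else {
      col <- as.integer(sub("^x", "", s))
      if (col > ncol(X)) stop("terminal ", s, " exceeds feature count")
      vals[[j]] <- unname(X[, col])
    }
  }
  unname(clamp_val(vals[[1L]]))
}

#' Predictions of a chromosome
#'
#' Each gene is decoded and evaluated with its own constant; gene outputs
#' are linked by addition.
#'
#' @param chromosome A chromosome (list with `genes`, `constants`).
#' @param X Feature matrix.
#' @return Numeric vector of predictions.
#' @export
predict_chromosome <- function(chromosome, X) {
  X <- as.matrix(X)
  out <- rep(0, nrow(X))
  for (g in seq_along(chromosome$genes)) {
    tree <- karva_decode(chromosome$genes[[g]])
    out <- out + evaluate_tree(tree, X, chromosome$constants[g])
  }
  clamp_val(out)
}

#' Fitness of a chromosome
#'
#' `1000 / (1 + RMSE)`: bounded, higher is better, 1000 for a perfect fit,
#' strictly decreasing in RMSE.
#'
#' @param chromosome A chromosome.
#' @param X Feature matrix.
#' @param y Targets.
#' @return Fitness in (0, 1000\].
#' @export
gep_fitness <- function(chromosome, X, y) {
  1000 / (1 + rmse(y, predict_chromosome(chromosome, X)))
}

mutate_chromosome <- function(chrom, config, terminals) {
  h <- config$head_length
  for (g in seq_along(chrom$genes)) {
    gene <- chrom$genes[[g]]
    hit <- which(stats::runif(length(gene)) < config$mutation_rate)
    for (pos in hit) {
      gene[pos] <- if (pos <= h) {
        sample(c(GEP_FUNCTIONS, terminals), 1L)
      } else {
        sample(terminals, 1L)
      }
    }
    chrom$genes[[g]] <- gene
    if (stats::runif(1L) < config$mutation_rate) {
      chrom$constants[g] <- stats::runif(1L, config$const_range[1L],
                                         config$const_range[2L])
    }
  }
  chrom$fitness <- NA_real_
  chrom
}

# One-point recombination over the concatenated symbol string. Because all
# chromosomes share the same head/tail layout, cutting at any aligned
# position preserves validity. Gene constants travel with the parent that
# contributes the gene's cut-side majority start.
crossover_chromosomes <- function(a, b, config) {
  gene_len <- config$head_length + gene_tail_length(config$head_length)
  total <- gene_len * config$n_genes
  cut <- sample.int(total - 1L, 1L)
  flat_a <- unlist(a$genes)
  flat_b <- unlist(b$genes)
  child_flat <- c(flat_a[seq_len(cut)], flat_b[(cut + 1L):total])
  genes <- unname(split(child_flat,
                        rep(seq_len(config$n_genes), each = gene_len)))
  genes <- lapply(genes, unname)
  constants <- ifelse(seq_len(config$n_genes) * gene_len <= cut,
                      a$constants, b$constants)
  list(genes = genes, constants = constants, fitness = NA_real_)
}

invert_chromosome <- function(chrom, config) {
  h <- config$head_length
  g <- sample.int(length(chrom$genes), 1L)
  if (h >= 2L) {
    pts <- sort(sample.int(h, 2L))
    seg <- pts[1L]:pts[2L]
    chrom$genes[[g]][seg] <- rev(chrom$genes[[g]][seg])
  }
  chrom$fitness <- NA_real_
  chrom
}

tournament_pick <- function(fitness, size = 3L) {
  cand <- sample.int(length(fitness), size, replace = TRUE)
  cand[which.max(fitness[cand])]
}

#' Evolve a GEP population for symbolic regression
#'
#' Generational loop with tournament selection (size 3), head-safe point
#' mutation, one-point recombination, head-segment inversion, and elitism
#' (the best individuals are copied unchanged, so best fitness never
#' decreases). Reproducible from `config$seed`.
#'
#' @param X N x n feature matrix.
#' @param y Length-N target vector. Constant targets short-circuit to an
#'   exact constant-expression solution with a warning.
#' @param config A [gep_config()].
#' @param check_validity Assert the head/tail invariant for every
#'   individual in every generation (default `TRUE`).
#' @return An object of class `gep_result`: `best` chromosome,
#'   `best_fitness`, `history` (best fitness per generation, length
#'   `generations + 1` including the initial population), `expression`
#'   (infix string) and the `config`.
#' @export
evolve_gep <- function(X, y, config = gep_config(), check_validity = TRUE) {
  stopifnot(inherits(config, "gep_config"))
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X and y sizes disagree")
  terminals <- gep_terminals(ncol(X))

  if (stats::sd(y) == 0) {
    warning("constant target: returning an exact constant-expression solution")
    gene_len <- config$head_length + gene_tail_length(config$head_length)
    const_gene <- rep("?", gene_len)
    best <- list(
      genes = replicate(config$n_genes, const_gene, simplify = FALSE),
      constants = c(y[1L], rep(0, config$n_genes - 1L)),
      fitness = 1000
    )
    return(structure(
      list(best = best, best_fitness = 1000, history = rep(1000, 1L),
           expression = format(y[1L]), config = config),
      class = "gep_result"
    ))
  }

  withr::with_seed(config$seed, {
    pop <- replicate(config$population_size,
                     random_chromosome(config, terminals), simplify = FALSE)
    history <- numeric(config$generations + 1L)

    eval_pop <- function(pop) {
      vapply(pop, function(ch) {
        if (is.na(ch$fitness)) gep_fitness(ch, X, y) else ch$fitness
      }, numeric(1))
    }

    fitness <- eval_pop(pop)
    pop <- Map(function(ch, f) { ch$fitness <- f; ch }, pop, fitness)
    history[1L] <- max(fitness)

    for (gen in seq_len(config$generations)) {
      if (check_validity) {
        ok <- vapply(pop, chromosome_valid, logical(1),
                     head_length = config$head_length, n_features = ncol(X))
        if (!all(ok)) stop("internal error: invalid chromosome in generation ",
                           gen)
      }
      elite_idx <- order(-fitness)[seq_len(config$elitism_count)]
      new_pop <- pop[elite_idx]
      while (length(new_pop) < config$population_size) {
        p1 <- pop[[tournament_pick(fitness)]]
        child <- if (stats::runif(1L) < config$crossover_rate) {
          p2 <- pop[[tournament_pick(fitness)]]
          crossover_chromosomes(p1, p2, config)
        } else {
          p1
        }
        child <- mutate_chromosome(child, config, terminals)
        if (stats::runif(1L) < config$inversion_rate) {
          child <- invert_chromosome(child, config)
        }
        new_pop[[length(new_pop) + 1L]] <- child
      }
      pop <- new_pop
      fitness <- eval_pop(pop)
      pop <- Map(function(ch, f) { ch$fitness <- f; ch }, pop, fitness)
      history[gen + 1L] <- max(fitness)
    }

    best_i <- which.max(fitness)
    structure(
      list(best = pop[[best_i]], best_fitness = fitness[best_i],
           history = history,
           expression = chromosome_to_infix(pop[[best_i]]),
           config = config),
      class = "gep_result"
    )
  })
}

#' @export
print.gep_result <- function(x, ...) {
  cat("GEP symbolic regression result\n")
  cat("  best fitness:", format(x$best_fitness), "\n")
  cat("  expression:", x$expression, "\n")
  invisible(x)
}

#' @export
predict.gep_result <- function(object, newdata, ...) {
  predict_chromosome(object$best, newdata)
}

tree_to_infix <- function(tree, constant) {
  rec <- function(j) {
    s <- tree$syms[j]
    if (s %in% GEP_FUNCTIONS) {
      ch <- tree$kids[[j]]
      switch(s,
        "+" = , "-" = , "*" = , "/" =
          paste0("(", rec(ch[1L]), " ", s, " ", rec(ch[2L]), ")"),
        "Q" = paste0("sqrt(", rec(ch[1L]), ")"),
        "L" = paste0("ln(", rec(ch[1L]), ")"),
        "E" = paste0("exp(", rec(ch[1L]), ")"),
        "P" = paste0(format(constant, digits = 4), "^(", rec(ch[1L]), ")")
      )
    } else if (s == "?") {
      format(constant, digits = 4)
    } else {
      s
    }
  }
  rec(1L)
}

#' Human-readable infix expression of a chromosome
#'
#' @param chromosome A chromosome.
#' @return A single string, gene expressions joined by `+`.
#' @export
chromosome_to_infix <- function(chromosome) {
  parts <- vapply(seq_along(chromosome$genes), function(g) {
    tree_to_infix(karva_decode(chromosome$genes[[g]]),
                  chromosome$constants[g])
  }, character(1))
  paste(parts, collapse = " + ")
}
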