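# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# The 300-sample synthetic study: phantoms, weighted-PCA features and
# metadata, reused by the end-to-end checks.
study_data <- function() {
  if (is.null(.fixtures$study)) {
    ds <- generate_dataset(balanced_quotas(300), seed = 11L)
    md <- dataset_metadata(ds)
    X <- dataset_image_matrix(ds)
    basis <- fit_weighted_pca(X)
    feats <- extract_features_matrix(X, basis)
    .fixtures$study <- list(
      metadata = md,
      features = feats,
      p = ncol(feats),
      total_finger_length = vapply(ds, function(s) {
        sum(s$geometry$finger_lengths)
      }, numeric(1))
    )
  }
  .fixtures$study
}

# A tiny deterministic image set for linear-algebra oracles.
toy_images <- function(n = 6L, d = 20L, seed = 42L) {
  withr::with_seed(seed, matrix(stats::rnorm(n * d), nrow = n))
}

# A small repository with one entry per gender x ethnicity category.
one_per_category_repo <- function(p = 4L, seed = 1L) {
  codes <- category_codes()
  feats <- withr::with_seed(seed, matrix(stats::rnorm(length(codes) * p),
                                         nrow = length(codes)))
  meta <- do.call(rbind, lapply(seq_along(codes), function(i) {
    tr <- parse_category(codes[i])
    data.frame(sample_id = sprintf("E%02d", i), age_years = 5 + i,
               gender = tr$gender, ethnicity = tr$ethnicity,
               stringsAsFactors = FALSE)
  }))
  build_repository(feats, meta)
}

# Independent recursive-descent Karva decoder used as an oracle against
# karva_decode(): consumes symbols depth-first from an explicit BFS queue
# bookkeeping, returning a nested-list expression evaluated recursively.
oracle_decode <- function(gene) {
  arity <- c("+" = 2L, "-" = 2L, "*" = 2L, "/" = 2L,
             "Q" = 1L, "L" = 1L, "E" = 1L, "P" = 1L)
  # compute each node's children by level-order walk, then build nested
  # lists recursively
  n_children <- function(s) if (s %in% names(arity)) arity[[s]] else 0L
  level_start <- 1L
  level_syms <- 1L
  used <- 1L
  levels <- list(1L)
  repeat {
    need <- sum(vapply(gene[levels[[length(levels)]]], n_children, integer(1)))
    if (need == 0L) break
    nxt <- (used + 1L):(used + need)
    levels[[length(levels) + 1L]] <- nxt
    used <- used + need
  }
  # assign children positions
  kids <- vector("list", used)
  for (li in seq_len(length(levels) - 1L)) {
    pool <- levels[[li + 1L]]
    offset <- 0L
    for (node in levels[[li]]) {
      nc <- n_children(gene[node])
      kids[[node]] <- if (nc > 0L) pool[(offset + 1L):(offset + nc)] else integer(0)
      offset <- offset + nc
    }
  }
  build <- function(i) {
    list(sym = gene[i], args = lapply(kids[[i]], build))
  }
  build(1L)
}

oracle_eval <- function(node, X, constant) {
  clamp <- function(v) {
    v[is.nan(v)] <- 0
    pmin(pmax(v, -1e12), 1e12)
  }
  s <- node$sym
  if (s == "?") return(rep(constant, nrow(X)))
  if (grepl("^x[0-9]+$", s)) return(X[, as.integer(sub("x", "", s))])
  a <- oracle_eval(node$args[[1]], X, constant)
  v <- switch(s,
    "+" = a + oracle_eval(node$args[[2]], X, constant),
    "-" = a - oracle_eval(node$args[[2]], X, constant),
    "*" = a * oracle_eval(node$args[[2]], X, constant),
    "/" = {
      b <- oracle_eval(node$args[[2]], X, constant)
      ifelse(abs(b) < 1e-12, 1.0, a / b)
    },
    "Q" = sqrt(abs(a)),
    "L" = ifelse(abs(a) < 1e-12, 0, log(pmax(abs(a), 1e-12))),
    "E" = exp(pmin(a, log(1e12))),
    "P" = if (abs(constant) < 1e-12) rep(0, length(a)) else
      exp(pmin(a * log(abs(constant)), log(1e12)))
  )
  clamp(v)
}
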