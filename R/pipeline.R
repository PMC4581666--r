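# Configuration and the end-to-end pipeline:
# generate -> fit features -> build repository -> CBIR evaluation ->
# train ELM / ANN / GEP -> held-out comparison report.
#
# Every stochastic stage derives its own seed from the single run seed via
# stage_seed(), so stages are independently re-runnable yet the whole run
# is reproducible bit-for-bit.

#' Default run configuration
#'
#' The reference model parameters: ELM and ANN hidden-size grid {3, 6, 10}
#' with one output; ANN backprop with 1000 iterations and sigmoid
#' activation; GEP population 512 with the reference head/gene/rate
#' settings; retrieval over k = 5 neighbours; a stratified 70/30
#' train/test split.
#'
#' @return A named list of configuration blocks (`seed`, `data`,
#'   `features`, `retrieval`, `elm`, `ann`, `gp`, `split`, `paths`).
#' @export
default_config <- function() {
  list(
    seed = 1L,
    data = list(
      n_samples = NULL   # NULL = the reference quota table
    ),
    features = list(
      p = NULL,          # NULL = smallest p reaching var_target
      var_target = 0.95,
      weighting = "variance",
      model_p = 3L       # leading features fed to the regression engines
    ),
    retrieval = list(
      k = 5L,
      metric = "neg_euclidean",
      filter = TRUE
    ),
    elm = list(
      hidden = c(3L, 6L, 10L),
      kind = "additive"
    ),
    ann = list(
      hidden = c(3L, 6L, 10L),
      iterations = 1000L,
      learning_rate = 0.1
    ),
    gp = list(
      population_size = 512L,
      head_length = 7L,
      n_genes = 2L,
      mutation_rate = 0.09146,
      crossover_rate = 0.03056,
      inversion_rate = 0.10853,
      generations = 50L,
      elitism_count = 1L
    ),
    split = list(
      train_frac = 0.7
    ),
    paths = list(
      image_dir = NULL,
      out_dir = NULL
    )
  )
}

merge_config <- function(defaults, user, prefix = "") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ",
         paste0(prefix, unknown, collapse = ", "))
  }
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      if (!is.list(user[[nm]])) {
        stop("configuration key ", prefix, nm, " must be a block")
      }
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                                     prefix = paste0(prefix, nm, "."))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Load a run configuration from a JSON file
#'
#' An empty file (or `{}`) yields the full default configuration; unknown
#' keys are rejected. Values override the defaults block-wise.
#'
#' @param path JSON file path.
#' @return A configuration list as from [default_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file does not exist: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  user <- if (!nzchar(trimws(txt))) list() else {
    jsonlite::fromJSON(txt, simplifyVector = TRUE)
  }
  cfg <- merge_config(default_config(), user)
  errs <- validate_config(cfg)
  if (length(errs)) stop("invalid configuration:\n  ",
                         paste(errs, collapse = "\n  "))
  cfg
}

#' Save a configuration as JSON
#'
#' @param config Configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' Validate a run configuration
#'
#' Checks every constraint and returns all violations, not just the first.
#'
#' @param config Configuration list.
#' @return Character vector of error messages (empty when valid).
#' @export
validate_config <- function(config) {
  errs <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)

  chk(is.numeric(config$seed) && length(config$seed) == 1L,
      "seed must be a single integer")
  chk(is.null(config$data$n_samples) ||
        (is.numeric(config$data$n_samples) && config$data$n_samples >= 24),
      "data.n_samples must be NULL or >= 24 (one per quota cell)")
  chk(is.null(config$features$p) ||
        (is.numeric(config$features$p) && config$features$p >= 1),
      "features.p must be NULL or >= 1")
  chk(is.numeric(config$features$var_target) &&
        config$features$var_target > 0 && config$features$var_target <= 1,
      "features.var_target must be in (0, 1]")
  chk(config$features$weighting %in% c("variance", "uniform"),
      "features.weighting must be 'variance' or 'uniform'")
  chk(is.numeric(config$features$model_p) && config$features$model_p >= 1,
      "features.model_p must be >= 1")
  chk(is.numeric(config$retrieval$k) && config$retrieval$k >= 1,
      "retrieval.k must be >= 1")
  chk(config$retrieval$metric %in% c("neg_euclidean", "cosine"),
      "retrieval.metric must be 'neg_euclidean' or 'cosine'")
  chk(is.logical(config$retrieval$filter),
      "retrieval.filter must be TRUE or FALSE")
  chk(is.numeric(config$elm$hidden) && all(config$elm$hidden >= 1),
      "elm.hidden must be positive sizes")
  chk(config$elm$kind %in% c("additive", "rbf"),
      "elm.kind must be 'additive' or 'rbf'")
  chk(is.numeric(config$ann$hidden) && all(config$ann$hidden >= 1),
      "ann.hidden must be positive sizes")
  chk(is.numeric(config$ann$iterations) && config$ann$iterations >= 1,
      "ann.iterations must be >= 1")
  chk(is.numeric(config$ann$learning_rate) && config$ann$learning_rate > 0,
      "ann.learning_rate must be > 0")
  for (r in c("mutation_rate", "crossover_rate", "inversion_rate")) {
    chk(is.numeric(config$gp[[r]]) && config$gp[[r]] >= 0 &&
          config$gp[[r]] <= 1,
        paste0("gp.", r, " must be a probability in [0, 1]"))
  }
  chk(is.numeric(config$gp$population_size) && config$gp$population_size >= 2,
      "gp.population_size must be >= 2")
  chk(is.numeric(config$gp$generations) && config$gp$generations >= 0,
      "gp.generations must be >= 0")
  chk(is.numeric(config$split$train_frac) && config$split$train_frac > 0 &&
        config$split$train_frac < 1,
      "split.train_frac must be in (0, 1)")
  if (!is.null(config$paths$image_dir)) {
    chk(dir.exists(config$paths$image_dir),
        paste0("paths.image_dir does not exist: ", config$paths$image_dir))
  }
  errs
}

#' Stratified train/test split by age group and category
#'
#' Samples a train fraction independently within every age-group x
#' gender x ethnicity stratum, so both parts cover all cells.
#'
#' @param metadata Metadata data frame.
#' @param train_frac Training fraction in (0, 1).
#' @param seed Integer seed.
#' @return A list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(metadata, train_frac = 0.7, seed = 1L) {
  group <- cut(metadata$age_years, breaks = c(0, 6, 12, 18),
               labels = AGE_GROUPS)
  strata <- interaction(group, metadata$gender, metadata$ethnicity,
                        drop = TRUE)
  train <- withr::with_seed(as.integer(seed), {
    unlist(lapply(split(seq_len(nrow(metadata)), strata), function(idx) {
      n_tr <- max(1L, round(train_frac * length(idx)))
      if (length(idx) == 1L) return(idx)
      sample(idx, min(n_tr, length(idx) - 1L))
    }), use.names = FALSE)
  })
  list(train = sort(train), test = sort(setdiff(seq_len(nrow(metadata)),
                                                train)))
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste0(..., collapse = "")))
}

#' Run the full assessment pipeline
#'
#' Generates (or loads nothing but generates) the phantom dataset, fits the
#' weighted-PCA basis, builds the repository, computes leave-one-out CBIR
#' predictions, trains the ELM, ANN and GEP regressors on the training
#' split of the feature matrix, and reports held-out RMSE / R-squared /
#' Pearson r for all four predictors plus a constant-mean baseline. With
#' `paths.out_dir` set, writes metadata, the report, scatter data and a
#' machine-readable run manifest.
#'
#' @param config Configuration list (see [default_config()]).
#' @return Invisibly, a list with the `report` (`eval_report`), the
#'   dataset `metadata`, the fitted `basis`, the CBIR leave-one-out
#'   predictions, the split, and the fitted models.
#' @export
run_pipeline <- function(config = default_config()) {
  errs <- validate_config(config)
  if (length(errs)) stop("invalid configuration:\n  ",
                         paste(errs, collapse = "\n  "))
  t0 <- Sys.time()

  quotas <- if (is.null(config$data$n_samples)) {
    reference_quotas()
  } else {
    balanced_quotas(config$data$n_samples)
  }
  log_stage("generate", "n=", sum(quotas))
  dataset <- generate_dataset(quotas, seed = stage_seed(config$seed,
                                                        "generate"))
  metadata <- dataset_metadata(dataset)
  images <- dataset_image_matrix(dataset)

  log_stage("fit-features", "weighting=", config$features$weighting)
  basis <- fit_weighted_pca(images, p = config$features$p,
                            var_target = config$features$var_target,
                            weighting = config$features$weighting)
  features <- extract_features_matrix(images, basis)

  log_stage("build-repo", "p=", ncol(features))
  repo <- build_repository(features, metadata)

  log_stage("cbir-loo", "k=", config$retrieval$k)
  cbir_pred <- cbir_loo_predictions(repo, k = config$retrieval$k,
                                    metric = config$retrieval$metric,
                                    filter = config$retrieval$filter)

  split <- stratified_split(metadata, config$split$train_frac,
                            seed = stage_seed(config$seed, "split"))
  tr <- split$train
  te <- split$test
  y <- metadata$age_years

  # The regression engines consume the leading model_p weighted-PCA
  # features (default 3, the reference input-layer width); retrieval keeps
  # the full feature vector.
  mp <- min(as.integer(config$features$model_p), ncol(features))
  mfeat <- features[, seq_len(mp), drop = FALSE]

  log_stage("train-elm", "grid=", paste(config$elm$hidden, collapse = ","))
  elm_fit <- select_elm_hidden(mfeat[tr, , drop = FALSE], y[tr],
                               grid = config$elm$hidden,
                               kind = config$elm$kind,
                               seed = stage_seed(config$seed, "elm"))
  elm_pred <- predict_elm(elm_fit$model, mfeat[te, , drop = FALSE])

  log_stage("train-ann", "iterations=", config$ann$iterations)
  ann_fit <- select_mlp_hidden(mfeat[tr, , drop = FALSE], y[tr],
                               grid = config$ann$hidden,
                               iterations = config$ann$iterations,
                               learning_rate = config$ann$learning_rate,
                               seed = stage_seed(config$seed, "ann"))
  ann_pred <- ann_fit$predict(mfeat[te, , drop = FALSE])

  log_stage("train-gp", "population=", config$gp$population_size,
            " generations=", config$gp$generations)
  gp_cfg <- gep_config(
    population_size = config$gp$population_size,
    head_length = config$gp$head_length,
    n_genes = config$gp$n_genes,
    mutation_rate = config$gp$mutation_rate,
    crossover_rate = config$gp$crossover_rate,
    inversion_rate = config$gp$inversion_rate,
    generations = config$gp$generations,
    elitism_count = config$gp$elitism_count,
    seed = stage_seed(config$seed, "gp")
  )
  gp_fit <- evolve_gep(mfeat[tr, , drop = FALSE], y[tr], gp_cfg)
  gp_pred <- predict_chromosome(gp_fit$best, mfeat[te, , drop = FALSE])

  log_stage("compare", "n_test=", length(te))
  report <- compare_models(y[te], list(
    CBIR = cbir_pred[te],
    ELM = elm_pred,
    ANN = ann_pred,
    GP = gp_pred,
    baseline_mean = rep(mean(y[tr]), length(te))
  ))

  out <- list(report = report, metadata = metadata, basis = basis,
              features = features, cbir_predictions = cbir_pred,
              split = split, elm = elm_fit, ann = ann_fit, gp = gp_fit,
              config = config)

  if (!is.null(config$paths$out_dir)) {
    dir.create(config$paths$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$paths$out_dir
    write_metadata_csv(metadata, file.path(od, "metadata.csv"))
    write_eval_report(report, file.path(od, "report.csv"),
                      scatter_path = file.path(od, "scatter.csv"))
    manifest <- list(
      package = "boneage",
      version = as.character(utils::packageVersion("boneage")),
      config = config,
      n_samples = nrow(metadata),
      n_features = ncol(features),
      elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    )
    jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null",
                         digits = NA)
  }

  log_stage("done", sprintf("%.1fs", as.numeric(difftime(Sys.time(), t0,
                                                         units = "secs"))))
  invisible(out)
}
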