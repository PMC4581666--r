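# Content-based image retrieval over the feature repository, and the
# mean-of-top-k bone age estimator: the predicted bone age of a query is
# the arithmetic mean of the tagged ages of the k most similar stored
# radiographs (after an optional hard filter on gender and ethnicity).

#' Build a feature repository
#'
#' @param features Numeric matrix of feature vectors, one row per sample.
#' @param metadata Data frame with columns `sample_id`, `age_years`,
#'   `gender`, `ethnicity`, aligned with the feature rows.
#' @return An object of class `baa_repository`.
#' @export
build_repository <- function(features, metadata) {
  features <- as.matrix(features)
  missing <- setdiff(METADATA_COLUMNS, names(metadata))
  if (length(missing)) {
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(features) != nrow(metadata)) {
    stop("features and metadata must have the same number of rows")
  }
  if (anyDuplicated(metadata$sample_id)) {
    stop("sample_id values must be unique")
  }
  structure(
    list(features = features, metadata = as.data.frame(metadata)),
    class = "baa_repository"
  )
}

#' Build a repository directly from a synthetic dataset
#'
#' @param dataset A `baa_dataset`.
#' @param basis A `pca_basis` used to extract features.
#' @return A `baa_repository`.
#' @export
repository_from_dataset <- function(dataset, basis) {
  build_repository(
    extract_features_matrix(dataset_image_matrix(dataset), basis),
    dataset_metadata(dataset)
  )
}

#' @export
print.baa_repository <- function(x, ...) {
  cat("Feature repository:", nrow(x$features), "entries,",
      ncol(x$features), "features\n")
  invisible(x)
}

repository_size <- function(repo) nrow(repo$features)

#' Restrict a repository to one gender and ethnicity
#'
#' A hard trait filter applied before similarity ranking; entry order is
#' preserved. An empty result is allowed here and only becomes an error at
#' prediction time.
#'
#' @param repo A `baa_repository`.
#' @param gender `"F"` or `"M"`.
#' @param ethnicity One of `ETHNICITIES`.
#' @return The filtered `baa_repository`.
#' @export
filter_by_traits <- function(repo, gender, ethnicity) {
  stopifnot(inherits(repo, "baa_repository"))
  check_traits(gender, ethnicity)
  keep <- repo$metadata$gender == gender & repo$metadata$ethnicity == ethnicity
  build_repository(repo$features[keep, , drop = FALSE],
                   repo$metadata[keep, , drop = FALSE])
}

#' Similarity between two feature vectors
#'
#' Default is negative Euclidean distance in weighted-PCA space (component
#' weights are already folded into the features), so 0 is a perfect match
#' and scores decrease with dissimilarity. Cosine similarity is available
#' as an alternative metric.
#'
#' @param q,e Equal-length numeric feature vectors.
#' @param metric `"neg_euclidean"` (default) or `"cosine"`.
#' @return A single similarity score (higher = more similar).
#' @export
similarity_score <- function(q, e, metric = c("neg_euclidean", "cosine")) {
  metric <- match.arg(metric)
  q <- as.numeric(q)
  e <- as.numeric(e)
  if (length(q) != length(e)) {
    stop("feature vectors have different lengths (", length(q), " vs ",
         length(e), ")")
  }
  if (metric == "neg_euclidean") {
    -sqrt(sum((q - e)^2))
  } else {
    nq <- sqrt(sum(q^2))
    ne <- sqrt(sum(e^2))
    if (nq == 0 || ne == 0) return(0)
    sum(q * e) / (nq * ne)
  }
}

#' Rank repository entries by similarity to a query
#'
#' Scores every entry, sorts by decreasing similarity and returns the top
#' k. Ties are broken by `sample_id` lexicographic order, so the ranking is
#' invariant to repository input order.
#'
#' @param q Query feature vector.
#' @param repo A `baa_repository` (possibly trait-filtered).
#' @param k Number of entries to retrieve (>= 1).
#' @param metric Similarity metric, see [similarity_score()].
#' @return An object of class `ranked_retrieval`: a data frame with columns
#'   `sample_id`, `similarity`, `tagged_age`, at most k rows, scores
#'   non-increasing.
#' @export
rank_repository <- function(q, repo, k = 5L,
                            metric = c("neg_euclidean", "cosine")) {
  metric <- match.arg(metric)
  stopifnot(inherits(repo, "baa_repository"))
  if (!is.numeric(k) || length(k) != 1L || k < 1) stop("k must be >= 1")
  q <- as.numeric(q)
  n <- repository_size(repo)
  if (n > 0 && length(q) != ncol(repo$features)) {
    stop("query length does not match repository feature dimension")
  }
  if (n == 0L) {
    scores <- numeric(0)
    ord <- integer(0)
  } else if (metric == "neg_euclidean") {
    diff <- sweep(repo$features, 2L, q)
    scores <- -sqrt(rowSums(diff^2))
  } else {
    scores <- apply(repo$features, 1L, similarity_score, q = q,
                    metric = "cosine")
  }
  if (n > 0L) ord <- order(-scores, repo$metadata$sample_id)
  top <- utils::head(ord, as.integer(k))
  structure(
    data.frame(
      sample_id = repo$metadata$sample_id[top],
      similarity = scores[top],
      tagged_age = repo$metadata$age_years[top],
      stringsAsFactors = FALSE
    ),
    class = c("ranked_retrieval", "data.frame"),
    k = as.integer(k)
  )
}

#' Predicted bone age from a ranked retrieval
#'
#' The estimator is the arithmetic mean of the tagged ages of the retrieved
#' images: predicted bone age = (sum of retrieved ages) / (number
#' retrieved). It therefore always lies within the range of the retrieved
#' tagged ages.
#'
#' @param retrieval A `ranked_retrieval`.
#' @return Predicted bone age in years.
#' @export
predict_age <- function(retrieval) {
  stopifnot(inherits(retrieval, "ranked_retrieval"))
  if (nrow(retrieval) == 0L) {
    stop("cannot estimate age: retrieval is empty (no matching neighbours)")
  }
  mean(retrieval$tagged_age)
}

#' Assess bone age for a query radiograph
#'
#' The full estimation path: extract weighted-PCA features, hard-filter the
#' repository on gender and ethnicity (unless `filter = FALSE`), rank by
#' similarity, and return the mean-of-top-k age estimate together with the
#' ranked evidence.
#'
#' @param image Query image (260 x 256 matrix or flattened vector).
#' @param basis A `pca_basis`.
#' @param repo A `baa_repository`.
#' @param gender,ethnicity Query traits.
#' @param k Number of highest-ranked images averaged (default 5).
#' @param metric Similarity metric.
#' @param filter If `FALSE`, skip trait filtering (ablation mode).
#' @return A list with `predicted_age` (years) and `retrieval`
#'   (a `ranked_retrieval`).
#' @export
assess <- function(image, basis, repo, gender, ethnicity, k = 5L,
                   metric = c("neg_euclidean", "cosine"), filter = TRUE) {
  metric <- match.arg(metric)
  if (is.matrix(image)) image <- as.vector(t(image))
  sub <- if (filter) filter_by_traits(repo, gender, ethnicity) else repo
  if (repository_size(sub) == 0L) {
    stop("no repository entries for gender=", gender,
         ", ethnicity=", ethnicity)
  }
  q <- extract_features(image, basis)
  r <- rank_repository(q, sub, k = k, metric = metric)
  list(predicted_age = predict_age(r), retrieval = r)
}

#' Leave-one-out CBIR predictions over a repository
#'
#' For each entry, removes it from the repository, filters the remainder on
#' the entry's own traits (unless `filter = FALSE`), ranks by similarity
#' and predicts the mean of the top-k tagged ages.
#'
#' @param repo A `baa_repository`.
#' @param k Neighbours averaged.
#' @param metric Similarity metric.
#' @param filter Hard trait filter on/off.
#' @return Numeric vector of leave-one-out predicted ages, aligned with the
#'   repository rows.
#' @export
cbir_loo_predictions <- function(repo, k = 5L,
                                 metric = c("neg_euclidean", "cosine"),
                                 filter = TRUE) {
  metric <- match.arg(metric)
  stopifnot(inherits(repo, "baa_repository"))
  n <- repository_size(repo)
  preds <- numeric(n)
  for (i in seq_len(n)) {
    rest <- build_repository(repo$features[-i, , drop = FALSE],
                             repo$metadata[-i, , drop = FALSE])
    sub <- if (filter) {
      filter_by_traits(rest, repo$metadata$gender[i],
                       repo$metadata$ethnicity[i])
    } else {
      rest
    }
    if (repository_size(sub) == 0L) {
      stop("no neighbours left for sample ", repo$metadata$sample_id[i])
    }
    r <- rank_repository(repo$features[i, ], sub, k = k, metric = metric)
    preds[i] <- predict_age(r)
  }
  preds
}

#' Persist / restore a feature repository
#'
#' The repository is stored as a feature CSV (sample_id + feature columns)
#' next to a metadata CSV, both plain text.
#'
#' @param repo A `baa_repository`.
#' @param features_path,metadata_path File paths.
#' @return `save_repository` returns invisibly; `load_repository` returns
#'   the repository.
#' @export
save_repository <- function(repo, features_path, metadata_path) {
  stopifnot(inherits(repo, "baa_repository"))
  df <- data.frame(sample_id = repo$metadata$sample_id, repo$features)
  utils::write.csv(df, features_path, row.names = FALSE, quote = FALSE)
  write_metadata_csv(repo$metadata, metadata_path)
  invisible(list(features = features_path, metadata = metadata_path))
}

#' @rdname save_repository
#' @export
load_repository <- function(features_path, metadata_path) {
  fdf <- utils::read.csv(features_path, stringsAsFactors = FALSE)
  meta <- read_metadata_csv(metadata_path)
  if (!identical(fdf$sample_id, meta$sample_id)) {
    stop("feature and metadata files disagree on sample ids")
  }
  build_repository(as.matrix(fdf[, -1L, drop = FALSE]), meta)
}
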