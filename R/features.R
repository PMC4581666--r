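# Weighted-PCA eigenimage features.
#
# Classical PCA on mean-centered flattened images, with per-component
# weights equal to each retained component's share of the retained
# explained variance. Scores are multiplied by their weight, so
# high-variance components dominate Euclidean similarity in feature space.
# Uniform weighting (classical PCA scores) is available via `weighting`.

as_image_matrix <- function(images) {
  if (is.matrix(images)) return(images)
  if (is.list(images)) {
    d <- unique(lengths(images))
    if (length(d) != 1L) stop("all images must have the same length")
    return(do.call(rbind, lapply(images, as.numeric)))
  }
  stop("images must be a matrix (rows = images) or a list of vectors")
}

#' Fit a weighted-PCA basis to a set of flattened images
#'
#' Mean-centers the data and extracts the top `p` principal directions.
#' When there are more pixels than images (the usual eigenimage situation)
#' the decomposition is done through the n x n Gram matrix; otherwise
#' through the SVD of the centered data matrix. The d x d covariance is
#' never formed. Eigenvalues are the squared singular values divided by
#' n - 1; component weights are each retained eigenvalue's share of the
#' retained total, so they sum to 1.
#'
#' @param images Numeric matrix (one image per row, flattened row-major) or
#'   list of equal-length numeric vectors.
#' @param p Number of components, `1 <= p <= n - 1`. Default: the smallest
#'   p whose cumulative explained variance reaches `var_target` (capped at
#'   the data rank).
#' @param var_target Explained-variance target used when `p` is `NULL`.
#' @param weighting `"variance"` (default) for explained-variance-share
#'   weights, `"uniform"` for classical PCA (all weights `1/p`).
#' @return An object of class `pca_basis`: `mean_image` (length d),
#'   `components` (d x p, orthonormal columns), `eigenvalues` (length p,
#'   non-increasing), `weights` (length p, positive, sum 1), plus
#'   bookkeeping fields.
#' @export
fit_weighted_pca <- function(images, p = NULL, var_target = 0.95,
                             weighting = c("variance", "uniform")) {
  weighting <- match.arg(weighting)
  X <- as_image_matrix(images)
  n <- nrow(X)
  d <- ncol(X)
  if (n < 2L) stop("need at least 2 images to fit a basis")

  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)

  if (d > n) {
    G <- tcrossprod(Xc)
    ee <- eigen(G, symmetric = TRUE)
    sv <- sqrt(pmax(ee$values, 0))
    U <- ee$vectors
    tol <- max(n, d) * .Machine$double.eps * max(sv, 0)
    r <- sum(sv > tol)
    if (r == 0L) stop("degenerate basis: images have zero variance")
    V <- crossprod(Xc, U[, seq_len(r), drop = FALSE])
    V <- sweep(V, 2L, sv[seq_len(r)], "/")
  } else {
    s <- svd(Xc)
    sv <- s$d
    tol <- max(n, d) * .Machine$double.eps * max(sv, 0)
    r <- sum(sv > tol)
    if (r == 0L) stop("degenerate basis: images have zero variance")
    V <- s$v[, seq_len(r), drop = FALSE]
  }

  ev_all <- sv^2 / (n - 1)
  total_var <- sum(ev_all)

  r <- min(r, n - 1L)
  if (is.null(p)) {
    cum <- cumsum(ev_all[seq_len(r)]) / total_var
    p <- which(cum >= var_target)[1L]
    if (is.na(p)) p <- r
  }
  if (p < 1L || p > n - 1L) {
    stop("p must satisfy 1 <= p <= n - 1 (n = ", n, ")")
  }
  if (p > r) {
    stop("p = ", p, " exceeds the data rank (", r, ")")
  }

  components <- V[, seq_len(p), drop = FALSE]
  ortho_err <- max(abs(crossprod(components) - diag(p)))
  if (ortho_err > 1e-8) {
    stop("internal error: components not orthonormal (max deviation ",
         format(ortho_err), ")")
  }

  eigenvalues <- ev_all[seq_len(p)]
  weights <- if (weighting == "variance") {
    eigenvalues / sum(eigenvalues)
  } else {
    rep(1 / p, p)
  }

  structure(
    list(
      mean_image = mu,
      components = components,
      eigenvalues = eigenvalues,
      weights = weights,
      weighting = weighting,
      n_train = n,
      d = d,
      total_variance = total_var,
      explained = sum(eigenvalues) / total_var
    ),
    class = "pca_basis"
  )
}

#' @export
print.pca_basis <- function(x, ...) {
  cat(sprintf(
    "Weighted-PCA basis: %d components over %d pixels (%d training images, %.1f%% variance, %s weights)\n",
    ncol(x$components), x$d, x$n_train, 100 * x$explained, x$weighting))
  invisible(x)
}

#' Project an image onto a weighted-PCA basis
#'
#' The j-th feature is `weights_j * <component_j, image - mean_image>`.
#'
#' @param image Flattened image vector of length d.
#' @param basis A `pca_basis`.
#' @return Numeric feature vector of length p.
#' @export
extract_features <- function(image, basis) {
  stopifnot(inherits(basis, "pca_basis"))
  image <- as.numeric(image)
  if (length(image) != basis$d) {
    stop("image length ", length(image), " does not match basis dimension ",
         basis$d)
  }
  drop(crossprod(basis$components, image - basis$mean_image)) * basis$weights
}

#' Project many images at once
#'
#' @param images Matrix with one flattened image per row.
#' @param basis A `pca_basis`.
#' @return Matrix of feature vectors, one row per image.
#' @export
extract_features_matrix <- function(images, basis) {
  stopifnot(inherits(basis, "pca_basis"))
  X <- as_image_matrix(images)
  if (ncol(X) != basis$d) stop("image dimension does not match basis")
  scores <- sweep(X, 2L, basis$mean_image) %*% basis$components
  sweep(scores, 2L, basis$weights, "*")
}

#' Reconstruct an image from its weighted-PCA features
#'
#' Inverts [extract_features()]: `mean + sum_j (values_j / weights_j) *
#' component_j`. With `p = n - 1` the training images are recovered to
#' numerical tolerance.
#'
#' @param values Feature vector of length p.
#' @param basis A `pca_basis`.
#' @return Flattened image vector of length d.
#' @export
reconstruct <- function(values, basis) {
  stopifnot(inherits(basis, "pca_basis"))
  values <- as.numeric(values)
  p <- ncol(basis$components)
  if (length(values) != p) stop("feature vector length must be ", p)
  if (any(basis$weights <= .Machine$double.eps)) {
    stop("cannot reconstruct: basis has (near-)zero component weights")
  }
  drop(basis$mean_image + basis$components %*% (values / basis$weights))
}

#' Persist / restore a weighted-PCA basis
#'
#' Versioned RDS serialization of the basis arrays and metadata.
#'
#' @param basis A `pca_basis`.
#' @param path File path.
#' @return `save_pca_basis` returns `path` invisibly; `load_pca_basis`
#'   returns the basis.
#' @export
save_pca_basis <- function(basis, path) {
  stopifnot(inherits(basis, "pca_basis"))
  saveRDS(list(format = "boneage_pca_basis", version = 1L, basis = basis),
          path)
  invisible(path)
}

#' @rdname save_pca_basis
#' @export
load_pca_basis <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "boneage_pca_basis")) {
    stop("not a serialized PCA basis: ", path)
  }
  obj$basis
}
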