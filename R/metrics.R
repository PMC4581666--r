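# Evaluation statistics for the model comparison: RMSE, the product-moment
# Pearson correlation, and the coefficient of determination taken as the
# squared sample correlation between observed and predicted values (an
# alternative 1 - SSres/SStot definition is available for sensitivity
# checks). All statistics are reported on held-out test data only:
# training error is not a credible indicator of prediction quality.

#' Root-mean-square error
#'
#' `sqrt(sum((P_i - O_i)^2) / n)`.
#'
#' @param observed,predicted Equal-length numeric vectors (length >= 1).
#' @return RMSE, in the units of the inputs.
#' @export
rmse <- function(observed, predicted) {
  observed <- as.numeric(observed)
  predicted <- as.numeric(predicted)
  if (length(observed) == 0L) stop("rmse needs at least one value")
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have the same length")
  }
  sqrt(mean((predicted - observed)^2))
}

#' Pearson product-moment correlation
#'
#' Computed directly from the product-moment form
#' `(n sum(OP) - sum(O) sum(P)) / sqrt((n sum(O^2) - sum(O)^2)(n sum(P^2) - sum(P)^2))`,
#' clamped to \[-1, 1\] against floating-point overshoot.
#'
#' @param observed,predicted Equal-length numeric vectors, length >= 2,
#'   neither constant.
#' @return Correlation in \[-1, 1\].
#' @export
pearson_r <- function(observed, predicted) {
  O <- as.numeric(observed)
  P <- as.numeric(predicted)
  n <- length(O)
  if (n < 2L || length(P) != n) {
    stop("pearson_r needs two equal-length vectors of length >= 2")
  }
  den_o <- n * sum(O^2) - sum(O)^2
  den_p <- n * sum(P^2) - sum(P)^2
  if (den_o <= 0 || den_p <= 0) {
    stop("correlation undefined: at least one input is constant")
  }
  r <- (n * sum(O * P) - sum(O) * sum(P)) / sqrt(den_o * den_p)
  min(max(r, -1), 1)
}

#' Coefficient of determination
#'
#' Default: the squared sample correlation between observed and predicted
#' values, always in \[0, 1\]. `method = "one_minus_ss"` gives
#' `1 - SSres/SStot` instead (which can be negative for poor models).
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @param method `"squared_correlation"` (default) or `"one_minus_ss"`.
#' @return R-squared.
#' @export
r_squared <- function(observed, predicted,
                      method = c("squared_correlation", "one_minus_ss")) {
  method <- match.arg(method)
  if (method == "squared_correlation") {
    pearson_r(observed, predicted)^2
  } else {
    O <- as.numeric(observed)
    P <- as.numeric(predicted)
    ss_tot <- sum((O - mean(O))^2)
    if (ss_tot == 0) stop("R-squared undefined: observed values are constant")
    1 - sum((O - P)^2) / ss_tot
  }
}

#' Compare models on a common test set
#'
#' One record per model with RMSE, R-squared and Pearson r against the
#' observed test values, plus the per-model scatter data (observed vs
#' predicted) for plotting.
#'
#' @param observed Observed (true) test values.
#' @param predictions Named list of prediction vectors, one per model,
#'   each aligned with `observed`.
#' @return An object of class `eval_report`: a data frame with columns
#'   `model`, `rmse`, `r_squared`, `pearson_r`; attributes `n_test` and
#'   `scatter` (long data frame with columns `model`, `observed`,
#'   `predicted`).
#' @export
compare_models <- function(observed, predictions) {
  stopifnot(is.list(predictions), length(predictions) >= 1L,
            !is.null(names(predictions)))
  observed <- as.numeric(observed)
  rows <- lapply(names(predictions), function(nm) {
    p <- as.numeric(predictions[[nm]])
    if (length(p) != length(observed)) {
      stop("predictions for ", nm, " are not aligned with observed values")
    }
    # Constant predictors (e.g. the mean-age baseline) have a defined RMSE
    # but no defined correlation; report NA for r and R-squared.
    r <- tryCatch(pearson_r(observed, p), error = function(e) NA_real_)
    data.frame(
      model = nm,
      rmse = rmse(observed, p),
      r_squared = if (is.na(r)) NA_real_ else r^2,
      pearson_r = r,
      stringsAsFactors = FALSE
    )
  })
  report <- do.call(rbind, rows)
  scatter <- do.call(rbind, lapply(names(predictions), function(nm) {
    data.frame(model = nm, observed = observed,
               predicted = as.numeric(predictions[[nm]]),
               stringsAsFactors = FALSE)
  }))
  structure(report, class = c("eval_report", "data.frame"),
            n_test = length(observed), scatter = scatter)
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Model comparison on", attr(x, "n_test"), "test samples\n")
  df <- as.data.frame(x)
  df$rmse <- sprintf("%.4f", df$rmse)
  df$r_squared <- sprintf("%.4f", df$r_squared)
  df$pearson_r <- sprintf("%.4f", df$pearson_r)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report (and its scatter data) as CSV
#'
#' @param report An `eval_report`.
#' @param path Report CSV path.
#' @param scatter_path Optional path for the observed/predicted scatter
#'   CSV.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path, scatter_path = NULL) {
  stopifnot(inherits(report, "eval_report"))
  utils::write.csv(as.data.frame(report), path, row.names = FALSE,
                   quote = FALSE)
  if (!is.null(scatter_path)) {
    utils::write.csv(attr(report, "scatter"), scatter_path,
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
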