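make_repo <- function(ids, ages, feats, gender = "F", ethnicity = "Asian") {
  build_repository(
    feats,
    data.frame(sample_id = ids, age_years = ages,
               gender = rep_len(gender, length(ids)),
               ethnicity = rep_len(ethnicity, length(ids)),
               stringsAsFactors = FALSE)
  )
}

test_that("trait filtering returns exactly the matching entries", {
  repo <- one_per_category_repo()
  sub <- filter_by_traits(repo, "F", "Asian")
  expect_identical(nrow(sub$features), 1L)
  expect_identical(sub$metadata$gender, "F")
  expect_identical(sub$metadata$ethnicity, "Asian")

  # subset property over all categories
  for (code in category_codes()) {
    tr <- parse_category(code)
    sub <- filter_by_traits(repo, tr$gender, tr$ethnicity)
    expect_true(all(sub$metadata$gender == tr$gender))
    expect_true(all(sub$metadata$ethnicity == tr$ethnicity))
  }

  empty <- build_repository(matrix(numeric(0), 0, 4),
                            data.frame(sample_id = character(),
                                       age_years = numeric(),
                                       gender = character(),
                                       ethnicity = character()))
  expect_identical(nrow(filter_by_traits(empty, "M", "Hispanic")$features), 0L)
})

test_that("similarity score is negative Euclidean distance", {
  expect_identical(similarity_score(c(1, 2), c(1, 2)), 0)
  expect_identical(similarity_score(c(0, 0), c(3, 4)), -5)
  withr::with_seed(1, for (i in 1:10) {
    q <- rnorm(6); e <- rnorm(6)
    expect_equal(similarity_score(q, e), similarity_score(e, q))
    expect_lte(similarity_score(q, e), 0)
  })
  expect_error(similarity_score(c(1, 2), c(1, 2, 3)), "length")
})

test_that("ranking agrees with a full-sort oracle and breaks ties by id", {
  n <- 50
  feats <- withr::with_seed(5, matrix(rnorm(n * 3), n))
  ids <- sprintf("R%02d", withr::with_seed(5, sample(n)))
  repo <- make_repo(ids, runif(n, 1, 18), feats)
  q <- withr::with_seed(6, rnorm(3))
  for (k in c(1, 5, 50, 80)) {
    r <- rank_repository(q, repo, k = k)
    d <- -sqrt(colSums((t(feats) - q)^2))
    oracle <- order(-d, repo$metadata$sample_id)[seq_len(min(k, n))]
    expect_identical(r$sample_id, repo$metadata$sample_id[oracle])
    expect_true(all(diff(r$similarity) <= 0))
  }

  # exact duplicate of a stored vector ranks first
  r1 <- rank_repository(feats[17, ], repo, k = 3)
  expect_identical(r1$sample_id[1], repo$metadata$sample_id[17])

  # ranking invariant to repository row order
  perm <- withr::with_seed(7, sample(n))
  repo_p <- build_repository(feats[perm, ], repo$metadata[perm, ])
  expect_identical(rank_repository(q, repo, k = 10)$sample_id,
                   rank_repository(q, repo_p, k = 10)$sample_id)

  # equidistant entries sort lexicographically by id
  tie <- make_repo(c("B", "A", "C"), c(4, 5, 6),
                   rbind(c(1, 0), c(0, 1), c(2, 0)))
  rt <- rank_repository(c(0, 0), tie, k = 3)
  expect_identical(rt$sample_id, c("A", "B", "C"))
})

test_that("predicted age is the arithmetic mean of retrieved tagged ages", {
  repo <- make_repo(c("a", "b", "c"), c(8, 9, 10), diag(3))
  r <- rank_repository(c(0, 0, 0), repo, k = 3)
  expect_identical(predict_age(r), 9)

  single <- make_repo("only", 12.5, matrix(1, 1, 1))
  expect_identical(predict_age(rank_repository(0, single, k = 1)), 12.5)

  four <- make_repo(letters[1:4], c(7, 8, 12, 13), diag(4))
  expect_identical(predict_age(rank_repository(rep(0, 4), four, k = 4)), 10)

  empty <- rank_repository(c(0, 0), make_repo(character(), numeric(),
                                              matrix(numeric(0), 0, 2)), k = 5)
  expect_error(predict_age(empty), "empty")

  # convexity: prediction within [min, max] of retrieved ages
  withr::with_seed(8, for (i in 1:10) {
    feats <- matrix(rnorm(30), 10)
    repo <- make_repo(sprintf("s%02d", 1:10), runif(10, 1, 18), feats)
    r <- rank_repository(rnorm(3), repo, k = 4)
    p <- predict_age(r)
    expect_gte(p, min(r$tagged_age))
    expect_lte(p, max(r$tagged_age))
  })
})

test_that("assess runs extract-filter-rank-predict end to end", {
  X <- toy_images(n = 8, d = 24, seed = 12)
  basis <- fit_weighted_pca(X, p = 4)
  feats <- extract_features_matrix(X, basis)
  codes <- category_codes()
  meta <- do.call(rbind, lapply(1:8, function(i) {
    tr <- parse_category(codes[i])
    data.frame(sample_id = sprintf("q%d", i), age_years = i + 2,
               gender = tr$gender, ethnicity = tr$ethnicity,
               stringsAsFactors = FALSE)
  }))
  repo <- build_repository(feats, meta)

  # query identical to a stored image with k = 1 recovers its tagged age
  res <- assess(X[3, ], basis, repo, meta$gender[3], meta$ethnicity[3], k = 1)
  expect_equal(res$predicted_age, meta$age_years[3])
  expect_identical(res$retrieval$sample_id[1], meta$sample_id[3])

  # constant-age repository predicts that age for any query
  meta10 <- meta
  meta10$age_years <- rep(10, 8)
  repo10 <- build_repository(feats, meta10)
  res10 <- assess(withr::with_seed(1, rnorm(24)), basis, repo10,
                  "F", "Asian", k = 1, filter = FALSE)
  expect_identical(res10$predicted_age, 10)

  # empty-after-filter is an error, not a fallback
  male_only <- build_repository(feats[meta$gender == "M", ],
                                meta[meta$gender == "M", ])
  expect_error(assess(X[1, ], basis, male_only, "F", "Asian"),
               "no repository entries")
})

test_that("a repository survives CSV serialization", {
  repo <- one_per_category_repo()
  fp <- withr::local_tempfile(fileext = ".csv")
  mp <- withr::local_tempfile(fileext = ".csv")
  save_repository(repo, fp, mp)
  back <- load_repository(fp, mp)
  expect_equal(unname(back$features), unname(repo$features),
               tolerance = 1e-10)
  expect_equal(back$metadata$age_years, repo$metadata$age_years)
})
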