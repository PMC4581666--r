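# Canvas layout (pixels). Row 1 is the top of the image; the wrist sits at
# the bottom. Fingers are vertical bars rising from FINGER_BASE_ROW toward
# the top; carpal ossification blobs live in CARPAL_ROWS at the bottom.
IMG_HEIGHT <- 260L
IMG_WIDTH <- 256L
FINGER_BASE_ROW <- 190L
FINGER_COLS <- c(35L, 85L, 128L, 170L, 215L)
CARPAL_ROWS <- 205:255
CARPAL_SLOTS <- cbind(
  row = rep(c(218L, 242L), each = 4L),
  col = rep(c(60L, 105L, 150L, 195L), times = 2L)
)
CARPAL_RADIUS <- 7
BACKGROUND <- 20
BONE_INTENSITY <- 180
EPIPHYSIS_INTENSITY <- 200
CARPAL_INTENSITY <- 160
EPIPHYSIS_CAP_HEIGHT <- 6L

#' Valid gender and ethnicity levels
#'
#' The repository is stratified by two genders and four ethnicities; every
#' metadata record carries one level of each.
#' @format Character vectors of levels.
#' @name trait-levels
NULL

#' @rdname trait-levels
#' @export
GENDERS <- c("F", "M")

#' @rdname trait-levels
#' @export
ETHNICITIES <- c("Asian", "Caucasian", "AfricanAmerican", "Hispanic")

# Deterministic multiplicative scale offsets on bone geometry. Males are
# drawn 5% larger; ethnicity applies a small fixed factor so trait filtering
# in retrieval is meaningful rather than cosmetic.
GENDER_SCALE <- c(F = 1.00, M = 1.05)
ETHNICITY_SCALE <- c(
  Asian = 0.97, Caucasian = 1.00, AfricanAmerican = 1.03, Hispanic = 0.99
)

# Expected finger lengths grow linearly from 35% of the adult value at age 1
# to the full adult value at age 18 (pixels, thumb..little finger at 18).
FINGER_BASE_LENGTH <- c(55, 75, 85, 80, 65)
FINGER_GROWTH_MIN_FRAC <- 0.35
FINGER_LENGTH_SD <- 2
FINGER_WIDTH_SD <- 0.5
CARPAL_COUNT_SD <- 0.7
DEFAULT_NOISE_SIGMA <- 8

ETHNICITY_CODES <- c(
  Asian = "A", Caucasian = "C", AfricanAmerican = "AA", Hispanic = "H"
)
AGE_GROUPS <- c("1-6", "7-12", "13-18")

#' Gender x ethnicity category codes
#'
#' The eight repository categories: ethnicity code (`A`, `C`, `AA`, `H`)
#' followed by gender (`F`, `M`).
#' @return Character vector of the 8 codes, in table order.
#' @export
category_codes <- function() {
  as.vector(t(outer(ETHNICITY_CODES, GENDERS, paste0)))
}

#' Decode a category code into gender and ethnicity
#'
#' @param code One of the codes from [category_codes()], e.g. `"AAF"`.
#' @return A list with elements `gender` and `ethnicity`.
#' @export
parse_category <- function(code) {
  if (!is.character(code) || length(code) != 1L || !code %in% category_codes()) {
    stop("unknown category code: ", paste(code, collapse = ", "),
         " (expected one of ", paste(category_codes(), collapse = ", "), ")")
  }
  gender <- substr(code, nchar(code), nchar(code))
  eth_code <- substr(code, 1L, nchar(code) - 1L)
  list(
    gender = gender,
    ethnicity = names(ETHNICITY_CODES)[match(eth_code, ETHNICITY_CODES)]
  )
}

#' Reference category quotas for an evaluation set
#'
#' Per-cell sample counts over three age groups (1-6, 7-12, 13-18 years) and
#' the eight gender x ethnicity categories, matching the stratification used
#' to validate the assessment system.
#'
#' @return An integer matrix with age groups as rows and category codes as
#'   columns.
#' @export
reference_quotas <- function() {
  m <- matrix(
    c(4L, 4L, 4L, 4L, 4L, 3L, 4L, 4L,
      3L, 4L, 3L, 4L, 3L, 4L, 3L, 4L,
      4L, 4L, 4L, 3L, 4L, 4L, 4L, 4L),
    nrow = 3L, byrow = TRUE,
    dimnames = list(AGE_GROUPS, category_codes())
  )
  m
}

#' Build a balanced quota table of roughly n samples
#'
#' Distributes `n` samples as evenly as possible over the 24 age-group x
#' category cells (row-major remainder assignment), for running the pipeline
#' at sizes other than the reference evaluation set.
#'
#' @param n Total number of samples (>= 0).
#' @return An integer quota matrix like [reference_quotas()].
#' @export
balanced_quotas <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 0)
  n <- as.integer(n)
  cells <- 24L
  base <- n %/% cells
  extra <- n %% cells
  counts <- rep(base, cells)
  if (extra > 0L) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
  matrix(counts, nrow = 3L, byrow = TRUE,
         dimnames = list(AGE_GROUPS, category_codes()))
}

age_group_range <- function(group) {
  switch(group,
    "1-6" = c(1, 6),
    "7-12" = c(7, 12),
    "13-18" = c(13, 18),
    stop("unknown age group: ", group)
  )
}

check_traits <- function(gender, ethnicity) {
  if (!is.character(gender) || length(gender) != 1L || !gender %in% GENDERS) {
    stop("gender must be one of ", paste(GENDERS, collapse = ", "))
  }
  if (!is.character(ethnicity) || length(ethnicity) != 1L ||
      !ethnicity %in% ETHNICITIES) {
    stop("ethnicity must be one of ", paste(ETHNICITIES, collapse = ", "))
  }
  invisible(TRUE)
}

#' Latent phantom geometry for a given age, gender and ethnicity
#'
#' Maps chronological age to the latent skeletal geometry drawn on a phantom
#' radiograph. Expected finger lengths and the expected carpal ossification
#' count increase monotonically with age; the expected epiphysis-metaphysis
#' gap shrinks linearly and reaches exactly zero (fused growth plate) from
#' age 16 on. Gender and ethnicity apply the fixed multiplicative scale
#' factors documented in `GENDER_SCALE` / `ETHNICITY_SCALE`. Randomness is
#' drawn from the ambient R random number stream, so wrap calls in
#' [withr::with_seed()] (or `set.seed()`) for reproducibility.
#'
#' @param age_years Age in years, in \[1, 18\].
#' @param gender `"F"` or `"M"`.
#' @param ethnicity One of `ETHNICITIES`.
#' @return An object of class `phantom_geometry`: a list with
#'   `finger_lengths` (5 pixels), `finger_widths` (5 pixels),
#'   `carpal_count` (integer 0..8), `epiphysis_gap` (pixels >= 0) and
#'   `noise_sigma` (grayscale units).
#' @export
age_to_geometry <- function(age_years, gender, ethnicity) {
  if (!is.numeric(age_years) || length(age_years) != 1L ||
      is.na(age_years) || age_years < 1 || age_years > 18) {
    stop("age_years must be a single number in [1, 18]")
  }
  check_traits(gender, ethnicity)
  scale <- unname(GENDER_SCALE[gender] * ETHNICITY_SCALE[ethnicity])

  frac <- FINGER_GROWTH_MIN_FRAC +
    (1 - FINGER_GROWTH_MIN_FRAC) * (age_years - 1) / 17
  lengths <- pmax(FINGER_BASE_LENGTH * frac * scale +
                    stats::rnorm(5L, 0, FINGER_LENGTH_SD), 1)
  widths <- pmax((6 + 0.35 * age_years) * scale +
                   stats::rnorm(5L, 0, FINGER_WIDTH_SD), 1)

  carpal_mu <- 8 * (age_years / 18)^0.8
  carpal <- as.integer(min(8, max(0,
    round(carpal_mu + stats::rnorm(1L, 0, CARPAL_COUNT_SD)))))

  # Multiplicative noise keeps the fused (zero) gap exactly zero at age >= 16.
  gap_ramp <- max(0, 6 * (16 - age_years) / 15)
  gap <- gap_ramp * max(0, 1 + 0.1 * stats::rnorm(1L))

  structure(
    list(
      finger_lengths = lengths,
      finger_widths = widths,
      carpal_count = carpal,
      epiphysis_gap = gap,
      noise_sigma = DEFAULT_NOISE_SIGMA
    ),
    class = "phantom_geometry"
  )
}

draw_disk <- function(img, row, col, radius, intensity) {
  rr <- max(1L, floor(row - radius)):min(nrow(img), ceiling(row + radius))
  cc <- max(1L, floor(col - radius)):min(ncol(img), ceiling(col + radius))
  d2 <- outer((rr - row)^2, (cc - col)^2, `+`)
  patch <- img[rr, cc]
  patch[d2 <= radius^2] <- pmax(patch[d2 <= radius^2], intensity)
  img[rr, cc] <- patch
  img
}

draw_bar <- function(img, rows, cols, intensity) {
  rows <- rows[rows >= 1L & rows <= nrow(img)]
  cols <- cols[cols >= 1L & cols <= ncol(img)]
  if (length(rows) && length(cols)) {
    img[rows, cols] <- pmax(img[rows, cols], intensity)
  }
  img
}

#' Render a phantom hand radiograph from its latent geometry
#'
#' Draws five vertical finger bars (shaft plus an epiphysis cap separated by
#' the growth-plate gap), up to eight carpal blobs in the wrist region, and
#' adds Gaussian pixel noise clipped to \[0, 255\]. Rendering is
#' deterministic given the geometry and the RNG state. Geometry that would
#' extend beyond the canvas is clipped with a warning.
#'
#' @param geometry A `phantom_geometry` object.
#' @param noise If `FALSE`, skip the additive noise regardless of
#'   `geometry$noise_sigma`.
#' @return A 260 x 256 numeric matrix with values in \[0, 255\]; row 1 is
#'   the top of the image, the wrist is at the bottom.
#' @export
render_phantom <- function(geometry, noise = TRUE) {
  stopifnot(inherits(geometry, "phantom_geometry"))
  img <- matrix(BACKGROUND, nrow = IMG_HEIGHT, ncol = IMG_WIDTH)
  gap_px <- as.integer(round(geometry$epiphysis_gap))
  clipped <- FALSE

  for (f in seq_len(5L)) {
    len <- geometry$finger_lengths[f]
    half_w <- max(1L, as.integer(round(geometry$finger_widths[f] / 2)))
    tip <- as.integer(round(FINGER_BASE_ROW - len))
    cap_top <- tip - gap_px - EPIPHYSIS_CAP_HEIGHT
    if (cap_top < 1L) {
      clipped <- TRUE
      cap_top <- max(cap_top, 1L)
    }
    shaft_rows <- max(1L, tip):FINGER_BASE_ROW
    cols <- (FINGER_COLS[f] - half_w):(FINGER_COLS[f] + half_w)
    img <- draw_bar(img, shaft_rows, cols, BONE_INTENSITY)
    cap_rows <- cap_top:max(cap_top, tip - gap_px - 1L)
    img <- draw_bar(img, cap_rows, cols, EPIPHYSIS_INTENSITY)
  }

  for (i in seq_len(geometry$carpal_count)) {
    img <- draw_disk(img, CARPAL_SLOTS[i, "row"], CARPAL_SLOTS[i, "col"],
                     CARPAL_RADIUS, CARPAL_INTENSITY)
  }

  if (clipped) warning("phantom geometry exceeds canvas; shapes were clipped")

  if (noise && geometry$noise_sigma > 0) {
    img <- img + matrix(stats::rnorm(length(img), 0, geometry$noise_sigma),
                        nrow = IMG_HEIGHT)
  }
  pmin(pmax(img, 0), 255)
}

#' Generate a synthetic phantom dataset from a quota table
#'
#' Draws exactly the requested number of samples per (age group, category)
#' cell, with ages sampled uniformly (continuously) within the group range,
#' geometry from [age_to_geometry()] and images from [render_phantom()].
#' Fully reproducible from `seed`: cells are filled row-major in the quota
#' table's order.
#'
#' @param quotas Integer matrix of counts, age groups (`"1-6"`, `"7-12"`,
#'   `"13-18"`) as rows and [category_codes()] as columns. Defaults to the
#'   reference evaluation quotas.
#' @param seed Integer seed.
#' @return An object of class `baa_dataset`: a list of samples, each with
#'   `image`, `metadata` (sample_id, age_years, gender, ethnicity) and
#'   `geometry`.
#' @export
generate_dataset <- function(quotas = reference_quotas(), seed = 1L) {
  quotas <- as.matrix(quotas)
  if (is.null(rownames(quotas)) || is.null(colnames(quotas))) {
    stop("quotas must have age-group rownames and category colnames")
  }
  if (!all(rownames(quotas) %in% AGE_GROUPS)) {
    stop("unknown age group(s): ",
         paste(setdiff(rownames(quotas), AGE_GROUPS), collapse = ", "))
  }
  if (!all(colnames(quotas) %in% category_codes())) {
    stop("unknown category code(s): ",
         paste(setdiff(colnames(quotas), category_codes()), collapse = ", "))
  }
  if (any(is.na(quotas)) || any(quotas < 0) || any(quotas != round(quotas))) {
    stop("quotas must be non-negative integers")
  }

  samples <- withr::with_seed(as.integer(seed), {
    out <- vector("list", sum(quotas))
    idx <- 0L
    for (g in rownames(quotas)) {
      rng <- age_group_range(g)
      for (code in colnames(quotas)) {
        traits <- parse_category(code)
        for (i in seq_len(quotas[g, code])) {
          idx <- idx + 1L
          age <- stats::runif(1L, rng[1], rng[2])
          geom <- age_to_geometry(age, traits$gender, traits$ethnicity)
          img <- render_phantom(geom)
          out[[idx]] <- list(
            image = img,
            metadata = list(
              sample_id = sprintf("S%04d_%s", idx, code),
              age_years = age,
              gender = traits$gender,
              ethnicity = traits$ethnicity
            ),
            geometry = geom
          )
        }
      }
    }
    out
  })
  structure(samples, class = "baa_dataset", quotas = quotas, seed = seed)
}

#' @export
print.baa_dataset <- function(x, ...) {
  cat("Synthetic phantom dataset:", length(x), "samples",
      sprintf("(%dx%d px)\n", IMG_HEIGHT, IMG_WIDTH))
  invisible(x)
}

#' Metadata of a dataset as a data frame
#'
#' @param dataset A `baa_dataset`.
#' @return A data frame with columns `sample_id`, `age_years`, `gender`,
#'   `ethnicity`, one row per sample.
#' @export
dataset_metadata <- function(dataset) {
  stopifnot(inherits(dataset, "baa_dataset") || is.list(dataset))
  do.call(rbind, lapply(dataset, function(s) {
    data.frame(
      sample_id = s$metadata$sample_id,
      age_years = s$metadata$age_years,
      gender = s$metadata$gender,
      ethnicity = s$metadata$ethnicity,
      stringsAsFactors = FALSE
    )
  }))
}

#' Flatten dataset images into a samples x pixels matrix
#'
#' Images are flattened row-major (reading order: left to right, top to
#' bottom), fixing the coordinate convention for feature extraction.
#'
#' @param dataset A `baa_dataset`.
#' @return A numeric matrix, one row per sample, `260 * 256` columns.
#' @export
dataset_image_matrix <- function(dataset) {
  do.call(rbind, lapply(dataset, function(s) as.vector(t(s$image))))
}

METADATA_COLUMNS <- c("sample_id", "age_years", "gender", "ethnicity")

#' Write and read sample metadata as CSV
#'
#' Round-trip safe: `read_metadata_csv(write_metadata_csv(x, p))` recovers
#' all metadata fields. Reading validates column presence, numeric ages in
#' \[1, 18\] and trait levels, and fails naming the offending column.
#'
#' @param dataset A `baa_dataset` or a metadata data frame.
#' @param path File path.
#' @return `write_metadata_csv` returns `path` invisibly;
#'   `read_metadata_csv` returns a metadata data frame.
#' @export
write_metadata_csv <- function(dataset, path) {
  df <- if (is.data.frame(dataset)) dataset else dataset_metadata(dataset)
  if (is.null(df)) {
    df <- data.frame(sample_id = character(), age_years = numeric(),
                     gender = character(), ethnicity = character())
  }
  utils::write.csv(df[, METADATA_COLUMNS, drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_metadata_csv
#' @export
read_metadata_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(METADATA_COLUMNS, names(df))
  if (length(missing)) {
    stop("metadata file is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  age <- suppressWarnings(as.numeric(df$age_years))
  if (nrow(df) > 0 && any(is.na(age))) {
    stop("column age_years contains non-numeric values")
  }
  if (nrow(df) > 0 && (any(age < 1) || any(age > 18))) {
    stop("column age_years contains values outside [1, 18]")
  }
  if (nrow(df) > 0 && !all(df$gender %in% GENDERS)) {
    stop("column gender contains invalid levels")
  }
  if (nrow(df) > 0 && !all(df$ethnicity %in% ETHNICITIES)) {
    stop("column ethnicity contains invalid levels")
  }
  df$age_years <- age
  df[, METADATA_COLUMNS]
}

#' Write a phantom image as an 8-bit grayscale PNG
#'
#' @param image A 260 x 256 matrix in \[0, 255\], or a dataset sample.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phantom_png <- function(image, path) {
  if (is.list(image) && !is.null(image$image)) image <- image$image
  stopifnot(is.matrix(image))
  png::writePNG(image / 255, path)
  invisible(path)
}

#' Read an 8-bit grayscale PNG back into a \[0, 255\] matrix
#'
#' @param path PNG path.
#' @return A numeric matrix in \[0, 255\].
#' @export
read_phantom_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img * 255
}
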