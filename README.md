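# boneage

Fully automated skeletal-maturity (bone age) assessment from hand
radiographs, in R.

Bone age assessment estimates skeletal maturity from a left-hand/wrist
radiograph; discrepancies between bone age and chronological age flag
growth and endocrine disorders. Classical practice (Greulich–Pyle atlas
comparison, Tanner–Whitehouse scoring) is manual and observer-dependent.
This package implements a segmentation-free, fully automated alternative
built on content-based image retrieval (CBIR), plus three regression
engines for benchmarking the assessment:

- **CBIR estimator.** Each 256×260 grayscale radiograph is projected onto
  a weighted-PCA eigenimage basis; the feature of component *j* is
  *w<sub>j</sub> ⟨v<sub>j</sub>, x − x̄⟩* with *w<sub>j</sub>* the
  component's share of explained variance. The repository is hard-filtered
  on the query's gender and ethnicity, ranked by similarity (negative
  Euclidean distance in weighted feature space), and the predicted bone
  age is the arithmetic mean of the tagged ages of the *k* highest-ranked
  images: *predicted age = Σᵢ xᵢ / n*.
- **ELM.** Extreme learning machine regression: a single hidden layer of
  random additive-sigmoid nodes *G(a,b,x) = σ(a·x+b)* (or Gaussian RBF
  nodes *exp(−b‖x−a‖²)*), with output weights solved in one pass as
  *β = H⁺T*, the Moore–Penrose pseudoinverse computed by SVD.
- **ANN.** A three-layer sigmoid perceptron
  *z<sub>j</sub> = f(Σᵢ w<sub>ij</sub>x<sub>i</sub> − θ<sub>j</sub>)*,
  *y<sub>k</sub> = f(Σⱼ w<sub>kj</sub>z<sub>j</sub> − θ<sub>k</sub>)*
  trained by full-batch backpropagation (default 1000 iterations).
- **GP.** Gene-expression-programming symbolic regression: fixed-length
  head/tail chromosomes decoded breadth-first (Karva notation) over the
  function set {+, −, ×, ÷, √, ln, eˣ, aˣ}, population 512, evolved by
  tournament selection, mutation, one-point recombination, inversion and
  elitism.

Models are compared by RMSE, Pearson *r* and the coefficient of
determination *R²* on held-out data.

Real radiograph collections are third-party clinical data, so the package
ships a seeded **synthetic phantom generator**: age-, gender- and
ethnicity-conditioned hand phantoms (finger bones that lengthen and widen
with age, carpal ossification blobs that accumulate, an
epiphysis–metaphysis gap that fuses by age 16) with the category quotas of
the reference evaluation design. The whole pipeline is reproducible
offline from a single seed.

## Worked example

```r
library(boneage)

set.seed(1)
ds    <- generate_dataset(reference_quotas(), seed = 1)  # 90 phantoms
md    <- dataset_metadata(ds)
X     <- dataset_image_matrix(ds)
basis <- fit_weighted_pca(X)
repo  <- build_repository(extract_features_matrix(X, basis), md)

# assess one radiograph against the rest
q <- ds[[50]]
res <- assess(q$image, basis,
              build_repository(extract_features_matrix(X, basis)[-50, ],
                               md[-50, ]),
              gender = q$metadata$gender,
              ethnicity = q$metadata$ethnicity, k = 5)
res$predicted_age
#> [1] 11.64591
q$metadata$age_years
#> [1] 11.27373
```

The estimate is the mean tagged age of the 5 most similar repository
phantoms sharing the query's gender and ethnicity. With only ~11
same-trait entries in the 90-image reference repository, accuracy at the
age extremes is neighbour-limited (young queries borrow older
neighbours); the 300-phantom study in `scripts/acceptance.R` shows the
estimator at denser coverage (leave-one-out r ≈ 0.99, RMSE ≈ 0.7 years).

The full benchmark (CBIR + the three regression engines on a stratified
70/30 split):

```r
res <- run_pipeline()   # default: reference quotas, seed 1
res$report
#> Model comparison on 24 test samples
#>          model   rmse r_squared pearson_r
#>           CBIR 2.3137    0.8453    0.9194
#>            ELM 0.9242    0.9677    0.9837
#>            ANN 1.2568    0.9782    0.9891
#>             GP 2.0732    0.8483    0.9210
#>  baseline_mean 5.1337        NA        NA
```

RMSE is in years; the constant-mean baseline shows the spread a model must
beat. On these synthetic phantoms the ELM attains the lowest error of the
three regression engines, with single-pass (non-iterative) training.

A shell interface with `generate`, `fit-features`, `build-repo`,
`predict` and `run-all` subcommands lives at `inst/cli/boneage.R`:

```sh
Rscript inst/cli/boneage.R generate --out phantoms --n 90 --seed 1
Rscript inst/cli/boneage.R predict --image phantoms/S0001_AF.png \
    --basis basis.rds --features feat.csv --repo-metadata meta.csv \
    --gender F --ethnicity A --k 5
```

## Testing

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "boneage", load_package = "installed")'
```

The suite covers closed-form oracles (pseudoinverse vs normal equations,
backprop gradients vs central finite differences, Karva decoding vs an
independent recursive decoder, PCA eigenvalues vs brute-force covariance
eigendecomposition), the estimator's exact-mean contract, and end-to-end
age recovery on the synthetic study.

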