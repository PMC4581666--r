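---
title: "Methods: automated bone age assessment by retrieval and learning machines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated bone age assessment by retrieval and learning machines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boneage)
```

## The problem

Bone age assessment (BAA) estimates skeletal maturity from a hand/wrist
radiograph. The gap between bone age and chronological age is a clinical
signal for growth, chromosomal and endocrine disorders. Manual systems —
atlas comparison (Greulich–Pyle) and bone-by-bone scoring
(Tanner–Whitehouse) — are slow and observer-dependent, which motivates a
fully automated estimator. Segmentation-based automation has historically
been the weak point; the approach implemented here avoids segmentation
entirely by querying *whole images* against a reference repository
(content-based image retrieval, CBIR) and augments the image content with
two categorical traits, gender and ethnicity, that shift skeletal
maturation timing.

This vignette documents the models, every tunable parameter with its
default and rationale, the synthetic data the package is validated on,
and the numerical choices and limitations a maintainer should know.

## The CBIR estimator

**Features.** Each radiograph (256×260 pixels, 8-bit grayscale, flattened
row-major) is projected onto a *weighted PCA* basis fitted to the
repository images. Weighted PCA is named but rarely specified in the
recognition literature; the definition adopted here is explicit:
component scores are multiplied by per-component weights
$w_j = \lambda_j / \sum_{l \le p} \lambda_l$, each retained component's
share of the retained explained variance. Feature $j$ of image $x$ is

$$ f_j(x) = w_j \, \langle v_j,\; x - \bar{x} \rangle , $$

so high-variance (structural) components dominate Euclidean similarity
and low-variance (noise) components are suppressed *by construction*.
Setting `weighting = "uniform"` recovers classical PCA scores, making the
weighting an ablatable choice rather than a baked-in one.

The decomposition never forms the $d \times d$ pixel covariance: with
more pixels than images the $n \times n$ Gram matrix is eigendecomposed
(the standard eigenimage device), otherwise the data matrix is SVD'd.
Ties between equal singular values keep the factorization's order; this
is documented as arbitrary. Eigenvalues are squared singular values over
$n - 1$. Orthonormality of the returned components is asserted at fit
time to $10^{-8}$. Constant (zero-variance) image sets raise an error
rather than returning a degenerate basis.

**Parameters.**

| parameter | default | meaning |
|---|---|---|
| `p` | smallest $p$ with $\ge$ 95% cumulative explained variance | basis size; capped at data rank and $n-1$ |
| `var_target` | 0.95 | the threshold behind the default `p` |
| `weighting` | `"variance"` | score weighting; `"uniform"` = classical PCA |

**Retrieval and estimation.** A query is (1) projected to features, (2)
matched against repository entries sharing its gender and ethnicity (a
*hard* pre-ranking filter; `filter = FALSE` gives the ablation without
it), (3) ranked by similarity, and (4) assigned the arithmetic mean of
the tagged ages of the $k$ highest-ranked images:

$$ \widehat{\text{age}} = \frac{1}{n}\sum_{i=1}^{n} x_i , $$

with $x_i$ the tagged ages of the retrieved images. The estimate is a
convex combination, so it always lies inside the retrieved age range.
Similarity defaults to negative Euclidean distance in weighted feature
space (weights already folded into the features); cosine similarity is a
config option. How many "highest ranked" images the mean runs over is not
fixed by the estimator's definition, so $k$ is exposed everywhere and
defaults to 5 — small enough to stay local in age, large enough to
average tag noise. Ties in similarity break lexicographically by sample
id, making rankings invariant to repository row order. An
empty-after-filter repository is an error, never a silent fallback to the
unfiltered repository.

## The three regression engines

All three engines regress age (years) on the leading weighted-PCA
features. The reference architecture fixes three input neurons; the
pipeline accordingly feeds the engines the top `features.model_p = 3`
components (configurable). This matters: at the 95%-variance default the
basis keeps a long tail of noise-dominated components, and standardizing
those to unit variance before a small network drowns the age signal —
retrieval is immune because variance weighting shrinks the tail, but the
engines are not. The choice is therefore an architectural default, not a
tuning knob.

### Extreme learning machine

A single-hidden-layer feedforward network
$f_L(x) = \sum_{i=1}^{L} \beta_i \, G(a_i, b_i, x)$ whose hidden
parameters $(a_i, b_i)$ are random and *never trained*. Two node types:

- additive: $G(a,b,x) = \sigma(a \cdot x + b)$, sigmoid $\sigma$;
- RBF: $G(a,b,x) = \exp(-b\,\lVert x-a\rVert^2)$, $b > 0$. The literal
  reading "Gaussian of $b\,\lVert x-a\rVert$" is available as
  `variant = "scaled_distance"`; the quadratic form is the standard ELM
  convention and the default.

Training is one linear solve: stack the hidden outputs into
$H_{N \times L}$ ($H_{ji} = G(a_i,b_i,x_j)$) and set
$\beta = H^{+} T$, the Moore–Penrose pseudoinverse solution — the
minimum-norm least-squares minimiser of $\lVert H\beta - T\rVert$. $H^+$
is computed by SVD with singular values below
$\max(N,L)\,\varepsilon\,\sigma_{\max}$ treated as zero. With $L = N$
distinct samples $H$ is almost surely invertible and the fit
interpolates (training RMSE at machine precision); with $L < N$ the
training error decreases monotonically as nodes are added to a nested
layer — both properties are asserted in the test suite rather than
assumed.

Random-parameter distributions are a free choice in ELM theory (any
continuous distribution works); the package uses $U(-1,1)$ for additive
weights and biases, centres uniform over the training bounding box and
impact factors $U(0.1, 2]$ for RBF nodes, all from explicit seeds.
Inputs are standardized (train-fitted, per feature) by default;
`standardize = FALSE` disables. Hidden sizes default to the reference
grid $\{3, 6, 10\}$ with selection by validation RMSE on an internal
25% split.

### Backpropagation perceptron

The iterative baseline: a 3-layer sigmoid network

$$ z_j = f\Big(\sum_i w_{ij} x_i - \theta_j\Big), \qquad
   y_k = f\Big(\sum_j w_{kj} z_j - \theta_k\Big), $$

trained by *full-batch* gradient descent on mean squared error — the
era-typical setup for this baseline; no momentum, minibatching or
adaptive rates. Defaults: 1000 iterations (the reference setting),
learning rate 0.1 (unspecified in the reference; 0.1 is a conventional
sigmoid-network default, overridable), weights initialised $U(-0.5,0.5)$
from an explicit seed, hidden grid $\{3,6,10\}$ by validation. Because
outputs are sigmoidal, targets are affinely scaled to $[0.1, 0.9]$ —
off the saturated tails — and predictions are inverse-scaled back to
years; unscaled targets are rejected with the fix named in the error.
The analytic gradients are verified against central finite differences
to relative error $10^{-5}$ in the test suite; that gradient check is
the module's core correctness oracle.

### Gene-expression-programming symbolic regression

The reference configuration's vocabulary (head size, genes, chromosomes)
is that of *gene expression programming*: fixed-length chromosomes whose
genes each have a head of length $h$ (functions or terminals) and a tail
of length $t = h(\text{max arity} - 1) + 1 = h + 1$ (terminals only),
decoded breadth-first — Karva notation — into an expression tree; surplus
tail symbols are ignored, and a terminal-first gene is a single leaf.
Head/tail validity is checked for every individual in every generation.

Defaults and their reading of the reference table:

| parameter | default | note |
|---|---|---|
| population | 512 | as given |
| head length | 7 | middle of the given 5–9 range |
| genes | 2 | within the given 2–3; with $h=7$, $2 \times 15 = 30$ symbols, consistent with the given 20–30 chromosome length |
| mutation / crossover / inversion | 0.09146 / 0.03056 / 0.10853 | the table's 91.46 / 30.56 / 108.53 exceed 1 and are read as per-thousand event rates; the normalization is explicit in `gep_config()` and overridable |
| linking | addition | all gene outputs summed; max arity 2 |
| constants | one per gene, $U(-10,10)$, mutable | binds the `?` terminal and the base of $a^x$ |

Function set $\{+,-,\times,\div,\sqrt{\ },\ln,e^x,a^x\}$ with protected
semantics so every chromosome is a total function: division by
$|d| < 10^{-12}$ yields 1; $\sqrt{\ }$ and $\ln$ act on absolute values
($\ln 0 = 0$); exponentials clamp at $10^{12}$; every node output is
clamped to $\pm 10^{12}$.

Evolution: tournament selection (size 3), per-symbol head-safe point
mutation (tail positions mutate only to terminals), one-point
recombination over the aligned symbol string (validity-preserving by
construction), head-segment inversion, and elitism (≥ 1), which makes
best-so-far fitness non-decreasing. Fitness is $1000/(1+\text{RMSE})$:
bounded, monotone in RMSE, 1000 iff perfect. The fitness function and
selection scheme are not dictated by the reference and are documented
defaults, not reconstructions. A constant target short-circuits to an
exact constant-expression solution with a warning.

One emergent property worth knowing: with addition linking, a target
like $x_1 + x_2$ is expressible by two single-leaf genes, and a random
population of 512 almost surely contains it at generation 0 — evolution's
job is then retention, not search. Multiplicative targets (e.g.
$x_1 x_2 + x_1$) start imperfect and show the usual fitness climb; the
test suite exercises both regimes.

## Evaluation statistics

RMSE $\sqrt{\sum_i (P_i - O_i)^2 / n}$; Pearson $r$ computed directly
from the product-moment formula and clamped to $[-1,1]$ against
floating-point overshoot. $R^2$ is taken as the *squared sample
correlation* between observed and predicted values: the printed
determination formula in the source material garbles the standard
quantity (its denominator is not squared), and squared correlation is
the standard statistic it visibly intends; the alternative
$1 - SS_{res}/SS_{tot}$ (which penalises bias and can go negative) is
available via `method = "one_minus_ss"` for sensitivity checks. With the
default definition $R^2 = r^2$ holds to $10^{-10}$ and $R^2 \in [0,1]$
always. Constant predictors (the mean-age baseline) have a defined RMSE
but undefined correlation; `compare_models()` reports `NA` there instead
of erroring, while the scalar `pearson_r()` treats constancy as an error.

All model comparison happens on held-out data — training error is not a
credible indicator of prediction quality. The default protocol is a
stratified 70/30 split by age group × gender × ethnicity (the reference
names test data but no protocol; stratification keeps every cell
represented on both sides); the CBIR path is evaluated leave-one-out,
its natural protocol since it has no training phase.

## The synthetic phantom generator

The reference system was validated on a clinical radiograph collection
(1100 hand X-rays, 2 genders × 4 ethnicities) that is third-party data.
The package therefore generates *phantoms* whose statistical structure
carries what the pipeline actually exploits — a latent geometry monotone
in age, modulated by gender and ethnicity — without claiming anatomical
realism.

Each phantom is a 260×256 canvas (row 1 at top, wrist at bottom):

- **five finger bars**, expected length growing linearly from 35% of the
  adult value at age 1 to the full value at age 18 (adult lengths
  55–85 px per finger), width $6 + 0.35 \cdot \text{age}$ px; Gaussian
  jitter (SD 2 px length, 0.5 px width);
- **an epiphysis cap** above each finger, separated from the shaft by a
  growth-plate gap that shrinks linearly and is exactly 0 (fused) from
  age 16 — noise on the gap is multiplicative so fusion stays exact;
- **carpal ossification blobs** (0–8) in the wrist region, expected
  count $8(\text{age}/18)^{0.8}$, so young hands show few carpals;
- **trait scaling**: fixed multiplicative factors on lengths/widths —
  male 1.05; Asian 0.97, Caucasian 1.00, African-American 1.03, Hispanic
  0.99 — deterministic so trait filtering is meaningful;
- **pixel noise**: Gaussian, SD 8 gray levels, clipped to [0, 255].

Ages are continuous, sampled uniformly within age-group ranges, so
regression targets are non-degenerate. The reference quota table (three
age groups × eight gender-ethnicity categories, 90 samples in total)
drives `generate_dataset()` cell-exactly; `balanced_quotas(n)` scales the
same design to other sizes. Everything is reproducible bit-for-bit from
one seed.

What the phantoms do *not* emulate: real radiographic texture, hand pose
variation, exposure differences, anatomical shape variation beyond the
five-bar skeleton, and inter-subject variance not tied to age or traits.
Passing tests therefore demonstrate that the pipeline's machinery —
features, retrieval, estimators, statistics — is correct and that it
recovers a monotone latent age signal of realistic strength (the
generated age/geometry correlation exceeds 0.98); they do not certify
clinical accuracy on real radiographs, and the reference collection's
headline accuracy values are deliberately not reproduction targets.

## Problem sizes and numerical choices

The shipped studies use 90 phantoms (the reference quota design) for the
pipeline benchmark and 300 phantoms for the leave-one-out retrieval
study — large enough for stable statistics at interactive runtimes.
Key numerical choices, collected:

- pseudoinverse cutoff $\max(N,L)\,\varepsilon\,\sigma_{\max}$;
- PCA rank tolerance of the same form; degenerate bases error out;
- sigmoid via `stats::plogis` (overflow-safe at extreme arguments);
- reconstruction guards against (near-)zero component weights;
- GEP protection constants $10^{-12}$ (near-zero tests) and $10^{12}$
  (magnitude clamp);
- every stochastic stage of `run_pipeline()` draws its seed from the run
  seed through a stage-name hash, so stages re-run independently yet the
  whole run reproduces exactly.

## Known limitations

- Phantom realism as above; no DICOM ingestion, no real-collection
  loader.
- The CBIR estimator's accuracy is bounded by same-trait repository
  density: with ~11 same-trait entries, mean-of-5 smooths over ~half the
  age range at the extremes.
- The MLP uses plain gradient descent; very small hidden layers on hard
  targets can plateau within the default 1000 iterations.
- GEP expressions are not simplified; exported infix strings can carry
  neutral subterms (e.g. multiplication by a self-cancelling power).
- No approximate nearest-neighbour index: retrieval is exact and linear
  in repository size, appropriate at repository sizes in the hundreds.
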