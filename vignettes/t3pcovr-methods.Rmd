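---
title: "Tucker3 principal covariates regression: model, estimation and displays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tucker3 principal covariates regression: model, estimation and displays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

Behavioral studies often collect two blocks of measurements on the same
individuals: a three-way array **Y** (`I` objects × `J` attributes × `K`
sources — for instance persons × emotional responses × situations) and a
two-way matrix **X** (`I` objects × `L` covariates, e.g. dispositional
traits), with the matrix playing the explanatory role. Analyzing the
blocks separately loses exactly what the design was built to measure:
how the covariates relate to the patterns in the array. `t3pcovr`
estimates both structures at once.

## The model

The predictors are reduced to `R1` components that are linear
combinations of the observed covariates,

$$A = X W_X, \qquad X = A P_X^{\top} + E_X,$$

and the mode-A matricization of the criterion array (an `I × JK` matrix
whose columns enumerate (attribute, source) cells, attribute index
running fastest) is regressed on those same components,

$$Y_A = A P_Y^{\top} + E_A,$$

with the `JK × R1` regression-weight matrix constrained to a Tucker3
structure,

$$P_Y^{\top} = G_A (C \otimes B)^{\top},$$

where `B` (`J × R2`) and `C` (`K × R3`) are orthonormal component
matrices for the attribute and source modes and `G` is the
`R1 × R2 × R3` core array whose entries weight the three-way
interactions among components. The free weight `alpha` in `[0, 1]`
balances the two goals in the loss

$$L = \alpha\,\frac{\lVert X - A P_X^{\top}\rVert^2}{\lVert X\rVert^2}
  + (1-\alpha)\,\frac{\lVert Y_A - A G_A (C\otimes B)^{\top}\rVert^2}
  {\lVert Y_A\rVert^2}.$$

At `alpha = 1` the criterion block is ignored and the components are
the principal components of `X` (principal component regression); at
`alpha = 0` and full attribute/source rank (`R2 = J`, `R3 = K`) the
model is reduced rank regression of `Y_A` on `X`. Both limits are
verified numerically in the test suite. All losses the package reports
are on this normalized scale; internally the updates use the
algebraically equivalent concatenated form
$\lVert Q - A S^{\top}\rVert^2$ with
$Q = [\sqrt{\beta}X \mid \sqrt{1-\beta}\,Y_A]$ and
$\beta = \alpha\lVert Y_A\rVert^2 / (\alpha\lVert Y_A\rVert^2 +
(1-\alpha)\lVert X\rVert^2)$, which differs from the normalized loss
only by the parameter-free constant
$(\alpha\lVert Y_A\rVert^2 + (1-\alpha)\lVert X\rVert^2) /
(\lVert X\rVert^2 \lVert Y_A\rVert^2)$, so both order candidate
solutions identically.

The norms entering the loss and `beta` are computed on the matrices
actually passed to the fitting function — normally the preprocessed
blocks.

## Preprocessing

`preprocess()` standardizes each covariate (mean 0, s.d. 1, denominator
`n − 1`) and, for the array, centers every (attribute, source) cell
across objects and scales each *attribute* to pooled variance 1 across
all objects and sources. One scale per attribute — rather than per
(attribute, source) cell — keeps the relative magnitude of an attribute
across sources intact, which matches the usual treatment of
situation–response data where each response scale is normalized as a
whole; the full autoscaling variant is available as
`y_scale = "attribute-source"`. The choice of the `n − 1` denominator
is a convention; any global rescaling of a block is absorbed by the
loss normalization and does not change the fitted components. The
transforms are stored on the returned object, so new observations can
be mapped onto the fitted display (`interpolate_obs()`) and the raw
data recovered (`invert_preprocess()`).

A constant covariate or an attribute with no post-centering variation
has no well-defined scale and is reported as an error naming the
offending column, rather than being silently dropped.

## Estimation

`t3pcovr()` minimizes the loss by alternating least squares. Each cycle
performs four conditional updates:

1. **Weight step.** With everything else fixed, the weight matrix
   minimizing $\lVert Q - X W S^{\top}\rVert^2$ has the closed form
   $W = (X^{\top}X)^{+} X^{\top} Q\, S (S^{\top}S)^{+}$; the scores are
   then `A = X W`. Parameterizing the object scores through `W` (rather
   than re-estimating `A` freely) keeps `A` in the column space of `X`
   at every iteration, which is what makes interpolation of new
   observations exact and the regression-weight identity
   `X W_X P_Y' = fitted(Y_A)` hold to machine precision.
2. **Attribute step.** `B` is the orthonormal Procrustes minimizer of
   the mode-B matricized residual: the SVD of
   $Y_B (C \otimes A) G_B^{\top}$ gives $B = UV^{\top}$.
3. **Source step.** Same update for `C` on the mode-C matricization.
4. **Regression step.** The core and predictor loadings are the
   conditional least-squares solutions
   $P_X^{\top} = (A^{\top}A)^{-}A^{\top}X$ and
   $G_A = (A^{\top}A)^{-}A^{\top}Y_A(C \otimes B)$.

Because every step is a conditional minimizer, the loss is
non-increasing across cycles — a property asserted for every fitted
model in the package (the recorded `loss_history` must be monotone) and
exercised over hundreds of random problems in the tests. Orthonormality
of `B` and `C` costs no generality: any invertible transformation can
be absorbed into the core.

When `R1` exceeds the rank of `X` (allowed, since the admissibility
bound is `R1 ≤ min(I, L + J·K)`), `A = XW` is necessarily rank
deficient and the regression step switches to the Moore–Penrose
pseudoinverse, with a single warning per fit.

**Initialization and multi-start.** ALS converges monotonically but
only to a stationary point, so the fitter uses a multi-start scheme:
start 1 is the deterministic *rational* initialization (leading
singular vectors of the mode-B and mode-C matricizations for `B0` and
`C0`; leading left singular vectors of the concatenated block
`[X | Y_A]` for `A0`, so both blocks inform the shared mode; all signs
fixed by the largest-absolute-entry rule); the remaining starts perturb
the rational solution with Gaussian noise of s.d. `perturb_scale`
(default 0.1) or, optionally, draw fully random matrices. The default
`n_starts = 20` (1 rational + 19 perturbed) is a conventional
compromise for arrays of this size; the examples and tests use fewer
starts where the loss surface is benign. The lowest-loss start wins.
One master `seed` spawns independent per-start streams, making the
whole procedure reproducible.

**Convergence.** A start stops when the relative loss decrease falls
below `tol` (default `1e-8`) or after `max_iter` cycles (default 500).
For high-accuracy work there is a second, optional rule (`delta_tol`):
near a flat optimum the loss decrease can underflow in double
precision while the parameters are still contracting, so convergence
can additionally require the fitted criterion values to move less than
`delta_tol` per cycle. The reduced-rank-regression equivalence checks
in the test suite use `delta_tol = 1e-11` for exactly this reason;
ordinary analyses do not need it and it is off by default.

**Identifiability.** The solution is determined only up to rotation
(see below) and, after rotation is fixed, up to permutation and
reflection of components. For reproducible output the fitter applies a
sign convention: in each column of `A`, `B` and `C` the entry largest
in absolute value is made positive, with the core (and for `A` also
`P_X`, `W_X`) counter-adjusted so fitted values are untouched.

## Choosing the complexity

`select_ranks()` fits every admissible complexity `(R1, R2, R3)` up to
a user ceiling — triples violating `R1 ≤ R2·R3`, `R2 ≤ R1·R3`,
`R3 ≤ R1·R2` or the mode dimensions are excluded — and applies the
CHULL heuristic: per total complexity `c = R1 + R2 + R3` keep the
best model, retain the lower-left convex hull of the (complexity,
loss) cloud, and score each interior hull model by the st-ratio, the
loss decrease per unit complexity gained before the model divided by
the decrease after it. The model with the largest st-ratio sits at the
scree elbow and is selected; hull endpoints are ineligible. Ties in
the st-ratio go to the lower complexity and ties in loss at equal
complexity are broken lexicographically on `(R1, R2, R3)` — arbitrary
but deterministic. Models exactly on a hull segment are kept (the drop
test uses a relative `1e-12` collinearity tolerance), so a perfectly
linear scree yields st = 1 everywhere and the simplest model. With
fewer than three hull points no st-ratio exists; the function then
returns the lowest-loss model with a warning. The weight `alpha` is a
substantive user choice, not something the package selects.

## Rotation

The decomposition has rotational freedom: `B`, `C`, or the predictor
side (`P_X` together with `A` and `W_X`) can be rotated orthogonally
provided the core is counterrotated on the corresponding mode.
`rotate_fit()` applies varimax (with Kaiser normalization, via
`stats::varimax`) or user-supplied orthogonal matrices and performs the
exact counterrotation; fitted values and loss are invariant to machine
precision, which the tests assert for varimax and for random orthogonal
matrices. Rotating the predictor side drags `A` and `W_X` along with
`P_X` so that both factorizations stay consistent through the shared
object mode. Core-simplicity rotations (making the core sparse at the
expense of the component matrices) are deliberately not implemented;
only component-side varimax is offered.

## Biplot constructions

All displays are computed as coordinate sets (`row_markers`,
`col_markers`, optionally predictor markers); plotting is a thin layer
on top, and the full-dimensional coordinates are always retained so
the defining identities can be checked exactly. When more than two
columns exist, 2-D displays take the first two (for joint biplots, the
two largest singular values of the core slice); this is a convention —
nothing in the model privileges a particular pair.

* **Joint biplot** (`joint_biplot`): for one component `r` of a
  reference mode, the core slice is decomposed `G_r = U D V'` and the
  two display modes get markers `(n1/n2)^(1/4) A U D^(1/2)` and
  `(n2/n1)^(1/4) B V D^(1/2)`; the fourth-root factors compensate the
  different numbers of levels. The marker product reproduces
  `A G_r B'` exactly since the factors cancel.
* **Interactive biplot** (`interactive_biplot`): objects against all
  `J × K` (attribute, source) cells, column markers the rows of
  `P_Y`; inner products reproduce the fitted criterion. Cell labels
  follow the compact `SkRPj` scheme (source `k`, response `j`). For
  large `J × K` the display can be filtered to one attribute or one
  source.
* **Triplot** (`triplot`): the interactive biplot plus predictor
  markers from `P_X`, giving objects, predictors and responses in one
  display; `A P_X'` reproduces the fitted predictor block.
* **Regression-weight biplot** (`regression_weight_biplot`): rows of
  `W_X` against rows of `P_Y`; inner products are the regression
  weights `Z = W_X P_Y'` of each original covariate on each response
  cell, and `X Z` reproduces the fitted criterion.
* **Interpolation** (`interpolate_obs`): a new predictor profile is
  placed at `a = x' W_X` after applying the stored preprocessing; for
  a training row this returns its row of `A` exactly because
  `A = X W_X` by construction. Graded axis scales
  (`axis_scale_markers`) mark values along a direction at
  `mu * (w1, w2)` and label them in the variable's original units
  (`mean + sd * mu`), so `mu = 0` sits at the origin and predicts the
  variable's mean.

## The synthetic-data generator

`simulate_t3pcovr()` draws orthonormal `A`, `B`, `C`, a standard-normal
core and loadings, builds the noiseless blocks `X = A P_X'` and
`Y_A = A G_A (C ⊗ B)'`, and adds i.i.d. Gaussian noise scaled so the
Frobenius signal-to-noise ratio of each block matches the request —
the noise model implied by the least-squares loss. The true weight
matrix satisfies `A = X W_X` exactly in the noiseless limit, so a fit
at the true complexity then reaches a numerically zero loss. Default
dimensions are 8 × 7 × 6 with 10 covariates and complexity (2, 2, 2) —
the shape of a small persons × responses × situations study explained
by dispositions — and SNR 10 per block, a regime where the generating
subspaces are clearly recoverable but the data are visibly noisy.

What the generator does *not* emulate: ordinal 5-/7-point response
scales (everything is Gaussian), heteroscedastic or correlated noise,
block-specific structure not shared through the object mode, and
missing cells. Passing recovery tests on these data therefore shows
that the estimator finds low-rank coupled structure under clean noise;
it does not certify behavior under discretization or structured error.

Recovery is scored by `subspace_congruence` — the mean cosine of the
principal angles between the generating and estimated component
subspaces — on fits of the *raw* simulated blocks: preprocessing
rescales the attributes and thereby the attribute-mode subspace, so
congruence against the generating matrices is only meaningful on the
raw scale.

## Numerical choices and problem sizes

Pseudoinverses use `MASS::ginv` throughout; eigenvector/singular-vector
signs are fixed by the largest-absolute-entry rule; rank-deficient
rational initializations are padded with a deterministic orthonormal
complement (with a warning). The test suite and the acceptance script
run on small problems — arrays up to 12 × 6 × 6, 100-replicate
property sweeps, 20-seed recovery panels, and a 10-instance comparison
against a BFGS multi-start on 12-parameter rank-(1,1,1) problems —
sizes at which the brute-force oracles (elementwise trilinear sums,
full SVDs, generic optimizers) are exact and fast.

## Known limitations

Missing cells, categorical predictors, arrays of order higher than
three, oblique rotations, core-simplicity rotation, cross-validated
selection of `alpha` or of the complexity are all out of scope. ALS
converges to a stationary point only; the multi-start scheme mitigates
but cannot eliminate local optima. The CHULL heuristic needs at least
three hull points to rank models, and inherits the usual scree-test
ambiguity when the loss declines almost linearly in complexity.
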