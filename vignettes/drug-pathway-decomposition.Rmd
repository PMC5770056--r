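---
title: "Joint pathway decomposition of expression and drug-response data"
author: "ipad21"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint pathway decomposition of expression and drug-response data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipad21)
```

## The model

Drugs rarely act through a single gene: their effect is better described at
the level of biological pathways.  Given a gene-expression matrix
$Y^{(1)}\ (N \times G_1)$ and a drug-response matrix $Y^{(2)}\ (N \times
G_2)$ measured on the same $N$ samples (typically cell lines), the package
fits the joint factor model

$$Y^{(1)} = XB^{(1)} + E^{(1)}, \qquad Y^{(2)} = XB^{(2)} + E^{(2)},$$

where the columns of $X\ (N \times K)$ are per-sample activity scores of
$K$ known pathways, $B^{(1)}\ (K \times G_1)$ are gene loadings and
$B^{(2)}\ (K \times G_2)$ are drug loadings.  The estimate minimizes

$$\|Y^{(1)} - XB^{(1)}\|_F^2 + \|Y^{(2)} - XB^{(2)}\|_F^2 +
  \lambda \|B^{(2)}\|_{2,1}$$

subject to two identifiability constraints: every column of $X$ lies in the
unit ball ($\sum_i X_{ik}^2 \le 1$), and $B^{(1)}$ is zero wherever the
binary pathway-membership matrix $L^{(1)}$ is zero, so each pathway's gene
loadings live only on its member genes.  The penalty is the L2,1 norm —
the sum over rows of each row's Euclidean norm — whose minimization zeroes
*entire rows* of $B^{(2)}$.  A zero row means "this pathway drives no
drug"; surviving nonzero entries are the reported drug–pathway
associations.  Row sparsity is the point of the method: an entrywise
(lasso) penalty scatters isolated nonzeros across the matrix, while the
row-grouped penalty removes irrelevant pathways coherently.

An optional binary drug–pathway prior $L^{(2)}$ marks pairs that should
not be penalized toward zero; its entries carry a squared-L2 (ridge)
penalty instead, solved in closed form.  In the experiments the package
targets, $L^{(2)}$ is the all-zero matrix, and then the penalty is exactly
$\lambda\|B^{(2)}\|_{2,1}$.  (The ridge form is used for the prior part
because only the squared norm admits the closed-form update; the
unsquared variant has no such solution.)

## The optimizer

`ipad()` alternates four steps until the relative change of the penalized
objective falls below `rel_tol` (default $10^{-6}$, `max_outer` 500):

1. **Completion.**  Missing entries of each block are replaced by the
   current prediction $XB$ (soft-impute).  Observed entries are never
   altered, and masked entries never contribute to the objective.
2. **Gene loadings.**  Each gene is an independent least-squares problem
   of its observed values on the activity columns of its pathways;
   rank-deficient designs get the minimum-norm solution.
3. **Drug loadings.**  The row-sparse problem is solved by iteratively
   reweighted ridge: $B^{(2)} \leftarrow (X^TX + \lambda D)^{-1}X^TY^{(2)}$
   with $d_{ii} = 1/(2\|b^i\|_2)$.  Each solve minimizes a quadratic
   majorizer of the L2,1 term, so the objective never increases.  Three
   numerical guards matter: row norms are floored at `reweight_eps`
   ($10^{-10}$) before inversion; the all-zero solution is returned exactly
   when $\lambda \ge 2\max_i\|(X^TY^{(2)})^i\|_2$ (the subgradient
   condition at zero, exposed as `lambda_max()`); and because reweighting
   approaches zero rows only geometrically, rows below `row_zero_tol`
   ($10^{-6}$, relative to the largest row norm) are zeroed on output.
   Iterations stop at a first-order (KKT) optimality check, so warm starts
   cost nothing once converged.
4. **Activities.**  With loadings fixed, $X$ is updated by projected
   gradient descent with Nesterov acceleration on the completed data,
   using the inverse Lipschitz step $1/(2\sigma_{\max}(BB^T))$, a restart
   whenever the objective would increase, and Euclidean projection of each
   column onto the unit ball.  Projection is per column — the per-column
   constraint is what makes the problem identifiable, and normalizing the
   whole matrix would shrink already-feasible columns.

The completion in step 1 is refreshed with the current loadings before
step 4; completing at the current iterate is what makes the complete-data
objective a true majorizer of the masked objective, and the recorded
objective trace is then non-increasing (within $10^{-8}$ per step, a
property the tests assert).

**Initialization.**  Each activity column starts as the leading singular
vector of its pathway's member-gene expression (the pathway "eigengene"),
sign-fixed for reproducibility, after mean-imputing missing values.  This
respects the membership constraints from the first iteration.  We found a
membership-agnostic start (singular vectors of the concatenated data) can
leave the alternating scheme in a spurious stationary point whose rotation
the support constraints cannot undo; the anchored start fits noiseless
synthetic data to ~$10^{-7}$ relative residual in a few dozen iterations.

**Update order.**  One outer pass runs completion, then $B^{(1)}$, then
$B^{(2)}$, then $X$, so the first activity update already sees
least-squares-consistent loadings.  The order is a free choice of the
implementation; any fixed order yields the same monotone-descent
guarantee.

## Choosing the penalty

`lambda_max()` anchors the grid: above it the drug-loading matrix is
exactly zero.  `ipad_cv()` scans a descending log-spaced grid (default 20
points from $0.999\,\lambda_{max}$ of an initial fit down to 0.1) with
warm starts, and selects the penalty with the smallest mean held-out
residual sum of squares under ten-fold cross-validation, ties going to the
sparser model.  The folds partition the *observed entries* of the response
matrix rather than whole samples: held-out entries are simply marked
missing and flow through the soft-impute machinery unchanged, and every
sample keeps contributing to the activity estimate.  `ipad_path()` fits
the same grid and records, for every drug–pathway pair, the largest
penalty at which it becomes nonzero — pairs activating earlier are the
stronger associations, and the ranking is reported alongside the
coefficients.

A caveat worth knowing: minimum-RSS cross-validation is a *prediction*
criterion, and on this model it tends to select penalties below the point
where noise-driven rows activate (the familiar overselection of
cross-validated sparse regression).  The geometry sharpens the effect
here: activity columns are constrained to unit norm, so each drug-loading
entry carries an estimation error of the order of the noise standard
deviation regardless of the sample count, and inactive rows have a noise
floor of about $\sigma\sqrt{G_2}$ in row norm.  On synthetic data the
CV-selected fit therefore typically includes all pathways with small
spurious coefficients; the activation order from `ipad_path()` and the
permutation p-values — not the raw support at the CV penalty — are the
quantities that separate real from spurious associations.

## Significance

`ipad_permute()` refits the model `n_perm` times (2000 by default, matching
common practice for this analysis) with the sample rows of the response
matrix permuted — breaking the activity–response link while preserving
each drug's marginal distribution — and reports, per pair,

$$P_{ij} = \frac{1}{T}\sum_{t=1}^{T}
  \mathbf{1}\left(|B^{(2)(t)}_{ij}| \ge |B^{(2)}_{ij}|\right),$$

the fraction of permuted refits whose coefficient magnitude reaches the
observed one.  Ties count toward the null, zero observed coefficients get
$P = 1$, and a coefficient exceeding all permuted values gets $P = 0$ (no
add-one correction, so reported zeros are possible).  The penalty is held
at its cross-validated value for all permutations; re-selecting it per
permutation would change the estimand and multiply the cost by the grid
size.  Each permutation draws from seed + t, so runs are reproducible and
independent of execution order.  `significant_pairs()` applies the
conventional raw-p thresholds (0.05, 0.005); no multiplicity correction is
applied, matching how such association screens are usually reported.

## Synthetic data

`ipad_simulate()` draws data from the model's own assumptions: activity
columns with i.i.d. normal entries normalized to *exactly* unit norm (the
constraint is active, so the projection is exercised), a random
membership matrix with every pathway nonempty and overlaps permitted,
normal gene loadings on the membership support, `n_active` nonzero
drug-loading rows with normal entries (`signal_scale`, default 1), and
homoscedastic Gaussian noise per block (`noise_sd`, default 0.1).
`inject_missing()` removes entries completely at random at a given rate,
keeping the withheld truth for evaluation.  Because the factors are
identifiable only up to the constraint geometry, recovery is judged on
the row support of $B^{(2)}$ and on the product $XB^{(2)}$, never on raw
factor entries.

What the generator does *not* emulate: library-size and batch effects,
heavy-tailed expression distributions, structured (non-MCAR) missingness,
and correlated noise across drugs.  Tests passing on this generator
demonstrate the estimator's correctness under its own assumptions, not
robustness to real-data violations of them.

The test suite and the acceptance script run at desk scale — dozens to a
couple of hundred samples and pathways (e.g. N = 100, K = 8, G1 = 200,
G2 = 30 for recovery studies; 200 permutations for null calibration) —
sizes chosen so the whole suite completes in minutes while still
exercising every code path at the conditions stated above.

## Degenerate inputs and numerical choices

* K = 1 pathways and single-drug (G2 = 1) inputs work; the L2,1 norm of a
  single column is its L1 norm.
* A gene in no pathway keeps an all-zero loading column; a pathway with no
  member genes is rejected at construction.
* `lambda = 0` solves unpenalized least squares (minimum-norm via the
  pseudo-inverse when singular, flagged on the result).
* Fold draws that would empty every observation of some drug or sample are
  redrawn a bounded number of times, then fail loudly.
* All randomness (generator, folds, permutations) is seed-derived;
  repeated runs are bit-identical.

## Limitations

The joint problem is convex in each block but not jointly; the alternating
scheme converges to a stationary point that depends on initialization.
The pathway-anchored start has been reliable on data with the assumed
structure, but multi-start strategies are not provided.  P-values are
conditional on the selected penalty; selection uncertainty is not
propagated.  And as noted above, the support at the CV-selected penalty is
an overestimate by design of the selection criterion — use the permutation
test to prune it.
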