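---
title: "Parsimonious hidden Markov models for matrix-variate longitudinal data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parsimonious hidden Markov models for matrix-variate longitudinal data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matrixhmm)
```

## The data and the model

`matrixhmm` targets balanced four-way longitudinal data: $I$ units, each
observed at $T$ equally indexed occasions, where every observation is a
$P \times R$ real matrix $X_{it}$ — for example an outcome cross-classified
by two factors (gender by age class, variable by location, ...). The data
form a $P \times R \times I \times T$ array, exchanged as a tidy long table
with columns `unit`, `time`, `row`, `col`, `value`.

Each unit follows a latent first-order homogeneous Markov chain
$S_{it} \in \{1, \dots, K\}$ with initial law $\pi$ and transition matrix
$\Pi$ ($\pi_{k|j}$ = probability of moving from state $j$ to $k$). Given the
state, the observation is matrix-normal,

$$
\phi(X \mid M_k, \Sigma_k, \Psi_k) =
\frac{\exp\{-\tfrac12 \mathrm{tr}[\Sigma_k^{-1}(X - M_k)\Psi_k^{-1}(X - M_k)']\}}
     {(2\pi)^{PR/2}\,|\Sigma_k|^{R/2}\,|\Psi_k|^{P/2}},
$$

with mean matrix $M_k$, row covariance $\Sigma_k$ ($P \times P$) and column
covariance $\Psi_k$ ($R \times R$). Equivalently,
$\mathrm{vec}(X) \sim N(\mathrm{vec}(M_k),\ \Psi_k \otimes \Sigma_k)$, which
is the identity the test suite uses as an independent density oracle.

Because $(a\Sigma, a^{-1}\Psi)$ gives the same density for any $a > 0$, the
two covariances are only identified up to a reciprocal scalar. The package
follows the usual convention of fixing $|\Psi_k| = 1$, which removes the
column-side volume parameter.

## The 98 parsimonious structures

Both covariances are constrained through the eigen decomposition
$\Phi_k = \lambda_k \Gamma_k \Delta_k \Gamma_k'$, where
$\lambda_k = |\Phi_k|^{1/Q}$ is the volume, $\Gamma_k$ the orthogonal
orientation and $\Delta_k$ the unit-determinant diagonal shape. Letting each
component be equal (E) or variable (V) across states, or fixing the matrix
to be axis-aligned or spherical (I), yields 14 row structures
(`EII` ... `VVV`). On the column side the $|\Psi_k| = 1$ restriction removes
the volume letter, leaving 7 structures (`II` ... `VV`); the family is their
cross, $14 \times 7 = 98$ models, addressed as `"VEE-EE"` and enumerated by
`structure_pairs()`.

## Estimation

Parameters are estimated by maximum likelihood with an
expectation-conditional maximization (ECM) algorithm.

* **E-step.** Scaled forward–backward recursions per unit: forward vectors
  are normalized to sum to one at each occasion and the log scale factors
  accumulated; the backward pass reuses the same constants. Within each
  occasion the state log-densities are shifted by their maximum before
  exponentiation, so sequences with log-density ranges of hundreds of units
  (the suite checks 200+ over $T = 1000$) stay finite. The step returns the
  smoothed memberships $\hat z_{itk}$ and transition posteriors
  $\hat{zz}_{itjk}$.
* **CM-step 1** updates $\pi$, $\Pi$, $M_k$ in closed form, then $\Sigma_k$
  from the row scatter matrices
  $Y_k = \sum_{it} \hat z_{itk} (X_{it} - M_k) \Psi_k^{-1} (X_{it} - M_k)'$,
  evaluated at the previous $\Psi$ iterate.
* **CM-step 2** updates $\Psi_k$ from the column scatters
  $W_k = \sum_{it} \hat z_{itk} (X_{it} - M_k)' \Sigma_k^{-1} (X_{it} - M_k)$,
  evaluated at the freshly updated $\Sigma$.

Most structure-specific updates are closed forms built from traces,
diagonals and normalized determinants of the scatters. Two families need
more:

* `EEV`/`VEV` (and column `EV`): the per-state eigen decomposition of each
  scatter supplies the orientation, and shapes/volumes follow from the
  eigenvalues. Eigenvalues are kept in descending order and each
  eigenvector's largest-magnitude entry is made positive, so the
  decomposition is reproducible. The decomposition is applied once per
  sweep, as a conditional update.
* `EVE`/`VVE` (and column `VE`): the shared orientation has no closed form.
  A minorization–maximization (MM) loop bounds the concave part of
  $f(\Gamma) = \sum_k \mathrm{tr}(Y_k \Gamma \Delta_k^{-1} \Gamma')$ by its
  tangent, giving a linear surrogate whose minimizer over the orthogonal
  group is an orthogonal Procrustes problem solved by one singular value
  decomposition per inner iteration. For the variable-volume `VVE` the
  criterion carries the $1/\lambda_k$ weights — dropping them breaks the
  monotonicity of the outer algorithm, which is how the implementation was
  validated. The inner loop runs to a criterion change below `1e-8` with at
  most 100 iterations; the rotation is checked against a 10^4^-point
  planar-angle grid in the tests.

Updates whose printed form involves previous-iteration values (`VEI`,
`VEE`, `VEV` volumes; `EVE`/`VVE`/`VE` orientations and shapes) use exactly
those one-sweep conditional updates rather than inner fixed-point loops;
this preserves the ascent property, which the suite asserts for every one of
the 98 structures on a shared dataset.

Convergence is declared when the relative log-likelihood change falls below
`tol` (default `1e-8`, at most `max_iter = 500` sweeps). The trace is
monotone up to `1e-8` slack by construction. Degenerate states (vanishing
responsibility mass) abort the run and trigger a fresh initialization, up to
five times, rather than silently flooring covariances — the estimators stay
exactly the printed ones.

### Initialization

Fitting uses short-EM: `init_runs = 100` random starts are advanced for
`init_iters = 1` sweep each and the start with the highest log-likelihood
seeds the full run. Each random start draws hard random state memberships
per (unit, occasion), estimates the chain from the implied counts (lightly
smoothed so no state is structurally excluded), and computes covariance
first M-steps from the memberships. The state means, however, are placed at
$K$ randomly drawn observed matrices rather than at the membership-weighted
averages: with $I \cdot T$ in the hundreds, membership-weighted means of
random assignments all but coincide with the grand mean, and every start
then sits on the merged-states saddle — a failure mode observed directly
during development (all 100 starts of a well-separated two-state scenario
converged to a two-states-merged optimum about 1,000 log-likelihood units
below the separated one). Random exemplar positions break that symmetry
while keeping the rest of the scheme.

### Label switching

The likelihood is invariant under state relabeling. Fits are returned with
states sorted by the ascending grand mean of $\hat M_k$ (`align_labels()`),
with $\pi$, $\Pi$, posteriors and decoded labels permuted consistently.
When simulation experiments compare a fit against generating parameters
whose mean ordering is ambiguous, the comparison falls back to the
permutation minimizing the total squared mean error (at most $K! \le 24$
candidates).

## Model selection and the sojourn test

`mvhmm_select()` fits a grid of structures and state counts and ranks
converged fits by $\mathrm{BIC} = -2\ell + m\log(n)$, smaller being better;
ties break toward fewer parameters, then fewer states. The sample size $n$
is $I \cdot T$ matrix observations by default (`nobs = "occasions"`); the
per-unit convention $n = I$ is exposed as an option since both appear in the
panel literature. The parameter count adds $(K-1)$ initial probabilities,
$K(K-1)$ transition probabilities, $KPR$ means and the two structure counts;
the suite verifies the covariance counts independently by the numerical rank
of a smooth parameterization of each constrained family.

Under a homogeneous hidden Markov model, sojourn (segment) lengths in state
$k$ are geometric with continuation probability $\pi_{k|k}$.
`sojourn_test()` compares the observed run lengths of the decoded sequences
against that law with one $\chi^2$ goodness-of-fit test per state and
combines the $K$ p-values by Holm's step-down procedure, rejecting the
global geometric hypothesis when the smallest adjusted p-value falls below
$\alpha$. Numerical choices, stated as the package's own: runs touching the
sequence boundaries count as observed lengths (no censoring correction);
run lengths are binned greedily from below until each bin's expected count
reaches 5, with the final bin absorbing the infinite tail (merged backwards
if undersized); degrees of freedom are bins minus one, with no reduction for
$\hat\Pi$ being estimated from the full model rather than from the run
lengths. A state never visited is dropped from the adjustment with a
warning.

## The simulator and what passing tests show

`simulate_mvhmm()` draws the chain and then each observation from its
state's matrix-normal law (lower-triangular Cholesky factors, so seeds
reproduce across platforms). `scenario_preset()` encodes the validation
scenarios: dimensions `D1` ($2 \times 2$) or `D2` ($4 \times 8$), horizons
`T1`/`T2` (5 or 10 occasions), 2 or 4 states, $I = 100$ units, and two
overlap levels — adjacent state means separated by 2 (`O1`) or 4 (`O2`)
within-state standard deviation units per entry. The transition matrix has
0.9 on the diagonal; covariances are built to satisfy the named structure
(`EII-II`: unit spherical; `VVE-EV`: volumes 0.6–1.4, shared row
orientation from a fixed Givens chain, per-state column orientations with a
shared shape). These presets are this package's own choices of realistic
study conditions; recovery results are therefore assessed as trends and
magnitude bounds, not against any external table.

The generator emulates exactly the model's assumptions — Gaussian states,
homogeneous chain, balanced panel, no missingness. Passing recovery tests
show the estimation machinery inverts the generative process at these sizes;
they say nothing about robustness to heavy tails, skewness, unbalanced
panels or covariate-driven transitions, all outside the model family.

## Validation scales

The heavier checks run at sizes chosen to exercise the full family while
staying desk-scale: the ascent and constraint sweeps fit all 98 structures
on one $I = 30$, $T = 4$ dataset; parameter recovery uses 10 replicates per
cell of the `D1` O2 scenarios; BIC recovery fits the full
$98 \times K \in \{1,2,3\}$ grid on 10 replicates of an `EII-II` $K = 2$
generator with $I = 50$, using 5 short-EM starts per grid fit (the grid is a
screening exercise; the default 100 starts are for final fits); the sojourn
size experiment uses 100 replicates of 500 runs per state. The
`scripts/acceptance.R` script recomputes all of these from scratch.

## A worked example

```{r example, eval = FALSE}
library(matrixhmm)

scn <- scenario_preset("D1-T1-K2-O2")
sim <- simulate_mvhmm(scn$params, I = 50, T = 5, seed = 9)

fit <- mvhmm(sim$data, "EII-II", K = 2, seed = 1)
glance(fit)
augment(fit)            # decoded state and memberships per (unit, occasion)
autoplot(fit, "states") # unit-by-occasion state map

sel <- mvhmm_select(sim$data, structures = "all", K = 1:3,
                    init_runs = 5, seed = 10)
sel$best
sojourn_test(sel$best_fit)
```

## Known limitations

* Only balanced panels: every unit must be observed at every occasion.
* Local (posterior) decoding only; most-probable-path decoding is
  deliberately not provided.
* The chain is homogeneous; transitions cannot depend on time or
  covariates.
* Matrix-normal states only; heavy-tailed or skewed state densities are out
  of scope.
* The BIC grid search is embarrassingly parallel (`jobs`), but memory use
  grows with the stored posterior arrays for very large panels.
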