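---
title: "Generating virtual patient cohorts with Dirichlet-process Gaussian mixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating virtual patient cohorts with Dirichlet-process Gaussian mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virtualcohort)
```

`virtualcohort` generates synthetic tabular cohorts of virtual patients
from a real clinical dataset. This vignette is the package's account of the
model and the numerical choices behind it: what is fitted, which knobs
matter, what the synthetic-data fixtures do and do not emulate, and where
the design was genuinely open.

## The generative model

The cohort is modelled as a finite mixture of multivariate Gaussians in the
robust-scaled feature space. Mixture weights follow a truncated
stick-breaking representation of a Dirichlet process: independent stick
fractions $V_t \sim \mathrm{Beta}(1, \gamma)$ for $t = 1, \dots, T-1$
compose weights $w_t = V_t \prod_{s<t} (1 - V_s)$, and the last stick is
fixed at one so the final component absorbs the remaining mass. Each
component carries a conjugate Normal–Wishart prior on its mean and
precision:

$$ \Lambda_t \sim \mathcal{W}(W_0, \nu_0), \qquad
   \mu_t \mid \Lambda_t \sim \mathcal{N}(m_0, (\beta_0 \Lambda_t)^{-1}). $$

Fitting is coordinate-ascent variational inference: responsibilities are
updated from digamma expectations of the Beta and Wishart posteriors, and
the stick and Normal–Wishart parameters are updated in closed form from the
responsibility-weighted statistics. The evidence lower bound (ELBO) is
computed in full at every iteration; because each update is an exact
coordinate maximizer, the trace must be non-decreasing, and the fitter
treats a drop beyond `1e-8` as an internal error rather than a warning —
a non-monotone ELBO always indicates a wrong update, never "noise".

### Choosing the number of components

The truncation level $T$ is not guessed. The curated cohort is clustered
spectrally for every candidate $k$ in a range (default $[2, 20]$): a
Gaussian-kernel affinity on pairwise Euclidean distances, sparsified to a
symmetrized $m$-nearest-neighbour graph and normalized into
$L_{\mathrm{sym}} = I - D^{-1/2} W D^{-1/2}$, whose $k$ smallest eigenpairs
are found with a LOBPCG solver; k-means on the row-normalized eigenvectors
yields the partition, which is scored with the Davies–Bouldin index
*in the scaled feature space*. The best $k$ under the selection rule
becomes `opt`, and the scan stops early once `patience = 5` consecutive
evaluations fail to improve the running best.

Two selection rules are exposed because they genuinely disagree. The
Davies–Bouldin index is a ratio of within-cluster scatter to
between-centroid separation, so *lower* values indicate better-separated
clusters, and `rule = "min"` is the statistically sound choice — it is what
the package's own acceptance checks use, and it recovers the true component
count on separated Gaussian blobs. `rule = "max"` (the default) preserves
the published behaviour of selecting the *highest* score; whether that
wording referred to the raw index or a reversed score is unknowable from
the text, so neither reading is silently discarded.

### The weight-concentration parameter

The Dirichlet-process concentration $\gamma$ controls how many components
receive appreciable weight. Setting $\gamma = 1/\mathrm{opt}$ assumes a
linear relationship between concentration and component count; the
generator instead uses the exponential rule $\gamma = e^{-\mathrm{opt}}$
(`gamma_mode = "exp"`), which shrinks surplus components much more
aggressively as the selected count grows. The linear rule is retained as
`gamma_mode = "inverse"` for comparison. On simulated data with fewer true
clusters than $T$, the exponential rule leaves at most "true + 1"
components with expected weight above 0.01.

### Sampling

Virtual patients are drawn by (i) composing mixture weights from the stick
posteriors — by default one Beta draw per stick (`posterior_draw`), so
every generated cohort carries the posterior's weight uncertainty; expected
sticks are available as `weight_mode = "expected"` — (ii) categorical
component assignment, and (iii) a Gaussian draw per patient with the
component's posterior-expected mean and moment-matched covariance
$(\nu_t W_t)^{-1} (\beta_t + 1)/\beta_t$. Training happens in robust-scaled
space; samples are inverse-transformed so synthetic cohorts, fidelity
indicators and density overlays are all in measured clinical units.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `missing_threshold` | 0.30 | strict upper bound on a feature's missing fraction; 30% exactly is excluded |
| `contamination` | 0.05 | isolation-forest outlier fraction (rows flagged: `ceiling(contamination * n)`) |
| `knn_k` | 5 | neighbours for imputation |
| `dup_corr_threshold` | 0.999 | absolute Pearson correlation that marks a value duplicate |
| `dup_name_distance` | 1 | case-insensitive Levenshtein distance that marks a name duplicate |
| `k_min`, `k_max` | 2, 20 | component-scan range |
| `patience` | 5 | consecutive non-improving scans before early stop |
| `db_rule` | `"max"` | Davies–Bouldin selection rule (`"min"` is the sound one; see above) |
| `gamma_mode` | `"exp"` | $\gamma = e^{-\mathrm{opt}}$ vs $1/\mathrm{opt}$ |
| `tol`, `max_iter` | `1e-5`, 500 | ELBO convergence controls |
| `bins` | 50 | histogram bins of the KL indicator |

## Numerical choices

* **Robust scaling** centers on the median and scales by the IQR with the
  linear-interpolation quantile convention; zero-IQR features are flagged
  degenerate and only centered. This keeps hidden outliers from inflating
  the scale the clustering and the mixture see.
* **Affinity graph**: bandwidth = median pairwise distance (a scale-free
  heuristic), $m = \max(10, \lceil \log_2 n \rceil)$ neighbours,
  symmetrization by edge union. Disconnected graphs are fine — the zero
  eigenvalue simply gains multiplicity.
* **LOBPCG**: residual tolerance `1e-8`, at most 2000 iterations, random
  orthonormal start from the run seed, Jacobi (diagonal) preconditioner.
  Problems smaller than `max(40, 8k)` rows go straight to a dense
  eigendecomposition, as does any non-converged solve (with a warning); on
  moderate problems the iterate matches the dense solver to eigenvalue
  error below `1e-6` and principal subspace angle below `1e-5`.
* **k-means** on the embedding uses greedy k-means++ seeding, ten restarts,
  and re-seeds any restart that produces an empty cluster.
* **Ties** in the component scan resolve toward smaller `k` (the running
  best is only replaced by a strict improvement). "Patience" counts
  consecutive evaluations that fail to improve the global running best.
* **Degenerate components** during training (singular precision updates)
  receive a `1e-6` ridge with a logged warning.
* **Imputation distances** over mutually observed features are rescaled by
  $\sqrt{d / n_{\text{shared}}}$ so rows with different overlap are
  comparable; ties between equally distant donors break by row order for
  determinism.
* **KL smoothing.** The histogram KL indicator bins both cohorts on shared
  equal-width bins spanning the union range. Smoothing uses a fixed
  frequency floor (`eps = 1e-6` added to normalized frequencies, then
  renormalized) rather than add-one count smoothing: the count-based
  variant is not invariant under row duplication and, with the real cohort
  fixed, its value *grows* roughly like $\log P$ as the virtual population
  $P$ expands the union range — an artifact of the estimator, not a loss of
  fidelity. The frequency-floor variant is exactly duplication-invariant
  and converges as $P$ grows; count smoothing remains available via
  `smoothing = "laplace"`.
* **Validation target.** The pipeline scores synthetic cohorts against the
  *outlier-free* curated rows — the data the model is asked to mimic.
  Flagged patients stay in the curated output for provenance, but comparing
  the generator against rows it was explicitly told to ignore would measure
  the artifacts rather than the generator.

## What the synthetic fixtures emulate

`simulate_cohort()` builds a registry-shaped table: by default 648 patients
and 20 continuous features organized in correlated blocks, each block
driven by a latent categorical mode (2–4 modes), giving a mix of unimodal
and multimodal marginals on feature-specific scales — plus one feature with
40 % missingness, light (1 %) missingness on a few others, 5 % of rows
displaced by 8–12 standard deviations on about half their features, one
exact-duplicate column and one case-twin column, all recorded in an
annotation object so curation can be verified against ground truth.

Two deliberate properties of the fixture deserve mention. Displaced rows
are generated fully observed, because outlier flagging operates on
complete-case rows; injecting missingness into them would make the
flagging-recall check meaningless rather than harder. And feature names are
drawn from a pool of clinical-style names with pairwise edit distance at
least 2, so only the injected twin trips the name-deduplication rule —
generic numbered names (`f1`, `f2`, …) differ by one edit and would be
collapsed by design.

What the fixture does **not** emulate: real marginal shapes of any disease
cohort, clinically meaningful ranges or units, categorical or ordinal
variables, informative (non-random) missingness, and measurement error
correlated with outcomes. Passing tests therefore demonstrate that the
machinery recovers structure it can represent — Gaussian-mixture-shaped
continuous data — not that any particular clinical dataset is faithfully
reproduced.

## Testing strategy and problem sizes

The test-suite oracles are independent re-implementations: a straight-from-
formula Davies–Bouldin loop, an element-wise responsibility step from the
digamma expectations, dense eigendecompositions against LOBPCG, closed-form
Gaussian KL, and brute-force label-permutation matching. Simulation sizes
are chosen so each property is measurable yet quick: component recovery
uses 3 blobs of 1500 points over 20 seeds; eigensolver equivalence n = 200,
k = 4; ELBO monotonicity 50 randomized fits at n ≤ 120; metric convergence
n ∈ {10², 10³, 10⁴} over 20 seeds; the population-size sweep spans
P = 1000…10000 with nine sampling seeds.

The sweep check formalizes "indicators do not degrade as the virtual
population grows". Decay with $P$ is observable only while sampling noise
dominates model misfit, so the check runs on a cohort that is itself a
separated Gaussian mixture (the well-specified regime) and compares
endpoint medians up to twice the large-sample standard error of a median
($1.2533 \cdot \mathrm{MAD}/\sqrt{m}$) — the correlation indicators reach
their noise floor so quickly that a strict inequality would be testing
sign-noise, not the property.

## Known limitations

* Continuous features only: categorical columns are excluded during
  curation with a logged reason; Gaussian components cannot emit categories
  faithfully.
* Gaussian tails: heavy-tailed or bounded clinical variables are mimicked
  only up to their first two moments within components; synthetic values
  can fall outside physiological ranges.
* The Davies–Bouldin scan assumes the spectral partitions are meaningful at
  every `k`; on structureless data the selected `opt` is arbitrary (the
  mixture's shrinkage then prunes surplus components, which is the
  intended safety net).
* Fidelity indicators measure distributional similarity, not disclosure
  risk; the package makes no privacy claims.
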