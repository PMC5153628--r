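---
title: "Methods: weighted, imputed logistic matrix factorization for protein-chemical interaction prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted, imputed logistic matrix factorization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The statistical model

Interaction screening data is *one-class*: a 1 in the m × n
protein-chemical matrix R is a verified interaction, but a 0 conflates
"does not bind" with "never tested". `cosine` therefore never treats the
zeros as trustworthy negatives. Instead it fits a low-rank logistic
factorization: each target i and chemical j get latent vectors
$f_i, g_j \in \mathbb{R}^r$ and the interaction probability is
$p_{ij} = \sigma(f_i \cdot g_j)$. The working assumption — which the
synthetic generator realizes literally — is that proteins and chemicals
fall into a modest number of groups with shared binding preferences, so a
small r suffices.

The training objective is the weighted negative log-likelihood of the
logistic model plus four penalties:

$$
L(F, G) = \sum_{ij} w_{ij}\left[\log(1 + e^{x_{ij}}) - t_{ij} x_{ij}\right]
 + \frac{\lambda_F}{2}\lVert F\rVert_F^2
 + \frac{\lambda_G}{2}\lVert G\rVert_F^2
 + \frac{\lambda_M}{2} h(F, M) + \frac{\lambda_N}{2} h(G, N)
$$

with scores $x_{ij} = f_i \cdot g_j$, effective targets
$t_{ij} = r_{ij} + q_{ij}$, and the homophily penalty
$h(L, S) = \tfrac12 \sum_{ij} s_{ij} \lVert l_i - l_j \rVert^2
= \operatorname{tr}(L^\top (D - S) L)$, the graph-Laplacian quadratic form
of the similarity matrix. The Frobenius terms are the negative log of
Gaussian priors on the factors, so the whole objective is a negative log
posterior; the test suite verifies this correspondence by recomputing the
likelihood-times-prior product entrywise on a small instance. A linear
variant replaces the data term by weighted squared error
$\sum w_{ij}(t_{ij} - x_{ij})^2$; the logistic form is the default because
its output is a calibrated probability.

Two conventions are fixed here and absorbed into the λ's: every penalty
carries a factor 1/2 so that gradients come out as $\lambda_F F$ and
$\lambda_M (D_M - M) F$ without stray 2's, and the homophily sum is over
ordered pairs divided by two. Any other scaling is a reparameterization of
$\lambda$.

## Confidence weighting and the two-pass scheme

The position-specific weights encode how many effective observations an
entry is worth. Verified interactions start at $w_{ij} = 6$, everything
else at 1 — a verified positive is worth several untested zeros, and the
6:1 ratio is the scheme's fixed starting point. Training happens twice:

1. **Pass one** minimizes $L$ with $Q = 0$ and the initial weights.
2. The pass-one probabilities then update the inputs: entries predicted
   confidently in either direction ($p_{ij} < p_\text{low}$ or
   $p_{ij} \ge p_\text{high}$) gain one unit of weight, and the imputation
   rule sets the effective target to 1 where $p_{ij} \ge p_\text{high}$
   and to $\max(r_{ij}, p_{ij})$ elsewhere — so a verified 1 is never
   watered down, and a plausible zero enters pass two as a soft positive.
3. **Pass two** re-minimizes with the updated W and R + Q, warm-starting
   from the pass-one factors with fresh AdaGrad accumulators. Warm
   starting makes pass two a refinement of pass one rather than an
   independent fit, and keeps the two passes comparable in the regression
   tests.

Boundary conventions are arbitrary but fixed and tested: the upper branch
is closed ($p \ge p_\text{high}$ triggers both the weight increment and
the impute-to-1 rule), the lower branch open ($p < p_\text{low}$). The
thresholds default to $p_\text{low} = 0.1$, $p_\text{high} = 0.9$ — "only
move an entry when the model is quite sure" — and are plain config keys
logged with every run, since no canonical values exist. One consequence
worth knowing: imputation deliberately contradicts raw labels for
suspected false negatives, so the *training-label* AUC of pass two can dip
by a sliver relative to pass one even as held-out recovery improves; the
tests pin "no material degradation" rather than strict monotonicity.

A user-supplied Q (external experimental evidence) can replace the
probability-driven rule through the `Q_override` argument of
`cosine_fit()`; no evidence-file parser is provided.

## Optimization

The loss is minimized by full-batch AdaGrad: each coordinate moves by
$-\eta\, g / (\sqrt{\sum g^2_\text{past}} + \varepsilon)$. Full-batch
gradients keep runs bit-deterministic for a fixed seed, which the test
suite asserts end to end. Defaults:

| knob | default | why |
|------|---------|-----|
| rank r | 5 | a handful of binding-preference patterns; must satisfy r ≤ min(m, n) |
| λ_F, λ_G | 0.2 | Gaussian-prior shrinkage keeping factors O(1) |
| λ_M, λ_N | 0.2 | similarity information worth roughly as much as the priors |
| learning rate η | 0.7 | see below |
| ε | 1e-8 | standard AdaGrad floor |
| iterations | 600 | fixed-length runs (no early stopping) for reproducibility |
| init | N(0, 1/r) entries | keeps initial scores O(1); seeded |

The learning rate and penalty strengths were calibrated jointly on small
synthetic instances so that optimization on a small dataset (tens of
targets) is effectively converged after about fifty iterations, with the
remaining iterations polishing the optimum — the regime this family of
models is known to operate in on small interaction datasets. Weaker
penalties or smaller steps shift real convergence past iteration 100 on
the same instances; both choices are exposed in `cosine_config()` and
recorded in every run manifest. At η below ~0.5 the loss trace is strictly
non-increasing after the first few iterations; at the default 0.7 an
occasional plateau wiggle of order 1e-3 appears, which AdaGrad's shrinking
steps dampen. A diverging run (non-finite loss) aborts immediately, naming
the iteration.

## Cold start: the weighted profile

For a chemical with no observed interactions, the trained row of G
carries only shrinkage and homophily information. The weighted-profile
rule replaces it by

$$
g_j^{\text{cold}} = v\, g_j + (1 - v)\, \frac{1}{S_N}\sum_{k \in J_j} n_{jk}\, g_k,
\qquad S_N = \sum_{k \in J_j} n_{jk},
$$

where $J_j$ is the set of the J most similar chemicals *with interaction
data* (cold entities never serve as neighbors), and symmetrically for new
targets with M. The blend weight v interpolates between pure neighbor
profile (v = 0) and the untouched trained row (v = 1); the v-blend is the
general form of which "sum of own and neighbor preferences" readings are
special cases. Defaults J = 5, v = 0.5 — enough neighbors to average out
a noisy similarity, equal trust in the trained row and the
neighborhood — are logged in every evaluation report. Ties in the top-J
selection break by entity index, zero-similarity neighbors are excluded,
and an entity whose candidate neighbors all have similarity zero keeps
its trained row with a warning (a silent zero profile would erase the
shrinkage information for no gain).

## The synthetic generator

`simulate_screen()` draws cluster centroids in latent space, scatters
entity vectors around them (`cluster_spread`), scores all pairs by inner
products, and marks the top `interaction_density` fraction of scores as
observed interactions. Thresholding is deterministic by quantile, so
positive counts are exact and tests can be tight; a Bernoulli mode exists
behind a flag. Similarities are radial-basis-function kernels of latent
distance (bandwidth = median squared distance), optionally perturbed with
symmetric Gaussian noise, then clipped to [0, 1] with unit diagonal. Both
the low-rank and the homophily assumptions therefore hold *by
construction*, and the `similarity_noise` knob breaks homophily
controllably.

Two canonical fixtures are exported. `standard_benchmark_spec()`
(50 × 80, rank 3, 4 × 5 clusters, 8% density, noise 0.05) is the
workhorse for recovery and robustness experiments at a size where a full
two-pass fit takes about a second. `coldstart_benchmark_spec()`
(100 × 120, rank 4, 8 × 8 clusters, 5% density, noise 0.15) is larger and
noisier because cold-start evaluation needs headroom: on the standard
fixture the homophily regularizer alone already places most hidden
single targets in the top 10% of ranks, so a saturated metric could not
distinguish the weighted profile from the raw rows. Problem sizes across
the test suite (up to 100 × 120, 600 iterations, five seeds per
experiment) were chosen so the full suite runs in about a minute.

What passing these benchmarks does *not* show: real chemical fingerprint
statistics (Tanimoto similarities are far from RBF kernels of a latent
geometry), protein-family block structure, assay biases, or the extreme
sparsity and scale (thousands by tens of thousands) of public screening
data. The generator validates the machinery under the model's own
assumptions; performance claims on real data require real data.

## Evaluation protocols

All protocols hold out *whole chemicals* (columns), the cold-start
setting, rather than random entries:

- **Chemical-wise k-fold CV** (`run_chemical_cv`): test chemicals'
  columns are zeroed in training (weights fall back to 1), the refit
  model cold-starts them, and AUC / AUPR are computed per fold over all
  (test chemical, target) pairs, then averaged. A fold whose chemicals
  have no interactions yields NA with a warning rather than a crash.
- **Leave-one-out Top-1** (`loocv_top1`): per chemical, hide all its
  interactions, retrain, cold-start, and score whether the top-ranked
  target is a hidden true one. Full retraining per chemical is the
  reference semantics; `retrain = "fast"` fits once with all evaluated
  columns jointly zeroed and only recomputes each chemical's cold-start
  row — cheaper, not identical, and always recorded in the report.
- **TPR@top-r%** (`tpr_at_top_percent`): fraction of a chemical's true
  targets ranked within the top `round(n_targets * r / 100)` positions
  (floored at rank 1, so a top-ranked target always counts; with 3500
  targets and r = 1 the cutoff is rank 35). Cold-start recovery is
  stratified by ligands-per-target bins (1–5, 6–10, 11–15, 16–20, >20)
  and by maximum-chemical-similarity bins of width 0.1, each stratum
  halved into test and train.
- Metric conventions: AUC is the normalized Mann–Whitney statistic with
  ties worth 1/2; AUPR is step-wise integration over distinct-score
  thresholds with no interpolation; rank ties always take the *worst*
  rank, so no reported number ever benefits from ties. Per-fold metric
  pairs are compared by a paired t-test (`fold_significance`), with a
  zero-variance difference reported as degenerate rather than
  significant.

## Numerical and I/O details

- $\log(1 + e^x)$ is computed by the softplus/`log1p` trick and the
  sigmoid saturates without overflow; probabilities are clamped to
  $[10^{-300}, 1 - 2^{-53}]$ so they remain strictly inside (0, 1) even
  at extreme scores.
- Similarity matrices are standardized on input: symmetrized as
  $(S + S^\top)/2$ (raw normalized alignment scores can be mildly
  asymmetric; no canonical rule exists, averaging is the unbiased one),
  clipped to [0, 1] with a warning, diagonal forced to 1. A missing
  similarity row for any interaction entity is a hard error, not a
  silent zero — a zero row would quietly disable cold start for that
  entity.
- Oriented parsing: interaction tables may store targets or chemicals in
  rows; the orientation flag only affects parsing, never semantics.
- Degenerate inputs are contracts, not crashes: an all-zero interaction
  matrix trains to uniformly sub-0.5 probabilities; single-class metric
  inputs raise informative errors; infeasible densities and flip counts
  are rejected.
- Checkpoints (`save_model`/`load_model`) are plain text: factor
  matrices, training-state matrices and the resolved config (YAML at full
  double precision, so a reloaded config reproduces runs exactly).

## Known limitations

- Hyperparameters are not tuned per dataset; no nested cross-validation
  is built in. The defaults are sensible for the synthetic regime and are
  starting points, not universal choices, for real data.
- The homophily penalty uses dense similarity matrices; cost grows as
  m² r + n² r per iteration, fine into the low thousands of entities,
  unexplored beyond.
- Cold start requires informative similarities; entities with no usable
  similarity information are out of scope by design.
- Computing the similarity matrices themselves (Smith–Waterman, Tanimoto,
  pharmacological profiles) is upstream of this package.
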