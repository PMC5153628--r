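# cosine

One-class collaborative filtering for genome-scale multi-target virtual
screening.

## The problem

Protein–chemical interaction data is one-class: databases record verified
interactions (`r_ij = 1`), but a zero entry is ambiguous — the pair may not
interact, or may simply never have been tested. `cosine` completes such a
sparse binary interaction matrix **R** (m protein targets × n chemicals) and
ranks candidate targets for every chemical, including *brand-new* chemicals
with no interaction data at all (the cold-start problem). It is aimed at
computational chemists and bioinformaticians doing polypharmacology /
off-target prediction, where the question is "which proteins will this
compound bind?" rather than "which compound binds this one protein?".

## The model

The interaction matrix is approximated by a low-rank factorization
**R ≈ σ(F Gᵀ)**, where the rows of F (m × r) and G (n × r) are latent
preference vectors for targets and chemicals and σ is the logistic link, so
p_ij = σ(f_i·g_j) is the modeled interaction probability (a linear variant
without the link is also available). Training minimizes

```
L = Σ_ij w_ij [ log(1 + exp(f_i·g_j)) − (r_ij + q_ij)(f_i·g_j) ]
    + λ_F/2 ‖F‖²  + λ_G/2 ‖G‖²
    + λ_M/2 Σ_ij m_ij ‖f_i − f_j‖²/2  + λ_N/2 Σ_ij n_ij ‖g_i − g_j‖²/2
```

- **w_ij** are position-specific confidence weights (6 on verified
  interactions, 1 elsewhere) and **q_ij** are imputation values;
- **M** = (m_ij) and **N** = (n_ij) are protein–protein (e.g. normalized
  Smith–Waterman) and chemical–chemical (e.g. Tanimoto) similarity
  matrices; the graph-Laplacian homophily terms pull similar entities
  toward similar latent vectors.

The loss is minimized twice with AdaGrad: pass one with Q = 0 and the
initial weights; then entries predicted confidently (p below `p_low` or at
least `p_high`) gain one unit of weight, entries with p ≥ `p_high` are
imputed to 1 and the rest to max(r, p), and pass two refits. Chemicals (or
targets) with no interaction data receive the *weighted profile*
`v·g + (1−v)·Σ_J n_j g_j / Σ_J n_j` built from their J most similar trained
neighbors.

## Worked example

```r
library(cosine)

spec <- standard_benchmark_spec(seed = 42)   # 50 x 80, rank 3, 8% density
fx   <- simulate_screen(spec)
fx$data
#> interaction_dataset: 50 targets x 80 chemicals, 320 known interactions (density 0.0800)

masked <- hide_positives(fx$data, fraction = 0.25, seed = 42)
fit <- cosine_fit(masked$data, fx$target_sim, fx$chem_sim,
                  cosine_config(rank = 5, seed = 42))
fit
#> cosine_fit: 50 targets x 80 chemicals, rank 5, logistic link
#>   pass-1 final loss 1156.7872, pass-2 final loss 1459.3756

P <- predict(fit)                       # m x n interaction probabilities
unobserved <- masked$data$R == 0
auc_score(P[unobserved], fx$data$R[unobserved])
#> 0.979
```

The AUC of 0.979 says that a randomly chosen *hidden* interaction outranks a
randomly chosen non-interacting pair 98% of the time. (Pass-2 loss is not
comparable to pass-1 loss: the second pass optimizes a different objective,
with larger weights and imputed targets.) Cold-starting a chemical ranks
targets from its neighbors' latent profiles:

```r
cold <- apply_cold_start(fit, chem_sim = fx$chem_sim,
                         new_chemicals = "c7", J = 5, v = 0.5)
head(sort(predict(cold)[, "c7"], decreasing = TRUE), 3)
#>       t48       t41       t32
#> 0.8382674 0.7971037 0.7683114
```

Real data drops in through `read_interaction_matrix()` /
`read_similarity_matrix()` (tab-delimited adjacency tables, header row of
chemical ids, first column of target ids) and `align_datasets()`.
Benchmarks run through `run_chemical_cv()`, `loocv_top1()` and
`run_benchmark()`; a command-line interface (`exec/cosine`) wraps
simulate / fit / predict / eval for shell pipelines.

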