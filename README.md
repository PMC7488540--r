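# snspmf

Weighted, sparse, semi-nonnegative matrix factorization for multi-tissue eQTL
effect sizes, with stability-based model selection, per-eQTL factor
assignment, heuristic baselines, a simulation framework, and downstream
enrichment statistics.

## The problem

An expression quantitative trait locus (eQTL) study measured across many
tissues produces, for each gene–variant pair, a vector of estimated effect
sizes (slopes) and their standard errors — one per tissue. Some eQTLs act in
essentially every tissue (*ubiquitous*), others in a small group of related
tissues (*tissue-specific*). Characterizing this sharing structure matters
because it reflects which regulatory elements are active where, and because a
variant's disease relevance often hinges on the tissues in which it acts.

Pairwise sharing summaries do not capture group structure, and per-tissue
significance thresholds are miscalibrated when power differs across tissues.
This package instead learns the structure directly from the effect-size
matrix.

## The model

Let `X` be the `N × T` matrix of effect sizes (eQTLs × tissues) and `W` the
matrix of weights, `W[i,t] = 1/SE[i,t]`, with `W[i,t] = 0` where the pair was
not tested. The model factorizes

```
X ≈ L Fᵀ
```

where `F` (`T × K`) holds **nonnegative** tissue factors — each column is an
interpretable pattern of tissue activity — and `L` (`N × K`) holds sparse,
real-valued loadings (an eQTL may load on a factor with either sign). The fit
minimizes the weighted, L1-penalized objective

```
(1 / 2D) · || (X − L Fᵀ) ⊙ W ||²_F  +  α ||L||₁  +  λ ||F||₁
```

with `D = N` by alternating least squares: each half-step solves a set of
independent weighted lasso problems (rows of `L`, then rows of `F` with a
nonnegativity constraint) by cyclic coordinate descent, so the objective is
non-increasing at every half-step. Iteration stops when `||ΔF||_F < 0.01` or
after 100 iterations. Factors that become entirely zero are removed, so the
returned rank `K′` may be smaller than the requested `K`.

Because weights differ across entries, this is not a problem standard
factorization libraries solve; the coordinate-descent core is implemented in
C++ and is exact for each one-dimensional subproblem (soft-thresholding
against the weighted covariance).

## What else is in the package

- **Model selection** (`evaluateGrid`, `selectModel`): for each `(K, α, λ)`
  on a grid, the model is refit from many random initializations; run-to-run
  agreement of eQTL-to-factor assignments is summarized in a consensus matrix
  and scored by cophenetic correlation. Settings are eliminated in three
  stages (unstable `K` groups, unstable individual settings, then
  between-factor correlation), with ties resolved toward smaller `K` and
  stronger penalties.
- **Factor assignment** (`mapEqtlsToFactors`, `assignFactors`): each eQTL's
  effect vector is regressed on the learned factors by weighted least squares
  (weights `1/SE²`); factor relevance is tested per coefficient with a single
  Benjamini–Hochberg family across all eQTLs and factors; perfectly linked
  variants are pruned per gene beforehand and significant labels propagated
  back. Two discrepancy filters drop unreliable assignments (coefficient sign
  contradicting the weighted partial effect on the factor's support;
  opposite-sign coefficients with no strong per-tissue signal).
- **Heuristic baselines** (`heuristic1Classify`, `heuristic2Classify`):
  threshold rules on per-tissue p-values and credible-set membership, for
  single tissues and for predefined tissue subsets.
- **Simulation and scoring** (`simulateDataset`, `alignAndScore`, `rrmse`):
  generates data with one dense factor plus sparse factors and known labels,
  and scores recovered factors/loadings (greedy column alignment, Pearson
  correlation) and classification (precision/recall for ubiquitous and
  tissue-specific calls).
- **Enrichment statistics** (`sampleMatchedBackground`,
  `chromatinStateEnrichment`, `tfbsEnrichment`, `fisherExact`,
  `randomEffectsCombine`, `asbBinomialTest`): matched background sampling
  (MAF, TSS distance, SNPs per gene), interval-overlap Fisher exact tests by
  direct hypergeometric enumeration, DerSimonian–Laird random-effects
  combination of log odds ratios, and exact binomial tests of allelic
  imbalance.
- **Pipeline and CLI** (`runPipeline`, `exec/snspmf`): a config-driven,
  bit-reproducible pipeline (simulate or load TSVs → grid → select → fit →
  assign) writing TSV artifacts plus an md5 manifest, and subcommands
  `simulate`, `fit`, `select`, `assign`, `evaluate`, `run`.

## Worked example

Simulate 100 eQTLs across 10 tissues from 5 factors (one dense), fit with
ten random restarts, keep the best fit by objective, and map eQTLs to
factors:

```r
library(snspmf)
sim <- simulateDataset(N = 100, T = 10, K = 5, sigma2 = 0.001, seed = 42)
sim$effects
#> MultiTissueEffects: 100 eQTLs x 10 tissues (100.0% observed)

fits <- lapply(1:10, function(r)
  fitSnSpMF(sim$effects, K = 5, alpha = 4.9, lambda = 4.9,
            seed = deriveSeed(42, "restart", r)))
objs <- vapply(fits, function(f) tail(objectiveTrace(f), 1), numeric(1))
fit <- fits[[which.min(objs)]]
fit
#> FactorModel: 10 tissues x 5 factors (requested K = 5)
#>   alpha = 4.9, lambda = 4.9, converged after 96 iterations

round(factorMatrix(fit), 2)
#>          Factor1 Factor2 Factor3 Factor4 Factor5
#> tissue1     0.00    0.00    1.32    0.00    3.08
#> tissue2     1.52    0.00    2.30    2.91    0.00
#> tissue3     3.68    0.00    1.23    0.00    0.00
#> tissue4     0.00    1.32    2.12    0.00    0.00
#> tissue5     4.17    0.00    1.00    0.00    2.69
#> tissue6     0.00    0.00    1.62    4.13    0.00
#> tissue7     0.00    3.75    1.99    0.00    0.00
#> tissue8     0.00    3.90    1.00    0.00    0.00
#> tissue9     0.00    0.00    1.84    3.82    0.00
#> tissue10    0.00    0.00    0.60    0.00    4.34
```

Factor3 is active in all ten tissues — the recovered ubiquitous pattern;
the other factors cover small tissue groups. Score against the simulated
truth and classify each eQTL:

```r
sc <- alignAndScore(factorMatrix(fit), loadingMatrix(fit), sim$truth)
cat("factor correlation:", round(sc$factor_corr, 3),
    " loading correlation:", round(sc$loading_corr, 3), "\n")
#> factor correlation: 0.896  loading correlation: 0.951

u_idx <- sc$permutation[1]     # learned column aligned to the dense factor
m <- mapEqtlsToFactors(sim$effects, factorMatrix(fit), ubiquitous = u_idx)
head(m$labels, 5)
#>    eqtl_id u_eqtl              ts_factors n_kept
#> 1 gene1:v1   TRUE Factor1,Factor4,Factor5      4
#> 2 gene2:v2   TRUE Factor1,Factor2,Factor5      4
#> 3 gene3:v3  FALSE                 Factor1      1
#> 4 gene4:v4  FALSE                 Factor4      1
#> 5 gene5:v5  FALSE         Factor2,Factor5      2

sc2 <- alignAndScore(factorMatrix(fit), loadingMatrix(fit), sim$truth,
                     labels = m$labels)
#> u-eQTL precision/recall: 0.93 / 0.83
#> ts-eQTL precision/recall: 0.83 / 0.89
```

Multiple restarts matter: a single fit at this penalty strength can land in
a local optimum that merges two sparse factors into a rank-4 solution, and
at strong penalties the *global* optimum itself occasionally prefers such a
merge (see the vignette's limitations section).

The same analysis runs end to end from a config file:

```sh
snspmf run --config config.yaml        # or: Rscript exec/snspmf run ...
```

## Reproducing results

- **Unit, property, and acceptance tests** (testthat, 3rd edition):

  ```r
  testthat::test_dir("tests/testthat", package = "snspmf",
                     load_package = "installed")
  ```

  `tests/testthat/test-acceptance.R` contains one block per acceptance
  criterion: ALS monotonicity and one-dimensional grid-search oracles, WLS
  against explicit normal equations, parameter recovery at low noise over
  ten simulation seeds, model-selection accuracy over ten replicates, exact
  reference values for the Fisher/binomial/random-effects statistics, null
  calibration of the enrichment pipeline, and bit-reproducibility of the CLI
  across thread counts. Two recovery-related assertions document known
  structural limits of the penalized objective on these simulations (factor
  merging at strong penalties; stability-based selection favoring the
  smallest stable rank) and are expected to fail; the analysis is in the
  vignette.

- **Acceptance script** — runs the installed package end to end and writes
  its main computed quantities (recovery scores, RRMSE by noise level,
  selected model, exact statistics, null calibration rate) as JSON:

  ```sh
  Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
  ```

  All randomness derives from `--seed`; repeated runs with the same seed are
  bit-identical.

## License

MIT (see `LICENSE`).
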