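# cspattern

Chromatin-state segmentations of many epigenomes assign every cell type
an integer state (promoter-, enhancer-, transcription-, repression-like,
quiescent, ...) at each 200 bp window of the genome. Comparing those
labels *across* epigenomes at one position reveals cell-type
specificity: groups of epigenomes whose states share one local
distribution while other groups differ. `cspattern` is for regulatory
genomicists who want to

* discover the small set of recurring **cell-type-specificity patterns
  (CSPs)** — epigenome partitions — that explain genome-wide
  specificity,
* test whether a trait's GWAS risk variants are enriched or depleted in
  particular CSPs,
* use CSP likelihoods and chromatin-state enrichment scores to classify
  risk versus null variants, and
* translate a classifier's precision-recall profile into GWAS detection
  power under prior-weighted significance thresholds.

## The model

At window $j$, the states $X_{\cdot j}$ of $N$ epigenomes are modelled
by a partition $\Omega_{M_j}$ drawn from a catalog of $C$ patterns:
within each group $k$ of the partition, states follow a window-specific
multinomial with a Dirichlet($\vec\alpha$) prior, marginalized to

$$
\Pr(X_{\cdot j}\mid\Omega_{M_j}) = \prod_{k=1}^{K}
  \frac{\Gamma(|\vec\alpha|)}{\prod_s \Gamma(\alpha_s)}
  \frac{\prod_s \Gamma(n_{kjs}+\alpha_s)}{\Gamma(|\vec n_{kj}|+|\vec\alpha|)} .
$$

Group memberships and pattern frequencies carry Dirichlet(1) priors,
also integrated analytically, giving a closed-form joint posterior over
the catalog and the per-window pattern indices. Fitting is by
conditional maximization with a data-seeded exploration phase; the
Bayesian Occam penalty empties superfluous patterns, so the catalog
size is learned up to its capacity. A two-group mixture with a
Beta$(1,\beta)$ prior ($\beta$ = 10 or the largest LD-cluster size)
then sub-selects the risk variants whose CSP co-occurrence departs from
genome background. See `vignette("cspattern-methods")` for the full
account.

## Worked example

Simulate a 12-epigenome, 2,000-window genome with four planted
patterns, refit the catalog, and test a risk-variant set planted with
10-fold enrichment in the half-split pattern:

```r
library(cspattern)

sim <- gen_state_matrix(N = 12, L = 2000, S = 6, seed = 42)
fit <- fit_csp_model(sim$states, C = 12, K = 5, n_iter = 60,
                     anneal_iters = 25, train_fraction = 1, seed = 42)
fit$catalog
#> CSPCatalog: 4 patterns over 12 epigenomes (K = 5)
#>   groups per pattern: 1-3
#>   top pattern covers 71.0% of assigned positions
round(fit$catalog$freqs, 3)
#> [1] 0.088 0.710 0.100 0.102
```

All four planted partitions are recovered: the constitutive pattern
(every epigenome in one group) covers 71% of windows, the interleaved,
three-group and half-split patterns about 10% each.

```r
vs <- gen_variants(sim$states, sim$truth, enriched_patterns = 2,
                   enrichment_fold = 10, seed = 43)
gr <- fit_enrichment(vs$risk, fit$catalog, seed = 44)
gr
#> RiskGrouping: 104 of 200 variants CSP-associated (group 1, 52.0%)

csp_permutation_test(gr$M, fit$assignment, n_perm = 10000, seed = 45,
                     n_patterns = 4)
#>   pattern observed expected p_two_sided signed_log10p
#> 1       1        4     17.6       2e-04          -3.7
#> 2       2       72    142.0       2e-04          -3.7
#> 3       3       20     20.0       1e+00           0.0
#> 4       4      104     20.4       2e-04           3.7
```

Half of the risk variants are flagged as CSP-associated, and the
permutation test localizes the signal: fitted pattern 4 (the planted
half-split, which the enriched windows carry) holds 104 risk variants
against 20 expected (signed $-\log_{10} p = 3.7$, the smallest
two-sided p attainable at 10,000 permutations), with the constitutive
pattern correspondingly depleted. The same variants feed the
classifier benchmark:

```r
cl <- cluster_definition(setNames(c(rep(1L, 6), rep(2L, 6)),
                                  sim$states$epigenome_ids))
evaluate_trait(vs$risk, vs$null, "csp+enrichment", fit$catalog, cl,
               S = 6, n_repeats = 10, n_components = 6, seed = 46)
#> EvalResult [csp+enrichment]: mean PR-AUC 0.389 over 10 repeats
```

against a null-variant prevalence baseline of 0.167.

A command-line wrapper over the same functions is installed as
`exec/cspattern` (subcommands `simulate`, `fit-csp`, `assign`,
`enrich`, `zscores`, `predict`, `power`).

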