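# bnsbm — bipartite noisy stochastic block models for structured multiple testing

`bnsbm` performs simultaneous inference on a matrix of association
z-scores — the canonical use case is a taxa-by-metabolites matrix of
differential-correlation statistics — while *learning and exploiting* the
latent structure of the association network instead of treating every
test as independent.

The truth indicators are modelled as the adjacency matrix of a latent
bipartite stochastic block model: row features carry one of `B1` blocks
(mixing proportions `alpha1`), column features one of `B2` blocks
(`alpha2`), edges appear with block-pair probabilities `Pi[q, l]`, and
the observed score for a pair is drawn from a standard-normal-type null
`g0 = N(0, sigma0^2)` when the pair is null and from a block-specific
Gaussian alternative `N(mu[q, l], sigma2[q, l])` when it is not. Fitting
is by variational EM (closed-form M-step, fixed-point membership
updates, compiled inner loop), the number of blocks is chosen by the
integrated classification likelihood (ICL) with a BIC-type penalty, and
hypotheses are rejected by thresholding *structured l-values*

    l(x, q, l) = (1 - Pi[q, l]) g0(x) / (Pi[q, l] g(x; nu[q, l]) + (1 - Pi[q, l]) g0(x))

at the largest cutoff whose running mean — the plug-in estimate of the
marginal false discovery rate — stays below the nominal level. Because
the l-value pools information across a whole block, dense modules are
detected at far higher power than p-value ranking (Benjamini–Hochberg,
Storey q-values; both included as baselines) at comparable FDR.

The package also ships the score front-end for paired omics tables
(modified centred log-ratio transform for compositional counts,
within-group standardization, cross-correlations with influence-function
variances, and the two-group differential-correlation z statistic) and
seeded simulators for three benchmark regimes: modular, fully nested
(single generalist per vertex type) and bipartite preferential
attachment.

## Worked example

Simulate the modular benchmark (150 x 200 scores, three equal blocks per
side, within-block connectivity 0.8 vs 0.1 between, alternative means 1
on the dense diagonal blocks and 3 elsewhere), fit at the true block
counts, and test at a 10% marginal-FDR target:

```r
library(bnsbm)

sim <- sample_noisysbm(150, 200, scenario_a_params(), seed = 1)
fit <- fit_bnsbm(sim$X, fit_options(3, 3, seed = 1))
fit
#> bnsbm_fit: B1 = 3, B2 = 3, max iterations reached after 100 iterations
#>   final ELBO -48405.267
#>   row block sizes: 60 48 42
#>   column block sizes: 74 66 60

round(fit$theta_hat$Pi, 2)       # block connectivities (true: 0.8 / 0.1)
#>      [,1] [,2] [,3]
#> [1,] 0.10 0.72 0.10
#> [2,] 0.09 0.11 0.74
#> [3,] 0.76 0.12 0.10

dec <- decide(sim$X, fit, alpha = 0.1)
dec
#> bnsbm_decision: 6514 of 30000 hypotheses rejected at alpha = 0.1
#>   tau = 0.2129, estimated mFDR = 0.1

empirical_rates(dec, sim$truth)[c("fdp", "tdp")]
#> $fdp
#> [1] 0.07491557
#>
#> $tdp
#> [1] 0.6036866

# Benjamini-Hochberg on the same scores, same nominal level
bh <- bh_reject(z_to_pvalue(sim$X$values), 0.1)
empirical_rates(list(reject = bh), sim$truth)[c("fdp", "tdp")]
#> $fdp
#> [1] 0.0619644
#>
#> $tdp
#> [1] 0.1425566
```

Both procedures hold the 10% target (empirical FDP 0.075 vs 0.062), but
the structured procedure recovers 60% of the true associations against
BH's 14% — the power gain bought by modelling the block structure. The
block connectivity estimates sit within sampling error of the truth
(rows/columns are reported in canonical order, largest block first, so
the dense blocks appear off the diagonal here).

When the block counts are unknown, `select_model()` scans a grid and
maximizes ICL; `decide()` then works off the selected fit:

```r
sel <- select_model(sim$X, 1:4, 1:4, fit_options(1, 1, seed = 1))
sel$best
#> B1 B2
#>  3  3
```

A thin command-line wrapper over the same functions is installed with
the package (`system.file("cli", "bnsbm.R", package = "bnsbm")`) with
subcommands `simulate`, `fit`, `select`, `test`, `zscores` and
`benchmark`; all randomized commands take `--seed` and are
byte-reproducible for a fixed seed.

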