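---
title: "Structured multiple testing with bipartite noisy stochastic block models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structured multiple testing with bipartite noisy stochastic block models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnsbm)
```

## The problem

Association screens between two feature families — canonically taxa
against metabolites — produce a matrix $X = (x_{ij})$ of z-scores, one per
pair, and ask which pairs are truly associated. Classical answers rank
p-values (Benjamini–Hochberg, q-values) and treat every test as an
island. But real association networks are not islands: associated pairs
concentrate in modules, so the very pattern of which hypotheses are null
carries information that entrywise procedures throw away.

`bnsbm` models that pattern explicitly. The unknown truth indicator
matrix $A \in \{0,1\}^{n_1 \times n_2}$ ($A_{ij} = 1$ when the null for
pair $(i,j)$ is false) is treated as the adjacency matrix of a latent
bipartite graph drawn from a stochastic block model: rows carry one of
$B_1$ latent blocks with mixing proportions $\alpha_1$, columns one of
$B_2$ blocks with proportions $\alpha_2$, and
$A_{ij} \mid Z \sim \mathrm{Bernoulli}(\pi_{Z_{i1} Z_{j2}})$. The scores
are noisy emissions of that graph,

$$x_{ij} \mid A, Z \;\sim\;
\begin{cases}
g_0(\cdot\,;\nu_0) & A_{ij} = 0\\
g(\cdot\,;\nu_{Z_{i1} Z_{j2}}) & A_{ij} = 1,
\end{cases}$$

with a Gaussian null $g_0 = N(0, \sigma_0^2)$ (mean fixed at zero; a
z-score's null location is part of its definition) and one Gaussian
alternative $N(\mu_{ql}, \sigma_{ql}^2)$ per block pair. The full
parameter set is $\theta = (\alpha_1, \alpha_2, \Pi, \nu_0, \nu)$.

Keeping the two vertex types separate matters: collapsing rows and
columns into one clustering mixes feature types into the same
communities and degrades both interpretation and error control, whereas
the bipartite factorization splits inference into two smaller,
type-specific subproblems.

## Decisions: structured l-values and marginal FDR

All decisions flow through the *structured l-value*, the posterior
probability that a null is true given the data and latent structure:

$$\ell(x, q, l; \theta) =
\frac{(1 - \pi_{ql})\, g_0(x)}
     {\pi_{ql}\, g(x; \nu_{ql}) + (1 - \pi_{ql})\, g_0(x)}.$$

This is a local false discovery rate that borrows strength across every
entry of the block — an entry with a modest score inside a dense, strong
block can be called while the same score in a sparse block is not.
Sorting the plug-in l-values increasingly, `mfdr_threshold()` finds the
largest $k$ whose running mean stays below the target level $\alpha$;
the running mean of the rejected l-values is exactly the plug-in
estimate of the marginal FDR (the ratio-of-expectations version of FDR,
asymptotically equivalent to it for large matrices), so the rejection
set satisfies the estimated-mFDR constraint by construction. Ties at the
threshold are all rejected, making the rule deterministic.

`empirical_rates()` reports false and true discovery proportions against
a known truth, with the conventional "or 1" guard in the FDP denominator
so that making no rejections counts as zero error.

## Fitting: variational EM

The likelihood integrates over $A$ and both membership vectors and is
intractable, so `fit_bnsbm()` maximizes an evidence lower bound over a
factorized variational family: independent categorical posteriors
$\beta_1, \beta_2$ over row and column memberships, with the conditional
law of $A$ given $(Z, X)$ kept exact — its entries are the Bernoulli
responsibilities $\rho_{ij}^{ql}$, recomputed from the current $\theta$
whenever needed rather than stored, which keeps them consistent with the
parameters by construction.

* **E-step.** Memberships satisfy fixed-point equations in which each
  row's log-weights are block-averaged sums of per-entry terms
  $d_{ij}^{ql}$; at the responsibility implied by $\theta$ these reduce
  to per-block log mixture densities. Five alternating sweeps are run
  per outer iteration — enough for the fixed point to stabilize, and a
  fixed count keeps iterations comparable across fits.
* **M-step.** With memberships fixed, every parameter has a closed-form
  weighted-moment update. Blocks whose membership weight falls below
  $10^{-8}$ keep their previous parameters so the model dimensions stay
  intact for criterion comparisons; the fit records this and warns.
* **Initialization.** In order: k-means on rows and on columns (one-hot
  memberships); a rough edge indicator from thresholding two-sided null
  p-values at $0.5$; block means of that indicator for $\Pi$; moment
  estimates of the densities given the initial memberships; then a
  refresh of the responsibilities before the first M-step.
* **Restarts.** The surface is non-convex, so the fit runs several
  seeded initializations (default 5; restart $r$ uses `seed + r - 1`)
  and keeps the best final ELBO. Output labels are canonicalized by
  decreasing mixing proportion (ties by alternative mean) so a seeded
  run is reproducible end to end.

The outer loop stops when the relative ELBO change drops below $10^{-6}$
(default) or after 100 iterations. The trace is non-decreasing up to
numerical slack because both steps maximize the same objective; the
suite asserts this across hundreds of random instances. One practical
consequence of ELBO-based stopping is worth knowing: near a flat ridge
of the likelihood (e.g. the trade-off between $\pi$ and $\mu$ when the
alternative barely separates from the null), an ELBO change below
$10^{-6}$ still allows parameter movement of order $10^{-4}$, so two
correct implementations with different stopping rules agree to about
that precision, not machine precision.

The per-iteration kernel (per-block mixture densities, responsibilities,
membership sweeps, moment updates) is implemented in C++
(RcppArmadillo), mirroring the exported R reference functions
`e_step()`, `m_step()` and `elbo()` to machine precision; the suite
checks the two paths against each other and against enumeration oracles.

### Collapsed blocks

When a block contains no detectable edges, its fitted alternative
density collapses onto the null and the model walks a likelihood-flat
ridge: every $(\pi_{ql}, \nu_{ql})$ with $\nu_{ql} = \nu_0$ fits
identically, so plain EM parks $\pi_{ql}$ wherever initialization
happened to leave it (typically near $0.5$, the mass of the p-value
threshold used at initialization). Reporting an arbitrary ridge point
would be misleading — it suggests half the block is associated — and it
inflates the entropy term of the selection criterion. `fit_bnsbm()`
therefore detects collapse by the KL divergence between the fitted
alternative and the null (threshold $10^{-3}$; genuinely informative
blocks in all our simulations sit at $0.5$ or above, three orders of
magnitude away) and reports the parsimonious member of the ridge,
$\pi_{ql}$ at the numerical floor, alongside a diagnostic warning. This
is a reporting convention for an unidentified parameter, not a change to
the fitted likelihood. More generally, identifiability of the model
requires the block alternatives to differ from the null; the warning is
the user-facing symptom when that assumption fails in a block.

## Choosing the number of blocks

`select_model()` fits a grid of $(B_1, B_2)$ pairs and maximizes the
integrated classification likelihood
$\mathrm{ICL} = E_{\hat Q}[\log L_{\text{complete}}] - \mathrm{pen}$,
computed as ELBO minus the entropy of the fitted variational
distribution minus a BIC penalty

$$\mathrm{pen}(B_1, B_2) = (B_1 - 1)\log n_1 + (B_2 - 1)\log n_2 +
\bigl[d_0 + (1 + d_1)\,B_1 B_2\bigr] \log(n_1 n_2),$$

with $d_1 = 2$ Gaussian alternative parameters per block and $d_0$
following the null: 0 when the null is fixed (the default, matching how
the simulations are run), 1 when its variance is estimated. The entropy
term charges fuzzy posteriors, so the criterion favours compact,
well-separated biclusterings. Ties break toward fewer total blocks, then
fewer row blocks. The default grid `1:5 x 1:5` covers the benchmark
scenarios with margin.

`stability_score()` complements the criterion with a subsampling
reproducibility score (mean pairwise adjusted Rand index of clusterings
across random 80% subsamples, single-block axes scoring 1 by
convention). It is deliberately simple plumbing for relative comparisons
between candidate grids on one dataset, not a calibrated procedure.

## The simulators, and what they do and do not emulate

`simulate_scenario()` generates the three benchmark regimes at their
study sizes ($n_1 = 150$, $n_2 = 200$, standard normal null):

* **(a) modular** — `scenario_a_params()`: three equal-probability
  blocks per side, within-block connectivity 0.8 against 0.1 between,
  unit-variance alternatives with mean 1 on the dense diagonal blocks
  and mean 3 elsewhere, so sparse blocks carry the larger effects. Mean
  edge density $(3 \times 0.8 + 6 \times 0.1)/9 = 1/3$.
* **(b) nested** — a fixed fully nested graph with a single generalist
  per vertex type (`nested_graph()`: row 1 joined to every column,
  column 1 to every row, $n_1 + n_2 - 1$ edges), scores $N(0,1)$ off
  edges and $N(2,1)$ on them. The graph violates the block-model
  assumption by design; a degree-sequence generalization
  (`nested_graph_from_degrees()`) is exposed for sensitivity checks.
  The single-generalist topology is the minimal graph matching the
  description of this regime and the connectivity estimates reported
  for it (about 0.99 generalist-specialist, about 0
  specialist-specialist); conclusions for this scenario are conditional
  on that choice.
* **(c) preferential attachment** — `pa_graph()`: type-I vertices arrive
  with degrees uniform on $\{2,\dots,6\}$ and attach each edge to a new
  type-II vertex with probability $1 - \lambda$ ($\lambda = 0.8$) or to
  an existing one proportionally to degree. Two policies are ours, the
  growth process itself being silent on them: duplicate pairs are
  redrawn within the existing pool (up to 50 attempts, then a fresh
  vertex opens), and an exact column count is met by padding with
  isolated vertices or restarting under a sub-seed. With the defaults
  the pre-padding type-II count averages just above
  $n_1 \bar d (1-\lambda) = 120$, the excess coming from forced-new
  events.

All generators are pure functions of their integer seed under R's
default Mersenne-Twister RNG, so seeds are portable across platforms.

These simulators emulate the *score-level* world the model assumes:
independent Gaussian emissions given a latent graph. They do not emulate
zero inflation, compositional sum constraints, or dependence between
scores sharing a row or column — all present in real paired omics data.
Passing the simulation suite therefore demonstrates correctness of the
machinery and calibration under the stated model, not robustness to
those real-data pathologies (the nested and preferential-attachment
scenarios do probe graph-level misspecification).

## From paired omics tables to z-scores

`differential_z()` implements the score front-end for two-group designs:
within each group, columns are centred and scaled with denominator $m$
(so the plug-in cross-correlation
$\hat\rho_{ij} = m^{-1} \sum_k \tilde Y_{1,ki} \tilde Y_{2,kj}$ is a
true correlation), the asymptotic variance of each correlation is
estimated by an influence-function form, and the two-group statistic is

$$x_{ij} = \frac{2(\hat\rho^{(1)}_{ij} - \hat\rho^{(2)}_{ij})}
{\sqrt{s^{(1)}_{ij}/m_1 + s^{(2)}_{ij}/m_2}}.$$

Two conventions deserve explicit notes. First, the variance: the form
sometimes displayed for this estimator,
$s_{ij} = m^{-1}\sum_k (2\tilde Y_{1}\tilde Y_{2} - \hat\rho \tilde Y_1 -
\hat\rho \tilde Y_2)^2$, uses unsquared centring terms and does not
vanish at perfect correlation, which a variance must. The delta-method
influence function squares them:
$(2\tilde Y_1 \tilde Y_2 - \hat\rho \tilde Y_1^2 - \hat\rho \tilde
Y_2^2)^2$. The package defaults to the squared form and preserves the
other behind `form = "as_printed"`; neither is silently corrected, and
the factor 2 in the numerator is kept exactly as displayed (it is
consistent with $s$ estimating the variance of twice the influence
term: for independent features $s \approx 4$ and $x$ is standard
normal). Second, the compositional transform: `mclr()` applies the
centred log-ratio per sample over positive entries only and shifts all
positive results by one global constant ($|\min t| + \varepsilon$,
$\varepsilon = 1$) so zeros remain exactly zero, positives remain
positive, and cross-sample ordering is preserved — a global rather than
per-sample shift is what makes the last property hold.

## Numerical conventions

Probabilities ($\pi$, $\rho$, $\beta$, $\alpha$ inside logarithms) are
clipped to $[10^{-10}, 1 - 10^{-10}]$; the variational identities divide
by $\rho$ and $1 - \rho$, and the conventions $0\log 0 = 0$ and
$0\log(\cdot/0) = 0$ are applied where exact zeros are meaningful
(one-hot memberships). All density work is in log space, stable for
$|x|$ at least up to 40. Alternative variances are floored at $10^{-8}$
(a one-entry block legitimately has zero within-block variance).
`responsibility()` and `ell_value()` honour exact boundary connectivities
($\pi \le 0$, $\pi \ge 1$) with exact 0/1 answers before clipping enters.
k-means initialization retries up to 10 times on empty clusters, then
errors; an all-restart failure aggregates the messages.

## Problem sizes used by the checks

The shipped suite exercises: enumeration oracles up to $4 \times 4$
matrices and 2 blocks per side (256 membership assignments); ELBO
monotonicity on 200 random instances up to $14 \times 14$; recovery
(with the tolerance tightened to $10^{-9}$ and the iteration cap raised,
because an estimation-accuracy check must run the optimizer past the
flat ridge that the default stopping rule is content to stop on),
error rates and selection frequencies at the full benchmark size
$150 \times 200$ with 10–20 replicates and 2–5 restarts per fit (the
acceptance script uses 5 restarts throughout, matching the study
conditions; fewer replicates than the original 100 widens the binomial
bands the checks allow for). On one core this keeps the whole suite and
the acceptance script each within tens of minutes.

## Known limitations

* Only Gaussian null and alternative families are implemented; the
  density interface is the extension point, and model-based FDR control
  should not be trusted when the statistic's family is unknown.
* The plug-in procedure ignores uncertainty in $(\hat Z, \hat\theta)$;
  with very low signal-to-noise, estimation error eats the power
  advantage and mFDR calibration degrades.
* ICL is evaluated by exhaustive grid search; greedy block-merging
  schemes would scale to larger grids but are not provided.
* The mFDR plug-in estimator (running mean of sorted l-values) is the
  standard local-fdr thresholding construction; it controls the
  *estimated* marginal FDR, with the usual asymptotic (not
  finite-sample) link to FDR.
* Scores are modelled as independent given the graph; shared-row and
  shared-column dependence of real cross-correlation statistics is not
  represented.
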