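---
title: "Detecting shifts in the structure of phylogenetic integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting shifts in the structure of phylogenetic integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covshift)
```

## The model

covshift asks where on a phylogeny the *structure* of evolutionary
covariation among continuous traits changes. The quantity being modelled
is the correlation matrix **V** of branch-wise evolutionary divergences: as
k traits diverge along a tree, each branch contributes a length-k vector of
changes, and V captures which trait pairs change together, in which
direction, and how strongly. V is the long-timescale footprint of genetic
constraint and correlated selection acting together; a shift in V on some
clade is evidence that this internal architecture was reorganised there.

The inference chain is deliberately simple and modular:

1. **Reconstruction.** `asr_bm()` reconstructs each trait at every internal
   node by joint maximum likelihood under Brownian motion. For BM this is
   identical to weighted squared-change parsimony — internal states
   minimise the sum over branches of (change)²/(branch length) — and is
   computed exactly by a two-pass scheme: a tipward pass folds each
   subtree into a conditional mean and effective variance, and a rootward
   pass resolves each node as the precision-weighted average of its
   subtree message and its parent's resolved state. The test suite checks
   this against direct numerical minimisation of the objective and against
   an independent implementation.
2. **Divergences.** `branch_divergences()` emits one row per branch:
   child-node state minus parent-node state. The direction of subtraction
   is a pure convention — flipping it negates every row, which leaves every
   covariance and correlation matrix unchanged — but it is fixed and
   documented (change accumulated tipward). A rooted binary tree with n
   tips yields exactly 2n − 2 rows, and rows telescope along any
   root-to-tip path to (tip value − root value).
3. **Regime matrices.** For any set of branches,
   `shrunk_covariance()` computes the empirical covariance S (divisor =
   number of rows, taken about the row mean) and shrinks it toward an
   isotropic target: (1 − α)·S + α·(tr S/k)·I; `cov_to_corr()` then
   rescales to a correlation matrix. Shrinkage exists because small clades
   produce erratic covariance estimates whose spurious extremes would
   masquerade as structural shifts.
4. **Likelihood and AIC.** Under BM the expected net change on any branch
   is zero, so each divergence vector is scored by the zero-mean
   multivariate normal log density with its regime's matrix
   (`branch_loglik()`, `tree_loglik()`); `aic_score()` counts
   k(k − 1)/2 free parameters per regime — the off-diagonal entries of a
   correlation matrix.
5. **Search.** `greedy_search()` evaluates every clade with at least
   `min_size` tips as a two-regime model, ranks improving candidates by
   their AIC gain over the single-matrix base model, and walks the ranked
   list, retaining each shift that still lowers the AIC of the combined
   model built from the previously retained shifts. `shift_search()` wraps
   the whole chain from a trait matrix.

## Parameters that matter

* **`alpha`** (shrinkage coefficient, unitless in [0, 1]; default 0.1). A
  mild regularisation suited to clades whose branch counts only modestly
  exceed the trait count. Note the cost: shrinkage biases correlations
  toward zero by roughly a factor (1 − α), so an 0.8 generating
  correlation is estimated near 0.72 at α = 0.1. Raise `alpha` only if
  regime matrices come out singular.
* **`min_size`** (tips; default max(10, k + 1)). Clades below this are
  never candidate shift points: covariance matrices estimated from fewer
  branches than traits are rank-deficient before shrinkage, and small
  clades inflate the multiple-testing burden of the search.
* **`min_delta_aic`** (AIC units; default 0). The retention rule is strict
  improvement; a conservative cutoff (e.g. 2) trades sensitivity for a
  lower false-positive rate (see *Calibration* below).
* **`scale_by_time`** (default off). The mixture model applies one V per
  branch with no time factor, so divergences are not standardised by
  √(branch length) by default; the flag enables the standardised variant
  in both the divergence step and the simulator. With time scaling off,
  long branches carry more reconstructed change and are implicitly
  up-weighted; with it on, the model matches the classic
  independent-contrasts standardisation instead.
* **`background`** (`"reestimate"` default). Whether each candidate's
  complement matrix is re-fitted or the global base matrix is reused.
  Re-estimation is the default because with a strong shifted clade the
  global matrix is a blend of two regimes and misrepresents the
  background; measured on planted-shift simulations, reusing the global
  matrix destroys recovery.
* **`assume_zero_mean`** (default off). The BM expectation of a divergence
  is zero, so second moments about zero are defensible; the default
  centres at the sample mean, matching the convention of standard
  shrinkage-covariance implementations.
* **`param_count`** (`"correlation"` default). AIC can alternatively count
  k(k + 1)/2 covariance parameters per regime for sensitivity analysis;
  the default counts only the free off-diagonals actually estimated.

Two structural conventions are fixed rather than exposed. A shift lives
*at* a clade root: the clade's stem branch stays in the parent regime,
because the divergence along the stem accrued before the shifted regime
existed. And after the retention walk, any regime carved below k + 1
branches by nested shifts is dissolved into its parent, then all matrices
are re-estimated once from the final branch assignment.

## Numerical choices

Zero-length branches are replaced by 10⁻⁸ × tree height so inverse-length
weights stay finite. All densities are computed in log space through
Cholesky factors; a factorisation failure raises an error suggesting more
shrinkage rather than silently regularising. Ties in the candidate ranking
are broken by larger clade, then preorder position, making the search
fully deterministic — two runs on identical inputs produce byte-identical
reports. The summary statistic `mean_abs_correlation()` averages |r| over
the k(k − 1)/2 off-diagonal upper-triangle entries only; including the
unit diagonal would pin the statistic near 1 for small k and hide regime
differences.

## The simulator, and what passing tests do and do not show

`sim_yule()` draws a pure-birth tree; `sim_divergences()` draws, for every
branch, a zero-mean multivariate normal increment with the covariance of
the branch's regime (unit per-branch variance by default, time-scaled under
`scale_by_time`), accumulating increments root-to-tip into tip traits. The
default unscaled mode mirrors the inference model exactly, which is the
point: `recovery_experiment()` feeds the *true* increments to
`greedy_search()`, so calibration and recovery are measured for the search
itself, uncontaminated by reconstruction error (`use_asr = TRUE` switches
to the full empirical chain, where ASR smoothing adds correlated error
across branches and noticeably inflates spurious shifts).

The validation scenarios, fixed once:

* **Null calibration** — 20 replicates, 64 tips, k = 3, one regime with
  equicorrelation 0.5, a strength comparable to what the method reports on
  empirical leaf-trait data.
* **Planted shift** — 20 replicates, 128 tips, a ~32-tip clade with
  equicorrelation +0.8 inside; outside, the same matrix with trait 1's
  correlations negated (`flip_sign()`). The sign-flip construction keeps
  the background positive definite (a k = 3 matrix with all off-diagonals
  −0.8 is not a valid correlation matrix) while preserving the overall
  strength 0.8, so the contrast is purely structural.
* **Matrix accuracy** — one replicate at 256 tips with a ~64-tip planted
  clade, comparing estimated regime matrices entrywise with the
  generating ones.

These are also the problem sizes the acceptance checks use; they run in
seconds. What passing them shows is internal consistency: the estimator
recovers the generating structure, and the search finds a strongly
contrasting clade of reasonable size. What they do not show is performance
on real data, where traits are measured with error, evolution is not
Brownian, divergences come from reconstruction rather than observation,
and regime contrasts are far subtler than ±0.8.

## Calibration, honestly

The per-candidate behaviour is well calibrated: under the null a *fixed*
candidate clade improves AIC only rarely (the two extra matrix-fits cost
2·Δm = 6 AIC units at k = 3, and the expected log-likelihood gain is
smaller). But the search evaluates many overlapping candidates and the
ranked walk gives each a fresh chance at retention, so the *family-wise*
rate of admitting at least one spurious shift is substantially higher —
on the null scenario above the base model is returned in roughly half to
two-thirds of replicates, and on the planted-shift scenario the planted
node is essentially always detected and top-ranked while small nested
extras are admitted in a substantial minority of replicates.
`scripts/acceptance.R` recomputes these rates from scratch (null
base-model rate, exact-recovery rate, detection rate) for any seed. This
is the known cost of a greedy AIC scan with a strict improvement rule;
`min_delta_aic = 2` measurably reduces both spurious rates at little cost
in detection, and is the recommended setting when parsimony of regimes
matters more than sensitivity.

## Climate module

`classify_freezing()` applies the occurrence-based rule — freezing
tolerant if at least 2.5 % of a species' occurrences have minimum
coldest-month temperature (BIO6) at or below 0 °C, with species under 10
occurrences excluded; both boundaries are inclusive. Inputs are
pre-extracted `species,bio6` tables; occurrence harvesting, coordinate
cleaning and raster extraction are upstream concerns. `fitch_map()` scores
the binary habit by parsimony and reports, for every node, the exact set
of states attainable in *some* most-parsimonious labelling (computed by
unit-cost dynamic programming down- and up-passes). Ambiguous nodes stay
ambiguous: no accelerated/delayed-transformation resolution is imposed.
Tips excluded by the occurrence filter are pruned before mapping.

## Known limitations

Reconstructed divergences are inferences, not observations: they are
mutually correlated and shrunken relative to the true changes, and the
mixture likelihood treats them as independent draws. This is adequate for
locating strong, clade-scale rearrangements of correlation structure —
the use case here — but unsuitable for fine estimation of individual
correlations. The decomposition of V into genetic constraint and selection
components is conceptual; nothing here separates them. The search
considers only clade-shaped regimes with shifts at nodes, only
correlation (not rate) shifts, and its greedy walk neither revisits
earlier retentions nor re-ranks candidates mid-walk. AIC-based retention
overfits at the margins, as quantified above.
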