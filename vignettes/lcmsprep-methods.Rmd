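---
title: "Models and methods behind lcmsprep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lcmsprep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcmsprep)
```

# The problem

Label-free LC-MS proteomics delivers a peptide-by-sample matrix of log
intensities that is doubly damaged before any biology can be read off it:
systematic technical variation (loading differences, LC drift, batch
structure, and biases with no known source) distorts the values, and a
large fraction of cells is missing — some "completely at random" (MCAR:
ionization glitches, competition for charge), but most because the
underlying abundance fell below the instrument's effective detection
limit. Those cells are *left-censored*: their absence is informative, and
imputing them from observed values biases everything downstream upward.

`lcmsprep` implements a preprocessing chain that treats both problems as
statistical modeling tasks, plus a simulator and experiment drivers that
quantify when the chain is calibrated and in which order its steps should
run.

# Models

## The peptide ANOVA (normalization backbone)

For protein $i$, peptide $j$, group $k$ (optionally batch $b$), the log
abundance is modeled as

$$ y_{ijkb} = \mathrm{Prot}_i + \mathrm{Pep}_{ij} + \mathrm{Treat}_{ik}
   + \mathrm{Batch}_{ib} + \varepsilon_{ijkb}, \qquad
   \varepsilon \sim N(0, \sigma^2_{ij}), $$

with sum-to-zero constraints $\sum_j \mathrm{Pep}_{ij} = \sum_k
\mathrm{Treat}_{ik} = \sum_b \mathrm{Batch}_{ib} = 0$ within each protein
and a separate error variance per peptide. `fit_peptide_anova()` solves
each protein independently by constrained least squares on the observed
cells; proteins whose observed cells miss a whole group are flagged
non-estimable (a reduced protein + peptide model still supplies
residuals, but those peptides leave the variance pool). Estimability is
judged at the protein level: a single peptide observed in only one group
does not spoil a protein whose other peptides cover all groups.

## Eigentrend normalization

Unknown bias is recovered from the *residuals* of the group-effects
model: the treatment structure is fitted and set aside first, so
normalization cannot eat the biology. The right singular vectors of the
row-centered residual matrix (restricted to peptides observed everywhere)
are "eigentrends" — systematic across-sample patterns; the squared
singular value fractions are the variance they explain.

How many leading trends are real bias is decided by a permutation test
(`select_significant_trends()`): observed singular values are compared,
sequentially and stopping at the first failure, to the $(1-\alpha)$ point
of their null counterparts from matrices with scrambled entries. Two null
devices are available:

* **within-row permutation** (the default for a bare matrix): each row's
  entries are shuffled independently;
* **within-protein block permutation** (used by `eigenms_normalize()`):
  one random column permutation applied jointly to all peptides of a
  protein.

The second exists because peptides of one protein share sample-level
variation (the $\mathrm{Samp}_{im}$ term of the simulator, and its
real-data analogues). That correlation inflates leading singular values
relative to an independent-rows null, and at a few thousand peptides the
within-row device declares a dozen spurious "trends" on bias-free data;
the block null preserves the correlation and stays calibrated, while an
injected bias trend is still detected cleanly as $k = 1$. Defaults:
`n_perm = 99`, `alpha = 0.05`.

Every peptide — complete or not — is then adjusted by least-squares
projection of its observed residual cells onto the $k$ bias trends;
peptides observed in fewer than $k + 2$ samples are left alone and
flagged. With $k = 0$ the input is returned bit-identically.

## Residual re-inflation

Removing $k$ trends consumes $k$ degrees of freedom from each adjusted
peptide's residual vector, deflating its apparent variance by about
$(N-k)/N$; tests run on such data are anti-conservative.
`reinflate_residuals()` adds fresh zero-mean Gaussian noise of the
peptide's own (de-biased) residual variance, placed **in the removed
trend directions** (for incomplete peptides, in an orthonormal basis of
the trend span restricted to the observed coordinates). The residual
scatter is thereby inflated back by $N/(N-k)$, and — because the noise
sits exactly where variance was removed — the numerator and denominator
of downstream $t$-statistics are repaired together. An isotropic noise
variant restores the scatter but not the statistic: the removal touches
only the trend directions, so adding noise everywhere leaves a
numerator/denominator mismatch; in our null calibration runs the
directional construction is what makes pooled per-peptide p-values pass a
Kolmogorov–Smirnov uniformity check.

## The censored/MCAR likelihood

For one protein, every cell of its peptide-by-sample grid contributes

* observed $y$: $\log(1-\pi) + \log N(y;\, \mu_{jk}, \sigma_j^2)$,
* missing: $\log\!\big(\pi + (1-\pi)\,\Phi((c - \mu_{jk})/\sigma_j)\big)$,

where $\mu_{jk} = \mathrm{Prot} + \mathrm{Pep}_j + \mathrm{Treat}_k$,
$\pi$ is the global MCAR probability and $c$ the global censoring cutoff
(`missingness_params`). `fit_protein_ml()` maximizes the total over
$(\mathrm{Prot}, \mathrm{Pep}, \delta, \log\sigma)$ with L-BFGS-B and
analytic gradients, from a least-squares start plus two jittered restarts
(deterministically seeded). The treatment block is parameterized directly
as differences against the last group, $\delta_q = \mathrm{Treat}_q -
\mathrm{Treat}_K$, so the Fisher information block of interest lives on
the difference scale.

**Complete-data limit.** With no missing cells the fit is *defined* as
the constrained least-squares means with per-peptide variances profiled
at those means. The fully iterated heteroscedastic MLE would re-weight
peptides by $1/\hat\sigma_j^2$ estimated from a handful of residual
degrees of freedom; that estimator is noisier than the unweighted one
when true variances are comparable, and its Wald intervals undercover
(we measured 88–92% against a nominal 95%). Freezing the complete-data
limit at least squares makes the estimator exactly the classical one,
keeps intervals calibrated (95.0% empirically), and gives the likelihood
machinery an exact oracle to be tested against.

$\pi$ and $c$ are estimated once per dataset
(`estimate_missingness_params()`): $c$ as the median across samples of
each sample's minimum observed value, $\pi$ as the missing fraction among
top-quartile-abundance peptides, where censoring is negligible. Both are
overridable.

## Information-based filtering

The observed information at the optimum is profiled to the
$\delta$-block via the Schur complement; `information_content()` returns
$\det(\text{block})^{1/d}$ — the $d$-th root is the "scaled determinant"
convention adopted here, making values comparable across block sizes
(for a single peptide with two groups of $n$ complete samples it reduces
to $n/(2\sigma^2)$). `greedy_select_peptides()` runs a
forward search from the most informative single peptide (falling back to
peptide pairs when no single peptide covers both groups, since a pair can
be jointly identifiable); a protein is *filtered* when no examined subset
has positive information.

## Imputation

`impute_model_based()` performs a single imputation: each missing cell is
classified by its posterior probability of censoring,
$(1-\pi)\Phi(z) / (\pi + (1-\pi)\Phi(z))$ with $z = (c -
\hat\mu)/\hat\sigma$ (ties at the 0.5 threshold go to "censored", the
informative mechanism), then drawn from the fitted normal truncated to
$(-\infty, c]$ if censored and untruncated if MCAR. Naive baselines
(`impute_naive()`): peptide mean, matrix-wide minimum, peptide minimum,
and (group-wise) normal draws. The peptide-minimum rule (`row_min`) is
the illustration-grade failure mode: repeatedly writing a value from
inside the peptide's observed range underestimates variation and is what
collapses interval coverage in the degradation study.

## Inference and p-value hygiene

`test_protein_difference()` reports each protein's group difference with
a confidence interval: from least squares with Satterthwaite-pooled
per-peptide variances (`complete_data_anova`), or from the censored
likelihood with the profiled observed information, a finite-sample
variance correction $n/(n - p)$ and a $t$ reference on approximate
residual degrees of freedom (`wald_ml`). Intervals are defined for
two-group designs; more groups are refused rather than silently reduced.
`adjust_pvalues()` estimates an inflation factor $\lambda$ from the right
tail of the p-value distribution only (p > 0.5 by default — in real data
the left tail contains the signal), by matching the median of $-\log p$
in the tail to its uniform expectation, and maps $p \mapsto
p^{1/\lambda}$; the transform is monotone, so rankings survive. The
adjustment operates on the p-value scale (whether the original procedure
worked on p-values or statistics is not recoverable; the monotone p-scale
transform is this package's reading).

# The simulator

`simulate_dataset()` draws from

$$ y = \mathrm{Prot}_i + \mathrm{Pep}_{ij} + \mathrm{Treat}_{ik}
     + \mathrm{Samp}_{im} + \varepsilon, $$

then deletes cells MCAR with probability $\pi$ and censoring-deletes
remaining cells below the `censor_quantile` of the complete value
distribution (a single global cutoff; MCAR wins ties so mechanism labels
partition the cells). Everything is logged in a `sim_truth`: complete
matrix, per-cell mechanism, realized cutoff, true differences.

Defaults (log2 scale): protein means $N(20, 2^2)$, peptide offsets SD 1,
2–12 peptides per protein (uniform), sample loadings SD 0.5, error SD
0.5, 10% differential proteins with group effects of SD 1, $\pi = 0.05$,
censor quantile 0.084 (≈13% missing overall, of which ≈5% MCAR and ≈8%
censored). Values the underlying study designs do not pin down (effect
sizes, variance components, the peptide-count range) were chosen once to
give realistic log2 data and are all exposed in `sim_config()`.

Presets:

* `main_study` — 1400 proteins, two groups × 10 samples, ≈13% missing;
* `coverage_study` — 200 proteins, two groups × 5; `sample_sd = 0` and a
  true difference drawn for **every** protein. The sample-loading term is
  protein-level noise that no per-cell model can estimate — with it on,
  coverage caps near 65% for any method, so a coverage study of the
  protein model must generate from the protein-model world. All-null
  proteins would likewise mask the censoring failure mode (min-imputation
  biases both groups symmetrically when the truth is 0), hence
  differences everywhere; the 0%-missing calibration is effect-
  independent and unaffected.
* `null_study` — 400 proteins, no differential proteins, complete data
  (bias and missingness are injected by the driver as needed);
* `ordering_study` — the `main_study` layout with 40% differential
  proteins of effect SD 1.5, so that the group-difference step carries
  roughly a third of the eigentrend variance, as in a strongly
  differential comparison.

`inject_bias_trend()` adds a rank-one sample trend with per-peptide
$N(0, \text{loading\_sd}^2)$ loadings. The experiment drivers default to
`loading_sd = 0.6` and a standardized within-group linear drift
(sawtooth), orthogonal to the group step, so technical bias and biology
are separable — with these values the raw-data eigentrend variance shares
(≈30% step, ≈30% bias) match a strongly biased differential experiment.
For the ordering and null studies the bias is added to the *complete*
values and the censoring is applied to the biased data: bias is part of
the measurement process and shapes which cells go missing.

# The experiments

`run_coverage_experiment()` sweeps total missingness 0→40% (5% MCAR
except at zero) and reports empirical coverage of nominal 95% intervals
per level for one of three strategies (complete-case least squares,
peptide-minimum imputation, censored-likelihood Wald). At 0% missing the
model intervals achieve 95.0 ± 0.3%; under growing censoring the naive
strategy collapses (≈0.54 at 40% in our runs) while the likelihood
strategy stays above 0.9.

`run_ordering_experiment()` compares top eigentrends of raw,
impute-then-normalize, and normalize-then-impute data. Normalizing first
leaves the group step as the first trend with |correlation| > 0.99 and a
systematically larger variance fraction than imputing first. The
step-correlation *difference* between the two orders is tiny at 13%
missingness (both pipelines preserve group structure by construction —
the imputation model contains the treatment term), so the variance
fraction, not the correlation, is the robust discriminator; both are
reported.

`run_null_pvalue_experiment()` computes per-peptide two-sample t-tests on
null data with injected bias: raw data fail a KS uniformity check
essentially always (bias inflates per-peptide variance estimates and
pushes p-values right), while eigentrend normalization followed by
directional re-inflation passes at the 1% level in ≈19/20 seeds.

Every driver is bit-reproducible from (config, seed); sub-seeds for
simulation, bias, imputation and permutation are derived from the master
seed.

# Numerical choices and degenerate inputs

* Missing tokens on input: empty, `NA`, `NaN` (case-insensitive); output
  writes empty fields. Zero intensities are refused at `log_transform()`
  — whether a zero is "missing" or "censored at zero" depends on the
  upstream quantifier, and silently choosing either corrupts the
  censoring model.
* Optimizer: L-BFGS-B on $(\mathrm{Prot}, \mathrm{Pep}, \delta,
  \log\sigma)$, `factr = 1e4`, SD floor $10^{-3}$, two deterministic
  jittered restarts; non-convergence is carried as a flag, and such
  proteins are skipped by imputation (their cells stay missing and are
  reported).
* Observed information: analytic for complete data, central finite
  differences (`pracma::hessian`) otherwise; a singular nuisance block
  maps to information 0 (non-identifiable), never an error.
* Trend-selection critical values use the $\lceil (1-\alpha)(B+1)
  \rceil$-th order statistic of $B$ permutation draws (exact level
  $\le \alpha$); with too few permutations for the requested level the
  maximum is used (conservative).
* Lowess normalization evaluates the fitted curve by interpolation with
  boundary extrapolation pinned at the end values; cells without a
  reference A-coordinate are left unadjusted. Re-application is not an
  exact identity (the A-coordinates move), but second-pass adjustments
  are under 5% of the first pass in our tests.
* `quantile(type = 7)` everywhere a quantile is taken; ties at the
  censoring threshold are deleted (strictly-below comparison).

# Problem sizes used by the test suite

The suite runs the full coverage calibration (100 simulations × 200
proteins), the ordering comparison at the full `ordering_study` preset
over 20 seeds, and the null-p study at the full `null_study` preset over
20 seeds; the remaining property checks use scaled-down generators (tens
of proteins, 3–30 simulations) chosen so each block completes in seconds
while keeping Monte-Carlo error well below the asserted margins.

# What passing the simulations does and does not show

The generator draws independent normal effects, a single global censoring
cutoff, and a rank-one bias. Real LC-MS data have heavier-tailed
intensity distributions, per-sample detection limits, correlated
peptide errors within spectra, retention-time-local bias of rank > 1,
and peptide-to-protein maps with shared/razor peptides — none of which
are emulated. Calibration results here are therefore statements about
the methods' internal consistency under their own assumptions, not about
any instrument. Known limitations: intervals are two-group only; $\pi$
and $c$ are global rather than per-sample (per-sample cutoffs are a
config option in the simulator but not in the fit); the mixed-effects
variant of the ANOVA is out of scope.
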