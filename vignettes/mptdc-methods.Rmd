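---
title: "Joint modeling of accuracy, confidence and response time in recognition memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint modeling of accuracy, confidence and response time in recognition memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mptdc)
```

## The modeling problem

In an old/new recognition test a participant studies a word list and is
later shown a mixture of studied ("old") and unstudied ("new") items,
responding "old" or "new" to each, typically together with a confidence
rating and with a measurable response time (RT). Two families of process
models compete to explain these data:

* **Two-high-threshold (2HT)** — a discrete-state account. An old item is
  *detected* with probability $do$ (a new item with probability $dn$);
  detection of the wrong stimulus class is impossible (the "high
  thresholds"). Undetected items fall into a guessing state, answering
  "old" with bias $g_j$. Because the proportion of old items in a test
  block shifts guessing but not detection, $g_j$ varies over the $J$
  target-proportion conditions while $do$ and $dn$ do not.
* **Signal detection theory (SDT)** — a continuous account. Each test item
  evokes a familiarity value: new items from $N(0, 1)$, old items from
  $N(d', \sigma)$. The response is "old" when familiarity exceeds a
  criterion $c_j$, which varies across target-proportion conditions
  while $d'$ and $\sigma$ do not.

This package implements both families as multinomial processing tree
models with discrete and discretized-continuous variables (MPT-DC). Each
family comes in four variants: `classic` (responses only), `CL` (adding a
3-point confidence scale), `RT` (adding fast/slow RT bins), and `CL_RT`
(both). The data layout is always $2J$ multinomial trees — one old-item
and one new-item tree per condition — whose categories are
response $\times$ confidence bin $\times$ RT bin.

## The eight variants and their parameters

Confidence enters the 2HT family through nested branch parameters: given
a latent state $s$, the probability of a high-confidence response is
$L_{s1}$, of medium confidence $(1-L_{s1})L_{s2}$, and of low confidence
$(1-L_{s1})(1-L_{s2})$. In the SDT family, confidence comes from a finer
partition of the familiarity axis: $K = 5$ ordered criteria delimit six
regions ("new-high" at the lowest familiarity through "old-high" at the
highest; the old/new boundary is the middle criterion). Condition shifts
move all criteria rigidly, so only the base criterion $c_{1j}$ is
condition-specific, plus four non-negative increments
$\Delta c_2,\dots,\Delta c_5$ with
$c_{kj} = c_{1j} + \sum_{2}^{k}\Delta c$.

RT bins enter both families the same way (the nonparametric MPT-DC
route): each branch splits into a fast and a slow sub-branch with
probability $H_b$ and $1-H_b$, where the branch class $b$ is the latent
state (2HT-RT), the response category Hit/Miss/FA/CR (SDT-RT), or those
crossed with the confidence bin in the joint models. $L$ and $H$
parameters are shared across conditions; this is what fixes the free
parameter totals:

```{r param-counts}
sapply(c("classic", "CL", "RT", "CL_RT"), function(v)
  c(`2HT` = n_parameters(mptdc_model("2HT", v)),
    SDT = n_parameters(mptdc_model("SDT", v))))
```

A deliberate layout choice: the classic SDT criterion $c_j$ is a free
parameter of its own model and is *not* tied to any particular criterion
of the CL variant fitted to the same data — the variants are distinct
models compared by information criteria, not nested reparameterizations
of one another. Category order within a tree is fixed (response, then
confidence high→low, then fast→slow) so that serialized specifications
(`model_to_json()`) are stable.

## RT discretization

RT bins are set per subject by the log-normal approximation: log the RTs,
take the mean and SD of the logs, place cutoffs at the equal-probability
normal quantiles, and exponentiate back. With two bins the cutoff is the
geometric mean $\exp(\overline{\log rt})$. Ties at a cutoff go to the
faster bin (an RT must *exceed* the cutoff to be slow). Cutoffs pool all
of a subject's analyzed trials across conditions and stimulus classes —
one criterion per subject. More than two bins are supported by the same
quantile construction, but two is the validated default: with three bins
the per-cell counts at realistic trial numbers become so sparse that the
observed information matrix is frequently singular and SEs undefined.

## Estimation and fit assessment

Fitting maximizes the multinomial likelihood kernel
$\sum_k n_k \log p_k(\theta)$ summed over trees. The optimizer
(`nlminb`) works in transformed coordinates — log-odds for probability
parameters, log for $\sigma$ and the $\Delta c$ increments (which also
enforces criterion ordering), identity for $d'$ and base criteria — from
one deterministic mid-range start plus random restarts (default 10).
Transformed coordinates are boxed (e.g. $\pm 16$ on the log-odds scale)
so estimates remain finite; an estimate at such a box edge is a boundary
solution. Standard errors are delta-method transforms of the inverse
observed information computed at the optimum in transformed space, and
are reported `NA` when the information matrix is singular or the
estimate sits on a bound — the realistic failure mode with sparse
bins rather than an exception.

Fit statistics are Pearson $\chi^2$ and the likelihood-ratio $G^2$
against the fitted expected counts, with
$df = \sum_{trees}(\text{categories}-1) - p$. Because the extended
variants routinely produce cells with small expectations, the package's
goodness-of-fit decision is a parametric bootstrap: simulate $B$
datasets from the fitted parameters holding the observed per-tree totals
fixed, refit each (warm-started at the original solution), and reject
when the observed $\chi^2$ exceeds the empirical $(1-\alpha)$ quantile
— taken as the order statistic at $\lceil (1-\alpha) m \rceil$ of the
$m$ successful refits, a conservative convention; failed refits are
excluded and counted. Model comparison uses
$AICc = AIC + 2p(p+1)/(n-p-1)$ with $n$ the subject's total trial
count (the trial count, not the cell count, keeps the correction
comparable across variants that re-bin the same trials). The
multinomial constant is omitted from the log-likelihood throughout; AIC
*differences*, the quantity model selection uses, are unaffected.
Per-subject winners across two comparisons are crossed into 2×2 tables
tested by the uncorrected Pearson independence $\chi^2$ with effect size
$\phi = \sqrt{\chi^2/N}$; no continuity correction is applied because
the package's reproduction checks of published crosstab statistics match
the uncorrected statistic.

## What the simulator emulates

`simulation_design()` mirrors the generating paradigm: three test blocks
with target proportions .35/.50/.65 of 100 trials each, so a block
contributes $100 \cdot tp$ old-item and $100(1-tp)$ new-item trials
(`trials_per_tree` overrides this, e.g. a balanced 100 per tree for
methodological studies). One global seed spawns per-subject child seeds,
making each subject independently reproducible. Counts are drawn
per tree from the model's multinomial. Trial-level simulation
(`simulate_trials()`) instead samples a latent branch per trial and
emits a continuous RT from a per-branch-class log-normal — consistent
with the log-normal binning approximation — so the full pipeline
(trials → binning → aggregation → fitting) can be exercised; the
RT-variant's $H$ estimates then reflect each class's mass below the
pooled geometric mean.

Default generating values (`reference_params()`) are mid-range choices a
recognition experiment plausibly produces: moderate detection
$do = dn = .6$ with guessing tracking target proportion
$g = (.3, .5, .7)$; $d' = 1.5$ with old-item $\sigma = 1.3$ (old-item
variance above 1, the usual finding); confidence mass concentrated on
high confidence in detection states and flatter under guessing; and
detection responses faster than guesses ($H \approx .7$ vs $.4$).
These were fixed once from the above considerations and are
configuration, not tuning knobs.

What the simulator does *not* emulate: subject-level parameter
heterogeneity (every simulated subject shares the generating values),
sequential effects, RT contamination (anticipations, lapses), and
deadline censoring. Passing recovery tests therefore demonstrate that
the estimator is consistent and approximately calibrated under the
model's own assumptions at realistic trial counts — not that real
recognition data satisfy those assumptions.

## Numerical choices and degenerate inputs

* Branch products are evaluated as `exp(M %*% log v)` over a compiled
  term-incidence matrix; zero terms are floored at `1e-300` so structural
  zeros survive the log path exactly (mass below `1e-300` is zero).
* Criterion increments are strictly positive under the log transform;
  a fitted increment below `1e-5` is treated as a boundary solution.
* `Inf` likelihood (observed count in a zero-probability cell) is
  handled by assigning a large finite penalty inside the optimizer.
* Empty trees are rejected before fitting; zero-count cells are allowed
  and contribute nothing to $\chi^2$ when their expectation is 0.
* Exact AICc ties are reported as ties, never broken arbitrarily.
* Constant RTs give a valid geometric-mean cutoff for two bins but no
  distinct quantiles for more; that degenerate case errors.

## Problem sizes in the test suite

The packaged checks run at the sizes the statistical claims are stated
for: parameter recovery uses 200 simulated subjects per variant at 100
trials per tree (mean estimates within 3 Monte-Carlo SEs of truth;
pooled 95%-interval coverage in [.90, .99]); bootstrap calibration uses
100 subjects with $B = 200$ replicates (rejection rate in [.01, .12] at
$\alpha = .05$); recovery direction uses 100 subjects per generator with
shared seeds. Bootstrap refits and recovery fits use 2 optimizer starts
(the warm/default start plus one random restart), which the restart
stability tests justify for well-conditioned simulated data. The
`scripts/acceptance.R` summary re-runs the stochastic studies at 40
subjects with $B = 100$, sizes chosen to keep a single-CPU re-run short
while leaving the binomial noise on the reported proportions small
relative to the effects of interest.

Two statistical properties of ML at these trial counts are worth
stating plainly, because the recovery checks measure them. First, with
only ~600 trials per subject the classic variants are nearly saturated
(one residual degree of freedom), and maximum likelihood carries a
finite-sample bias of a few hundredths on some parameters (for example
the detect-new probability and SDT base criteria); with enough simulated
subjects the Monte-Carlo band around the subject-mean becomes narrower
than that bias, so mean-unbiasedness fails even though the estimator is
consistent and exact on expected counts. Second, the unequal-variance
SDT likelihood has no interior maximum for a small fraction (~1%) of
datasets generated at these conditions — whenever the empirical z-ROC
slope is non-negative the fitted $\sigma$ diverges — so those subjects'
estimates sit on the optimizer box and standard errors are flagged
undefined. Both are properties of the models at this design size, not of
the implementation; users averaging estimates across subjects should
inspect boundary flags first.

## Known limitations

* No hierarchical (random-effects) extension; subjects are fitted
  independently, as in the individual-fit analyses the package targets.
* The parametric route to RT modeling (ex-Gaussian branch distributions)
  is out of scope; RT information enters only through bins.
* Guessing bias is shared between old- and new-item trees ($g$ and
  $1-g$); the alternative with separate biases is not implemented.
* Three or more RT bins are constructible but frequently yield singular
  information matrices at realistic trial counts; the package flags
  rather than repairs this.
* AICc's $n$ is taken as the subject's trial total; with very few trials
  per tree other conventions (cell counts) would differ noticeably.
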