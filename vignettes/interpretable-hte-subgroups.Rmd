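---
title: "Interpretable treatment-effect subgroups: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpretable treatment-effect subgroups: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(upliftrules)
```

## The problem

Randomized trials frequently read out neutral: the average treatment effect
over the enrolled population is indistinguishable from zero even though some
subpopulation may respond. `upliftrules` addresses the question *which
covariate-defined subgroups respond*, under three constraints that shape
every design decision here: the answer must be **interpretable** (a short
conjunction of thresholds a clinician can read), the trial is **small**
(hundreds of subjects, so external and synthetic data are worth borrowing),
and the outcome is **binary** (e.g. a dichotomized disability score, where
functional independence — mRS ≤ 2 — is coded Y = 1, so responsive subgroups
have a positive effect).

Under the potential-outcome framework with randomized assignment, the
heterogeneous treatment effect (HTE) is the conditional risk difference

τ(x) = E[Y | X = x, T = 1] − E[Y | X = x, T = 0].

## The estimation pipeline

**1. Uplift forest.** Trees recursively partition the covariate space to
maximize the divergence between arm outcome distributions. For a candidate
split of node *w* into children *w_L*, *w_R*, the gain is

(n_L/n)·KL(p_t^L ‖ p_c^L) + (n_R/n)·KL(p_t^R ‖ p_c^R) − KL(p_t ‖ p_c),

where p_t, p_c are the arm success rates and KL is the binary
Kullback–Leibler divergence with natural logarithm. Each leaf estimates τ as
the unsmoothed rate difference; the forest estimate is the uniform average
over bootstrapped trees (n-out-of-n, stratified by arm).

Numerical choices the criterion leaves open, fixed here:

* *Rate smoothing.* KL is undefined at 0 or 1, so all KL inputs use
  Jeffreys add-½ smoothing, p = (s + ½)/(n + 1). This keeps gains finite at
  empty outcome cells while perturbing a 100-subject node's rate by < 0.5%.
  Leaf τ estimates stay unsmoothed.
* *Candidate splits.* Continuous features offer up to k = 10 in-node
  empirical quantile thresholds (probabilities i/(k+1), type-7 quantiles);
  binary features one threshold; categorical features one-vs-rest level
  splits. A candidate that empties either arm of either child is rejected.
* *Tie-breaking.* Equal-gain splits resolve to the lowest schema feature
  index, then the smallest threshold, making trees a deterministic function
  of (data, seed).
* *Stopping.* Depth ≤ 3 (so printed rules interact at most a handful of
  features and stay readable), plus minimum node size 100, minimum treated
  count 25, and strictly positive gain. The minimums are configurable; the
  defaults suit trials in the 500–2000 subject range.
* *No gain normalization.* Some uplift-tree variants divide the gain by an
  entropy penalty; the criterion implemented here is the bare KL difference.
* *Unseen categorical levels* at prediction time are routed to the child
  with more training samples.

**2. Rule extraction.** Every non-root node of every tree defines a rule:
the conjunction of split conditions from the root. Nodes whose 2×2
arm-by-outcome Pearson chi-square (1 df, no continuity correction) has
p < 0.05 are retained; same-feature conditions merge into intervals
(`DBP >= 70 and DBP < 147`), and exact duplicates collapse keeping first
provenance. Note a selection subtlety: splits are *chosen* to maximize arm
divergence, so chi-square statistics at selected nodes are biased upward
relative to a node chosen at random — the test is a screening device, not a
calibrated inference, and the package's calibration checks therefore use
randomly partitioned nodes.

**3. Complementary selection.** With the forest estimate τ̂(X) as a
pseudo-label, an L1-penalized linear model is fit on the rule indicators
plus the raw features:

minimize Σᵢ (τ̂(xᵢ) − [Σₘ aₘΠₘ(xᵢ) + Σ_d b_d x_{id} + c])² + λ·Σ(|aₘ|+|b_d|),

by cyclic coordinate descent with an unpenalized intercept. Continuous
linear terms are z-scored internally and coefficients reported on the
original scale. λ defaults to 4-fold cross-validation on the pseudo-label
regression MSE; the pseudo-label is the out-of-bag forest estimate where a
subject has out-of-bag trees (every in-bag subject falls back to the full
forest), which decouples the regression target from the rules the same tree
generated. Rules are ranked by the rule-ensemble importance
I_m = |a_m|·√(s_m(1−s_m)) (s_m the training support fraction) — the absolute
coefficient scaled by the indicator's standard deviation — and reported top-k
per coefficient sign, with within-subgroup ATEs (risk difference with
binomial standard error) on held-out data.

## Data augmentation

Small trials can be enlarged in two ways, both re-balanced by propensity
matching because each one breaks randomization:

* **Historical controls**: an external control-only pool is filtered by the
  trial's eligibility criteria; an elastic-net logistic model of treatment
  on covariates (fit on trial + pool) supplies propensity scores; pool
  controls are matched 1:1 to the trial's *treated* subjects.
* **Synthetic subjects**: a generator fit on all real data draws new rows
  (default 500 per arm). Synthetic controls are matched to real treated
  subjects and synthetic treated to the real control side, with a fresh
  propensity model per stage.

Matching is greedy 1:1 without replacement on the *logit* of the propensity
score, iterating the real side in descending score order, with a caliper of
0.2 pooled logit SDs. The conventional logit scale is used because the
caliper literature defines it there; order and replacement policy are fixed
for determinism. Unmatched *real* subjects are always kept — augmentation
may only add comparable rows, never discard trial data — and augmented rows
are used in training only, never in evaluation. If the propensity model
degenerates to constant scores (an intercept-only elastic net, which happens
precisely when the two groups are indistinguishable), the workflow pairs
subjects in order at distance zero rather than failing, since every pairing
is then equally good.

Diagnostics: standardized mean differences per feature (pooled-SD
denominator; < 0.1 is conventionally balanced), the in-sample AUC of a fresh
propensity model for discriminating arms (in-sample on purpose — this is a
balance diagnostic, not a generalization claim), and per-variable
real-vs-synthetic similarity (1 − KS statistic for continuous variables,
1 − total-variation distance for categorical ones).

The built-in generator is a deliberately simple smoothed bootstrap:
resampling within (T, Y) cells with Gaussian jitter at Silverman's bandwidth
on continuous features and within-cell resampling of categoricals. The
framework's claims are generator-agnostic, so deep tabular generators (GANs,
VAEs) plug in behind the same fit/sample interface; the baseline keeps the
pipeline self-contained, deterministic given a seed, and honest about what
it is — it interpolates the real data and cannot invent genuinely new modes.

## Evaluation

Ranking quality uses the **Qini coefficient**: subjects sorted by predicted
uplift (ties as one block), cumulative incremental gain
g = Σy_t − Σy_c·(n_t/n_c) per prefix, curve g/n against the prefix
fraction, coefficient = trapezoidal area between curve and the random
diagonal. A constant score gives exactly zero; the coefficient is invariant
to monotone transforms of the scores. The exact construction (prefix
formula, tie grouping, normalization by total subject count) is fixed as
stated; published absolute values may differ from other Qini conventions by
a constant factor, so all internal comparisons use this one construction.
Held-out evaluation always uses real randomized subjects only.

## The simulation fixture

The simulator generates what the framework assumes: a randomized trial
(T ~ Bernoulli(0.5) independent of X) plus a confounded control-only pool,
with planted rule-defined subgroups. Outcomes follow
P(Y=1|X,T) = plogis(β₀ + βᵀX + T·δ(X)), δ(X) summing the planted logit
effects; planting on the logit scale keeps probabilities proper, and the
ground-truth risk difference is computed analytically, not sampled.

Default conditions, chosen once: 800 randomized subjects; 4 continuous
covariates (equicorrelated Gaussians, ρ = 0.2) and 2 categoricals; a
favorable two-feature rule `x1 >= -1 and x2 < 1.5` (support ≈ 0.79,
mirroring the high-support two-threshold blood-pressure subgroups such
analyses report) with logit effect +1.0, and an unfavorable rule `x1 < -1`
on the complementary boundary with effect −1.5 — subgroup risk differences
of roughly +0.2 and −0.3, sized so that an 800-subject trial has realistic
power to recover them; a 2000-subject pool with a 0.5 SD confounding shift
on x1 and x2. What the fixture does **not** emulate: real marginal
distributions, missingness, measurement error, or effect gradients that are
not rule-shaped. Passing tests show the machinery recovers planted
rule-shaped heterogeneity under randomization; they do not certify behavior
under hidden confounding or smooth effect surfaces.

Problem sizes used by the validation suite — 100-tree forests, 30-seed
repetitions, 200-node split oracles, exhaustive Qini permutations at n ≤ 6 —
are chosen so the whole suite runs on a single desk CPU in minutes while
keeping seed-majority claims statistically meaningful.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)           # default planted fixture
sim <- simulate_rct(cfg)
forest <- grow_forest(sim$data, forest_params(n_trees = 100, seed = 1))
tau_hat <- predict_tau(forest, sim$data, oob = TRUE)
rules <- extract_rules(forest, alpha = 0.05, reference = sim$data)
model <- fit_rule_model(tau_hat, rules, sim$data, seed = 1)
rank_and_select(model, ds_test = sim$data)
```

## Known limitations

* The chi-square screen is anti-conservative at gain-maximized nodes (see
  above); treat retained rules as candidates, not confirmatory findings.
* Greedy matching is order-dependent and not optimal; optimal or full
  matching is out of scope.
* The lasso's pseudo-label regression inherits the forest's biases; it
  re-describes τ̂, it does not re-estimate τ.
* The exact *order* at the top of the importance ranking is unstable across
  seeds: near-duplicate rule variants share the L1 coefficient mass, and
  the √(s(1−s)) weight favors mid-support truncations of a broad subgroup,
  so the single top-ranked rule can be a noise-narrowed subset of the true
  one even when a near-exact variant sits immediately below it. Read the
  reported rule set as a family describing one subgroup, not as five
  independent findings — the published analyses this mirrors show the same
  redundancy in their top rules.
* Borrowed and synthetic data can only balance *observed* covariates;
  hidden confounding in the external pool propagates silently.
* The smoothed-bootstrap generator underestimates tail behavior and cannot
  extrapolate beyond the convex hull of the real data.
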