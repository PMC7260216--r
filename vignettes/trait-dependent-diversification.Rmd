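---
title: "Trait-dependent diversification: models, simulation and attribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait-dependent diversification: models, simulation and attribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefdiv)
```

# The scientific problem

Speciation rates vary enormously across the tree of life, and a central
question in macroevolution is how much of that variation is explained by
what species *are* — their diet, their body size — versus where they
live. `reefdiv` implements a complete, testable workflow for this
question on time-calibrated phylogenies, motivated by the biology of
reef fishes and their six classical trophic guilds (generalized
carnivores GC, mobile invertivores MI, omnivores OM, planktivores PK,
sessile invertivores SI, herbivores/detritivores HD):

1. estimate recent ("tip") speciation rates with the DR statistic and
   pool them across a set of trees;
2. attribute tip-rate variation to ecological and geographical
   predictors with a bootstrapped gradient-boosting protocol;
3. estimate guild-dependent speciation, extinction and transition rates
   historically, over the whole tree, with a multi-state
   speciation-extinction (MuSSE) model, by maximum likelihood and MCMC,
   with a hidden-regime (HiSSE-style) extension;
4. quantify the directionality of guild transitions with
   ancestral-state-conditioned stochastic character maps.

Because the real inputs of such a study (a global chronogram, trait
databases, occurrence grids) are large external downloads, the package
is built around a first-class synthetic-data module: trees are grown
forward in time under a k-state birth-death process whose true
character history is recorded, and trait tables are generated with a
known rate-generating function. Every downstream method can therefore
be validated against a known truth, which is exactly what the test
suite does.

# The multi-state birth-death model

A lineage in character state $i$ speciates at rate $\lambda_i$, goes
extinct at rate $\mu_i$, and moves to state $j$ at rate $q_{ij}$ (all
per Myr). Net diversification is $r_i = \lambda_i - \mu_i$. The MuSSE
likelihood of tip data on a rooted binary tree integrates, along every
branch (tipward to rootward), the coupled ODEs

$$\frac{dE_i}{dt} = \mu_i - (\lambda_i + \mu_i + \textstyle\sum_{j \ne i} q_{ij}) E_i
  + \lambda_i E_i^2 + \textstyle\sum_{j \ne i} q_{ij} E_j$$

$$\frac{dD_i}{dt} = -(\lambda_i + \mu_i + \textstyle\sum_{j \ne i} q_{ij}) D_i
  + 2 \lambda_i E_i D_i + \textstyle\sum_{j \ne i} q_{ij} D_j$$

where $E_i(t)$ is the probability that a lineage in state $i$ at time
$t$ before the present leaves no sampled descendants, and $D_i(t)$ is
the likelihood of the observed subtree data. At an interior node the
daughters merge as $D_i \leftarrow \lambda_i D_i^{L} D_i^{R}$.
Integration uses a Dormand–Prince 5(4) adaptive stepper implemented in
C++ (relative tolerance `1e-8` by default), with per-branch
renormalisation of $D$ and an accumulated log scaler so thousand-tip
trees do not underflow. Tips contribute indicator vectors over their
admissible states, which is also how missing data and hidden-state
expansions enter; sampling is assumed complete.

## Root treatment and conditioning

Two conventions matter numerically and are exposed in `sse_options()`:

* `root_mode`: `"fitzjohn"` (default) weights root states by their
  share of the root partial likelihood; `"flat"` uses $1/k$; `"given"`
  takes user probabilities. Published analyses rarely state whether
  they conditioned on survival; conditioning
  (`condition_survival = TRUE`, dividing by
  $\sum_i \pi_i \lambda_i (1-E_i)^2$) is the default here and can be
  switched off.
* a degenerate corner: with $\lambda \equiv 0$ the per-node factors
  annihilate the likelihood, so tests of the pure-character limit
  compare likelihood *ratios* across tip configurations (the
  $\lambda$ factors cancel), with $\lambda = 10^{-8}$, a flat root and
  no conditioning.

## Fitting, tying and the hidden-regime extension

`musse_ml()` maximises the likelihood on the log scale (L-BFGS-B with
restarts; a fit is flagged, not errored, if a restart still improves
the log-likelihood by more than `1e-4`). Every entry of the full
parameter vector `c(lam, mu, q_offdiag)` can be tied to a shared free
parameter or pinned to a constant through `par_map`/`fixed`. The
hidden-regime models are nothing but this machinery on an expanded
state space: `hidden_spec(n_observed, n_hidden)` splits each observed
state into hidden regimes, `expand_hidden()` makes each tip ambiguous
over its hidden copies, and two stock tying schemes implement the usual
comparison — `"unconstrained"` (rates differ between observed states,
one hidden regime per state) against `"cid"` (rates differ only between
hidden regimes). Simultaneous observed-and-hidden changes get rate 0;
observed-state transitions are shared across hidden layers; hidden
switches happen at one common rate.

`musse_mcmc()` samples the posterior under independent exponential
priors. The default sampler is univariate slice sampling with stepping
out — essentially tuning-free, with widths set from a preliminary run
(default 100 generations), mirroring common practice; a random-walk
Metropolis kernel is available for comparison. Defaults follow the
workflow the package emulates: 2000 main generations, 10% burn-in,
effective sample sizes reported per parameter with a warning below
200. The default prior rate is $1/(2\hat r)$ with $\hat r$ a tree-wide
Yule-type rate estimate, the standard working heuristic when no prior
information is available. Draw sets from several trees are pooled by
concatenation (`pool_and_summarize()`), and net diversification
$r_i = \lambda_i - \mu_i$ is derived per draw; summaries report the
kernel-density mode and central credibility intervals, matching how
such posteriors are usually displayed.

# Ancestral states and stochastic maps

`marginal_asr()` computes, for every node, the probability of each
state as the full-tree likelihood with that node clamped, renormalised
over states. The implementation caches the pruning partials and
re-propagates only the node-to-root path — mathematically identical to
brute-force clamp-and-recompute (the test oracle) but linear in tree
size.

`sample_histories()` reproduces a "marginals as input" mapping
protocol: node states are drawn top-down, the root from its marginal
and every child from its marginal re-weighted by the parent-to-child
branch transition probability (the row of $e^{Qt}$); each branch path
is then drawn conditioned on its endpoints by uniformization (a
dominating Poisson process with bridge-sampled jumps), which has
bounded runtime even for improbable endpoint pairs. Because the
marginals come from the state-dependent model, diversification-rate
heterogeneity informs the node states; the along-branch process uses
$Q$ alone, a known approximation shared with the standard mapping
tools this protocol modifies. The textbook joint top-down sampler is
available behind `method = "joint"` for comparison. There is no single
canonical way to reconcile marginals with branch-transition
feasibility; the re-weighting above is this package's declared choice,
and endpoint pairs with zero probability trigger bounded
resampling and then an explicit error naming the edge.

`count_transitions()` averages $i \to j$ segment boundaries across maps
(and trees), and `chord_table()` emits the long-format from/to table
behind chord-diagram figures.

# The synthetic-data generator

`simulate_mbd_tree()` is an exact Gillespie simulation (exponential
waiting times; no time discretisation). Design choices:

* **Crown start by default** (two lineages in the root state), because
  SSE likelihoods condition on the crown; a stem option exists and
  returns the pre-speciation stem as a root edge with its own history.
* **Stopping**: `max_time` keeps extinct outcomes (needed for honest
  birth-death expectations); `n_extant` stops at the first instant the
  extant count reaches the target and retries (capped, default 1000)
  on extinction. Stopping at the hitting time leaves the newest cherry
  with zero-length pendants and slightly favours trees that speciate
  early; this mild bias is accepted for test fixtures and documented
  here.
* The full pre-pruning tree, the segment-by-segment true history and
  exact transition counts are returned, giving downstream stages a
  ground truth.

`simulate_trait_table()` draws the ten-predictor table. Only guild and
body size carry rate signal (`rate_fn(guild, size)` times gamma noise
with mean 1); the geographical columns are independent draws from
documented distributions (range: shifted negative binomial, mean ~60
cells; absolute latitude: half-normal, sd 12°, capped at 60°; distance
to the Indo-Australian Archipelago: lognormal around 6000 km; SST:
normal 27 ± 2 °C; productivity: lognormal around 500). Real occurrence
data have strong spatial covariance among these variables; the
generator deliberately does not emulate that, because the attribution
tests need controllable signal and noise. Passing tests therefore
demonstrate correct *method* behaviour, not robustness to collinear
real-world geography.

# The attribution stage

The response is the per-tip rate (median-pooled across trees when the
trees share tips); the model is a gradient-boosted tree ensemble with a
gamma deviance objective, appropriate for strictly positive,
right-skewed rates. The protocol is:

* **two-step tuning** — a systematic sweep over learning rate, depth,
  minimum split loss and subsampling (default grid
  0.01–0.3 × 2–8 × 0–5 × 0.5–1, a conventional grid since the original
  one is unstated), then 1000 uniform redraws within ±10% of the
  stage-1 best, scored by held-out rmse;
* **1000 × 80/20 cross-validation** — accuracy is the signed mean
  bias (observed − predicted), reported raw and as % of the mean
  response (reported bias figures are often ambiguous between the two
  units, so both are emitted); precision is the R² between measured and predicted rates;
* **1000 bootstrap refits** for gain-based relative importance
  (one-hot dummies are aggregated back to their source variable;
  encoding is recorded because attribution differs across encodings),
  prediction profiles per guild (and per guild × size with other
  covariates held at mean/mode), and per-size-class effects (guild
  median minus global median within < 10 cm, 10–30 cm, > 30 cm).

The chance-expectation line is 100/p % for p predictors — the uniform
benchmark — and is configurable; a permutation-null alternative can be
obtained by permuting a column and re-running, which is also what a
test does. Bootstrap resampling treats species rows as exchangeable;
phylogenetic non-independence is *not* corrected, mirroring the
protocol this stage implements — a caveat to keep in mind for real
data. Row filters (`run_config(filter = ...)`) rerun the identical
protocol on subsets, which is how family-level sensitivity analyses
are expressed.

# Pipeline, reproducibility and problem sizes

`run_pipeline()` chains simulate → DR → traits → boosting → MuSSE
ML/MCMC → ASR → maps → transition tables, writes every stage's files
plus a manifest (config echo, package version, md5 per file, per-stage
wall clock), and is bit-reproducible from a single master seed: each
stage derives a child seed by hashing the stage name
(`derive_seed()`), so stages can be re-run independently.

One structural point deserves emphasis. Empirical tree ensembles
usually share their tip set (the trees differ only in where imputed
tips attach), so per-tip medians across trees are natural there. Independent
simulated trees do not share tips; the pipeline therefore stacks
per-tree rows (tip × tree, with that tree's DR rate and trait draws)
for the attribution stage and uses `pool_median()` only when label
sets coincide. This is the package's resolution of an acknowledged
mismatch between the tree-ensemble semantics of the original data and
an independent-replicates simulator.

Numerical and study-size choices used by the test suite (chosen once,
as desk-scale study sizes):

* likelihood oracle checks run on ≤ 5-tip fixtures; Euler oracle step
  2.5e-4;
* parameter recovery uses 20 replicate 500-tip trees at
  $\lambda = (0.1, 0.2)$, $\mu = (0.03, 0.03)$, $q = 0.01$; chains run
  400 generations after a 50-generation tuning run — slice sampling
  has near-zero autocorrelation here, so this yields effective sizes
  in the hundreds, ample for a 95%-interval calibration check;
* mapping recovery uses 20 trees × 10 maps at $\mu = 0$ (so the pruned
  tree carries the entire true history and mapped counts are
  commensurable with recorded truth);
* the attribution criteria use n = 2000 species and 200 bootstraps;
* the end-to-end discrimination study uses 10 trees × 200 tips with
  the HD speciation rate twice the GC rate.

# Known limitations

* DR estimates recent *speciation*, not net diversification; output is
  labelled accordingly, and externally computed rates (e.g. from
  Bayesian rate-shift programs) can be substituted via
  `read_tip_rates()` in the same schema. On Yule trees the tip-mean DR
  overshoots $\lambda$ by roughly a third (young cherries dominate the
  mean) while the tip-median tracks it within ~15%; the tests encode
  exactly this oracle-verified behaviour.
* Complete sampling is assumed throughout; there is no
  incomplete-sampling correction, no time-dependent rates, and no
  geographic or quantitative-trait SSE variants.
* Along-branch path sampling ignores state-dependent birth/death
  within a branch (see above).
* The simulator's trait table draws geography independently; tests on
  it say nothing about collinearity-induced attribution artefacts in
  real data.
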