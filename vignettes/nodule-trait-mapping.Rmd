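---
title: "Mapping the loss of root-nodule symbiosis: model, methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping the loss of root-nodule symbiosis: model, methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noduleTrace)
```

# The question and the model

Root-nodule symbiosis in legumes comes in two anatomies: fixation-thread
nodules (FT), in which bacteroids stay enclosed in cell-wall-bound
threads, and symbiosome nodules (SYM), in which bacteroids are released
into membrane-bound compartments inside host cells. Many lineages have
lost nodulation altogether (NON). `noduleTrace` infers how these three
states evolved on a time-calibrated phylogeny (a chronogram, branch
lengths in millions of years, Myr).

The character evolves under a three-state continuous-time Markov chain
(CTMC) with rate matrix $Q$, where $q_{ij}$ ($i \ne j$) is the
instantaneous rate of change from state $i$ to $j$ per Myr and
$q_{ii} = -\sum_{j \ne i} q_{ij}$. The default, *constrained* model
encodes the working hypothesis that symbiosome nodules evolve from
fixation-thread nodules and that loss is irreversible:

* allowed: FT → NON, FT → SYM, SYM → NON;
* forbidden: everything out of NON (absorbing), and SYM → FT;
* root state fixed to FT (prior mass 1 on FT).

`constrainedMask()` builds this mask; `allTransitionsMask()` gives the
unconstrained 6-rate alternative for sensitivity analysis, and
`transitionModel()` accepts any mask/rate combination. Rates are in
events per lineage per Myr.

Tip data are observation categories, not states: `FT`, `SYM`,
`nonnodulating`, `nodulating_unknown_type` (nodulates, anatomy
unscored: likelihood 1 on both FT and SYM) and `unknown` (likelihood 1
on all three states). The category-to-likelihood map is configurable
(`categoryVectors`) so scoring assumptions can themselves be varied.

# Likelihood and rate estimation

`pruneLoglik()` computes the tip-data likelihood by Felsenstein's
pruning algorithm: a postorder pass propagating conditional likelihood
vectors, with per-node rescaling to prevent underflow on long trees.
Branch transition probabilities $P(t) = e^{Qt}$ use the Armadillo
matrix exponential (scaling-and-squaring); both the exponential and the
pruning pass are implemented in C++, and the per-edge $P(t)$ matrices
are computed once per model evaluation.

`fitRates()` maximizes the likelihood over the allowed rates with
L-BFGS-B on log-rates, bounds $[10^{-8}, 10]$ per rate. Because the
surface can be multimodal, it runs five random starts plus a
deterministic start at $1/\text{tree height}$, keeps the best, and
records all starts, convergence codes and the final gradient norm in
the fit report.

Two identifiability remarks:

* If every tip is `unknown`, the likelihood is constant and
  `fitRates()` refuses to fit rather than return an arbitrary point.
* If no lineage ever visits SYM on the maximum-likelihood path (for
  example, all tips FT), the SYM → NON rate does not enter the
  likelihood and is *unidentifiable* — its fitted value is meaningless
  rather than "small". Downstream summaries that depend on it should
  not be read in that situation.

# Stochastic character mapping

`stochasticMaps()` draws full trait histories — states at every node
plus timed changes along every branch — from their exact distribution
conditional on the tips, the model and the root prior. Each history is
produced in two exact steps:

1. **Joint node states.** After a pruning pass, a preorder sweep samples
   the root from (root prior × root partial likelihood) and each child
   from (its branch's $P(t)$ row given the parent draw × the child's
   partial likelihood). This is a joint draw, not a per-node marginal.
2. **Endpoint-conditioned paths by uniformization.** Each branch's path
   given its endpoint states is sampled by uniformization: the CTMC is
   represented as a Poisson($\mu t$) number of jumps of the discrete
   chain $R = I + Q/\mu$ with $\mu = 1.05 \max_i |q_{ii}|$ (5%
   headroom above the minimum dominating rate). The jump count $n$ is
   drawn with weight $\text{Poisson}(n; \mu t) \, R^n[a,b]$, truncated
   at $n_{\max} = \text{qpois}(1 - 10^{-12}, \mu t) + 5$; jump states
   are then sampled backward-consistently and jump times are uniform
   order statistics on the branch. Virtual (self) jumps are removed.
   This is exact — no discretization and no rejection.

**Reproducibility.** Each history $h$ is drawn under its own substream
seed derived deterministically from the master seed, so history $h$ is
bit-identical whether 1 or 500 histories are requested, and a whole run
is byte-reproducible from one seed. (A finer-grained alternative —
counter-based streams keyed by history *and branch* — would also make
histories invariant under tree re-traversal, but R's RNG has no native
counter streams; fixed-order traversal inside a per-history substream
achieves the same reproducibility guarantees for this package's API.)

# Summaries

`summarizeHistories()` condenses a `MappedHistorySet` into:

* **Node-state proportions** (`nodeStateFrequencies()`): per node, the
  fraction of histories in each state — the numbers behind node "pies".
* **Majority-rule transitions** (`majorityTransitions()`): each node
  takes its modal state; every branch whose parent and child modal
  states differ yields one transition. Sister branches count
  separately, so an FT parent with two NON children is two losses (a
  "double loss"). Nodes whose top two proportions tie are flagged
  ambiguous and their branches reported unresolved, never guessed.
* **Event-count distributions** (`eventCountDistribution()`): per
  transition class, the distribution across histories of realized event
  counts.
* **Loss rates per Myr** (`lossRates()`), in two deliberately separate
  readings: the instantaneous $Q$ entries of the fitted model (the
  primary, model-based reading) and realized per-history rates (events
  divided by dwelling time in the source state, with mean and
  2.5/97.5 percentiles). Histories with zero dwelling time in a source
  state are excluded from that class with a logged count.
* **Transition age bounds** (`transitionAgeBounds()`): a transition on
  a branch happened between the parent's age (maximum) and the child's
  age (minimum); per class the span of maximum ages is reported.

# Synthetic data

`syntheticScenario()` + `makeBenchmark()` generate fully scored test
problems: a birth–death chronogram conditioned on the number of extant
tips (via `ape::rphylo`, which conditions exactly — a rejection
simulator would duplicate an established tool), a forward-simulated
trait history from a chosen root state, and observation masking
(`maskObservations()`): a fraction `pUnknown` of tips become `unknown`
and, of the remaining nodulators, a fraction `pTypeUnknown` become
`nodulating_unknown_type`. Nonnodulating tips are never type-masked
(there is no type to hide). Truth (events and node states) is recorded
*before* masking.

The defaults (150 tips, 60 Myr, loss rates 0.0174 and 0.0028 /Myr,
gain rate 0.002 /Myr, 15% unknown, 30% type-unknown) are study
conditions, not tuning knobs: they describe a realistic, hard problem.
Tests that pass on synthetic data show the machinery is internally
correct (likelihoods match enumeration, samplers match exact
conditionals, truth is recovered when signal is strong); they do *not*
show that any particular empirical dataset identifies the rates well.

# Numerical choices

* Chronograms must be ultrametric within `tol = 1e-3` (relative to tree
  height); tip ages are then snapped to 0.
* Pruning uses per-node rescaling; log-likelihoods match full
  enumeration to better than $10^{-10}$ on enumerable trees.
* Dwelling times are conserved exactly: per history they sum to the
  total tree length within $10^{-9}$.
* All derived seeds are kept below $2^{31}$; repeated runs under one
  seed are byte-identical through to written output files.

# Limitations

* **Estimator dispersion.** Tips share deep branches, so a 300-tip tree
  carries far fewer than 300 independent draws about the rates. Under
  the constrained model a single early FT → SYM event (or its absence)
  dominates all information about SYM rates; replicates whose tip set
  is degenerate (no SYM tips, or all NON) push the MLE to a bound. In
  simulation at the study's rate magnitudes, individual rates land
  within ±50% of truth in only 50–75% of 300-tip replicates even though
  the fits are verifiably exact MLEs. Treat fitted rates as
  order-of-magnitude quantities with simulation-calibrated uncertainty,
  not point estimates.
* **Majority-rule placement.** Branch-level summaries can relocate true
  events: a true double loss on a cherry (two sister NON tips) is often
  summarized as a single loss on the stem branch (the
  parsimony-equivalent reading); an event may shift to the adjacent
  parent or child edge when posterior mass is split. Event *counts* per
  class are much more stable than event *placements*.
* **Masked pendant transitions are unrecoverable.** A fully-unknown tip
  below an FT parent is modally FT, so a true pendant loss through it
  cannot appear in a majority-rule summary; likewise a type-masked tip
  hides a fresh pendant FT → SYM gain. This is an identifiability
  fact about the data, not a defect of the summary.

# Problem sizes and cost

Design-point costs on one CPU core: a 300-tip maximum-likelihood fit
(6 starts) takes about 1 s; fitting plus 500 stochastic maps on a
200-tip tree takes well under 1 s of mapping time; the full synthetic
default pipeline (150 tips, fit, 500 maps, summaries, outputs) runs in
a few seconds. The acceptance-style simulation studies (20 replicates
of fit or fit+map) complete in about a minute each.
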