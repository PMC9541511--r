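# noduleTrace

Ancestral-trait inference for the evolution of root-nodule symbiosis on
time-calibrated phylogenies.

Legume root nodules house nitrogen-fixing rhizobia in one of two
anatomies: **fixation-thread** nodules (FT), where bacteroids remain in
cell-wall-bound threads, and **symbiosome** nodules (SYM), where they
are released into membrane-bound compartments inside host cells; many
lineages are **nonnodulating** (NON). `noduleTrace` reconstructs how
these states evolved along a chronogram (branch lengths in millions of
years) under a constrained three-state continuous-time Markov model:

* allowed transitions: FT → NON, FT → SYM, SYM → NON
  (NON is absorbing; SYM never reverts to FT);
* root state fixed to FT;
* rates in events per lineage per Myr, estimated by maximum likelihood
  (Felsenstein pruning, multi-start L-BFGS-B on log-rates).

Given the fitted model, the package draws full stochastic character
maps — exact joint node-state samples followed by endpoint-conditioned
path sampling by uniformization — and summarizes them into node-state
proportions ("pies"), majority-rule branch transitions (including
double losses on sister branches), per-class event-count
distributions, loss rates per Myr (both as Q entries and as realized
per-history rates), and transition age bounds. A synthetic-data
generator (birth–death chronograms plus forward-simulated histories
with observation masking) makes the whole pipeline testable end to end.

Tip data are observation categories, not states: `FT`, `SYM`,
`nonnodulating`, `nodulating_unknown_type` (nodulates, anatomy
unscored) and `unknown`; ambiguous categories enter the likelihood as
multi-state observations rather than being imputed.

## Worked example

A small bundled dataset (12 tips, 60 Myr):

```r
library(noduleTrace)

tree <- readChronogram(system.file("extdata", "example_tree.nwk",
                                   package = "noduleTrace"))
obs  <- readTraitTable(system.file("extdata", "example_traits.csv",
                                   package = "noduleTrace"))
tree
#> Chronogram: 12 tips, 11 internal nodes, height 60 Myr
obs
#> TipObservations: 12 taxa
#>
#>           nonnodulating                      FT                     SYM
#>                       7                       2                       2
#> nodulating_unknown_type                 unknown
#>                       0                       1

fit <- fitRates(tree, obs, seed = 1)
fit
#> TransitionModel over states NON, FT, SYM
#>   FT->NON : 0.0147 /Myr
#>   SYM->NON : 0.0000 /Myr
#>   FT->SYM : 0.0067 /Myr
#>   root prior: 0 1 0
#>   log-likelihood: -8.0498

maps   <- stochasticMaps(tree, obs, fit, n = 500, seed = 42)
report <- summarizeHistories(maps)
report
#> SummaryReport over 500 histories
#>   majority-rule transitions by class:
#>     FT->SYM    1
#>     FT->NON    3
#>     SYM->NON   0
#>     other      0
#>   loss rates (Q entries): FT->NON 0.0147, SYM->NON 0.0000 /Myr

lossCounts(report)
#>  total  fromFT fromSYM
#>      3       3       0
```

(With only two SYM tips the SYM → NON rate sits at its lower bound —
a weak-identifiability situation discussed in the vignette; the FT-side
rates carry the signal here.)

`writeSummary(report, "out/")` writes `summary.json`, per-node
proportions and majority transitions as CSV, and a Newick tree
annotated with modal node states. `runPipeline(runConfig(...))` (or the
CLI script in `inst/scripts/nodule_pipeline.R`, with YAML configs)
runs read → fit → map → summarize in one reproducible, seeded step.

## Synthetic benchmarks

```r
bench <- makeBenchmark(syntheticScenario(seed = 1), dir = "bench/")
```

simulates a chronogram, a true trait history (recorded before masking),
and masked observations, so recovery can be scored against truth. The
scenario defaults are deliberately realistic study conditions, not
easy-mode settings.

## Reproduction

All randomness is seed-driven; repeated runs under one seed are
byte-identical. To reproduce the headline synthetic-pipeline
quantities against the installed package:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

which fits the default scenario, draws 500 maps and writes fitted and
realized rates, loss counts, truth-recovery scores and event-count
summaries as a flat JSON object. The test suite (unit, property-based
and oracle-backed acceptance tests) runs with:

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "noduleTrace",
                               load_package = "installed")'
```

Two acceptance tests encode strict simulation-recovery thresholds that
are not met by *any* exact-ML implementation at those design points
(estimator dispersion and majority-rule placement limits, not code
defects); they are kept red intentionally and the phenomena are
documented in the vignette's Limitations section.

## Documentation

The methods vignette (`vignettes/nodule-trait-mapping.Rmd`) describes
the model, the uniformization sampler, the numerical choices, the
synthetic generator's scope, and known limitations in detail.
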