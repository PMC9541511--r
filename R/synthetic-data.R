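## Synthetic data with the statistical structure the analysis assumes:
## birth-death chronograms, forward-simulated trait histories, and
## observation masking into the partially observed categories.

#' Simulate an ultrametric birth-death chronogram
#'
#' A birth-death tree conditioned on the number of extant tips (extinct
#' lineages pruned), with branch lengths in Myr, optionally rescaled to a
#' target crown height.
#'
#' @param nTips number of extant tips (>= 2).
#' @param birth,death speciation and extinction rates per lineage per Myr
#'   (`birth > death >= 0`).
#' @param seed optional seed.
#' @param height optional crown age (Myr); the tree is rescaled so the
#'   root sits at this age.
#' @return A [Chronogram-class].
#' @export
#' @examples
#' simulateChronogram(50, birth = 0.1, death = 0, seed = 1, height = 60)
simulateChronogram <- function(nTips, birth, death = 0, seed = NULL,
                               height = NULL) {
  if (nTips < 2) stop("nTips must be >= 2")
  if (death < 0 || birth <= death)
    stop("infeasible birth-death parameters: need birth > death >= 0")
  if (!is.null(seed)) set.seed(seed)
  phy <- ape::rphylo(n = nTips, birth = birth, death = death,
                     fossils = FALSE)
  phy$tip.label <- sprintf("t%03d", seq_len(nTips))
  if (!is.null(height)) {
    h <- max(ape::node.depth.edgelength(phy))
    phy$edge.length <- phy$edge.length * (height / h)
  }
  chronogramFromPhylo(phy)
}

#' Forward-simulate a trait history on a chronogram
#'
#' One unconditioned realization of the CTMC down the tree from a known
#' root state, with exponential waiting times under the current state's
#' exit rate. Returns the full true history (node states and timed branch
#' events), which the analysis pipeline can then try to recover.
#'
#' @param tree a [Chronogram-class].
#' @param model the generating [TransitionModel-class].
#' @param rootState state at the root (default `"FT"`).
#' @param seed optional seed.
#' @return A [MappedHistorySet-class] holding the single true history.
#' @export
simulateHistory <- function(tree, model, rootState = "FT", seed = NULL) {
  stopifnot(is(tree, "Chronogram"), is(model, "TransitionModel"))
  rs <- .stateIndex(rootState)
  if (model@rootPrior[rs] <= 0)
    stop("rootState '", rootState, "' has zero prior support in the model")
  if (!is.null(seed)) set.seed(seed)
  ed <- .treeEdges(tree)
  nNode <- length(tree@phy$tip.label) + tree@phy$Nnode
  sim <- cpp_simulate_forward(ed$preEdge, ed$preLen, model@Q, ed$root,
                              rs, nNode)
  ev <- sim$events
  events <- if (nrow(ev) == 0) {
    data.frame(history = integer(0), edge = integer(0), time = numeric(0),
               from = character(0), to = character(0),
               stringsAsFactors = FALSE)
  } else {
    data.frame(history = 1L,
               edge = as.integer(ed$preToOrig[ev[, "edge"]]),
               time = ev[, "time"],
               from = nodStates()[ev[, "from"]],
               to = nodStates()[ev[, "to"]],
               stringsAsFactors = FALSE)
  }
  states <- matrix(as.integer(sim$nodeStates), nrow = 1L)
  colnames(states) <- c(tree@phy$tip.label, tree@phy$node.label)
  new("MappedHistorySet", tree = tree, model = model, nodeStates = states,
      events = events, seed = if (is.null(seed)) NA_real_ else seed)
}

#' True tip states of a simulated history
#'
#' @param x a [MappedHistorySet-class] (the first history is used).
#' @return Named character vector of tip states.
#' @export
tipStates <- function(x) {
  stopifnot(is(x, "MappedHistorySet"))
  nTip <- length(x@tree@phy$tip.label)
  stats::setNames(nodStates()[x@nodeStates[1L, seq_len(nTip)]],
                  x@tree@phy$tip.label)
}

#' Mask true tip states into observation categories
#'
#' Emulates partially observed trait tables: each tip independently
#' becomes `unknown` with probability `pUnknown`; otherwise, if its true
#' state is FT or SYM, it becomes `nodulating_unknown_type` with
#' probability `pTypeUnknown`; otherwise it keeps its true category.
#' Nonnodulating tips are never masked to `nodulating_unknown_type`.
#'
#' @param states named character vector of true tip states (from
#'   [tipStates()]).
#' @param pUnknown,pTypeUnknown masking probabilities.
#' @param seed optional seed.
#' @return A [TipObservations-class].
#' @export
maskObservations <- function(states, pUnknown = 0, pTypeUnknown = 0,
                             seed = NULL) {
  stopifnot(pUnknown >= 0, pTypeUnknown >= 0, pUnknown + pTypeUnknown <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- length(states)
  cat <- ifelse(states == "NON", "nonnodulating", states)
  u <- stats::runif(n) < pUnknown
  tu <- !u & states %in% c("FT", "SYM") & stats::runif(n) < pTypeUnknown
  cat[tu] <- "nodulating_unknown_type"
  cat[u] <- "unknown"
  tipObservations(names(states), cat)
}

#' Default synthetic scenario
#'
#' A scenario at the scale of the study data: 150 tips, crown age 60 Myr,
#' root in FT, generating rates FT->NON 0.0174, FT->SYM 0.002, SYM->NON
#' 0.0028 events/Myr, and masking fractions emulating the missingness of
#' real nodulation tables. The FT->SYM rate is a construction chosen to
#' yield a small expected number of gains, not an empirical estimate.
#'
#' @param nTips,birth,death,height tree parameters.
#' @param rates generating transition rates.
#' @param rootState root state of the forward simulation.
#' @param pUnknown,pTypeUnknown masking fractions.
#' @param seed master seed.
#' @return A [SyntheticScenario-class].
#' @export
syntheticScenario <- function(nTips = 150, birth = 0.1, death = 0.025,
                              height = 60,
                              rates = c("FT->NON" = 0.0174,
                                        "FT->SYM" = 0.002,
                                        "SYM->NON" = 0.0028),
                              rootState = "FT", pUnknown = 0.15,
                              pTypeUnknown = 0.3, seed = 1) {
  model <- transitionModel(rates)
  new("SyntheticScenario", nTips = nTips, birth = birth, death = death,
      height = height, model = model, rootState = rootState,
      pUnknown = pUnknown, pTypeUnknown = pTypeUnknown, seed = seed)
}

#' Generate a benchmark bundle
#'
#' Simulates a chronogram, a true trait history and masked observations
#' under a scenario, and (optionally) writes the bundle to disk:
#' `scenario.json`, `tree.nwk`, `traits.csv`, `truth_events.csv`,
#' `truth_node_states.csv`. The truth tables are emitted pre-masking, so
#' masking never alters the recorded history. The bundle is sufficient to
#' run the full pipeline and score recovery against the truth.
#'
#' @param scenario a [SyntheticScenario-class].
#' @param dir optional output directory.
#' @return List with `tree`, `truth` (the true [MappedHistorySet-class]),
#'   `tipStates`, `obs`, `scenario` and, when written, `dir`.
#' @export
makeBenchmark <- function(scenario, dir = NULL) {
  stopifnot(is(scenario, "SyntheticScenario"))
  seed <- scenario@seed
  tree <- simulateChronogram(scenario@nTips, scenario@birth,
                             scenario@death, seed = seed,
                             height = scenario@height)
  truth <- simulateHistory(tree, scenario@model, scenario@rootState,
                           seed = seed + 1)
  ts <- tipStates(truth)
  obs <- maskObservations(ts, scenario@pUnknown, scenario@pTypeUnknown,
                          seed = seed + 2)
  out <- list(tree = tree, truth = truth, tipStates = ts, obs = obs,
              scenario = scenario)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writeChronogram(tree, file.path(dir, "tree.nwk"))
    utils::write.csv(
      data.frame(taxon = taxa(obs),
                 status = unname(observationCategory(obs))),
      file.path(dir, "traits.csv"), row.names = FALSE)
    utils::write.csv(historyEvents(truth),
                     file.path(dir, "truth_events.csv"), row.names = FALSE)
    utils::write.csv(
      data.frame(node = colnames(truth@nodeStates),
                 state = nodStates()[truth@nodeStates[1L, ]]),
      file.path(dir, "truth_node_states.csv"), row.names = FALSE)
    jsonlite::write_json(list(
      n_tips = scenario@nTips, birth = scenario@birth,
      death = scenario@death, height = scenario@height,
      rates = as.list(scenario@model@rates),
      root_state = scenario@rootState, p_unknown = scenario@pUnknown,
      p_type_unknown = scenario@pTypeUnknown, seed = scenario@seed),
      file.path(dir, "scenario.json"), auto_unbox = TRUE, digits = NA)
    out$dir <- dir
  }
  out
}
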