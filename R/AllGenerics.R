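#' Node ages of a chronogram
#'
#' @param x a [Chronogram-class].
#' @return Numeric vector of ages (Myr before present) indexed by ape node
#'   number; tips are at age 0.
#' @export
setGeneric("nodeAges", function(x) standardGeneric("nodeAges"))

#' @rdname nodeAges
#' @export
setMethod("nodeAges", "Chronogram", function(x) x@nodeAges)

#' Tree height (root age) of a chronogram
#'
#' @param x a [Chronogram-class].
#' @return Root age in Myr.
#' @export
setGeneric("treeHeight", function(x) standardGeneric("treeHeight"))

#' @rdname treeHeight
#' @export
setMethod("treeHeight", "Chronogram", function(x) {
  x@nodeAges[length(x@phy$tip.label) + 1L]
})

#' Underlying ape tree of a chronogram
#'
#' @param x a [Chronogram-class].
#' @return The wrapped `ape::phylo` object.
#' @export
setGeneric("apeTree", function(x) standardGeneric("apeTree"))

#' @rdname apeTree
#' @export
setMethod("apeTree", "Chronogram", function(x) x@phy)

#' Tip labels
#'
#' @param x a [Chronogram-class] or [TipObservations-class].
#' @return Character vector of taxon names.
#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))

#' @rdname taxa
#' @export
setMethod("taxa", "Chronogram", function(x) x@phy$tip.label)

#' @rdname taxa
#' @export
setMethod("taxa", "TipObservations", function(x) x@taxa)

#' Observation categories per taxon
#'
#' @param x a [TipObservations-class].
#' @return Named character vector of categories.
#' @export
setGeneric("observationCategory",
           function(x) standardGeneric("observationCategory"))

#' @rdname observationCategory
#' @export
setMethod("observationCategory", "TipObservations", function(x) {
  stats::setNames(x@category, x@taxa)
})

#' State-likelihood matrix of tip observations
#'
#' @param x a [TipObservations-class].
#' @return Numeric matrix (taxa x 3) of state likelihood weights.
#' @export
setGeneric("stateLikelihoods",
           function(x) standardGeneric("stateLikelihoods"))

#' @rdname stateLikelihoods
#' @export
setMethod("stateLikelihoods", "TipObservations", function(x) {
  m <- x@likMatrix
  dimnames(m) <- list(x@taxa, nodStates())
  m
})

#' Rate matrix of a transition model
#'
#' @param x a [TransitionModel-class].
#' @return The 3x3 rate matrix Q (events per lineage per Myr; rows sum to
#'   zero).
#' @export
setGeneric("rateMatrix", function(x) standardGeneric("rateMatrix"))

#' @rdname rateMatrix
#' @export
setMethod("rateMatrix", "TransitionModel", function(x) x@Q)

#' Per-transition rates of a model
#'
#' @param x a [TransitionModel-class].
#' @return Named numeric vector of rates for the allowed transitions.
#' @export
setGeneric("transitionRates", function(x) standardGeneric("transitionRates"))

#' @rdname transitionRates
#' @export
setMethod("transitionRates", "TransitionModel", function(x) x@rates)

#' Root-state prior of a model
#'
#' @param x a [TransitionModel-class].
#' @return Probability vector over [nodStates()].
#' @export
setGeneric("rootPrior", function(x) standardGeneric("rootPrior"))

#' @rdname rootPrior
#' @export
setMethod("rootPrior", "TransitionModel", function(x) {
  stats::setNames(x@rootPrior, nodStates())
})

#' Number of histories in a mapped set
#'
#' @param x a [MappedHistorySet-class].
#' @return Integer count of independent histories.
#' @export
setGeneric("nHistories", function(x) standardGeneric("nHistories"))

#' @rdname nHistories
#' @export
setMethod("nHistories", "MappedHistorySet", function(x) nrow(x@nodeStates))

#' Transition events of mapped histories
#'
#' @param x a [MappedHistorySet-class].
#' @return data.frame with one row per event: `history`, `edge`, `time`
#'   (Myr from branch start), `from`, `to`.
#' @export
setGeneric("historyEvents", function(x) standardGeneric("historyEvents"))

#' @rdname historyEvents
#' @export
setMethod("historyEvents", "MappedHistorySet", function(x) x@events)

#' Sampled node states of mapped histories
#'
#' @param x a [MappedHistorySet-class].
#' @return Character matrix (histories x nodes) of state names.
#' @export
setGeneric("historyNodeStates",
           function(x) standardGeneric("historyNodeStates"))

#' @rdname historyNodeStates
#' @export
setMethod("historyNodeStates", "MappedHistorySet", function(x) {
  m <- matrix(nodStates()[x@nodeStates], nrow = nrow(x@nodeStates))
  colnames(m) <- colnames(x@nodeStates)
  m
})

setMethod("show", "Chronogram", function(object) {
  phy <- object@phy
  cat(sprintf(
    "Chronogram: %d tips, %d internal nodes, height %.4g Myr%s\n",
    length(phy$tip.label), phy$Nnode, treeHeight(object),
    if (!ape::is.binary(phy)) " (contains polytomies)" else ""))
})

setMethod("show", "TipObservations", function(object) {
  cat(sprintf("TipObservations: %d taxa\n", length(object@taxa)))
  print(table(factor(object@category, names(observationCategories()))))
})

setMethod("show", "TransitionModel", function(object) {
  cat("TransitionModel over states", paste(object@states, collapse = ", "),
      "\n")
  allowed <- which(object@mask, arr.ind = TRUE)
  for (k in seq_len(nrow(allowed))) {
    i <- allowed[k, 1L]; j <- allowed[k, 2L]
    cat(sprintf("  %s->%s : %.4f /Myr\n", object@states[i],
                object@states[j], object@Q[i, j]))
  }
  cat("  root prior:", paste(sprintf("%.3g", object@rootPrior),
                             collapse = " "), "\n")
  if (!is.na(object@logLik))
    cat(sprintf("  log-likelihood: %.4f\n", object@logLik))
})

setMethod("show", "MappedHistorySet", function(object) {
  cat(sprintf(
    "MappedHistorySet: %d histories on a %d-tip chronogram, %d events total\n",
    nHistories(object), length(object@tree@phy$tip.label),
    nrow(object@events)))
})

setMethod("show", "SummaryReport", function(object) {
  cat(sprintf("SummaryReport over %d histories\n", object@nHistories))
  cat("  majority-rule transitions by class:\n")
  for (cl in names(object@countsByClass))
    cat(sprintf("    %-10s %d\n", cl, object@countsByClass[[cl]]))
  q <- object@rates$q
  cat(sprintf("  loss rates (Q entries): FT->NON %.4f, SYM->NON %.4f /Myr\n",
              q[["FT->NON"]], q[["SYM->NON"]]))
})

setMethod("show", "SyntheticScenario", function(object) {
  cat(sprintf(
    "SyntheticScenario: %g tips, birth %.3g / death %.3g, height %.3g Myr, root %s\n",
    object@nTips, object@birth, object@death, object@height,
    object@rootState))
  cat(sprintf("  masking: unknown %.2f, type-unknown %.2f; seed %g\n",
              object@pUnknown, object@pTypeUnknown, object@seed))
})
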