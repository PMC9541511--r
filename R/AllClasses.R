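#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib noduleTrace, .registration = TRUE
NULL

#' Ordered character states of the nodulation model
#'
#' The three character states, in the fixed order used by every matrix and
#' vector in the package: `NON` (nonnodulating), `FT` (fixation-thread
#' nodules) and `SYM` (symbiosome nodules).
#'
#' @return Character vector `c("NON", "FT", "SYM")`.
#' @export
#' @examples
#' nodStates()
nodStates <- function() c("NON", "FT", "SYM")

#' Observation categories accepted in trait tables
#'
#' The five tip observation categories and the binary state-likelihood vector
#' each one induces over [nodStates()]: a tip scored `nonnodulating` is
#' compatible only with NON, `nodulating_unknown_type` with FT or SYM, and
#' `unknown` with all three states (equal weight).
#'
#' @return Named list of 0/1 likelihood vectors, one per category.
#' @export
#' @examples
#' observationCategories()[["nodulating_unknown_type"]]
observationCategories <- function() {
  list(
    nonnodulating           = c(NON = 1, FT = 0, SYM = 0),
    FT                      = c(NON = 0, FT = 1, SYM = 0),
    SYM                     = c(NON = 0, FT = 0, SYM = 1),
    nodulating_unknown_type = c(NON = 0, FT = 1, SYM = 1),
    unknown                 = c(NON = 1, FT = 1, SYM = 1)
  )
}

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Chronogram: a rooted, ultrametric, time-calibrated tree
#'
#' Wraps an [ape::phylo] object whose branch lengths are in millions of
#' years, together with node ages measured backwards from the present
#' (tips at age 0). Validity enforces rootedness, non-negative branch
#' lengths, ultrametricity within a relative tolerance, and parent ages
#' strictly exceeding child ages along positive-length branches.
#'
#' @slot phy an `ape::phylo` tree (rooted; polytomies permitted).
#' @slot nodeAges numeric vector of ages (Myr before present) indexed by
#'   ape node number (tips `1..Ntip`, then internal nodes).
#' @slot tol relative ultrametricity tolerance used at validation
#'   (fraction of tree height).
#' @export
setClass("Chronogram",
  representation(phy = "ANY", nodeAges = "numeric", tol = "numeric"))

setValidity("Chronogram", function(object) {
  phy <- object@phy
  if (!inherits(phy, "phylo")) return("'phy' must be an ape 'phylo' object")
  if (!ape::is.rooted(phy)) return("tree must be rooted")
  if (is.null(phy$edge.length)) return("tree must have branch lengths")
  if (any(phy$edge.length < 0)) {
    bad <- which(phy$edge.length < 0)[1L]
    child <- phy$edge[bad, 2L]
    lab <- if (child <= length(phy$tip.label)) phy$tip.label[child]
           else paste0("node ", child)
    return(sprintf("negative branch length on the branch to '%s'", lab))
  }
  nNode <- length(phy$tip.label) + phy$Nnode
  if (length(object@nodeAges) != nNode)
    return("nodeAges must have one entry per node")
  dev <- .ultrametricDeviation(phy)
  h <- max(ape::node.depth.edgelength(phy))
  if (h > 0 && dev > object@tol * h)
    return(sprintf(
      "tree is not ultrametric: worst root-to-tip deviation %.6g exceeds %.3g x height",
      dev, object@tol))
  parents <- phy$edge[, 1L]; children <- phy$edge[, 2L]
  pos <- phy$edge.length > 0
  if (any(object@nodeAges[parents[pos]] <= object@nodeAges[children[pos]] - 1e-12))
    return("parent node ages must exceed child node ages on positive-length branches")
  TRUE
})

#' Tip trait observations
#'
#' Per-taxon observation categories with the induced state-likelihood matrix
#' over [nodStates()]. Every row of the likelihood matrix is binary (unless a
#' custom category weighting is supplied) with at least one positive entry.
#'
#' @slot taxa character vector of taxon names (unique).
#' @slot category character vector of observation categories, parallel to
#'   `taxa`.
#' @slot likMatrix numeric matrix (taxa x 3) of state likelihood weights.
#' @export
setClass("TipObservations",
  representation(taxa = "character", category = "character",
                 likMatrix = "matrix"))

setValidity("TipObservations", function(object) {
  n <- length(object@taxa)
  if (anyDuplicated(object@taxa))
    return(sprintf("duplicate taxon: '%s'",
                   object@taxa[duplicated(object@taxa)][1L]))
  if (length(object@category) != n) return("category must parallel taxa")
  if (!all(dim(object@likMatrix) == c(n, 3L)))
    return("likMatrix must be n x 3")
  if (any(object@likMatrix < 0)) return("likelihood weights must be >= 0")
  if (any(rowSums(object@likMatrix) == 0))
    return("every taxon needs at least one compatible state")
  TRUE
})

#' Constrained continuous-time Markov model of nodule evolution
#'
#' Holds the allowed-transition mask, the per-transition rates (events per
#' lineage per Myr), the resulting 3x3 rate matrix Q (off-diagonal
#' `q[i, j]` = rate of i to j if allowed, else 0; diagonal forces zero row
#' sums) and the root-state prior. Under the default constrained mask
#' (FT->NON, FT->SYM, SYM->NON) the NON state is absorbing and SYM cannot
#' revert to FT.
#'
#' @slot states the fixed state order, `c("NON","FT","SYM")`.
#' @slot mask 3x3 logical matrix of allowed off-diagonal transitions.
#' @slot rates named numeric vector, one non-negative rate per allowed
#'   transition, names like `"FT->NON"`.
#' @slot Q 3x3 rate matrix (rows sum to zero).
#' @slot rootPrior probability vector over states (sums to 1); the primary
#'   analysis fixes it to `(0, 1, 0)`, i.e. root = FT.
#' @slot logLik log-likelihood at these rates, if fitted (else `NA`).
#' @slot fitReport list with optimizer details when produced by
#'   [fitRates()].
#' @export
setClass("TransitionModel",
  representation(states = "character", mask = "matrix", rates = "numeric",
                 Q = "matrix", rootPrior = "numeric", logLik = "numeric",
                 fitReport = "list"))

setValidity("TransitionModel", function(object) {
  if (!identical(object@states, nodStates()))
    return("states must be NON, FT, SYM in that order")
  if (!all(dim(object@mask) == c(3L, 3L)) || !is.logical(object@mask))
    return("mask must be a 3x3 logical matrix")
  if (any(diag(object@mask))) return("mask diagonal must be FALSE")
  if (!all(dim(object@Q) == c(3L, 3L))) return("Q must be 3x3")
  off <- object@Q; diag(off) <- 0
  if (any(off < 0)) return("off-diagonal rates must be >= 0")
  if (any(off[!object@mask] != 0)) return("masked transitions must have rate 0")
  if (any(abs(rowSums(object@Q)) > 1e-12)) return("rows of Q must sum to 0")
  if (length(object@rootPrior) != 3L || any(object@rootPrior < 0) ||
      abs(sum(object@rootPrior) - 1) > 1e-12)
    return("rootPrior must be a probability vector over the 3 states")
  TRUE
})

#' A set of stochastically mapped character histories
#'
#' Each history is one full realization of the trait process on the tree:
#' a state for every node (ambiguous tips receive concrete sampled states)
#' plus timed transition events along branches. Events on a branch are
#' time-ordered and chained (each event starts from the state the previous
#' one produced; the branch starts in the parent's state and ends in the
#' child's), and per-branch dwelling times sum to the branch length.
#'
#' @slot tree the [Chronogram-class] the histories live on.
#' @slot model the [TransitionModel-class] that generated them.
#' @slot nodeStates integer matrix (histories x nodes) of state indices
#'   into [nodStates()], columns indexed by ape node number.
#' @slot events data.frame with columns `history`, `edge` (row of
#'   `phy$edge`), `time` (Myr from branch start), `from`, `to` (state
#'   names).
#' @slot seed the master seed the set was drawn under.
#' @export
setClass("MappedHistorySet",
  representation(tree = "Chronogram", model = "TransitionModel",
                 nodeStates = "matrix", events = "data.frame",
                 seed = "numeric"))

setValidity("MappedHistorySet", function(object) {
  phy <- object@tree@phy
  nNode <- length(phy$tip.label) + phy$Nnode
  if (ncol(object@nodeStates) != nNode)
    return("nodeStates needs one column per node")
  if (nrow(object@nodeStates) < 1L) return("at least one history required")
  need <- c("history", "edge", "time", "from", "to")
  if (!all(need %in% names(object@events)))
    return("events must have columns history, edge, time, from, to")
  TRUE
})

#' Summary of a set of mapped histories
#'
#' The tabular analogue of a stochastic-mapping figure: per-node state
#' proportions (the node "pies"), majority-rule branch transitions with age
#' bounds, per-class transition counts and event-count distributions, and
#' loss rates both as fitted Q entries and as realized per-history rates.
#'
#' @slot tree the [Chronogram-class] summarized over.
#' @slot nodeProportions numeric matrix (nodes x 3) of state frequencies.
#' @slot majorityTransitions data.frame of branch transitions between
#'   modal node states (columns `edge`, `from`, `to`, `class`,
#'   `parentAge`, `childAge`).
#' @slot countsByClass named integer vector of majority transitions per
#'   class.
#' @slot eventCounts list per transition class: table of realized event
#'   counts per history, as frequencies.
#' @slot rates list with `q` (instantaneous Q-entry rates, the primary
#'   reading) and `realized` (per-history events / dwelling time: mean and
#'   2.5/97.5 percentiles per class).
#' @slot ageSpans data.frame of per-class spans of the transition maximum
#'   ages.
#' @slot ambiguousNodes integer vector of nodes whose modal state was tied
#'   (flagged, never broken arbitrarily).
#' @slot nHistories number of histories summarized.
#' @export
setClass("SummaryReport",
  representation(tree = "Chronogram", nodeProportions = "matrix",
                 majorityTransitions = "data.frame",
                 countsByClass = "integer", eventCounts = "list",
                 rates = "list", ageSpans = "data.frame",
                 ambiguousNodes = "integer", nHistories = "integer"))

setValidity("SummaryReport", function(object) {
  p <- object@nodeProportions
  if (ncol(p) != 3L) return("nodeProportions must have 3 columns")
  if (any(abs(rowSums(p) - 1) > 1e-9))
    return("node proportions must sum to 1 per node")
  mt <- object@majorityTransitions
  if (nrow(mt) > 0 && any(mt$parentAge <= mt$childAge - 1e-12))
    return("majority transitions must have parentAge > childAge")
  if (sum(object@countsByClass) != nrow(mt))
    return("countsByClass must total the number of majority transitions")
  TRUE
})

#' Synthetic benchmark scenario
#'
#' Parameters of a simulated data set with the statistical structure the
#' analysis assumes: a birth-death chronogram, a generating transition
#' model, a root state, and masking fractions turning true tip states into
#' the partially observed categories of real trait tables.
#'
#' @slot nTips number of extant tips.
#' @slot birth,death speciation and extinction rates (per lineage per Myr).
#' @slot height target crown age in Myr (tree rescaled to this height).
#' @slot model generating [TransitionModel-class].
#' @slot rootState state the forward simulation starts from.
#' @slot pUnknown fraction of tips masked to category `unknown`.
#' @slot pTypeUnknown fraction of nodulating tips masked to
#'   `nodulating_unknown_type`.
#' @slot seed master seed.
#' @export
setClass("SyntheticScenario",
  representation(nTips = "numeric", birth = "numeric", death = "numeric",
                 height = "numeric", model = "TransitionModel",
                 rootState = "character", pUnknown = "numeric",
                 pTypeUnknown = "numeric", seed = "numeric"))

setValidity("SyntheticScenario", function(object) {
  if (object@nTips < 2) return("nTips must be >= 2")
  if (object@death < 0 || object@birth <= object@death)
    return("need birth > death >= 0")
  if (object@pUnknown < 0 || object@pTypeUnknown < 0 ||
      object@pUnknown + object@pTypeUnknown > 1)
    return("masking fractions must be in [0,1] with sum <= 1")
  if (!object@rootState %in% nodStates()) return("unknown rootState")
  TRUE
})
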