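## Collapse a set of mapped histories into the reported quantities:
## node-state proportions, majority-rule branch transitions, event-count
## distributions, loss rates per Myr, and transition age bounds.

.transitionClass <- function(from, to) {
  cls <- paste0(from, "->", to)
  ifelse(cls %in% c("FT->SYM", "FT->NON", "SYM->NON"), cls, "other")
}

.classLevels <- c("FT->SYM", "FT->NON", "SYM->NON", "other")

#' Node-state frequencies across mapped histories
#'
#' For each node (including ambiguous tips, whose states were sampled),
#' the fraction of histories in which it is in each state — the numbers
#' behind per-node "pie" summaries.
#'
#' @param x a [MappedHistorySet-class].
#' @return Numeric matrix (nodes x 3), rows named by node label, rows
#'   summing to 1.
#' @export
nodeStateFrequencies <- function(x) {
  stopifnot(is(x, "MappedHistorySet"))
  st <- x@nodeStates
  out <- vapply(1:3, function(s) colMeans(st == s),
                numeric(ncol(st)))
  dimnames(out) <- list(colnames(st), nodStates())
  out
}

#' Majority-rule branch transitions
#'
#' Assigns each node its modal state across histories, then emits one
#' transition for every branch whose parent and child modal states differ
#' (parent modal to child modal). Sibling branches count separately, so a
#' parent in FT with both children in NON yields two FT->NON losses — the
#' "double loss" pattern. Nodes whose top two proportions tie are flagged
#' ambiguous and their incident branches reported unresolved, never
#' guessed.
#'
#' @param freq node-state frequency matrix from [nodeStateFrequencies()].
#' @param tree the [Chronogram-class] the frequencies were computed on.
#' @return List with `transitions` (data.frame: `edge`, `parent`, `child`,
#'   `from`, `to`, `class`, `parentAge`, `childAge`), `countsByClass`,
#'   `modalStates`, `ambiguousNodes` (node numbers with tied modes) and
#'   `unresolvedEdges`.
#' @export
majorityTransitions <- function(freq, tree) {
  stopifnot(is(tree, "Chronogram"))
  phy <- tree@phy
  nNode <- length(phy$tip.label) + phy$Nnode
  if (nrow(freq) != nNode)
    stop("frequency matrix does not match the tree (",
         nrow(freq), " rows for ", nNode, " nodes)")
  modal <- integer(nNode)
  tied <- logical(nNode)
  for (i in seq_len(nNode)) {
    o <- order(freq[i, ], decreasing = TRUE)
    modal[i] <- o[1L]
    tied[i] <- freq[i, o[1L]] == freq[i, o[2L]]
  }
  labels <- c(phy$tip.label, phy$node.label)
  parents <- phy$edge[, 1L]; children <- phy$edge[, 2L]
  unresolved <- which(tied[parents] | tied[children])
  usable <- setdiff(which(modal[parents] != modal[children]), unresolved)
  ages <- tree@nodeAges
  transitions <- data.frame(
    edge = usable,
    parent = labels[parents[usable]],
    child = labels[children[usable]],
    from = nodStates()[modal[parents[usable]]],
    to = nodStates()[modal[children[usable]]],
    parentAge = ages[parents[usable]],
    childAge = ages[children[usable]],
    stringsAsFactors = FALSE)
  transitions$class <- if (nrow(transitions) > 0)
    .transitionClass(transitions$from, transitions$to) else character(0)
  counts <- table(factor(transitions$class, .classLevels))
  list(transitions = transitions,
       countsByClass = stats::setNames(as.integer(counts), .classLevels),
       modalStates = stats::setNames(nodStates()[modal], labels),
       ambiguousNodes = which(tied),
       unresolvedEdges = unresolved)
}

#' Per-class distribution of realized event counts
#'
#' For each transition class, the empirical distribution over histories of
#' the number of realized events of that class — the histogram summaries
#' of a stochastic-mapping figure.
#'
#' @param x a [MappedHistorySet-class].
#' @return Named list per class; each element a named numeric vector
#'   mapping event count to frequency (sums to 1).
#' @export
eventCountDistribution <- function(x) {
  stopifnot(is(x, "MappedHistorySet"))
  nH <- nHistories(x)
  ev <- x@events
  cls <- if (nrow(ev) > 0) .transitionClass(ev$from, ev$to) else character(0)
  out <- lapply(.classLevels, function(cl) {
    counts <- integer(nH)
    if (length(cls) > 0) {
      tab <- table(ev$history[cls == cl])
      counts[as.integer(names(tab))] <- as.integer(tab)
    }
    tt <- table(counts) / nH
    stats::setNames(as.numeric(tt), names(tt))
  })
  stats::setNames(out, .classLevels)
}

#' Loss rates per million years
#'
#' Two readings of the loss rates are computed and reported side by side:
#' the instantaneous Q-entry rates of the fitted model (the primary
#' reading) and realized per-history rates, i.e. events of a class divided
#' by the history's dwelling time in the source state, summarized by mean
#' and 2.5/97.5 percentiles. Histories with zero dwelling time in a source
#' state are excluded from that class with a logged count.
#'
#' @param model the fitted [TransitionModel-class].
#' @param x the [MappedHistorySet-class] generated under it.
#' @return List with `q` (named vector of instantaneous rates for
#'   FT->NON, SYM->NON and FT->SYM), `ratio` (FT->NON / SYM->NON),
#'   and `realized` (data.frame: class, mean, lo, hi, nExcluded).
#' @export
lossRates <- function(model, x) {
  stopifnot(is(model, "TransitionModel"), is(x, "MappedHistorySet"))
  Q <- model@Q
  q <- c("FT->NON" = Q["FT", "NON"], "SYM->NON" = Q["SYM", "NON"],
         "FT->SYM" = Q["FT", "SYM"])
  dwell <- dwellingTimes(x)
  nH <- nHistories(x)
  ev <- x@events
  cls <- if (nrow(ev) > 0) .transitionClass(ev$from, ev$to) else character(0)
  realized <- do.call(rbind, lapply(names(q), function(cl) {
    src <- sub("->.*", "", cl)
    counts <- integer(nH)
    if (length(cls) > 0) {
      tab <- table(ev$history[cls == cl])
      counts[as.integer(names(tab))] <- as.integer(tab)
    }
    d <- dwell[, src]
    ok <- d > 0
    r <- counts[ok] / d[ok]
    data.frame(class = cl,
               mean = if (any(ok)) mean(r) else NA_real_,
               lo = if (any(ok)) unname(stats::quantile(r, 0.025)) else NA_real_,
               hi = if (any(ok)) unname(stats::quantile(r, 0.975)) else NA_real_,
               nExcluded = sum(!ok),
               stringsAsFactors = FALSE)
  }))
  if (any(realized$nExcluded > 0))
    message("realized rates: excluded histories with zero source dwelling ",
            "time: ",
            paste(sprintf("%s: %d", realized$class, realized$nExcluded)[
              realized$nExcluded > 0], collapse = ", "))
  list(q = q, ratio = unname(q[["FT->NON"]] / q[["SYM->NON"]]),
       realized = realized)
}

#' Age bounds of majority-rule transitions
#'
#' A transition inferred on a branch happened somewhere along it, so its
#' age is bounded by the parent node's age (maximum) and the child node's
#' age (minimum). Per class, the span of maximum ages (oldest and youngest
#' maximum age across that class's branches) is reported.
#'
#' @param transitions the result of [majorityTransitions()] (or its
#'   `transitions` data.frame).
#' @return List with `perTransition` (the transitions with `maxAge`,
#'   `minAge`) and `spans` (data.frame: class, n, oldestMaxAge,
#'   youngestMaxAge).
#' @export
transitionAgeBounds <- function(transitions) {
  tr <- if (is.list(transitions) && !is.data.frame(transitions))
    transitions$transitions else transitions
  tr$maxAge <- tr$parentAge
  tr$minAge <- tr$childAge
  spans <- do.call(rbind, lapply(unique(tr$class), function(cl) {
    m <- tr$maxAge[tr$class == cl]
    data.frame(class = cl, n = length(m), oldestMaxAge = max(m),
               youngestMaxAge = min(m), stringsAsFactors = FALSE)
  }))
  if (is.null(spans))
    spans <- data.frame(class = character(0), n = integer(0),
                        oldestMaxAge = numeric(0),
                        youngestMaxAge = numeric(0))
  list(perTransition = tr, spans = spans)
}

#' Summarize a set of mapped histories
#'
#' Runs all the summaries ([nodeStateFrequencies()],
#' [majorityTransitions()], [eventCountDistribution()], [lossRates()],
#' [transitionAgeBounds()]) and bundles them into a
#' [SummaryReport-class].
#'
#' @param x a [MappedHistorySet-class].
#' @return A [SummaryReport-class].
#' @export
summarizeHistories <- function(x) {
  stopifnot(is(x, "MappedHistorySet"))
  freq <- nodeStateFrequencies(x)
  mt <- majorityTransitions(freq, x@tree)
  ages <- transitionAgeBounds(mt)
  new("SummaryReport", tree = x@tree, nodeProportions = freq,
      majorityTransitions = ages$perTransition,
      countsByClass = mt$countsByClass,
      eventCounts = eventCountDistribution(x),
      rates = lossRates(x@model, x),
      ageSpans = ages$spans,
      ambiguousNodes = as.integer(mt$ambiguousNodes),
      nHistories = as.integer(nHistories(x)))
}

#' Number of majority-rule losses, split by ancestral nodule type
#'
#' Losses are transitions into the nonnodulating state regardless of
#' source; they are reported split by the ancestral (source) state.
#'
#' @param report a [SummaryReport-class].
#' @return Named vector: `total`, `fromFT`, `fromSYM`.
#' @export
lossCounts <- function(report) {
  stopifnot(is(report, "SummaryReport"))
  cbc <- report@countsByClass
  c(total = unname(cbc[["FT->NON"]] + cbc[["SYM->NON"]]),
    fromFT = unname(cbc[["FT->NON"]]),
    fromSYM = unname(cbc[["SYM->NON"]]))
}

#' Write summary outputs to a directory
#'
#' Writes `summary.json` (counts, rates, age spans), per-node proportions
#' and majority transitions as CSV, and an annotated Newick with modal
#' states appended to node labels.
#'
#' @param report a [SummaryReport-class].
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
writeSummary <- function(report, dir) {
  stopifnot(is(report, "SummaryReport"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  freq <- report@nodeProportions
  utils::write.csv(
    data.frame(node = rownames(freq), freq, check.names = FALSE),
    file.path(dir, "node_proportions.csv"), row.names = FALSE)
  utils::write.csv(report@majorityTransitions,
                   file.path(dir, "majority_transitions.csv"),
                   row.names = FALSE)
  modal <- nodStates()[apply(freq, 1L, which.max)]
  phy <- report@tree@phy
  nTip <- length(phy$tip.label)
  phy$node.label <- paste0(phy$node.label, "|",
                           modal[(nTip + 1L):length(modal)])
  writeLines(ape::write.tree(phy), file.path(dir, "annotated_tree.nwk"))
  lc <- lossCounts(report)
  out <- list(
    n_histories = report@nHistories,
    counts_by_class = as.list(report@countsByClass),
    losses = list(total = lc[["total"]], from_FT = lc[["fromFT"]],
                  from_SYM = lc[["fromSYM"]]),
    rates_q_per_myr = as.list(round(report@rates$q, 4)),
    rate_ratio_FT_vs_SYM = report@rates$ratio,
    rates_realized = report@rates$realized,
    age_spans = report@ageSpans,
    event_count_distribution = report@eventCounts,
    ambiguous_nodes = report@ambiguousNodes)
  jsonlite::write_json(out, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
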