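## Stochastic character mapping: joint node-state draws from the exact
## conditional distribution given tip data, then endpoint-conditioned
## path sampling along every branch by uniformization.

# Everything the samplers need, computed once per (tree, obs, model):
# preorder edge transition matrices, conditional likelihoods from the
# pruning pass, and the uniformized-chain powers for path sampling.
.mapContext <- function(tree, obs, model) {
  ed <- .treeEdges(tree)
  lik <- .nodeLik(tree, obs)
  Ppost <- cpp_edge_probs(model@Q, ed$postLen)
  pr <- cpp_prune(ed$postEdge, Ppost, lik, ed$root, model@rootPrior)
  if (pr$impossible)
    stop("tip data are impossible under the constrained model ",
         "(zero likelihood given the transition mask and root prior)")
  Ppre <- cpp_edge_probs(model@Q, ed$preLen)
  mu <- 1.05 * max(-diag(model@Q))  # strict domination with headroom
  maxLen <- max(ed$preLen)
  nmax <- if (mu * maxLen > 0) {
    stats::qpois(1 - 1e-12, mu * maxLen) + 5L
  } else 1L
  Rpow <- .uniformizedPowers(model@Q, mu, nmax)
  list(ed = ed, partials = pr$partials, loglik = pr$loglik, Ppre = Ppre,
       mu = mu, Rpow = Rpow)
}

# slices 1..(n+1) hold R^0 .. R^n for R = I + Q/mu
.uniformizedPowers <- function(Q, mu, nmax) {
  k <- nrow(Q)
  out <- array(0, c(k, k, nmax + 1L))
  out[, , 1L] <- diag(k)
  if (mu > 0) {
    R1 <- diag(k) + Q / mu
    R1[R1 < 0] <- 0  # clip tiny negative round-off
    acc <- diag(k)
    for (n in seq_len(nmax)) {
      acc <- acc %*% R1
      out[, , n + 1L] <- acc
    }
  }
  out
}

# substream seed for history h under master seed: fixed mixing keeps every
# history reproducible on its own, independent of how many are drawn
.historySeed <- function(seed, h) {
  (((seed %% 65011) + 1) * 31013 + h * 7919) %% 2147483647L
}

#' Sample node states from their joint conditional distribution
#'
#' Draws exact joint samples of all node states given the tip data: the
#' root from `rootPrior(s) L_root(s)`, then each child in preorder from
#' `P[parentState, s](branch) L_child(s)`, where `L` are the conditional
#' likelihoods of the pruning pass. Ambiguous tips receive concrete
#' sampled states. Uses R's RNG stream (set a seed beforehand for
#' reproducibility).
#'
#' @param tree a [Chronogram-class].
#' @param obs a [TipObservations-class] covering every tip.
#' @param model a [TransitionModel-class].
#' @param n number of independent draws.
#' @return Character matrix (n x nodes) of state names; columns named by
#'   tip labels then internal node labels.
#' @export
sampleNodeStates <- function(tree, obs, model, n = 1) {
  stopifnot(n >= 1)
  ctx <- .mapContext(tree, obs, model)
  st <- cpp_sample_node_states(ctx$ed$preEdge, ctx$Ppre, ctx$partials,
                               ctx$ed$root, model@rootPrior, as.integer(n))
  out <- matrix(nodStates()[st], nrow = n)
  colnames(out) <- c(tree@phy$tip.label, tree@phy$node.label)
  out
}

#' Endpoint-conditioned path sampling on a single branch
#'
#' Samples one realization of the CTMC on `[0, t]` conditioned to start in
#' `from` and end in `to`, by uniformization: the number of candidate
#' jumps is Poisson(`mu t`) reweighted by n-step probabilities of the
#' uniformized chain, jump states are drawn by conditioning each step on
#' the endpoint, jump times are uniform order statistics, and virtual
#' (self) jumps are discarded.
#'
#' @param from,to endpoint states (names from [nodStates()]).
#' @param t branch duration in Myr.
#' @param model a [TransitionModel-class].
#' @return data.frame with columns `time`, `from`, `to`, one row per
#'   transition event, time-ordered.
#' @export
#' @examples
#' m <- transitionModel(c("FT->NON" = 0.05, "FT->SYM" = 0.02,
#'                        "SYM->NON" = 0.01))
#' set.seed(1)
#' samplePath("FT", "NON", 30, m)
samplePath <- function(from, to, t, model) {
  stopifnot(is(model, "TransitionModel"), t >= 0)
  a <- .stateIndex(from); b <- .stateIndex(to)
  P <- cpp_expm(model@Q, t)
  if (P[a, b] <= 0)
    stop("endpoint unreachable: P[", from, ",", to, "](", t, ") = 0")
  mu <- 1.05 * max(-diag(model@Q))
  nmax <- if (mu * t > 0) stats::qpois(1 - 1e-12, mu * t) + 5L else 1L
  ev <- cpp_sample_path(a, b, t, P, .uniformizedPowers(model@Q, mu, nmax),
                        mu)
  data.frame(time = ev[, 1L], from = nodStates()[ev[, 2L]],
             to = nodStates()[ev[, 3L]], stringsAsFactors = FALSE)
}

#' Stochastic character maps
#'
#' Generates `n` independent full character histories conditional on the
#' tip data, the model and the root prior: a joint node-state draw
#' followed by endpoint-conditioned path sampling on every branch. Fully
#' reproducible from `seed`: each history is drawn under its own
#' substream seed derived from the master seed, so history h is identical
#' whether 1 or 500 histories are requested.
#'
#' @param tree a [Chronogram-class].
#' @param obs a [TipObservations-class] covering every tip.
#' @param model a [TransitionModel-class] (usually the ML fit).
#' @param n number of histories (the study design uses 500).
#' @param seed master seed.
#' @return A [MappedHistorySet-class].
#' @export
stochasticMaps <- function(tree, obs, model, n = 500, seed = 1) {
  stopifnot(n >= 1)
  ctx <- .mapContext(tree, obs, model)
  nNode <- length(tree@phy$tip.label) + tree@phy$Nnode
  states <- matrix(NA_integer_, n, nNode)
  evList <- vector("list", n)
  for (h in seq_len(n)) {
    set.seed(.historySeed(seed, h))
    st <- cpp_sample_node_states(ctx$ed$preEdge, ctx$Ppre, ctx$partials,
                                 ctx$ed$root, model@rootPrior, 1L)
    ev <- cpp_map_histories(ctx$ed$preEdge, ctx$ed$preLen, ctx$Ppre,
                            ctx$Rpow, ctx$mu, st)
    states[h, ] <- st[1L, ]
    if (nrow(ev) > 0) {
      ev[, "history"] <- h
      # report edges as rows of the tree's own edge matrix
      ev[, "edge"] <- ctx$ed$preToOrig[ev[, "edge"]]
      evList[[h]] <- ev
    }
  }
  evAll <- do.call(rbind, evList)
  events <- if (is.null(evAll)) {
    data.frame(history = integer(0), edge = integer(0), time = numeric(0),
               from = character(0), to = character(0),
               stringsAsFactors = FALSE)
  } else {
    data.frame(history = as.integer(evAll[, "history"]),
               edge = as.integer(evAll[, "edge"]),
               time = evAll[, "time"],
               from = nodStates()[evAll[, "from"]],
               to = nodStates()[evAll[, "to"]],
               stringsAsFactors = FALSE)
  }
  colnames(states) <- c(tree@phy$tip.label, tree@phy$node.label)
  new("MappedHistorySet", tree = tree, model = model, nodeStates = states,
      events = events, seed = as.numeric(seed))
}

#' Dwelling times per state
#'
#' Total time each history spends in each state, summed over all branches
#' (the denominator of realized loss rates). Per history the dwelling
#' times sum to the total tree branch length.
#'
#' @param x a [MappedHistorySet-class].
#' @return Numeric matrix (histories x 3), columns [nodStates()], in Myr.
#' @export
dwellingTimes <- function(x) {
  stopifnot(is(x, "MappedHistorySet"))
  phy <- x@tree@phy
  nH <- nrow(x@nodeStates)
  out <- matrix(0, nH, 3L, dimnames = list(NULL, nodStates()))
  parents <- phy$edge[, 1L]
  len <- phy$edge.length
  # baseline: every branch spent entirely in its parent's state
  for (h in seq_len(nH)) {
    ps <- x@nodeStates[h, parents]
    out[h, ] <- vapply(1:3, function(s) sum(len[ps == s]), numeric(1))
  }
  ev <- x@events
  if (nrow(ev) > 0) {
    # each event moves the remainder of its branch from 'from' to 'to';
    # chained events compose correctly because each hands off the tail
    rest <- len[ev$edge] - ev$time
    fromIdx <- match(ev$from, nodStates())
    toIdx <- match(ev$to, nodStates())
    for (i in seq_len(nrow(ev))) {
      h <- ev$history[i]
      out[h, fromIdx[i]] <- out[h, fromIdx[i]] - rest[i]
      out[h, toIdx[i]] <- out[h, toIdx[i]] + rest[i]
    }
  }
  out
}
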