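# Independent oracles used against the package's implementation. They use
# Matrix::expm for transition probabilities (an independent route from the
# package's Armadillo exponential) and brute-force enumeration/simulation
# instead of pruning/uniformization.

oracleP <- function(Q, t) {
  if (t == 0) return(diag(3))
  as.matrix(Matrix::expm(Q * t))
}

# Likelihood by full enumeration: sum over every assignment of states to
# ALL nodes of rootPrior x product of branch transition probabilities x
# product of tip observation weights. Exact for any tree small enough to
# enumerate (3^nNodes terms).
oracleLoglik <- function(tree, obs, model) {
  phy <- apeTree(tree)
  nTip <- length(phy$tip.label)
  nNode <- nTip + phy$Nnode
  Q <- rateMatrix(model)
  Pedge <- lapply(seq_len(nrow(phy$edge)),
                  function(e) oracleP(Q, phy$edge.length[e]))
  lik <- stateLikelihoods(obs)[phy$tip.label, , drop = FALSE]
  rp <- rootPrior(model)
  root <- nTip + 1L
  grid <- as.matrix(expand.grid(rep(list(1:3), nNode)))
  total <- 0
  for (g in seq_len(nrow(grid))) {
    s <- grid[g, ]
    w <- unname(rp[s[root]])
    if (w == 0) next
    for (t in seq_len(nTip)) {
      w <- w * lik[t, s[t]]
      if (w == 0) break
    }
    if (w == 0) next
    for (e in seq_len(nrow(phy$edge))) {
      w <- w * Pedge[[e]][s[phy$edge[e, 1L]], s[phy$edge[e, 2L]]]
      if (w == 0) break
    }
    total <- total + w
  }
  log(total)
}

# Exact marginal node-state posteriors by the same enumeration.
oracleNodeMarginals <- function(tree, obs, model) {
  phy <- apeTree(tree)
  nTip <- length(phy$tip.label)
  nNode <- nTip + phy$Nnode
  Q <- rateMatrix(model)
  Pedge <- lapply(seq_len(nrow(phy$edge)),
                  function(e) oracleP(Q, phy$edge.length[e]))
  lik <- stateLikelihoods(obs)[phy$tip.label, , drop = FALSE]
  rp <- rootPrior(model)
  root <- nTip + 1L
  grid <- as.matrix(expand.grid(rep(list(1:3), nNode)))
  post <- matrix(0, nNode, 3L)
  for (g in seq_len(nrow(grid))) {
    s <- grid[g, ]
    w <- unname(rp[s[root]])
    for (t in seq_len(nTip)) w <- w * lik[t, s[t]]
    if (w == 0) next
    for (e in seq_len(nrow(phy$edge)))
      w <- w * Pedge[[e]][s[phy$edge[e, 1L]], s[phy$edge[e, 2L]]]
    if (w == 0) next
    for (i in seq_len(nNode)) post[i, s[i]] <- post[i, s[i]] + w
  }
  sweep(post, 1L, rowSums(post), "/")
}

# Unconditioned forward simulation of the CTMC on one interval; returns the
# end state and the number of real transition events.
oracleForward <- function(a, t, Q) {
  cur <- a
  tt <- 0
  n <- 0L
  repeat {
    exit <- -Q[cur, cur]
    if (exit <= 0) break
    tt <- tt + stats::rexp(1, exit)
    if (tt >= t) break
    probs <- Q[cur, ]
    probs[cur] <- 0
    cur <- sample.int(3L, 1L, prob = probs)
    n <- n + 1L
  }
  list(end = cur, n = n)
}

# Rejection sampler for endpoint-conditioned paths: simulate forward from
# a, keep draws ending in b; returns realized event counts.
oracleRejectionCounts <- function(a, b, t, Q, nKeep) {
  out <- integer(nKeep)
  k <- 0L
  while (k < nKeep) {
    sim <- oracleForward(a, t, Q)
    if (sim$end == b) {
      k <- k + 1L
      out[k] <- sim$n
    }
  }
  out
}

# random ultrametric test tree with a fixed state of the RNG
randomChronogram <- function(nTip, scale = 10) {
  phy <- ape::rcoal(nTip)
  phy$edge.length <- phy$edge.length * scale /
    max(ape::node.depth.edgelength(phy))
  chronogramFromPhylo(phy)
}

randomModel <- function(mask = constrainedMask(),
                        rootPrior = rootPriorFT(), rmax = 0.3) {
  nms <- character(0)
  for (i in 1:3) for (j in 1:3)
    if (mask[i, j]) nms <- c(nms, paste0(nodStates()[i], "->", nodStates()[j]))
  transitionModel(stats::setNames(stats::runif(length(nms), 0.01, rmax), nms),
                  mask = mask, rootPrior = rootPrior)
}

randomObservations <- function(taxa) {
  cats <- names(observationCategories())
  tipObservations(taxa, sample(cats, length(taxa), replace = TRUE))
}

# branch-level endpoint transitions of a history (edge row -> from/to)
endpointTransitions <- function(maps, history = 1L) {
  phy <- apeTree(maps@tree)
  st <- maps@nodeStates[history, ]
  p <- st[phy$edge[, 1L]]
  k <- st[phy$edge[, 2L]]
  diff <- which(p != k)
  data.frame(edge = diff, from = nodStates()[p[diff]],
             to = nodStates()[k[diff]], stringsAsFactors = FALSE)
}
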