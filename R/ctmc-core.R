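## The three-state CTMC: masks, rate matrices, transition probabilities,
## pruning likelihood, and maximum-likelihood rate estimation.

.stateIndex <- function(s) {
  i <- match(s, nodStates())
  if (anyNA(i)) stop("unknown state: ", paste(s[is.na(i)], collapse = ", "))
  i
}

.parseTransition <- function(name) {
  parts <- strsplit(name, "->", fixed = TRUE)[[1L]]
  if (length(parts) != 2L)
    stop("transition names must look like 'FT->NON', got '", name, "'")
  .stateIndex(trimws(parts))
}

#' Allowed-transition masks
#'
#' `constrainedMask()` is the single-gain / multiple-losses model: only
#' FT->NON, FT->SYM and SYM->NON are allowed, which makes NON absorbing and
#' the FT->SYM transition irreversible. `allTransitionsMask()` allows every
#' off-diagonal transition (the sensitivity model).
#'
#' @return 3x3 logical matrix over [nodStates()].
#' @export
#' @examples
#' constrainedMask()
constrainedMask <- function() {
  m <- matrix(FALSE, 3L, 3L, dimnames = list(nodStates(), nodStates()))
  m["FT", "NON"] <- TRUE
  m["FT", "SYM"] <- TRUE
  m["SYM", "NON"] <- TRUE
  m
}

#' @rdname constrainedMask
#' @export
allTransitionsMask <- function() {
  m <- matrix(TRUE, 3L, 3L, dimnames = list(nodStates(), nodStates()))
  diag(m) <- FALSE
  m
}

#' Root-state priors
#'
#' `rootPriorFT()` fixes the root to the FT state (the primary analysis:
#' nodulation evolved once, ancestrally with fixation threads);
#' `rootPriorUniform()` puts equal weight on all three states.
#'
#' @return Probability vector over [nodStates()].
#' @export
rootPriorFT <- function() c(NON = 0, FT = 1, SYM = 0)

#' @rdname rootPriorFT
#' @export
rootPriorUniform <- function() c(NON = 1, FT = 1, SYM = 1) / 3

#' Build a constrained rate matrix
#'
#' Assembles a [TransitionModel-class] from per-transition rates (events
#' per lineage per Myr) under an allowed-transition mask. Off-diagonal
#' `Q[i, j]` is the rate of i to j when allowed and exactly 0 otherwise;
#' the diagonal is forced so every row sums to zero. Allowed transitions
#' without a supplied rate get rate 0; a rate supplied for a masked
#' transition is an error.
#'
#' @param rates named numeric vector, names like `"FT->NON"`.
#' @param mask 3x3 logical allowed-transition mask (default
#'   [constrainedMask()]).
#' @param rootPrior probability vector over [nodStates()] (default: root
#'   fixed to FT); any non-negative weights are normalized.
#' @return A [TransitionModel-class].
#' @export
#' @examples
#' m <- transitionModel(c("FT->NON" = 0.0174, "FT->SYM" = 0.01,
#'                        "SYM->NON" = 0.0028))
#' rateMatrix(m)
transitionModel <- function(rates, mask = constrainedMask(),
                            rootPrior = rootPriorFT()) {
  stopifnot(is.numeric(rates), !is.null(names(rates)))
  if (any(rates < 0)) stop("rates must be >= 0")
  dimnames(mask) <- list(nodStates(), nodStates())
  Q <- matrix(0, 3L, 3L, dimnames = list(nodStates(), nodStates()))
  for (nm in names(rates)) {
    ij <- .parseTransition(nm)
    if (!mask[ij[1L], ij[2L]])
      stop("rate supplied for masked transition '", nm, "'")
    Q[ij[1L], ij[2L]] <- rates[[nm]]
  }
  diag(Q) <- -rowSums(Q)
  allowed <- which(t(mask), arr.ind = TRUE)  # row-major order of names
  nms <- paste0(nodStates()[allowed[, 2L]], "->", nodStates()[allowed[, 1L]])
  full <- stats::setNames(Q[cbind(allowed[, 2L], allowed[, 1L])], nms)
  rp <- as.numeric(rootPrior)
  if (length(rp) != 3L || any(rp < 0) || sum(rp) <= 0)
    stop("rootPrior must be 3 non-negative weights")
  rp <- rp / sum(rp)
  new("TransitionModel", states = nodStates(), mask = mask, rates = full,
      Q = Q, rootPrior = rp, logLik = NA_real_, fitReport = list())
}

#' Transition probability matrix P(t)
#'
#' The matrix exponential `exp(Q t)`: `P[i, j](t)` is the probability of
#' being in state j after t million years given state i now. `P(0)` is the
#' identity exactly (no exponential call for zero durations).
#'
#' @param model a [TransitionModel-class].
#' @param t duration in Myr (>= 0).
#' @return 3x3 stochastic matrix (rows sum to 1).
#' @export
#' @examples
#' m <- transitionModel(c("SYM->NON" = 0.0028))
#' transitionProbability(m, 50)["SYM", "NON"]  # 1 - exp(-0.14)
transitionProbability <- function(model, t) {
  stopifnot(is(model, "TransitionModel"))
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("t must be a single non-negative duration")
  P <- cpp_expm(model@Q, t)
  dimnames(P) <- list(nodStates(), nodStates())
  P
}

# Align observations to tip order and build the node-likelihood matrix
# (tips = observation vectors, internal nodes = 1).
.nodeLik <- function(tree, obs) {
  phy <- tree@phy
  nTip <- length(phy$tip.label)
  idx <- match(.normalizeTaxon(phy$tip.label), .normalizeTaxon(obs@taxa))
  if (anyNA(idx))
    stop("tips without a trait observation: ",
         paste(phy$tip.label[is.na(idx)], collapse = ", "),
         " (use matchTips() first)")
  lik <- matrix(1, nTip + phy$Nnode, 3L)
  lik[seq_len(nTip), ] <- obs@likMatrix[idx, , drop = FALSE]
  lik
}

# Postorder / preorder edge structures reused across likelihood, fitting
# and mapping.
.treeEdges <- function(tree) {
  phy <- tree@phy
  post <- ape::reorder.phylo(phy, "postorder")
  pre <- ape::reorder.phylo(phy, "cladewise")
  list(
    nTip = length(phy$tip.label),
    root = length(phy$tip.label) + 1L,
    postEdge = post$edge, postLen = post$edge.length,
    preEdge = pre$edge, preLen = pre$edge.length,
    # map a preorder edge position back to the row of phy$edge
    preToOrig = match(pre$edge[, 2L], phy$edge[, 2L])
  )
}

.pruneRaw <- function(tree, obs, model) {
  ed <- .treeEdges(tree)
  P <- cpp_edge_probs(model@Q, ed$postLen)
  cpp_prune(ed$postEdge, P, .nodeLik(tree, obs), ed$root, model@rootPrior)
}

#' Pruning log-likelihood of tip data
#'
#' Felsenstein's pruning algorithm: a postorder recursion over conditional
#' likelihood vectors with per-branch transition matrices `P(t_e)` and a
#' root contribution `sum_s rootPrior(s) L_root(s)`, rescaled per node so
#' deep trees do not underflow.
#'
#' @param tree a [Chronogram-class].
#' @param obs a [TipObservations-class] covering every tip.
#' @param model a [TransitionModel-class].
#' @return The log-likelihood (a scalar).
#' @export
pruneLoglik <- function(tree, obs, model) {
  res <- .pruneRaw(tree, obs, model)
  if (res$impossible)
    stop("tip data are impossible under the constrained model ",
         "(zero likelihood given the transition mask and root prior)")
  res$loglik
}

#' Maximum-likelihood estimation of transition rates
#'
#' Fits the allowed transition rates by maximizing the pruning
#' log-likelihood. Optimization is bounded quasi-Newton (`L-BFGS-B`) on
#' log-rates, bounds `[lower, upper]` events/Myr, with `nStarts` seeded
#' random starts plus one start at 1/tree-height. The fit report records
#' every start, the optimizer iterations and the final numerical gradient
#' norm.
#'
#' @param tree a [Chronogram-class].
#' @param obs a [TipObservations-class] covering every tip.
#' @param mask allowed-transition mask (default [constrainedMask()]).
#' @param rootPrior root-state prior (default: fixed FT).
#' @param nStarts number of random starts in addition to the
#'   1/tree-height start.
#' @param seed seed for the random starts.
#' @param lower,upper rate bounds in events/Myr.
#' @return A fitted [TransitionModel-class] with `logLik` and `fitReport`
#'   populated.
#' @export
fitRates <- function(tree, obs, mask = constrainedMask(),
                     rootPrior = rootPriorFT(), nStarts = 5, seed = 1,
                     lower = 1e-8, upper = 10) {
  stopifnot(is(tree, "Chronogram"), is(obs, "TipObservations"))
  if (!any(mask)) stop("at least one transition must be allowed")
  lik <- .nodeLik(tree, obs)
  nTip <- length(tree@phy$tip.label)
  if (all(lik[seq_len(nTip), ] == 1))
    stop("all tips are uninformative ('unknown'): rates are not identifiable")
  ed <- .treeEdges(tree)
  rp <- as.numeric(rootPrior) / sum(rootPrior)
  allowed <- which(t(mask), arr.ind = TRUE)
  nms <- paste0(nodStates()[allowed[, 2L]], "->", nodStates()[allowed[, 1L]])
  npar <- length(nms)

  nll <- function(logr) {
    r <- stats::setNames(exp(logr), nms)
    Q <- matrix(0, 3L, 3L)
    Q[cbind(allowed[, 2L], allowed[, 1L])] <- r
    diag(Q) <- -rowSums(Q)
    P <- cpp_edge_probs(Q, ed$postLen)
    res <- cpp_prune(ed$postEdge, P, lik, ed$root, rp)
    if (res$impossible || !is.finite(res$loglik)) return(1e10)
    -res$loglik
  }

  h <- treeHeight(tree)
  starts <- list(rep(log(1 / max(h, 1e-6)), npar))
  set.seed(seed)
  for (i in seq_len(nStarts))
    starts[[i + 1L]] <- stats::runif(npar, log(1e-4), log(1))
  lb <- rep(log(lower), npar); ub <- rep(log(upper), npar)
  fits <- lapply(starts, function(s0) {
    tryCatch(
      stats::optim(pmin(pmax(s0, lb), ub), nll, method = "L-BFGS-B",
                   lower = lb, upper = ub,
                   control = list(factr = 1e-8 / .Machine$double.eps,
                                  maxit = 500)),
      error = function(e) list(value = Inf, par = s0, convergence = 99,
                               counts = c(`function` = 0L), message = conditionMessage(e)))
  })
  vals <- vapply(fits, function(f) f$value, numeric(1))
  if (!any(is.finite(vals)) || min(vals) >= 1e10)
    stop("optimization failed from every start; best value ", min(vals))
  spread <- diff(range(vals[is.finite(vals)]))
  best <- fits[[which.min(vals)]]
  if (all(vapply(fits, function(f) f$convergence != 0, logical(1))))
    stop("optimizer did not converge from any start; best loglik ",
         -best$value)
  # numerical gradient at the optimum (central differences on log-rates)
  eps <- 1e-5
  grad <- vapply(seq_len(npar), function(j) {
    d <- rep(0, npar); d[j] <- eps
    (nll(best$par + d) - nll(best$par - d)) / (2 * eps)
  }, numeric(1))
  rates <- stats::setNames(exp(best$par), nms)
  fitted <- transitionModel(rates, mask = mask, rootPrior = rp)
  fitted@logLik <- -best$value
  fitted@fitReport <- list(
    nStarts = length(starts),
    startValues = lapply(starts, exp),
    startLogliks = -vals,
    loglikSpreadAcrossStarts = spread,
    iterations = best$counts,
    convergence = best$convergence,
    gradientNorm = sqrt(sum(grad^2)),
    bounds = c(lower = lower, upper = upper),
    seed = seed)
  fitted
}

#' Serialize a fitted model to JSON
#'
#' Writes state order, mask, per-transition rates, Q, root prior,
#' log-likelihood and an optimizer trace summary.
#'
#' @param model a [TransitionModel-class].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeModelJson <- function(model, path) {
  stopifnot(is(model, "TransitionModel"))
  rep <- model@fitReport
  out <- list(
    states = nodStates(),
    mask = unname(apply(model@mask, 1L, as.logical, simplify = FALSE)),
    rates = as.list(model@rates),
    Q = unname(apply(model@Q, 1L, as.numeric, simplify = FALSE)),
    root_prior = as.numeric(model@rootPrior),
    loglik = model@logLik,
    fit = if (length(rep) > 0) list(
      n_starts = rep$nStarts,
      start_logliks = rep$startLogliks,
      convergence = rep$convergence,
      gradient_norm = rep$gradientNorm,
      seed = rep$seed) else NULL)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a fitted model back from JSON
#'
#' @param path a file written by [writeModelJson()].
#' @return A [TransitionModel-class].
#' @export
readModelJson <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  mask <- if (is.matrix(x$mask)) x$mask
          else matrix(unlist(x$mask), 3L, 3L, byrow = TRUE)
  storage.mode(mask) <- "logical"
  m <- transitionModel(unlist(x$rates), mask = mask,
                       rootPrior = as.numeric(x$root_prior))
  if (!is.null(x$loglik)) m@logLik <- as.numeric(x$loglik)
  m
}
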