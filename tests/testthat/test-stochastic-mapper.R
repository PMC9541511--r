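test_that("irreversibility forces node states when all tips are FT", {
  set.seed(12)
  chr <- randomChronogram(8, scale = 40)
  m <- transitionModel(c("FT->NON" = 0.02, "FT->SYM" = 0.01,
                         "SYM->NON" = 0.005))
  obs <- tipObservations(taxa(chr), rep("FT", 8))
  st <- sampleNodeStates(chr, obs, m, n = 50)
  expect_true(all(st == "FT"))  # NON absorbs and SYM cannot revert
})

test_that("the degenerate root prior pins the root state", {
  set.seed(13)
  chr <- randomChronogram(6, scale = 40)
  m <- randomModel()
  obs <- randomObservations(taxa(chr))
  st <- sampleNodeStates(chr, obs, m, n = 200)
  root <- length(taxa(chr)) + 1L
  expect_true(all(st[, root] == "FT"))
})

test_that("joint node-state draws match enumerated conditionals", {
  # two-tip tree, tips NON and FT, equal branches
  chr <- readChronogram("(A:10,B:10);")
  m <- transitionModel(c("FT->NON" = 0.05, "FT->SYM" = 0.02,
                         "SYM->NON" = 0.01))
  obs <- readTraitTable("taxon,status\nA,nonnodulating\nB,FT\n")
  exact <- oracleNodeMarginals(chr, obs, m)
  nDraw <- 20000
  set.seed(77)
  st <- sampleNodeStates(chr, obs, m, n = nDraw)
  for (node in seq_len(ncol(st))) {
    for (s in 1:3) {
      p <- exact[node, s]
      phat <- mean(st[, node] == nodStates()[s])
      se <- sqrt(max(p * (1 - p), 1e-12) / nDraw)
      expect_lt(abs(phat - p), max(3 * se, 1e-9))
    }
  }
})

test_that("endpoint-conditioned paths are empty when no path can exist", {
  m <- transitionModel(c("FT->NON" = 0.05, "FT->SYM" = 0.02,
                         "SYM->NON" = 0.01))
  set.seed(1)
  for (i in 1:50) {
    expect_equal(nrow(samplePath("NON", "NON", 30, m)), 0L)
    expect_equal(nrow(samplePath("FT", "FT", 30, m)), 0L)
  }
  expect_error(samplePath("NON", "FT", 10, m), "unreachable")
})

test_that("conditioned paths are chained, ordered and land on the endpoint", {
  m <- transitionModel(c("FT->NON" = 0.08, "FT->SYM" = 0.05,
                         "SYM->NON" = 0.04))
  set.seed(21)
  for (i in 1:200) {
    ev <- samplePath("FT", "NON", 25, m)
    expect_gte(nrow(ev), 1L)
    expect_true(all(diff(ev$time) > 0))
    expect_equal(ev$from[1], "FT")
    expect_equal(ev$to[nrow(ev)], "NON")
    if (nrow(ev) > 1)
      expect_equal(ev$from[-1], ev$to[-nrow(ev)])
    # every event uses an allowed transition
    expect_true(all(paste0(ev$from, "->", ev$to) %in%
                      c("FT->NON", "FT->SYM", "SYM->NON")))
  }
})

test_that("conditioned event counts match the rejection oracle", {
  Q <- rateMatrix(transitionModel(c("FT->NON" = 0.05, "FT->SYM" = 0.02,
                                    "SYM->NON" = 0.01)))
  m <- transitionModel(c("FT->NON" = 0.05, "FT->SYM" = 0.02,
                         "SYM->NON" = 0.01))
  n <- 20000
  set.seed(5)
  unif <- vapply(seq_len(n),
                 function(i) nrow(samplePath("FT", "NON", 30, m)),
                 numeric(1))
  rej <- oracleRejectionCounts(2L, 1L, 30, Q, n)
  for (k in sort(unique(c(unif, rej)))) {
    p <- mean(rej == k)
    phat <- mean(unif == k)
    se <- sqrt(p * (1 - p) / n + phat * (1 - phat) / n)
    expect_lt(abs(phat - p), max(3.5 * se, 5e-4))
  }
})

test_that("stochastic maps are reproducible and structurally valid", {
  set.seed(31)
  chr <- randomChronogram(10, scale = 50)
  m <- transitionModel(c("FT->NON" = 0.02, "FT->SYM" = 0.01,
                         "SYM->NON" = 0.01))
  obs <- randomObservations(taxa(chr))
  a <- stochasticMaps(chr, obs, m, n = 30, seed = 9)
  b <- stochasticMaps(chr, obs, m, n = 30, seed = 9)
  expect_identical(historyEvents(a), historyEvents(b))
  expect_identical(a@nodeStates, b@nodeStates)

  # per-history substreams: history h does not depend on how many were drawn
  c5 <- stochasticMaps(chr, obs, m, n = 5, seed = 9)
  expect_identical(c5@nodeStates, a@nodeStates[1:5, ])
  ea <- historyEvents(a)[historyEvents(a)$history <= 5, ]
  rownames(ea) <- NULL
  expect_identical(historyEvents(c5), ea)

  # no forbidden events under the constrained mask
  ev <- historyEvents(a)
  expect_true(all(paste0(ev$from, "->", ev$to) %in%
                    c("FT->NON", "FT->SYM", "SYM->NON")))

  # events are consistent with the sampled endpoint states
  phy <- apeTree(chr)
  for (h in unique(ev$history)) {
    sub <- ev[ev$history == h, ]
    for (e in unique(sub$edge)) {
      see <- sub[sub$edge == e, ]
      see <- see[order(see$time), ]
      states <- nodStates()[a@nodeStates[h, ]]
      expect_equal(see$from[1], states[phy$edge[e, 1L]])
      expect_equal(see$to[nrow(see)], states[phy$edge[e, 2L]])
    }
  }
})

test_that("zero-rate models yield event-free histories", {
  chr <- readChronogram("((A:1,B:1):1,C:2);")
  m <- transitionModel(c("FT->NON" = 0, "FT->SYM" = 0, "SYM->NON" = 0))
  obs <- tipObservations(taxa(chr), rep("FT", 3))
  maps <- stochasticMaps(chr, obs, m, n = 20, seed = 1)
  expect_equal(nrow(historyEvents(maps)), 0L)
  expect_true(all(maps@nodeStates == 2L))
})

test_that("dwelling times are non-negative and conserve total tree length", {
  set.seed(41)
  chr <- randomChronogram(12, scale = 60)
  m <- transitionModel(c("FT->NON" = 0.03, "FT->SYM" = 0.02,
                         "SYM->NON" = 0.02))
  obs <- randomObservations(taxa(chr))
  maps <- stochasticMaps(chr, obs, m, n = 50, seed = 2)
  dt <- dwellingTimes(maps)
  expect_true(all(dt >= -1e-12))
  total <- sum(apeTree(chr)$edge.length)
  expect_true(all(abs(rowSums(dt) - total) < 1e-9))

  # single-branch arithmetic: one event at time 4 on a branch of length 10
  chr2 <- readChronogram("(A:10,B:10);")
  m2 <- transitionModel(c("FT->NON" = 0.1))
  maps2 <- new("MappedHistorySet", tree = chr2, model = m2,
               nodeStates = matrix(c(1L, 2L, 2L), 1,
                                   dimnames = list(NULL, c("A", "B", "N3"))),
               events = data.frame(history = 1L, edge = 1L, time = 4,
                                   from = "FT", to = "NON",
                                   stringsAsFactors = FALSE),
               seed = 1)
  dt2 <- dwellingTimes(maps2)
  expect_equal(unname(dt2[1, ]), c(6, 14, 0))  # NON 6, FT 4 + 10, SYM 0
})

test_that("unconditional tip-pattern frequencies match the likelihood", {
  # ties the sampler to prune_loglik: tip-unconstrained maps binned by
  # realized tip pattern reproduce pattern probabilities
  chr <- readChronogram("((A:5,B:5):5,C:10);")
  m <- transitionModel(c("FT->NON" = 0.05, "FT->SYM" = 0.03,
                         "SYM->NON" = 0.02))
  obsFree <- tipObservations(taxa(chr), rep("unknown", 3))
  n <- 20000
  set.seed(55)
  st <- sampleNodeStates(chr, obsFree, m, n = n)
  pat <- apply(st[, 1:3], 1L, paste, collapse = "")
  for (states in list(c("NON", "NON", "NON"), c("FT", "FT", "FT"),
                      c("NON", "FT", "SYM"), c("SYM", "SYM", "NON"))) {
    obsP <- tipObservations(taxa(chr),
                            ifelse(states == "NON", "nonnodulating", states))
    p <- exp(pruneLoglik(chr, obsP, m))
    phat <- mean(pat == paste(states, collapse = ""))
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(phat - p), max(3 * se, 1e-9))
  }
})
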