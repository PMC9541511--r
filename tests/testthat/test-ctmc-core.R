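test_that("rate matrices respect the mask and zero row sums", {
  m <- transitionModel(c("FT->NON" = 0.0174, "FT->SYM" = 0.01,
                         "SYM->NON" = 0.0028))
  Q <- rateMatrix(m)
  expect_equal(Q["FT", "FT"], -0.0274)
  expect_equal(unname(Q["NON", ]), c(0, 0, 0))  # NON is absorbing
  expect_equal(unname(rowSums(Q)), c(0, 0, 0))
  expect_equal(Q["SYM", "FT"], 0)               # irreversible

  expect_equal(rateMatrix(transitionModel(c("FT->NON" = 0))),
               matrix(0, 3, 3, dimnames = list(nodStates(), nodStates())))
  expect_error(transitionModel(c("NON->FT" = 0.1)), "masked")
  expect_error(transitionModel(c("FT->NON" = -1)), ">= 0")
})

test_that("transition probabilities match closed forms", {
  # identity at t = 0
  m <- transitionModel(c("FT->NON" = 0.05, "FT->SYM" = 0.02,
                         "SYM->NON" = 0.01))
  expect_equal(unname(transitionProbability(m, 0)), diag(3))

  # single irreversible transition: P[SYM,NON] = 1 - exp(-q t)
  m1 <- transitionModel(c("SYM->NON" = 0.0028))
  expect_equal(transitionProbability(m1, 50)["SYM", "NON"],
               1 - exp(-0.14), tolerance = 1e-12)

  # FT is left irreversibly, so its survival is exponential in the total
  # exit rate
  for (t in c(0.5, 7, 30, 120)) {
    P <- transitionProbability(m, t)
    expect_equal(P["FT", "FT"], exp(-(0.05 + 0.02) * t), tolerance = 1e-12)
    expect_equal(unname(rowSums(P)), c(1, 1, 1), tolerance = 1e-10)
    expect_true(all(P >= 0 & P <= 1 + 1e-12))
  }
  expect_error(transitionProbability(m, -1), "non-negative")
})

test_that("P satisfies the semigroup property and irreversibility", {
  set.seed(3)
  for (i in 1:10) {
    mask <- if (i %% 2 == 0) constrainedMask() else allTransitionsMask()
    m <- randomModel(mask = mask)
    t1 <- runif(1, 0, 20); t2 <- runif(1, 0, 20)
    expect_equal(transitionProbability(m, t1 + t2),
                 transitionProbability(m, t1) %*%
                   transitionProbability(m, t2),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  # under the constrained mask NON stays NON and SYM never returns to FT
  m <- randomModel(mask = constrainedMask())
  for (t in c(1, 10, 100)) {
    P <- transitionProbability(m, t)
    expect_equal(unname(P["NON", ]), c(1, 0, 0))
    expect_equal(P["SYM", "FT"], 0)
  }
})

test_that("pruning likelihood matches closed forms on simple trees", {
  # two tips: one NON, the other uninformative; only FT->NON allowed, root
  # FT, so the likelihood is the single-branch absorption probability
  q <- 0.03; t1 <- 12
  chr <- readChronogram(sprintf("(A:%g,B:%g);", t1, t1))
  m <- transitionModel(c("FT->NON" = q))
  obs <- readTraitTable("taxon,status\nA,nonnodulating\nB,unknown\n")
  expect_equal(pruneLoglik(chr, obs, m), log(1 - exp(-q * t1)),
               tolerance = 1e-12)

  # all-unknown data carry no information: likelihood is exactly 1
  set.seed(5)
  chr2 <- randomChronogram(9)
  obsU <- tipObservations(taxa(chr2), rep("unknown", 9))
  m2 <- randomModel()
  expect_equal(pruneLoglik(chr2, obsU, m2), 0, tolerance = 1e-12)
})

test_that("pruning equals the enumeration oracle on small trees", {
  set.seed(17)
  for (i in 1:20) {
    chr <- randomChronogram(sample(3:6, 1))
    mask <- if (i %% 3 == 0) allTransitionsMask() else constrainedMask()
    rp <- if (i %% 2 == 0) rootPriorFT() else rootPriorUniform()
    m <- randomModel(mask = mask, rootPrior = rp)
    obs <- randomObservations(taxa(chr))
    ll <- tryCatch(pruneLoglik(chr, obs, m), error = function(e) e)
    if (inherits(ll, "error")) {
      expect_match(conditionMessage(ll), "impossible")
      expect_equal(oracleLoglik(chr, obs, m), -Inf)
    } else {
      expect_equal(ll, oracleLoglik(chr, obs, m), tolerance = 1e-10)
    }
  }
})

test_that("likelihood is invariant to the order of children", {
  set.seed(23)
  chr <- randomChronogram(7)
  m <- randomModel()
  obs <- randomObservations(taxa(chr))
  ll <- pruneLoglik(chr, obs, m)
  rot <- chronogramFromPhylo(ape::rotateConstr(
    apeTree(chr), sample(taxa(chr))))
  expect_equal(pruneLoglik(rot, obs, m), ll, tolerance = 1e-10)
})

test_that("impossible data raise an explicit error, not -Inf", {
  # root forced SYM but an FT tip exists: FT is unreachable from SYM
  chr <- readChronogram("(A:5,B:5);")
  m <- transitionModel(c("FT->NON" = 0.1, "FT->SYM" = 0.1,
                         "SYM->NON" = 0.1), rootPrior = c(0, 0, 1))
  obs <- readTraitTable("taxon,status\nA,FT\nB,SYM\n")
  expect_error(pruneLoglik(chr, obs, m), "impossible")
})

test_that("pruning agrees with an established Mk implementation", {
  skip_if_not_installed("phytools")
  set.seed(31)
  chr <- randomChronogram(12)
  m <- randomModel(mask = allTransitionsMask(),
                   rootPrior = rootPriorUniform())
  states <- sample(nodStates(), 12, replace = TRUE)
  obs <- tipObservations(taxa(chr), ifelse(states == "NON",
                                           "nonnodulating", states))
  x <- stats::setNames(states, taxa(chr))
  ord <- sort(nodStates())  # fitMk orders states alphabetically
  fit <- phytools::fitMk(apeTree(chr), x, fixedQ = rateMatrix(m)[ord, ord],
                         pi = rep(1 / 3, 3))
  expect_equal(pruneLoglik(chr, obs, m), unclass(stats::logLik(fit)),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("model JSON round-trips", {
  m <- transitionModel(c("FT->NON" = 0.0174, "FT->SYM" = 0.002,
                         "SYM->NON" = 0.0028))
  m@logLik <- -12.5
  path <- tempfile(fileext = ".json")
  writeModelJson(m, path)
  back <- readModelJson(path)
  expect_equal(rateMatrix(back), rateMatrix(m))
  expect_equal(rootPrior(back), rootPrior(m))
  expect_equal(back@logLik, -12.5)
})
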