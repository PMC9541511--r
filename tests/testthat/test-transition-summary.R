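# small hand-built history sets keep the summary arithmetic transparent
makeToyMaps <- function(tree, nodeStates, events = NULL, model = NULL) {
  if (is.null(model))
    model <- transitionModel(c("FT->NON" = 0.0174, "FT->SYM" = 0.002,
                               "SYM->NON" = 0.0028))
  if (is.null(events))
    events <- data.frame(history = integer(0), edge = integer(0),
                         time = numeric(0), from = character(0),
                         to = character(0), stringsAsFactors = FALSE)
  labels <- c(apeTree(tree)$tip.label, apeTree(tree)$node.label)
  colnames(nodeStates) <- labels
  new("MappedHistorySet", tree = tree, model = model,
      nodeStates = nodeStates, events = events, seed = 1)
}

test_that("node-state frequencies count histories and sum to one", {
  chr <- readChronogram("((A:1,B:1):1,C:2);")
  # 5 histories; internal node (N5) FT in 4 of 5
  st <- matrix(2L, 5, 5)
  st[, 1] <- 1L                 # tip A always NON
  st[5, 5] <- 3L                # one history has the (A,B) ancestor SYM
  maps <- makeToyMaps(chr, st)
  freq <- nodeStateFrequencies(maps)
  expect_equal(unname(freq["N5", ]), c(0, 0.8, 0.2))
  expect_equal(unname(freq["A", ]), c(1, 0, 0))   # clamped by data
  expect_equal(unname(rowSums(freq)), rep(1, 5))
})

test_that("majority transitions are emitted per branch with ages", {
  # ((A,B),C): root FT, internal NON, tips A,B NON, C FT
  chr <- readChronogram("((A:1,B:1):1,C:2);")
  freq <- rbind(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0),  # A, B, C
                c(0, 1, 0), c(1, 0, 0))              # root, internal
  rownames(freq) <- c("A", "B", "C", "N4", "N5")
  mt <- majorityTransitions(freq, chr)
  expect_equal(nrow(mt$transitions), 1L)
  expect_equal(mt$transitions$from, "FT")
  expect_equal(mt$transitions$to, "NON")
  expect_equal(mt$transitions$child, "N5")  # on the internal branch
  expect_equal(mt$transitions$parentAge, 2)
  expect_equal(mt$transitions$childAge, 1)
  expect_equal(unname(mt$countsByClass["FT->NON"]), 1L)
  expect_equal(sum(mt$countsByClass), nrow(mt$transitions))
})

test_that("double losses on sibling branches count separately", {
  chr <- readChronogram("((A:1,B:1):1,C:2);")
  # parent of A and B modal FT, both children modal NON
  freq <- rbind(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0),
                c(0, 1, 0), c(0.2, 0.8, 0))
  rownames(freq) <- c("A", "B", "C", "N4", "N5")
  mt <- majorityTransitions(freq, chr)
  expect_equal(unname(mt$countsByClass["FT->NON"]), 2L)
  expect_setequal(mt$transitions$child, c("A", "B"))
})

test_that("modal ties flag nodes instead of guessing", {
  chr <- readChronogram("((A:1,B:1):1,C:2);")
  freq <- rbind(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0),
                c(0, 1, 0), c(0.5, 0.5, 0))          # tied internal node
  rownames(freq) <- c("A", "B", "C", "N4", "N5")
  mt <- majorityTransitions(freq, chr)
  expect_equal(mt$ambiguousNodes, 5L)
  # edges touching the tied node are unresolved, not guessed
  phy <- apeTree(chr)
  touching <- which(phy$edge[, 1L] == 5L | phy$edge[, 2L] == 5L)
  expect_setequal(mt$unresolvedEdges, touching)
  expect_false(any(mt$transitions$edge %in% touching))
})

test_that("event-count distributions are per-class frequencies", {
  chr <- readChronogram("((A:1,B:1):1,C:2);")
  st <- matrix(2L, 3, 5)
  ev <- data.frame(
    history = c(1L, 1L, 2L, 2L, 2L, 3L, 3L),
    edge = 1L, time = 0.5,
    from = "FT", to = "NON", stringsAsFactors = FALSE)
  maps <- makeToyMaps(chr, st, ev)
  d <- eventCountDistribution(maps)
  expect_equal(d[["FT->NON"]], c(`2` = 2 / 3, `3` = 1 / 3))
  expect_equal(d[["FT->SYM"]], c(`0` = 1))
  for (cl in names(d)) expect_equal(sum(d[[cl]]), 1)
})

test_that("loss rates report both the Q entries and realized rates", {
  chr <- readChronogram("(A:50,B:50);")
  # one history: everything FT, two FT->NON events would contradict the
  # endpoint states, so build the arithmetic case directly: tips NON,
  # 2 loss events, dwelling FT = 100 - sum(rest)
  st <- matrix(c(1L, 1L, 2L), 1)
  ev <- data.frame(history = 1L, edge = c(1L, 2L), time = c(20, 30),
                   from = "FT", to = "NON", stringsAsFactors = FALSE)
  m <- transitionModel(c("FT->NON" = 0.0174, "FT->SYM" = 0.002,
                         "SYM->NON" = 0.0028))
  maps <- makeToyMaps(chr, st, ev, model = m)
  lr <- lossRates(m, maps)
  expect_equal(unname(lr$q[["FT->NON"]]), 0.0174)
  expect_equal(unname(lr$q[["SYM->NON"]]), 0.0028)
  expect_equal(lr$ratio, 0.0174 / 0.0028, tolerance = 1e-12)
  # realized: 2 events over 20 + 30 Myr of FT dwelling = 0.04 /Myr
  real <- lr$realized
  expect_equal(real$mean[real$class == "FT->NON"], 2 / 50)
  # no SYM dwelling at all: the class is excluded, with a logged count
  expect_equal(real$nExcluded[real$class == "SYM->NON"], 1L)
})

test_that("zero-rate classes have zero realized rates", {
  set.seed(61)
  chr <- randomChronogram(8, scale = 40)
  m <- transitionModel(c("FT->NON" = 0.05, "FT->SYM" = 0.05,
                         "SYM->NON" = 0))
  obs <- tipObservations(taxa(chr), rep("unknown", 8))
  maps <- stochasticMaps(chr, obs, m, n = 30, seed = 3)
  lr <- lossRates(m, maps)
  r <- lr$realized
  sym <- r[r$class == "SYM->NON", ]
  if (!is.na(sym$mean)) expect_equal(sym$mean, 0)
})

test_that("age bounds and spans follow the branch endpoints", {
  tr <- data.frame(
    edge = 1:3,
    parent = "p", child = "c",
    from = c("FT", "FT", "FT"), to = c("SYM", "NON", "NON"),
    class = c("FT->SYM", "FT->NON", "FT->NON"),
    parentAge = c(46, 59, 24), childAge = c(41, 30, 0),
    stringsAsFactors = FALSE)
  ab <- transitionAgeBounds(tr)
  expect_equal(ab$perTransition$maxAge, c(46, 59, 24))
  expect_equal(ab$perTransition$minAge, c(41, 30, 0))
  spans <- ab$spans
  ftnon <- spans[spans$class == "FT->NON", ]
  expect_equal(ftnon$oldestMaxAge, 59)
  expect_equal(ftnon$youngestMaxAge, 24)
  # single-transition class: span collapses to its own maximum age
  ftsym <- spans[spans$class == "FT->SYM", ]
  expect_equal(ftsym$oldestMaxAge, 46)
  expect_equal(ftsym$youngestMaxAge, 46)
})

test_that("summaries are invariant to history order and tip relabeling", {
  set.seed(71)
  chr <- randomChronogram(10, scale = 50)
  m <- transitionModel(c("FT->NON" = 0.03, "FT->SYM" = 0.02,
                         "SYM->NON" = 0.02))
  obs <- randomObservations(taxa(chr))
  maps <- stochasticMaps(chr, obs, m, n = 40, seed = 5)
  rep1 <- summarizeHistories(maps)

  perm <- sample(40)
  maps2 <- maps
  maps2@nodeStates <- maps@nodeStates[perm, ]
  ev <- historyEvents(maps)
  ev$history <- match(ev$history, perm)
  maps2@events <- ev
  rep2 <- summarizeHistories(maps2)
  expect_equal(rep2@countsByClass, rep1@countsByClass)
  expect_equal(rep2@nodeProportions, rep1@nodeProportions)

  # relabeling tips changes nothing but the labels
  chr3 <- chr
  chr3@phy$tip.label <- paste0("x_", chr3@phy$tip.label)
  maps3 <- maps
  maps3@tree <- chr3
  colnames(maps3@nodeStates) <- c(chr3@phy$tip.label, chr3@phy$node.label)
  rep3 <- summarizeHistories(maps3)
  expect_equal(rep3@countsByClass, rep1@countsByClass)
})

test_that("summary reports validate and write their outputs", {
  set.seed(81)
  chr <- randomChronogram(8, scale = 50)
  m <- transitionModel(c("FT->NON" = 0.02, "FT->SYM" = 0.01,
                         "SYM->NON" = 0.01))
  obs <- randomObservations(taxa(chr))
  maps <- stochasticMaps(chr, obs, m, n = 25, seed = 4)
  report <- summarizeHistories(maps)
  expect_s4_class(report, "SummaryReport")
  lc <- lossCounts(report)
  expect_equal(lc[["total"]], lc[["fromFT"]] + lc[["fromSYM"]])

  dir <- tempfile()
  writeSummary(report, dir)
  expect_true(file.exists(file.path(dir, "summary.json")))
  expect_true(file.exists(file.path(dir, "node_proportions.csv")))
  expect_true(file.exists(file.path(dir, "majority_transitions.csv")))
  # the annotated tree re-parses and keeps modal states as labels
  ann <- ape::read.tree(file.path(dir, "annotated_tree.nwk"))
  expect_true(all(grepl("\\|(NON|FT|SYM)$", ann$node.label)))
  js <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(js$n_histories, 25L)
  expect_equal(length(js$counts_by_class), 4L)
})
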