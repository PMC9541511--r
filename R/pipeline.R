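## Run orchestration: configuration, fitting, mapping, summarizing, and
## full runs writing a self-contained run directory.

#' Build a run configuration
#'
#' Collects everything one analysis run needs. Presets: `mask` is
#' `"constrained"` (FT->NON, FT->SYM, SYM->NON only; the primary model) or
#' `"all"` (every transition allowed; the sensitivity model); `root` is
#' `"FT"` (root fixed to the fixation-thread state) or `"uniform"`, or a
#' custom 3-vector of weights. `stateOverrides` re-scores named tips
#' before fitting (e.g. to inject additional hypothesized losses), so
#' sensitivity variants need no edits to the input table.
#'
#' @param tree path to a Newick chronogram.
#' @param traits path to a `taxon,status` CSV.
#' @param mask transition-mask preset or a 3x3 logical matrix.
#' @param root root-prior preset or a numeric 3-vector.
#' @param nMaps number of stochastic maps (default 500, the study design).
#' @param seed master seed.
#' @param out output directory (`NULL` for no file output).
#' @param stateOverrides named character vector tip -> category.
#' @param autoUnknown score tips missing from the table as `unknown`.
#' @param categoryVectors per-category likelihood vectors (see
#'   [readTraitTable()]).
#' @return A validated config list of class `nodRunConfig`.
#' @export
runConfig <- function(tree, traits, mask = "constrained", root = "FT",
                      nMaps = 500, seed = 1, out = NULL,
                      stateOverrides = character(0), autoUnknown = FALSE,
                      categoryVectors = observationCategories()) {
  if (nMaps < 1) stop("nMaps must be >= 1")
  maskM <- if (is.matrix(mask)) mask
  else switch(match.arg(mask, c("constrained", "all")),
              constrained = constrainedMask(), all = allTransitionsMask())
  rootV <- if (is.numeric(root)) {
    if (length(root) != 3L) stop("custom root prior must have 3 weights")
    root / sum(root)
  } else switch(match.arg(root, c("FT", "uniform")),
                FT = rootPriorFT(), uniform = rootPriorUniform())
  structure(list(tree = tree, traits = traits, mask = maskM,
                 root = rootV, nMaps = as.integer(nMaps), seed = seed,
                 out = out, stateOverrides = stateOverrides,
                 autoUnknown = autoUnknown,
                 categoryVectors = categoryVectors),
            class = "nodRunConfig")
}

#' Read a run configuration from YAML
#'
#' Recognized keys: `tree`, `traits`, `mask`, `root`, `n_maps`, `seed`,
#' `out`, `auto_unknown`, `state_overrides` (a mapping taxon: category).
#' Arguments passed directly override file values.
#'
#' @param path YAML file.
#' @param ... overrides forwarded to [runConfig()].
#' @return A config list (see [runConfig()]).
#' @export
readRunConfig <- function(path, ...) {
  y <- yaml::read_yaml(path)
  args <- list(
    tree = y$tree, traits = y$traits,
    mask = if (is.null(y$mask)) "constrained" else y$mask,
    root = if (is.null(y$root)) "FT" else y$root,
    nMaps = if (is.null(y$n_maps)) 500 else y$n_maps,
    seed = if (is.null(y$seed)) 1 else y$seed,
    out = y$out,
    stateOverrides = if (is.null(y$state_overrides)) character(0)
                     else unlist(y$state_overrides),
    autoUnknown = isTRUE(y$auto_unknown))
  override <- list(...)
  args[names(override)] <- override
  do.call(runConfig, args)
}

# load + match inputs per a config
.loadInputs <- function(config) {
  tree <- readChronogram(config$tree)
  obs <- readTraitTable(config$traits,
                        categoryVectors = config$categoryVectors)
  if (length(config$stateOverrides) > 0) {
    cat <- observationCategory(obs)
    nm <- .normalizeTaxon(names(config$stateOverrides))
    missing <- setdiff(nm, names(cat))
    if (length(missing) > 0)
      stop("stateOverrides name taxa absent from the table: ",
           paste(missing, collapse = ", "))
    cat[nm] <- config$stateOverrides
    obs <- tipObservations(names(cat), unname(cat),
                           categoryVectors = config$categoryVectors)
  }
  m <- matchTips(tree, obs, autoUnknown = config$autoUnknown)
  list(tree = m$tree, obs = m$obs)
}

#' Fit the transition model for a configured run
#'
#' Loads and matches the inputs, fits the rates by maximum likelihood and,
#' when the config has an output directory, writes `model.json`.
#'
#' @param config a config from [runConfig()] / [readRunConfig()].
#' @return The fitted [TransitionModel-class].
#' @export
fitModel <- function(config) {
  inp <- .loadInputs(config)
  model <- fitRates(inp$tree, inp$obs, mask = config$mask,
                    rootPrior = config$root, seed = .asSeed(config$seed))
  if (!is.null(config$out)) {
    .ensureDir(config$out)
    writeModelJson(model, file.path(config$out, "model.json"))
  }
  model
}

#' Generate stochastic maps for a configured run
#'
#' @param config a run config.
#' @param model a fitted [TransitionModel-class] (defaults to fitting one).
#' @return A [MappedHistorySet-class]; with an output directory set,
#'   writes `events.csv` and `node_states.csv`.
#' @export
mapHistories <- function(config, model = NULL) {
  inp <- .loadInputs(config)
  if (is.null(model)) model <- fitModel(config)
  maps <- stochasticMaps(inp$tree, inp$obs, model, n = config$nMaps,
                         seed = .asSeed(config$seed))
  if (!is.null(config$out)) {
    .ensureDir(config$out)
    utils::write.csv(historyEvents(maps),
                     file.path(config$out, "events.csv"),
                     row.names = FALSE)
    st <- historyNodeStates(maps)
    utils::write.csv(
      data.frame(history = rep(seq_len(nrow(st)), ncol(st)),
                 node = rep(colnames(st), each = nrow(st)),
                 state = as.vector(st)),
      file.path(config$out, "node_states.csv"), row.names = FALSE)
  }
  maps
}

#' Summarize a configured run
#'
#' @param config a run config.
#' @param maps a [MappedHistorySet-class].
#' @return A [SummaryReport-class]; with an output directory set, writes
#'   the summary files (see [writeSummary()]).
#' @export
summarizeRun <- function(config, maps) {
  report <- summarizeHistories(maps)
  if (!is.null(config$out)) writeSummary(report, config$out)
  report
}

#' Run the whole pipeline
#'
#' Fit, map, summarize; when the config has an output directory, writes a
#' config snapshot (`config.yaml`), a log file with the seeds used, the
#' fitted model, the history tables and the summary files — enough to
#' re-run the analysis bit-identically.
#'
#' @param config a run config.
#' @return List with `model`, `maps`, `report` and `dir`.
#' @export
runPipeline <- function(config) {
  t0 <- Sys.time()
  if (!is.null(config$out)) {
    .ensureDir(config$out)
    snap <- list(tree = config$tree, traits = config$traits,
                 mask = if (identical(config$mask, constrainedMask()))
                   "constrained" else "all",
                 root = as.numeric(config$root), n_maps = config$nMaps,
                 seed = config$seed, auto_unknown = config$autoUnknown,
                 state_overrides = as.list(config$stateOverrides))
    yaml::write_yaml(snap, file.path(config$out, "config.yaml"))
  }
  model <- fitModel(config)
  maps <- mapHistories(config, model)
  report <- summarizeRun(config, maps)
  if (!is.null(config$out)) {
    lc <- lossCounts(report)
    log <- c(
      sprintf("seed: %s", format(config$seed)),
      sprintf("n_maps: %d", config$nMaps),
      sprintf("loglik: %.6f", model@logLik),
      sprintf("rates: %s",
              paste(sprintf("%s=%.4f", names(model@rates), model@rates),
                    collapse = " ")),
      sprintf("losses: total=%d from_FT=%d from_SYM=%d", lc[["total"]],
              lc[["fromFT"]], lc[["fromSYM"]]),
      sprintf("elapsed_s: %.1f",
              as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    writeLines(log, file.path(config$out, "run.log"))
  }
  list(model = model, maps = maps, report = report, dir = config$out)
}

.ensureDir <- function(d) if (!dir.exists(d)) dir.create(d, recursive = TRUE)

.asSeed <- function(s) as.integer(s %% 2147483647)
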