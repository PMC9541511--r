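## Stage 0 of the pipeline: chronograms and tip-trait tables.

# worst spread among root-to-tip path lengths (0 for a perfectly
# ultrametric tree)
.ultrametricDeviation <- function(phy) {
  depths <- ape::node.depth.edgelength(phy)[seq_along(phy$tip.label)]
  max(depths) - min(depths)
}

.normalizeTaxon <- function(x) gsub("\\s+", "_", trimws(x))

#' Read and validate a time-calibrated tree
#'
#' Parses a rooted Newick tree with branch lengths in millions of years and
#' validates it as a chronogram: no negative branch lengths, ultrametric
#' within a relative tolerance, parent ages above child ages. Node ages are
#' measured backwards from the present, with tip ages forced to exactly 0
#' after validation. Internal nodes without labels receive stable
#' auto-assigned ids (`N<number>`); polytomies are retained as hard
#' polytomies.
#'
#' @param newick a Newick string, or the path of a file containing one.
#' @param tol relative ultrametricity tolerance, as a fraction of tree
#'   height (default `1e-3`; dating pipelines emit rounded branch lengths).
#' @return A [Chronogram-class].
#' @export
#' @examples
#' chr <- readChronogram("((A:1,B:1):1,C:2);")
#' treeHeight(chr)
readChronogram <- function(newick, tol = 1e-3) {
  stopifnot(is.character(newick), length(newick) == 1L)
  phy <- if (grepl("\\(", newick) && grepl(";", newick)) {
    ape::read.tree(text = newick)
  } else {
    ape::read.tree(file = newick)
  }
  if (is.null(phy)) stop("could not parse Newick input")
  chronogramFromPhylo(phy, tol = tol)
}

#' Build a chronogram from an existing ape tree
#'
#' Validation and node-age computation shared by [readChronogram()] and the
#' synthetic-data generator.
#'
#' @param phy an `ape::phylo` object with branch lengths in Myr.
#' @param tol relative ultrametricity tolerance (see [readChronogram()]).
#' @return A [Chronogram-class].
#' @export
chronogramFromPhylo <- function(phy, tol = 1e-3) {
  if (!inherits(phy, "phylo")) stop("'phy' must be an ape phylo object")
  if (is.null(phy$edge.length)) stop("tree must have branch lengths")
  nTip <- length(phy$tip.label)
  if (any(phy$edge.length < 0)) {
    bad <- which(phy$edge.length < 0)[1L]
    child <- phy$edge[bad, 2L]
    lab <- if (child <= nTip) phy$tip.label[child] else paste0("node ", child)
    stop(sprintf("negative branch length (%.6g) on the branch to '%s'",
                 phy$edge.length[bad], lab))
  }
  if (is.null(phy$node.label) ||
      any(!nzchar(phy$node.label)) || anyNA(phy$node.label)) {
    lab <- phy$node.label
    if (is.null(lab)) lab <- rep("", phy$Nnode)
    empty <- !nzchar(lab) | is.na(lab)
    lab[empty] <- paste0("N", nTip + which(empty))
    phy$node.label <- lab
  }
  depths <- ape::node.depth.edgelength(phy)
  height <- max(depths[seq_len(nTip)])
  dev <- max(depths[seq_len(nTip)]) - min(depths[seq_len(nTip)])
  if (height > 0 && dev > tol * height) {
    worst <- which.min(depths[seq_len(nTip)])
    stop(sprintf(
      paste0("tree is not ultrametric: root-to-tip paths differ by %.6g Myr ",
             "(worst tip '%s'), beyond %.3g x height = %.6g"),
      dev, phy$tip.label[worst], tol, tol * height))
  }
  ages <- height - depths
  ages[seq_len(nTip)] <- 0  # tips sit exactly at the present
  new("Chronogram", phy = phy, nodeAges = ages, tol = tol)
}

#' Write a chronogram to Newick
#'
#' @param x a [Chronogram-class].
#' @param file optional path; if `NULL` the Newick string is returned.
#' @param digits significant digits for branch lengths.
#' @return The Newick string (invisibly when written to a file).
#' @export
writeChronogram <- function(x, file = NULL, digits = 12) {
  stopifnot(is(x, "Chronogram"))
  txt <- ape::write.tree(x@phy, digits = digits)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Prune a chronogram to representative tips
#'
#' Restricts the tree to a kept taxon set (e.g. one representative taxon per
#' genus), collapsing unifurcating internal nodes by summing branch lengths
#' so that all pairwise path lengths among kept tips are unchanged.
#'
#' @param tree a [Chronogram-class].
#' @param keep character vector of tip labels to retain (at least 2).
#' @return The pruned [Chronogram-class].
#' @export
#' @examples
#' chr <- readChronogram("((A:1,B:1):1,C:2);")
#' taxa(pruneToRepresentatives(chr, c("A", "C")))
pruneToRepresentatives <- function(tree, keep) {
  stopifnot(is(tree, "Chronogram"))
  keep <- unique(as.character(keep))
  missing <- setdiff(keep, tree@phy$tip.label)
  if (length(missing) > 0)
    stop("taxa not in tree: ", paste(missing, collapse = ", "))
  if (length(keep) < 2) stop("need at least 2 tips to keep")
  phy <- ape::keep.tip(tree@phy, keep)
  chronogramFromPhylo(phy, tol = tree@tol)
}

#' Read a tip trait table
#'
#' Parses a CSV with header columns `taxon,status`, where `status` is one of
#' the five observation categories (case-insensitive; extra aliases
#' configurable). Each category is expanded to a state-likelihood vector
#' over [nodStates()]; the vectors themselves are configurable so that
#' alternative weightings of missing data can be analyzed.
#'
#' @param csv a CSV string or file path.
#' @param aliases named character vector mapping extra status spellings to
#'   canonical categories (names are lower-cased before matching).
#' @param categoryVectors named list of per-category likelihood vectors
#'   (default [observationCategories()]).
#' @return A [TipObservations-class].
#' @export
#' @examples
#' obs <- readTraitTable("taxon,status\nErythrophleum_ivorense,FT\n")
#' stateLikelihoods(obs)
readTraitTable <- function(csv, aliases = character(0),
                           categoryVectors = observationCategories()) {
  stopifnot(is.character(csv), length(csv) == 1L)
  df <- if (grepl("\n", csv) || grepl(",", csv)) {
    utils::read.csv(text = csv, stringsAsFactors = FALSE)
  } else {
    utils::read.csv(csv, stringsAsFactors = FALSE)
  }
  names(df) <- tolower(names(df))
  if (!all(c("taxon", "status") %in% names(df)))
    stop("trait table must have header columns 'taxon,status'")
  tipObservations(df$taxon, df$status, aliases = aliases,
                  categoryVectors = categoryVectors)
}

#' Construct tip observations from vectors
#'
#' @param taxa character vector of taxon names.
#' @param status observation categories, parallel to `taxa`.
#' @inheritParams readTraitTable
#' @return A [TipObservations-class].
#' @export
tipObservations <- function(taxa, status, aliases = character(0),
                            categoryVectors = observationCategories()) {
  taxa <- .normalizeTaxon(taxa)
  canon <- names(observationCategories())
  lut <- stats::setNames(canon, tolower(canon))
  lut <- c(lut, stats::setNames(as.character(aliases),
                                tolower(names(aliases))))
  key <- tolower(gsub("[ -]", "_", trimws(status)))
  cat <- unname(lut[key])
  if (anyNA(cat)) {
    bad <- which(is.na(cat))[1L]
    stop(sprintf("unknown status '%s' for taxon '%s' (row %d)",
                 status[bad], taxa[bad], bad))
  }
  if (anyDuplicated(taxa))
    stop("duplicate taxon in trait table: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  vecs <- categoryVectors[cat]
  lik <- do.call(rbind, lapply(vecs, as.numeric))
  dimnames(lik) <- list(taxa, nodStates())
  new("TipObservations", taxa = taxa, category = cat, likMatrix = lik)
}

#' Match tip observations to a chronogram
#'
#' Verifies that every tip of the tree has exactly one observation (exact
#' string match after whitespace/underscore normalization; no fuzzy
#' matching) and reorders the observations to tip order. Table rows that
#' match no tip are reported with a warning, never silently dropped. Tips
#' without an observation are an error unless `autoUnknown = TRUE`, in
#' which case they are scored `unknown` and reported.
#'
#' @param tree a [Chronogram-class].
#' @param obs a [TipObservations-class].
#' @param autoUnknown assign the `unknown` category to unmatched tips
#'   instead of failing.
#' @return List with elements `tree`, `obs` (tip-ordered) and `unmatched`
#'   (table rows that matched no tip).
#' @export
matchTips <- function(tree, obs, autoUnknown = FALSE) {
  stopifnot(is(tree, "Chronogram"), is(obs, "TipObservations"))
  tips <- .normalizeTaxon(tree@phy$tip.label)
  idx <- match(tips, obs@taxa)
  missingTips <- tree@phy$tip.label[is.na(idx)]
  if (length(missingTips) > 0 && !autoUnknown)
    stop("tips without a trait observation: ",
         paste(missingTips, collapse = ", "),
         " (set autoUnknown = TRUE to score them 'unknown')")
  unmatched <- setdiff(obs@taxa, tips)
  if (length(unmatched) > 0)
    warning(length(unmatched), " trait-table row(s) match no tip: ",
            paste(unmatched, collapse = ", "))
  cat <- ifelse(is.na(idx), "unknown", obs@category[idx])
  if (length(missingTips) > 0)
    message("scored ", length(missingTips), " tip(s) as 'unknown': ",
            paste(missingTips, collapse = ", "))
  lik <- matrix(NA_real_, length(tips), 3L,
                dimnames = list(tips, nodStates()))
  known <- !is.na(idx)
  lik[known, ] <- obs@likMatrix[idx[known], , drop = FALSE]
  lik[!known, ] <- rep(as.numeric(observationCategories()$unknown),
                       each = sum(!known))
  ordered <- new("TipObservations", taxa = tips, category = cat,
                 likMatrix = lik)
  list(tree = tree, obs = ordered, unmatched = unmatched)
}
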