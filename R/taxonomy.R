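#' Build a taxonomy tree from per-sample rank labels
#'
#' Collects the distinct display names at each rank, assigns dense 0-based
#' category ids in lexicographic (C collation) order within each level, and
#' records the parent of every category from the observed label tuples. The
#' result is invariant under duplication and permutation of the records.
#'
#' @param records a data.frame or matrix of display names with one column per
#'   level (coarsest first) and one row per sample, or a list of equal-length
#'   character vectors (one vector per sample).
#' @param levelNames character vector naming the levels, coarsest first.
#' @return a [TaxonomyTree-class].
#' @examples
#' tree <- buildTaxonomy(
#'   data.frame(k = c("Animalia", "Animalia", "Plantae"),
#'              s = c("wolf", "lynx", "oak")),
#'   levelNames = c("Kingdom", "Species"))
#' levelSizes(tree)
#' @export
buildTaxonomy <- function(records, levelNames) {
  m <- asLabelMatrix(records, length(levelNames))
  L <- length(levelNames)
  if (nrow(m) == 0L) stopf("buildTaxonomy: no records")
  if (anyNA(m) || any(m == "")) stopf("buildTaxonomy: every record needs one label per level")
  nms <- vector("list", L)
  parent <- vector("list", L)
  parent[[1L]] <- integer(0)
  for (i in seq_len(L)) nms[[i]] <- csort(unique(m[, i]))
  for (i in seq_len(L)[-1L]) {
    pair <- unique(data.frame(child = m[, i], par = m[, i - 1L],
                              stringsAsFactors = FALSE))
    dup <- pair$child[duplicated(pair$child)]
    if (length(dup))
      stopf("inconsistent labels: %s '%s' appears under two distinct parents",
            levelNames[i], dup[1L])
    idx <- match(nms[[i]], pair$child)
    parent[[i]] <- match(pair$par[idx], nms[[i - 1L]]) - 1L
  }
  new("TaxonomyTree", levelNames = as.character(levelNames),
      names = nms, parent = parent)
}

asLabelMatrix <- function(records, L) {
  if (is.list(records) && !is.data.frame(records)) {
    records <- do.call(rbind, lapply(records, function(r) as.character(unlist(r))))
  }
  m <- as.matrix(as.data.frame(records, stringsAsFactors = FALSE))
  storage.mode(m) <- "character"
  if (ncol(m) != L) stopf("expected %d label columns, got %d", L, ncol(m))
  m
}

#' Root-to-leaf label path of a finest-level category
#'
#' @param tree a [TaxonomyTree-class].
#' @param leafId 0-based category id at the finest level.
#' @return integer vector of 0-based ids, one per level, forming the unique
#'   root-to-leaf path ending at `leafId`.
#' @export
ancestorPath <- function(tree, leafId) {
  L <- nLevels(tree)
  K <- levelSizes(tree)[L]
  leafId <- as.integer(leafId)
  if (length(leafId) != 1L || is.na(leafId) || leafId < 0L || leafId >= K)
    stopf("unknown leaf id %s (finest level has %d categories)", leafId, K)
  path <- integer(L)
  path[L] <- leafId
  for (i in rev(seq_len(L - 1L))) path[i] <- tree@parent[[i + 1L]][path[i + 1L] + 1L]
  path
}

#' Do per-level labels form a valid root-to-leaf path?
#'
#' The per-rank heads of a multilevel classifier are independent, so their
#' argmax labels need not be hierarchically consistent; this diagnostic
#' quantifies cross-level agreement.
#'
#' @param tree a [TaxonomyTree-class].
#' @param labels integer vector of 0-based ids, one per level.
#' @return TRUE iff consecutive entries are parent and child in `tree`.
#' @export
isConsistentPrediction <- function(tree, labels) {
  L <- nLevels(tree)
  labels <- as.integer(labels)
  if (length(labels) != L) stopf("expected %d labels, got %d", L, length(labels))
  sizes <- levelSizes(tree)
  if (any(labels < 0L) || any(labels >= sizes)) return(FALSE)
  for (i in seq_len(L)[-1L]) {
    if (tree@parent[[i]][labels[i] + 1L] != labels[i - 1L]) return(FALSE)
  }
  TRUE
}

#' Display names of a label path
#'
#' @param tree a [TaxonomyTree-class].
#' @param labels integer vector of 0-based ids, one per level.
#' @return character vector of display names.
#' @export
labelNames <- function(tree, labels) {
  vapply(seq_len(nLevels(tree)),
         function(i) tree@names[[i]][labels[i] + 1L], "")
}

#' Serialize a taxonomy to JSON
#'
#' Document layout: `{level_names, nodes: [{level, id, name, parent_id}]}`
#' with 0-based `level` and `id`; root-level nodes have `parent_id: null`.
#'
#' @param tree a [TaxonomyTree-class].
#' @param path optional file to write to.
#' @return the JSON string, invisibly when `path` is given.
#' @export
taxonomyToJSON <- function(tree, path = NULL) {
  nodes <- do.call(rbind, lapply(seq_len(nLevels(tree)), function(i) {
    n <- length(tree@names[[i]])
    data.frame(level = i - 1L, id = seq_len(n) - 1L, name = tree@names[[i]],
               parent_id = if (i == 1L) rep(NA_integer_, n) else tree@parent[[i]],
               stringsAsFactors = FALSE)
  }))
  doc <- list(level_names = tree@levelNames, nodes = nodes)
  txt <- jsonlite::toJSON(doc, dataframe = "rows", auto_unbox = TRUE,
                          pretty = TRUE, na = "null")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Read a taxonomy from its JSON serialization
#'
#' @param path file path or JSON string as produced by [taxonomyToJSON()].
#' @return a [TaxonomyTree-class].
#' @export
taxonomyFromJSON <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  lv <- as.character(doc$level_names)
  L <- length(lv)
  nodes <- doc$nodes
  nms <- vector("list", L)
  parent <- vector("list", L)
  parent[[1L]] <- integer(0)
  for (i in seq_len(L)) {
    sub <- nodes[nodes$level == i - 1L, , drop = FALSE]
    sub <- sub[order(sub$id), , drop = FALSE]
    nms[[i]] <- sub$name
    if (i > 1L) parent[[i]] <- as.integer(sub$parent_id)
  }
  new("TaxonomyTree", levelNames = lv, names = nms, parent = parent)
}
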