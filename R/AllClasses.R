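#' @import methods
NULL

#' TaxonomyTree: the multi-rank label hierarchy
#'
#' Stores the named rank levels (coarsest first), the display names of every
#' category at every level, and the single-parent links between consecutive
#' levels. Category ids are dense 0-based integers per level, assigned in
#' lexicographic (C collation) order of display names, so a tree rebuilt from
#' the same labels always carries the same ids.
#'
#' @slot levelNames character vector of rank names, coarsest first.
#' @slot names list of character vectors; element `i` holds the display names
#'   at level `i` indexed by `id + 1`.
#' @slot parent list of integer vectors; element `i` (for `i >= 2`) maps each
#'   node id at level `i` to its parent id at level `i - 1`. Element 1 is an
#'   empty integer vector.
#' @export
setClass("TaxonomyTree", representation(
  levelNames = "character",
  names = "list",
  parent = "list"
))

setValidity("TaxonomyTree", function(object) {
  L <- length(object@levelNames)
  if (length(object@names) != L || length(object@parent) != L)
    return("names and parent must have one element per level")
  for (i in seq_len(L)) {
    nm <- object@names[[i]]
    if (anyDuplicated(nm)) return(sprintf("duplicate display names at level %d", i))
    if (i == 1L) {
      if (length(object@parent[[1L]]) != 0L)
        return("level 1 must have no parent links")
    } else {
      p <- object@parent[[i]]
      if (length(p) != length(nm))
        return(sprintf("level %d: parent vector length mismatch", i))
      if (any(p < 0L | p >= length(object@names[[i - 1L]])))
        return(sprintf("level %d: parent id out of range", i))
    }
  }
  # every non-leaf node must have at least one child (paths touch every level)
  for (i in seq_len(L - 1L)) {
    nchild <- length(object@names[[i]])
    if (length(unique(object@parent[[i + 1L]])) != nchild)
      return(sprintf("level %d has childless categories", i))
  }
  TRUE
})

#' DatasetManifest: a split-tagged collection of labelled image records
#'
#' Each record is one image reference plus its per-rank label vector (dense
#' 0-based category ids, one per level) and a split tag. Records produced by
#' augmentation additionally carry the path of their source image, the name of
#' the transform pipeline, and the seed that makes the transform reproducible.
#'
#' @slot records data.frame with columns `path`, `split`,
#'   `label_level0..label_level{L-1}`, `source_path`, `transform`,
#'   `transform_seed`.
#' @slot tree the [TaxonomyTree-class] the labels refer to.
#' @slot imageRoot directory against which relative `path`s are resolved.
#' @export
setClass("DatasetManifest", representation(
  records = "data.frame",
  tree = "TaxonomyTree",
  imageRoot = "character"
))

setValidity("DatasetManifest", function(object) {
  df <- object@records
  L <- nLevels(object@tree)
  need <- c("path", "split", paste0("label_level", seq_len(L) - 1L))
  miss <- setdiff(need, names(df))
  if (length(miss)) return(paste("missing record columns:", paste(miss, collapse = ", ")))
  if (nrow(df) && !all(df$split %in% c("train", "test")))
    return("split must be 'train' or 'test'")
  sizes <- levelSizes(object@tree)
  for (i in seq_len(L)) {
    lab <- df[[paste0("label_level", i - 1L)]]
    if (nrow(df) && (any(lab < 0L) || any(lab >= sizes[i])))
      return(sprintf("label out of range at level %d", i))
  }
  TRUE
})

#' PredictionSet: per-rank class probabilities for a batch of images
#'
#' One probability matrix per taxonomy level; row `s` of matrix `i` is the
#' probability vector over the categories of level `i` for sample `s`, and
#' sums to 1 (within 1e-6).
#'
#' @slot probs list of numeric matrices, one per level, all with the same
#'   number of rows.
#' @slot levelNames character vector naming the levels.
#' @export
setClass("PredictionSet", representation(
  probs = "list",
  levelNames = "character"
))

setValidity("PredictionSet", function(object) {
  if (length(object@probs) != length(object@levelNames))
    return("one probability matrix per level required")
  n <- if (length(object@probs)) nrow(object@probs[[1L]]) else 0L
  for (i in seq_along(object@probs)) {
    p <- object@probs[[i]]
    if (!is.matrix(p) || nrow(p) != n) return("matrices must share the row count")
    if (any(p < -1e-9)) return("negative probability")
    if (n && any(abs(rowSums(p) - 1) > 1e-6))
      return(sprintf("rows of level %d do not sum to 1", i))
  }
  TRUE
})

#' Backbone: contract for a convolutional feature extractor
#'
#' A backbone maps a batch of `resolution x resolution x 3` images in `[0,1]`
#' to a `batch x featureDim` matrix of finite features. Full-scale
#' architectures can be plugged in behind this contract; the package ships a
#' small fixed-filter convolutional backbone (see [tinyBackbone()]) that runs
#' on a CPU in seconds.
#'
#' @slot name backbone identifier.
#' @slot inputResolution expected square input size in pixels.
#' @slot featureDim length of the output feature vector.
#' @slot forward function(list of H x W x 3 arrays) -> batch x featureDim matrix.
#' @export
setClass("Backbone", representation(
  name = "character",
  inputResolution = "numeric",
  featureDim = "numeric",
  forward = "function"
))

#' HeadLayout: flat or multilevel classification head configuration
#'
#' @slot kind "flat" (one head over the finest level) or "multilevel" (one
#'   head per taxonomy level).
#' @slot levelSizes integer vector of head widths, coarsest first; a flat
#'   layout stores the single finest-level width.
#' @slot levelNames names for the heads.
#' @export
setClass("HeadLayout", representation(
  kind = "character",
  levelSizes = "numeric",
  levelNames = "character"
))

setValidity("HeadLayout", function(object) {
  if (!object@kind %in% c("flat", "multilevel")) return("kind must be flat or multilevel")
  if (object@kind == "flat" && length(object@levelSizes) != 1L)
    return("flat layout has exactly one head")
  if (length(object@levelSizes) != length(object@levelNames))
    return("levelSizes and levelNames must align")
  if (any(object@levelSizes < 1)) return("head widths must be positive")
  TRUE
})

#' MultilevelModel: shared backbone plus parallel per-rank softmax heads
#'
#' Every head consumes the same feature vector produced by the backbone;
#' head `i` is a fully connected layer of width `levelSizes[i]` followed by a
#' softmax. Features are standardised with the training-set mean and standard
#' deviation stored in the model.
#'
#' @slot backbone the [Backbone-class] feature extractor.
#' @slot layout the [HeadLayout-class].
#' @slot heads list with one `list(W, b)` per head.
#' @slot featCenter,featScale feature standardisation parameters.
#' @slot trained logical flag.
#' @export
setClass("MultilevelModel", representation(
  backbone = "Backbone",
  layout = "HeadLayout",
  heads = "list",
  featCenter = "numeric",
  featScale = "numeric",
  trained = "logical"
))

#' CascadeModel: coarse-rank router plus one specialist per routed category
#'
#' The router predicts the category at `routingLevel`; the sample is then
#' forwarded to the specialist trained only on that category's subtree, which
#' predicts all finer levels in subtree-local label spaces. `localToGlobal`
#' maps those local ids back to global ids.
#'
#' @slot tree the global [TaxonomyTree-class].
#' @slot routingLevel 1-based index of the routing level.
#' @slot router a [MultilevelModel-class] with a single head over the routing
#'   level.
#' @slot specialists list of [MultilevelModel-class], one per routing category.
#' @slot localToGlobal list (per routing category) of lists (per finer level)
#'   of integer vectors: global id (0-based) of each local category.
#' @export
setClass("CascadeModel", representation(
  tree = "TaxonomyTree",
  routingLevel = "numeric",
  router = "ANY",
  specialists = "list",
  localToGlobal = "list"
))

#' StackModel: fully connected stacking meta-classifier
#'
#' A single fully connected layer with one softmax group per level. Its input
#' is the concatenation of all members' per-level log-probabilities, so an
#' identity-initialised single-member stack reproduces that member exactly.
#'
#' @slot heads list of `list(W, b)` per level.
#' @slot levelSizes widths of the member (and output) levels.
#' @slot levelNames level names.
#' @slot nMembers number of ensemble members the stack was fitted on.
#' @export
setClass("StackModel", representation(
  heads = "list",
  levelSizes = "numeric",
  levelNames = "character",
  nMembers = "numeric"
))

#' EvalReport: per-rank evaluation of a classifier
#'
#' @slot perLevel data.frame with one row per level: `level`, `top1`, `top5`,
#'   `loss` columns (`top5` is `NA` where the level has fewer than 5 classes
#'   would still be valid; k is capped at the level size).
#' @slot perClass data.frame of finest-level per-class precision/recall/F1 and
#'   support.
#' @slot weightedF1 support-weighted mean F1 at the finest level.
#' @slot auc macro one-vs-rest ROC AUC at the finest level (NA when undefined).
#' @slot f1Normal named numeric: `mu`, `sigma`, `within1`, `within2` — normal
#'   fit to the per-class F1 distribution and empirical coverage.
#' @export
setClass("EvalReport", representation(
  perLevel = "data.frame",
  perClass = "data.frame",
  weightedF1 = "numeric",
  auc = "numeric",
  f1Normal = "numeric"
))
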