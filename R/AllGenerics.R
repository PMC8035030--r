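#' Number of taxonomy levels
#' @param x a TaxonomyTree, DatasetManifest, PredictionSet or model object.
#' @return integer.
#' @export
setGeneric("nLevels", function(x) standardGeneric("nLevels"))

#' Level (rank) names, coarsest first
#' @param x an object carrying a taxonomy or level structure.
#' @return character vector.
#' @export
setGeneric("levelNames", function(x) standardGeneric("levelNames"))

#' Number of categories at each level
#' @param x an object carrying a taxonomy or level structure.
#' @return integer vector, coarsest first.
#' @export
setGeneric("levelSizes", function(x) standardGeneric("levelSizes"))

#' Record table of a manifest
#' @param x a DatasetManifest.
#' @return data.frame of records.
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' Taxonomy of an object
#' @param x a DatasetManifest or CascadeModel.
#' @return a TaxonomyTree.
#' @export
setGeneric("taxonomy", function(x) standardGeneric("taxonomy"))

#' Per-finest-level-class histogram of the training split
#' @param x a DatasetManifest.
#' @return integer vector of length `levelSizes(taxonomy(x))[nLevels(x)]`.
#' @export
setGeneric("classCounts", function(x) standardGeneric("classCounts"))

## ---- methods ----

#' @describeIn nLevels levels of a taxonomy
#' @export
setMethod("nLevels", "TaxonomyTree", function(x) length(x@levelNames))
#' @describeIn nLevels levels of a manifest's taxonomy
#' @export
setMethod("nLevels", "DatasetManifest", function(x) nLevels(x@tree))
#' @describeIn nLevels number of probability matrices
#' @export
setMethod("nLevels", "PredictionSet", function(x) length(x@probs))
#' @describeIn nLevels number of heads
#' @export
setMethod("nLevels", "MultilevelModel", function(x) length(x@layout@levelSizes))

#' @describeIn levelNames of a taxonomy
#' @export
setMethod("levelNames", "TaxonomyTree", function(x) x@levelNames)
#' @describeIn levelNames of a manifest's taxonomy
#' @export
setMethod("levelNames", "DatasetManifest", function(x) x@tree@levelNames)
#' @describeIn levelNames of a prediction set
#' @export
setMethod("levelNames", "PredictionSet", function(x) x@levelNames)
#' @describeIn levelNames of a model's head layout
#' @export
setMethod("levelNames", "MultilevelModel", function(x) x@layout@levelNames)

#' @describeIn levelSizes of a taxonomy
#' @export
setMethod("levelSizes", "TaxonomyTree", function(x) vapply(x@names, length, 1L))
#' @describeIn levelSizes of a manifest's taxonomy
#' @export
setMethod("levelSizes", "DatasetManifest", function(x) levelSizes(x@tree))
#' @describeIn levelSizes head widths
#' @export
setMethod("levelSizes", "MultilevelModel", function(x) as.integer(x@layout@levelSizes))
#' @describeIn levelSizes widths of the probability matrices
#' @export
setMethod("levelSizes", "PredictionSet", function(x) vapply(x@probs, ncol, 1L))

#' @describeIn records accessor
#' @export
setMethod("records", "DatasetManifest", function(x) x@records)

#' @describeIn taxonomy accessor
#' @export
setMethod("taxonomy", "DatasetManifest", function(x) x@tree)
#' @describeIn taxonomy accessor
#' @export
setMethod("taxonomy", "CascadeModel", function(x) x@tree)

#' @describeIn classCounts histogram over finest-level train labels
#' @export
setMethod("classCounts", "DatasetManifest", function(x) {
  L <- nLevels(x)
  K <- levelSizes(x)[L]
  lab <- x@records[[paste0("label_level", L - 1L)]][x@records$split == "train"]
  tabulate(lab + 1L, nbins = K)
})

#' @export
setMethod("show", "TaxonomyTree", function(object) {
  cat("TaxonomyTree with", nLevels(object), "levels\n")
  cat(paste0("  ", object@levelNames, ": ", levelSizes(object),
             " categories", collapse = "\n"), "\n")
})

#' @export
setMethod("show", "DatasetManifest", function(object) {
  df <- object@records
  cat("DatasetManifest:", nrow(df), "records (",
      sum(df$split == "train"), "train /", sum(df$split == "test"), "test )\n")
  cat("  taxonomy:", paste(levelSizes(object), collapse = "/"), "\n")
})

#' @export
setMethod("show", "PredictionSet", function(object) {
  n <- if (length(object@probs)) nrow(object@probs[[1L]]) else 0L
  cat("PredictionSet:", n, "samples x", nLevels(object), "levels (widths",
      paste(levelSizes(object), collapse = "/"), ")\n")
})

#' @export
setMethod("show", "MultilevelModel", function(object) {
  cat("MultilevelModel [", object@layout@kind, "] backbone=", object@backbone@name,
      " heads=", paste(object@layout@levelSizes, collapse = "/"),
      if (object@trained) " (trained)\n" else " (untrained)\n", sep = "")
})

#' @export
setMethod("show", "CascadeModel", function(object) {
  cat("CascadeModel routed at level", object@routingLevel, "(",
      levelNames(object@tree)[object@routingLevel], ") with",
      length(object@specialists), "specialists\n")
})

#' @export
setMethod("show", "EvalReport", function(object) {
  cat("EvalReport\n")
  print(object@perLevel, row.names = FALSE)
  cat("weighted F1:", round(object@weightedF1, 4),
      " macro AUC:", round(object@auc, 4), "\n")
})
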