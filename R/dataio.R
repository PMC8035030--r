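recordColumns <- function(L) {
  c("path", "split", paste0("label_level", seq_len(L) - 1L),
    "source_path", "transform", "transform_seed")
}

emptyRecords <- function(L) {
  df <- data.frame(path = character(0), split = character(0),
                   stringsAsFactors = FALSE)
  for (i in seq_len(L) - 1L) df[[paste0("label_level", i)]] <- integer(0)
  df$source_path <- character(0)
  df$transform <- character(0)
  df$transform_seed <- integer(0)
  df
}

normalizeRecords <- function(df, L) {
  if (is.null(df$source_path)) df$source_path <- NA_character_
  if (is.null(df$transform)) df$transform <- NA_character_
  if (is.null(df$transform_seed)) df$transform_seed <- NA_integer_
  for (i in seq_len(L) - 1L) {
    col <- paste0("label_level", i)
    df[[col]] <- as.integer(df[[col]])
  }
  df$transform_seed <- as.integer(df$transform_seed)
  rownames(df) <- NULL
  df[, recordColumns(L)]
}

#' Construct a DatasetManifest
#'
#' @param records data.frame of records (see [DatasetManifest-class]).
#' @param tree the [TaxonomyTree-class] the labels refer to.
#' @param imageRoot directory against which relative paths resolve.
#' @return a [DatasetManifest-class].
#' @export
DatasetManifest <- function(records, tree, imageRoot = ".") {
  new("DatasetManifest", records = normalizeRecords(records, nLevels(tree)),
      tree = tree, imageRoot = imageRoot)
}

#' Read an iNaturalist-competition annotation file
#'
#' Parses the COCO-style JSON dialect used by the iNaturalist 2019 Kaggle
#' challenge: top-level `images` (id, file_name), `annotations` (image_id,
#' category_id) and `categories`, where each category carries its full rank
#' path in the fields `kingdom, phylum, class, order, family, genus, name`.
#' One record is produced per annotation and the taxonomy is rebuilt from the
#' category rank paths via [buildTaxonomy()].
#'
#' @param annotationFile path to the JSON file.
#' @param imageRoot directory containing the image files.
#' @param split split tag applied to all records in the file ("train" or
#'   "test"); the competition ships one file per split and the splits are
#'   adopted verbatim.
#' @param rankFields category fields naming the ranks, coarsest first.
#' @return a [DatasetManifest-class].
#' @export
readINatAnnotations <- function(annotationFile, imageRoot = dirname(annotationFile),
                                split = "train",
                                rankFields = c("kingdom", "phylum", "class",
                                               "order", "family", "genus", "name")) {
  doc <- jsonlite::fromJSON(annotationFile, simplifyVector = TRUE)
  for (k in c("images", "annotations", "categories"))
    if (is.null(doc[[k]])) stopf("annotation file lacks '%s'", k)
  cats <- as.data.frame(doc$categories, stringsAsFactors = FALSE)
  miss <- setdiff(rankFields, names(cats))
  if (length(miss))
    stopf("categories lack rank field(s): %s", paste(miss, collapse = ", "))
  if (anyNA(cats[, rankFields]))
    stopf("missing rank value in categories")
  tree <- buildTaxonomy(cats[, rankFields, drop = FALSE],
                        levelNames = c("Kingdom", "Phylum", "Class", "Order",
                                       "Family", "Genus", "Species")[seq_along(rankFields)])
  ann <- doc$annotations
  imgIdx <- match(ann$image_id, doc$images$id)
  catIdx <- match(ann$category_id, cats$id)
  if (anyNA(imgIdx)) stopf("annotation references unknown image id %s",
                           ann$image_id[which(is.na(imgIdx))[1L]])
  if (anyNA(catIdx)) stopf("annotation references unknown category id %s",
                           ann$category_id[which(is.na(catIdx))[1L]])
  L <- nLevels(tree)
  labm <- matrix(0L, nrow(ann), L)
  for (i in seq_len(L))
    labm[, i] <- match(cats[[rankFields[i]]][catIdx], tree@names[[i]]) - 1L
  df <- data.frame(path = doc$images$file_name[imgIdx],
                   split = split, stringsAsFactors = FALSE)
  for (i in seq_len(L)) df[[paste0("label_level", i - 1L)]] <- labm[, i]
  DatasetManifest(df, tree, imageRoot)
}

#' Write a manifest to CSV
#'
#' Columns: `path`, `split`, one quoted display-name column per level
#' (`label_level0..`), plus augmentation provenance (`source_path`,
#' `transform`, `transform_seed`). Display names rather than ids are stored so
#' the file is self-describing; [readManifestCSV()] rebuilds the taxonomy from
#' them.
#'
#' @param manifest a [DatasetManifest-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeManifestCSV <- function(manifest, path) {
  df <- manifest@records
  L <- nLevels(manifest)
  tree <- manifest@tree
  out <- df
  for (i in seq_len(L)) {
    col <- paste0("label_level", i - 1L)
    out[[col]] <- tree@names[[i]][df[[col]] + 1L]
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read a manifest from CSV
#'
#' Inverse of [writeManifestCSV()]: `read(write(m))` preserves paths, labels
#' and splits exactly. The taxonomy is rebuilt from the label columns unless
#' one is supplied (required for an empty manifest).
#'
#' @param path CSV path.
#' @param imageRoot image directory; defaults to the CSV's directory.
#' @param tree optional [TaxonomyTree-class] to label against.
#' @return a [DatasetManifest-class].
#' @export
readManifestCSV <- function(path, imageRoot = dirname(path), tree = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  labCols <- grep("^label_level", names(df), value = TRUE)
  L <- length(labCols)
  base <- c("path", "split")
  if (!all(base %in% names(df)) || L == 0L)
    stopf("malformed manifest CSV: need path, split and label_level* columns")
  if (nrow(df) == 0L) {
    if (is.null(tree))
      tree <- new("TaxonomyTree", levelNames = paste0("level", seq_len(L) - 1L),
                  names = rep(list(character(0)), L),
                  parent = rep(list(integer(0)), L))
    return(DatasetManifest(emptyRecords(L), tree, imageRoot))
  }
  if (is.null(tree))
    tree <- buildTaxonomy(df[, labCols, drop = FALSE],
                          levelNames = paste0("level", seq_len(L) - 1L))
  out <- data.frame(path = df$path, split = df$split, stringsAsFactors = FALSE)
  for (i in seq_len(L)) {
    ids <- match(df[[labCols[i]]], tree@names[[i]]) - 1L
    if (anyNA(ids)) stopf("unknown %s label in manifest", labCols[i])
    out[[labCols[i]]] <- ids
  }
  out$source_path <- if ("source_path" %in% names(df))
    ifelse(df$source_path == "", NA_character_, df$source_path) else NA_character_
  out$transform <- if ("transform" %in% names(df))
    ifelse(df$transform == "", NA_character_, df$transform) else NA_character_
  out$transform_seed <- if ("transform_seed" %in% names(df))
    suppressWarnings(as.integer(df$transform_seed)) else NA_integer_
  DatasetManifest(out, tree, imageRoot)
}

#' Bilinear resize of an image array
#'
#' Corner-aligned bilinear interpolation: output corner pixels reproduce the
#' input corner pixels exactly. Non-square inputs are resized anisotropically
#' to the requested square (no letterboxing).
#'
#' @param img H x W x C array in `[0,1]`.
#' @param height,width output size in pixels.
#' @return height x width x C array.
#' @export
bilinearResize <- function(img, height, width = height) {
  d <- dim(img)
  H <- d[1L]; W <- d[2L]; C <- if (length(d) >= 3L) d[3L] else 1L
  img <- array(img, c(H, W, C))
  srcIdx <- function(n, outN) {
    if (outN == 1L || n == 1L) rep(1, outN)
    else 1 + (seq_len(outN) - 1) * (n - 1) / (outN - 1)
  }
  ry <- srcIdx(H, height); rx <- srcIdx(W, width)
  y0 <- pmin(floor(ry), H - 1L + (H == 1L)); x0 <- pmin(floor(rx), W - 1L + (W == 1L))
  y0 <- pmax(y0, 1); x0 <- pmax(x0, 1)
  y1 <- pmin(y0 + 1, H); x1 <- pmin(x0 + 1, W)
  fy <- ry - y0; fx <- rx - x0
  fxm <- matrix(fx, height, width, byrow = TRUE)
  fym <- matrix(fy, height, width)
  out <- array(0, c(height, width, C))
  for (ch in seq_len(C)) {
    m <- img[, , ch]
    top <- m[y0, x0, drop = FALSE] * (1 - fxm) + m[y0, x1, drop = FALSE] * fxm
    bot <- m[y1, x0, drop = FALSE] * (1 - fxm) + m[y1, x1, drop = FALSE] * fxm
    out[, , ch] <- top * (1 - fym) + bot * fym
  }
  out
}

readImageFile <- function(path) {
  if (!file.exists(path)) stopf("cannot read image '%s': no such file", path)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg") &&
             requireNamespace("EBImage", quietly = TRUE)) {
    aperm(EBImage::imageData(EBImage::readImage(path)), c(2L, 1L, 3L)[seq_len(
      length(dim(EBImage::imageData(EBImage::readImage(path)))))])
  } else {
    stopf("cannot read image '%s': unsupported format '%s'", path, ext)
  }
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE] # drop alpha
  if (dim(img)[3L] == 1L) img <- array(rep(img, 3L), c(dim(img)[1:2], 3L))
  img
}

#' Load one record's image as a uniform tensor
#'
#' Reads the image (PNG, or JPEG when EBImage is installed), replicates
#' grayscale to 3 channels, drops any alpha channel, replays the record's
#' augmentation pipeline when the record is an augmented copy (crop before
#' resize, then the standard operators), and resizes to
#' `resolution x resolution x 3` with corner-aligned bilinear interpolation.
#' Values are real in `[0,1]`, channel-last.
#'
#' @param record one-row data.frame (a row of [records()]) or a path string.
#' @param resolution output side length in pixels.
#' @param imageRoot root for relative paths.
#' @param policy an [AugmentPolicy] (list) used to replay augmented records;
#'   `NULL` loads the stored transform's defaults.
#' @return resolution x resolution x 3 array in `[0,1]`.
#' @export
loadImage <- function(record, resolution, imageRoot = ".", policy = NULL) {
  if (is.character(record)) record <- data.frame(path = record, split = "train",
                                                 source_path = NA, transform = NA,
                                                 transform_seed = NA,
                                                 stringsAsFactors = FALSE)
  aug <- !is.na(record$transform) && !is.na(record$transform_seed)
  src <- if (aug && !is.na(record$source_path)) record$source_path else record$path
  p <- if (file.exists(src)) src else file.path(imageRoot, src)
  img <- readImageFile(p)
  if (aug) img <- replayTransform(img, record$transform, record$transform_seed, policy)
  bilinearResize(clip01(img), resolution, resolution)
}

#' True label matrix of a manifest split
#'
#' @param manifest a [DatasetManifest-class].
#' @param split optional split filter ("train" or "test").
#' @return integer matrix (records x levels) of 0-based category ids.
#' @export
labelsMatrix <- function(manifest, split = NULL) {
  df <- manifest@records
  if (!is.null(split)) df <- df[df$split == split, , drop = FALSE]
  L <- nLevels(manifest)
  m <- matrix(0L, nrow(df), L)
  for (i in seq_len(L)) m[, i] <- df[[paste0("label_level", i - 1L)]]
  m
}
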