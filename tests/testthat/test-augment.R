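asym_image <- function(n = 8) {
  arr <- array(0, c(n, n, 3))
  arr[, , 1] <- matrix(seq(0, 1, length.out = n * n), n, n)
  arr[, , 2] <- matrix(seq(1, 0, length.out = n * n), n, n, byrow = TRUE)
  arr[2, 3, 3] <- 1
  arr
}

flip_only <- function(p) augmentPolicy(pFlipH = p, pFlipV = 0, pShift = 0,
                                       pBrightness = 0, pContrast = 0,
                                       pNoise = 0, pBlur = 0)

test_that("a certain horizontal flip is an exact involutive mirror", {
  img <- asym_image()
  pol <- flip_only(1)
  once <- standardAugment(img, pol, seed = 1)
  expect_identical(once, img[, 8:1, , drop = FALSE])
  expect_identical(standardAugment(once, pol, seed = 99), img)
})

test_that("degenerate operator ranges give the identity or exact arithmetic", {
  img <- asym_image()
  # noise-only with sd range [0,0] is the identity
  noisePol <- augmentPolicy(pFlipH = 0, pFlipV = 0, pShift = 0, pBrightness = 0,
                            pContrast = 0, pNoise = 1, pBlur = 0,
                            noiseSdRange = c(0, 0))
  expect_equal(standardAugment(img, noisePol, seed = 5), img)
  # brightness-only +0.2 on a constant 0.9 image clips to exactly 1
  brightPol <- augmentPolicy(pFlipH = 0, pFlipV = 0, pShift = 0, pBrightness = 1,
                             pContrast = 0, pNoise = 0, pBlur = 0,
                             brightnessRange = c(0.2, 0.2))
  const <- array(0.9, c(4, 4, 3))
  expect_identical(standardAugment(const, brightPol, seed = 1),
                   array(1, c(4, 4, 3)))
})

test_that("at least one operator is always applied and output stays in range", {
  img <- asym_image(12)
  # only the horizontal flip is enabled, with low probability: the >=1 rule
  # must force it on every draw
  pol <- flip_only(0.05)
  for (s in 1:20)
    expect_identical(standardAugment(img, pol, seed = s),
                     img[, 12:1, , drop = FALSE])
  # with several operators enabled the output stays a valid image
  mixed <- augmentPolicy()
  for (s in 1:10) {
    out <- standardAugment(img, mixed, seed = s)
    expect_identical(dim(out), dim(img))
    expect_true(all(out >= 0 & out <= 1))
  }
})

test_that("centralCrop follows the offset arithmetic", {
  img <- array(seq_len(10 * 10 * 3) / 300, c(10, 10, 3))
  crop <- centralCrop(img, 0.8)
  expect_identical(dim(crop), c(8L, 8L, 3L))
  expect_identical(crop, img[2:9, 2:9, , drop = FALSE]) # rows/cols 1..8 0-based
  expect_identical(centralCrop(img, 1), img)
  const <- array(0.4, c(7, 7, 3))
  small <- centralCrop(const, 0.5)
  expect_true(all(small == 0.4))
  expect_error(centralCrop(img, 0), "fraction")
  expect_error(centralCrop(array(1, c(1, 1, 3)), 0.3), "zero-size")
})

test_that("composing central crops matches the product fraction up to rounding", {
  img <- array(runif(40 * 40 * 3), c(40, 40, 3))
  ab <- centralCrop(centralCrop(img, 0.8), 0.5)
  direct <- centralCrop(img, 0.4)
  expect_identical(dim(ab), dim(direct))
  expect_equal(ab, direct)
})

test_that("multiscaleCrops returns 3 reproducible crops in the stated range", {
  img <- array(runif(30 * 30 * 3), c(30, 30, 3))
  crops <- multiscaleCrops(img, seed = 12)
  expect_length(crops, 3L)
  for (cr in crops) {
    expect_gte(dim(cr)[1], 15L) # 0.5 * 30
    expect_lte(dim(cr)[1], 24L) # 0.8 * 30
  }
  expect_identical(crops, multiscaleCrops(img, seed = 12))
  # minimal 2x2 input: fraction 0.5 gives valid 1x1 crops
  tiny <- multiscaleCrops(array(1, c(2, 2, 3)), seed = 1, range = c(0.5, 0.5))
  expect_identical(dim(tiny[[1]]), c(1L, 1L, 3L))
})

test_that("balancing equalises finest-level counts and preserves originals", {
  d <- withr::local_tempdir()
  # counts {A:3, B:5} -> total 10, A gains 2 augmented records
  tree <- buildTaxonomy(data.frame(k = "K", s = c("A", "B")), c("k", "s"))
  df <- data.frame(path = sprintf("img%d.png", 1:8),
                   split = "train", stringsAsFactors = FALSE)
  df$label_level0 <- 0L
  df$label_level1 <- c(rep(0L, 3), rep(1L, 5))
  m <- DatasetManifest(df, tree, d)
  bal <- balanceDataset(m, augmentPolicy(mode = "standard", seed = 3))
  expect_identical(nrow(records(bal)), 10L)
  expect_identical(classCounts(bal), c(5L, 5L))
  added <- records(bal)[9:10, ]
  expect_identical(added$transform, rep("standard", 2))
  expect_false(any(is.na(added$transform_seed)))
  expect_identical(added$source_path, added$path)
  # originals unchanged
  expect_identical(records(bal)[1:8, names(df)], records(m)[, names(df)])
  # already uniform counts: unchanged record count
  uni <- DatasetManifest(df[c(1:3, 4:6), ], tree, d)
  expect_identical(nrow(records(balanceDataset(uni, augmentPolicy()))), 6L)
  # mode none is the identity
  expect_identical(records(balanceDataset(m, augmentPolicy(mode = "none"))),
                   records(m))
})

test_that("balancing 1010 classes to a 350 maximum yields 353500 records", {
  tree <- makeShapedTaxonomy(c(4L, 1010L))
  counts <- withr::with_seed(1, sample(1:349, 1010, replace = TRUE))
  counts[17] <- 350L
  df <- data.frame(path = sprintf("img%07d.png", seq_len(sum(counts))),
                   split = "train", stringsAsFactors = FALSE)
  df$label_level1 <- rep(seq_len(1010L) - 1L, counts)
  df$label_level0 <- tree@parent[[2]][df$label_level1 + 1L]
  m <- DatasetManifest(df, tree, ".")
  bal <- balanceDataset(m, augmentPolicy(mode = "standard"))
  expect_identical(nrow(records(bal)), 1010L * 350L)
  expect_true(all(classCounts(bal) == 350L))
})

test_that("crop regimes add records and never touch the test split", {
  m <- clean_dataset()
  polM <- augmentPolicy(mode = "multiscale_crop", seed = 5)
  bal <- balanceDataset(m, polM)
  df0 <- records(m); df1 <- records(bal)
  expect_identical(df1[df1$split == "test", names(df0)],
                   df0[df0$split == "test", ])
  # 3 crops per source: every class count equals 4x the maximum original
  expect_true(all(classCounts(bal) == 4L * max(classCounts(m))))
  # augmented records replay to valid in-range images
  aug <- df1[!is.na(df1$transform), ][1, , drop = FALSE]
  img <- loadImage(aug, 24, m@imageRoot, polM)
  expect_identical(dim(img), c(24L, 24L, 3L))
  expect_true(all(img >= 0 & img <= 1))
  # replay is deterministic
  expect_identical(img, loadImage(aug, 24, m@imageRoot, polM))
})
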