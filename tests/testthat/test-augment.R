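test_that("flip and rotation group identities hold", {
  img <- randomImage(7)
  expect_equal(flipImage(flipImage(img, "horizontal"), "horizontal"), img)
  expect_equal(flipImage(flipImage(img, "vertical"), "vertical"), img)
  r <- img
  for (i in 1:4) r <- rotateImage(r, 1)
  expect_equal(r, img)
  expect_equal(rotateImage(img, 2),
               flipImage(flipImage(img, "horizontal"), "vertical"))
})

test_that("noise injection respects mean, sigma = 0 and clipping", {
  img <- randomImage(8)
  expect_equal(addImageNoise(img, mean = 0, sigma = 0), img)
  z <- array(0, c(100, 100, 3))
  expect_equal(addImageNoise(z, mean = 0.1, sigma = 0),
               array(0.1, c(100, 100, 3)))
  out <- withr::with_seed(1, addImageNoise(img, 0.3, 0.5))
  expect_true(all(out >= 0 & out <= 1))
})

test_that("expandToN balances classes exactly with recorded provenance", {
  imgs <- separableImages(2)      # 2 originals per class
  aug <- expandToN(imgs, n_per_class = 10, seed = 3)
  expect_equal(sum(imageLabels(aug) == 0L), 10)
  expect_equal(sum(imageLabels(aug) == 1L), 10)
  meta <- imageMeta(aug)
  expect_equal(sum(meta$op == "original"), 4)
  expect_equal(sum(meta$op != "original"), 16)
  expect_true(all(meta$op[meta$op != "original"] %in%
    c("flip_h", "flip_v", "rot90", "rot180", "rot270",
      "noise_0.1", "noise_0.2", "noise_0.3")))
  # augmented images cite an original of the same label as source
  augd <- meta[meta$op != "original", ]
  expect_true(all(imageLabels(imgs)[augd$source] ==
                  imageLabels(aug)[meta$op != "original"]))
  # determinism
  aug2 <- expandToN(imgs, n_per_class = 10, seed = 3)
  expect_identical(aug@pixels, aug2@pixels)
  expect_identical(imageMeta(aug)$op, imageMeta(aug2)$op)
  # a single-class input is rejected
  expect_error(expandToN(imgs[imageLabels(imgs) == 0L], 10, 1), "class")
})

test_that("stratified 7:3 split partitions the expanded set", {
  labels <- rep(c(0L, 1L), each = 5000)
  sp <- splitTrainVal(labels, ratio = 0.7, seed = 5)
  expect_equal(length(sp$train), 7000)
  expect_equal(length(sp$val), 3000)
  expect_equal(length(intersect(sp$train, sp$val)), 0)
  expect_equal(sort(c(sp$train, sp$val)), seq_along(labels))
  expect_equal(sum(labels[sp$train] == 0L), 3500)  # stratified
  sp2 <- splitTrainVal(labels, ratio = 0.7, seed = 5)
  expect_identical(sp, sp2)
})
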