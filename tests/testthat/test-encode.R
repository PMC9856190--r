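pointMatrix <- function() {
  prep <- preprocessSpectra(withr::with_seed(31,
    synthPoint(defaultTissueProfile("cancerous", "protein"))))
  assembleMatrix(prep)
}

test_that("assembleMatrix produces the 12 x 1780 angle-ordered matrix", {
  m <- pointMatrix()
  expect_equal(dim(m), c(12, 1780))
  # shuffled columns give the identical matrix (rows sorted by angle)
  prep <- preprocessSpectra(withr::with_seed(31,
    synthPoint(defaultTissueProfile("cancerous", "protein"))))
  shuf <- withr::with_seed(2, prep[, sample(ncol(prep))])
  expect_equal(assembleMatrix(shuf), m)
  # a missing angle is reported by name
  expect_error(assembleMatrix(prep[, -3]), "60")
})

test_that("identical spectra at all angles give a rank-1 matrix", {
  g <- wavenumberGrid()
  y <- exp(-(g - 1200)^2 / 100)
  cd <- S4Vectors::DataFrame(patient_id = "p", sample_id = "s",
    tissue_class = "normal", component = "protein", point_id = 1L,
    polarization_deg = seq(0, 330, 30))
  rs <- RamanSpectra(vapply(1:12, function(i) y, numeric(1780)), g, cd)
  m <- assembleMatrix(rs)
  expect_equal(qr(m)$rank, 1)
})

test_that("density slicing quantizes, clips and degrades gracefully", {
  expect_true(all(densitySlice(matrix(3.3, 5, 5)) == 0L))
  m <- matrix(0:63, 8, 8)
  expect_equal(as.vector(densitySlice(m, n_levels = 64, clip = c(0, 100))),
               0:63)
  lev <- densitySlice(pointMatrix())
  expect_true(all(lev >= 0 & lev <= 63))
})

test_that("constant offsets before clipping do not change the encoding", {
  m <- pointMatrix()
  img1 <- toPseudocolor(densitySlice(m))
  img2 <- toPseudocolor(densitySlice(m + 11.5))
  expect_identical(img1[, , ], img2[, , ])
})

test_that("pseudo-color encoding has the fixed output geometry", {
  m <- pointMatrix()
  img <- toPseudocolor(densitySlice(m))
  expect_equal(dim(img), c(100, 100, 3))
  expect_true(all(img >= 0 & img <= 1))
  # all-zero levels map to a uniform LUT[0] image
  z <- matrix(0L, 12, 1780); attr(z, "n_levels") <- 64L
  u <- toPseudocolor(z)
  expect_equal(length(unique(as.vector(u[, , 1]))), 1)
  expect_equal(length(unique(as.vector(u[, , 3]))), 1)
  expect_error(toPseudocolor(z, colormap = "viridis"), "arg")
})

test_that("encoding is deterministic and PNG round-trips are exact", {
  imgs <- encodeCohort(preprocessSpectra(smallCohort()))
  imgs2 <- encodeCohort(preprocessSpectra(smallCohort()))
  expect_identical(imgs@pixels, imgs2@pixels)
  d <- withr::local_tempdir()
  writeImagePNG(imgs[1:3], d)
  back <- readImagePNG(d)
  expect_identical(back@pixels, imgs[1:3]@pixels)
  expect_identical(imageLabels(back), imageLabels(imgs[1:3]))
})

test_that("the default cohort encodes to the expected image census", {
  imgs <- defaultImages()
  expect_equal(nImages(imgs), 300)
  expect_equal(sum(imageLabels(imgs) == 0L), 200)  # cancerous
  expect_equal(sum(imageLabels(imgs) == 1L), 100)  # normal
  expect_equal(dim(imgs@pixels)[1:3], c(100, 100, 3))
})
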