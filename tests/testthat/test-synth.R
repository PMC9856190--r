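test_that("cos-squared anisotropy law evaluates and is 180-degree periodic", {
  b <- bandProfile(1247, 12, a_iso = 1, a_aniso = 2, orientation_deg = 0)
  expect_equal(bandAmplitudeAtAngle(b, 60), 1 + 2 * 0.25)
  expect_equal(bandAmplitudeAtAngle(b, 0), 3)   # maximum at the orientation
  iso <- bandProfile(1003, 9, a_iso = 0.7)
  expect_equal(bandAmplitudeAtAngle(iso, c(0, 37, 122)), rep(0.7, 3))
  th <- seq(0, 179, by = 7)
  expect_equal(bandAmplitudeAtAngle(b, th), bandAmplitudeAtAngle(b, th + 180))
})

test_that("A(theta) + A(theta + 90) = 2 a_iso + a_aniso for random bands", {
  withr::with_seed(3, {
    for (i in 1:25) {
      b <- bandProfile(1000, 10, a_iso = runif(1, 0, 2),
                       a_aniso = runif(1, 0, 3),
                       orientation_deg = runif(1, 0, 180))
      th <- runif(1, 0, 270)
      expect_equal(bandAmplitudeAtAngle(b, th) + bandAmplitudeAtAngle(b, th + 90),
                   2 * b$a_iso + b$a_aniso)
    }
  })
})

test_that("conventional amplitude equals the mean over the 12 angles", {
  b <- bandProfile(1247, 12, a_iso = 0.4, a_aniso = 1.3, orientation_deg = 35)
  angles <- seq(0, 330, by = 30)
  expect_equal(mean(bandAmplitudeAtAngle(b, angles)), b$a_iso + b$a_aniso / 2)
})

test_that("synthSpectrum obeys its degenerate-case contracts", {
  g <- wavenumberGrid(503, 2003, 301)   # 5 cm^-1 spacing, 1003 on-grid
  prof <- defaultTissueProfile("normal", "protein")
  # single Gaussian band, no background, no noise: peak at nearest channel
  one <- tissueProfile("normal", "protein",
    rbind(bandProfile(1003, 12, a_iso = 2), bandProfile(1247, 12, a_iso = 0.5)),
    noise_sigma = 0)
  sp <- synthSpectrum(one, theta = 0, grid = g, baseline = rep(0, 301),
                      noise = FALSE)
  y <- assay(sp, "intensity")[, 1]
  expect_equal(which.max(y), which.min(abs(g - 1003)))
  expect_equal(max(y), 2, tolerance = 1e-6)
  # grid/lineshape mismatch is rejected
  expect_error(polarRaman:::.synthIntensities(prof, 0, g,
    L = matrix(0, 10, nrow(prof$bands))), "grid")
})

test_that("a polarization series has 12 unique ascending angles plus conventional", {
  prof <- defaultTissueProfile("cancerous", "protein")
  pt <- withr::with_seed(5, synthPoint(prof))
  ang <- polarizationAngle(pt)
  expect_identical(ang[1:12], seq(0, 330, by = 30))
  expect_true(is.na(ang[13]))
  expect_equal(length(unique(ang[1:12])), 12)
  expect_equal(length(unique(sampleId(pt))), 1)
})

test_that("noise-free series: theta and theta+180 coincide; conventional = angular mean", {
  prof <- defaultTissueProfile("normal", "protein")
  pt <- withr::with_seed(6, synthPoint(prof, noise = FALSE))
  Y <- assay(pt, "intensity")
  for (i in 1:6) expect_equal(Y[, i], Y[, i + 6], ignore_attr = TRUE)
  expect_equal(rowMeans(Y[, 1:12]), Y[, 13], ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("cohort generation is bit-reproducible and respects counts", {
  cfg <- synthConfig(n_cancerous = 1, n_normal = 1, n_paracancerous = 0,
                     points_per_sample = 2)
  a <- synthCohort(cfg, seed = 9)
  b <- synthCohort(cfg, seed = 9)
  expect_identical(assay(a, "intensity"), assay(b, "intensity"))
  # 2 samples x 2 points x 13 spectra
  expect_equal(ncol(a), 2 * 2 * 13)
  expect_equal(nrow(unique(as.data.frame(colData(a))[, c("sample_id", "point_id")])),
               4)  # 4 polarization series
  expect_true(all(assay(a, "intensity") >= 0))
  expect_error(synthConfig(n_cancerous = -1), "counts")
})

test_that("default profiles carry the marker bands and the amide I shift", {
  pc <- defaultTissueProfile("cancerous", "protein")
  pn <- defaultTissueProfile("normal", "protein")
  expect_true(all(c(1003, 1247) %in% pn$bands$center))
  expect_true(1656 %in% pc$bands$center)
  expect_true(1660 %in% pn$bands$center)
  lp <- defaultTissueProfile("normal", "lipid")
  expect_true(all(c(1084, 1745) %in% lp$bands$center))
  expect_error(tissueProfile("normal", "protein",
    bandProfile(1100, 10, a_iso = 1)), "marker")
})
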