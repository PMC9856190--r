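test_that("Welch t-test matches an independent formula evaluation", {
  a <- c(1, 2, 3, 4, 5); b <- c(6, 7, 8, 9, 10)
  res <- ttestBand(a, b)
  # independent evaluation of the Welch statistic and Welch-Satterthwaite df
  se2a <- var(a) / length(a); se2b <- var(b) / length(b)
  t_ref <- (mean(a) - mean(b)) / sqrt(se2a + se2b)
  df_ref <- (se2a + se2b)^2 /
    (se2a^2 / (length(a) - 1) + se2b^2 / (length(b) - 1))
  p_ref <- 2 * pt(-abs(t_ref), df_ref)
  expect_equal(res$t, -5)
  expect_equal(res$t, t_ref, tolerance = 1e-12)
  expect_equal(res$p, p_ref, tolerance = 1e-9)
  expect_equal(p_ref, 0.00105, tolerance = 0.01)
})

test_that("Welch t-test symmetry and degenerate conventions", {
  a <- c(1.2, 3.1, 2.2, 4.4); b <- c(2.0, 2.5, 5.1, 3.3)
  r1 <- ttestBand(a, b); r2 <- ttestBand(b, a)
  expect_equal(r1$t, -r2$t)
  expect_equal(r1$p, r2$p)
  same <- ttestBand(c(2, 2, 2), c(2, 2))
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  diff <- ttestBand(c(2, 2), c(3, 3))
  expect_equal(diff$p, 0)
  ident <- ttestBand(a, a)
  expect_equal(ident$t, 0); expect_equal(ident$p, 1)
})

test_that("band-area tables: single spectrum gives sd 0; column order is irrelevant", {
  sm <- preprocessSpectra(smallCohort())
  tab <- bandAreaTable(sm, bands = c(1003, 1450), component = "protein")
  expect_true(all(tab$sd_area[tab$n == 1] == 0, na.rm = TRUE))
  shuf <- withr::with_seed(1, sm[, sample(ncol(sm))])
  tab2 <- bandAreaTable(shuf, bands = c(1003, 1450), component = "protein")
  expect_equal(tab$mean_area, tab2$mean_area)
  # missing class/band combinations are flagged, not fabricated
  no_para <- sm[, sm$tissue_class != "paracancerous"]
  tab3 <- bandAreaTable(no_para, bands = 1003, component = "protein")
  para_row <- tab3[tab3$tissue_class == "paracancerous", ]
  expect_equal(para_row$n, 0)
  expect_true(is.na(para_row$mean_area))
})

test_that("bimodal ratio: equal sub-band height curves give ratio 1", {
  g <- wavenumberGrid()
  Y <- vapply(seq(0, 330, 30), function(th)
    exp(-(g - 1247)^2 / 60) + exp(-(g - 1269)^2 / 60), numeric(1780))
  cd <- S4Vectors::DataFrame(patient_id = "p1", sample_id = "s1",
    tissue_class = "normal", component = "protein", point_id = 1L,
    polarization_deg = seq(0, 330, 30))
  rs <- RamanSpectra(Y, g, cd)
  rc <- bimodalRatioCurve(rs)
  expect_equal(rc$ratio, rep(1, 12), tolerance = 0.02)
  expect_error(bimodalRatioCurve(rs[, integer(0)]), "no polarized")
})

test_that("noise-free ratio curves are 180-degree periodic", {
  prof <- defaultTissueProfile("normal", "protein")
  pt <- withr::with_seed(21, synthPoint(prof, noise = FALSE))
  rc <- bimodalRatioCurve(preprocessSpectra(pt))
  expect_equal(rc$ratio[1:6], rc$ratio[7:12], tolerance = 1e-8)
})

test_that("hydroxyproline and unsaturation ratios: algebraic properties", {
  g <- wavenumberGrid()
  y <- exp(-(g - 875)^2 / 80) + exp(-(g - 921)^2 / 80)
  expect_equal(hydroxyprolineRatio(y, grid = g), 1, tolerance = 0.02)
  expect_equal(hydroxyprolineRatio(5 * y, grid = g),
               hydroxyprolineRatio(y, grid = g))
  yl <- exp(-(g - 1652)^2 / 100) + exp(-(g - 1442)^2 / 100)
  expect_equal(unsaturationRatio(yl, grid = g), 1, tolerance = 0.02)
  expect_equal(unsaturationRatio(3 * yl, grid = g),
               unsaturationRatio(yl, grid = g))
})

test_that("cohort-level calibration examples hold on the default cohort", {
  prep <- defaultPreprocessed()
  # cancerous polarized lipid C=C band area
  lt <- bandAreaTable(prep, bands = 1652, component = "lipid",
                      mode = "polarized")
  a1652 <- lt$mean_area[lt$tissue_class == "cancerous"]
  expect_gt(a1652, 17.54 * 0.75)
  expect_lt(a1652, 17.54 * 1.25)
  # cancerous polarized protein amide III main sub-band
  ptab <- bandAreaTable(prep, bands = 1247, component = "protein",
                        mode = "polarized")
  a1247 <- ptab$mean_area[ptab$tissue_class == "cancerous"]
  expect_gt(a1247, 5.88 * 0.75)
  expect_lt(a1247, 5.88 * 1.25)
  # hydroxyproline/proline ratio on the class-average conventional spectrum
  conv <- prep[, is.na(polarizationAngle(prep)) & prep$component == "protein"]
  g <- wavenumbers(prep)
  hyp <- hydroxyprolineRatio(
    meanSpectrum(conv[, conv$tissue_class == "cancerous"]), grid = g)
  expect_gt(hyp, 0.79 * 0.75)
  expect_lt(hyp, 0.79 * 1.25)
  # unsaturation ratio rises with cancerization
  lipc <- prep[, is.na(polarizationAngle(prep)) & prep$component == "lipid"]
  u_c <- mean(unsaturationRatio(lipc[, lipc$tissue_class == "cancerous"]),
              na.rm = TRUE)
  u_n <- mean(unsaturationRatio(lipc[, lipc$tissue_class == "normal"]),
              na.rm = TRUE)
  expect_gt(u_c, u_n)
})
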