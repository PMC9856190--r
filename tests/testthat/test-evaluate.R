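# sample table matching the default study design without synthesizing spectra
designTable <- function() {
  data.frame(
    sample_id = c(sprintf("canc_s%02d", 1:20), sprintf("norm_s%02d", 1:10)),
    patient_id = c(sprintf("p%02d", 1:20), sprintf("p%02d", 1:10)),
    tissue_class = rep(c("cancerous", "normal"), c(20, 10)))
}

test_that("grouped 10-fold plan partitions samples without patient leakage", {
  plan <- groupedKFold(designTable(), k = 10, seed = 4)
  expect_length(plan, 10)
  all_samples <- unlist(plan)
  expect_equal(sort(all_samples), sort(designTable()$sample_id))  # partition
  pat <- attr(plan, "patients")
  for (g in plan) {
    cls <- designTable()$tissue_class[match(g, designTable()$sample_id)]
    expect_equal(sum(cls == "cancerous"), 2)
    expect_equal(sum(cls == "normal"), 1)
    # the group's patients appear nowhere else
    others <- setdiff(all_samples, g)
    expect_length(intersect(pat[g], pat[others]), 0)
  }
  # malformed designs are rejected with an explanation
  bad <- designTable()[-1, ]
  expect_error(groupedKFold(bad, k = 10), "2k cancerous")
})

test_that("confusion aggregation follows the stated arithmetic", {
  perfect <- matrix(c(1, 0, 0, 1), 2, 2)
  agg <- aggregateConfusion(list(perfect, perfect, perfect))
  expect_equal(agg$mean, perfect, ignore_attr = TRUE)
  expect_equal(agg$mse, matrix(0, 2, 2), ignore_attr = TRUE)
  expect_equal(agg$accuracy, 1)
  # two folds with diagonals (1.0, 0.8) and (0.8, 1.0): overall accuracy 0.9
  f1 <- matrix(c(1.0, 0.2, 0.0, 0.8), 2, 2)
  f2 <- matrix(c(0.8, 0.0, 0.2, 1.0), 2, 2)
  agg2 <- aggregateConfusion(list(f1, f2))
  expect_equal(agg2$accuracy, 0.9)
  # permutation invariance over folds
  agg3 <- aggregateConfusion(list(f2, f1))
  expect_equal(agg2$mean, agg3$mean)
  expect_equal(agg2$mse, agg3$mse)
})

test_that("confusion ratios are row-normalized", {
  cm <- confusionRatios(pred = c(0, 0, 1, 1, 1), truth = c(0, 0, 0, 1, 1))
  expect_equal(rowSums(cm), c(`0` = 1, `1` = 1))
  expect_equal(cm[1, 1], 2 / 3)
  expect_equal(cm[2, 2], 1)
})

test_that("the 1D balancing expands by noise injection only and is seeded", {
  X <- matrix(runif(50 * 6), 50, 6)
  lab <- c(0L, 0L, 1L, 1L, 1L, 0L)
  out <- polarRaman:::.expandSpectra(X, lab, n_per_class = 5, seed = 2)
  expect_equal(sum(out$labels == 0L), 5)
  expect_equal(sum(out$labels == 1L), 5)
  expect_true(all(out$x >= 0))
  out2 <- polarRaman:::.expandSpectra(X, lab, n_per_class = 5, seed = 2)
  expect_identical(out$x, out2$x)
  expect_error(polarRaman:::.expandSpectra(X, rep(0L, 6), 5, 1), "class")
})
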