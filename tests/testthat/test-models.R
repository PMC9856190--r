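test_that("pooling arithmetic and parameter counts match closed forms", {
  m2 <- buildCNN2D(cnnConfig("2d"))
  expect_equal(m2$dims$pooled2, c(25L, 25L))     # 100 / 2 / 2
  expect_equal(m2$dims$flat, 25 * 25 * 32)
  # conv1 448 + bn 32 + conv2 4640 + bn 64 + fc1 2560128 + fc2 129
  expect_equal(nParams(m2), 448 + 32 + 4640 + 64 +
                 (20000 * 128 + 128) + (128 + 1))
  m1 <- buildCNN1D(cnnConfig("1d"))
  expect_equal(m1$dims$pooled2[2], 445L)          # 1780 / 2 / 2
  expect_equal(m1$dims$flat, 445 * 32)
  expect_error(buildCNN2D(cnnConfig("1d")), "2d")
})

test_that("convolution kernels agree with a naive R implementation", {
  withr::with_seed(10, {
    x <- array(rnorm(6 * 7 * 2 * 2), c(6, 7, 2, 2))
    w <- matrix(rnorm(3 * 18), 3, 18)     # 3 filters, 3x3x2 patches
    b <- rnorm(3)
  })
  y <- polarRaman:::.convForward(x, w, b, 3L, 3L, 1L, 1L)
  naive <- array(0, c(6, 7, 3, 2))
  for (n in 1:2) {
    xp <- array(0, c(8, 9, 2)); xp[2:7, 2:8, ] <- x[, , , n]
    for (f in 1:3) for (i in 1:6) for (j in 1:7)
      naive[i, j, f, n] <-
        sum(xp[i:(i + 2), j:(j + 2), ] * array(w[f, ], c(3, 3, 2))) + b[f]
  }
  expect_equal(y, naive, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("fused BN/activation/pool layers pass a numeric gradient check", {
  set.seed(2)
  m <- buildCNN2D(cnnConfig("2d", dropout_p = 0))
  X <- array(runif(100 * 100 * 3 * 3), c(100, 100, 3, 3))
  y <- c(0, 1, 0)
  fw <- polarRaman:::.forwardCNN(m, X, training = TRUE)
  gr <- polarRaman:::.backwardCNN(m, fw$cache, fw$prob, y)
  loss_at <- function(mod) {
    f <- polarRaman:::.forwardCNN(mod, X, training = TRUE)
    polarRaman:::.bceLoss(f$prob, y)
  }
  eps <- 1e-5
  for (nm in c("W1", "g1", "be1", "W2", "g2", "Wf1", "Wf2", "bf2")) {
    idx <- withr::with_seed(3, sample(length(m$params[[nm]]),
                                      min(2, length(m$params[[nm]]))))
    for (i in idx) {
      mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
      mm <- m; mm$params[[nm]][i] <- mm$params[[nm]][i] - eps
      num <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-4,
                   label = paste("grad", nm, i))
    }
  }
})

test_that("forward pass yields probabilities and training separates trivial classes", {
  imgs <- separableImages(16)
  m <- buildCNN2D(cnnConfig("2d", batch_size = 8, max_iters = 40,
                            eval_every = 10, patience = 4, lr = 1e-3,
                            val_subsample = 16))
  p0 <- predictProb(m, imgs)
  expect_true(all(p0 > 0 & p0 < 1))
  m <- trainModel(m, imgs, imageLabels(imgs), imgs, imageLabels(imgs),
                  seed = 1)
  acc <- mean((predictProb(m, imgs) > 0.5) == (imageLabels(imgs) == 1))
  expect_equal(acc, 1)
  # retained checkpoint is the best validation loss seen
  expect_lte(m$best_val_loss,
             min(m$trace$val_loss, na.rm = TRUE) + 1e-12)
})

test_that("training is bit-reproducible under a fixed seed", {
  imgs <- separableImages(8)
  cfg <- cnnConfig("2d", batch_size = 8, max_iters = 12, eval_every = 4,
                   patience = 3, lr = 1e-3, val_subsample = 8)
  m1 <- trainModel(buildCNN2D(cfg), imgs, imageLabels(imgs),
                   imgs, imageLabels(imgs), seed = 7)
  m2 <- trainModel(buildCNN2D(cfg), imgs, imageLabels(imgs),
                   imgs, imageLabels(imgs), seed = 7)
  expect_identical(m1$trace, m2$trace)
  expect_identical(m1$params$Wf2, m2$params$Wf2)
})

test_that("the 1D network trains on spectra and keeps the contract shapes", {
  withr::with_seed(30, {
    n <- 40
    X <- matrix(rnorm(1780 * n, 1, 0.05), 1780, n)
    lab <- rep(c(0L, 1L), each = n / 2)
    X[800:850, lab == 1L] <- X[800:850, lab == 1L] + 2  # class marker band
  })
  cfg <- cnnConfig("1d", batch_size = 8, max_iters = 60, eval_every = 15,
                   patience = 4, lr = 1e-3, val_subsample = 16)
  m <- trainModel(buildCNN1D(cfg), X, lab, X, lab, seed = 2)
  acc <- mean((predictProb(m, X) > 0.5) == (lab == 1))
  expect_gte(acc, 0.95)
})

test_that("knnPredict matches class::knn and honors its tie rule", {
  skip_if_not_installed("class")
  withr::with_seed(12, {
    tr <- matrix(rnorm(20 * 30), 20, 30)
    lab <- rep(c(0L, 1L), 10)
    te <- matrix(rnorm(8 * 30), 8, 30)
  })
  for (k in c(1, 3, 5)) {
    ours <- knnPredict(tr, lab, te, k)
    ref <- as.integer(as.character(class::knn(tr, te, factor(lab), k = k)))
    expect_equal(ours, ref, label = paste("k =", k))
  }
  # k = 1 on the training set itself recalls perfectly
  expect_equal(knnPredict(tr, lab, tr, 1), lab)
  # an equidistant tie at k = 2 resolves to the smaller label
  tr2 <- matrix(c(0, 2), 2, 1); te2 <- matrix(1, 1, 1)
  expect_equal(knnPredict(tr2, c(1L, 0L), te2, 2), 0L)
  expect_error(knnPredict(tr2, c(1L, 0L), te2, 5), "exceeds")
})
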