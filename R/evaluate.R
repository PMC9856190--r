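#' Patient-grouped k-fold plan
#'
#' Partitions the discrimination samples (cancerous + normal) into `k`
#' disjoint groups, each holding two cancerous samples and one normal
#' sample, such that no patient's samples span two groups. Every normal
#' sample is grouped with its own patient's cancerous sample; the remaining
#' cancerous samples (from patients without a normal sample) fill the
#' second slot, in seeded random order.
#'
#' @param sample_meta data.frame with one row per sample: columns
#'   `sample_id`, `patient_id`, `tissue_class` (paracancerous rows are
#'   ignored). Use [sampleTable()] to derive it from a cohort.
#' @param k number of folds (default 10).
#' @param seed RNG seed for the fill assignment.
#' @return list of `k` character vectors of sample ids (the test group of
#'   each fold), of class `"foldPlan"`.
#' @export
groupedKFold <- function(sample_meta, k = 10, seed = 1) {
  sm <- sample_meta[sample_meta$tissue_class %in% c("cancerous", "normal"), ]
  canc <- sm[sm$tissue_class == "cancerous", ]
  norm <- sm[sm$tissue_class == "normal", ]
  if (nrow(canc) != 2 * k || nrow(norm) != k)
    stop("grouped k-fold needs 2k cancerous and k normal samples ",
         "(got ", nrow(canc), " and ", nrow(norm), " for k = ", k, ")")
  paired_canc <- canc$sample_id[match(norm$patient_id, canc$patient_id)]
  if (any(is.na(paired_canc)))
    stop("every normal sample's patient must also provide a cancerous sample")
  rest <- setdiff(canc$sample_id, paired_canc)
  if (length(rest) != k)
    stop("after pairing, ", length(rest), " cancerous samples remain for ",
         k, " folds")
  withr::with_seed(seed, rest <- sample(rest))
  plan <- lapply(seq_len(k), function(i)
    c(norm$sample_id[i], paired_canc[i], rest[i]))
  structure(plan, class = "foldPlan",
            patients = stats::setNames(sm$patient_id, sm$sample_id))
}

#' Per-sample metadata table of a cohort
#'
#' @param x a [RamanSpectra-class].
#' @return data.frame with one row per sample: `sample_id`, `patient_id`,
#'   `tissue_class`.
#' @export
sampleTable <- function(x) {
  cd <- as.data.frame(colData(x)[, c("sample_id", "patient_id", "tissue_class")])
  unique(cd[order(cd$sample_id), ])
}

#' Row-normalized confusion matrix
#'
#' @param pred,truth integer 0/1 vectors.
#' @return 2 x 2 matrix of row-normalized ratios (rows = truth 0/1,
#'   columns = predicted 0/1).
#' @export
confusionRatios <- function(pred, truth) {
  m <- matrix(0, 2, 2, dimnames = list(truth = c("0", "1"),
                                       pred = c("0", "1")))
  for (t in 0:1) {
    sel <- truth == t
    if (any(sel))
      m[t + 1, ] <- c(mean(pred[sel] == 0), mean(pred[sel] == 1))
  }
  m
}

#' Aggregate per-fold confusion matrices
#'
#' Cell-wise mean of the row-normalized confusion matrices across folds,
#' the mean squared deviation of each cell from its cross-fold mean (MSE),
#' and the overall accuracy defined as the mean of the two diagonal means.
#'
#' @param per_fold list of 2 x 2 row-normalized confusion matrices.
#' @return list with `mean` (2 x 2), `mse` (2 x 2), `accuracy` (scalar)
#'   and `n_folds`.
#' @export
aggregateConfusion <- function(per_fold) {
  stopifnot(length(per_fold) >= 1)
  arr <- simplify2array(per_fold)
  mean_m <- apply(arr, c(1, 2), mean)
  mse_m <- apply(arr, c(1, 2), function(v) mean((v - mean(v))^2))
  list(mean = mean_m, mse = mse_m,
       accuracy = mean(diag(mean_m)), n_folds = length(per_fold))
}

# Balance a 1-D spectral training set to n_per_class per label by cycling
# originals and adding non-zero-mean Gaussian noise (means 0.1/0.2/0.3,
# like the image noise augmentations; flips/rotations are not meaningful
# for a spectrum).
.expandSpectra <- function(X, labels, n_per_class, seed, sigma = 0.05) {
  withr::with_seed(seed, {
    cols <- list(); labs <- list()
    for (lab in c(0L, 1L)) {
      orig <- which(labels == lab)
      if (!length(orig)) stop("empty class ", lab)
      n_extra <- max(0, n_per_class - length(orig))
      src <- rep(orig, length.out = n_extra)
      mu <- sample(c(0.1, 0.2, 0.3), n_extra, replace = TRUE)
      aug <- if (n_extra) {
        X[, src, drop = FALSE] +
          matrix(rnorm(nrow(X) * n_extra, rep(mu, each = nrow(X)), sigma),
                 nrow(X), n_extra)
      } else {
        X[, integer(0), drop = FALSE]
      }
      cols[[as.character(lab)]] <- cbind(X[, orig, drop = FALSE], pmax(aug, 0))
      labs[[as.character(lab)]] <- rep(lab, length(orig) + n_extra)
    }
    list(x = do.call(cbind, cols), labels = unlist(labs, use.names = FALSE))
  })
}

#' Experiment configuration
#'
#' Bundles every stage's parameters. The default profile reproduces the
#' full emulated study design (10 folds, 5000 images per class, long
#' training); the `fast` profile is a desk-scale version (2 folds, 500
#' images per class, short training with a larger learning rate) used by
#' the test suite and the acceptance script.
#'
#' @param fast use the desk-scale profile?
#' @param models character subset of `c("cnn2d", "cnn1d", "knn")`.
#' @param ... replacements for individual top-level entries (`synth`,
#'   `n_per_class`, `split_ratio`, `k_folds`, `folds_to_run`, `cnn2d`,
#'   `cnn1d`, `knn_k`, `encode`).
#' @return config list of class `"experimentConfig"`.
#' @export
experimentConfig <- function(fast = FALSE,
                             models = c("cnn2d", "cnn1d", "knn"), ...) {
  base <- list(
    synth = synthConfig(),
    encode = list(n_levels = 64, clip = c(1, 99), colormap = "jet"),
    n_per_class = if (fast) 500 else 5000,
    split_ratio = 0.7,
    k_folds = 10,
    folds_to_run = if (fast) 2 else 10,
    models = models,
    knn_k = c(1, 3, 5, 7, 9),
    cnn2d = cnnConfig("2d",
                      lr = if (fast) 1e-3 else 5e-5,
                      batch_size = if (fast) 32 else 64,
                      max_iters = if (fast) 150 else 5000,
                      eval_every = if (fast) 15 else 100,
                      patience = if (fast) 4 else 10,
                      val_subsample = if (fast) 128 else 256),
    cnn1d = cnnConfig("1d",
                      lr = if (fast) 1e-3 else 5e-5,
                      batch_size = if (fast) 32 else 64,
                      max_iters = if (fast) 150 else 5000,
                      eval_every = if (fast) 15 else 100,
                      patience = if (fast) 4 else 10,
                      val_subsample = if (fast) 128 else 256))
  structure(modifyList(base, list(...)), class = "experimentConfig")
}

#' Run the full discrimination experiment
#'
#' Executes the whole pipeline: synthesize a cohort, preprocess it, encode
#' the pseudo-color images, build the patient-grouped fold plan, and for
#' each fold augment the training images, split 7:3 into train/validation,
#' train the requested models and evaluate them on the held-out fold.
#' Augmentation sources are strictly the fold's training samples (asserted
#' at run time).
#'
#' @param config from [experimentConfig()].
#' @param seed master seed; all stage seeds derive from it.
#' @param verbose print per-fold progress?
#' @return list of class `"pmrsExperiment"`: `summary` (per-model mean
#'   train/val/test accuracy), `folds` (per-fold confusion matrices and
#'   accuracies), `aggregate` (per-model [aggregateConfusion()] output on
#'   the test sets), `knn_sweep` (per-k test accuracy, if KNN ran),
#'   `config`, `seed`.
#' @export
runExperiment <- function(config = experimentConfig(fast = TRUE), seed = 1,
                          verbose = FALSE) {
  stopifnot(inherits(config, "experimentConfig"))
  cohort <- synthCohort(config$synth, seed = seed)
  prep <- preprocessSpectra(cohort)
  images <- encodeCohort(prep, n_levels = config$encode$n_levels,
                         clip = config$encode$clip,
                         colormap = config$encode$colormap)
  meta <- imageMeta(images)
  plan <- groupedKFold(sampleTable(cohort), k = config$k_folds, seed = seed)

  # conventional spectra (one per detection point, matching image order)
  conv <- prep[, is.na(prep$polarization_deg) &
                 prep$tissue_class %in% c("cancerous", "normal")]
  conv_key <- paste(conv$sample_id, conv$point_id, sep = "|")
  img_key <- paste(meta$sample_id, meta$point_id, sep = "|")
  conv <- conv[, match(img_key, conv_key)]
  Xconv <- assay(conv, "intensity")

  folds <- list()
  per_model_cm <- list()
  knn_acc <- list()
  run_folds <- seq_len(min(config$folds_to_run, length(plan)))
  for (f in run_folds) {
    test_samples <- plan[[f]]
    test_idx <- which(meta$sample_id %in% test_samples)
    train_idx <- setdiff(seq_len(nImages(images)), test_idx)
    # leakage check: no test patient among training samples
    test_pat <- unique(meta$patient_id[test_idx])
    stopifnot(!any(meta$patient_id[train_idx] %in% test_pat))

    fold_seed <- (seed %% 100000) * 1000 + f  # stays well inside 32-bit range
    fold <- list(fold = f, test_samples = test_samples)
    test_y <- imageLabels(images)[test_idx]

    if (any(c("cnn2d", "knn") %in% config$models)) {
      aug <- expandToN(images[train_idx], config$n_per_class,
                       seed = fold_seed)
      stopifnot(!any(imageMeta(aug)$patient_id %in% test_pat))
      sp <- splitTrainVal(imageLabels(aug), config$split_ratio,
                          seed = fold_seed)
    }
    if ("cnn2d" %in% config$models) {
      m2 <- buildCNN2D(config$cnn2d)
      m2 <- trainModel(m2, aug[sp$train], imageLabels(aug)[sp$train],
                       aug[sp$val], imageLabels(aug)[sp$val],
                       seed = fold_seed, verbose = verbose)
      fold$cnn2d <- .evalModel(m2, list(train = aug[sp$train],
                                        val = aug[sp$val],
                                        test = images[test_idx]),
                               list(train = imageLabels(aug)[sp$train],
                                    val = imageLabels(aug)[sp$val],
                                    test = test_y))
      per_model_cm$cnn2d <- c(per_model_cm$cnn2d,
                              list(fold$cnn2d$test$confusion))
    }
    if ("knn" %in% config$models) {
        tr_x <- flattenImages(aug[sp$train])
        te_x <- flattenImages(images[test_idx])
        va_x <- flattenImages(aug[sp$val])
        fold$knn <- lapply(config$knn_k, function(k) {
          pred <- knnPredict(tr_x, imageLabels(aug)[sp$train], te_x, k)
          list(k = k, confusion = confusionRatios(pred, test_y),
               accuracy = mean(pred == test_y),
               val_accuracy = mean(knnPredict(tr_x,
                                              imageLabels(aug)[sp$train],
                                              va_x, k) ==
                                     imageLabels(aug)[sp$val]))
        })
        knn_acc[[length(knn_acc) + 1]] <-
          vapply(fold$knn, function(z) z$accuracy, numeric(1))
        per_model_cm$knn <- c(per_model_cm$knn,
                              list(fold$knn[[3]]$confusion))
    }

    if ("cnn1d" %in% config$models) {
      tr1 <- .expandSpectra(Xconv[, train_idx, drop = FALSE],
                            imageLabels(images)[train_idx],
                            config$n_per_class, seed = fold_seed)
      sp1 <- splitTrainVal(tr1$labels, config$split_ratio, seed = fold_seed)
      m1 <- buildCNN1D(config$cnn1d)
      m1 <- trainModel(m1, tr1$x[, sp1$train, drop = FALSE],
                       tr1$labels[sp1$train],
                       tr1$x[, sp1$val, drop = FALSE], tr1$labels[sp1$val],
                       seed = fold_seed, verbose = verbose)
      fold$cnn1d <- .evalModel(m1,
                               list(train = tr1$x[, sp1$train, drop = FALSE],
                                    val = tr1$x[, sp1$val, drop = FALSE],
                                    test = Xconv[, test_idx, drop = FALSE]),
                               list(train = tr1$labels[sp1$train],
                                    val = tr1$labels[sp1$val],
                                    test = test_y))
      per_model_cm$cnn1d <- c(per_model_cm$cnn1d,
                              list(fold$cnn1d$test$confusion))
    }
    folds[[f]] <- fold
    if (verbose) message("fold ", f, " done")
  }

  agg <- lapply(per_model_cm, aggregateConfusion)
  summary <- do.call(rbind, lapply(names(agg), function(mo) {
    accs <- function(set) mean(vapply(folds[run_folds], function(fl)
      if (!is.null(fl[[mo]])) fl[[mo]][[set]]$accuracy else NA_real_,
      numeric(1)), na.rm = TRUE)
    data.frame(model = mo,
               train_accuracy = if (mo == "knn") NA_real_ else accs("train"),
               val_accuracy = if (mo == "knn") NA_real_ else accs("val"),
               test_accuracy = agg[[mo]]$accuracy)
  }))
  structure(list(summary = summary, folds = folds[run_folds],
                 aggregate = agg,
                 knn_sweep = if (length(knn_acc))
                   data.frame(k = config$knn_k,
                              test_accuracy = colMeans(do.call(rbind, knn_acc)))
                 else NULL,
                 config = config, seed = seed),
            class = "pmrsExperiment")
}

.evalModel <- function(model, data_sets, label_sets) {
  out <- list()
  for (nm in names(data_sets)) {
    pred <- as.integer(predictProb(model, data_sets[[nm]]) > 0.5)
    out[[nm]] <- list(confusion = confusionRatios(pred, label_sets[[nm]]),
                      accuracy = mean(pred == label_sets[[nm]]))
  }
  out$trace <- model$trace
  out
}

#' @export
print.pmrsExperiment <- function(x, ...) {
  cat("Polarized-Raman discrimination experiment (seed ", x$seed, ", ",
      length(x$folds), " fold(s))\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
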