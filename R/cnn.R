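#' CNN configuration
#'
#' Hyperparameters of the compact discrimination networks. Both networks
#' share the same depth and ordering:
#' Conv1 - BN - LeakyReLU - MaxPool - Conv2 - BN - LeakyReLU - MaxPool -
#' flatten - FC1 - LeakyReLU - dropout - FC2 - sigmoid, trained with
#' binary cross-entropy and Adam (with global gradient-norm clipping).
#' The 2D network consumes 100 x 100 x 3 pseudo-color images; the 1D
#' network consumes the 1780-channel conventional spectrum. The max-pooling kernel is fixed at 2 with stride
#' 2 (two pools: 100 -> 25 spatial positions in 2D, 1780 -> 445 in 1D).
#'
#' @param type `"2d"` or `"1d"`.
#' @param conv_channels channels of Conv1 and Conv2 (default `c(16, 32)`).
#' @param kernel convolution kernel: 3 (3x3) for 2D, 7 for 1D.
#' @param fc_width width of FC1 (default 128; FC2 outputs the single
#'   cancerous/normal logit).
#' @param dropout_p dropout probability after FC1 (default 0.5).
#' @param leaky_slope negative slope of the LeakyReLU (default 0.01).
#' @param lr Adam learning rate (default 5e-5).
#' @param batch_size minibatch size (default 64).
#' @param max_iters maximum training iterations (default 5000).
#' @param eval_every validation-evaluation period, iterations (default 100).
#' @param patience early stopping: stop after this many consecutive
#'   evaluations without a validation-loss improvement > `min_improve`
#'   (default 10).
#' @param min_improve minimum validation-loss improvement (default 1e-4).
#' @param val_subsample number of validation images used per evaluation
#'   (a fixed random subset; default 256).
#' @param bn_momentum running-statistics momentum of the BN layers.
#' @param clip_norm global gradient-norm clipping threshold (default 5;
#'   `Inf` disables clipping).
#' @return a config list of class `"cnnConfig"`.
#' @export
cnnConfig <- function(type = c("2d", "1d"), conv_channels = c(16, 32),
                      kernel = NULL, fc_width = 128, dropout_p = 0.5,
                      leaky_slope = 0.01, lr = 5e-5, batch_size = 64,
                      max_iters = 5000, eval_every = 100, patience = 10,
                      min_improve = 1e-4, val_subsample = 256,
                      bn_momentum = 0.9, clip_norm = 5) {
  type <- match.arg(type)
  if (is.null(kernel)) kernel <- if (type == "2d") 3 else 7
  stopifnot(length(conv_channels) == 2, all(conv_channels >= 1),
            kernel %% 2 == 1, fc_width >= 1,
            dropout_p >= 0, dropout_p < 1, lr > 0, batch_size >= 1,
            max_iters >= 1, eval_every >= 1, patience >= 1)
  structure(list(type = type, conv_channels = as.integer(conv_channels),
                 kernel = as.integer(kernel), pool = 2L,
                 fc_width = as.integer(fc_width), dropout_p = dropout_p,
                 leaky_slope = leaky_slope, lr = lr,
                 batch_size = as.integer(batch_size),
                 max_iters = as.integer(max_iters),
                 eval_every = as.integer(eval_every),
                 patience = as.integer(patience), min_improve = min_improve,
                 val_subsample = as.integer(val_subsample),
                 bn_momentum = bn_momentum, clip_norm = clip_norm),
            class = "cnnConfig")
}

# Layer geometry derived from the config.
.cnnDims <- function(cfg) {
  if (cfg$type == "2d") {
    input <- c(100L, 100L, 3L)
    kh <- cfg$kernel; kw <- cfg$kernel
    ph <- 2L; pw <- 2L
  } else {
    input <- c(1L, 1780L, 1L)
    kh <- 1L; kw <- cfg$kernel
    ph <- 1L; pw <- 2L
  }
  h1 <- input[1] %/% ph; w1 <- input[2] %/% pw
  h2 <- h1 %/% ph; w2 <- w1 %/% pw
  list(input = input, kh = kh, kw = kw, ph = ph, pw = pw,
       padh = if (kh > 1) (kh - 1L) %/% 2L else 0L,
       padw = (kw - 1L) %/% 2L,
       pooled1 = c(h1, w1), pooled2 = c(h2, w2),
       flat = h2 * w2 * cfg$conv_channels[2])
}

#' Build the discrimination networks
#'
#' `buildCNN2D` builds the image network, `buildCNN1D` the spectral
#' counterpart with identical depth and layer ordering (1-D convolutions
#' over the 1780-channel conventional spectrum). Weights are initialized
#' (He-scaled) deterministically; [trainModel()] re-initializes them under
#' its own seed.
#'
#' @param config a [cnnConfig()] of the matching type.
#' @return a model object (list with `config`, `dims`, `params`).
#' @examples
#' m <- buildCNN2D(cnnConfig("2d"))
#' nParams(m)  # 2,565,441 for the default configuration
#' @export
buildCNN2D <- function(config = cnnConfig("2d")) {
  stopifnot(inherits(config, "cnnConfig"))
  if (config$type != "2d") stop("config$type must be '2d'")
  .buildCNN(config)
}

#' @rdname buildCNN2D
#' @export
buildCNN1D <- function(config = cnnConfig("1d")) {
  stopifnot(inherits(config, "cnnConfig"))
  if (config$type != "1d") stop("config$type must be '1d'")
  .buildCNN(config)
}

.buildCNN <- function(cfg) {
  dims <- .cnnDims(cfg)
  model <- structure(list(config = cfg, dims = dims, params = NULL,
                          trained = FALSE, trace = NULL),
                     class = "polarRamanCNN")
  model$params <- withr::with_seed(0L, .initParams(model))
  model
}

.initParams <- function(model) {
  cfg <- model$config; d <- model$dims
  c1 <- cfg$conv_channels[1]; c2 <- cfg$conv_channels[2]
  k1 <- d$kh * d$kw * d$input[3]
  k2 <- d$kh * d$kw * c1
  he <- function(nr, nc, fan) matrix(rnorm(nr * nc, 0, sqrt(2 / fan)), nr, nc)
  list(W1 = he(c1, k1, k1), b1 = numeric(c1),
       g1 = rep(1, c1), be1 = numeric(c1),
       W2 = he(c2, k2, k2), b2 = numeric(c2),
       g2 = rep(1, c2), be2 = numeric(c2),
       Wf1 = he(cfg$fc_width, d$flat, d$flat), bf1 = numeric(cfg$fc_width),
       Wf2 = he(1, cfg$fc_width, cfg$fc_width), bf2 = numeric(1),
       rm1 = numeric(c1), rv1 = rep(1, c1),
       rm2 = numeric(c2), rv2 = rep(1, c2))
}

#' Number of learnable parameters
#'
#' @param model a model from [buildCNN2D()] / [buildCNN1D()].
#' @return integer count of learnable parameters (convolution and FC
#'   weights and biases, BN scale and shift; running statistics excluded).
#' @export
nParams <- function(model) {
  p <- model$params
  learn <- c("W1", "b1", "g1", "be1", "W2", "b2", "g2", "be2",
             "Wf1", "bf1", "Wf2", "bf2")
  sum(vapply(p[learn], length, numeric(1)))
}

.BN_EPS <- 1e-5

# Forward pass; returns cache for backward when training = TRUE. BN and
# LeakyReLU are fused in compiled code; the backward pass recomputes the
# normalized activations from the cached convolution outputs, keeping the
# per-iteration allocation footprint small.
.forwardCNN <- function(model, X, training = FALSE, update_running = FALSE) {
  p <- model$params; cfg <- model$config; d <- model$dims
  cache <- list(X = X)
  z1 <- .convForward(X, p$W1, p$b1, d$kh, d$kw, d$padh, d$padw)
  if (training) {
    pl1 <- .bnActPoolForward(z1, p$g1, p$be1, .BN_EPS, cfg$leaky_slope,
                             d$ph, d$pw)
    if (update_running) {
      mom <- cfg$bn_momentum
      model$params$rm1 <- mom * p$rm1 + (1 - mom) * pl1$mean
      model$params$rv1 <- mom * p$rv1 + (1 - mom) * pl1$var
    }
  } else {
    pl1 <- list(y = .bnActPoolEval(z1, p$g1, p$be1, p$rm1, p$rv1, .BN_EPS,
                                   cfg$leaky_slope, d$ph, d$pw))
  }
  z2 <- .convForward(pl1$y, p$W2, p$b2, d$kh, d$kw, d$padh, d$padw)
  if (training) {
    pl2 <- .bnActPoolForward(z2, p$g2, p$be2, .BN_EPS, cfg$leaky_slope,
                             d$ph, d$pw)
    if (update_running) {
      mom <- cfg$bn_momentum
      model$params$rm2 <- mom * p$rm2 + (1 - mom) * pl2$mean
      model$params$rv2 <- mom * p$rv2 + (1 - mom) * pl2$var
    }
  } else {
    pl2 <- list(y = .bnActPoolEval(z2, p$g2, p$be2, p$rm2, p$rv2, .BN_EPS,
                                   cfg$leaky_slope, d$ph, d$pw))
  }
  B <- dim(X)[4]
  f <- matrix(pl2$y, d$flat, B)
  h1 <- p$Wf1 %*% f + p$bf1
  a1 <- ifelse(h1 < 0, cfg$leaky_slope * h1, h1)
  if (training && cfg$dropout_p > 0) {
    mask <- matrix(runif(length(h1)) >= cfg$dropout_p, nrow(h1), ncol(h1)) /
      (1 - cfg$dropout_p)
    h1d <- a1 * mask
  } else {
    mask <- NULL
    h1d <- a1
  }
  z <- drop(p$Wf2 %*% h1d + p$bf2)
  prob <- 1 / (1 + exp(-z))
  if (training)
    cache <- list(X = X, z1 = z1, z2 = z2, pl1 = pl1, pl2 = pl2,
                  f = f, h1 = h1, mask = mask, h1d = h1d)
  list(prob = prob, cache = cache, model = model)
}

.bceLoss <- function(prob, y) {
  p <- pmin(pmax(prob, 1e-7), 1 - 1e-7)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

.backwardCNN <- function(model, cache, prob, y) {
  p <- model$params; cfg <- model$config; d <- model$dims
  B <- length(y)
  dz <- matrix((prob - y) / B, 1, B)
  grads <- list()
  grads$Wf2 <- tcrossprod(dz, cache$h1d)
  grads$bf2 <- sum(dz)
  dh1d <- crossprod(p$Wf2, dz)
  da1 <- if (is.null(cache$mask)) dh1d else dh1d * cache$mask
  dh1 <- ifelse(cache$h1 < 0, cfg$leaky_slope * da1, da1)
  grads$Wf1 <- tcrossprod(dh1, cache$f)
  grads$bf1 <- rowSums(dh1)
  df <- crossprod(p$Wf1, dh1)
  dpl2 <- array(df, dim(cache$pl2$y))
  bb2 <- .bnActPoolBackward(dpl2, cache$pl2$idx, cache$z2, p$g2, p$be2,
                            cache$pl2$mean, cache$pl2$var, .BN_EPS,
                            cfg$leaky_slope)
  grads$g2 <- bb2$dgamma; grads$be2 <- bb2$dbeta
  cb2 <- .convBackward(cache$pl1$y, p$W2, bb2$dx, d$kh, d$kw,
                       d$padh, d$padw, TRUE)
  grads$W2 <- cb2$dw; grads$b2 <- cb2$db
  dpl1 <- cb2$dx
  bb1 <- .bnActPoolBackward(dpl1, cache$pl1$idx, cache$z1, p$g1, p$be1,
                            cache$pl1$mean, cache$pl1$var, .BN_EPS,
                            cfg$leaky_slope)
  grads$g1 <- bb1$dgamma; grads$be1 <- bb1$dbeta
  cb1 <- .convBackward(cache$X, p$W1, bb1$dx, d$kh, d$kw,
                       d$padh, d$padw, FALSE)
  grads$W1 <- cb1$dw; grads$b1 <- cb1$db
  grads
}

.adamInit <- function(params, learn) {
  st <- list(t = 0)
  for (nm in learn) {
    st[[paste0("m_", nm)]] <- params[[nm]] * 0
    st[[paste0("v_", nm)]] <- params[[nm]] * 0
  }
  st
}

.adamStep <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(grads)) {
    upd <- .adamUpdate(params[[nm]], grads[[nm]],
                       st[[paste0("m_", nm)]], st[[paste0("v_", nm)]],
                       lr, beta1, beta2, eps, bc1, bc2)
    attributes(upd) <- attributes(params[[nm]])
    params[[nm]] <- upd
  }
  list(params = params, state = st)
}

# Assemble a minibatch array from the supported containers.
.getBatch <- function(data, idx, type) {
  if (is(data, "EncodedImageSet")) {
    sub <- data@pixels[, , , idx, drop = FALSE]
    return(array(as.integer(sub) / 255, dim(sub)))
  }
  if (is.matrix(data)) {  # channels x n spectra
    sub <- data[, idx, drop = FALSE]
    return(array(sub, c(1L, nrow(data), 1L, length(idx))))
  }
  if (is.array(data) && length(dim(data)) == 4)
    return(data[, , , idx, drop = FALSE])
  stop("unsupported training-data container")
}

.nObs <- function(data) {
  if (is(data, "EncodedImageSet")) return(nImages(data))
  if (is.matrix(data)) return(ncol(data))
  if (is.array(data)) return(dim(data)[4])
  stop("unsupported training-data container")
}

#' Train a CNN with Adam, BCE loss and early stopping
#'
#' Minibatch training with binary cross-entropy on the sigmoid output
#' (labels: cancerous = 0, normal = 1). Every `eval_every` iterations the
#' validation loss is computed on a fixed random subsample; training stops
#' early when it has not improved by more than `min_improve` for
#' `patience` consecutive evaluations, and the parameters of the best
#' validation checkpoint are retained. Fully reproducible for a fixed
#' `seed` (weight initialization, batching, dropout).
#'
#' @param model from [buildCNN2D()] / [buildCNN1D()].
#' @param train,val training/validation data: an [EncodedImageSet-class]
#'   for the 2D model, or a `1780 x n` spectral matrix for the 1D model.
#' @param train_labels,val_labels integer 0/1 labels.
#' @param seed RNG seed.
#' @param verbose print progress?
#' @return the trained model; `model$trace` holds the per-iteration
#'   training loss/accuracy and the periodic validation loss/accuracy
#'   (`NA` between evaluations), `model$best_val_loss` the retained
#'   checkpoint's validation loss.
#' @export
trainModel <- function(model, train, train_labels, val, val_labels,
                       seed = 1, verbose = FALSE) {
  stopifnot(inherits(model, "polarRamanCNN"))
  cfg <- model$config
  n_train <- .nObs(train)
  n_val <- .nObs(val)
  stopifnot(length(train_labels) == n_train, length(val_labels) == n_val)
  learn <- c("W1", "b1", "g1", "be1", "W2", "b2", "g2", "be2",
             "Wf1", "bf1", "Wf2", "bf2")
  withr::with_seed(seed, {
    model$params <- .initParams(model)
    adam <- .adamInit(model$params, learn)
    val_idx <- sample(n_val, min(cfg$val_subsample, n_val))
    Xval <- .getBatch(val, val_idx, cfg$type)
    yval <- val_labels[val_idx]
    best <- list(loss = Inf, params = NULL)
    stall <- 0
    tr <- data.frame(iter = seq_len(cfg$max_iters), train_loss = NA_real_,
                     train_acc = NA_real_, val_loss = NA_real_,
                     val_acc = NA_real_)
    last_it <- cfg$max_iters
    for (it in seq_len(cfg$max_iters)) {
      idx <- sample(n_train, min(cfg$batch_size, n_train))
      X <- .getBatch(train, idx, cfg$type)
      y <- train_labels[idx]
      fw <- .forwardCNN(model, X, training = TRUE, update_running = TRUE)
      model <- fw$model
      loss <- .bceLoss(fw$prob, y)
      if (!is.finite(loss))
        stop("training diverged: non-finite loss at iteration ", it)
      tr$train_loss[it] <- loss
      tr$train_acc[it] <- mean((fw$prob > 0.5) == (y == 1))
      grads <- .backwardCNN(model, fw$cache, fw$prob, y)
      if (is.finite(cfg$clip_norm)) {
        gn <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
        if (gn > cfg$clip_norm)
          grads <- lapply(grads, function(g) g * (cfg$clip_norm / gn))
      }
      upd <- .adamStep(model$params[learn], grads, adam, cfg$lr)
      model$params[learn] <- upd$params
      adam <- upd$state
      if (it %% cfg$eval_every == 0) {
        pv <- .forwardCNN(model, Xval, training = FALSE)$prob
        vloss <- .bceLoss(pv, yval)
        tr$val_loss[it] <- vloss
        tr$val_acc[it] <- mean((pv > 0.5) == (yval == 1))
        if (verbose)
          message(sprintf("iter %d: train %.4f val %.4f (acc %.3f)",
                          it, loss, vloss, tr$val_acc[it]))
        if (vloss < best$loss - cfg$min_improve) {
          best <- list(loss = vloss, params = model$params)
          stall <- 0
        } else {
          stall <- stall + 1
          if (stall >= cfg$patience) { last_it <- it; break }
        }
      }
    }
    if (!is.null(best$params)) model$params <- best$params
    model$best_val_loss <- best$loss
    model$trace <- tr[seq_len(last_it), ]
    model$trained <- TRUE
    model$seed <- seed
  })
  model
}

#' Predict class probabilities
#'
#' @param model a trained model.
#' @param data an [EncodedImageSet-class] (2D) or `1780 x n` matrix (1D).
#' @param batch_size evaluation batch size.
#' @return numeric vector: probability of label 1 (normal) per input.
#' @export
predictProb <- function(model, data, batch_size = 64) {
  stopifnot(inherits(model, "polarRamanCNN"))
  n <- .nObs(data)
  out <- numeric(n)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    X <- .getBatch(data, idx, model$config$type)
    out[idx] <- .forwardCNN(model, X, training = FALSE)$prob
  }
  out
}

#' @export
print.polarRamanCNN <- function(x, ...) {
  cat(sprintf("polarRaman %s-CNN: conv %s, kernel %d, FC %d, %s\n",
              toupper(x$config$type),
              paste(x$config$conv_channels, collapse = "/"),
              x$config$kernel, x$config$fc_width,
              if (x$trained) "trained" else "untrained"))
  cat("  parameters:", nParams(x), "\n")
  invisible(x)
}
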