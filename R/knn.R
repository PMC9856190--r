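#' K-nearest-neighbour baseline
#'
#' Euclidean-distance KNN on flattened pixel vectors with majority vote.
#' Neighbour order is deterministic (distance, then index); a tied vote
#' (possible only for even `k`) is broken towards the smallest label.
#'
#' @param train_x numeric matrix, observations in rows (use
#'   [flattenImages()] for an image set).
#' @param train_y integer 0/1 labels.
#' @param test_x numeric matrix with the same number of columns.
#' @param k number of neighbours (odd values recommended; must not exceed
#'   the number of training rows).
#' @return integer vector of predicted labels.
#' @export
knnPredict <- function(train_x, train_y, test_x, k = 5) {
  stopifnot(is.matrix(train_x), is.matrix(test_x),
            ncol(train_x) == ncol(test_x),
            length(train_y) == nrow(train_x))
  if (k > nrow(train_x)) stop("k exceeds the number of training observations")
  train_y <- as.integer(train_y)
  tn2 <- rowSums(train_x^2)
  out <- integer(nrow(test_x))
  block <- max(1L, as.integer(2^22 / nrow(train_x)))  # cap the distance block
  for (start in seq(1, nrow(test_x), by = block)) {
    idx <- start:min(start + block - 1, nrow(test_x))
    G <- test_x[idx, , drop = FALSE] %*% t(train_x)
    D2 <- outer(rowSums(test_x[idx, , drop = FALSE]^2), tn2, `+`) - 2 * G
    for (r in seq_along(idx)) {
      nb <- order(D2[r, ], seq_len(ncol(D2)))[seq_len(k)]
      votes <- tabulate(train_y[nb] + 1L, 2L)
      out[idx[r]] <- if (votes[1] >= votes[2]) 0L else 1L
    }
  }
  out
}

#' Flatten an image set to a pixel matrix
#'
#' @param x an [EncodedImageSet-class].
#' @return numeric matrix `n x 30000` (pixels in `[0, 1]`).
#' @export
flattenImages <- function(x) {
  n <- nImages(x)
  m <- matrix(as.integer(x@pixels) / 255, nrow = 100 * 100 * 3, ncol = n)
  t(m)
}
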