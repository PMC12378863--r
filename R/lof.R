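# Local outlier factor in novelty mode, implemented from the published
# reachability-distance definition (no package in the declared dependency set
# provides it). The model is fitted once on training records; unseen records
# are scored against the training neighborhoods only, matching a
# train-once / score-later monitoring pipeline.

LRD_CAP <- 1e10  # local reachability density cap for duplicate-saturated neighborhoods

# k nearest training neighbors per row of a distance matrix (self-distances
# must already be Inf); ties broken by index
knn_from_dist <- function(d, k) {
  idx <- apply(d, 1, function(row) order(row)[seq_len(k)])
  if (k == 1L) matrix(idx, ncol = 1L) else t(idx)
}

#' Fit a local outlier factor model (novelty mode)
#'
#' Computes, for every training record, its `n_neighbors`-distance and local
#' reachability density (lrd) under the Euclidean metric. New records are
#' then scored as the ratio of their neighbors' mean lrd to their own lrd:
#' about 1 inside a homogeneous cluster, and increasingly above 1 in regions
#' sparser than their neighborhoods.
#'
#' @param x training records (data.frame or numeric matrix).
#' @param n_neighbors neighborhood size k (default 50); the training set must
#'   be strictly larger than k.
#' @return an object of class `lof_model`.
#' @examples
#' set.seed(1)
#' train <- matrix(rnorm(400), ncol = 2)
#' m <- fit_lof(train, n_neighbors = 10)
#' predict(m, rbind(c(0, 0), c(8, 8)))  # interior ~1, far point >> 1
#' @export
fit_lof <- function(x, n_neighbors = 50) {
  x <- as_feature_matrix(x)
  n <- nrow(x)
  k <- as.integer(n_neighbors)
  if (n <= k) stop("training size must exceed n_neighbors")
  d <- cross_dist(x, x)
  diag(d) <- Inf
  nb <- knn_from_dist(d, k)
  kdist <- d[cbind(seq_len(n), nb[, k])]
  lrd <- numeric(n)
  for (i in seq_len(n)) {
    reach <- pmax(kdist[nb[i, ]], d[i, nb[i, ]])
    m <- mean(reach)
    lrd[i] <- if (m > 0) 1 / m else LRD_CAP
  }
  structure(list(x = x, k = k, kdist = kdist, lrd = lrd, n = n),
            class = "lof_model")
}

#' Score records with a fitted LOF model
#'
#' @param object an `lof_model`.
#' @param newdata records to score against the training neighborhoods.
#' @param ... unused.
#' @return positive LOF scores; ~1 for records inside homogeneous training
#'   regions, higher is more anomalous.
#' @export
predict.lof_model <- function(object, newdata, ...) {
  xq <- as_feature_matrix(newdata)
  d <- cross_dist(xq, object$x)
  nb <- knn_from_dist(d, object$k)
  out <- numeric(nrow(xq))
  for (i in seq_len(nrow(xq))) {
    reach <- pmax(object$kdist[nb[i, ]], d[i, nb[i, ]])
    m <- mean(reach)
    lrd_p <- if (m > 0) 1 / m else LRD_CAP
    out[i] <- mean(object$lrd[nb[i, ]]) / lrd_p
  }
  out
}

#' @export
print.lof_model <- function(x, ...) {
  cat(sprintf("LOF model (novelty mode): k=%d, Euclidean metric, fitted on %d records\n",
              x$k, x$n))
  invisible(x)
}
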