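# Small study configuration used where full-size data would add nothing.
small_config <- function(seed = 1, ...) {
  generator_config(n_train = 300, n_threshold = 60, n_test = 60, seed = seed, ...)
}

# one clean adult record
adult_record <- function(weight = 58, dose = 204, dlp = 300) {
  data.frame(weight_kg = weight, pet_dose_mbq = dose, dlp_mgycm = dlp)
}

# --- independent oracles -----------------------------------------------------

# Mahalanobis quadratic form computed directly from first principles
hotelling_bruteforce <- function(train, query) {
  mu <- colMeans(train)
  n <- nrow(train)
  sigma <- matrix(0, ncol(train), ncol(train))
  for (i in seq_len(n)) sigma <- sigma + tcrossprod(train[i, ] - mu)
  sigma <- sigma / n
  apply(query, 1, function(x) drop(t(x - mu) %*% solve(sigma) %*% (x - mu)))
}

# PCA projection / reconstruction from a full eigendecomposition of cor()
mspc_bruteforce <- function(train, query, ncomp) {
  n <- nrow(train)
  mu <- colMeans(train)
  sd_ml <- sqrt(colMeans(sweep(train, 2, mu)^2))
  z_tr <- sweep(sweep(train, 2, mu), 2, sd_ml, "/")
  eig <- eigen(stats::cor(train), symmetric = TRUE)
  w <- eig$vectors[, seq_len(ncomp), drop = FALSE]
  lam <- eig$values[seq_len(ncomp)]
  t(apply(query, 1, function(x) {
    z <- (x - mu) / sd_ml
    s <- drop(t(w) %*% z)
    zhat <- drop(w %*% s)
    c(t2 = sum(s^2 / lam), q = sum((z - zhat)^2))
  }))
}

# LOF from the published reachability-distance definition: neighborhoods are
# all points within the k-distance (equals exactly-k when there are no ties)
lof_bruteforce <- function(train, query, k) {
  n <- nrow(train)
  d <- as.matrix(stats::dist(train))
  kdist <- function(i) sort(d[i, -i])[k]
  nbhd <- function(i) setdiff(which(d[i, ] <= kdist(i)), i)
  lrd <- function(i) {
    nb <- nbhd(i)
    1 / mean(pmax(vapply(nb, kdist, 1), d[i, nb]))
  }
  apply(query, 1, function(x) {
    dq <- sqrt(colSums((t(train) - x)^2))
    kq <- sort(dq)[k]
    nb <- which(dq <= kq)
    lrd_q <- 1 / mean(pmax(vapply(nb, kdist, 1), dq[nb]))
    mean(vapply(nb, lrd, 1)) / lrd_q
  })
}

# ROC-AUC by exhaustive positive-negative pair counting, ties worth half
roc_auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# average precision by explicit sweep over every unique threshold
pr_auc_bruteforce <- function(scores, labels) {
  npos <- sum(labels)
  ap <- 0
  prev_recall <- 0
  for (th in sort(unique(scores), decreasing = TRUE)) {
    flagged <- scores >= th
    precision <- sum(flagged & labels) / sum(flagged)
    recall <- sum(flagged & labels) / npos
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

# empirical quantile by explicit order-statistic interpolation
quantile_bruteforce <- function(scores, p) {
  s <- sort(scores)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}
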