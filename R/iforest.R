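# Isolation forest, implemented from the published algorithm: an ensemble of
# random binary trees, each grown on a subsample of size psi by recursively
# splitting a uniformly chosen attribute at a uniform point between its
# subsample min and max. Records that are isolated after few splits (short
# root-to-leaf paths) are anomalous. No R package in the declared dependency
# set provides this detector, so it lives here.

# average unsuccessful-search path length in a BST of n points; the
# normalizing constant and the credit assigned to unresolved leaves
c_factor <- function(n) {
  ifelse(n < 2, 0,
         ifelse(n == 2, 1,
                2 * (log(n - 1) + 0.5772156649015329) - 2 * (n - 1) / n))
}

grow_itree <- function(x, idx, max_depth) {
  var <- integer(0); val <- numeric(0)
  left <- integer(0); right <- integer(0); size <- integer(0)
  build <- function(idx, depth) {
    id <- length(size) + 1L
    var[id] <<- NA_integer_; val[id] <<- NA_real_
    left[id] <<- 0L; right[id] <<- 0L; size[id] <<- length(idx)
    if (depth >= max_depth || length(idx) <= 1L) return(id)
    sub <- x[idx, , drop = FALSE]
    spread <- apply(sub, 2, function(v) diff(range(v)))
    cand <- which(spread > 0)
    if (!length(cand)) return(id)  # all remaining points identical
    v <- if (length(cand) == 1L) cand else sample(cand, 1L)
    rng <- range(sub[, v])
    sp <- runif(1, rng[1], rng[2])
    l <- idx[x[idx, v] < sp]
    r <- idx[x[idx, v] >= sp]
    if (!length(l) || !length(r)) return(id)  # degenerate split draw
    var[id] <<- v; val[id] <<- sp
    # note: children are appended after this node, ids fixed by recursion
    left[id] <<- build(l, depth + 1L)
    right[id] <<- build(r, depth + 1L)
    id
  }
  build(idx, 0L)
  list(var = var, val = val, left = left, right = right, size = size)
}

# vectorized root-to-leaf traversal; returns adjusted path length per row
itree_path_length <- function(tree, x) {
  m <- nrow(x)
  node <- rep(1L, m)
  depth <- numeric(m)
  out <- numeric(m)
  active <- seq_len(m)
  while (length(active)) {
    at_leaf <- is.na(tree$var[node[active]])
    if (any(at_leaf)) {
      a <- active[at_leaf]
      out[a] <- depth[a] + c_factor(tree$size[node[a]])
      active <- active[!at_leaf]
      if (!length(active)) break
    }
    nd <- node[active]
    goes_left <- x[cbind(active, tree$var[nd])] < tree$val[nd]
    node[active] <- ifelse(goes_left, tree$left[nd], tree$right[nd])
    depth[active] <- depth[active] + 1
  }
  out
}

#' Fit an isolation forest
#'
#' Grows `n_trees` random isolation trees, each on a subsample of
#' `max_samples` training records (default: the standard "auto" rule,
#' `min(256, n)`), with depth capped at `ceiling(log2(max_samples))`.
#' The anomaly score of a record is `2^(-E[h(x)] / c(psi))` where `E[h(x)]`
#' is its average adjusted path length over the trees and `c(psi)` the
#' expected path length in a tree of the subsample size; scores lie in
#' (0, 1) and deeper average isolation means a lower score.
#'
#' @param x training records (data.frame or numeric matrix).
#' @param n_trees number of trees (default 100).
#' @param max_samples subsample size per tree; `NULL` applies the auto rule.
#' @param contamination expected anomaly proportion (default 0.1). Carried as
#'   metadata only: operative thresholds come from [decide_threshold()].
#' @param max_features fraction of features available per split (default 1.0;
#'   metadata, all features are used).
#' @param seed integer seed for the tree-growing randomness; the caller's RNG
#'   state is saved and restored, so fitting does not perturb surrounding
#'   seeded code. Fits are bit-reproducible given the seed.
#' @return an object of class `iforest_model`.
#' @examples
#' ds <- generate_dataset(generator_config(n_train = 300, n_threshold = 50,
#'                                         n_test = 50))
#' m <- fit_iforest(ds$train, seed = 1)
#' range(predict(m, ds$test))
#' @export
fit_iforest <- function(x, n_trees = 100, max_samples = NULL,
                        contamination = 0.1, max_features = 1.0, seed = NULL) {
  x <- as_feature_matrix(x)
  n <- nrow(x)
  if (n < 2) stop("isolation forest needs at least 2 training records")
  if (is.null(max_samples)) max_samples <- min(256L, n)
  max_samples <- min(as.integer(max_samples), n)
  max_depth <- ceiling(log2(max_samples))

  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(seed)
  }

  trees <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    idx <- if (max_samples < n) sample(n, max_samples) else seq_len(n)
    trees[[t]] <- grow_itree(x, idx, max_depth)
  }
  structure(list(trees = trees, psi = max_samples, n_trees = n_trees,
                 contamination = contamination, max_features = max_features,
                 seed = seed, n = n),
            class = "iforest_model")
}

#' Score records with a fitted isolation forest
#'
#' @param object an `iforest_model`.
#' @param newdata records to score.
#' @param ... unused.
#' @return numeric scores in (0, 1); higher is more anomalous.
#' @export
predict.iforest_model <- function(object, newdata, ...) {
  x <- as_feature_matrix(newdata)
  pl <- vapply(object$trees, itree_path_length, numeric(nrow(x)), x = x)
  paths <- rowMeans(matrix(pl, nrow = nrow(x)))
  2^(-paths / c_factor(object$psi))
}

#' @export
print.iforest_model <- function(x, ...) {
  cat(sprintf("Isolation forest: %d trees, subsample %d, fitted on %d records (seed %s)\n",
              x$n_trees, x$psi, x$n,
              if (is.null(x$seed)) "unset" else x$seed))
  invisible(x)
}
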