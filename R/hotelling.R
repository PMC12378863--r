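#' Fit Hotelling's T-squared control model
#'
#' Estimates the mean vector and covariance matrix of the training data by
#' maximum likelihood (covariance divisor N, not N-1) and precomputes the
#' inverse covariance. The anomaly score of a record x is the squared
#' Mahalanobis distance T2 = (x - mu)' Sigma^-1 (x - mu), which under
#' multivariate normality of the clean process follows a chi-square
#' distribution with as many degrees of freedom as there are variables.
#' T2 is invariant under per-variable affine rescaling of the inputs, so the
#' three dose variables can be used in their raw units.
#'
#' @param x training records: a data.frame with the canonical dose columns or
#'   a numeric matrix (any number of columns >= 2).
#' @return an object of class `hotelling_model` with elements `mu`, `sigma`,
#'   `sigma_inv`, `dof` and `n`.
#' @examples
#' m <- fit_hotelling(cbind(c(0, 1, 2, 1), c(0, 1, 0, -1)))
#' m$mu            # (1, 0)
#' predict(m, rbind(c(2, 2)))  # 10
#' @export
fit_hotelling <- function(x) {
  x <- as_feature_matrix(x)
  n <- nrow(x)
  if (n < 4) stop("Hotelling's T2 needs at least 4 training records")
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sigma <- crossprod(xc) / n  # maximum-likelihood divisor N
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  kp <- ev[1] / ev[length(ev)]  # condition number of the symmetric PSD matrix
  if (!is.finite(kp) || kp < 0 || kp > 1e12) {
    stop("covariance matrix is singular or ill-conditioned; ",
         "add jitter or more varied training data")
  }
  sigma_inv <- solve(sigma)
  structure(list(mu = mu, sigma = sigma, sigma_inv = sigma_inv,
                 dof = ncol(x), n = n),
            class = "hotelling_model")
}

#' Score records with a fitted Hotelling model
#'
#' @param object a `hotelling_model`.
#' @param newdata records to score (same columns as the training data).
#' @param ... unused.
#' @return numeric vector of non-negative T2 scores; higher is more anomalous.
#' @export
predict.hotelling_model <- function(object, newdata, ...) {
  x <- as_feature_matrix(newdata)
  xc <- sweep(x, 2, object$mu)
  rowSums((xc %*% object$sigma_inv) * xc)
}

#' @export
print.hotelling_model <- function(x, ...) {
  cat(sprintf("Hotelling T2 model: %d variables, fitted on %d records\n",
              x$dof, x$n))
  cat("  mean:", paste(signif(x$mu, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Fit a multivariate statistical process control (MSPC) model
#'
#' Autoscales the training data (zero mean, unit maximum-likelihood standard
#' deviation per variable) and extracts the leading principal directions of
#' the correlation matrix. Two complementary anomaly statistics follow:
#' the subspace T2 (Hotelling's statistic on the retained principal scores,
#' each normalized by its eigenvalue) measures unusual variation *inside*
#' the model plane, and the Q statistic (squared reconstruction error,
#' Q = sum_m (z_m - zhat_m)^2 in standardized units) measures departure
#' *from* the plane, i.e. broken correlation structure.
#'
#' @param x training records (data.frame or numeric matrix).
#' @param ncomp number of retained principal components (default 2, the
#'   3-to-2-dimensional reduction used for the three dose variables).
#' @return an object of class `mspc_model` with `center`, `scale`,
#'   `loadings` (orthonormal columns), `component_variances` (descending
#'   eigenvalues), `all_variances` and `cumulative_contribution`.
#' @examples
#' ds <- generate_dataset(generator_config(n_train = 300, n_threshold = 50,
#'                                         n_test = 50))
#' m <- fit_mspc(ds$train)
#' m$cumulative_contribution
#' head(predict(m, ds$test))
#' @export
fit_mspc <- function(x, ncomp = 2) {
  x <- as_feature_matrix(x)
  n <- nrow(x)
  if (n < 4) stop("MSPC needs at least 4 training records")
  stopifnot(ncomp >= 1, ncomp <= ncol(x))
  center <- colMeans(x)
  xc <- sweep(x, 2, center)
  scale <- sqrt(colSums(xc^2) / n)  # MLE sd, consistent with fit_hotelling
  if (any(scale < .Machine$double.eps^0.5)) {
    stop("zero-variance variable; MSPC autoscaling is undefined")
  }
  z <- sweep(xc, 2, scale, "/")
  corr <- crossprod(z) / n  # correlation matrix of the training data
  eig <- eigen(corr, symmetric = TRUE)
  structure(list(center = center, scale = scale,
                 loadings = eig$vectors[, seq_len(ncomp), drop = FALSE],
                 component_variances = eig$values[seq_len(ncomp)],
                 all_variances = eig$values,
                 cumulative_contribution =
                   sum(eig$values[seq_len(ncomp)]) / sum(eig$values),
                 ncomp = ncomp, n = n),
            class = "mspc_model")
}

#' Score records with a fitted MSPC model
#'
#' @param object an `mspc_model`.
#' @param newdata records to score.
#' @param ... unused.
#' @return a two-column matrix with the subspace `t2` and reconstruction
#'   error `q` per record; both non-negative, higher is more anomalous.
#' @export
predict.mspc_model <- function(object, newdata, ...) {
  x <- as_feature_matrix(newdata)
  z <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  s <- z %*% object$loadings
  t2 <- rowSums(sweep(s^2, 2, object$component_variances, "/"))
  zhat <- s %*% t(object$loadings)
  q <- rowSums((z - zhat)^2)
  cbind(t2 = t2, q = q)
}

#' @export
print.mspc_model <- function(x, ...) {
  cat(sprintf("MSPC model: %d -> %d principal components, fitted on %d records\n",
              length(x$center), x$ncomp, x$n))
  cat(sprintf("  cumulative contribution rate: %.1f%%\n",
              100 * x$cumulative_contribution))
  invisible(x)
}
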