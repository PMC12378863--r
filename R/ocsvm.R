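#' Fit a one-class support vector machine on raw dose features
#'
#' Thin wrapper around [e1071::svm()] in one-classification mode with an RBF
#' kernel. The boundary encloses the bulk of the training data; the anomaly
#' score is the distance beyond the boundary, i.e. the negated decision
#' value, so scores are positive outside the boundary and negative for
#' deep-interior points. Features are used in raw units (no scaling): the
#' default `gamma = 1e-5` is meaningful only on squared distances of the
#' order of the raw dose variables.
#'
#' @param x training records (data.frame or numeric matrix).
#' @param gamma RBF kernel width (default 1e-5).
#' @param nu upper bound on the training-outlier fraction / lower bound on
#'   the support-vector fraction (default 0.01); plays the role of the
#'   regularization constant in the one-class formulation.
#' @return an object of class `ocsvm_model`.
#' @examples
#' ds <- generate_dataset(generator_config(n_train = 300, n_threshold = 50,
#'                                         n_test = 50))
#' m <- fit_ocsvm(ds$train)
#' summary(predict(m, ds$test))
#' @export
fit_ocsvm <- function(x, gamma = 1e-5, nu = 0.01) {
  x <- as_feature_matrix(x)
  if (nrow(x) < 2) stop("OCSVM needs at least 2 training records")
  rng <- apply(x, 2, function(v) diff(range(v)))
  if (all(rng == 0)) stop("degenerate training set: all records identical")
  fit <- e1071::svm(x, y = NULL, type = "one-classification",
                    kernel = "radial", gamma = gamma, nu = nu, scale = FALSE)
  structure(list(svm = fit, gamma = gamma, nu = nu, n = nrow(x)),
            class = "ocsvm_model")
}

#' Score records with a fitted one-class SVM
#'
#' @param object an `ocsvm_model`.
#' @param newdata records to score.
#' @param ... unused.
#' @return numeric scores; higher = farther outside the boundary = more
#'   anomalous. Interior points score below zero.
#' @export
predict.ocsvm_model <- function(object, newdata, ...) {
  x <- as_feature_matrix(newdata)
  pr <- predict(object$svm, x, decision.values = TRUE)
  -as.numeric(attr(pr, "decision.values"))
}

#' @export
print.ocsvm_model <- function(x, ...) {
  cat(sprintf("One-class SVM (RBF): gamma=%g, nu=%g, %d support vectors, fitted on %d records\n",
              x$gamma, x$nu, x$svm$tot.nSV, x$n))
  invisible(x)
}
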