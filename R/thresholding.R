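#' Threshold candidates and the dual-candidate decision rule
#'
#' Operative anomaly thresholds are set from a small labeled threshold
#' dataset by combining two candidates and keeping the smaller:
#' \describe{
#'   \item{quantile method}{the empirical `(1 - anomaly_fraction)` quantile
#'     of the threshold-dataset scores (higher-is-anomalous orientation),
#'     with linear interpolation between order statistics. With two labeled
#'     anomalies among 685 records the fraction is 2/685, about 0.3\%.}
#'   \item{labeling method}{the lowest score among the labeled anomalies, so
#'     every known anomaly is flagged by construction.}
#' }
#' Records scoring at or above the final threshold are classified anomalous
#' (the labeling candidate equals an actual anomaly's score, which must count
#' as detected).
#'
#' @param scores anomaly scores of the threshold dataset (higher = more
#'   anomalous).
#' @param anomaly_fraction assumed anomaly proportion in `(0, 1)`; in
#'   [decide_threshold()] pass `NULL` to use the labeled proportion
#'   `sum(anomalies) / length(scores)`.
#' @param labels anomaly labels aligned with `scores` (logical, 0/1, or
#'   `"normal"/"anomaly"/"unlabeled"` characters).
#' @param method optional detector name recorded in the decision.
#' @return `quantile_candidate()` and `labeling_candidate()` return a single
#'   score; `decide_threshold()` returns a `threshold_decision` with fields
#'   `method`, `quantile_candidate`, `labeling_candidate`,
#'   `final` (= the minimum of the two) and `quantile_used`.
#' @examples
#' scores <- c(rnorm(100), 25, 40)
#' labels <- c(rep(0, 100), 1, 1)
#' decide_threshold(scores, labels)
#' @export
quantile_candidate <- function(scores, anomaly_fraction) {
  if (length(scores) == 0) stop("empty score vector")
  stopifnot(anomaly_fraction > 0, anomaly_fraction < 1)
  quantile(scores, probs = 1 - anomaly_fraction, names = FALSE, type = 7)
}

#' @rdname quantile_candidate
#' @export
labeling_candidate <- function(scores, labels) {
  if (length(scores) == 0) stop("empty score vector")
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  anom <- as_anomaly_indicator(labels)
  if (!any(anom)) {
    stop("no labeled anomalies in the threshold dataset; ",
         "the labeling method needs at least one (scores were non-empty)")
  }
  min(scores[anom])
}

#' @rdname quantile_candidate
#' @export
decide_threshold <- function(scores, labels, anomaly_fraction = NULL,
                             method = NA_character_) {
  anom <- as_anomaly_indicator(labels)
  if (is.null(anomaly_fraction)) {
    anomaly_fraction <- sum(anom) / length(scores)
  }
  qc <- quantile_candidate(scores, anomaly_fraction)
  lc <- labeling_candidate(scores, labels)
  structure(list(method = method,
                 quantile_candidate = qc,
                 labeling_candidate = lc,
                 final = min(qc, lc),
                 quantile_used = anomaly_fraction),
            class = "threshold_decision")
}

#' @export
print.threshold_decision <- function(x, ...) {
  cat(sprintf("Threshold decision%s\n",
              if (is.na(x$method)) "" else paste0(" [", x$method, "]")))
  cat(sprintf("  quantile candidate (fraction %.5f): %.6g\n",
              x$quantile_used, x$quantile_candidate))
  cat(sprintf("  labeling candidate (min anomaly score): %.6g\n",
              x$labeling_candidate))
  cat(sprintf("  final threshold (min of the two):       %.6g\n", x$final))
  invisible(x)
}
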