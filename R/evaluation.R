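#' Confusion counts at a score threshold
#'
#' A record is predicted anomalous iff its score is greater than or equal to
#' the threshold.
#'
#' @param scores anomaly scores (higher = more anomalous).
#' @param labels anomaly labels aligned with `scores`.
#' @param threshold operative threshold.
#' @return named integer vector `c(tp, fp, fn, tn)`.
#' @export
confusion_counts <- function(scores, labels, threshold) {
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  anom <- as_anomaly_indicator(labels)
  pred <- scores >= threshold
  c(tp = sum(pred & anom), fp = sum(pred & !anom),
    fn = sum(!pred & anom), tn = sum(!pred & !anom))
}

#' Precision, recall and F1 from confusion counts
#'
#' precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F1 = 2 TP / (2 TP + FN + FP). A metric whose denominator is zero is
#' undefined and reported as `NA`, never as 0.
#'
#' @param tp,fp,fn true-positive, false-positive, false-negative counts.
#' @return named numeric vector `c(precision, recall, f1)`.
#' @examples
#' prf(2, 7, 0)  # precision 2/9, recall 1, F1 4/11
#' @export
prf <- function(tp, fp, fn) {
  tp <- unname(tp); fp <- unname(fp); fn <- unname(fn)
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  c(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    f1 = if (2 * tp + fn + fp > 0) 2 * tp / (2 * tp + fn + fp) else NA_real_)
}

#' Area under the ROC curve
#'
#' Computed as the rank-based Mann-Whitney statistic: the probability that a
#' uniformly drawn anomaly outranks a uniformly drawn normal record, with
#' ties counted half.
#'
#' @param scores anomaly scores.
#' @param labels anomaly labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  anom <- as_anomaly_indicator(labels)
  np <- sum(anom); nn <- sum(!anom)
  if (np == 0 || nn == 0) {
    stop("ROC-AUC needs at least one anomaly and one normal record")
  }
  r <- rank(scores)
  (sum(r[anom]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve (average precision)
#'
#' Uses the average-precision step rule: sweeping the threshold down through
#' the unique score values, AP = sum over steps of
#' (recall_i - recall_(i-1)) * precision_i. Tied scores enter as a single
#' threshold step. Other PR interpolations can differ by about 1e-2 on
#' small, heavily imbalanced test sets.
#'
#' @param scores anomaly scores.
#' @param labels anomaly labels; at least one anomaly required.
#' @return average precision in \[0, 1\].
#' @export
pr_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  anom <- as_anomaly_indicator(labels)
  np <- sum(anom)
  if (np == 0) stop("PR-AUC needs at least one labeled anomaly")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- anom[ord]
  # indices closing each block of tied scores = threshold steps
  step <- which(!duplicated(s, fromLast = TRUE))
  ctp <- cumsum(y)[step]
  cn <- step  # records flagged at each threshold
  precision <- ctp / cn
  recall <- ctp / np
  sum(diff(c(0, recall)) * precision)
}

#' Univariate statistical process control limits
#'
#' The USPC baseline sets an independent lower and upper control limit per
#' variable from the training data, either as empirical quantiles (default
#' `[0.001, 0.999]`) or as `mean +/- k_sd` standard deviations. A record is
#' flagged iff any variable lies strictly outside its limits; a value exactly
#' at a limit is not flagged. USPC catches order-of-magnitude input errors
#' but misses values that are wrong for the patient yet inside the marginal
#' population range.
#'
#' @param x training records (data.frame or numeric matrix).
#' @param quantiles length-2 probabilities for the empirical limits.
#' @param k_sd if non-`NULL`, use `mean +/- k_sd * sd` instead of quantiles.
#' @return an object of class `uspc_limits`: a matrix with one row per
#'   variable and columns `lower`, `upper`.
#' @examples
#' ds <- generate_dataset(generator_config(n_train = 300, n_threshold = 50,
#'                                         n_test = 50))
#' lim <- uspc_limits(ds$train)
#' uspc_flag(lim, data.frame(weight_kg = 448, pet_dose_mbq = 150, dlp_mgycm = 98))
#' @export
uspc_limits <- function(x, quantiles = c(0.001, 0.999), k_sd = NULL) {
  x <- as_feature_matrix(x)
  if (is.null(k_sd)) {
    stopifnot(length(quantiles) == 2, quantiles[1] < quantiles[2])
    lim <- t(apply(x, 2, quantile, probs = quantiles, names = FALSE))
  } else {
    mu <- colMeans(x); s <- apply(x, 2, stats::sd)
    lim <- cbind(mu - k_sd * s, mu + k_sd * s)
  }
  colnames(lim) <- c("lower", "upper")
  if (any(lim[, 1] >= lim[, 2])) {
    stop("degenerate control limits (lower >= upper); more varied data needed")
  }
  structure(lim, class = c("uspc_limits", class(lim)))
}

#' @rdname uspc_limits
#' @param limits a `uspc_limits` object.
#' @param records records to check.
#' @return `uspc_flag()` returns a logical vector, `TRUE` where any variable
#'   violates its limits.
#' @export
uspc_flag <- function(limits, records) {
  x <- as_feature_matrix(records)
  stopifnot(ncol(x) == nrow(limits))
  low <- matrix(limits[, 1], nrow(x), ncol(x), byrow = TRUE)
  up <- matrix(limits[, 2], nrow(x), ncol(x), byrow = TRUE)
  rowSums(x < low | x > up) > 0
}

#' Mean dose variables by 10-kg weight interval
#'
#' Summarizes training records into half-open weight bins
#' `[k*w, (k+1)*w)`, reporting the mean PET dose, mean DLP and record count
#' per occupied bin. This is the stratified view underlying range-based QC:
#' informative for mid-range habitus, unstable where bins hold few patients.
#'
#' @param records dose records containing the canonical columns.
#' @param bin_width_kg bin width in kg (default 10).
#' @return data.frame with columns `weight_range`, `mean_pet_dose_mbq`,
#'   `mean_dlp_mgycm`, `n`; empty bins are omitted.
#' @export
weight_interval_summary <- function(records, bin_width_kg = 10) {
  stopifnot(nrow(records) > 0)
  x <- as_feature_matrix(records)
  lo <- floor(x[, 1] / bin_width_kg) * bin_width_kg
  groups <- split(seq_len(nrow(x)), lo)
  lower <- sort(as.numeric(names(groups)))
  groups <- groups[as.character(lower)]
  data.frame(weight_range = sprintf("[%g, %g)", lower, lower + bin_width_kg),
             mean_pet_dose_mbq = vapply(groups, function(i) mean(x[i, 2]), 1),
             mean_dlp_mgycm = vapply(groups, function(i) mean(x[i, 3]), 1),
             n = vapply(groups, length, 1L),
             bin_lower = lower,
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' One-row evaluation report for a detector on a labeled dataset
#'
#' Combines confusion counts at the operative threshold with the
#' threshold-free ranking metrics.
#'
#' @param scores anomaly scores on the labeled dataset.
#' @param labels anomaly labels.
#' @param threshold operative threshold (record flagged iff score >=
#'   threshold).
#' @param method detector name for the report row.
#' @return one-row data.frame: `method, tp, fp, fn, tn, precision, recall,
#'   f1, pr_auc, roc_auc, threshold`.
#' @export
evaluate_scores <- function(scores, labels, threshold, method = NA_character_) {
  cc <- confusion_counts(scores, labels, threshold)
  p <- prf(cc["tp"], cc["fp"], cc["fn"])
  data.frame(method = method,
             tp = unname(cc["tp"]), fp = unname(cc["fp"]),
             fn = unname(cc["fn"]), tn = unname(cc["tn"]),
             precision = unname(p["precision"]),
             recall = unname(p["recall"]),
             f1 = unname(p["f1"]),
             pr_auc = pr_auc(scores, labels),
             roc_auc = roc_auc(scores, labels),
             threshold = threshold,
             stringsAsFactors = FALSE)
}
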