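#' Configuration for the synthetic dose-record generator
#'
#' Builds and validates the parameter set that [generate_dataset()] consumes.
#' The defaults encode the study conditions the generator emulates: a
#' chronologically ordered stream of whole-body FDG PET-CT examinations in
#' which the administered activity is chosen from five fixed calibration
#' levels by body-weight band and decay-corrected for the offset between
#' calibration and administration time (F-18 half-life 109.77 min), DLP under
#' automatic exposure control rises with body habitus (Pearson r with weight
#' around 0.7456), the weight distribution has a small pediatric tail, and
#' rare manual input errors are typically off by orders of magnitude.
#'
#' @param n_train number of training records (chronologically first).
#' @param n_threshold size of the labeled threshold-determination subset;
#'   always the chronological prefix of the training set.
#' @param n_test number of test records (chronologically after training).
#' @param n_errors_threshold number of labeled input errors injected into the
#'   threshold subset.
#' @param n_errors_test number of labeled input errors injected into the test
#'   set.
#' @param train_contamination_rate fraction of the non-threshold training
#'   remainder that receives unlabeled dose-elevation/reduction events
#'   (rescans, fixed-dose protocols, delayed administration, ...). These are
#'   genuine doses, not input errors, and carry the label `"unlabeled"`.
#' @param calibration_levels the fixed activity levels (MBq) at calibration
#'   time, strictly increasing.
#' @param weight_band_cuts weight cut points (kg) mapping a patient to a
#'   calibration level: weights in `[cuts[1], cuts[2])` get `levels[2]`, and
#'   so on. Must have length `length(calibration_levels) - 1`.
#' @param pediatric_dose_model list with `intercept` and `slope` (MBq and
#'   MBq/kg): patients below the first band cut receive a weight-proportional
#'   calibration activity `intercept + slope * weight` instead of a fixed
#'   level, as published pediatric mean doses (well below the lowest fixed
#'   level) require. The defaults are fitted to the sub-30-kg 10-kg-bin mean
#'   administered doses, de-adjusted by the mean decay factor of the default
#'   administration offset.
#' @param half_life_min radionuclide half-life in minutes (F-18: 109.77).
#' @param admin_offset_range_min range (minutes) of the administration-time
#'   offset before calibration time; administration before calibration means
#'   the administered activity exceeds the calibration value.
#' @param weight_model list with `adult_meanlog`, `adult_sdlog` (log-normal
#'   adult component, truncated to (2.5, 129.9) kg), `pediatric_fraction`,
#'   and `pediatric_range` (uniform pediatric component, kg).
#' @param dlp_model list with `intercept`, `slope` of the mean log(DLP) vs
#'   log(weight) line and `sdlog`, the multiplicative log-normal noise scale.
#'   The defaults are calibrated against published 10-kg-bin mean DLP values
#'   so that the clean weight-DLP correlation lands near
#'   `target_weight_dlp_corr`.
#' @param target_weight_dlp_corr the Pearson correlation between weight and
#'   DLP the clean training data should exhibit (documentation/audit value;
#'   the generator does not re-tune itself at run time).
#' @param error_kinds kinds (see [inject_error()]) sampled for the labeled
#'   input errors. Defaults to the two order-of-magnitude kinds.
#' @param seed integer seed; [generate_dataset()] is deterministic given the
#'   config (including this seed).
#'
#' @return an object of class `generator_config` (a validated list).
#' @seealso [generate_dataset()], [inject_error()], [assign_pet_dose()]
#' @examples
#' cfg <- generator_config(n_train = 200, n_threshold = 50, n_test = 40)
#' ds <- generate_dataset(cfg)
#' nrow(ds$train)
#' @export
generator_config <- function(n_train = 3509,
                             n_threshold = 685,
                             n_test = 499,
                             n_errors_threshold = 2,
                             n_errors_test = 2,
                             train_contamination_rate = 0.008,
                             calibration_levels = c(111, 148, 185, 222, 259),
                             weight_band_cuts = c(30, 45, 57, 75),
                             pediatric_dose_model = list(intercept = 30.9,
                                                         slope = 2.457),
                             half_life_min = 109.77,
                             admin_offset_range_min = c(0, 30),
                             weight_model = list(adult_meanlog = log(58),
                                                 adult_sdlog = 0.22,
                                                 pediatric_fraction = 0.03,
                                                 pediatric_range = c(4, 40)),
                             dlp_model = list(intercept = 1.8536,
                                              slope = 0.9007,
                                              sdlog = 0.196),
                             target_weight_dlp_corr = 0.7456,
                             error_kinds = c("magnitude_error", "weight_typo"),
                             seed = 1L) {
  cfg <- list(n_train = as.integer(n_train),
              n_threshold = as.integer(n_threshold),
              n_test = as.integer(n_test),
              n_errors_threshold = as.integer(n_errors_threshold),
              n_errors_test = as.integer(n_errors_test),
              train_contamination_rate = train_contamination_rate,
              calibration_levels = as.numeric(calibration_levels),
              weight_band_cuts = as.numeric(weight_band_cuts),
              pediatric_dose_model = pediatric_dose_model,
              half_life_min = half_life_min,
              admin_offset_range_min = as.numeric(admin_offset_range_min),
              weight_model = weight_model,
              dlp_model = dlp_model,
              target_weight_dlp_corr = target_weight_dlp_corr,
              error_kinds = error_kinds,
              seed = as.integer(seed))
  validate_generator_config(cfg)
  class(cfg) <- "generator_config"
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(cfg$n_train > 0, cfg$n_test > 0, cfg$n_threshold > 0)
  if (cfg$n_threshold > cfg$n_train) {
    stop("n_threshold must not exceed n_train (the threshold subset is a prefix of the training data)")
  }
  if (cfg$n_errors_threshold > cfg$n_threshold) {
    stop("inconsistent config: n_errors_threshold exceeds n_threshold")
  }
  if (cfg$n_errors_test > cfg$n_test) {
    stop("inconsistent config: n_errors_test exceeds n_test")
  }
  if (cfg$n_errors_threshold < 0 || cfg$n_errors_test < 0) {
    stop("error counts must be non-negative")
  }
  if (is.unsorted(cfg$calibration_levels, strictly = TRUE)) {
    stop("calibration_levels must be strictly increasing")
  }
  if (length(cfg$weight_band_cuts) != length(cfg$calibration_levels) - 1L) {
    stop("weight_band_cuts must have one fewer element than calibration_levels")
  }
  if (cfg$train_contamination_rate < 0 || cfg$train_contamination_rate > 1) {
    stop("train_contamination_rate must lie in [0, 1]")
  }
  if (cfg$dlp_model$sdlog <= 0 || cfg$weight_model$adult_sdlog <= 0) {
    stop("noise scales must be positive")
  }
  if (cfg$half_life_min <= 0) stop("half_life_min must be positive")
  bad <- !cfg$error_kinds %in% INPUT_ERROR_KINDS
  if (any(bad)) {
    stop("error_kinds must be input-error kinds: ",
         paste(INPUT_ERROR_KINDS, collapse = ", "))
  }
  invisible(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic dose-record generator configuration\n")
  cat(sprintf("  splits: %d train (first %d labeled for thresholding) / %d test\n",
              x$n_train, x$n_threshold, x$n_test))
  cat(sprintf("  labeled input errors: %d (threshold subset), %d (test)\n",
              x$n_errors_threshold, x$n_errors_test))
  cat(sprintf("  unlabeled dose-event contamination: %.3f of training remainder\n",
              x$train_contamination_rate))
  cat(sprintf("  calibration levels (MBq): %s; half-life %.2f min\n",
              paste(x$calibration_levels, collapse = ", "), x$half_life_min))
  cat(sprintf("  target weight-DLP correlation: %.4f; seed %d\n",
              x$target_weight_dlp_corr, x$seed))
  invisible(x)
}

# error taxonomy ------------------------------------------------------------

# The first three kinds are manual input errors (labeled anomalies); the
# remaining four are real dose events, unlabeled contamination in training.
INPUT_ERROR_KINDS <- c("magnitude_error", "wrong_patient_value", "weight_typo")
DOSE_EVENT_KINDS <- c("fixed_dose_no_aec", "rescan_double_dlp",
                      "planning_ct_high_dlp", "delayed_administration_low_dose")
ALL_ERROR_KINDS <- c(INPUT_ERROR_KINDS, DOSE_EVENT_KINDS)

# sampling helpers -----------------------------------------------------------

sample_weight <- function(n, wm) {
  ped <- runif(n) < wm$pediatric_fraction
  w <- numeric(n)
  w[ped] <- runif(sum(ped), wm$pediatric_range[1], wm$pediatric_range[2])
  n_adult <- sum(!ped)
  wa <- rlnorm(n_adult, wm$adult_meanlog, wm$adult_sdlog)
  # truncate the adult component to a plausible habitus range
  while (any(bad <- wa <= 2.5 | wa >= 129.9)) {
    wa[bad] <- rlnorm(sum(bad), wm$adult_meanlog, wm$adult_sdlog)
  }
  w[!ped] <- wa
  w
}

sample_dlp <- function(weight, dm) {
  mu <- dm$intercept + dm$slope * log(weight)
  dlp <- exp(mu + rnorm(length(weight), 0, dm$sdlog))
  # keep clean records inside the plausible DLP range
  while (any(bad <- dlp <= 20 | dlp >= 2000)) {
    dlp[bad] <- exp(mu[bad] + rnorm(sum(bad), 0, dm$sdlog))
  }
  dlp
}

#' Administered PET activity for a given weight and administration offset
#'
#' Maps body weight to a calibration activity — one of the fixed levels via
#' the configured weight bands for adults, a weight-proportional activity
#' (`pediatric_dose_model`) below the first band cut — then decay-corrects
#' for administration `offset_min` minutes *before* the calibration time, so
#' the administered activity is `level * 2^(offset_min / half_life)`. At zero
#' offset the calibration value is returned exactly; the result is strictly
#' increasing in the offset.
#'
#' @param weight body weight in kg (vectorized), positive.
#' @param offset_min administration-time offset in minutes before calibration.
#' @param config a [generator_config()].
#' @return administered activity in MBq.
#' @examples
#' cfg <- generator_config()
#' assign_pet_dose(80, 0, cfg)        # heaviest band, calibration value
#' assign_pet_dose(55, 8, cfg)        # decay-adjusted above 222 MBq
#' @export
assign_pet_dose <- function(weight, offset_min, config) {
  stopifnot(all(weight > 0), all(offset_min >= 0))
  level <- config$calibration_levels[
    findInterval(weight, c(-Inf, config$weight_band_cuts))]
  ped <- weight < config$weight_band_cuts[1]
  if (any(ped)) {
    pdm <- config$pediatric_dose_model
    level[ped] <- pdm$intercept + pdm$slope * weight[ped]
  }
  level * 2^(offset_min / config$half_life_min)
}

make_clean_records <- function(n, config) {
  w <- sample_weight(n, config$weight_model)
  off <- runif(n, config$admin_offset_range_min[1], config$admin_offset_range_min[2])
  data.frame(weight_kg = w,
             pet_dose_mbq = assign_pet_dose(w, off, config),
             dlp_mgycm = sample_dlp(w, config$dlp_model))
}

#' Inject a single recording error or dose event into a clean record
#'
#' Mutates exactly one field of a clean dose record according to the error
#' taxonomy. Input-error kinds (labeled `"anomaly"`):
#' \describe{
#'   \item{magnitude_error}{one variable multiplied by a factor drawn
#'     log-uniformly from \[8, 100\], the envelope of documented entry-error
#'     magnitudes (a misplaced decimal point or appended digits); pass
#'     `factor = 0.1` for the decimal-shift-down variant, or any other
#'     factor explicitly.}
#'   \item{wrong_patient_value}{one variable replaced by the same variable
#'     from a donor record — the subtle kind that can stay inside every
#'     marginal range while breaking the correlation structure.}
#'   \item{weight_typo}{a digit appended to (x10) or dropped from (/10) the
#'     weight entry.}
#' }
#' Dose-event kinds (label `"unlabeled"`; real doses, not input errors):
#' `fixed_dose_no_aec` (DLP replaced by a high fixed-protocol value),
#' `rescan_double_dlp` (DLP doubled), `planning_ct_high_dlp` (DLP times
#' 2.5-4), `delayed_administration_low_dose` (activity times 0.2-0.6).
#'
#' The original record is retained as `attr(, "original")` for ground-truth
#' audit.
#'
#' @param record a one-row data.frame with the canonical dose columns.
#' @param kind one of the kinds above.
#' @param variable which variable to corrupt (`"weight_kg"`,
#'   `"pet_dose_mbq"`, `"dlp_mgycm"`); sampled if `NULL` where the kind
#'   allows a choice.
#' @param factor multiplicative factor for `magnitude_error`; drawn
#'   log-uniform from \[8, 1000\] if `NULL`.
#' @param donor one-row data.frame supplying the replacement value for
#'   `wrong_patient_value`.
#' @param typo `"append"` or `"drop"` for `weight_typo`; sampled if `NULL`.
#' @return the mutated record with `label` and `error_kind` set.
#' @examples
#' rec <- data.frame(weight_kg = 58, pet_dose_mbq = 204, dlp_mgycm = 300)
#' inject_error(rec, "magnitude_error", variable = "pet_dose_mbq", factor = 10)
#' inject_error(rec, "rescan_double_dlp")
#' @export
inject_error <- function(record, kind, variable = NULL, factor = NULL,
                         donor = NULL, typo = NULL) {
  if (!kind %in% ALL_ERROR_KINDS) {
    stop("unknown error kind: ", kind)
  }
  stopifnot(is.data.frame(record), nrow(record) == 1)
  original <- record
  out <- record
  if (kind == "magnitude_error") {
    if (is.null(variable)) variable <- sample(DOSE_VARS, 1)
    if (is.null(factor)) factor <- exp(runif(1, log(8), log(100)))
    out[[variable]] <- out[[variable]] * factor
  } else if (kind == "wrong_patient_value") {
    if (is.null(variable)) variable <- sample(DOSE_VARS, 1)
    if (is.null(donor)) stop("wrong_patient_value requires a donor record")
    out[[variable]] <- donor[[variable]]
  } else if (kind == "weight_typo") {
    if (is.null(typo)) typo <- sample(c("append", "drop"), 1)
    out$weight_kg <- if (typo == "append") out$weight_kg * 10 else out$weight_kg / 10
  } else if (kind == "fixed_dose_no_aec") {
    out$dlp_mgycm <- runif(1, 900, 1600)
  } else if (kind == "rescan_double_dlp") {
    out$dlp_mgycm <- out$dlp_mgycm * 2
  } else if (kind == "planning_ct_high_dlp") {
    out$dlp_mgycm <- out$dlp_mgycm * runif(1, 2.5, 4)
  } else if (kind == "delayed_administration_low_dose") {
    out$pet_dose_mbq <- out$pet_dose_mbq * runif(1, 0.2, 0.6)
  }
  out$label <- if (kind %in% INPUT_ERROR_KINDS) "anomaly" else "unlabeled"
  out$error_kind <- kind
  attr(out, "original") <- original
  out
}

#' Generate a chronologically ordered synthetic dose-record study dataset
#'
#' Draws `n_train + n_test` clean examinations, splits them chronologically
#' (training first; the first `n_threshold` training records form the labeled
#' threshold-determination subset), then injects the configured number of
#' labeled input errors into the threshold subset and the test set and
#' unlabeled dose events into the non-threshold training remainder. The
#' result is fully deterministic given the config (including its seed).
#'
#' @param config a [generator_config()].
#' @return an object of class `dose_dataset`: a list with data.frames
#'   `train`, `threshold` (the labeled prefix of `train`), `test`, and
#'   `manifest`, a ground-truth audit table of every injected record (kind,
#'   original and corrupted values).
#' @examples
#' ds <- generate_dataset(generator_config(n_train = 300, n_threshold = 80,
#'                                         n_test = 60, seed = 7))
#' table(ds$threshold$label)
#' @export
generate_dataset <- function(config) {
  validate_generator_config(config)
  set.seed(config$seed)
  n_total <- config$n_train + config$n_test

  rec <- make_clean_records(n_total, config)
  rec$exam_index <- seq_len(n_total)
  rec$split <- rep(c("train", "test"), c(config$n_train, config$n_test))
  rec$split[seq_len(config$n_threshold)] <- "threshold"
  rec$label <- "normal"
  rec$error_kind <- NA_character_
  rec <- rec[, c("exam_index", "split", DOSE_VARS, "label", "error_kind")]

  manifest <- list()
  corrupt <- function(i, kind) {
    donor <- NULL
    if (kind == "wrong_patient_value") {
      donor <- rec[sample(setdiff(seq_len(n_total), i), 1), ]
    }
    # study conditions: injected typos shift the entry upward (appended
    # digit), matching the upward order-of-magnitude errors this kind of
    # manual entry produces; the drop variant stays available via
    # inject_error() directly
    mutated <- inject_error(rec[i, ], kind, donor = donor,
                            typo = if (kind == "weight_typo") "append" else NULL)
    entry <- data.frame(exam_index = rec$exam_index[i], split = rec$split[i],
                        kind = kind,
                        weight_orig = rec$weight_kg[i],
                        dose_orig = rec$pet_dose_mbq[i],
                        dlp_orig = rec$dlp_mgycm[i],
                        weight_new = mutated$weight_kg,
                        dose_new = mutated$pet_dose_mbq,
                        dlp_new = mutated$dlp_mgycm)
    rec[i, ] <<- mutated[, names(rec)]
    manifest[[length(manifest) + 1L]] <<- entry
  }

  if (config$n_errors_threshold > 0) {
    idx <- sample(seq_len(config$n_threshold), config$n_errors_threshold)
    kinds <- sample(config$error_kinds, config$n_errors_threshold, replace = TRUE)
    for (j in seq_along(idx)) corrupt(idx[j], kinds[j])
  }
  if (config$n_errors_test > 0) {
    idx <- config$n_train + sample(seq_len(config$n_test), config$n_errors_test)
    kinds <- sample(config$error_kinds, config$n_errors_test, replace = TRUE)
    for (j in seq_along(idx)) corrupt(idx[j], kinds[j])
  }
  remainder <- setdiff(seq_len(config$n_train), seq_len(config$n_threshold))
  n_events <- round(config$train_contamination_rate * length(remainder))
  if (n_events > 0) {
    idx <- sample(remainder, n_events)
    kinds <- sample(DOSE_EVENT_KINDS, n_events, replace = TRUE)
    for (j in seq_along(idx)) corrupt(idx[j], kinds[j])
  }

  manifest <- if (length(manifest)) do.call(rbind, manifest) else
    data.frame(exam_index = integer(), split = character(), kind = character(),
               weight_orig = numeric(), dose_orig = numeric(), dlp_orig = numeric(),
               weight_new = numeric(), dose_new = numeric(), dlp_new = numeric())

  train <- rec[seq_len(config$n_train), ]
  out <- list(train = train,
              threshold = train[seq_len(config$n_threshold), ],
              test = rec[config$n_train + seq_len(config$n_test), ],
              manifest = manifest,
              config = config)
  class(out) <- "dose_dataset"
  out
}

#' @export
print.dose_dataset <- function(x, ...) {
  cat(sprintf("Synthetic dose-record dataset (seed %d)\n", x$config$seed))
  cat(sprintf("  train: %d records (threshold prefix: %d, %d labeled anomalies)\n",
              nrow(x$train), nrow(x$threshold),
              sum(x$threshold$label == "anomaly")))
  cat(sprintf("  test:  %d records (%d labeled anomalies)\n",
              nrow(x$test), sum(x$test$label == "anomaly")))
  cat(sprintf("  injected records (manifest): %d\n", nrow(x$manifest)))
  invisible(x)
}

#' Read / write dose-record CSV files
#'
#' The on-disk schema is one row per examination with columns
#' `exam_index,split,weight_kg,pet_dose_mbq,dlp_mgycm,label,error_kind`
#' (UTF-8, `.` decimal separator, header required). [run_study()] accepts
#' files in this schema in place of the generator, so the pipeline runs
#' unchanged on institutional exports.
#'
#' @param x a data.frame of dose records or a `dose_dataset` (all splits are
#'   concatenated).
#' @param path file path.
#' @return `read_dose_csv()` returns a validated data.frame;
#'   `write_dose_csv()` returns `path` invisibly.
#' @export
write_dose_csv <- function(x, path) {
  if (inherits(x, "dose_dataset")) {
    x <- rbind(x$train, x$test)
  }
  stopifnot(all(c("exam_index", DOSE_VARS) %in% names(x)))
  if (!"split" %in% names(x)) x$split <- "train"
  if (!"label" %in% names(x)) x$label <- "unlabeled"
  if (!"error_kind" %in% names(x)) x$error_kind <- NA_character_
  write.csv(x[, c("exam_index", "split", DOSE_VARS, "label", "error_kind")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dose_csv
#' @export
read_dose_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("exam_index", DOSE_VARS)
  if (!all(need %in% names(x))) {
    stop("dose CSV must contain columns: ", paste(need, collapse = ", "))
  }
  if (!"split" %in% names(x)) x$split <- "train"
  if (!"label" %in% names(x)) x$label <- "unlabeled"
  bad <- !x$label %in% c("normal", "anomaly", "unlabeled")
  if (any(bad)) stop("label column must be one of normal/anomaly/unlabeled")
  x
}
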