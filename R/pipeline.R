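#' Study configuration for the end-to-end anomaly-detection pipeline
#'
#' @param generator a [generator_config()], or a path to a dose-record CSV in
#'   the [write_dose_csv()] schema whose `split` column carries
#'   `train`/`threshold`/`test` assignments (external-data mode; `threshold`
#'   rows must precede `train` rows chronologically).
#' @param methods anomaly indicators to run, a subset of
#'   `c("hotelling", "mspc_t2", "mspc_q", "ocsvm", "iforest", "lof", "uspc")`.
#'   The MSPC model is fitted once and contributes the `mspc_t2` and `mspc_q`
#'   rows; `uspc` is the univariate control-limit baseline (binary flags, no
#'   score-based threshold decision).
#' @param anomaly_fraction quantile-method fraction; `NULL` (auto) uses the
#'   labeled anomaly proportion of the threshold dataset.
#' @param seed study seed; overrides the generator seed so one integer
#'   reproduces the whole run.
#' @param out_dir optional directory; when set, [run_study()] writes score
#'   CSVs, model/threshold/evaluation JSON and score charts there.
#' @return an object of class `study_config`.
#' @export
study_config <- function(generator = generator_config(),
                         methods = c("hotelling", "mspc_t2", "mspc_q",
                                     "ocsvm", "iforest", "lof"),
                         anomaly_fraction = NULL,
                         seed = 1L,
                         out_dir = NULL) {
  known <- c("hotelling", "mspc_t2", "mspc_q", "ocsvm", "iforest", "lof", "uspc")
  if (length(methods) == 0) stop("at least one method is required")
  bad <- setdiff(methods, known)
  if (length(bad)) stop("unknown methods: ", paste(bad, collapse = ", "))
  if (is.character(generator) && !file.exists(generator)) {
    stop("external data file not found: ", generator)
  }
  structure(list(generator = generator, methods = methods,
                 anomaly_fraction = anomaly_fraction,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "study_config")
}

load_study_data <- function(config) {
  if (is.character(config$generator)) {
    rec <- read_dose_csv(config$generator)
    train <- rec[rec$split %in% c("threshold", "train"), , drop = FALSE]
    out <- list(train = train,
                threshold = rec[rec$split == "threshold", , drop = FALSE],
                test = rec[rec$split == "test", , drop = FALSE],
                manifest = NULL)
    if (nrow(out$threshold) == 0) stop("external data have no threshold split")
    if (nrow(out$test) == 0) stop("external data have no test split")
    return(out)
  }
  gen <- config$generator
  gen$seed <- config$seed
  generate_dataset(gen)
}

#' Run the full anomaly-detection study
#'
#' Executes the whole monitoring pipeline: generate (or load) the
#' chronologically split dose records, fit every configured detector on the
#' full training set (unsupervised, including any unlabeled contamination),
#' score the labeled threshold subset, set each indicator's operative
#' threshold by the dual-candidate minimum rule, score the test set, and
#' evaluate against the test labels. No test record influences any fitted
#' model or threshold. The run is fully reproducible from the seed.
#'
#' @param config a [study_config()].
#' @return an object of class `dose_study`: a list with `evaluation` (one row
#'   per indicator: confusion counts, precision/recall/F1, PR-AUC, ROC-AUC,
#'   threshold), `thresholds` (the `threshold_decision` objects), `scores`
#'   (per split and indicator), `models`, `data`, `manifest` and `meta`.
#' @examples
#' cfg <- study_config(generator_config(n_train = 400, n_threshold = 100,
#'                                      n_test = 80),
#'                     methods = c("hotelling", "mspc_t2", "mspc_q"),
#'                     seed = 3)
#' res <- run_study(cfg)
#' res$evaluation[, c("method", "precision", "recall", "roc_auc")]
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  stage <- "data"
  result <- tryCatch({
    data <- load_study_data(config)
    labels_thr <- data$threshold$label
    labels_test <- data$test$label

    stage <- "fit/score"
    methods <- config$methods
    models <- list()
    scores <- list(train = data.frame(exam_index = data$train$exam_index),
                   threshold = data.frame(exam_index = data$threshold$exam_index),
                   test = data.frame(exam_index = data$test$exam_index))
    add_scores <- function(name, model) {
      for (split in names(scores)) {
        sc <- predict(model, data[[split]])
        if (is.matrix(sc)) sc <- sc[, sub("^mspc_", "", name)]
        scores[[split]][[name]] <<- as.numeric(sc)
      }
      models[[name]] <<- model
    }
    if ("hotelling" %in% methods) add_scores("hotelling", fit_hotelling(data$train))
    if (any(c("mspc_t2", "mspc_q") %in% methods)) {
      mspc <- fit_mspc(data$train)
      if ("mspc_t2" %in% methods) add_scores("mspc_t2", mspc)
      if ("mspc_q" %in% methods) add_scores("mspc_q", mspc)
    }
    if ("ocsvm" %in% methods) add_scores("ocsvm", fit_ocsvm(data$train))
    if ("iforest" %in% methods) {
      add_scores("iforest", fit_iforest(data$train, seed = config$seed))
    }
    if ("lof" %in% methods) add_scores("lof", fit_lof(data$train))

    stage <- "threshold"
    score_methods <- setdiff(methods, "uspc")
    thresholds <- lapply(score_methods, function(m) {
      decide_threshold(scores$threshold[[m]], labels_thr,
                       anomaly_fraction = config$anomaly_fraction, method = m)
    })
    names(thresholds) <- score_methods

    stage <- "evaluate"
    evaluation <- do.call(rbind, lapply(score_methods, function(m) {
      evaluate_scores(scores$test[[m]], labels_test,
                      thresholds[[m]]$final, method = m)
    }))
    if ("uspc" %in% methods) {
      limits <- uspc_limits(data$train)
      models$uspc <- limits
      for (split in names(scores)) {
        scores[[split]]$uspc <- as.numeric(uspc_flag(limits, data[[split]]))
      }
      cc <- confusion_counts(scores$test$uspc, labels_test, 1)
      p <- prf(cc["tp"], cc["fp"], cc["fn"])
      evaluation <- rbind(evaluation, data.frame(
        method = "uspc", tp = unname(cc["tp"]), fp = unname(cc["fp"]),
        fn = unname(cc["fn"]), tn = unname(cc["tn"]),
        precision = unname(p["precision"]), recall = unname(p["recall"]),
        f1 = unname(p["f1"]), pr_auc = NA_real_, roc_auc = NA_real_,
        threshold = 1, stringsAsFactors = FALSE))
    }
    rownames(evaluation) <- NULL

    out <- list(config = config, data = data,
                models = models, thresholds = thresholds, scores = scores,
                evaluation = evaluation, manifest = data$manifest,
                meta = list(seed = config$seed,
                            package_version = as.character(utils::packageVersion("dosewatch")),
                            r_version = R.version.string))
    class(out) <- "dose_study"
    out
  }, error = function(e) {
    stop(sprintf("study failed at stage '%s': %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  if (!is.null(config$out_dir)) write_study_artifacts(result, config$out_dir)
  result
}

#' @export
print.dose_study <- function(x, digits = 3, ...) {
  cat(sprintf("Dose-record anomaly-detection study (seed %d)\n", x$meta$seed))
  cat(sprintf("  train %d / threshold subset %d / test %d records\n",
              nrow(x$data$train), nrow(x$data$threshold), nrow(x$data$test)))
  cat(sprintf("  labeled anomalies: %d (threshold), %d (test)\n\n",
              sum(x$data$threshold$label == "anomaly"),
              sum(x$data$test$label == "anomaly")))
  tab <- x$evaluation
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], signif, digits = digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.dose_study <- function(object, ...) {
  print(object, ...)
  cat("\nThresholds (final = min of quantile and labeling candidates):\n")
  for (d in object$thresholds) {
    cat(sprintf("  %-9s final %.6g (quantile %.6g, labeling %.6g)\n",
                d$method, d$final, d$quantile_candidate, d$labeling_candidate))
  }
  if (!is.null(object$models$mspc_t2)) {
    cat(sprintf("\nMSPC cumulative contribution rate: %.1f%%\n",
                100 * object$models$mspc_t2$cumulative_contribution))
  }
  if (!is.null(object$manifest) && nrow(object$manifest)) {
    cat(sprintf("\nInjected records: %d (see $manifest for the audit trail)\n",
                nrow(object$manifest)))
  }
  invisible(object)
}

#' Score-versus-examination-index control chart
#'
#' Plots each record's anomaly score against its chronological examination
#' index, marks labeled anomalies, and draws the operative threshold as a
#' dotted red line.
#'
#' @param scores anomaly scores in examination order.
#' @param labels optional anomaly labels; labeled anomalies are circled red.
#' @param threshold optional threshold to draw.
#' @param exam_index x-axis positions (defaults to `seq_along(scores)`).
#' @param main plot title.
#' @param log_y plot scores on a log axis (useful for heavy-tailed scores).
#' @param ... passed to [plot()].
#' @return invisibly, `NULL`; called for its side effect.
#' @export
score_chart <- function(scores, labels = NULL, threshold = NULL,
                        exam_index = seq_along(scores), main = "anomaly scores",
                        log_y = FALSE, ...) {
  plot(exam_index, scores, pch = 16, cex = 0.5, col = "grey40",
       xlab = "examination number", ylab = "anomaly score", main = main,
       log = if (log_y) "y" else "", ...)
  if (!is.null(labels)) {
    anom <- as_anomaly_indicator(labels)
    if (any(anom)) {
      points(exam_index[anom], scores[anom], col = "red", pch = 1,
             cex = 1.6, lwd = 2)
    }
  }
  if (!is.null(threshold)) abline(h = threshold, col = "red", lty = 3)
  invisible(NULL)
}

#' @export
plot.dose_study <- function(x, split = "test", methods = NULL, ask = NULL, ...) {
  sc <- x$scores[[split]]
  if (is.null(sc)) stop("unknown split: ", split)
  methods <- methods %||% setdiff(names(sc), "exam_index")
  labels <- x$data[[split]]$label
  if (is.null(ask)) ask <- length(methods) > 1 && interactive()
  if (ask) {
    old <- par(ask = TRUE); on.exit(par(old))
  }
  for (m in methods) {
    thr <- if (!is.null(x$thresholds[[m]])) x$thresholds[[m]]$final else NULL
    score_chart(sc[[m]], labels, thr, exam_index = sc$exam_index,
                main = sprintf("%s scores (%s data)", m, split), ...)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# JSON-serializable parameter view of each fitted model
model_params <- function(model) UseMethod("model_params")
#' @export
model_params.hotelling_model <- function(model) {
  list(type = "hotelling", mu = model$mu, sigma = model$sigma, dof = model$dof)
}
#' @export
model_params.mspc_model <- function(model) {
  list(type = "mspc", center = model$center, scale = model$scale,
       loadings = model$loadings, component_variances = model$component_variances,
       cumulative_contribution = model$cumulative_contribution)
}
#' @export
model_params.ocsvm_model <- function(model) {
  list(type = "ocsvm", gamma = model$gamma, nu = model$nu,
       n_support = model$svm$tot.nSV, rho = model$svm$rho)
}
#' @export
model_params.iforest_model <- function(model) {
  list(type = "iforest", n_trees = model$n_trees, max_samples = model$psi,
       contamination = model$contamination, max_features = model$max_features,
       seed = model$seed)
}
#' @export
model_params.lof_model <- function(model) {
  list(type = "lof", n_neighbors = model$k, metric = "euclidean", n = model$n)
}
#' @export
model_params.uspc_limits <- function(model) {
  list(type = "uspc", lower = model[, 1], upper = model[, 2])
}

write_study_artifacts <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (split in names(study$scores)) {
    sc <- study$scores[[split]]
    long <- do.call(rbind, lapply(setdiff(names(sc), "exam_index"), function(m) {
      data.frame(exam_index = sc$exam_index, method = m, score = sc[[m]])
    }))
    write.csv(long, file.path(out_dir, paste0("scores_", split, ".csv")),
              row.names = FALSE)
  }
  jsonlite::write_json(
    lapply(study$thresholds, unclass),
    file.path(out_dir, "thresholds.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    lapply(study$models, model_params),
    file.path(out_dir, "models.json"), auto_unbox = TRUE, digits = NA)
  write.csv(study$evaluation, file.path(out_dir, "evaluation.csv"),
            row.names = FALSE)
  if (!is.null(study$manifest)) {
    write.csv(study$manifest, file.path(out_dir, "manifest.csv"),
              row.names = FALSE)
  }
  if (is.character(study$config$generator)) {
    # external mode: nothing to re-export
  } else {
    write_dose_csv(study$data, file.path(out_dir, "records.csv"))
  }
  for (m in setdiff(names(study$scores$test), "exam_index")) {
    png(file.path(out_dir, paste0("chart_", m, ".png")), width = 900, height = 500)
    thr <- if (!is.null(study$thresholds[[m]])) study$thresholds[[m]]$final else NULL
    score_chart(study$scores$test[[m]], study$data$test$label, thr,
                exam_index = study$scores$test$exam_index,
                main = sprintf("%s scores (test data)", m))
    dev.off()
  }
  invisible(out_dir)
}
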