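test_that("confusion counts classify at score >= threshold", {
  expect_equal(confusion_counts(c(5, 1, 1), c(1, 0, 0), 5),
               c(tp = 1, fp = 0, fn = 0, tn = 2))
  # threshold below every score flags everything
  expect_equal(confusion_counts(c(5, 1, 1), c(1, 0, 0), 0),
               c(tp = 1, fp = 2, fn = 0, tn = 0))
  # boundary: a record exactly at the threshold is flagged
  expect_equal(unname(confusion_counts(c(3, 2), c(1, 0), 3)["tp"]), 1)
  expect_error(confusion_counts(1:3, c(0, 1), 1), "length")
  # 499-record layout: both anomalies and one normal above threshold
  scores <- c(rep(1, 496), 9, 50, 60)
  labels <- c(rep(0, 497), 1, 1)
  expect_equal(confusion_counts(scores, labels, 8),
               c(tp = 2, fp = 1, fn = 0, tn = 496))
})

test_that("precision/recall/F1 follow their definitions, NA when undefined", {
  expect_equal(prf(2, 7, 0), c(precision = 2 / 9, recall = 1, f1 = 4 / 11))
  p <- prf(0, 0, 3)
  expect_true(is.na(p["precision"]))
  expect_equal(unname(p[["recall"]]), 0)
  p2 <- prf(0, 0, 0)
  expect_true(all(is.na(p2)))
})

test_that("ROC-AUC equals Mann-Whitney pair counting", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(rep(2, 10), c(rep(0, 5), rep(1, 5))), 0.5)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "at least one")
  set.seed(4)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # force ties
    labels <- runif(n) < 0.4
    if (!any(labels) || all(labels)) next
    expect_equal(roc_auc(scores, labels), roc_auc_bruteforce(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("PR-AUC is the average-precision step rule", {
  expect_equal(pr_auc(c(9, 8, 1, 2), c(1, 1, 0, 0)), 1.0)
  # single positive ranked last among n: AP = 1/n
  expect_equal(pr_auc(c(4, 3, 2, 1), c(0, 0, 0, 1)), 1 / 4)
  expect_error(pr_auc(1:3, c(0, 0, 0)), "anomaly")
  set.seed(5)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    labels <- runif(n) < 0.3
    if (!any(labels)) next
    expect_equal(pr_auc(scores, labels), pr_auc_bruteforce(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("recall is monotone non-increasing in the threshold", {
  set.seed(6)
  scores <- rnorm(200)
  labels <- runif(200) < 0.1
  ths <- sort(unique(scores))
  recalls <- vapply(ths, function(t) {
    cc <- confusion_counts(scores, labels, t)
    cc[["tp"]] / (cc[["tp"]] + cc[["fn"]])
  }, 1)
  expect_true(all(diff(recalls) <= 0))
})

test_that("USPC flags marginal-range violations, strictly outside only", {
  set.seed(7)
  train <- data.frame(weight_kg = rnorm(2000, 58, 12),
                      pet_dose_mbq = rnorm(2000, 220, 40),
                      dlp_mgycm = rnorm(2000, 300, 90))
  lim <- uspc_limits(train)
  expect_true(all(lim[, "lower"] < lim[, "upper"]))
  # an order-of-magnitude PET dose error breaches its marginal limit
  expect_true(uspc_flag(lim, adult_record(dose = 2040)))
  # a wrong-patient DLP inside the adult range passes unflagged
  inside_dlp <- unname(quantile(train$dlp_mgycm, 0.9))
  expect_false(uspc_flag(lim, adult_record(dlp = inside_dlp)))
  # exactly at a limit is not flagged
  at_limit <- adult_record()
  at_limit$weight_kg <- lim["weight_kg", "upper"]
  expect_false(uspc_flag(lim, at_limit))
  above <- at_limit; above$weight_kg <- above$weight_kg + 1e-9
  expect_true(uspc_flag(lim, above))
  # mean +/- k sd variant
  lim2 <- uspc_limits(train, k_sd = 3)
  expect_equal(unname(lim2["weight_kg", ]),
               mean(train$weight_kg) + c(-3, 3) * sd(train$weight_kg))
})

test_that("weight-interval summary reports per-bin means over occupied bins", {
  one <- data.frame(weight_kg = c(52, 55), pet_dose_mbq = c(200, 220),
                    dlp_mgycm = c(300, 340))
  tab <- weight_interval_summary(one)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$mean_pet_dose_mbq, 210)
  two <- data.frame(weight_kg = c(5, 15), pet_dose_mbq = c(40, 80),
                    dlp_mgycm = c(40, 100))
  tab2 <- weight_interval_summary(two)
  expect_equal(tab2$weight_range, c("[0, 10)", "[10, 20)"))
  expect_equal(tab2$mean_dlp_mgycm, c(40, 100))
})

test_that("generated bin mean doses track the calibration activities", {
  cfg <- generator_config(seed = 31)
  ds <- generate_dataset(cfg)
  clean <- ds$train[ds$train$label == "normal", ]
  tab <- weight_interval_summary(clean)
  for (i in seq_len(nrow(tab))) {
    lo <- tab$bin_lower[i]; hi <- lo + 10
    lev <- assign_pet_dose(c(lo + 1e-9, hi - 1e-9), 0, cfg)
    expect_gte(tab$mean_pet_dose_mbq[i], min(lev))
    expect_lte(tab$mean_pet_dose_mbq[i], 1.3 * max(lev))
  }
})

test_that("evaluate_scores assembles a coherent report row", {
  scores <- c(rep(1, 8), 20, 30)
  labels <- c(rep(0, 8), 1, 1)
  rep_row <- evaluate_scores(scores, labels, 15, method = "hotelling")
  expect_equal(rep_row$tp + rep_row$fn, sum(labels))
  expect_equal(rep_row$precision, 1)
  expect_equal(rep_row$recall, 1)
  expect_equal(rep_row$roc_auc, 1)
  expect_equal(rep_row$pr_auc, 1)
  expect_equal(rep_row$method, "hotelling")
})
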