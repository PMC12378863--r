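# OCSVM, isolation forest, LOF behavior, plus cross-detector contracts

train_fixture <- function(seed = 1, n = 800) {
  ds <- generate_dataset(generator_config(n_train = n, n_threshold = 50,
                                          n_test = 50, n_errors_threshold = 0,
                                          n_errors_test = 0,
                                          train_contamination_rate = 0,
                                          seed = seed))
  ds$train
}

test_that("OCSVM scores orient outward and match its own decision function", {
  train <- train_fixture(1)
  m <- fit_ocsvm(train)
  x <- as.matrix(train[, c("weight_kg", "pet_dose_mbq", "dlp_mgycm")])
  # deep-interior training point (closest to the medoid) lies inside the boundary
  med <- apply(x, 2, median)
  interior <- x[which.min(colSums((t(x) - med)^2)), , drop = FALSE]
  expect_lte(predict(m, interior), 0)
  # a point with DLP 100x the training maximum outscores every clean record
  far <- interior; far[3] <- 100 * max(x[, 3])
  expect_gt(predict(m, far), max(predict(m, x)))
  # brute-force evaluation of the fitted decision function from SVs/coefs/rho
  sv <- m$svm$SV; coefs <- m$svm$coefs; rho <- m$svm$rho
  q <- rbind(interior, far, x[1:20, ])
  kern <- exp(-m$gamma * cross_dist(q, sv)^2)
  expect_equal(unname(predict(m, q)), unname(-(drop(kern %*% coefs) - rho)),
               tolerance = 1e-8)
  # swapping training records leaves the decision function unchanged up to
  # the QP solver's termination tolerance
  swapped <- train
  swapped[c(1, 2), ] <- train[c(2, 1), ]
  m2 <- fit_ocsvm(swapped)
  expect_equal(predict(m, q), predict(m2, q), tolerance = 1e-2)
  expect_error(fit_ocsvm(matrix(1, 10, 3)), "degenerate")
})

test_that("isolation forest isolates a symmetric pair at equal depth", {
  pair <- rbind(c(0, 0, 0), c(1, 1, 1))
  m <- fit_iforest(pair, n_trees = 1, seed = 5)
  sc <- predict(m, pair)
  expect_equal(sc[1], sc[2])
  # both isolated at depth 1 of a 2-point tree: score 2^(-1/c(2)) = 0.5
  expect_equal(unname(sc[1]), 0.5)
})

test_that("isolation forest is seeded-deterministic and in (0,1)", {
  train <- train_fixture(2, n = 400)
  s1 <- predict(fit_iforest(train, seed = 9), train)
  s2 <- predict(fit_iforest(train, seed = 9), train)
  expect_identical(s1, s2)
  s3 <- predict(fit_iforest(train, seed = 10), train)
  expect_false(identical(s1, s3))
  expect_true(all(s1 > 0 & s1 < 1))
})

test_that("isolation forest does not disturb the caller's RNG stream", {
  train <- train_fixture(3, n = 100)
  set.seed(123); a <- runif(1)
  set.seed(123); invisible(fit_iforest(train, seed = 4))
  b <- runif(1)
  expect_identical(a, b)
})

test_that("a magnitude error outscores clean records on average over seeds", {
  train <- train_fixture(4, n = 500)
  bad <- inject_error(train[17, ], "magnitude_error",
                      variable = "pet_dose_mbq", factor = 50)
  gaps <- vapply(1:20, function(s) {
    m <- fit_iforest(train, seed = s)
    predict(m, bad) - mean(predict(m, train))
  }, 1)
  expect_gt(mean(gaps), 0)
})

test_that("LOF matches the brute-force reachability definition", {
  set.seed(11)
  train <- matrix(runif(16), 8, 2)
  query <- matrix(runif(6), 3, 2)
  m <- fit_lof(train, n_neighbors = 2)
  expect_equal(unname(predict(m, query)),
               unname(lof_bruteforce(train, query, 2)), tolerance = 1e-9)
})

test_that("LOF scores ~1 inside a homogeneous cluster and >1.5 far outside", {
  set.seed(12)
  train <- matrix(runif(600, 0, 10), ncol = 2)
  m <- fit_lof(train, n_neighbors = 20)
  # duplicate of a deep-interior training point
  interior <- train[which.min(rowSums((train - 5)^2)), , drop = FALSE]
  expect_equal(unname(predict(m, interior)), 1, tolerance = 0.2)
  far <- matrix(c(60, 60), 1, 2)
  expect_gt(predict(m, far), 1.5)
  expect_equal(unname(predict(m, far)),
               unname(lof_bruteforce(train, far, 20)), tolerance = 1e-9)
  expect_error(fit_lof(train[1:20, ], n_neighbors = 20), "exceed")
})

test_that("every detector strictly increases on x100 magnitude errors", {
  train <- train_fixture(6, n = 800)
  models <- list(hotelling = fit_hotelling(train),
                 mspc = fit_mspc(train),
                 ocsvm = fit_ocsvm(train),
                 iforest = fit_iforest(train, seed = 1),
                 lof = fit_lof(train))
  set.seed(99)
  for (trial in 1:100) {
    rec <- train[sample(nrow(train), 1), ]
    bad <- inject_error(rec, "magnitude_error",
                        variable = sample(c("weight_kg", "pet_dose_mbq",
                                            "dlp_mgycm"), 1),
                        factor = 100)
    for (nm in names(models)) {
      before <- predict(models[[nm]], rec)
      after <- predict(models[[nm]], bad)
      if (nm == "mspc") {
        expect_gt(after[1, "t2"], before[1, "t2"])
        expect_gt(after[1, "q"], before[1, "q"])
      } else {
        expect_gt(after, before)
      }
    }
  }
})

test_that("only Hotelling is invariant to per-variable rescaling", {
  train <- train_fixture(7, n = 300)
  x <- as.matrix(train[, c("weight_kg", "pet_dose_mbq", "dlp_mgycm")])
  q <- x[1:15, ] * 1.05
  rescale <- function(m) sweep(m, 2, c(10, 0.01, 1), "*")
  expect_equal(predict(fit_hotelling(x), q),
               predict(fit_hotelling(rescale(x)), rescale(q)), tolerance = 1e-8)
  s_ocsvm <- predict(fit_ocsvm(x), q)
  s_ocsvm2 <- predict(fit_ocsvm(rescale(x)), rescale(q))
  expect_false(isTRUE(all.equal(s_ocsvm, s_ocsvm2, tolerance = 1e-6)))
  s_lof <- predict(fit_lof(x, 20), q)
  s_lof2 <- predict(fit_lof(rescale(x), 20), rescale(q))
  expect_false(isTRUE(all.equal(s_lof, s_lof2, tolerance = 1e-6)))
})
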