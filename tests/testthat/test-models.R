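# Stratified splitting, random-forest fits, evaluation, importance.

test_that("stratified split rounds nearest-ties-up within each stratum", {
  sizes <- c(indigenous = 61, exotic = 72, horticulture = 139,
             pastoral = 334)
  strata <- stats::setNames(rep(names(sizes), sizes),
                            sprintf("site_%03d", seq_len(sum(sizes))))
  sp <- stratified_split(strata, fraction = 0.8, seed = 1)
  train_by <- table(strata[sp$train_ids])
  expect_equal(as.integer(train_by[names(sizes)]), c(49, 58, 111, 267))
  expect_setequal(c(sp$train_ids, sp$test_ids), names(strata))
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  # determinism under the seed
  sp2 <- stratified_split(strata, fraction = 0.8, seed = 1)
  expect_identical(sp$train_ids, sp2$train_ids)
  # a stratum of 10 at 0.8 gives exactly 8 train / 2 test
  small <- stats::setNames(rep(c("a", "b"), c(10, 10)), paste0("s", 1:20))
  sp3 <- stratified_split(small, fraction = 0.8, seed = 2)
  expect_equal(unname(table(small[sp3$train_ids])[c("a", "b")]),
               as.integer(c(8, 8)), ignore_attr = TRUE)
  expect_error(stratified_split(c(a = "x", b = "y"), fraction = 0.8), "fewer")
  expect_error(stratified_split(small, fraction = 1.2), "fraction")
})

test_that("classifier separates a one-OTU toy problem", {
  set.seed(40)
  n <- 60
  x <- matrix(rnorm(n * 5), n, dimnames = list(paste0("s", 1:n),
                                               paste0("OTU_", 1:5)))
  y <- rep(c("a", "b"), each = n / 2)
  x[, 1] <- ifelse(y == "a", 5, -5) + rnorm(n, sd = 0.1)
  fit <- fit_classifier(x[1:40, ], y[1:40], seed = 1)
  oob_acc <- 1 - fit$err.rate[fit$ntree, "OOB"]
  expect_gt(oob_acc, 0.95)
  res <- evaluate_classification(fit, x[41:60, ], y[41:60])
  expect_equal(res$accuracy, 1)
  expect_true(all(diag(res$confusion) == rowSums(res$confusion)))
  # degenerate single-stump forest still finds the informative split
  tiny <- fit_classifier(x[1:40, ], y[1:40], ntree = 1, mtry = 5,
                         maxnodes = 2, seed = 1)
  expect_gt(evaluate_classification(tiny, x[41:60, ], y[41:60])$accuracy,
            0.9)
  expect_error(fit_classifier(x, rep("a", n)), "2 classes")
})

test_that("classifier accuracy is at chance under shuffled labels", {
  set.seed(41)
  accs <- sapply(1:20, function(s) {
    n <- 60
    x <- matrix(rnorm(n * 10), n)
    rownames(x) <- paste0("s", 1:n)
    y <- sample(rep(c("a", "b", "c"), each = n / 3))
    fit <- fit_classifier(x[1:45, ], y[1:45], ntree = 200, seed = s)
    evaluate_classification(fit, x[46:60, ], y[46:60])$accuracy
  })
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 1 / 3), 3 * se + 0.05)
})

test_that("regressor recovers a noiseless linear target", {
  set.seed(42)
  n <- 100
  x <- matrix(runif(n * 4), n, dimnames = list(paste0("s", 1:n),
                                               paste0("OTU_", 1:4)))
  y <- 3 * x[, 2]
  fit <- fit_regressor(x[1:70, ], y[1:70], seed = 1)
  res <- evaluate_regression(fit, x[71:100, ], y[71:100])
  expect_gt(res$r2, 0.9)
  expect_error(fit_regressor(x, rep(1, n)), "constant")
  # target independent of the features: held-out R2 stays low
  r2_null <- sapply(1:20, function(s) {
    set.seed(500 + s)
    yn <- rnorm(n)
    f <- fit_regressor(x[1:70, ], yn[1:70], ntree = 200, seed = s)
    evaluate_regression(f, x[71:100, ], yn[71:100])$r2
  })
  expect_lte(mean(r2_null), 0.1)
})

test_that("regression evaluation matches closed-form OLS", {
  actual <- c(1, 2, 3, 4, 10)
  pred <- c(1.2, 1.9, 3.5, 3.9, 9.1)
  # closed-form slope/intercept of predicted ~ actual
  sxx <- sum((actual - mean(actual))^2)
  sxy <- sum((actual - mean(actual)) * (pred - mean(pred)))
  slope <- sxy / sxx
  intercept <- mean(pred) - slope * mean(actual)
  r2 <- sxy^2 / (sxx * sum((pred - mean(pred))^2))
  res <- microsoilq:::ols_eval(pred, actual)
  expect_equal(res$slope, slope, tolerance = 1e-12)
  expect_equal(res$intercept, intercept, tolerance = 1e-12)
  expect_equal(res$r2, r2, tolerance = 1e-12)
  expect_equal(res$adj_r2, 1 - (1 - r2) * 4 / 3, tolerance = 1e-12)
  # perfect predictions: slope 1, adjusted R2 1; constant predictions: slope 0
  y <- c(0.3, 1.7, 2.2, 5.1, 0.4)
  # lm warns about the exact fits; only the coefficients matter here
  perfect <- suppressWarnings(microsoilq:::ols_eval(y, y))
  expect_equal(perfect$slope, 1, tolerance = 1e-12)
  expect_equal(perfect$adj_r2, 1, tolerance = 1e-12)
  expect_equal(suppressWarnings(microsoilq:::ols_eval(rep(7, 5), y))$slope, 0,
               tolerance = 1e-12)
  expect_error(microsoilq:::ols_eval(pred, rep(2, 5)), "zero variance")
  expect_error(microsoilq:::ols_eval(pred[1:2], actual[1:2]), "3 test")
})

test_that("permutation importance singles out the determining feature", {
  set.seed(44)
  n <- 120
  x <- matrix(rnorm(n * 6), n, dimnames = list(NULL, paste0("OTU_", 1:6)))
  y <- 4 * x[, 3] + rnorm(n, sd = 0.2)
  fit <- fit_regressor(x[1:80, ], y[1:80], seed = 1)
  imp <- permutation_importance(fit, x[81:120, ], y[81:120], n_repeats = 5,
                                seed = 2, top_k = 3)
  expect_equal(imp$feature[1], "OTU_3")
  expect_gt(imp$importance[1], 10 * max(abs(imp$importance[-1])))
  # irrelevant features sit near zero
  expect_lt(max(abs(imp$importance[-1])), 0.3 * imp$importance[1])
  expect_equal(sum(imp$top), 3)
  expect_equal(imp$rank, 1:6)
  # the top feature is stable across repeat counts
  imp20 <- permutation_importance(fit, x[81:120, ], y[81:120],
                                  n_repeats = 20, seed = 2, top_k = 3)
  expect_equal(imp20$feature[1], "OTU_3")
})

test_that("phylum aggregation and cross-model overlap", {
  taxonomy <- data.frame(otu_id = paste0("OTU_", 1:30),
                         phylum = rep(c("Acidobacteria", "Proteobacteria",
                                        "Chloroflexi"), each = 10))
  imp1 <- data.frame(feature = paste0("OTU_", 1:15),
                     importance = 15:1, top = TRUE)
  counts <- aggregate_importance_by_phylum(imp1, taxonomy)
  expect_equal(as.integer(counts[c("Acidobacteria", "Proteobacteria")]),
               c(10, 5))
  # feature missing from the taxonomy counts as unclassified
  imp_na <- data.frame(feature = c("OTU_1", "OTU_999"),
                       importance = c(2, 1), top = TRUE)
  expect_equal(as.integer(aggregate_importance_by_phylum(
    imp_na, taxonomy)["unclassified"]), 1)
  # two models sharing exactly 3 top features: histogram {1: 24, 2: 3}
  imp2 <- data.frame(feature = paste0("OTU_", 13:27),
                     importance = 15:1, top = TRUE)
  ov <- importance_overlap(list(imp1, imp2))
  expect_equal(as.integer(ov$histogram[c("1", "2")]), c(24, 3))
})

test_that("repeated splits summarize metric distributions", {
  runner <- function(seed) {
    set.seed(seed)
    c(accuracy = 0.8 + rnorm(1, sd = 0.01))
  }
  out <- repeated_splits(runner, n_repeats = 20, base_seed = 5)
  expect_equal(nrow(out$metrics), 20)
  expect_lt(out$summary$sd, 0.1 * out$summary$mean)
  # identical seeds give identical metrics
  a <- runner(7); b <- runner(7)
  expect_identical(a, b)
  # failures are recorded, not fatal
  flaky <- function(seed) if (seed %% 2 == 0) stop("boom") else c(m = 1)
  out2 <- repeated_splits(flaky, n_repeats = 6, base_seed = 1)
  expect_equal(nrow(out2$metrics), 3)
  expect_length(out2$failures, 3)
})
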