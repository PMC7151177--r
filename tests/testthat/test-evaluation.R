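test_that("holdout stratification uses round-half-up with a floor of one", {
  labels <- rep(c("benign", "malignant"), c(458, 241))

  p50 <- stratified_holdout(labels, 0.5, repetitions = 2, base_seed = 1)
  expect_identical(unname(p50$train_counts), c(229L, 121L))
  u <- p50$units[[1]]
  expect_identical(length(u$train), 350L)
  expect_identical(sort(c(u$train, u$test)), seq_along(labels))
  expect_identical(length(intersect(u$train, u$test)), 0L)
  expect_identical(sum(labels[u$train] == "malignant"), 121L)

  p01 <- stratified_holdout(labels, 0.01, repetitions = 1, base_seed = 1)
  expect_identical(unname(p01$train_counts), c(5L, 2L))

  expect_error(stratified_holdout(labels, 0), class = "apclass_domain_error")
  expect_error(stratified_holdout(labels, 1), class = "apclass_domain_error")
  expect_warning(stratified_holdout(c("a", "b", "b"), 0.5, 1, 1),
                 "single record")
})

test_that("k-fold stratification balances per-class fold sizes", {
  balanced <- rep(c("a", "b"), each = 50)
  kb <- stratified_kfold(balanced, k = 10, repetitions = 1, base_seed = 3)
  for (u in kb$units) {
    expect_identical(length(u$test), 10L)
    expect_identical(sum(balanced[u$test] == "a"), 5L)
  }

  wbcd_labels <- rep(c("benign", "malignant"), c(458, 241))
  kw <- stratified_kfold(wbcd_labels, k = 10, repetitions = 10, base_seed = 5)
  expect_identical(length(kw$units), 100L)
  for (u in kw$units) {
    expect_true(sum(wbcd_labels[u$test] == "benign") %in% c(45L, 46L))
    expect_true(sum(wbcd_labels[u$test] == "malignant") %in% c(24L, 25L))
  }

  expect_error(stratified_kfold(balanced, k = 200),
               class = "apclass_domain_error")
  expect_error(stratified_kfold(balanced, k = 1),
               class = "apclass_domain_error")
  expect_warning(stratified_kfold(rep(c("a", "b"), c(50, 3)), k = 10,
                                  repetitions = 1), "smaller than k")
})

test_that("resubstitution on the worked example is perfectly accurate", {
  d <- worked_example()
  res <- evaluate_classifier(d, apc_classifier(), resubstitution_plan(2))
  expect_identical(res$accuracy, 1)
  expect_identical(res$rejection_rate, 0)
})

test_that("the majority classifier scores the base rate on imbalanced labels", {
  d <- wbcd_like_fixture(seed = 8, n_missing = 0)
  res <- evaluate_classifier(d, constant_classifier(),
                             resubstitution_plan(nrow(d)))
  expect_equal(res$accuracy, 458 / 699, tolerance = 1e-12)
})

test_that("well-separated classes are classified almost perfectly", {
  d <- synth_gaussian(list(rep(0, 4), rep(5, 4)), 1, c(60, 60), seed = 13)
  plan <- stratified_holdout(d$class, 0.5, repetitions = 20, base_seed = 13)
  g <- glance(evaluate_classifier(d, apc_classifier(), plan))
  expect_gte(g$mean_accuracy, 0.99)

  res <- evaluate_classifier(d, apc_classifier(), plan)
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 1))
  expect_equal(g$mean_accuracy, mean(res$accuracy), tolerance = 1e-12)
})

test_that("imputation statistics come from the training portion only", {
  xtr <- rbind(c(1, 2), c(3, NA), c(5, 6))
  xte <- rbind(c(100, 200), c(NA, 300))
  filled <- apclass:::impute_unit(xtr, xte, missing_policy("impute_global_mean"))
  # train-column means: col1 mean(1,3,5)=3, col2 mean(2,6)=4 — test values
  # (100..300) must not contaminate them
  expect_identical(filled$train[2, 2], 4)
  expect_identical(filled$test[2, 1], 3)

  # canary: perturbing test-set features does not change fitted models
  d <- wbcd_like_fixture(seed = 21)
  plan <- stratified_holdout(d$class, 0.5, repetitions = 1, base_seed = 21)
  u <- plan$units[[1]]
  d_perturbed <- d
  d_perturbed$clump_thickness[u$test] <-
    d_perturbed$clump_thickness[u$test] + 1000
  fit_unit <- function(dd) {
    parts <- apclass:::dataset_parts(dd, "class")
    xtr <- parts$x[u$train, ]; xte <- parts$x[u$test, ]
    filled <- apclass:::impute_unit(xtr, xte,
                                    missing_policy("impute_global_mean"))
    apclass:::apc_fit_matrix(filled$train, parts$class_index[u$train], 2)
  }
  expect_identical(fit_unit(d)$M, fit_unit(d_perturbed)$M)
})

test_that("classifier failures are recorded without aborting the run", {
  boom <- apclass:::new_classifier("boom",
    fit = function(x, ci, m) stop("no fit"),
    predict = function(model, x) stop("unreached"))
  d <- worked_example()
  res <- evaluate_classifier(d, boom, resubstitution_plan(2))
  expect_true(res$failed)
  expect_true(is.na(res$accuracy))
})

test_that("the nearest-centroid classifier picks the closest class", {
  train <- tibble::tibble(f1 = c(-1, 1, 9, 11), f2 = 0,
                          class = c("a", "a", "b", "b"))
  pred <- mdc_fit_predict(train, rbind(c(1, 0), c(9, 0), c(5, 0)))
  expect_identical(pred$.pred_class, c("a", "b", "a"))  # tie at 5 -> class 1
})

test_that("the learning curve reduces to evaluation and improves with data", {
  d <- synth_gaussian(list(rep(0, 3), rep(3, 3)), 1, c(100, 100), seed = 17)
  curve <- learning_curve(d, apc_classifier(),
                          fractions = c(0.01, 0.1, 0.3, 0.5, 0.7),
                          repetitions = 10, base_seed = 17)
  expect_identical(nrow(curve), 5L)
  expect_gte(curve$mean_accuracy[5], curve$mean_accuracy[1] - 0.02)

  single <- learning_curve(d, apc_classifier(), fractions = 0.5,
                           repetitions = 10, base_seed = 17)
  plan <- stratified_holdout(d$class, 0.5, repetitions = 10, base_seed = 17)
  direct <- glance(evaluate_classifier(d, apc_classifier(), plan))
  expect_equal(single$mean_accuracy, direct$mean_accuracy, tolerance = 1e-12)

  expect_error(learning_curve(d, apc_classifier(), fractions = c(0.5, 0.1)),
               class = "apclass_usage_error")
})

test_that("baseline adapters delegate to established implementations", {
  avail <- available_baselines()
  expect_identical(names(avail), c("baseline", "package", "available"))

  if (requireNamespace("class", quietly = TRUE)) {
    d <- worked_example()
    knn1 <- baseline_classifier("knn", k = 1)
    fs <- as_fundamental_set(d)
    model <- knn1$fit(fs$x, fs$class_index, fs$m)
    expect_identical(knn1$predict(model, rbind(c(6, 5, 2))), 1L)
  }
  expect_error(baseline_classifier("mystery"))
})

test_that("tidy and glance summarise evaluations consistently", {
  d <- synth_gaussian(list(rep(0, 3), rep(4, 3)), 1, c(30, 30), seed = 23)
  plan <- stratified_kfold(d$class, k = 5, repetitions = 2, base_seed = 23)
  res <- evaluate_classifier(d, mdc_classifier(), plan)
  td <- tidy(res)
  expect_identical(nrow(td), 10L)
  expect_identical(unique(td$classifier), "MDC")
  g <- glance(res)
  expect_identical(g$units, 10L)
  expect_equal(g$mean_accuracy, mean(td$accuracy), tolerance = 1e-12)
})
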