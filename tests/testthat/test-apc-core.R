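test_that("one-hot encoding places a single 1 at the class index", {
  expect_equal(encode_one_hot(1, 2), c(1, 0))
  expect_equal(encode_one_hot(2, 2), c(0, 1))
  expect_equal(encode_one_hot(3, 3), c(0, 0, 1))
  expect_error(encode_one_hot(0, 2), class = "apclass_domain_error")
  expect_error(encode_one_hot(3, 2), class = "apclass_domain_error")
  expect_error(encode_one_hot(1.5, 3), class = "apclass_domain_error")
})

test_that("pattern mean and translation match hand arithmetic", {
  x <- rbind(c(6, 5, 2), c(-4, 11, -8))
  expect_identical(pattern_mean(x), c(1, 8, -3))
  expect_identical(pattern_mean(rbind(c(2.5, -1))), c(2.5, -1))
  expect_identical(pattern_mean(rbind(c(1, 1), c(-1, -1))), c(0, 0))
  expect_error(pattern_mean(x[0, , drop = FALSE]),
               class = "apclass_domain_error")

  ctr <- c(1, 8, -3)
  expect_identical(translate_patterns(c(6, 5, 2), ctr), c(5, -3, 5))
  expect_identical(translate_patterns(c(-4, 11, -8), ctr), c(-5, 3, -5))
  expect_identical(translate_patterns(c(4, 7, -1), ctr), c(3, -1, 2))
  expect_error(translate_patterns(c(1, 2), ctr),
               class = "apclass_domain_error")
})

test_that("association matrix accumulates translated class sums", {
  x <- rbind(c(6, 5, 2), c(-4, 11, -8))
  M <- association_matrix(x, c(1, 2), m = 2)
  expect_identical(unname(M), rbind(c(5, -3, 5), c(-5, 3, -5)))

  # single class: translated patterns sum to zero by construction
  x1 <- matrix(runif(12), nrow = 4)
  expect_equal(association_matrix(x1, rep(1, 4), m = 1),
               matrix(0, 1, 3), tolerance = 1e-12)

  # entrywise agreement with direct summation on random instances
  withr::with_seed(42, {
    for (rep in 1:10) {
      n <- sample(2:6, 1); p <- sample(3:20, 1); m <- sample(2:4, 1)
      x <- matrix(rnorm(p * n), nrow = p)
      cls <- c(seq_len(m), sample(seq_len(m), p - m, replace = TRUE))
      ctr <- colMeans(x)
      M <- association_matrix(x, cls, m, ctr)
      direct <- t(vapply(seq_len(m), function(j) {
        colSums(sweep(x[cls == j, , drop = FALSE], 2, ctr))
      }, numeric(n)))
      expect_equal(M, direct, tolerance = 1e-12)
    }
  })
})

test_that("learning the worked example reproduces every printed quantity", {
  fit <- apc(worked_example())
  expect_identical(fit$p, 2L)
  expect_identical(fit$n, 3L)
  expect_identical(fit$m, 2L)
  expect_identical(unname(fit$mean), c(1, 8, -3))
  expect_identical(unname(fit$M), rbind(c(5, -3, 5), c(-5, 3, -5)))

  s1 <- apc_scores(fit, c(6, 5, 2))
  expect_identical(c(s1$.score_class_1, s1$.score_class_2), c(59, -59))
  expect_identical(s1$.pred_index, 1L)
  expect_identical(s1$.decision, "classified")

  s2 <- apc_scores(fit, c(4, 7, -1))
  expect_identical(c(s2$.score_class_1, s2$.score_class_2), c(28, -28))
  expect_identical(s2$.pred_index, 1L)

  s3 <- apc_scores(fit, fit$mean)
  expect_identical(s3$.decision, "neutral")
  expect_true(is.na(s3$.pred_class))
})

test_that("degenerate fundamental sets behave as the algebra dictates", {
  # identical patterns: translation annihilates everything, all queries neutral
  d <- tibble::tibble(f1 = rep(2, 4), f2 = rep(-1, 4),
                      class = c("a", "a", "b", "b"))
  fit <- apc(d)
  expect_equal(unname(fit$M), matrix(0, 2, 2))
  s <- apc_scores(fit, c(100, -3))
  expect_identical(s$.decision, "neutral")

  # learning is order-invariant
  d2 <- random_labeled_data(n = 4, p = 12, m = 3, seed = 5)
  perm <- withr::with_seed(9, sample(nrow(d2)))
  f1 <- apc(d2)
  f2 <- apc(d2[perm, ])
  expect_equal(f1$mean, f2$mean)
  expect_equal(f1$M, f2$M)

  # a class with no training pattern is rejected by name
  d3 <- tibble::tibble(f1 = c(1, 2), f2 = c(3, 4), class = c("a", "a"))
  attr(d3, "class_levels") <- c("a", "b")
  expect_error(apc(d3), "b", class = "apclass_domain_error")
})

test_that("prediction applies the tie policy and rejects the neutral zone", {
  fit <- apc(worked_example())
  pred <- predict(fit, rbind(c(6, 5, 2), c(4, 7, -1)))
  expect_identical(pred$.pred_class, c("class_1", "class_1"))

  expect_true(is.na(predict(fit, fit$mean)$.pred_class))

  # antisymmetry around the mean: opposite queries get opposite decisions
  withr::with_seed(11, {
    for (i in 1:20) {
      v <- rnorm(3)
      pair <- rbind(fit$mean + v, fit$mean - v)
      p <- predict(fit, pair)
      if (all(p$.decision == "classified")) {
        expect_identical(sort(p$.pred_index), c(1L, 2L))
      } else {
        expect_true(all(is.na(p$.pred_index)))
      }
    }
  })

  expect_error(apc_scores(fit, c(6, 5, 2), tie_policy = "flip"),
               class = "apclass_usage_error")
  expect_error(apc_scores(fit, c(1, 2)), class = "apclass_domain_error")
})

test_that("an ambiguous tie rejects or takes the lowest index per policy", {
  # two coincident class pairs make both matrix rows equal up to sign with a
  # query scoring identically for both classes
  d <- tibble::tibble(f1 = c(1, 1, -1, -1), f2 = c(1, -1, 1, -1),
                      class = c("a", "b", "b", "a"))
  fit <- apc(d)
  q <- c(5, 5)
  z <- apc_scores(fit, q)
  if (z$.decision == "ambiguous") {
    expect_true(is.na(z$.pred_index))
    low <- apc_scores(fit, q, tie_policy = "lowest_index")
    expect_identical(low$.pred_index, 1L)
  }
  expect_identical(apc_scores(fit, c(0, 0))$.decision, "neutral")
})

test_that("tidy and glance expose the model in tabular form", {
  fit <- apc(worked_example())
  td <- tidy(fit)
  expect_identical(nrow(td), 6L)
  expect_identical(td$weight[td$class == "class_1"], c(5, -3, 5))
  g <- glance(fit)
  expect_identical(g$p, 2L)
  expect_identical(g$row_sum_max_dev, 0)
})

test_that("model serialization round-trips bit-faithfully", {
  d <- random_labeled_data(n = 5, p = 17, m = 3, seed = 77)
  d[-ncol(d)] <- lapply(d[-ncol(d)], function(v) v * pi / 3)
  fit <- apc(d)
  path <- withr::local_tempfile(fileext = ".json")
  write_apc(fit, path)
  back <- read_apc(path)
  expect_identical(back$mean, fit$mean)
  expect_identical(back$M, fit$M)
  expect_identical(back$class_levels, fit$class_levels)
  expect_identical(back$tie_policy, fit$tie_policy)
  expect_identical(back$p, fit$p)

  # and the recovered model classifies identically
  q <- features_of(random_labeled_data(n = 5, p = 8, m = 2, seed = 3))
  expect_identical(predict(back, q), predict(fit, q))

  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"format": "other"}', bad)
  expect_error(read_apc(bad), class = "apclass_parse_error")
})
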