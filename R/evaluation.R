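#' Stratified repeated holdout split plan
#'
#' Builds `repetitions` independent stratified train/test splits.  Per
#' class, the training count is round-half-up(`fraction` times the class
#' size), floored at 1 so that even a 1% split leaves every class row of
#' the association matrix defined.  Repetition `r` draws from seed
#' `base_seed + r`, so plans are reproducible across runs and platforms.
#'
#' @param labels Vector of class labels (one per record).
#' @param fraction Training fraction in (0, 1).
#' @param repetitions Number of independent re-stratifications.
#' @param base_seed Integer base seed.
#' @return An `"apc_split_plan"` with one `(train, test)` index pair per
#'   repetition.
#' @examples
#' plan <- stratified_holdout(rep(c("a", "b"), c(458, 241)),
#'                            fraction = 0.5, repetitions = 3, base_seed = 1)
#' lengths(plan$units[[1]])   # train 350 (= 229 + 121), test 349
#' @export
stratified_holdout <- function(labels, fraction, repetitions = 100,
                               base_seed = 1) {
  if (fraction <= 0 || fraction >= 1) {
    abort_domain("`fraction` must lie strictly between 0 and 1")
  }
  labels <- as.character(labels)
  lvls <- unique(labels)
  sizes <- table(factor(labels, levels = lvls))
  if (any(sizes == 0)) abort_domain("every class needs at least one record")
  if (any(sizes == 1)) {
    warn(sprintf(
      "class(es) with a single record are always assigned to training: %s",
      paste(names(sizes)[sizes == 1], collapse = ", ")))
  }
  n_train <- as.integer(pmin(as.integer(sizes),
                             pmax(1, round_half_up(fraction * as.integer(sizes)))))
  if (sum(as.integer(sizes) - n_train) == 0) {
    abort_domain("the split leaves no test records; lower `fraction`")
  }
  units <- lapply(seq_len(repetitions), function(r) {
    with_seed_local(base_seed + r, {
      train <- integer(0)
      for (j in seq_along(lvls)) {
        idx <- which(labels == lvls[j])
        train <- c(train, sample(idx)[seq_len(n_train[j])])
      }
      train <- sort(train)
      list(train = train, test = setdiff(seq_along(labels), train),
           repetition = r, fold = NA_integer_)
    })
  })
  structure(
    list(kind = "holdout", fraction = fraction, repetitions = repetitions,
         base_seed = base_seed, n_records = length(labels),
         train_counts = setNames(n_train, lvls), units = units),
    class = "apc_split_plan"
  )
}

#' Stratified repeated k-fold split plan
#'
#' Per repetition, shuffles each class and deals it round-robin into `k`
#' folds, so per-class fold sizes differ by at most one.  Repetition `r`
#' uses seed `base_seed + r`.
#'
#' @param labels Vector of class labels.
#' @param k Number of folds (>= 2).
#' @param repetitions Number of independent fold assignments.
#' @param base_seed Integer base seed.
#' @return An `"apc_split_plan"` with `repetitions * k` evaluation units.
#' @export
stratified_kfold <- function(labels, k = 10, repetitions = 10,
                             base_seed = 1) {
  labels <- as.character(labels)
  if (k < 2) abort_domain("`k` must be at least 2")
  if (k > length(labels)) {
    abort_domain(sprintf("k = %d exceeds the dataset size %d", k,
                         length(labels)))
  }
  lvls <- unique(labels)
  sizes <- table(factor(labels, levels = lvls))
  if (any(sizes < k)) {
    warn(sprintf("class(es) smaller than k = %d: %s", k,
                 paste(names(sizes)[sizes < k], collapse = ", ")))
  }
  units <- list()
  for (r in seq_len(repetitions)) {
    fold_of <- with_seed_local(base_seed + r, {
      f <- integer(length(labels))
      for (lvl in lvls) {
        idx <- which(labels == lvl)
        f[sample(idx)] <- rep_len(seq_len(k), length(idx))
      }
      f
    })
    for (f in seq_len(k)) {
      units[[length(units) + 1]] <- list(
        train = which(fold_of != f), test = which(fold_of == f),
        repetition = r, fold = f)
    }
  }
  structure(
    list(kind = "kfold", k = k, repetitions = repetitions,
         base_seed = base_seed, n_records = length(labels), units = units),
    class = "apc_split_plan"
  )
}

#' @export
print.apc_split_plan <- function(x, ...) {
  if (x$kind == "holdout") {
    cat(sprintf(
      "Stratified holdout plan: fraction %.2f, %d repetitions, seed %d, %d records\n",
      x$fraction, x$repetitions, x$base_seed, x$n_records))
  } else {
    cat(sprintf(
      "Stratified %d-fold plan: %d repetitions (%d units), seed %d, %d records\n",
      x$k, x$repetitions, length(x$units), x$base_seed, x$n_records))
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# Classifier objects: a name plus fit(x, class_index, m) -> model and
# predict(model, x) -> integer class indices (NA = rejected).

new_classifier <- function(name, fit, predict) {
  structure(list(name = name, fit = fit, predict = predict),
            class = "apc_eval_classifier")
}

#' @export
print.apc_eval_classifier <- function(x, ...) {
  cat(sprintf("<classifier: %s>\n", x$name))
  invisible(x)
}

#' APC as an evaluation-harness classifier
#'
#' @param tie_policy Passed to the scorer; under `"reject"` ambiguous and
#'   neutral queries are unclassified (counted as errors by
#'   [evaluate_classifier()]).
#' @return An `"apc_eval_classifier"`.
#' @export
apc_classifier <- function(tie_policy = c("reject", "lowest_index")) {
  tie_policy <- match.arg(tie_policy)
  new_classifier(
    name = "APC",
    fit = function(x, class_index, m) apc_fit_matrix(x, class_index, m),
    predict = function(model, x) {
      scored <- apc_score_matrix(model$mean, model$M, x)
      idx <- vapply(scored$decisions, function(d) {
        if (d$kind == "classified") d$index
        else if (d$kind == "ambiguous" && tie_policy == "lowest_index") {
          min(d$tied)
        } else NA_integer_
      }, integer(1))
      idx
    }
  )
}

#' Minimum-distance (nearest class centroid) classifier
#'
#' Assigns each query to the class whose training centroid is nearest in
#' Euclidean distance; ties break to the lowest class index.  For balanced
#' two-class data this decision coincides with the APC's on every non-tied
#' query, which makes it a useful analytic cross-check.
#'
#' @return An `"apc_eval_classifier"`.
#' @export
mdc_classifier <- function() {
  new_classifier(
    name = "MDC",
    fit = function(x, class_index, m) {
      counts <- tabulate(class_index, nbins = m)
      if (any(counts == 0)) {
        abort_domain(sprintf("empty class(es): %s",
                             paste(which(counts == 0), collapse = ", ")))
      }
      centroids <- rowsum(x, group = class_index) / counts
      list(centroids = centroids)
    },
    predict = function(model, x) {
      # squared distances via ||x||^2 - 2 x.c + ||c||^2; max.col(-d, "first")
      # gives the lowest-index tie break.
      cross <- x %*% t(model$centroids)
      d2 <- sweep(-2 * cross, 2, rowSums(model$centroids^2), `+`)
      max.col(-d2, ties.method = "first")
    }
  )
}

#' Nearest-centroid fit/predict in one call
#'
#' @param data Labeled training data frame.
#' @param new_data Query patterns (data frame or matrix).
#' @param class_col Label column in `data`.
#' @return A tibble with `.pred_index` and `.pred_class`.
#' @export
mdc_fit_predict <- function(data, new_data, class_col = "class") {
  fs <- as_fundamental_set(data, class_col)
  clf <- mdc_classifier()
  model <- clf$fit(fs$x, fs$class_index, fs$m)
  x <- if (is.data.frame(new_data)) {
    as.matrix(new_data[intersect(colnames(fs$x), names(new_data))])
  } else if (is.null(dim(new_data))) {
    matrix(as.numeric(new_data), nrow = 1)
  } else {
    as.matrix(new_data)
  }
  idx <- clf$predict(model, x)
  tibble::tibble(.pred_index = idx, .pred_class = fs$class_levels[idx])
}

#' Constant (majority-class) classifier
#'
#' Predicts the most frequent training class for every query (ties to the
#' lowest class index).  Useful as a no-information floor: on the 458/241
#' class balance it scores 458/699.
#'
#' @return An `"apc_eval_classifier"`.
#' @export
constant_classifier <- function() {
  new_classifier(
    name = "majority",
    fit = function(x, class_index, m) {
      list(index = which.max(tabulate(class_index, nbins = m)))
    },
    predict = function(model, x) rep(model$index, nrow(x))
  )
}

#' Adapters to established baseline classifiers
#'
#' Thin fit/predict wrappers delegating to installed implementations:
#' naive Bayes and SVM (\pkg{e1071}), k-nearest neighbours (\pkg{class}),
#' a single-hidden-layer backpropagation network (\pkg{nnet}) and a
#' CART decision tree (\pkg{rpart}, standing in for C4.5).  These exist
#' for benchmarking only; hyperparameters are the delegates' defaults and
#' results should be read as indicative.
#'
#' @param name One of `"nb"`, `"knn"`, `"svm"`, `"bp"`, `"tree"`.
#' @param k Neighbourhood size for `"knn"`.
#' @param size Hidden units for `"bp"`.
#' @return An `"apc_eval_classifier"`.
#' @export
baseline_classifier <- function(name = c("nb", "knn", "svm", "bp", "tree"),
                                k = 3, size = 5) {
  name <- match.arg(name)
  pkg <- switch(name, nb = "e1071", knn = "class", svm = "e1071",
                bp = "nnet", tree = "rpart")
  if (!requireNamespace(pkg, quietly = TRUE)) {
    abort_usage(sprintf("baseline '%s' requires the '%s' package", name, pkg))
  }
  switch(
    name,
    nb = new_classifier("NB",
      fit = function(x, class_index, m) {
        e1071::naiveBayes(x, factor(class_index, levels = seq_len(m)))
      },
      predict = function(model, x) {
        as.integer(as.character(predict(model, x)))
      }),
    knn = new_classifier(sprintf("%d-NN", k),
      fit = function(x, class_index, m) {
        list(x = x, y = factor(class_index, levels = seq_len(m)))
      },
      predict = function(model, x) {
        as.integer(as.character(class::knn(model$x, x, model$y, k = k)))
      }),
    svm = new_classifier("SVM",
      fit = function(x, class_index, m) {
        e1071::svm(x, factor(class_index, levels = seq_len(m)))
      },
      predict = function(model, x) {
        as.integer(as.character(predict(model, x)))
      }),
    bp = new_classifier("BP",
      fit = function(x, class_index, m) {
        y <- diag(m)[class_index, , drop = FALSE]
        nnet::nnet(x, y, size = size, trace = FALSE, maxit = 200,
                   softmax = m > 1, entropy = FALSE)
      },
      predict = function(model, x) max.col(predict(model, x), "first")),
    tree = new_classifier("CART",
      fit = function(x, class_index, m) {
        df <- as.data.frame(x)
        df$.class <- factor(class_index, levels = seq_len(m))
        rpart::rpart(.class ~ ., data = df, method = "class")
      },
      predict = function(model, x) {
        as.integer(as.character(
          predict(model, as.data.frame(x), type = "class")))
      })
  )
}

#' Which baseline adapters can run here?
#'
#' @return A tibble of baseline names and availability of their backing
#'   package.
#' @export
available_baselines <- function() {
  spec <- c(nb = "e1071", knn = "class", svm = "e1071", bp = "nnet",
            tree = "rpart")
  tibble::tibble(
    baseline = names(spec),
    package = unname(spec),
    available = vapply(spec, requireNamespace, logical(1), quietly = TRUE)
  )
}

# ---------------------------------------------------------------------------

#' Evaluate a classifier under a split plan
#'
#' For every evaluation unit of the plan: fits the classifier on the
#' training indices, predicts the test indices, and records accuracy
#' (rejections count as errors) and rejection rate.  Missing feature
#' values are handled per unit with statistics computed from the training
#' portion only, so no test information leaks into fitting.  A classifier
#' failure on a unit is recorded (`failed = TRUE`) and the run continues.
#'
#' @param data Labeled data frame (may contain `NA` features if the policy
#'   imputes them).
#' @param classifier An `"apc_eval_classifier"`, e.g. [apc_classifier()].
#' @param plan An `"apc_split_plan"` built on `data`'s labels.
#' @param class_col Label column name.
#' @param policy A [missing_policy()] applied per unit (train-derived
#'   statistics).  `drop_record` drops affected records up front,
#'   deterministically, before indices are interpreted — build the plan on
#'   the already-dropped data in that case.
#' @return An `"apc_evaluation"`: a tibble with one row per unit
#'   (`repetition`, `fold`, `accuracy`, `rejection_rate`, `n_test`,
#'   `failed`) carrying classifier/plan metadata; see [glance.apc_evaluation()].
#' @examples
#' d <- synth_gaussian(list(c(0, 0), c(6, 6)), 1, c(40, 40), seed = 3)
#' plan <- stratified_holdout(d$class, 0.5, repetitions = 5, base_seed = 9)
#' glance(evaluate_classifier(d, apc_classifier(), plan))
#' @export
evaluate_classifier <- function(data, classifier, plan,
                                class_col = "class",
                                policy = missing_policy("impute_global_mean")) {
  stopifnot(inherits(classifier, "apc_eval_classifier"),
            inherits(plan, "apc_split_plan"))
  parts <- dataset_parts(data, class_col)
  if (nrow(parts$x) != plan$n_records) {
    abort_domain(sprintf(
      "plan was built for %d records but `data` has %d",
      plan$n_records, nrow(parts$x)))
  }
  m <- length(parts$class_levels)

  rows <- purrr::map(plan$units, function(u) {
    res <- tryCatch({
      xtr <- parts$x[u$train, , drop = FALSE]
      xte <- parts$x[u$test, , drop = FALSE]
      if (anyNA(xtr) || anyNA(xte)) {
        filled <- impute_unit(xtr, xte, policy)
        xtr <- filled$train; xte <- filled$test
      }
      model <- classifier$fit(xtr, parts$class_index[u$train], m)
      pred <- classifier$predict(model, xte)
      truth <- parts$class_index[u$test]
      list(accuracy = mean(!is.na(pred) & pred == truth),
           rejection_rate = mean(is.na(pred)),
           failed = FALSE)
    }, error = function(e) {
      list(accuracy = NA_real_, rejection_rate = NA_real_, failed = TRUE)
    })
    tibble::tibble(
      repetition = u$repetition, fold = u$fold,
      accuracy = res$accuracy, rejection_rate = res$rejection_rate,
      n_test = length(u$test), failed = res$failed
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out,
            class = c("apc_evaluation", class(out)),
            classifier = classifier$name,
            plan_kind = plan$kind,
            plan = plan[setdiff(names(plan), "units")],
            class_levels = parts$class_levels)
}

# Train-only imputation for one evaluation unit.
impute_unit <- function(xtr, xte, policy) {
  if (policy$mode == "drop_record") {
    keep <- !apply(is.na(xtr), 1, any)
    if (anyNA(xte)) {
      abort_domain(paste("drop_record cannot remove test records during",
                         "evaluation; drop before building the plan"))
    }
    if (!all(keep)) {
      abort_domain(paste("drop_record cannot remove training records during",
                         "evaluation; drop before building the plan"))
    }
    return(list(train = xtr, test = xte))
  }
  fill <- if (policy$mode == "impute_constant") {
    rep(policy$value, ncol(xtr))
  } else {
    colMeans(xtr, na.rm = TRUE)
  }
  for (j in seq_len(ncol(xtr))) {
    xtr[is.na(xtr[, j]), j] <- fill[j]
    xte[is.na(xte[, j]), j] <- fill[j]
  }
  list(train = xtr, test = xte)
}

#' @export
print.apc_evaluation <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "Evaluation of %s (%s): %d units, mean accuracy %.4f (sd %.4f), rejection %.4f\n",
    attr(x, "classifier"), attr(x, "plan_kind"), g$units,
    g$mean_accuracy, g$sd_accuracy, g$mean_rejection_rate))
  invisible(x)
}

#' Per-unit results of an evaluation
#'
#' @param x An `"apc_evaluation"`.
#' @param ... Unused.
#' @return A plain tibble with one row per evaluation unit, including the
#'   classifier and protocol columns, suitable for binding across runs.
#' @method tidy apc_evaluation
#' @export
tidy.apc_evaluation <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(classifier = attr(x, "classifier"),
                   protocol = attr(x, "plan_kind")),
    tibble::as_tibble(x)
  )
}

#' One-row summary of an evaluation
#'
#' @param x An `"apc_evaluation"`.
#' @param ... Unused.
#' @return A tibble with classifier, protocol, unit counts, mean/sd
#'   accuracy over non-failed units, mean rejection rate, and failures.
#' @method glance apc_evaluation
#' @export
glance.apc_evaluation <- function(x, ...) {
  acc <- x$accuracy[!x$failed]
  tibble::tibble(
    classifier = attr(x, "classifier"),
    protocol = attr(x, "plan_kind"),
    units = nrow(x),
    failed_units = sum(x$failed),
    mean_accuracy = mean(acc),
    sd_accuracy = stats::sd(acc),
    mean_rejection_rate = mean(x$rejection_rate[!x$failed])
  )
}

#' Learning curve over training fractions
#'
#' Runs one repeated stratified holdout evaluation per training fraction
#' (sharing `base_seed`) and tabulates mean accuracy.  With the fraction
#' grid `c(0.01, 0.1, 0.3, 0.5, 0.7)` this reproduces the repeated-holdout
#' protocol across its five training/test ratios, and it probes where
#' accuracy stabilises — for the APC that point sits around a training set
#' one tenth the size of the smallest class.
#'
#' @param data Labeled data frame.
#' @param classifier An `"apc_eval_classifier"`.
#' @param fractions Ascending training fractions in (0, 1).
#' @param repetitions Repetitions per fraction.
#' @param base_seed Integer base seed.
#' @param class_col Label column name.
#' @param policy A [missing_policy()].
#' @return An `"apc_learning_curve"` tibble: `fraction`, `mean_accuracy`,
#'   `sd_accuracy`, `mean_rejection_rate`, `repetitions`.
#' @export
learning_curve <- function(data, classifier,
                           fractions = c(0.01, 0.1, 0.3, 0.5, 0.7),
                           repetitions = 20, base_seed = 1,
                           class_col = "class",
                           policy = missing_policy("impute_global_mean")) {
  if (is.unsorted(fractions, strictly = TRUE)) {
    abort_usage("`fractions` must be strictly ascending")
  }
  rows <- purrr::map(fractions, function(f) {
    plan <- stratified_holdout(data[[class_col]], f, repetitions, base_seed)
    g <- glance(evaluate_classifier(data, classifier, plan, class_col, policy))
    tibble::tibble(fraction = f, mean_accuracy = g$mean_accuracy,
                   sd_accuracy = g$sd_accuracy,
                   mean_rejection_rate = g$mean_rejection_rate,
                   repetitions = repetitions)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("apc_learning_curve", class(out)),
            classifier = attr(classifier, "name") %||% classifier$name,
            base_seed = base_seed)
}
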