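#' One-hot encoding of a class index
#'
#' Encodes class `class_index` out of `m` classes as a 0/1 vector with a
#' single 1 at position `class_index`.  This is the output-pattern encoding
#' the associative pattern classifier (APC) learns against.
#'
#' @param class_index Integer class index in `1..m`.
#' @param m Number of classes.
#' @return Numeric vector of length `m` with a single 1.
#' @examples
#' encode_one_hot(1, 2)  # c(1, 0)
#' encode_one_hot(3, 3)  # c(0, 0, 1)
#' @export
encode_one_hot <- function(class_index, m) {
  if (length(class_index) != 1 || length(m) != 1 ||
      is.na(class_index) || is.na(m)) {
    abort_usage("`class_index` and `m` must be single integers")
  }
  if (m < 1 || class_index < 1 || class_index > m ||
      class_index != as.integer(class_index)) {
    abort_domain(sprintf("class index %s out of range 1..%s", class_index, m))
  }
  y <- numeric(m)
  y[class_index] <- 1
  y
}

#' Componentwise mean of a set of patterns
#'
#' @param x Numeric matrix, one pattern per row.
#' @return Numeric vector of column means.
#' @export
pattern_mean <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 1) abort_domain("cannot take the mean of an empty pattern set")
  colMeans(x)
}

#' Translate patterns by a mean vector
#'
#' Subtracts `center` from every row of `x`.  Translation by the fundamental
#' set's mean is what lets the outer-product learning rule separate classes
#' without requiring orthogonal inputs.
#'
#' @param x Numeric matrix (patterns in rows) or a single numeric vector.
#' @param center Numeric vector of length `ncol(x)`.
#' @return Matrix (or vector) of the same shape as `x`.
#' @export
translate_patterns <- function(x, center) {
  vec <- is.null(dim(x))
  x <- if (vec) matrix(as.numeric(x), nrow = 1) else as.matrix(x)
  if (ncol(x) != length(center)) {
    abort_domain(sprintf(
      "dimension mismatch: patterns have %d components, center has %d",
      ncol(x), length(center)))
  }
  out <- sweep(x, 2, as.numeric(center))
  if (vec) drop(out) else out
}

#' Association matrix of the APC
#'
#' Builds the m-by-n association matrix `M = sum_k y_k (x_k - center)^T`
#' where `y_k` is the one-hot label of pattern `k`.  Row `j` of `M` is the
#' sum of the translated patterns of class `j`.
#'
#' @param x Numeric matrix of patterns (rows).
#' @param class_index Integer vector of 1-based class indices per row.
#' @param m Number of classes.
#' @param center Translation vector; defaults to `pattern_mean(x)`.
#' @return m-by-n numeric matrix.
#' @export
association_matrix <- function(x, class_index, m, center = pattern_mean(x)) {
  x <- as.matrix(x)
  if (nrow(x) != length(class_index)) {
    abort_domain("one class index per pattern is required")
  }
  xt <- translate_patterns(x, center)
  M <- matrix(0, nrow = m, ncol = ncol(x))
  present <- rowsum(xt, group = class_index)
  M[as.integer(rownames(present)), ] <- present
  M
}

# Core fit on a raw matrix + class indices; shared by apc() and the
# evaluation-harness classifier objects.
apc_fit_matrix <- function(x, class_index, m, class_levels = NULL) {
  p <- nrow(x)
  if (p < 1) abort_domain("the fundamental set is empty")
  if (anyNA(x)) {
    abort_domain("patterns contain missing values; apply a missing-value policy first")
  }
  counts <- tabulate(class_index, nbins = m)
  if (any(counts == 0)) {
    missing_classes <- if (is.null(class_levels)) {
      paste(which(counts == 0), collapse = ", ")
    } else {
      paste(class_levels[counts == 0], collapse = ", ")
    }
    abort_domain(sprintf(
      "every class needs at least one training pattern; empty class(es): %s",
      missing_classes))
  }
  center <- pattern_mean(x)
  M <- association_matrix(x, class_index, m, center)
  # Translation guarantees the rows of M sum to the zero vector; a violation
  # indicates numerical corruption upstream.
  tol <- 1e-9 * max(1, max(abs(M)))
  if (max(abs(colSums(M))) > tol) {
    abort_domain("association matrix rows do not sum to zero; input is corrupt")
  }
  list(mean = center, M = M, n = ncol(x), m = m, p = p,
       class_counts = counts)
}

#' Fit an associative pattern classifier
#'
#' Learns an APC from a labeled data frame in one shot: the fundamental
#' set's mean vector is computed, every pattern is translated by it, and the
#' m-by-n association matrix is accumulated as the sum of one-hot-label
#' outer products with the translated patterns.  Recovery scores a query by
#' translating it and multiplying by the matrix; the predicted class is the
#' row with the (strictly unique) maximal score.
#'
#' @param data Data frame with numeric feature columns and a label column.
#'   An optional `id` column is ignored as a feature.
#' @param class_col Name of the label column (default `"class"`).
#' @param feature_cols Optional character vector naming the feature columns;
#'   defaults to all numeric non-label, non-id columns.
#' @param tie_policy Default decision policy for tied maxima when
#'   predicting: `"reject"` (report unclassified) or `"lowest_index"`.
#' @return An object of class `"apc"` with elements `mean` (the learned
#'   translation vector), `M` (the association matrix, one row per class),
#'   `n`, `m`, `p`, `class_levels`, `feature_names` and `tie_policy`.
#' @examples
#' fit <- apc(worked_example())
#' fit$mean                    # (1, 8, -3)
#' fit$M                       # rbind(c(5,-3,5), c(-5,3,-5))
#' predict(fit, data.frame(f1 = 6, f2 = 5, f3 = 2))
#' @export
apc <- function(data, class_col = "class", feature_cols = NULL,
                tie_policy = c("reject", "lowest_index")) {
  tie_policy <- match.arg(tie_policy)
  parts <- dataset_parts(data, class_col, feature_cols)
  m <- length(parts$class_levels)
  if (m < 2) {
    abort_domain(paste("learning requires at least two classes with training",
                       "patterns; the data has only one"))
  }
  fit <- apc_fit_matrix(parts$x, parts$class_index, m, parts$class_levels)
  structure(
    list(
      mean = setNames(fit$mean, parts$feature_cols),
      M = matrix(fit$M, nrow = m,
                 dimnames = list(parts$class_levels, parts$feature_cols)),
      n = fit$n, m = m, p = fit$p,
      class_levels = parts$class_levels,
      class_counts = setNames(fit$class_counts, parts$class_levels),
      feature_names = parts$feature_cols,
      tie_policy = tie_policy
    ),
    class = "apc"
  )
}

# Decision for one score vector z.  The neutral zone is the exact point
# where the translated query is zero (z is identically zero); in floating
# point we use a band scaled by the magnitudes involved.  Ties at the
# maximum that are not all-zero are "ambiguous".
decide_scores <- function(z, max_abs_M, max_abs_xt) {
  tol <- 1e-9 * (1 + max_abs_M * max_abs_xt)
  if (max(abs(z)) <= tol) {
    return(list(kind = "neutral", index = NA_integer_, tied = integer()))
  }
  top <- which(z >= max(z) - tol)
  if (length(top) == 1L) {
    list(kind = "classified", index = top, tied = top)
  } else {
    list(kind = "ambiguous", index = NA_integer_, tied = top)
  }
}

# Score a matrix of queries against a fitted model (matrix form).
# Returns list(z = queries x m score matrix, decisions = list).
apc_score_matrix <- function(mean, M, x) {
  x <- if (is.null(dim(x))) matrix(as.numeric(x), nrow = 1) else as.matrix(x)
  if (ncol(x) != length(mean)) {
    abort_domain(sprintf(
      "dimension mismatch: model expects %d features, queries have %d",
      length(mean), ncol(x)))
  }
  xt <- translate_patterns(x, mean)
  z <- xt %*% t(M)
  max_abs_M <- max(abs(M), 0)
  decisions <- lapply(seq_len(nrow(z)), function(i) {
    decide_scores(z[i, ], max_abs_M, max(abs(xt[i, ]), 0))
  })
  list(z = z, decisions = decisions)
}

#' Class scores and decisions for query patterns
#'
#' Translates each query by the model's mean vector, multiplies by the
#' association matrix, and reports the per-class scores `z` together with
#' the decision.  A query whose translation is the zero vector scores zero
#' for every class and falls in the neutral zone (unclassifiable); a tied
#' non-zero maximum is ambiguous.
#'
#' @param object A fitted `"apc"` model.
#' @param new_data Data frame (feature columns matched by name when present),
#'   numeric matrix, or a single numeric vector of queries.
#' @param tie_policy Overrides the model's tie policy. Under `"reject"`,
#'   ambiguous and neutral queries get `NA` predictions; under
#'   `"lowest_index"`, ambiguous queries take the smallest tied class index
#'   (neutral queries still reject).
#' @return A tibble with one row per query: `.score_*` columns (one per
#'   class), `.decision` (`"classified"`, `"ambiguous"` or `"neutral"`),
#'   `.pred_index` and `.pred_class` (`NA` when unclassified).
#' @examples
#' fit <- apc(worked_example())
#' apc_scores(fit, rbind(c(6, 5, 2), c(4, 7, -1)))
#' @export
apc_scores <- function(object, new_data, tie_policy = NULL) {
  stopifnot(inherits(object, "apc"))
  tie_policy <- tie_policy %||% object$tie_policy
  if (!tie_policy %in% c("reject", "lowest_index")) {
    abort_usage(sprintf("unknown tie policy '%s'", tie_policy))
  }
  x <- query_matrix(new_data, object)
  scored <- apc_score_matrix(object$mean, object$M, x)

  kind <- vapply(scored$decisions, `[[`, character(1), "kind")
  idx <- vapply(scored$decisions, `[[`, integer(1), "index")
  if (tie_policy == "lowest_index") {
    amb <- kind == "ambiguous"
    idx[amb] <- vapply(scored$decisions[amb],
                       function(d) min(d$tied), integer(1))
  }

  scores <- tibble::as_tibble(scored$z, .name_repair = "minimal")
  names(scores) <- paste0(".score_", object$class_levels)
  dplyr::bind_cols(
    scores,
    tibble::tibble(
      .decision = kind,
      .pred_index = idx,
      .pred_class = object$class_levels[idx]
    )
  )
}

# Coerce query input to a numeric matrix aligned with the model's features.
query_matrix <- function(new_data, object) {
  if (is.data.frame(new_data)) {
    cols <- object$feature_names
    if (all(cols %in% names(new_data))) {
      x <- as.matrix(new_data[cols])
    } else {
      num <- new_data[vapply(new_data, is.numeric, logical(1))]
      num <- num[setdiff(names(num), "id")]
      x <- as.matrix(num)
    }
  } else if (is.null(dim(new_data))) {
    x <- matrix(as.numeric(new_data), nrow = 1)
  } else {
    x <- as.matrix(new_data)
  }
  storage.mode(x) <- "double"
  x
}

#' Predict classes with a fitted APC
#'
#' @inheritParams apc_scores
#' @param type `"class"` for decisions only, `"scores"` to include the
#'   per-class score columns.
#' @param ... Unused.
#' @return A tibble with `.pred_class`, `.pred_index` and `.decision`
#'   columns (plus `.score_*` when `type = "scores"`).
#' @examples
#' fit <- apc(worked_example())
#' predict(fit, data.frame(f1 = c(6, 4), f2 = c(5, 7), f3 = c(2, -1)))
#' @export
predict.apc <- function(object, new_data, tie_policy = NULL,
                        type = c("class", "scores"), ...) {
  type <- match.arg(type)
  out <- apc_scores(object, new_data, tie_policy)
  if (type == "class") {
    out <- out[c(".pred_class", ".pred_index", ".decision")]
  }
  out
}

#' @export
print.apc <- function(x, ...) {
  cat(sprintf(
    "Associative pattern classifier: %d classes, %d features, %d patterns\n",
    x$m, x$n, x$p))
  cat("Classes:", paste(sprintf("%s (%d)", x$class_levels, x$class_counts),
                        collapse = ", "), "\n")
  cat("Mean vector:\n")
  print(x$mean)
  cat("Association matrix:\n")
  print(x$M)
  cat(sprintf("Tie policy: %s\n", x$tie_policy))
  invisible(x)
}

#' Tidy an APC model into class/feature weights
#'
#' @param x A fitted `"apc"` model.
#' @param ... Unused.
#' @return A tibble with columns `class`, `feature`, `weight` (the entries
#'   of the association matrix) and `center` (the mean-vector component).
#' @method tidy apc
#' @export
tidy.apc <- function(x, ...) {
  tibble::tibble(
    class = rep(x$class_levels, each = x$n),
    feature = rep(x$feature_names, times = x$m),
    weight = as.vector(t(x$M)),
    center = rep(unname(x$mean), times = x$m)
  )
}

#' One-row model summary of an APC
#'
#' @param x A fitted `"apc"` model.
#' @param ... Unused.
#' @return A tibble with `n`, `m`, `p` and `row_sum_max_dev`, the largest
#'   absolute componentwise sum of the matrix rows (zero up to rounding by
#'   construction).
#' @method glance apc
#' @export
glance.apc <- function(x, ...) {
  tibble::tibble(
    n = x$n, m = x$m, p = x$p,
    row_sum_max_dev = max(abs(colSums(x$M))),
    tie_policy = x$tie_policy
  )
}
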