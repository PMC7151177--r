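#' Generate a labeled Gaussian mixture dataset
#'
#' Draws `class_sizes[j]` patterns for class `j` from a multivariate normal
#' with mean `class_means[[j]]` and a covariance shared across classes
#' (per-class covariance is available behind `per_class_covariance`).  The
#' output is fully reproducible from `seed` and leaves the caller's random
#' stream untouched.
#'
#' @param class_means List of m numeric mean vectors (or an m-by-n matrix,
#'   one row per class).
#' @param covariance Shared covariance: a scalar variance (isotropic), a
#'   length-n vector of variances, or a symmetric positive-semidefinite
#'   n-by-n matrix.
#' @param class_sizes Integer vector of m class sizes (each >= 1).
#' @param seed Integer seed.
#' @param class_names Optional class names; default `class_1..class_m`.
#' @param feature_names Optional feature names; default `f1..fn`.
#' @param per_class_covariance Optional list of m covariance specifications
#'   overriding `covariance` per class.
#' @return A tibble with columns `id`, the features, and `class`, carrying a
#'   `class_levels` attribute.
#' @examples
#' d <- synth_gaussian(list(c(0, 0), c(10, 10)), covariance = 1,
#'                     class_sizes = c(50, 50), seed = 7)
#' dplyr::count(d, class)
#' @export
synth_gaussian <- function(class_means, covariance = 1, class_sizes,
                           seed = 1, class_names = NULL,
                           feature_names = NULL,
                           per_class_covariance = NULL) {
  if (is.matrix(class_means)) {
    class_means <- asplit(class_means, 1)
  }
  m <- length(class_means)
  n <- length(class_means[[1]])
  if (!all(lengths(class_means) == n)) {
    abort_domain("all class means must share the same dimension")
  }
  if (length(class_sizes) != m || any(class_sizes < 1)) {
    abort_domain("`class_sizes` needs one size >= 1 per class")
  }
  class_names <- class_names %||% paste0("class_", seq_len(m))
  feature_names <- feature_names %||% paste0("f", seq_len(n))

  covs <- if (is.null(per_class_covariance)) {
    rep(list(as_covariance(covariance, n)), m)
  } else {
    if (length(per_class_covariance) != m) {
      abort_domain("`per_class_covariance` needs one entry per class")
    }
    lapply(per_class_covariance, as_covariance, n = n)
  }

  x <- with_seed_local(seed, {
    do.call(rbind, lapply(seq_len(m), function(j) {
      MASS::mvrnorm(class_sizes[j], mu = as.numeric(class_means[[j]]),
                    Sigma = covs[[j]])
    }))
  })
  if (is.null(dim(x))) x <- matrix(x, ncol = n)  # mvrnorm drops for size 1
  colnames(x) <- feature_names
  out <- dplyr::bind_cols(
    tibble::tibble(id = sprintf("s%05d", seq_len(sum(class_sizes)))),
    tibble::as_tibble(x),
    tibble::tibble(class = rep(class_names, times = class_sizes))
  )
  attr(out, "class_levels") <- class_names
  out
}

as_covariance <- function(covariance, n) {
  if (is.matrix(covariance)) {
    if (nrow(covariance) != n || ncol(covariance) != n) {
      abort_domain(sprintf("covariance must be %d-by-%d", n, n))
    }
    if (max(abs(covariance - t(covariance))) > 1e-8 * max(1, max(abs(covariance)))) {
      abort_domain("covariance matrix must be symmetric")
    }
    ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(1, max(abs(ev)))) {
      abort_domain("covariance matrix must be positive semi-definite")
    }
    covariance
  } else if (length(covariance) == 1) {
    if (covariance < 0) abort_domain("variance must be non-negative")
    diag(as.numeric(covariance), n)
  } else if (length(covariance) == n) {
    if (any(covariance < 0)) abort_domain("variances must be non-negative")
    diag(as.numeric(covariance), n)
  } else {
    abort_domain("covariance must be a scalar, length-n vector or n-by-n matrix")
  }
}

#' The two-association worked example
#'
#' The minimal fundamental set used throughout the documentation:
#' pattern (6, 5, 2) in class 1 and (-4, 11, -8) in class 2
#' (p = 2, n = 3, m = 2).  Learning from it yields mean vector (1, 8, -3)
#' and association matrix rbind(c(5, -3, 5), c(-5, 3, -5)).
#'
#' @return A two-row labeled tibble with features `f1..f3`.
#' @examples
#' apc(worked_example())
#' @export
worked_example <- function() {
  out <- tibble::tibble(
    id = c("x1", "x2"),
    f1 = c(6, -4), f2 = c(5, 11), f3 = c(2, -8),
    class = c("class_1", "class_2")
  )
  attr(out, "class_levels") <- c("class_1", "class_2")
  out
}

#' Synthetic dataset shaped like the Wisconsin Breast Cancer database
#'
#' Generates 699 records with the WBCD schema: 9 integer cytological
#' features on the 1–10 scale (Gaussian draws rounded then clamped),
#' 458 benign and 241 malignant records, and a configurable number of
#' missing cells (default 16, all in `bare_nuclei`, one per affected
#' record).  This exercises the file reader and the evaluation protocol
#' end-to-end without the external download; it reproduces the real
#' dataset's shape and class balance, not its feature correlations.
#'
#' @param seed Integer seed.
#' @param n_missing Number of `NA` cells to place in `bare_nuclei`.
#' @param class_sizes Benign / malignant record counts.
#' @return A tibble in [read_wbcd()] layout (with `NA` for missing cells),
#'   serializable with [write_wbcd()].
#' @examples
#' d <- wbcd_like_fixture(seed = 1)
#' nrow(d)                       # 699
#' sum(is.na(d$bare_nuclei))     # 16
#' @export
wbcd_like_fixture <- function(seed = 1, n_missing = 16,
                              class_sizes = c(458, 241)) {
  n_total <- sum(class_sizes)
  feats <- with_seed_local(seed, {
    benign <- matrix(rnorm(class_sizes[1] * 9, mean = 2.5, sd = 1.8),
                     ncol = 9)
    malignant <- matrix(rnorm(class_sizes[2] * 9, mean = 7, sd = 1.8),
                        ncol = 9)
    x <- rbind(benign, malignant)
    x <- pmin(pmax(round(x), 1), 10)
    miss_rows <- if (n_missing > 0) sample(n_total, n_missing) else integer()
    list(x = x, miss_rows = miss_rows)
  })
  x <- feats$x
  colnames(x) <- wbcd_feature_names
  x[feats$miss_rows, "bare_nuclei"] <- NA
  out <- dplyr::bind_cols(
    tibble::tibble(id = as.character(1000000 + seq_len(n_total))),
    tibble::as_tibble(x),
    tibble::tibble(class = rep(c("benign", "malignant"), times = class_sizes))
  )
  attr(out, "class_levels") <- c("benign", "malignant")
  out
}
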