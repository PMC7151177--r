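wbcd_feature_names <- c(
  "clump_thickness", "cell_size_uniformity", "cell_shape_uniformity",
  "marginal_adhesion", "epithelial_cell_size", "bare_nuclei",
  "bland_chromatin", "normal_nucleoli", "mitoses"
)

#' Declare a missing-value policy
#'
#' @param mode One of `"impute_global_mean"` (fill each missing cell with the
#'   column mean of the observed values — during evaluation the mean is
#'   computed on the training portion only), `"drop_record"` (discard any
#'   record with a missing feature) or `"impute_constant"`.
#' @param value Constant used when `mode = "impute_constant"`.
#' @return A `"missing_policy"` object.
#' @export
missing_policy <- function(mode = c("impute_global_mean", "drop_record",
                                    "impute_constant"),
                           value = NULL) {
  mode <- match.arg(mode)
  if (mode == "impute_constant") {
    if (is.null(value) || !is.numeric(value) || length(value) != 1 ||
        is.na(value)) {
      abort_usage("impute_constant requires a single numeric `value`")
    }
  } else if (!is.null(value)) {
    abort_usage(sprintf("`value` is only meaningful for impute_constant, not %s",
                        mode))
  }
  structure(list(mode = mode, value = value), class = "missing_policy")
}

#' Apply a missing-value policy to the feature columns of a dataset
#'
#' @param data Labeled data frame.
#' @param policy A [missing_policy()].
#' @param feature_cols Feature columns; defaults to all numeric non-label,
#'   non-id columns.
#' @param class_col Label column name.
#' @param stats Optional named vector of per-column imputation means to use
#'   instead of means computed from `data` itself (pass training-portion
#'   means to avoid test-set leakage).
#' @param feature_range Optional length-2 numeric range; an imputation
#'   constant outside it is a domain error.
#' @return The data frame with the policy applied; records dropped under
#'   `drop_record` are removed.
#' @export
apply_missing_policy <- function(data, policy, feature_cols = NULL,
                                 class_col = "class", stats = NULL,
                                 feature_range = NULL) {
  stopifnot(inherits(policy, "missing_policy"))
  if (is.null(feature_cols)) {
    candidates <- setdiff(names(data), c(class_col, "id"))
    feature_cols <- candidates[vapply(data[candidates], is.numeric, logical(1))]
  }
  miss <- is.na(as.matrix(data[feature_cols]))
  if (!any(miss)) return(data)

  if (policy$mode == "drop_record") {
    return(data[!apply(miss, 1, any), , drop = FALSE])
  }
  if (policy$mode == "impute_constant") {
    if (!is.null(feature_range) &&
        (policy$value < feature_range[1] || policy$value > feature_range[2])) {
      abort_domain(sprintf(
        "imputation constant %s outside the declared feature range [%s, %s]",
        policy$value, feature_range[1], feature_range[2]))
    }
    fill <- setNames(rep(policy$value, length(feature_cols)), feature_cols)
  } else {
    fill <- stats %||%
      vapply(data[feature_cols], function(v) mean(v, na.rm = TRUE), numeric(1))
  }
  for (col in feature_cols) {
    nas <- is.na(data[[col]])
    if (any(nas)) {
      if (is.na(fill[[col]])) {
        abort_domain(sprintf(
          "column '%s' has no observed values to impute from", col))
      }
      data[[col]][nas] <- fill[[col]]
    }
  }
  data
}

#' Read a Wisconsin Breast Cancer (Original) file
#'
#' Parses the comma-separated, headerless dialect with 11 fields per row:
#' sample id, 9 integer cytological features valued 1–10, and a class code
#' (2 = benign, 4 = malignant).  `"?"` marks a missing value.  Benign maps
#' to class 1 and malignant to class 2.  Feature values outside 1–10 raise
#' a warning, not an error (historical revisions of the file moved 0s to 1s).
#'
#' @param path Path to the file.
#' @param policy A [missing_policy()]; the default imputes column means.
#' @return A tibble with columns `id`, the 9 named features and `class`
#'   (`"benign"`/`"malignant"`), with attributes `class_levels` and
#'   `load_summary` (records read, records retained, missing cells).
#'   Retrieve the summary with [load_summary()].
#' @export
read_wbcd <- function(path, policy = missing_policy("impute_global_mean")) {
  if (!file.exists(path)) abort_usage(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  rows <- vector("list", sum(keep))
  ln_of <- which(keep)
  for (i in seq_along(ln_of)) {
    ln <- ln_of[i]
    fields <- strsplit(lines[ln], ",", fixed = TRUE)[[1]]
    if (length(fields) != 11) {
      abort_parse(sprintf("expected 11 comma-separated fields, found %d",
                          length(fields)), line = ln)
    }
    feats <- fields[2:10]
    vals <- suppressWarnings(as.numeric(feats))
    bad <- is.na(vals) & feats != "?"
    if (any(bad)) {
      abort_parse(sprintf("non-numeric feature value '%s'",
                          feats[which(bad)[1]]), line = ln)
    }
    cls <- fields[11]
    if (!cls %in% c("2", "4")) {
      abort_parse(sprintf("unknown class code '%s' (expected 2 or 4)", cls),
                  line = ln)
    }
    rows[[i]] <- list(id = fields[1], vals = vals, cls = cls)
  }
  if (length(rows) == 0) abort_parse(sprintf("empty file: %s", path))

  feats <- do.call(rbind, lapply(rows, `[[`, "vals"))
  colnames(feats) <- wbcd_feature_names
  out_of_range <- sum(feats < 1 | feats > 10, na.rm = TRUE)
  if (out_of_range > 0) {
    warn(sprintf("%d feature value(s) outside the declared 1-10 range",
                 out_of_range))
  }
  data <- dplyr::bind_cols(
    tibble::tibble(id = vapply(rows, `[[`, character(1), "id")),
    tibble::as_tibble(feats),
    tibble::tibble(class = ifelse(
      vapply(rows, `[[`, character(1), "cls") == "2", "benign", "malignant"))
  )
  n_read <- nrow(data)
  n_missing <- sum(is.na(feats))
  data <- apply_missing_policy(data, policy,
                               feature_cols = wbcd_feature_names,
                               feature_range = c(1, 10))
  attr(data, "class_levels") <- c("benign", "malignant")
  attr(data, "load_summary") <- list(
    records_read = n_read,
    records_retained = nrow(data),
    missing_cells = n_missing,
    policy = policy$mode
  )
  data
}

#' Write a dataset in the Wisconsin Breast Cancer file dialect
#'
#' Inverse of [read_wbcd()]: 11 comma-separated fields per row, no header,
#' class benign written as 2 and malignant as 4, missing cells as `"?"`.
#'
#' @param data Tibble in the layout produced by [read_wbcd()] or
#'   [wbcd_like_fixture()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wbcd <- function(data, path) {
  missing_cols <- setdiff(c("id", wbcd_feature_names, "class"), names(data))
  if (length(missing_cols) > 0) {
    abort_usage(sprintf("data lacks WBCD column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  }
  feats <- as.matrix(data[wbcd_feature_names])
  txt <- apply(feats, 1, function(v) {
    s <- ifelse(is.na(v), "?", format(v, trim = TRUE, scientific = FALSE))
    paste(s, collapse = ",")
  })
  code <- ifelse(data$class == "benign", "2", "4")
  writeLines(paste(data$id, txt, code, sep = ","), path)
  invisible(path)
}

#' Read a generic labeled CSV
#'
#' Expects a header row, one label column and numeric feature columns.
#' Classes are indexed 1..m in order of first appearance; the mapping is
#' recorded in the `class_levels` attribute.
#'
#' @param path Path to a CSV file (RFC-4180-style quoting).
#' @param label_column Name of the label column.
#' @param policy A [missing_policy()].
#' @return A tibble of features plus the label column (renamed `class`),
#'   with `class_levels` and `load_summary` attributes.
#' @export
read_labeled_csv <- function(path, label_column = "class",
                             policy = missing_policy("impute_global_mean")) {
  if (!file.exists(path)) abort_usage(sprintf("file not found: %s", path))
  data <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort_parse(sprintf("cannot parse '%s': %s", path,
                                            conditionMessage(e))))
  if (nrow(data) == 0) abort_parse(sprintf("empty file: %s", path))
  if (!label_column %in% names(data)) {
    abort_usage(sprintf("label column '%s' not present in '%s'",
                        label_column, path))
  }
  feature_cols <- setdiff(names(data), c(label_column, "id"))
  non_numeric <- feature_cols[!vapply(data[feature_cols], is.numeric,
                                      logical(1))]
  if (length(non_numeric) > 0) {
    abort_parse(sprintf("non-numeric feature column(s): %s",
                        paste(non_numeric, collapse = ", ")))
  }
  labels <- as.character(data[[label_column]])
  data[[label_column]] <- labels
  names(data)[names(data) == label_column] <- "class"
  if ("id" %in% names(data)) data$id <- as.character(data$id)

  n_read <- nrow(data)
  n_missing <- sum(is.na(as.matrix(data[feature_cols])))
  data <- apply_missing_policy(data, policy, feature_cols = feature_cols)
  attr(data, "class_levels") <- unique(labels)
  attr(data, "load_summary") <- list(
    records_read = n_read,
    records_retained = nrow(data),
    missing_cells = n_missing,
    policy = policy$mode
  )
  data
}

#' Load summary of a dataset read by this package
#'
#' @param data A tibble returned by [read_wbcd()] or [read_labeled_csv()].
#' @return A one-row tibble: records read, records retained after the
#'   missing-value policy, missing cells encountered, and the policy mode.
#' @export
load_summary <- function(data) {
  s <- attr(data, "load_summary")
  if (is.null(s)) abort_usage("`data` carries no load summary")
  tibble::as_tibble(s)
}

#' Convert a labeled data frame to a fundamental set
#'
#' The fundamental set is the training collection the APC learns from:
#' a p-by-n pattern matrix plus 1-based class indices.  Residual missing
#' values are a domain error — apply a [missing_policy()] first.
#'
#' @param data Labeled data frame.
#' @param class_col Label column name.
#' @param feature_cols Optional feature column names.
#' @return A `"fundamental_set"` list with elements `x` (p-by-n matrix),
#'   `class_index`, `class_levels`, `id`, `n`, `m`, `p`.
#' @export
as_fundamental_set <- function(data, class_col = "class",
                               feature_cols = NULL) {
  parts <- dataset_parts(data, class_col, feature_cols)
  if (nrow(parts$x) == 0) abort_domain("the dataset is empty")
  if (anyNA(parts$x)) {
    abort_domain("residual missing values; apply a missing-value policy first")
  }
  structure(
    list(x = parts$x, class_index = parts$class_index,
         class_levels = parts$class_levels, id = parts$id,
         n = ncol(parts$x), m = length(parts$class_levels),
         p = nrow(parts$x)),
    class = "fundamental_set"
  )
}

#' Write predictions to CSV
#'
#' @param path Output path.
#' @param ids Character vector of record ids.
#' @param predictions Either the tibble returned by [predict.apc()] or a
#'   character vector of predicted class names with `NA` for unclassified.
#' @return `path`, invisibly.  The file has columns `id`,
#'   `predicted_class_name` (empty when unclassified) and `decision_kind`
#'   (`classified`/`unclassified`), in input order.
#' @export
write_predictions <- function(path, ids, predictions) {
  pred_class <- if (is.data.frame(predictions)) {
    predictions$.pred_class
  } else {
    as.character(predictions)
  }
  if (length(ids) != length(pred_class)) {
    abort_usage("`ids` and `predictions` must have equal length")
  }
  out <- tibble::tibble(
    id = as.character(ids),
    predicted_class_name = ifelse(is.na(pred_class), "", pred_class),
    decision_kind = ifelse(is.na(pred_class), "unclassified", "classified")
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
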