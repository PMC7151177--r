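#' @importFrom rlang abort warn %||%
#' @importFrom stats rnorm setNames
NULL

# Error classes: "apclass_domain_error" for bad data/parameters,
# "apclass_usage_error" for bad calls (CLI maps them to exit codes 1 / 2),
# "apclass_parse_error" (subclass of domain) for file dialect violations.
abort_domain <- function(msg, class = character()) {
  abort(msg, class = c(class, "apclass_domain_error"))
}

abort_usage <- function(msg) {
  abort(msg, class = "apclass_usage_error")
}

abort_parse <- function(msg, line = NULL) {
  if (!is.null(line)) msg <- sprintf("line %d: %s", line, msg)
  abort(msg, class = c("apclass_parse_error", "apclass_domain_error"))
}

# round() in R rounds half to even; stratified splits need round-half-up so
# that e.g. half of 241 gives 121 training patterns.
round_half_up <- function(x) floor(x + 0.5)

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream.
with_seed_local <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Resolve the feature / label structure of a labeled data frame.
# Feature columns default to every numeric column except the label and an
# optional "id" column.  Class levels come from (in order of precedence) the
# "class_levels" attribute, factor levels, or first appearance.
dataset_parts <- function(data, class_col = "class", feature_cols = NULL) {
  if (!is.data.frame(data)) {
    abort_domain("`data` must be a data frame of labeled patterns")
  }
  if (!class_col %in% names(data)) {
    abort_usage(sprintf("label column '%s' not found in `data`", class_col))
  }
  if (is.null(feature_cols)) {
    candidates <- setdiff(names(data), c(class_col, "id"))
    feature_cols <- candidates[vapply(data[candidates], is.numeric, logical(1))]
  } else {
    missing_cols <- setdiff(feature_cols, names(data))
    if (length(missing_cols) > 0) {
      abort_usage(sprintf("feature column(s) not found: %s",
                          paste(missing_cols, collapse = ", ")))
    }
  }
  if (length(feature_cols) == 0) {
    abort_domain("no numeric feature columns found in `data`")
  }
  x <- as.matrix(data[feature_cols])
  storage.mode(x) <- "double"

  labels <- data[[class_col]]
  levels_attr <- attr(data, "class_levels")
  if (!is.null(levels_attr) && all(as.character(labels) %in% levels_attr)) {
    class_levels <- levels_attr
  } else if (is.factor(labels)) {
    class_levels <- levels(labels)
  } else {
    class_levels <- unique(as.character(labels))
  }
  class_index <- match(as.character(labels), class_levels)

  list(
    x = x,
    feature_cols = feature_cols,
    class_index = class_index,
    class_levels = class_levels,
    id = if ("id" %in% names(data)) as.character(data$id) else
      as.character(seq_len(nrow(data)))
  )
}
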