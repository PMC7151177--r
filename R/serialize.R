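#' Write an APC model to a plain-text file
#'
#' Serializes the model as a versioned JSON document holding `n`, `m`, `p`,
#' the class levels, feature names, mean vector, association matrix and tie
#' policy.  Numbers are written with 17 significant digits so that
#' `read_apc(write_apc(m))` round-trips doubles bit-faithfully.
#'
#' @param object A fitted `"apc"` model.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_apc()]
#' @export
write_apc <- function(object, path) {
  stopifnot(inherits(object, "apc"))
  doc <- list(
    format = "apclass-model",
    version = 1L,
    n = object$n, m = object$m, p = object$p,
    class_levels = object$class_levels,
    class_counts = unname(object$class_counts),
    feature_names = object$feature_names,
    mean = unname(object$mean),
    matrix = apply(object$M, 1, identity, simplify = FALSE),
    tie_policy = object$tie_policy
  )
  json <- jsonlite::toJSON(doc, digits = I(17), auto_unbox = TRUE,
                           pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read an APC model written by [write_apc()]
#'
#' @param path Path to a serialized model file.
#' @return A fitted `"apc"` model.
#' @export
read_apc <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e) {
                    abort_parse(sprintf("cannot parse model file '%s': %s",
                                        path, conditionMessage(e)))
                  })
  if (!identical(doc$format, "apclass-model")) {
    abort_parse(sprintf("'%s' is not an apclass model file", path))
  }
  if (!identical(as.integer(doc$version), 1L)) {
    abort_parse(sprintf("unsupported model file version %s", doc$version))
  }
  M <- matrix(unlist(doc$matrix), nrow = doc$m, byrow = TRUE,
              dimnames = list(doc$class_levels, doc$feature_names))
  structure(
    list(
      mean = setNames(as.numeric(doc$mean), doc$feature_names),
      M = M,
      n = as.integer(doc$n), m = as.integer(doc$m), p = as.integer(doc$p),
      class_levels = as.character(doc$class_levels),
      class_counts = setNames(as.integer(doc$class_counts),
                              doc$class_levels),
      feature_names = as.character(doc$feature_names),
      tie_policy = doc$tie_policy
    ),
    class = "apc"
  )
}
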