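# Random labeled dataset with every class present at least once.
random_labeled_data <- function(n = 3, p = 10, m = 2, seed = 1,
                                balanced = FALSE) {
  withr::with_seed(seed, {
    x <- matrix(runif(p * n, -5, 5), nrow = p)
    cls <- if (balanced) {
      stopifnot(p %% m == 0)
      sample(rep(seq_len(m), each = p / m))
    } else {
      c(seq_len(m), sample(seq_len(m), p - m, replace = TRUE))
    }
    d <- tibble::as_tibble(x, .name_repair = ~ paste0("f", seq_len(n)))
    d$class <- paste0("c", cls)
    attr(d, "class_levels") <- paste0("c", seq_len(m))
    d
  })
}

# Independent score oracle: z_j = sum over training patterns k of class j of
# the dot product <x_k - mean, query - mean>.  Plain loops, no reuse of the
# package's matrix path.
oracle_scores <- function(x, class_index, m, query) {
  ctr <- colMeans(x)
  qt <- as.numeric(query) - ctr
  z <- numeric(m)
  for (k in seq_len(nrow(x))) {
    z[class_index[k]] <- z[class_index[k]] + sum((x[k, ] - ctr) * qt)
  }
  z
}

features_of <- function(d) as.matrix(d[grep("^f", names(d), value = TRUE)])

# Minimal WBCD-dialect fixture: 5 rows, one "?" in the bare-nuclei field.
wbcd_five_rows <- function(path) {
  writeLines(c(
    "1000025,5,1,1,1,2,1,3,1,1,2",
    "1002945,5,4,4,5,7,10,3,2,1,2",
    "1015425,3,1,1,1,2,2,3,1,1,2",
    "1016277,6,8,8,1,3,?,3,7,1,2",
    "1017023,8,10,10,8,7,10,9,7,1,4"
  ), path)
  path
}

# A degenerate resubstitution plan (train = test = everything).
resubstitution_plan <- function(p) {
  structure(
    list(kind = "holdout", fraction = NA_real_, repetitions = 1L,
         base_seed = 0L, n_records = p,
         units = list(list(train = seq_len(p), test = seq_len(p),
                           repetition = 1L, fold = NA_integer_))),
    class = "apc_split_plan"
  )
}
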