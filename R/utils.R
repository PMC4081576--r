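# Internal helpers shared across modules.

# Derive a child seed from a base seed and a stream label, staying well
# inside 32-bit integer range.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

# Assert that `x` is a descriptor table: a tibble whose first column is
# compound_id and whose remaining columns are numeric.
check_descriptor_tbl <- function(x, arg = "descriptors") {
  if (!is.data.frame(x) || !"compound_id" %in% names(x)) {
    abort(sprintf("`%s` must be a data frame with a `compound_id` column.", arg))
  }
  feat <- setdiff(names(x), "compound_id")
  bad <- feat[!vapply(x[feat], is.numeric, logical(1))]
  if (length(bad) > 0) {
    abort(sprintf("`%s` has non-numeric descriptor columns: %s",
                  arg, paste(head(bad, 5), collapse = ", ")))
  }
  invisible(x)
}

feature_names <- function(x) setdiff(names(x), "compound_id")

feature_matrix <- function(x) {
  m <- as.matrix(x[feature_names(x)])
  rownames(m) <- x$compound_id
  storage.mode(m) <- "double"
  m
}

# k-fold assignment, balanced fold sizes, reproducible under seed.
make_folds <- function(n, k, seed) {
  if (k < 2) abort("`cv_folds` must be at least 2.")
  if (k > n) abort("`cv_folds` cannot exceed the number of compounds.")
  withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
}
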