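# Shared fixtures. Descriptor computation goes through OpenBabel and is
# the slow step, so small generated datasets are cached per session.

fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = fixture_env, inherits = FALSE)) {
    assign(key, force(expr), envir = fixture_env)
  }
  get(key, envir = fixture_env, inherits = FALSE)
}

# A small wild-type quinazoline set plus its descriptors.
small_wild <- function() {
  cached("small_wild", {
    d <- generate_dataset(synth_config(n = 24, seed = 101))
    d$descriptors <- compute_descriptors(d$compounds)
    d
  })
}

# A random continuous descriptor tibble with no chemistry involved.
toy_descriptors <- function(n, p, seed = 1, prefix = "f") {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n * p), n, p)
    colnames(m) <- sprintf("%s%02d", prefix, seq_len(p))
    dplyr::bind_cols(
      tibble::tibble(compound_id = sprintf("c%03d", seq_len(n))),
      tibble::as_tibble(m))
  })
}

# Docking-energy tibble of independent Gaussian terms.
toy_energies <- function(n, seed = 1) {
  withr::with_seed(seed, {
    out <- tibble::tibble(compound_id = sprintf("c%03d", seq_len(n)))
    for (term in docking_energy_terms()) out[[term]] <- rnorm(n)
    out
  })
}

# Independent CFS merit oracle: enumerate every non-empty subset with
# utils::combn and score it straight from the definition.
cfs_oracle_best_merit <- function(x, y, max_subset = ncol(x)) {
  p <- ncol(x)
  acf <- abs(vapply(seq_len(p), function(i) stats::cor(x[, i], y),
                    numeric(1)))
  aff <- abs(stats::cor(x))
  best <- -Inf
  for (k in seq_len(min(p, max_subset))) {
    subsets <- utils::combn(p, k)
    for (j in seq_len(ncol(subsets))) {
      idx <- subsets[, j]
      rcf <- mean(acf[idx])
      rff <- if (k == 1) 0 else
        mean(aff[idx, idx][upper.tri(diag(k))])
      merit <- k * rcf / sqrt(k + k * (k - 1) * rff)
      if (merit > best) best <- merit
    }
  }
  best
}
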