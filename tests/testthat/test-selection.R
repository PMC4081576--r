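test_that("degenerate columns are removed and reported", {
  desc <- toy_descriptors(20, 4)
  desc$f05 <- 0
  desc$f06 <- 3.7
  out <- drop_degenerate(desc)
  expect_setequal(setdiff(names(out), "compound_id"),
                  c("f01", "f02", "f03", "f04"))
  rep <- selection_report(out)
  expect_equal(rep$reason[rep$column == "f05"], "all values zero")
  expect_equal(rep$reason[rep$column == "f06"], "zero variance")

  clean <- toy_descriptors(20, 4, seed = 2)
  expect_equal(drop_degenerate(clean), clean, ignore_attr = TRUE)

  allbad <- tibble::tibble(compound_id = c("a", "b"), x = 0, y = 1)
  expect_error(drop_degenerate(allbad), "no informative descriptors")
})

test_that("correlation pruning keeps the activity-relevant copy of a pair", {
  y <- withr::with_seed(1, rnorm(40))
  desc <- toy_descriptors(40, 3, seed = 2)
  desc$f01 <- y + withr::with_seed(3, rnorm(40, 0, 0.2))  # informative
  desc$dup <- desc$f01 + withr::with_seed(4, rnorm(40, 0, 1e-6))
  # make `dup` marginally less correlated with activity than f01
  desc$dup <- desc$dup + 0.05 * withr::with_seed(5, rnorm(40))
  out <- prune_correlated(desc, y, cutoff = 0.9)
  expect_true("f01" %in% names(out))
  expect_false("dup" %in% names(out))

  ortho <- toy_descriptors(40, 5, seed = 6)
  expect_equal(ncol(prune_correlated(ortho, y, 0.9)), 6)
})

test_that("pruned matrices never retain a pair above the cutoff", {
  for (i in 1:25) {
    dat <- withr::with_seed(200 + i, {
      n <- sample(20:60, 1)
      p <- sample(6:14, 1)
      desc <- toy_descriptors(n, p, seed = 300 + i)
      # plant a few near-duplicate columns
      for (j in seq_len(sample(1:3, 1))) {
        src <- sample(p, 1)
        desc[[sprintf("dup%02d", j)]] <-
          desc[[src + 1]] + rnorm(n, 0, 0.05)
      }
      list(desc = desc, y = rnorm(n))
    })
    out <- prune_correlated(dat$desc, dat$y, cutoff = 0.9)
    m <- as.matrix(out[-1])
    cm <- abs(stats::cor(m)); diag(cm) <- 0
    expect_lte(max(cm), 0.9)
    # every removed column violated the cutoff against some original column
    removed <- setdiff(names(dat$desc), names(out))
    for (rc in removed) {
      r_all <- abs(stats::cor(dat$desc[[rc]],
                              as.matrix(dat$desc[setdiff(names(dat$desc),
                                                         c("compound_id", rc))])))
      expect_gt(max(r_all), 0.9)
    }
  }
})

test_that("CFS merit has its closed forms for singletons and duplicated pairs", {
  y <- withr::with_seed(9, rnorm(30))
  f <- y + withr::with_seed(10, rnorm(30, 0, 0.5))
  one <- tibble::tibble(compound_id = as.character(1:30), f01 = f)
  sel1 <- cfs_select(one, y)
  expect_equal(attr(sel1, "merit"), abs(stats::cor(f, y)), tolerance = 1e-12)

  # duplicating an informative feature cannot beat the singleton: with
  # rff = 1 the pair merit 2r/sqrt(2 + 2) collapses to r itself, and the
  # tie resolves to the smaller subset
  two <- tibble::tibble(compound_id = as.character(1:30), f01 = f, f02 = f)
  r <- abs(stats::cor(f, y))
  merit_pair <- 2 * r / sqrt(2 + 2 * 1)
  expect_equal(merit_pair, r, tolerance = 1e-12)
  sel2 <- cfs_select(two, y)
  expect_equal(ncol(sel2), 2)  # picks the singleton
  expect_equal(attr(sel2, "merit"), r, tolerance = 1e-12)
})

test_that("CFS equals exhaustive enumeration on random 8-feature instances", {
  for (i in 1:10) {
    dat <- withr::with_seed(400 + i, {
      n <- 30
      x <- matrix(rnorm(n * 8), n, 8)
      y <- x[, 1] - 0.7 * x[, 2] + rnorm(n, 0, 0.8)
      list(x = x, y = y)
    })
    desc <- dplyr::bind_cols(
      tibble::tibble(compound_id = as.character(1:30)),
      tibble::as_tibble(dat$x, .name_repair = ~ sprintf("f%02d", 1:8)))
    sel <- cfs_select(desc, dat$y)
    expect_equal(attr(sel, "merit"),
                 cfs_oracle_best_merit(dat$x, dat$y), tolerance = 1e-10)
  }
})

test_that("backward elimination removes a pure-noise descriptor and keeps signal", {
  dat <- withr::with_seed(11, {
    n <- 60
    x <- matrix(rnorm(n * 6), n, 6)
    y <- x[, 1] + 0.9 * x[, 2] + 0.8 * x[, 3] + 0.7 * x[, 4] +
      0.6 * x[, 5] + rnorm(n, 0, 0.2)   # column 6 is pure noise
    list(x = x, y = y)
  })
  desc <- dplyr::bind_cols(
    tibble::tibble(compound_id = as.character(1:60)),
    tibble::as_tibble(dat$x, .name_repair = ~ c(sprintf("inf%d", 1:5), "noise")))
  cfg <- svr_config(kernel = "linear", seed = 2)
  out <- f_stepping(desc, dat$y, cfg)
  kept <- setdiff(names(out), "compound_id")
  expect_false("noise" %in% kept)
  expect_true(all(sprintf("inf%d", 1:5) %in% kept))

  traj <- attr(out, "trajectory")
  expect_true(all(diff(traj) >= 0))

  out2 <- f_stepping(desc, dat$y, cfg)
  expect_identical(out[names(out)], out2[names(out2)])
  expect_identical(attr(out, "trajectory"), attr(out2, "trajectory"))
})

test_that("the n/4 budget caps feature counts by activity correlation", {
  y <- withr::with_seed(12, rnorm(128))
  wide <- toy_descriptors(128, 40, seed = 13)
  out <- enforce_budget(wide, y, n_compounds = 128)
  expect_lte(ncol(out) - 1, 32)

  slim <- toy_descriptors(128, 10, seed = 14)
  expect_equal(enforce_budget(slim, y, n_compounds = 128), slim,
               ignore_attr = TRUE)

  y16 <- y[1:16]
  five <- toy_descriptors(16, 5, seed = 15)
  out2 <- enforce_budget(five, y16, n_compounds = 16)
  expect_equal(ncol(out2) - 1, 4)
  # the dropped feature is the one least correlated with activity
  r <- abs(stats::cor(as.matrix(five[-1]), y16))[, 1]
  expect_false(names(which.min(r)) %in% names(out2))
})

test_that("the selection pipeline is a pure function of its inputs", {
  d <- small_wild()
  y <- d$compounds$pic50
  cfg <- svr_config(seed = 5)
  a <- select_features(d$descriptors, y, config = cfg)
  b <- select_features(d$descriptors, y, config = cfg)
  expect_identical(a[names(a)], b[names(b)])
  expect_identical(selection_report(a), selection_report(b))
  # stages partition the input columns
  rep <- selection_report(a)
  expect_setequal(c(rep$column, setdiff(names(a), "compound_id")),
                  setdiff(names(d$descriptors), "compound_id"))
  expect_false(any(duplicated(rep$column)))
})
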