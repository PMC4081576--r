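linear_toy <- function(n = 50, seed = 1, noise = 0) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * 3), n, 3)
    y <- 2 * x[, 1] - x[, 2] + noise * rnorm(n)
    desc <- dplyr::bind_cols(
      tibble::tibble(compound_id = sprintf("c%03d", 1:n)),
      tibble::as_tibble(x, .name_repair = ~ c("fa", "fb", "fc")))
    list(desc = desc, y = y)
  })
}

test_that("a realizable linear relation is fitted nearly perfectly", {
  d <- linear_toy()
  cfg <- svr_config(kernel = "linear", epsilon = 0.001, C = 100)
  m <- train_svr(d$desc, d$y, cfg)
  expect_gte(m$training_R, 0.999)
  expect_lt(max(abs(predict(m, d$desc) - d$y)), 0.01)
})

test_that("pure-noise activity yields near-zero cross-validated correlation", {
  dat <- withr::with_seed(2, {
    x <- matrix(rnorm(100 * 5), 100, 5)
    list(x = x, y = rnorm(100))
  })
  desc <- dplyr::bind_cols(
    tibble::tibble(compound_id = sprintf("c%03d", 1:100)),
    tibble::as_tibble(dat$x, .name_repair = ~ sprintf("f%d", 1:5)))
  ev <- cross_validate(desc, dat$y, svr_config(seed = 3))
  expect_lt(abs(ev$R), 0.3)
})

test_that("training is deterministic for fixed data and configuration", {
  d <- linear_toy(seed = 4)
  cfg <- svr_config(seed = 9)
  m1 <- train_svr(d$desc, d$y, cfg)
  m2 <- train_svr(d$desc, d$y, cfg)
  expect_identical(m1$fit$coefs, m2$fit$coefs)
  expect_identical(m1$fit$rho, m2$fit$rho)
})

test_that("the explicit decision function reproduces the reference SVR engine", {
  for (kern in c("linear", "rbf", "polynomial")) {
    d <- linear_toy(seed = 5, noise = 0.3)
    cfg <- svr_config(kernel = kern, seed = 1)
    m <- train_svr(d$desc, d$y, cfg)
    ref <- e1071::svm(
      x = scale(as.matrix(d$desc[-1])), y = d$y, type = "eps-regression",
      kernel = switch(kern, rbf = "radial", kern),
      cost = cfg$C, epsilon = cfg$epsilon, gamma = 1 / 3,
      degree = cfg$degree, coef0 = cfg$coef0, scale = FALSE)
    expect_equal(unname(predict(m, d$desc)),
                 unname(predict(ref, scale(as.matrix(d$desc[-1])))),
                 tolerance = 1e-9)
  }
})

test_that("prediction aligns columns by name and flags missing features", {
  d <- linear_toy(seed = 6)
  m <- train_svr(d$desc, d$y, svr_config())
  shuffled <- d$desc[c("compound_id", "fc", "fa", "fb")]
  expect_equal(predict(m, shuffled), predict(m, d$desc))
  expect_error(predict(m, d$desc[c("compound_id", "fa", "fb")]),
               "missing feature fc")
})

test_that("zero-variance features are rejected at training time", {
  d <- linear_toy(seed = 7)
  d$desc$fc <- 1
  expect_error(train_svr(d$desc, d$y, svr_config()), "fc")
})

test_that("cross-validation recovers a learnable relation and respects the seed", {
  d <- linear_toy(seed = 8, noise = 0.05)
  cfg <- svr_config(kernel = "linear", epsilon = 0.01, seed = 11)
  ev1 <- cross_validate(d$desc, d$y, cfg)
  expect_gte(ev1$R, 0.99)
  ev2 <- cross_validate(d$desc, d$y, cfg)
  expect_identical(ev1, ev2)
  shuf <- withr::with_seed(12, sample(d$y))
  expect_lt(abs(cross_validate(d$desc, shuf, cfg)$R), 0.35)
})

test_that("saved models reload and predict identically", {
  d <- linear_toy(seed = 13, noise = 0.2)
  m <- train_svr(d$desc, d$y, svr_config(seed = 2), scope = "wild")
  path <- withr::local_tempfile(fileext = ".json")
  write_qsar_model(m, path)
  m2 <- read_qsar_model(path)
  expect_equal(predict(m2, d$desc), predict(m, d$desc), tolerance = 1e-9)
  expect_equal(m2$feature_names, m$feature_names)
  expect_equal(m2$scope, "wild")
})

test_that("an independent SVR implementation agrees on a smooth problem", {
  skip_if_not_installed("kernlab")
  d <- linear_toy(seed = 14, noise = 0.1)
  cfg <- svr_config(kernel = "rbf", seed = 1)
  m <- train_svr(d$desc, d$y, cfg)
  k <- kernlab::ksvm(scale(as.matrix(d$desc[-1])), d$y, type = "eps-svr",
                     kernel = "rbfdot",
                     kpar = list(sigma = 1 / 3), C = cfg$C,
                     epsilon = cfg$epsilon, scaled = FALSE)
  expect_gt(stats::cor(predict(m, d$desc),
                       kernlab::predict(k, scale(as.matrix(d$desc[-1])))),
            0.99)
})

test_that("hyperparameter tuning picks the best grid point by CV correlation", {
  d <- linear_toy(n = 60, seed = 21, noise = 0.3)
  cfg <- svr_config(kernel = "rbf", seed = 5)
  best <- tune_svr(d$desc, d$y, cfg, C_grid = c(0.01, 10),
                   gamma_grid = c(NA, 0.1))
  grid <- attr(best, "grid")
  expect_equal(nrow(grid), 4)
  expect_equal(max(grid$cv_R),
               grid$cv_R[grid$C == best$C &
                           (is.na(grid$gamma) == is.null(best$gamma))][1])
  # the tightly regularised corner cannot win on a strong linear signal
  expect_gt(best$C, 0.01)
})

test_that("tidy and glance summarise fitted models", {
  d <- linear_toy(seed = 22)
  m <- train_svr(d$desc, d$y, svr_config(kernel = "linear"), scope = "wild")
  td <- tidy(m)
  expect_equal(td$feature, c("fa", "fb", "fc"))
  expect_true("weight" %in% names(td))
  # linear SVR weights recover the generating coefficients approximately
  expect_equal(unname(td$weight[1] / td$weight[2]), -2, tolerance = 0.2)
  g <- glance(m)
  expect_equal(g$kernel, "linear")
  expect_equal(g$scope, "wild")
  expect_equal(g$n_train, 50L)
})

test_that("run_protocol produces the whole/train/valid report triple", {
  d <- small_wild()
  res <- suppressWarnings(run_protocol(
    d$compounds, protocol = "wild", config = svr_config(seed = 3),
    descriptors = d$descriptors))
  expect_s3_class(res, "qsar_protocol")
  expect_equal(res$evaluation$dataset,
               c("wild_whole", "wild_train", "wild_valid"))
  expect_equal(res$evaluation$n,
               c(24L, sum(res$split$subset == "train"),
                 sum(res$split$subset == "valid")))
  expect_error(run_protocol(d$compounds, protocol = "mutant"),
               "No compounds labelled")
  g <- glance(res)
  expect_equal(g$valid_R, res$evaluation$R[3])
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("strongly informative docking energies enter the hybrid feature set", {
  d <- cached("energy_signal_set", {
    out <- generate_dataset(synth_config(n = 48, seed = 19,
                                         energy_signal = 0.8))
    out$descriptors <- compute_descriptors(out$compounds)
    out
  })
  cfg <- svr_config(seed = 4)
  plain <- suppressWarnings(run_protocol(
    d$compounds, protocol = "wild", config = cfg,
    descriptors = d$descriptors))
  hybrid <- suppressWarnings(run_protocol(
    d$compounds, energies = d$energies, protocol = "wild", config = cfg,
    descriptors = d$descriptors))
  expect_false(any(startsWith(plain$features, "dock_")))
  expect_true(any(startsWith(hybrid$features, "dock_")))
})
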