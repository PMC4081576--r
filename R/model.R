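# Epsilon-SVR training, prediction, cross-validation, persistence, and
# the wild/mutant/hybrid modelling protocols.

#' Configure the epsilon-SVR engine
#'
#' Defaults: RBF kernel, `C = 10`, `epsilon = 0.1` log units,
#' `gamma = 1/n_features` (resolved at fit time when `NULL`), 5-fold
#' cross-validation. All randomness (fold assignment) derives from
#' `seed`.
#'
#' @param kernel `"rbf"`, `"linear"` or `"polynomial"`.
#' @param C Cost parameter (> 0).
#' @param epsilon Epsilon-insensitive band width (> 0).
#' @param gamma RBF/polynomial kernel coefficient; `NULL` means
#'   `1/n_features`.
#' @param degree Polynomial degree.
#' @param coef0 Polynomial offset.
#' @param cv_folds Number of cross-validation folds (>= 2).
#' @param seed Integer seed.
#' @return An object of class `svr_config`.
#' @export
svr_config <- function(kernel = c("rbf", "linear", "polynomial"),
                       C = 10, epsilon = 0.1, gamma = NULL,
                       degree = 3, coef0 = 0, cv_folds = 5, seed = 1) {
  kernel <- match.arg(kernel)
  if (C <= 0 || epsilon <= 0) abort("`C` and `epsilon` must be positive.")
  if (!is.null(gamma) && gamma <= 0) abort("`gamma` must be positive.")
  if (cv_folds < 2) abort("`cv_folds` must be at least 2.")
  structure(
    list(kernel = kernel, C = C, epsilon = epsilon, gamma = gamma,
         degree = degree, coef0 = coef0, cv_folds = as.integer(cv_folds),
         seed = as.integer(seed)),
    class = "svr_config")
}

resolve_gamma <- function(config, p) config$gamma %||% (1 / p)

# Low-level fit on a plain numeric matrix: standardizes columns, fits
# libsvm eps-regression, and keeps only what the explicit decision
# function needs (SVs, coefficients, rho, scaling).
fit_raw_svr <- function(x, y, config) {
  p <- ncol(x)
  center <- colMeans(x)
  scale_ <- apply(x, 2, sd)
  scale_[scale_ == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale_, "/")
  gamma <- resolve_gamma(config, p)
  fit <- e1071::svm(
    x = xs, y = y, type = "eps-regression",
    kernel = switch(config$kernel, rbf = "radial", linear = "linear",
                    polynomial = "polynomial"),
    cost = config$C, epsilon = config$epsilon, gamma = gamma,
    degree = config$degree, coef0 = config$coef0, scale = FALSE)
  list(center = center, scale = scale_, gamma = gamma,
       kernel = config$kernel, degree = config$degree,
       coef0 = config$coef0,
       sv = unname(as.matrix(fit$SV)),
       coefs = as.numeric(fit$coefs), rho = as.numeric(fit$rho))
}

kernel_matrix <- function(fit, xs) {
  sv <- fit$sv
  switch(fit$kernel,
    linear = xs %*% t(sv),
    polynomial = (fit$gamma * (xs %*% t(sv)) + fit$coef0)^fit$degree,
    rbf = {
      d2 <- outer(rowSums(xs^2), rowSums(sv^2), "+") - 2 * xs %*% t(sv)
      exp(-fit$gamma * pmax(d2, 0))
    })
}

predict_raw_svr <- function(fit, x) {
  xs <- sweep(sweep(x, 2, fit$center), 2, fit$scale, "/")
  drop(kernel_matrix(fit, xs) %*% fit$coefs) - fit$rho
}

#' Train an epsilon-SVR QSAR model
#'
#' Features are standardized (centre/scale stored with the model), then
#' an epsilon-SVR is fitted. Training is deterministic for fixed input
#' and configuration. Prediction uses an explicit kernel decision
#' function over the stored support vectors, so a model saved with
#' [write_qsar_model()] and reloaded predicts identically.
#'
#' @param descriptors Descriptor tibble of the selected features.
#' @param activity Numeric activity (pIC50) vector aligned to rows.
#' @param config An [svr_config()].
#' @param scope Optional model scope label (`"wild"`, `"mutant"`,
#'   `"hybrid"`).
#' @return An object of class `qsar_model`.
#' @export
train_svr <- function(descriptors, activity, config = svr_config(),
                      scope = NA_character_) {
  check_descriptor_tbl(descriptors)
  if (nrow(descriptors) < 2) abort("Need at least 2 compounds to train.")
  if (length(activity) != nrow(descriptors)) abort("`activity` length mismatch.")
  if (anyNA(descriptors) || anyNA(activity)) abort("Missing values in input.")
  feats <- feature_names(descriptors)
  if (length(feats) == 0) abort("No feature columns.")
  m <- feature_matrix(descriptors)
  zv <- feats[apply(m, 2, sd) == 0]
  if (length(zv) > 0) {
    abort(sprintf("Zero-variance feature(s) at training: %s (selection should have removed them)",
                  paste(zv, collapse = ", ")))
  }
  fit <- fit_raw_svr(m, activity, config)
  train_pred <- predict_raw_svr(fit, m)
  structure(
    list(fit = fit, feature_names = feats, config = config, scope = scope,
         n_train = nrow(m),
         training_R = if (sd(train_pred) > 0) cor(activity, train_pred) else NA_real_),
    class = "qsar_model")
}

#' Predict activity with a fitted QSAR model
#'
#' Columns are aligned by name, so column order in `newdata` does not
#' matter; a missing feature is an error naming it.
#'
#' @param object A `qsar_model`.
#' @param newdata Descriptor tibble providing every model feature.
#' @param ... Unused.
#' @return Numeric vector of predicted pIC50, one per compound.
#' @export
predict.qsar_model <- function(object, newdata, ...) {
  check_descriptor_tbl(newdata, "newdata")
  missing_f <- setdiff(object$feature_names, names(newdata))
  if (length(missing_f) > 0) {
    abort(sprintf("missing feature %s", paste(missing_f, collapse = ", ")))
  }
  m <- as.matrix(newdata[object$feature_names])
  storage.mode(m) <- "double"
  preds <- predict_raw_svr(object$fit, m)
  setNames(preds, newdata$compound_id)
}

#' @export
print.qsar_model <- function(x, ...) {
  cat(sprintf("<qsar_model> %s kernel, %d features, n_train = %d, scope = %s\n",
              x$fit$kernel, length(x$feature_names), x$n_train, x$scope))
  invisible(x)
}

#' @export
tidy.qsar_model <- function(x, ...) {
  out <- tibble(
    feature = x$feature_names,
    center = unname(x$fit$center),
    scale = unname(x$fit$scale))
  if (x$fit$kernel == "linear") {
    out$weight <- unname(drop(t(x$fit$sv) %*% x$fit$coefs) / x$fit$scale)
  }
  out
}

#' @export
glance.qsar_model <- function(x, ...) {
  tibble(
    n_train = x$n_train,
    n_features = length(x$feature_names),
    n_support_vectors = nrow(x$fit$sv),
    kernel = x$fit$kernel,
    C = x$config$C,
    epsilon = x$config$epsilon,
    gamma = x$fit$gamma,
    scope = x$scope,
    training_R = x$training_R)
}

#' Grid-search SVR hyperparameters by cross-validated correlation
#'
#' Evaluates a small grid of cost and kernel-width values by k-fold
#' cross-validated Pearson R (folds fixed by the configuration seed, so
#' all candidates see identical partitions) and returns the winning
#' configuration.
#'
#' @inheritParams train_svr
#' @param C_grid,gamma_grid Candidate values; `NA` in `gamma_grid`
#'   means the `1/n_features` default.
#' @return The best [svr_config()], carrying the full grid as attribute
#'   `"grid"` (a tibble of C, gamma, cv_R).
#' @export
tune_svr <- function(descriptors, activity, config = svr_config(),
                     C_grid = c(1, 10, 100),
                     gamma_grid = c(NA, 0.01, 0.1)) {
  check_descriptor_tbl(descriptors)
  m <- feature_matrix(descriptors)
  folds <- make_folds(nrow(m), config$cv_folds,
                      derive_seed(config$seed, "tune"))
  grid <- tidyr::expand_grid(C = C_grid, gamma = gamma_grid)
  grid$cv_R <- purrr::pmap_dbl(grid, function(C, gamma) {
    cand <- config
    cand$C <- C
    cand$gamma <- if (is.na(gamma)) NULL else gamma
    cv_pearson(m, activity, folds, cand)
  })
  best <- grid[order(-grid$cv_R, grid$C), ][1, ]
  out <- config
  out$C <- best$C
  out$gamma <- if (is.na(best$gamma)) NULL else best$gamma
  attr(out, "grid") <- grid
  out
}

#' Cross-validate an SVR on a descriptor table
#'
#' k-fold partition under the configuration seed; out-of-fold
#' predictions are pooled and scored with the standard statistics.
#'
#' @inheritParams train_svr
#' @param label Dataset tag recorded in the report.
#' @return One-row evaluation tibble (see [evaluate_predictions()])
#'   carrying the per-compound fold assignment as attribute
#'   `"fold_assignment"`.
#' @export
cross_validate <- function(descriptors, activity, config = svr_config(),
                           label = "cv") {
  check_descriptor_tbl(descriptors)
  n <- nrow(descriptors)
  folds <- make_folds(n, config$cv_folds, derive_seed(config$seed, "cv"))
  if (min(table(folds)) < 2) abort("A fold has fewer than 2 compounds.")
  m <- feature_matrix(descriptors)
  preds <- rep(NA_real_, n)
  for (k in sort(unique(folds))) {
    hold <- folds == k
    fit <- fit_raw_svr(m[!hold, , drop = FALSE], activity[!hold], config)
    preds[hold] <- predict_raw_svr(fit, m[hold, , drop = FALSE])
  }
  out <- evaluate_predictions(activity, preds, label = label)
  attr(out, "fold_assignment") <- tibble(
    compound_id = descriptors$compound_id, fold = folds)
  attr(out, "predictions") <- tibble(
    compound_id = descriptors$compound_id, observed = activity,
    predicted = preds)
  out
}

#' Run a full modelling protocol (wild, mutant or hybrid)
#'
#' Executes the pipeline end-to-end on a labelled compound set:
#' descriptor generation, optional docking-energy fusion, an 80/20
#' train/validation split, three-stage feature selection on the
#' training split, and three evaluations mirroring the
#' whole/train/validation reporting convention: in-sample fit of a
#' model trained on the whole set, pooled k-fold CV on the training
#' split, and validation-split prediction by the training-split model.
#'
#' @param compounds Compound tibble with `target_class` labels.
#' @param energies Optional docking-energy tibble to fuse as features.
#' @param protocol `"wild"`, `"mutant"` (single-class) or `"hybrid"`
#'   (both classes pooled).
#' @param config An [svr_config()].
#' @param fraction_valid Validation fraction for the split.
#' @param cutoff Pairwise-correlation pruning threshold.
#' @param families Descriptor families to compute.
#' @param descriptors Optional precomputed descriptor tibble covering
#'   all compounds (skips descriptor generation).
#' @return An object of class `qsar_protocol`: a list with the
#'   training-split `model`, `evaluation` (three-row tibble), selected
#'   `features`, `selection` report, `split`, and bookkeeping.
#' @export
run_protocol <- function(compounds, energies = NULL,
                         protocol = c("wild", "mutant", "hybrid"),
                         config = svr_config(), fraction_valid = 0.2,
                         cutoff = 0.9,
                         families = descriptor_families(),
                         descriptors = NULL) {
  protocol <- match.arg(protocol)
  keep <- if (protocol == "hybrid") rep(TRUE, nrow(compounds))
          else compounds$target_class == protocol
  if (!any(keep)) {
    abort(sprintf("No compounds labelled `%s` in the input.", protocol))
  }
  cmp <- compounds[keep, , drop = FALSE]

  if (is.null(descriptors)) {
    descriptors <- compute_descriptors(cmp, families = families)
  } else {
    check_descriptor_tbl(descriptors)
    descriptors <- descriptors |>
      filter(.data$compound_id %in% cmp$compound_id)
  }
  if (!is.null(energies)) {
    descriptors <- append_docking_columns(descriptors, energies,
                                          policy = "strict")
  }
  descriptors <- descriptors[match(cmp$compound_id, descriptors$compound_id), ]

  split <- split_dataset(cmp, fraction_valid = fraction_valid,
                         seed = config$seed)
  is_train <- split$subset == "train"
  d_train <- descriptors[is_train, , drop = FALSE]
  y_train <- cmp$pic50[is_train]
  d_valid <- descriptors[!is_train, , drop = FALSE]
  y_valid <- cmp$pic50[!is_train]

  selected <- select_features(d_train, y_train, cutoff = cutoff,
                              config = config)
  feats <- feature_names(selected)
  d_all_sel <- descriptors |> select("compound_id", dplyr::all_of(feats))
  d_train_sel <- d_all_sel[is_train, , drop = FALSE]
  d_valid_sel <- d_all_sel[!is_train, , drop = FALSE]

  model_train <- train_svr(d_train_sel, y_train, config = config,
                           scope = protocol)
  model_whole <- train_svr(d_all_sel, cmp$pic50, config = config,
                           scope = protocol)

  ev_whole <- evaluate_predictions(
    cmp$pic50, predict(model_whole, d_all_sel),
    label = sprintf("%s_whole", protocol))
  ev_train <- cross_validate(d_train_sel, y_train, config = config,
                             label = sprintf("%s_train", protocol))
  ev_valid <- evaluate_predictions(
    y_valid, predict(model_train, d_valid_sel),
    label = sprintf("%s_valid", protocol))

  structure(
    list(model = model_train, model_whole = model_whole,
         evaluation = bind_rows(ev_whole, ev_train, ev_valid),
         features = feats, selection = selection_report(selected),
         split = split, protocol = protocol, config = config,
         descriptors = d_all_sel,
         validation = tibble(compound_id = d_valid_sel$compound_id,
                             observed = y_valid,
                             predicted = predict(model_train, d_valid_sel))),
    class = "qsar_protocol")
}

#' @export
print.qsar_protocol <- function(x, ...) {
  cat(sprintf("<qsar_protocol> scope = %s, %d selected features\n",
              x$protocol, length(x$features)))
  print(x$evaluation)
  invisible(x)
}

#' @export
tidy.qsar_protocol <- function(x, ...) x$evaluation

#' @export
glance.qsar_protocol <- function(x, ...) {
  valid <- x$evaluation[nrow(x$evaluation), ]
  tibble(protocol = x$protocol,
         n_features = length(x$features),
         valid_R = valid$R, valid_R2 = valid$R2,
         valid_MAE = valid$MAE, valid_RMSE = valid$RMSE)
}

#' Save a fitted QSAR model as a JSON bundle
#'
#' The bundle stores support vectors, coefficients, bias, per-column
#' scaling and configuration at full precision; [read_qsar_model()]
#' reproduces predictions to at least 1e-9.
#'
#' @param model A `qsar_model`.
#' @param path Output path (JSON).
#' @return `path`, invisibly.
#' @export
write_qsar_model <- function(model, path) {
  payload <- list(
    format = "qsarkit_model",
    version = 1L,
    scope = model$scope,
    n_train = model$n_train,
    training_R = model$training_R,
    feature_names = model$feature_names,
    config = unclass(model$config),
    fit = list(
      kernel = model$fit$kernel, gamma = model$fit$gamma,
      degree = model$fit$degree, coef0 = model$fit$coef0,
      center = model$fit$center, scale = model$fit$scale,
      rho = model$fit$rho, coefs = model$fit$coefs,
      sv = model$fit$sv))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a QSAR model saved by [write_qsar_model()]
#'
#' @param path JSON bundle path.
#' @return A `qsar_model`.
#' @export
read_qsar_model <- function(path) {
  if (!file.exists(path)) abort(sprintf("Model file not found: %s", path))
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "qsarkit_model")) {
    abort("Not a qsarkit model bundle.")
  }
  gamma_cfg <- p$config$gamma
  if (length(gamma_cfg) == 0) gamma_cfg <- NULL
  cfg <- svr_config(kernel = p$config$kernel, C = p$config$C,
                    epsilon = p$config$epsilon, gamma = gamma_cfg,
                    degree = p$config$degree, coef0 = p$config$coef0,
                    cv_folds = p$config$cv_folds, seed = p$config$seed)
  fit <- list(center = setNames(p$fit$center, p$feature_names),
              scale = setNames(p$fit$scale, p$feature_names),
              gamma = p$fit$gamma, kernel = p$fit$kernel,
              degree = p$fit$degree, coef0 = p$fit$coef0,
              sv = matrix(as.numeric(p$fit$sv), nrow = nrow(p$fit$sv)),
              coefs = as.numeric(p$fit$coefs), rho = as.numeric(p$fit$rho))
  structure(
    list(fit = fit, feature_names = p$feature_names, config = cfg,
         scope = p$scope %||% NA_character_, n_train = p$n_train,
         training_R = p$training_R),
    class = "qsar_model")
}
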