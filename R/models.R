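#' Fit one surrogate regressor
#'
#' Fits a single model of the requested family on standardized dose features.
#' The solver internals are delegated to established implementations
#' (`xgboost`, `ranger`, `e1071::svm` with the radial-basis kernel,
#' `glmnet`); this function owns the uniform fit/predict contract, the
#' hyperparameter validation, and the determinism guarantees.
#'
#' Backend notes: the support-vector machine's targets are standardized
#' internally and back-transformed at prediction time (the epsilon tube is
#' scale-sensitive); the elastic net with zero penalty is fitted by ordinary
#' least squares so the unpenalized limit is exact; the random-forest backend
#' (`ranger`) realizes `n_estimators`, `max_features`, `max_depth` and
#' `min_samples_leaf`, while `min_samples_split`, `min_weight_fraction_leaf`
#' and `max_leaf_nodes` are validated against the declared space but have no
#' `ranger` equivalent and are recorded as inactive.
#'
#' @param model_kind `"XGB"`, `"RF"`, `"SVR"` or `"ENMLR"`.
#' @param hyperparams Named list of hyperparameters inside the family's
#'   declared space (see [hyperparameter_space()]).
#' @param X Numeric matrix of standardized features (rows = observations).
#' @param y Numeric response vector on the raw trait scale.
#' @param seed Integer seed; fits are deterministic given the seed.
#' @param standardizer Optional `standardizer` attached for raw-dose
#'   prediction via [predict.surrogate()].
#' @param trait,cultivar Optional labels stored on the model record.
#' @param validate Validate `hyperparams` against the declared space.
#' @param ... Passed to the backend fitting function (e.g. `ranger` sampling
#'   arguments).
#' @return An object of class `surrogate`.
#' @export
fit_surrogate <- function(model_kind, hyperparams, X, y, seed,
                          standardizer = NULL, trait = NULL, cultivar = NULL,
                          validate = TRUE, ...) {
  X <- as.matrix(X)
  if (nrow(X) != length(y) || length(y) < 2) stop("need |X| = |y| >= 2")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (validate) validate_hyperparams(hyperparameter_space(model_kind), hyperparams)
  hp <- as.list(hyperparams)
  fit <- switch(model_kind,
    XGB = fit_xgb(hp, X, y, seed, ...),
    RF = fit_rf(hp, X, y, seed, ...),
    SVR = fit_svr(hp, X, y, ...),
    ENMLR = fit_enmlr(hp, X, y, ...),
    stop("unknown model kind: ", model_kind)
  )
  structure(list(kind = model_kind, hyperparams = hp, fit = fit$object,
                 backend = fit$backend, notes = fit$notes, seed = seed,
                 feature_names = colnames(X),
                 standardizer = standardizer, trait = trait,
                 cultivar = cultivar),
            class = "surrogate")
}

fit_xgb <- function(hp, X, y, seed, ...) {
  params <- list(objective = "reg:squarederror",
                 eta = hp$learning_rate, gamma = hp$gamma,
                 max_depth = hp$max_depth, subsample = hp$subsample,
                 colsample_bytree = hp$colsample_bytree,
                 min_child_weight = hp$min_child_weight,
                 lambda = hp$reg_lambda, alpha = hp$reg_alpha,
                 nthread = 1, tree_method = "hist", max_bin = 16,
                 seed = seed)
  dm <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  booster <- with_seed(seed, function() {
    xgboost::xgb.train(params, dm, nrounds = hp$n_estimators, verbose = 0, ...)
  })
  list(object = booster, backend = "xgboost::xgb.train")
}

fit_rf <- function(hp, X, y, seed, ...) {
  mtry <- max(1L, min(ncol(X), as.integer(ceiling(hp$max_features * ncol(X)))))
  object <- ranger::ranger(y = y, x = X,
                           num.trees = hp$n_estimators, mtry = mtry,
                           max.depth = hp$max_depth,
                           min.node.size = hp$min_samples_leaf,
                           num.threads = 1, seed = seed, oob.error = FALSE, ...)
  list(object = object, backend = "ranger::ranger",
       notes = "inactive dims: min_samples_split, min_weight_fraction_leaf, max_leaf_nodes")
}

fit_svr <- function(hp, X, y, ...) {
  y_mu <- mean(y)
  y_sd <- stats::sd(y)
  if (y_sd == 0) {
    # constant target: the epsilon-insensitive fit is the constant itself
    return(list(object = list(constant = y_mu), backend = "constant",
                notes = "zero-variance target"))
  }
  object <- e1071::svm(x = X, y = (y - y_mu) / y_sd, type = "eps-regression",
                       kernel = "radial", gamma = hp$gamma, cost = hp$C,
                       epsilon = hp$epsilon, scale = FALSE, fitted = FALSE, ...)
  if (object$tot.nSV == 0) {
    # epsilon tube swallows every point: no support vectors, the flat
    # function at the target mean is an optimal solution
    return(list(object = list(constant = y_mu), backend = "constant",
                notes = "epsilon tube wider than target spread"))
  }
  list(object = list(svm = object, y_mu = y_mu, y_sd = y_sd),
       backend = "e1071::svm", notes = "target standardized internally")
}

fit_enmlr <- function(hp, X, y, ...) {
  if (hp$alpha == 0) {
    coefs <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)$coefficients
    coefs[is.na(coefs)] <- 0
    return(list(object = list(coef = coefs), backend = "stats::lm.fit",
                notes = "unpenalized limit via least squares"))
  }
  object <- glmnet::glmnet(X, y, alpha = hp$l1_ratio, lambda = hp$alpha,
                           standardize = FALSE, ...)
  list(object = object, backend = "glmnet::glmnet")
}

# Predict on already-standardized features (internal fast path used by
# tuning, stacking and the optimizer).
predict_std <- function(model, X) {
  X <- as.matrix(X)
  colnames(X) <- model$feature_names
  out <- switch(model$kind,
    XGB = stats::predict(model$fit, xgboost::xgb.DMatrix(X, nthread = 1)),
    RF = stats::predict(model$fit, data = X, num.threads = 1)$predictions,
    SVR = if (model$backend == "constant") rep(model$fit$constant, nrow(X)) else {
      as.numeric(stats::predict(model$fit$svm, X)) * model$fit$y_sd + model$fit$y_mu
    },
    ENMLR = if (model$backend == "stats::lm.fit") {
      as.numeric(cbind(1, X) %*% model$fit$coef)
    } else {
      as.numeric(stats::predict(model$fit, newx = X))
    },
    ESR = {
      Z <- do.call(cbind, lapply(model$bases, function(b) predict_std(b, X)))
      colnames(Z) <- names(model$bases)
      predict_std(model$meta, Z)
    },
    stop("unknown model kind: ", model$kind)
  )
  as.numeric(out)
}

#' Predict growth responses at raw dose pairs
#'
#' Applies the model's stored standardizer to the raw doses and evaluates the
#' fitted regressor. Doses must lie inside the experimental rectangle
#' (gibberellic acid in \[0, 0.5\] mg/L, zeatin in \[0, 0.75\] mg/L) unless
#' extrapolation is explicitly enabled; surrogates are not trusted outside
#' the design region.
#'
#' @param object A fitted `surrogate` with a standardizer attached.
#' @param doses Two-column matrix or data.frame of (ga3, zt) in mg/L.
#' @param extrapolate Allow doses outside the experimental bounds.
#' @param ... Unused.
#' @return Numeric vector of predictions on the trait scale.
#' @export
predict.surrogate <- function(object, doses, extrapolate = FALSE, ...) {
  doses <- as.matrix(doses)
  if (ncol(doses) != 2) stop("doses must have two columns (ga3, zt)")
  if (!extrapolate) {
    out_ga3 <- doses[, 1] < DOSE_BOUNDS$ga3[1] | doses[, 1] > DOSE_BOUNDS$ga3[2]
    out_zt <- doses[, 2] < DOSE_BOUNDS$zt[1] | doses[, 2] > DOSE_BOUNDS$zt[2]
    if (any(out_ga3 | out_zt)) {
      stop("dose outside the experimental bounds (row ",
           which(out_ga3 | out_zt)[1], "); set extrapolate = TRUE to override")
    }
  }
  if (is.null(object$standardizer)) {
    stop("surrogate has no standardizer attached; use standardized features")
  }
  preds <- predict_std(object, standardize(doses, object$standardizer))
  if (!all(is.finite(preds))) stop("non-finite prediction from ", object$kind)
  preds
}

#' @export
print.surrogate <- function(x, ...) {
  cat("Surrogate model:", x$kind,
      if (!is.null(x$cultivar)) paste0("[", x$cultivar, "/", x$trait, "]"), "\n")
  cat("  backend:", x$backend %||% "stacked", "\n")
  if (x$kind == "ESR") {
    cat("  bases:", paste(names(x$bases), collapse = ", "), "| meta: RF\n")
  }
  invisible(x)
}

#' Persist and restore a fitted surrogate
#'
#' Writes a human-readable JSON manifest (kind, hyperparameters, seed,
#' standardizer, labels, and a checksum of the training call) next to an
#' opaque binary blob holding the fitted state. `load_surrogate()` restores
#' the model and cross-checks it against the manifest.
#'
#' @param model A fitted `surrogate`.
#' @param path Base path; `<path>.json` and `<path>.rds` are written.
#' @return Base path (write) or the restored `surrogate` (load), invisibly.
#' @export
save_surrogate <- function(model, path) {
  stopifnot(inherits(model, "surrogate"))
  manifest <- list(kind = model$kind,
                   hyperparams = model$hyperparams %||% model$meta_params,
                   seed = model$seed,
                   trait = model$trait, cultivar = model$cultivar,
                   backend = model$backend %||% "stacked",
                   standardizer = if (!is.null(model$standardizer))
                     unclass(model$standardizer),
                   checksum = surrogate_checksum(model))
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  saveRDS(model, paste0(path, ".rds"))
  invisible(path)
}

#' @rdname save_surrogate
#' @export
load_surrogate <- function(path) {
  manifest <- jsonlite::read_json(paste0(path, ".json"))
  model <- readRDS(paste0(path, ".rds"))
  if (!identical(manifest$kind, model$kind) ||
      !identical(manifest$checksum, surrogate_checksum(model))) {
    stop("manifest does not match the stored model blob: ", path)
  }
  invisible(model)
}

# content fingerprint of the identifying fields (not the opaque fit)
surrogate_checksum <- function(model) {
  key <- jsonlite::toJSON(list(model$kind, model$hyperparams %||% model$meta_params,
                               model$seed, model$trait, model$cultivar),
                          auto_unbox = TRUE, digits = NA)
  as.character(sum(utf8ToInt(key) * (seq_along(utf8ToInt(key)) %% 97 + 1)))
}

# Out-of-fold base predictions: the meta training set of the stacking
# ensemble. Each row's prediction comes from a base fit that excluded it.
stacking_oof <- function(X, y, folds, base_params, seed) {
  oof <- matrix(NA_real_, nrow(X), length(BASE_KINDS),
                dimnames = list(NULL, BASE_KINDS))
  for (kind in BASE_KINDS) {
    for (k in sort(unique(folds))) {
      hold <- folds == k
      fit <- tryCatch(
        fit_surrogate(kind, base_params[[kind]], X[!hold, , drop = FALSE],
                      y[!hold], seed = substream_seed(seed, "oof", kind, k)),
        error = function(e) stop("stacking aborted: base ", kind,
                                 " failed on fold ", k, ": ", conditionMessage(e))
      )
      oof[hold, kind] <- predict_std(fit, X[hold, , drop = FALSE])
    }
  }
  oof
}

#' Fit the stacking ensemble (ESR)
#'
#' Builds the stacking regressor: gradient boosting, support vector and
#' elastic-net base regressors feed a random-forest meta-regressor. The meta
#' training set is the out-of-fold base predictions (one column per base), so
#' no base prediction used for meta-training was produced by a model that saw
#' that row; the base models are then refitted on all training rows to
#' generate meta-features at prediction time.
#'
#' @param X Standardized feature matrix (training rows).
#' @param y Response vector.
#' @param folds Integer fold assignment per training row (as in a
#'   [split_train_test()] plan).
#' @param base_params Named list of hyperparameter lists for `XGB`, `SVR`,
#'   `ENMLR`.
#' @param meta_params Hyperparameter list for the RF meta-regressor.
#' @param seed Integer seed.
#' @param standardizer,trait,cultivar As in [fit_surrogate()].
#' @param oof Optional precomputed out-of-fold meta-feature matrix produced
#'   with exactly these folds, base parameters and seed substreams (as the
#'   pipeline does when it tunes the meta-regressor); recomputed when `NULL`.
#' @param ... Passed to the meta-RF backend.
#' @return A `surrogate` of kind `"ESR"`. The out-of-fold meta-feature matrix
#'   and the fold assignment are kept on the object (`oof`, `folds`) for
#'   leakage auditing.
#' @export
fit_stacking <- function(X, y, folds, base_params, meta_params, seed,
                         standardizer = NULL, trait = NULL, cultivar = NULL,
                         oof = NULL, ...) {
  X <- as.matrix(X)
  if (length(folds) != nrow(X)) stop("folds must cover all training rows")
  missing_bases <- setdiff(BASE_KINDS, names(base_params))
  if (length(missing_bases)) {
    stop("missing base hyperparameters for: ", paste(missing_bases, collapse = ", "))
  }
  oof <- oof %||% stacking_oof(X, y, folds, base_params, seed)
  if (!identical(dim(oof), as.integer(c(nrow(X), length(BASE_KINDS))))) {
    stop("out-of-fold matrix must be ", nrow(X), " x ", length(BASE_KINDS))
  }
  meta <- fit_surrogate("RF", meta_params, oof, y,
                        seed = substream_seed(seed, "meta"), ...)
  bases <- lapply(BASE_KINDS, function(kind) {
    fit_surrogate(kind, base_params[[kind]], X, y,
                  seed = substream_seed(seed, "base", kind))
  })
  names(bases) <- BASE_KINDS
  structure(list(kind = "ESR", bases = bases, meta = meta,
                 base_params = base_params, meta_params = meta_params,
                 oof = oof, folds = folds, seed = seed,
                 feature_names = colnames(X),
                 standardizer = standardizer, trait = trait,
                 cultivar = cultivar),
            class = "surrogate")
}
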