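#' Tuning configuration
#'
#' @param budget Number of objective evaluations (>= 1).
#' @param K Cross-validation folds (>= 2).
#' @param objective Objective metric, currently `"rmse"` (the root mean square
#'   error on held-out folds, averaged over folds).
#' @param seed Integer seed driving the whole search.
#' @return A `tuning_config` list.
#' @export
tuning_config <- function(budget = 100, K = 10, objective = "rmse", seed) {
  if (budget < 1) stop("budget must be >= 1")
  if (K < 2) stop("K must be >= 2")
  structure(list(budget = as.integer(budget), K = as.integer(K),
                 objective = objective, seed = seed),
            class = "tuning_config")
}

# Balanced random fold assignment for n rows.
make_folds <- function(n, K, seed) {
  if (K < 2 || K > n) stop("K must be in [2, n]")
  with_seed(substream_seed(seed, "folds"), function() sample(rep_len(seq_len(K), n)))
}

#' Cross-validated objective for one configuration
#'
#' For each fold, fits the model on the remaining folds and scores its
#' predictions on the held-out fold; returns the mean across folds.
#'
#' @param model_kind Model family (see [fit_surrogate()]).
#' @param hyperparams Configuration to evaluate.
#' @param X Standardized feature matrix.
#' @param y Response vector.
#' @param folds Integer fold assignment per row.
#' @param seed Integer seed (per-fold fitting seeds are derived from it).
#' @param metric `"rmse"`.
#' @return Mean held-out RMSE (lower is better).
#' @export
cv_objective <- function(model_kind, hyperparams, X, y, folds, seed,
                         metric = "rmse") {
  X <- as.matrix(X)
  if (length(folds) != nrow(X)) stop("folds must cover all rows")
  fold_ids <- sort(unique(folds))
  if (any(tabulate(folds) < 1)) stop("every fold needs at least one validation row")
  scores <- vapply(fold_ids, function(k) {
    hold <- folds == k
    fit <- fit_surrogate(model_kind, hyperparams, X[!hold, , drop = FALSE],
                         y[!hold], seed = substream_seed(seed, "cv", k))
    pred <- predict_std(fit, X[hold, , drop = FALSE])
    sqrt(mean((y[hold] - pred)^2))
  }, numeric(1))
  mean(scores)
}

#' Sequential model-based hyperparameter search (TPE family)
#'
#' Minimizes a black-box objective over a declared space with a
#' tree-structured-Parzen-estimator-type sampler: after an initial random
#' stage, the evaluated configurations are split at the lower quartile of the
#' objective into "good" and "bad" sets, each modelled by a per-dimension
#' Gaussian kernel density in prior-rescaled unit coordinates; candidates are
#' drawn from the good-set density and the one maximizing the good/bad density
#' ratio is evaluated next. The search is fully seeded and the evaluated
#' sequence for a given seed is a prefix of the sequence for any larger
#' budget.
#'
#' @param space A `hp_space`.
#' @param objective Function taking a named hyperparameter list, returning a
#'   scalar to minimize. Any RNG the objective uses internally does not
#'   disturb the sampler's stream.
#' @param budget Number of evaluations.
#' @param seed Integer seed.
#' @param n_init Random evaluations before the density model starts (fixed,
#'   not budget-dependent, so the evaluated sequence for one seed is a prefix
#'   of the sequence at any larger budget).
#' @param gamma Quantile defining the "good" set.
#' @param n_candidates Candidates scored per iteration.
#' @return A `tuning_result`: `best_hyperparams`, `best_objective`, `history`
#'   (data.frame of evaluated configurations and objectives), `budget_used`,
#'   `sampler`.
#' @export
tune_space <- function(space, objective, budget, seed, n_init = 5,
                       gamma = 0.25, n_candidates = 24) {
  stopifnot(inherits(space, "hp_space"))
  if (budget < 1) stop("budget must be >= 1")
  dims <- space$dims
  nd <- length(dims)
  U <- matrix(NA_real_, budget, nd)  # unit-cube coordinates of evaluations
  obj <- rep(NA_real_, budget)
  params_hist <- vector("list", budget)

  rng <- new.env()
  run_sampler <- function(fn) with_seed_env(rng, fn)
  # initialize the sampler stream once
  init_seed_env(rng, substream_seed(seed, "tpe"))

  kde_log <- function(u, centers, bw) {
    # product of per-dimension mixtures, with a 5% uniform floor for support
    total <- 0
    for (j in seq_len(nd)) {
      dens <- mean(stats::dnorm(u[j], centers[, j], bw[j]))
      total <- total + log(0.95 * dens + 0.05)
    }
    total
  }

  for (t in seq_len(budget)) {
    u <- run_sampler(function() {
      done <- t - 1L
      if (done < max(n_init, 4L)) return(stats::runif(nd))
      ord <- order(obj[seq_len(done)])
      n_good <- max(2L, ceiling(gamma * done))
      good <- U[ord[seq_len(n_good)], , drop = FALSE]
      bad <- U[ord[-seq_len(n_good)], , drop = FALSE]
      if (nrow(bad) < 2) return(stats::runif(nd))
      bw_of <- function(M) pmax(1.06 * apply(M, 2, stats::sd) * nrow(M)^-0.2, 0.08)
      bw_g <- bw_of(good); bw_b <- bw_of(bad)
      cand <- lapply(seq_len(n_candidates), function(i) {
        center <- good[sample.int(nrow(good), 1), ]
        pmin(pmax(stats::rnorm(nd, center, bw_g), 0), 1)
      })
      scores <- vapply(cand, function(u) {
        kde_log(u, good, bw_g) - kde_log(u, bad, bw_b)
      }, numeric(1))
      cand[[which.max(scores)]]
    })
    p <- lapply(seq_len(nd), function(j) dim_from_unit(dims[[j]], u[j]))
    names(p) <- names(dims)
    # store the quantized point's coordinates so the density model sees what
    # was actually evaluated
    U[t, ] <- vapply(seq_len(nd), function(j) dim_to_unit(dims[[j]], p[[j]]),
                     numeric(1))
    params_hist[[t]] <- p
    obj[t] <- objective(p)
    if (!is.finite(obj[t])) obj[t] <- .Machine$double.xmax
  }
  best <- which.min(obj)
  history <- cbind(do.call(rbind, lapply(params_hist, as.data.frame)),
                   objective = obj)
  structure(list(best_hyperparams = params_hist[[best]],
                 best_objective = obj[best],
                 history = history, budget_used = budget,
                 sampler = "tpe", seed = seed),
            class = "tuning_result")
}

# private RNG stream management: keeps the sampler's stream independent of
# any set.seed() calls the objective makes
init_seed_env <- function(env, seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

with_seed_env <- function(env, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", env$state, globalenv())
  out <- fn()
  env$state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  out
}

#' Tune one model family by cross-validated TPE search
#'
#' @param model_kind Model family whose declared space is searched.
#' @param X Standardized feature matrix (training rows only).
#' @param y Response vector.
#' @param config A [tuning_config()].
#' @param folds Optional fold assignment; derived from the config seed if
#'   omitted.
#' @param space Optional space override (defaults to the family's declared
#'   space).
#' @return A `tuning_result` (see [tune_space()]).
#' @export
tune_model <- function(model_kind, X, y, config, folds = NULL, space = NULL) {
  stopifnot(inherits(config, "tuning_config"))
  X <- as.matrix(X)
  space <- space %||% hyperparameter_space(model_kind)
  folds <- folds %||% make_folds(nrow(X), config$K, config$seed)
  objective <- function(params) {
    cv_objective(model_kind, params, X, y, folds,
                 seed = substream_seed(config$seed, "cv-fit", model_kind),
                 metric = config$objective)
  }
  tune_space(space, objective, budget = config$budget,
             seed = substream_seed(config$seed, "tune", model_kind))
}

#' Serialize a tuning result (full history) to JSON
#'
#' @param result A `tuning_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tuning_result <- function(result, path) {
  stopifnot(inherits(result, "tuning_result"))
  jsonlite::write_json(list(best_hyperparams = result$best_hyperparams,
                            best_objective = result$best_objective,
                            budget_used = result$budget_used,
                            sampler = result$sampler,
                            history = result$history),
                       path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
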