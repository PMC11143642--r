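#' Hyperparameter search-space definitions
#'
#' Declares the tunable dimensions of each surrogate family: name, closed or
#' half-open bounds, integer/continuous type, and the sampling prior used by
#' the tuner (tree-count dimensions are sampled on a log scale because their
#' range spans two orders of magnitude; everything else is uniform).
#'
#' @param model_kind One of `"XGB"`, `"RF"`, `"SVR"`, `"ENMLR"`.
#' @return An object of class `hp_space`: a list of dimension definitions
#'   created with [hp_dim()].
#' @export
hyperparameter_space <- function(model_kind) {
  dims <- switch(model_kind,
    XGB = list(
      hp_dim("n_estimators", 10, 1500, "int", prior = "log"),
      hp_dim("learning_rate", 0.001, 0.3),
      hp_dim("gamma", 0, 10),
      hp_dim("max_depth", 1, 20, "int"),
      hp_dim("subsample", 0.001, 1),
      hp_dim("colsample_bytree", 0.01, 1),
      hp_dim("min_child_weight", 1, 10),
      hp_dim("reg_lambda", 0, 5),
      hp_dim("reg_alpha", 0, 5)
    ),
    RF = list(
      hp_dim("n_estimators", 10, 1500, "int", prior = "log"),
      hp_dim("max_features", 0, 1, lower_open = TRUE),
      hp_dim("max_depth", 2, 50, "int"),
      hp_dim("min_samples_split", 1, 100, "int"),
      hp_dim("min_samples_leaf", 1, 15, "int"),
      hp_dim("min_weight_fraction_leaf", 0, 0.5),
      hp_dim("max_leaf_nodes", 2, 200, "int")
    ),
    ENMLR = list(
      hp_dim("alpha", 0, 5),
      hp_dim("l1_ratio", 0, 1)
    ),
    SVR = list(
      hp_dim("gamma", 0, 10, lower_open = TRUE),
      hp_dim("C", 0, 50, lower_open = TRUE),
      hp_dim("epsilon", 0, 5, lower_open = TRUE)
    ),
    stop("no declared hyperparameter space for model kind: ", model_kind)
  )
  new_hp_space(dims, model_kind)
}

#' Declare one search dimension
#'
#' @param name Dimension name.
#' @param lower,upper Bounds.
#' @param type `"cont"` or `"int"` (integer dimensions are sampled quantized,
#'   not as rounded continuous draws).
#' @param lower_open If `TRUE` the interval is half-open `(lower, upper]`.
#' @param prior `"uniform"` or `"log"` sampling prior.
#' @return A `hp_dim` list.
#' @export
hp_dim <- function(name, lower, upper, type = c("cont", "int"),
                   lower_open = FALSE, prior = c("uniform", "log")) {
  type <- match.arg(type)
  prior <- match.arg(prior)
  if (upper <= lower) stop("empty interval for dimension ", name)
  if (prior == "log" && lower <= 0) stop("log prior needs a positive lower bound: ", name)
  structure(list(name = name, lower = lower, upper = upper, type = type,
                 lower_open = lower_open, prior = prior), class = "hp_dim")
}

#' @rdname hyperparameter_space
#' @param dims List of [hp_dim()] definitions.
#' @param kind Label for the space (defaults to `"custom"`).
#' @export
new_hp_space <- function(dims, kind = "custom") {
  stopifnot(all(vapply(dims, inherits, TRUE, "hp_dim")))
  names(dims) <- vapply(dims, `[[`, character(1), "name")
  structure(list(kind = kind, dims = dims), class = "hp_space")
}

#' @export
print.hp_space <- function(x, ...) {
  cat("Hyperparameter space:", x$kind, "(", length(x$dims), "dimensions )\n")
  for (d in x$dims) {
    cat(sprintf("  %-26s %s%g, %g] %s%s\n", d$name,
                if (d$lower_open) "(" else "[", d$lower, d$upper, d$type,
                if (d$prior == "log") " (log prior)" else ""))
  }
  invisible(x)
}

#' Validate a hyperparameter configuration against its space
#'
#' @param space A `hp_space`.
#' @param params Named list/vector of values, one per dimension.
#' @return `params` (as a named list), invisibly valid; errors name the
#'   offending dimension.
#' @export
validate_hyperparams <- function(space, params) {
  stopifnot(inherits(space, "hp_space"))
  params <- as.list(params)
  missing <- setdiff(names(space$dims), names(params))
  if (length(missing)) stop("missing hyperparameter(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(names(params), names(space$dims))
  if (length(extra)) stop("unknown hyperparameter(s): ", paste(extra, collapse = ", "))
  for (d in space$dims) {
    v <- params[[d$name]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      stop("hyperparameter ", d$name, " must be a finite scalar")
    }
    low_ok <- if (d$lower_open) v > d$lower else v >= d$lower
    if (!low_ok || v > d$upper) {
      stop("hyperparameter ", d$name, " = ", v, " outside ",
           if (d$lower_open) "(" else "[", d$lower, ", ", d$upper, "]")
    }
    if (d$type == "int" && v != round(v)) {
      stop("hyperparameter ", d$name, " must be integer-valued")
    }
  }
  invisible(params)
}

# --- unit-cube coordinate transforms used by the samplers ------------------

# map a raw value to [0,1] under the dimension's prior
dim_to_unit <- function(d, v) {
  if (d$prior == "log") {
    (log(v) - log(d$lower)) / (log(d$upper) - log(d$lower))
  } else {
    (v - d$lower) / (d$upper - d$lower)
  }
}

# map a [0,1] coordinate back to a raw (quantized if integer) value
dim_from_unit <- function(d, u) {
  u <- pmin(pmax(u, 0), 1)
  v <- if (d$prior == "log") {
    exp(log(d$lower) + u * (log(d$upper) - log(d$lower)))
  } else {
    d$lower + u * (d$upper - d$lower)
  }
  if (d$type == "int") v <- round(v)
  if (d$lower_open && v <= d$lower) {
    # nudge off an open lower bound: smallest representable step inward
    v <- if (d$type == "int") d$lower + 1 else d$lower + (d$upper - d$lower) * 1e-6
  }
  pmin(pmax(v, if (d$lower_open) v else d$lower), d$upper)
}

#' Sample configurations uniformly from a space
#'
#' Draws each dimension independently under its declared prior; integer
#' dimensions are quantized.
#'
#' @param space A `hp_space`.
#' @param n Number of configurations.
#' @param seed Integer seed.
#' @return A list of `n` named hyperparameter lists, each valid in `space`.
#' @export
sample_hyperparams <- function(space, n, seed) {
  stopifnot(inherits(space, "hp_space"))
  with_seed(substream_seed(seed, "hp-sample"), function() {
    lapply(seq_len(n), function(i) {
      p <- lapply(space$dims, function(d) dim_from_unit(d, stats::runif(1)))
      names(p) <- names(space$dims)
      p
    })
  })
}
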