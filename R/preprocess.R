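#' Fit a feature standardizer
#'
#' Computes per-feature mean and standard deviation over the given rows (the
#' training subset), for centring to zero mean and scaling to unit variance.
#' Targets are left on their original trait scale; only the dose features are
#' standardized.
#'
#' @param table An `observation_table` (or any data.frame with the feature
#'   columns).
#' @param indices Row indices to fit on (training rows). Defaults to all rows.
#' @param features Feature column names.
#' @return An object of class `standardizer` with elements `mu` and `sigma`.
#' @export
fit_standardizer <- function(table, indices = seq_len(nrow(table)),
                             features = c("ga3_mg_per_L", "zt_mg_per_L")) {
  if (!length(indices)) stop("cannot fit a standardizer on an empty index set")
  x <- as.matrix(table[indices, features, drop = FALSE])
  mu <- colMeans(x)
  sigma <- apply(x, 2, stats::sd)
  if (any(sigma == 0)) {
    stop("zero variance in feature(s): ",
         paste(features[sigma == 0], collapse = ", "),
         "; standardization undefined")
  }
  structure(list(mu = mu, sigma = sigma, features = features),
            class = "standardizer")
}

#' Standardize feature values
#'
#' Applies `(x - mu) / sigma` per feature.
#'
#' @param x Matrix or data.frame of raw feature values (columns matching the
#'   standardizer's features), or a numeric vector for a single feature set.
#' @param params A `standardizer`.
#' @return A numeric matrix of standardized values.
#' @export
standardize <- function(x, params) {
  stopifnot(inherits(params, "standardizer"))
  x <- as.matrix(x)
  if (ncol(x) != length(params$mu)) stop("feature count mismatch")
  sweep(sweep(x, 2, params$mu, "-"), 2, params$sigma, "/")
}

#' Invert a standardization
#'
#' @param z Matrix of standardized values.
#' @inheritParams standardize
#' @return Matrix on the original scale (`z * sigma + mu`).
#' @export
unstandardize <- function(z, params) {
  stopifnot(inherits(params, "standardizer"))
  z <- as.matrix(z)
  sweep(sweep(z, 2, params$sigma, "*"), 2, params$mu, "+")
}

#' Split rows into training and testing sets with CV folds
#'
#' Draws a seeded random 80/20 (by default) train/test split and assigns the
#' training rows to K cross-validation folds whose sizes differ by at most one.
#'
#' @param table Data to split (only `nrow` is used).
#' @param fraction Training fraction in (0, 1).
#' @param seed Integer seed.
#' @param K Number of cross-validation folds over the training rows.
#' @return An object of class `split_plan`: `train_indices`, `test_indices`,
#'   `fold_assignment` (integer fold id per training row, parallel to
#'   `train_indices`), `seed`, `K`, `fraction`.
#' @export
split_train_test <- function(table, fraction = 0.8, seed, K = 10) {
  n <- nrow(table)
  if (!n) stop("cannot split an empty table")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be inside (0, 1)")
  if (K < 2) stop("K must be >= 2")
  n_train <- floor(fraction * n + 0.5)
  plan <- with_seed(substream_seed(seed, "split"), function() {
    train <- sort(sample.int(n, n_train))
    folds <- sample(rep_len(seq_len(K), n_train))
    list(train = train, folds = folds)
  })
  structure(list(train_indices = plan$train,
                 test_indices = setdiff(seq_len(n), plan$train),
                 fold_assignment = plan$folds,
                 seed = seed, K = K, fraction = fraction),
            class = "split_plan")
}

#' Serialize / restore a split plan
#'
#' A split plan round-trips through JSON so any pipeline stage can be replayed
#' bit-exactly.
#'
#' @param plan A `split_plan`.
#' @param path JSON file path.
#' @return `path` invisibly (write) or the restored `split_plan` (read).
#' @export
write_split_plan <- function(plan, path) {
  stopifnot(inherits(plan, "split_plan"))
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_split_plan
#' @export
read_split_plan <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$train_indices <- as.integer(obj$train_indices)
  obj$test_indices <- as.integer(obj$test_indices)
  obj$fold_assignment <- as.integer(obj$fold_assignment)
  structure(obj, class = "split_plan")
}

#' Screen for multivariate outliers on principal components
#'
#' Projects the standardized response matrix (leaf number, proliferation rate,
#' survival, shoot length) onto its first two principal components and flags
#' rows whose score on either component exceeds three standard deviations of
#' that component's scores. Rows are flagged for inspection, never dropped
#' automatically.
#'
#' @param table An `observation_table`.
#' @param n_sd Flagging threshold in component-score standard deviations.
#' @return Integer vector of flagged row indices (possibly empty).
#' @export
pca_outlier_screen <- function(table, n_sd = 3) {
  responses <- c("LN", "PR", "ES_pct", "SL_cm")
  if (nrow(table) < 3) stop("need at least 3 rows to screen for outliers")
  m <- as.matrix(table[, responses])
  sds <- apply(m, 2, stats::sd)
  if (all(sds == 0)) {
    warning("degenerate response matrix (all rows identical); nothing to screen")
    return(integer(0))
  }
  keep <- sds > 0
  pca <- stats::prcomp(m[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  k <- min(2, ncol(pca$x))
  flagged <- logical(nrow(m))
  for (j in seq_len(k)) {
    s <- pca$x[, j]
    if (stats::sd(s) == 0) next
    flagged <- flagged | abs(s) > n_sd * stats::sd(s)
  }
  which(flagged)
}
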