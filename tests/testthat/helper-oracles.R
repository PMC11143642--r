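# Independent brute-force oracles and small fixture builders used across tests.

# O(n^2 * m) dominance check by explicit double loop (maximization).
brute_nondominated_sort <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (!n) return(list())
  dominates <- function(a, b) all(a >= b) && any(a > b)
  remaining <- seq_len(n)
  fronts <- list()
  while (length(remaining)) {
    front <- integer(0)
    for (i in remaining) {
      dominated <- FALSE
      for (j in remaining) {
        if (i != j && dominates(points[j, ], points[i, ])) {
          dominated <- TRUE
          break
        }
      }
      if (!dominated) front <- c(front, i)
    }
    fronts[[length(fronts) + 1]] <- front
    remaining <- setdiff(remaining, front)
  }
  fronts
}

# Definitional crowding distance, written independently of the package's.
brute_crowding <- function(front) {
  front <- as.matrix(front)
  n <- nrow(front)
  if (n <= 2) return(rep(Inf, n))
  d <- rep(0, n)
  for (k in seq_len(ncol(front))) {
    v <- front[, k]
    rg <- max(v) - min(v)
    if (rg == 0) next
    ord <- order(v)
    d[ord[1]] <- Inf
    d[ord[n]] <- Inf
    for (i in 2:(n - 1)) {
      d[ord[i]] <- d[ord[i]] + (v[ord[i + 1]] - v[ord[i - 1]]) / rg
    }
  }
  d
}

# 2-objective hypervolume w.r.t. a reference point (maximization).
hv_2d <- function(front, ref) {
  front <- front[order(front[, 1], decreasing = TRUE), , drop = FALSE]
  keep <- front[, 1] > ref[1] & front[, 2] > ref[2]
  front <- front[keep, , drop = FALSE]
  if (!nrow(front)) return(0)
  hv <- 0
  y_prev <- ref[2]
  for (i in seq_len(nrow(front))) {
    if (front[i, 2] > y_prev) {
      hv <- hv + (front[i, 1] - ref[1]) * (front[i, 2] - y_prev)
      y_prev <- front[i, 2]
    }
  }
  hv
}

# small noisy nonlinear regression problem on standardized-ish features
toy_regression <- function(n = 80, seed = 1, noise = 0.3) {
  set.seed(seed)
  X <- cbind(ga3 = runif(n, -1.2, 1.2), zt = runif(n, -1.2, 1.2))
  y <- 3 + 1.5 * X[, 1] - X[, 2]^2 + 0.5 * X[, 1] * X[, 2] + rnorm(n, 0, noise)
  list(X = X, y = y)
}

default_xgb_params <- function() {
  list(n_estimators = 60, learning_rate = 0.1, gamma = 0, max_depth = 4,
       subsample = 0.9, colsample_bytree = 1, min_child_weight = 1,
       reg_lambda = 1, reg_alpha = 0)
}

default_rf_params <- function() {
  list(n_estimators = 150, max_features = 1, max_depth = 20,
       min_samples_split = 2, min_samples_leaf = 2,
       min_weight_fraction_leaf = 0, max_leaf_nodes = 200)
}

default_svr_params <- function() list(gamma = 0.5, C = 10, epsilon = 0.1)

default_enmlr_params <- function() list(alpha = 0.01, l1_ratio = 0.5)

default_base_params <- function() {
  list(XGB = default_xgb_params(), SVR = default_svr_params(),
       ENMLR = default_enmlr_params())
}
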