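#' Non-dominated sorting of objective vectors
#'
#' Partitions points into Pareto fronts under maximization (or minimization):
#' front 1 is the non-dominated set; front k is the set that becomes
#' non-dominated once fronts 1..k-1 are removed. A point dominates another if
#' it is at least as good in every objective and strictly better in one.
#'
#' @param points Numeric matrix, one row per point, one column per objective.
#' @param sense `"max"` or `"min"`.
#' @return List of integer index vectors, one per front; every point appears
#'   exactly once. Empty input yields an empty list.
#' @export
nondominated_sort <- function(points, sense = c("max", "min")) {
  sense <- match.arg(sense)
  points <- as.matrix(points)
  n <- nrow(points)
  if (!n) return(list())
  if (sense == "min") points <- -points
  m <- ncol(points)
  # D[i, j] = TRUE iff point i dominates point j (vectorized pairwise test)
  ge_all <- matrix(TRUE, n, n)
  gt_any <- matrix(FALSE, n, n)
  for (k in seq_len(m)) {
    o <- outer(points[, k], points[, k], `>=`)
    ge_all <- ge_all & o
    gt_any <- gt_any | outer(points[, k], points[, k], `>`)
  }
  D <- ge_all & gt_any
  dominated_by <- colSums(D)
  fronts <- list()
  remaining <- rep(TRUE, n)
  while (any(remaining)) {
    front <- which(remaining & dominated_by == 0)
    if (!length(front)) stop("dominance cycle detected (internal error)")
    fronts[[length(fronts) + 1]] <- front
    remaining[front] <- FALSE
    dominated_by <- dominated_by - colSums(D[front, , drop = FALSE])
  }
  fronts
}

#' Crowding distance within one front
#'
#' The NSGA-II diversity measure: per objective, points at the extremes get
#' infinite distance and interior points accumulate the normalized gap between
#' their nearest neighbours; fronts of one or two points are all infinite. A
#' degenerate objective (no spread) contributes zero.
#'
#' @param front Numeric matrix of objective vectors (one row per member).
#' @return Numeric vector of crowding distances.
#' @export
crowding_distance <- function(front) {
  front <- as.matrix(front)
  n <- nrow(front)
  if (!n) stop("front must be non-empty")
  if (n <= 2) return(rep(Inf, n))
  dist <- rep(0, n)
  for (k in seq_len(ncol(front))) {
    rg <- max(front[, k]) - min(front[, k])
    if (rg == 0) next
    ord <- order(front[, k])
    dist[ord[c(1, n)]] <- Inf
    dist[ord[2:(n - 1)]] <- dist[ord[2:(n - 1)]] +
      (front[ord[3:n], k] - front[ord[1:(n - 2)], k]) / rg
  }
  dist
}

#' NSGA-II optimizer configuration
#'
#' Defaults follow the study protocol: population 100, 200 generations,
#' simulated binary crossover at rate 0.9 with distribution index 15,
#' polynomial mutation with distribution index 20, binary tournament
#' selection, and search bounds equal to the experimental dose rectangle.
#'
#' @param population Even population size.
#' @param generations Number of generations.
#' @param crossover_prob SBX probability per mating pair.
#' @param crossover_eta SBX distribution index.
#' @param mutation_eta Polynomial-mutation distribution index.
#' @param mutation_prob Per-variable mutation probability (default `1/nvar`).
#' @param bounds List of per-variable `c(lower, upper)` bounds.
#' @param seed Integer seed.
#' @return An `optimizer_config` list.
#' @export
optimizer_config <- function(population = 100, generations = 200,
                             crossover_prob = 0.9, crossover_eta = 15,
                             mutation_eta = 20, mutation_prob = NULL,
                             bounds = DOSE_BOUNDS, seed) {
  if (population %% 2 != 0) stop("population must be even")
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 crossover_prob = crossover_prob, crossover_eta = crossover_eta,
                 mutation_eta = mutation_eta,
                 mutation_prob = mutation_prob %||% (1 / length(bounds)),
                 bounds = bounds, seed = seed),
            class = "optimizer_config")
}

# Simulated binary crossover (Deb & Agrawal) on a pair of parents; each
# variable crosses with probability 0.5 given the pair was selected.
sbx_pair <- function(p1, p2, eta, lower, upper) {
  c1 <- p1; c2 <- p2
  for (j in seq_along(p1)) {
    if (stats::runif(1) > 0.5 || abs(p1[j] - p2[j]) < 1e-14) next
    x1 <- min(p1[j], p2[j]); x2 <- max(p1[j], p2[j])
    u <- stats::runif(1)
    beta_q <- function(beta) {
      a <- 2 - beta^-(eta + 1)
      if (u <= 1 / a) (u * a)^(1 / (eta + 1)) else (1 / (2 - u * a))^(1 / (eta + 1))
    }
    b1 <- beta_q(1 + 2 * (x1 - lower[j]) / (x2 - x1))
    b2 <- beta_q(1 + 2 * (upper[j] - x2) / (x2 - x1))
    v1 <- 0.5 * ((x1 + x2) - b1 * (x2 - x1))
    v2 <- 0.5 * ((x1 + x2) + b2 * (x2 - x1))
    if (stats::runif(1) < 0.5) { tmp <- v1; v1 <- v2; v2 <- tmp }
    c1[j] <- min(max(v1, lower[j]), upper[j])
    c2[j] <- min(max(v2, lower[j]), upper[j])
  }
  rbind(c1, c2)
}

# Polynomial mutation (Deb) in place.
poly_mutate <- function(x, prob, eta, lower, upper) {
  for (j in seq_along(x)) {
    if (stats::runif(1) >= prob) next
    rg <- upper[j] - lower[j]
    u <- stats::runif(1)
    d1 <- (x[j] - lower[j]) / rg
    d2 <- (upper[j] - x[j]) / rg
    if (u < 0.5) {
      dq <- (2 * u + (1 - 2 * u) * (1 - d1)^(eta + 1))^(1 / (eta + 1)) - 1
    } else {
      dq <- 1 - (2 * (1 - u) + 2 * (u - 0.5) * (1 - d2)^(eta + 1))^(1 / (eta + 1))
    }
    x[j] <- min(max(x[j] + dq * rg, lower[j]), upper[j])
  }
  x
}

#' Run NSGA-II over a box-bounded decision space
#'
#' Evolves real-coded decision vectors (dose pairs, by default) to maximize a
#' vector-valued objective function, with non-dominated sorting, crowding
#' distance truncation, binary tournament selection, SBX crossover and
#' polynomial mutation. The returned rank-1 set is re-verified against this
#' package's own dominance sort.
#'
#' @param objectives Function mapping an n x nvar matrix of decision vectors
#'   to an n x m matrix of objective values (all maximized). See
#'   [surrogate_objectives()] for the surrogate-backed version.
#' @param config An [optimizer_config()].
#' @param trace Record the rank-1 objective values of every generation
#'   (returned as the `trace` attribute).
#' @return A `pareto_front` data.frame: decision variables, objective columns,
#'   `front_rank` (all 1) and `crowding`.
#' @export
run_nsga2 <- function(objectives, config, trace = FALSE) {
  stopifnot(inherits(config, "optimizer_config"))
  lower <- vapply(config$bounds, `[`, numeric(1), 1)
  upper <- vapply(config$bounds, `[`, numeric(1), 2)
  nvar <- length(lower)
  N <- config$population
  # objective evaluations are pure, so exact-duplicate individuals (common
  # once the population converges onto the bounds) are looked up, not re-run
  cache <- new.env(hash = TRUE, parent = emptyenv())
  evaluate <- function(X) {
    if (any(X < matrix(lower, nrow(X), nvar, byrow = TRUE) - 1e-12) ||
        any(X > matrix(upper, nrow(X), nvar, byrow = TRUE) + 1e-12)) {
      stop("individual escaped the decision bounds (internal error)")
    }
    keys <- apply(X, 1, function(r) paste(sprintf("%.15g", r), collapse = ","))
    new_keys <- unique(keys[!vapply(keys, exists, TRUE, envir = cache)])
    if (length(new_keys)) {
      Xn <- X[match(new_keys, keys), , drop = FALSE]
      Yn <- as.matrix(objectives(Xn))
      if (!all(is.finite(Yn))) stop("objective evaluation returned non-finite values")
      cache$.colnames <- colnames(Yn)
      for (i in seq_along(new_keys)) assign(new_keys[i], Yn[i, ], envir = cache)
    }
    Y <- t(vapply(keys, get, numeric(length(get(keys[1], envir = cache))),
                  envir = cache))
    rownames(Y) <- NULL
    colnames(Y) <- cache$.colnames
    Y
  }
  trace_list <- if (trace) vector("list", config$generations) else NULL

  run <- with_seed(substream_seed(config$seed, "nsga2"), function() {
    P <- matrix(stats::runif(N * nvar, rep(lower, each = N), rep(upper, each = N)),
                N, nvar)
    Y <- evaluate(P)
    rank_crowd <- function(Y) {
      fronts <- nondominated_sort(Y, "max")
      rank <- integer(nrow(Y))
      crowd <- numeric(nrow(Y))
      for (i in seq_along(fronts)) {
        rank[fronts[[i]]] <- i
        crowd[fronts[[i]]] <- crowding_distance(Y[fronts[[i]], , drop = FALSE])
      }
      list(rank = rank, crowd = crowd, fronts = fronts)
    }
    rc <- rank_crowd(Y)
    for (gen in seq_len(config$generations)) {
      # binary tournament by crowded comparison
      pick <- function() {
        ij <- sample.int(N, 2)
        i <- ij[1]; j <- ij[2]
        if (rc$rank[i] < rc$rank[j]) i
        else if (rc$rank[j] < rc$rank[i]) j
        else if (rc$crowd[i] >= rc$crowd[j]) i else j
      }
      Q <- matrix(NA_real_, N, nvar)
      for (p in seq_len(N / 2)) {
        a <- P[pick(), ]; b <- P[pick(), ]
        kids <- if (stats::runif(1) < config$crossover_prob) {
          sbx_pair(a, b, config$crossover_eta, lower, upper)
        } else rbind(a, b)
        kids[1, ] <- poly_mutate(kids[1, ], config$mutation_prob,
                                 config$mutation_eta, lower, upper)
        kids[2, ] <- poly_mutate(kids[2, ], config$mutation_prob,
                                 config$mutation_eta, lower, upper)
        Q[2 * p - 1, ] <- kids[1, ]
        Q[2 * p, ] <- kids[2, ]
      }
      YQ <- evaluate(Q)
      R <- rbind(P, Q)
      YR <- rbind(Y, YQ)
      rcR <- rank_crowd(YR)
      keep <- integer(0)
      for (f in rcR$fronts) {
        if (length(keep) + length(f) <= N) {
          keep <- c(keep, f)
        } else {
          room <- N - length(keep)
          if (room > 0) {
            cd <- crowding_distance(YR[f, , drop = FALSE])
            keep <- c(keep, f[order(-cd)][seq_len(room)])
          }
          break
        }
      }
      P <- R[keep, , drop = FALSE]
      Y <- YR[keep, , drop = FALSE]
      rc <- rank_crowd(Y)
      if (trace) trace_list[[gen]] <<- Y[rc$rank == 1, , drop = FALSE]
    }
    list(P = P, Y = Y, rc = rc)
  })

  first <- run$rc$fronts[[1]]
  # post-condition: the returned set is mutually non-dominated per our own sort
  stopifnot(length(nondominated_sort(run$Y[first, , drop = FALSE], "max")) == 1)
  out <- data.frame(run$P[first, , drop = FALSE])
  names(out) <- names(config$bounds)
  obj <- data.frame(run$Y[first, , drop = FALSE])
  if (!is.null(colnames(run$Y))) names(obj) <- colnames(run$Y)
  out <- cbind(out, obj)
  out$front_rank <- 1L
  out$crowding <- crowding_distance(run$Y[first, , drop = FALSE])
  if (trace) attr(out, "trace") <- trace_list
  class(out) <- c("pareto_front", "data.frame")
  out
}

#' Build a maximization objective from per-trait surrogates
#'
#' Wraps four fitted surrogates (one per growth trait) into a single
#' vector-valued objective over raw dose pairs. Survival predictions are
#' clipped to \[0, 100\] before dominance comparison.
#'
#' @param models Named list of fitted `surrogate`s, one per trait
#'   (names are the trait codes).
#' @return Function mapping an n x 2 dose matrix to an n x length(models)
#'   objective matrix.
#' @export
surrogate_objectives <- function(models) {
  force(models)
  function(doses) {
    Y <- vapply(names(models), function(trait) {
      clip_trait(predict(models[[trait]], doses), trait)
    }, numeric(nrow(as.matrix(doses))))
    matrix(Y, nrow = nrow(as.matrix(doses)),
           dimnames = list(NULL, names(models)))
  }
}

#' Select one compromise solution from a Pareto front
#'
#' Normalizes each objective over the front to \[0, 1\] and returns the
#' member closest (Euclidean) to the ideal point (all ones). Ties are broken
#' by the highest crowding distance, then by the lowest decision variables in
#' lexicographic order; a tie is flagged in the result.
#'
#' @param front A `pareto_front` from [run_nsga2()].
#' @param objective_cols Names of the objective columns (defaults to all
#'   columns except the decision variables, `front_rank` and `crowding`).
#' @return A list: `solution` (one-row data.frame), `rule`, `tie`.
#' @export
select_compromise <- function(front, objective_cols = NULL) {
  front <- as.data.frame(front)
  if (!nrow(front)) stop("front must be non-empty")
  meta_cols <- c("front_rank", "crowding")
  dec_cols <- setdiff(names(front), meta_cols)
  objective_cols <- objective_cols %||% setdiff(dec_cols, c("ga3", "zt"))
  dec_cols <- setdiff(dec_cols, objective_cols)
  Y <- as.matrix(front[, objective_cols, drop = FALSE])
  S <- apply(Y, 2, function(col) {
    rg <- max(col) - min(col)
    if (rg == 0) rep(0, length(col)) else (col - min(col)) / rg
  })
  S <- matrix(S, nrow = nrow(front))
  d <- sqrt(rowSums((1 - S)^2))
  best <- which(d == min(d))
  tie <- length(best) > 1
  if (tie) {
    cr <- front$crowding[best] %||% rep(0, length(best))
    best <- best[cr == max(cr)]
    if (length(best) > 1) {
      o <- do.call(order, as.list(front[best, dec_cols, drop = FALSE]))
      best <- best[o[1]]
    }
  }
  list(solution = front[best[1], , drop = FALSE],
       rule = "min-euclidean-distance-to-ideal-point", tie = tie)
}
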