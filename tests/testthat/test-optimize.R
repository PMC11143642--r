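test_that("dominance sorting matches hand-worked and brute-force examples", {
  pts <- rbind(c(2, 2), c(1, 1), c(0, 3))
  fronts <- nondominated_sort(pts, "max")
  expect_equal(fronts[[1]], c(1, 3))
  expect_equal(fronts[[2]], 2)

  # identical points never dominate each other
  same <- matrix(1, 5, 3)
  expect_length(nondominated_sort(same, "max"), 1)

  # minimization is the mirrored problem: (1,1) and (0,3) are non-dominated
  expect_equal(nondominated_sort(pts, "min")[[1]], c(2, 3))

  expect_length(nondominated_sort(matrix(numeric(0), 0, 2)), 0)
})

test_that("sorting and crowding agree with brute-force oracles at random", {
  set.seed(10)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    m <- sample(2:4, 1)
    pts <- matrix(rnorm(n * m), n, m)
    expect_identical(nondominated_sort(pts, "max"), brute_nondominated_sort(pts))
    f1 <- brute_nondominated_sort(pts)[[1]]
    expect_equal(crowding_distance(pts[f1, , drop = FALSE]),
                 brute_crowding(pts[f1, , drop = FALSE]))
  }
})

test_that("crowding distance boundary rules hold", {
  expect_equal(crowding_distance(rbind(c(1, 2), c(2, 1))), c(Inf, Inf))
  d <- crowding_distance(matrix(c(1, 2, 3), 3, 1))
  expect_equal(d, c(Inf, 1, Inf))
  # order invariance up to the permutation
  pts <- matrix(rnorm(24), 8, 3)
  perm <- sample(8)
  expect_equal(crowding_distance(pts)[perm], crowding_distance(pts[perm, ]))
  # degenerate objectives contribute nothing
  expect_equal(crowding_distance(cbind(c(1, 2, 3), c(5, 5, 5))), c(Inf, 1, Inf))
})

test_that("monotone objectives collapse the front onto the dose corner", {
  obj <- function(X) cbind(X[, 1] + X[, 2], 2 * X[, 1] + 0.5 * X[, 2],
                           X[, 1], X[, 2])
  cfg <- optimizer_config(population = 40, generations = 40, seed = 3)
  front <- run_nsga2(obj, cfg)
  # the true Pareto set is the single corner; a finite run gets arbitrarily
  # close but members within mutation noise of it are mutually non-dominated
  expect_true(all(abs(front$ga3 - 0.5) < 0.01))
  expect_true(all(abs(front$zt - 0.75) < 0.01))
  cmp <- select_compromise(front, objective_cols = setdiff(names(front),
                                                           c("ga3", "zt",
                                                             "front_rank",
                                                             "crowding")))
  expect_equal(cmp$solution$ga3, 0.5, tolerance = 0.01)
  expect_equal(cmp$solution$zt, 0.75, tolerance = 0.01)
})

test_that("two conflicting objectives span their analytic Pareto interval", {
  obj <- function(X) cbind(-(X[, 1] - 0.1)^2, -(X[, 1] - 0.4)^2)
  cfg <- optimizer_config(population = 60, generations = 60, seed = 5)
  front <- run_nsga2(obj, cfg)
  # Pareto set of the two concave objectives is ga3 in [0.1, 0.4]
  expect_true(all(front$ga3 > 0.1 - 0.02 & front$ga3 < 0.4 + 0.02))
  expect_lt(min(front$ga3), 0.12)
  expect_gt(max(front$ga3), 0.38)
  # the returned rank-1 set is mutually non-dominated per the brute oracle
  Y <- as.matrix(front[, c("X1", "X2")])
  expect_length(brute_nondominated_sort(Y), 1)
})

test_that("runs are seeded-reproducible and respect the dose bounds", {
  obj <- function(X) {
    expect_true(all(X[, 1] >= 0 & X[, 1] <= 0.5))
    expect_true(all(X[, 2] >= 0 & X[, 2] <= 0.75))
    cbind(sin(9 * X[, 1]), cos(7 * X[, 2]))
  }
  cfg <- optimizer_config(population = 30, generations = 25, seed = 12)
  f1 <- run_nsga2(obj, cfg)
  f2 <- run_nsga2(obj, cfg)
  expect_identical(as.data.frame(f1), as.data.frame(f2))
  expect_error(optimizer_config(population = 31, seed = 1), "even")
})

test_that("hypervolume never decreases over a monitored toy run", {
  obj <- function(X) cbind(-(X[, 1] - 0.1)^2 - 0.1 * X[, 2]^2,
                           -(X[, 1] - 0.4)^2 - 0.1 * (X[, 2] - 0.5)^2)
  cfg <- optimizer_config(population = 60, generations = 30, seed = 8)
  front <- run_nsga2(obj, cfg, trace = TRUE)
  gens <- attr(front, "trace")
  ref <- c(-1, -1)
  hv <- vapply(gens, function(Y) hv_2d(as.matrix(Y), ref), numeric(1))
  # elitist selection keeps the front's hypervolume from regressing beyond
  # crowding-truncation noise, and the run must make net progress
  expect_true(all(diff(hv) >= -1e-3 * max(hv)))
  expect_gt(hv[length(hv)], hv[1])
})

test_that("compromise selection handles singletons, ties, and records its rule", {
  single <- data.frame(ga3 = 0.2, zt = 0.3, A = 1, B = 2,
                       front_rank = 1, crowding = Inf)
  out <- select_compromise(single, objective_cols = c("A", "B"))
  expect_equal(out$solution$ga3, 0.2)
  expect_false(out$tie)
  expect_match(out$rule, "ideal")

  sym <- data.frame(ga3 = c(0.1, 0.4), zt = c(0.2, 0.2),
                    A = c(1, 0), B = c(0, 1),
                    front_rank = 1, crowding = c(Inf, Inf))
  out <- select_compromise(sym, objective_cols = c("A", "B"))
  expect_true(out$tie)
  # equal crowding: the lexicographically lowest doses win
  expect_equal(out$solution$ga3, 0.1)
})
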