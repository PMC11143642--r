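test_that("declared spaces accept boundaries, reject out-of-space values", {
  for (kind in c("XGB", "RF", "SVR", "ENMLR")) {
    space <- hyperparameter_space(kind)
    # random draws are always in-space
    for (p in sample_hyperparams(space, 25, seed = 1)) {
      expect_silent(validate_hyperparams(space, p))
    }
    # closed boundary values accepted
    at_bounds <- lapply(space$dims, function(d) {
      if (d$lower_open) d$upper else d$lower
    })
    expect_silent(validate_hyperparams(space, at_bounds))
    # stepping outside any single dimension is rejected, naming it
    for (d in space$dims) {
      bad <- lapply(space$dims, function(dd) if (dd$lower_open) dd$upper else dd$lower)
      bad[[d$name]] <- d$upper + 1
      expect_error(validate_hyperparams(space, bad), d$name, fixed = TRUE)
    }
  }
  # open lower bounds are exclusive
  expect_error(validate_hyperparams(hyperparameter_space("SVR"),
                                    list(gamma = 0, C = 1, epsilon = 1)),
               "gamma")
  # integer dimensions must be integer-valued
  p <- sample_hyperparams(hyperparameter_space("RF"), 1, seed = 2)[[1]]
  p$max_depth <- 10.5
  expect_error(validate_hyperparams(hyperparameter_space("RF"), p), "max_depth")
})

test_that("unpenalized elastic net reproduces an exact linear relationship", {
  X <- cbind(z1 = runif(25), z2 = runif(25))
  y <- 2 * X[, "z1"] + 1
  m <- fit_surrogate("ENMLR", list(alpha = 0, l1_ratio = 0.3), X, y, seed = 1)
  expect_lt(max(abs(culturopt:::predict_std(m, X) - y)), 1e-6)
})

test_that("a single unrestricted tree memorizes distinct training points", {
  pts <- cbind(a = 1:5 / 5, b = c(0.1, 0.9, 0.4, 0.7, 0.2))
  y <- c(1, 3, 2, 5, 4)
  # one deep tree on the full sample (bagging off); below the declared
  # tree-count range, so space validation is bypassed deliberately
  m <- fit_surrogate("RF", list(n_estimators = 1, max_features = 1,
                                max_depth = 50, min_samples_split = 2,
                                min_samples_leaf = 1,
                                min_weight_fraction_leaf = 0,
                                max_leaf_nodes = 200),
                     pts, y, seed = 3, validate = FALSE,
                     replace = FALSE, sample.fraction = 1)
  expect_equal(culturopt:::predict_std(m, pts), y)
})

test_that("RBF support vector regression recovers a constant target exactly", {
  X <- cbind(x1 = c(0, 0.5, 1), x2 = c(1, 0, 0.5))
  m <- fit_surrogate("SVR", list(gamma = 1, C = 10, epsilon = 0.1), X,
                     rep(4.2, 3), seed = 1)
  expect_equal(culturopt:::predict_std(m, X), rep(4.2, 3))
})

test_that("every family refits identically under the same seed", {
  toy <- toy_regression(n = 70, seed = 5)
  probe <- cbind(ga3 = runif(40, -1, 1), zt = runif(40, -1, 1))
  params <- list(XGB = default_xgb_params(), RF = default_rf_params(),
                 SVR = default_svr_params(), ENMLR = default_enmlr_params())
  for (kind in names(params)) {
    m1 <- fit_surrogate(kind, params[[kind]], toy$X, toy$y, seed = 11)
    m2 <- fit_surrogate(kind, params[[kind]], toy$X, toy$y, seed = 11)
    expect_lt(max(abs(culturopt:::predict_std(m1, probe) -
                      culturopt:::predict_std(m2, probe))), 1e-9)
  }
})

test_that("raw-dose prediction standardizes inputs, is pure, and guards bounds", {
  stats <- load_treatment_stats()
  obs <- generate_observations(stats, seed = 1, n_rep = 20, cultivars = "Atabaki")
  std <- fit_standardizer(obs)
  Z <- standardize(as.matrix(obs[, std$features]), std)
  m <- fit_surrogate("ENMLR", list(alpha = 0.1, l1_ratio = 0.5), Z, obs$SL_cm,
                     seed = 1, standardizer = std, trait = "SL")
  doses <- rbind(c(0.3, 0.6), c(0.3, 0.6))
  p <- predict(m, doses)
  expect_length(p, 2)
  expect_identical(p[1], p[2])
  # bounds enforced unless extrapolation is explicit
  expect_error(predict(m, rbind(c(0.7, 0.2))), "bounds")
  expect_silent(predict(m, rbind(c(0.7, 0.2)), extrapolate = TRUE))
  # survival predictions are clipped at report time over a dose grid
  mes <- fit_surrogate("ENMLR", list(alpha = 0, l1_ratio = 0), Z, obs$ES_pct,
                       seed = 1, standardizer = std, trait = "ES")
  grid <- as.matrix(expand.grid(ga3 = seq(0, 0.5, length.out = 21),
                                zt = seq(0, 0.75, length.out = 21)))
  clipped <- culturopt:::clip_trait(predict(mes, grid), "ES")
  expect_true(all(clipped >= 0 & clipped <= 100))
})

test_that("stacking builds a 3-column out-of-fold meta set with no leakage", {
  toy <- toy_regression(n = 60, seed = 2)
  folds <- culturopt:::make_folds(60, 5, seed = 4)
  esr <- fit_stacking(toy$X, toy$y, folds, default_base_params(),
                      default_rf_params(), seed = 8)
  expect_equal(dim(esr$oof), c(60L, 3L))
  expect_equal(colnames(esr$oof), c("XGB", "SVR", "ENMLR"))
  expect_false(anyNA(esr$oof))

  # leakage audit: recompute one fold's column from a fit that excluded it
  # and check it matches what the stacking stored
  k <- 3
  hold <- folds == k
  refit <- fit_surrogate("XGB", default_base_params()$XGB,
                         toy$X[!hold, ], toy$y[!hold],
                         seed = substream_seed(8, "oof", "XGB", k))
  expect_equal(esr$oof[hold, "XGB"],
               culturopt:::predict_std(refit, toy$X[hold, ]))
  # and it must differ from full-data (leaky) predictions
  leaky <- culturopt:::predict_std(esr$bases$XGB, toy$X[hold, ])
  expect_gt(max(abs(esr$oof[hold, "XGB"] - leaky)), 1e-8)
})

test_that("stacking equals the meta-regressor applied to base predictions", {
  toy <- toy_regression(n = 60, seed = 3)
  folds <- culturopt:::make_folds(60, 5, seed = 4)
  esr <- fit_stacking(toy$X, toy$y, folds, default_base_params(),
                      default_rf_params(), seed = 9)
  probe <- cbind(runif(15, -1, 1), runif(15, -1, 1))
  Z <- cbind(XGB = culturopt:::predict_std(esr$bases$XGB, probe),
             SVR = culturopt:::predict_std(esr$bases$SVR, probe),
             ENMLR = culturopt:::predict_std(esr$bases$ENMLR, probe))
  expect_equal(culturopt:::predict_std(esr, probe),
               culturopt:::predict_std(esr$meta, Z))
})

test_that("a memorizing meta-regressor returns the bases' consensus", {
  # if all bases agree and the meta forest memorizes its training set, the
  # ensemble passes the consensus through
  n <- 40
  X <- cbind(x = seq(0, 1, length.out = n), z = rep(0:1, n / 2))
  y <- 5 + 3 * X[, "x"]
  folds <- culturopt:::make_folds(n, 5, seed = 1)
  bp <- list(XGB = default_xgb_params(), SVR = default_svr_params(),
             ENMLR = list(alpha = 0, l1_ratio = 0))
  meta_memorize <- list(n_estimators = 10, max_features = 1, max_depth = 50,
                        min_samples_split = 2, min_samples_leaf = 1,
                        min_weight_fraction_leaf = 0, max_leaf_nodes = 200)
  esr <- fit_stacking(X, y, folds, bp, meta_memorize, seed = 2,
                      replace = FALSE, sample.fraction = 1)
  # consensus case at a training point: all three bases reproduce a linear
  # target closely, so the stacked prediction stays near it too
  p_bases <- sapply(esr$bases, function(b) culturopt:::predict_std(b, X[10, , drop = FALSE]))
  expect_lt(diff(range(p_bases)), 0.35)
  p <- culturopt:::predict_std(esr, X[10, , drop = FALSE])
  expect_lt(abs(p - y[10]), 0.35)
})

test_that("surrogates persist as manifest plus blob and restore intact", {
  toy <- toy_regression(n = 40, seed = 4)
  m <- fit_surrogate("XGB", default_xgb_params(), toy$X, toy$y, seed = 6,
                     trait = "SL", cultivar = "Atabaki")
  base <- file.path(withr::local_tempdir(), "model")
  save_surrogate(m, base)
  manifest <- jsonlite::read_json(paste0(base, ".json"))
  expect_equal(manifest$kind, "XGB")
  expect_equal(manifest$seed, 6)
  back <- load_surrogate(base)
  probe <- toy$X[1:10, ]
  expect_equal(culturopt:::predict_std(back, probe),
               culturopt:::predict_std(m, probe))
  # a blob/manifest mismatch is refused
  m2 <- fit_surrogate("XGB", default_xgb_params(), toy$X, toy$y, seed = 7)
  saveRDS(m2, paste0(base, ".rds"))
  expect_error(load_surrogate(base), "manifest does not match")
})

test_that("stacking failures name the failing base", {
  toy <- toy_regression(n = 30, seed = 6)
  bp <- default_base_params()
  bp$SVR$gamma <- NA_real_
  expect_error(fit_stacking(toy$X, toy$y, culturopt:::make_folds(30, 3, 1),
                            bp, default_rf_params(), seed = 1),
               "base SVR")
})
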