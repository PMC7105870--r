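test_that("near-zero-variance flagging follows the unique/ratio rule", {
  expect_true(flag_near_zero_variance(rep(1, 96)))
  expect_false(flag_near_zero_variance(rnorm(96)))
  expect_false(flag_near_zero_variance(c(rep(0, 95), rep(1, 5))))  # ratio 19
  expect_true(flag_near_zero_variance(c(rep(0, 96), rep(1, 4))))   # ratio 24
  expect_error(flag_near_zero_variance(numeric(0)), "non-empty")
})

test_that("correlation removal leaves no pair at or above the threshold", {
  withr::with_seed(50, {
    x <- rnorm(60)
    X2 <- cbind(a = x, b = x)
    rc <- remove_correlated(X2, 0.7)
    expect_length(rc$kept, 1)
    expect_length(rc$removed, 1)

    Xi <- matrix(rnorm(60 * 6), 60, 6,
                 dimnames = list(NULL, paste0("g", 1:6)))
    rci <- remove_correlated(Xi, 0.7)
    expect_length(rci$removed, 0)
  })
  X <- planted_feature_matrix(77)
  rc <- remove_correlated(X, 0.7)
  C <- abs(cor(X[, rc$kept]))
  diag(C) <- 0
  expect_lt(max(C), 0.7)  # exhaustive pair scan
})

test_that("VIFs match their definition and catch collinearity", {
  withr::with_seed(51, {
    n <- 400
    X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("v", 1:5)))
    v <- compute_vif(X)
    expect_true(all(v < 2))
    # independent oracle: diagonal of the inverse correlation matrix
    expect_equal(unname(v), unname(diag(solve(cor(X)))), tolerance = 1e-8)

    Xc <- cbind(X, v6 = X[, 1] + X[, 2] + rnorm(n, 0, 1e-3))
    expect_gt(max(compute_vif(Xc)), 10)

    Xr <- cbind(X, v6 = X[, 1] + X[, 2])
    expect_error(compute_vif(Xr), "rank deficient")
  })
})

test_that("the elastic net hits its analytic limits", {
  withr::with_seed(52, {
    X <- matrix(rnorm(20 * 5), 20, 5, dimnames = list(NULL, paste0("f", 1:5)))
    y <- 2 * X[, 1] - X[, 3] + rnorm(20, 0.3)

    big <- elastic_net_fit(X, y, alpha = 0.5, lambda = 1e4)
    expect_true(all(big$coefficients == 0))

    f0 <- elastic_net_fit(X, y, alpha = 0.5, lambda = 0)
    ols <- coef(lm(y ~ X))
    expect_lt(max(abs(c(f0$intercept, f0$coefficients) - ols)), 1e-6)

    expect_error(elastic_net_fit(X, y, alpha = 2, lambda = 1), "alpha")
    expect_error(elastic_net_fit(X, y, alpha = 1, lambda = -1), "lambda")
  })
})

test_that("the solver minimizes its objective and shrinks monotonically", {
  withr::with_seed(53, {
    X <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, paste0("f", 1:6)))
    y <- X[, 2] - 0.5 * X[, 5] + rnorm(40, 0, 0.5)
    ols <- coef(lm(y ~ X))
    for (alpha in c(0.2, 1)) {
      l1_prev <- Inf
      for (lambda in c(0.01, 0.05, 0.2, 1)) {
        f <- elastic_net_fit(X, y, alpha, lambda)
        obj <- enet_objective(X, y, f$intercept, f$coefficients, alpha, lambda)
        obj_zero <- enet_objective(X, y, mean(y), rep(0, 6), alpha, lambda)
        obj_ols <- enet_objective(X, y, ols[1], ols[-1], alpha, lambda)
        expect_lte(obj, obj_zero + 1e-10)
        expect_lte(obj, obj_ols + 1e-10)
        l1 <- sum(abs(f$coefficients))
        expect_lte(l1, l1_prev + 1e-8)
        l1_prev <- l1
      }
    }
  })
})

test_that("inner selection returns sane alpha/lambda choices", {
  withr::with_seed(54, {
    X <- matrix(rnorm(80 * 10), 80, 10, dimnames = list(NULL, paste0("f", 1:10)))
    y <- 3 * X[, 2] + 2 * X[, 7] + rnorm(80, 0, 0.5)

    one <- enet_config(alpha_grid = 0.35, n_inner_reps = 3, seed = 9)
    sel1 <- inner_select_alpha(X, y, one)
    expect_equal(sel1$alpha, 0.35)

    hits <- 0
    for (s in 1:10) {
      cfg <- enet_config(n_inner_reps = 3, seed = s)
      sel <- inner_select_alpha(X, y, cfg)
      fit <- elastic_net_fit(X, y, sel$alpha, sel$lambda)
      if (all(c("f2", "f7") %in% fit$selected)) hits <- hits + 1
    }
    expect_gte(hits, 9)

    expect_error(inner_select_alpha(X[1:12, ], y[1:12],
                                    enet_config(n_inner_folds = 10)),
                 "too few")
  })
})

test_that("the outer protocol is reproducible and sized as configured", {
  coup <- scale_coupling(beta_cv_awakenings = 0, noise_sd = 2)
  ft <- simulate_feature_table(60, seed = 2, coupling = coup)
  pp <- preprocess_features(ft$X)
  cfg <- enet_config(n_inner_reps = 2, n_outer_reps = 1, seed = 3)
  one <- outer_protocol(pp$X, ft$y, ft$participant_id, cfg)
  expect_equal(nrow(one$records), 1)

  cfg3 <- enet_config(n_inner_reps = 2, n_outer_reps = 3, seed = 3)
  a <- outer_protocol(pp$X, ft$y, ft$participant_id, cfg3)
  b <- outer_protocol(pp$X, ft$y, ft$participant_id, cfg3)
  expect_identical(a$records, b$records)
  expect_identical(a$selected, b$selected)

  # participant-level splits keep all visits of a participant together
  expect_true(all(table(ft$participant_id) <= 2))
})

test_that("feature importance follows the weighted selection formula", {
  fake <- structure(list(
    records = data.frame(s = 1:100, alpha = 1, lambda = 0.1, mse = 1,
                         r2 = 0.5, f_p = 0.01, f_sig = 1L, n_test = 10),
    selected = cbind(a = rep(1L, 100), b = rep(0L, 100),
                     c = rep(c(1L, 0L), 50)),
    features = c("a", "b", "c"),
    config = enet_config(n_outer_reps = 100)),
    class = "importance_result")
  im <- feature_importance(fake)
  expect_equal(im$raw[im$feature == "a"], 0.5)
  expect_equal(im$raw[im$feature == "b"], 0)
  expect_equal(im$raw[im$feature == "c"], 0.25)
  expect_equal(im$normalized, c(1, 0, 0.5))

  fake$records$f_sig <- 0L
  im0 <- feature_importance(fake)
  expect_true(all(im0$raw == 0))
  expect_true(attr(im0, "all_zero"))
  expect_true(all(im0$normalized == 0))
})

test_that("importance stays within its bounds on a real protocol run", {
  coup <- scale_coupling(beta_cv_awakenings = 0, noise_sd = 2)
  ft <- simulate_feature_table(60, seed = 6, coupling = coup)
  pp <- preprocess_features(ft$X)
  cfg <- enet_config(n_inner_reps = 2, n_outer_reps = 5, seed = 11)
  pr <- outer_protocol(pp$X, ft$y, ft$participant_id, cfg)
  im <- feature_importance(pr)
  expect_true(all(im$raw >= 0))
  expect_true(all(im$raw <= max(pmax(pr$records$r2, 0)) + 1e-12))
  expect_true(all(im$normalized >= 0 & im$normalized <= 1))
})
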