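# Simulated repeated-measures data with a known standardized slope: the
# variance budget (slope^2 + random-intercept + residual = 1) keeps the
# response at unit variance so the fitted standardized coefficient targets
# `slope` directly.
sim_mixed <- function(n_participants, slope, tau = NULL, sigma = 0.5,
                      visits = 2) {
  tau <- tau %||% sqrt(max(1 - slope^2 - sigma^2, 0.1))
  id <- rep(seq_len(n_participants), each = visits)
  u <- rnorm(n_participants, 0, tau)[id]
  x <- rnorm(n_participants * visits)
  y <- slope * x + u + rnorm(n_participants * visits, 0, sigma)
  data.frame(y = y, x = x, age = rnorm(n_participants * visits, 12, 4),
             sex = rbinom(n_participants * visits, 1, 0.7),
             iq = rnorm(n_participants * visits, 100, 15),
             id = as.character(id))
}

test_that("the mixed model flags degenerate designs", {
  withr::with_seed(42, {
    d <- sim_mixed(40, 0.5)
    d1 <- d[!duplicated(d$id), ]  # one visit each: no random effect possible
    r <- fit_scale_on_actigraphy(d1$y, d1$x, d1$age, d1$sex, d1$iq, d1$id)
    expect_true(r$degenerate)
    expect_true(is.finite(r$estimate))

    expect_error(fit_scale_on_actigraphy(rep(1, nrow(d)), d$x, d$age, d$sex,
                                         d$iq, d$id),
                 "constant")
    expect_error(fit_scale_on_actigraphy(d$y[1:2], d$x[1:2], d$age[1:2],
                                         d$sex[1:2], d$iq[1:2], c("a", "a")),
                 "participants")
  })
})

test_that("with no between-participant variance the fit approaches OLS", {
  withr::with_seed(43, {
    d <- sim_mixed(500, 0.5, tau = 0, sigma = 0.5)
    r <- fit_scale_on_actigraphy(d$y, d$x, d$age, d$sex, d$iq, d$id)
    zs <- function(v) (v - mean(v)) / sd(v)
    sdf <- data.frame(y = zs(d$y), x = zs(d$x), age = zs(d$age),
                      sex = zs(d$sex), iq = zs(d$iq))
    ols <- coef(lm(y ~ x + age + sex + iq, sdf))[["x"]]
    expect_lt(abs(r$estimate - ols), 1e-2)
  })
})

test_that("BH adjustment matches the hand-traced example and q >= p", {
  expect_equal(as.vector(bh_adjust(0.01)), 0.01)
  expect_equal(as.vector(bh_adjust(c(0.01, 0.04, 0.03))),
               c(0.03, 0.04, 0.04))
  expect_equal(as.vector(bh_adjust(rep(1, 5))), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  withr::with_seed(44, {
    for (i in 1:20) {
      p <- runif(sample(1:30, 1))
      q <- as.vector(bh_adjust(p))
      expect_true(all(q >= p - 1e-15))
    }
  })
})

test_that("partial Spearman reduces to Spearman and respects covariates", {
  withr::with_seed(45, {
    x <- rnorm(50)
    y <- 0.5 * x + rnorm(50)
    r0 <- partial_spearman(x, y)
    expect_equal(r0$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)

    mono <- partial_spearman(x, exp(x) + 5)
    expect_equal(mono$rho, 1)

    z <- rnorm(80)
    xz <- 2 * z + rnorm(80, 0, 0.05)
    yz <- -3 * z + rnorm(80, 0, 0.05)
    rz <- partial_spearman(xz, yz, covariates = data.frame(z = z))
    # brute-force oracle: residualize ranks on the covariate ranks explicitly
    rrx <- resid(lm(rank(xz) ~ rank(z)))
    rry <- resid(lm(rank(yz) ~ rank(z)))
    expect_equal(rz$rho, cor(rrx, rry), tolerance = 1e-12)
    expect_lt(abs(rz$rho), 0.2)

    expect_error(partial_spearman(1:3, 1:3), "at least 4")
    cons <- partial_spearman(rep(1, 10), rnorm(10))
    expect_true(is.na(cons$rho))
  })
})

test_that("group comparison is calibrated, powered, and confounder-adjusted", {
  withr::with_seed(46, {
    rej <- vapply(1:400, function(i) {
      g <- c(rep("ASD", 50), rep("TD", 20))
      s <- rnorm(70)
      compare_groups_linear(s, g, rbinom(70, 1, 0.5), rnorm(70, 12, 4))$p_value < 0.05
    }, TRUE)
    expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 400))

    big <- vapply(1:100, function(i) {
      g <- c(rep("ASD", 100), rep("TD", 30))
      s <- rnorm(130) + 2 * (g == "ASD")
      compare_groups_linear(s, g, rbinom(130, 1, 0.5), rnorm(130, 12, 4))$p_value
    }, 0)
    expect_gte(mean(big < 0.001), 0.99)

    # age drives the scale; group is imbalanced in age but has no effect
    age <- c(rnorm(150, 10, 2), rnorm(150, 16, 2))
    g <- rep(c("ASD", "TD"), each = 150)
    s <- 0.5 * age + rnorm(300, 0, 0.5)
    r <- compare_groups_linear(s, g, rbinom(300, 1, 0.5), age)
    expect_lt(abs(r$estimate), 0.25)
    expect_error(compare_groups_linear(s, rep("ASD", 300),
                                       rbinom(300, 1, 0.5), age),
                 "two non-empty groups")
  })
})

test_that("the chi-squared comparison matches the closed form", {
  same <- compare_proportions_chisq(c(rep(TRUE, 5), rep(FALSE, 5)),
                                    c(rep(TRUE, 10), rep(FALSE, 10)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  fa <- c(rep(TRUE, 4), rep(FALSE, 30))
  fb <- c(rep(TRUE, 47), rep(FALSE, 21))
  got <- compare_proportions_chisq(fa, fb)
  # closed-form Pearson chi-squared on the 2x2 table
  tab <- matrix(c(4, 30, 47, 21), 2, byrow = TRUE)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(got$statistic, sum((tab - E)^2 / E))

  expect_equal(flag_sleep_problem(c(0, 1, 2, 3, 4, 7)),
               c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_error(compare_proportions_chisq(rep(TRUE, 5), rep(TRUE, 5)),
               "margins")
})
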