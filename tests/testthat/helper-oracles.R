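# Independent oracles used across tests. These deliberately avoid the code
# paths they check.

# Hand-spelled minute score: the printed coefficients applied term by term.
oracle_minute_score <- function(w) {
  0.0033 * (1.06 * w[1] + 0.54 * w[2] + 0.58 * w[3] + 0.76 * w[4] +
              2.3 * w[5] + 0.74 * w[6] + 0.67 * w[7])
}

# Awakening counter on an S/W character vector: wake runs flanked by sleep
# on both sides, counted via regex on the collapsed string.
oracle_awakenings <- function(seg_sw) {
  s <- paste(ifelse(seg_sw == "sleep", "S", "W"), collapse = "")
  m <- gregexpr("(?<=S)W+(?=S)", s, perl = TRUE)[[1]]
  if (m[1] == -1) 0L else length(m)
}

oracle_efficiency <- function(seg_sw) {
  100 * mean(seg_sw == "sleep")
}

# Brute-force BH step-up: q_(i) = min_{j >= i} (m / j) p_(j), capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, m / i * p[o[i]])
    q[o[i]] <- min(running, 1)
  }
  q
}

# Elastic-net objective on original-scale data given a fit's standardized
# view: evaluated directly from the definition.
enet_objective <- function(X, y, intercept, beta, alpha, lambda) {
  st_x <- sqrt(colMeans(X^2) - colMeans(X)^2)
  b_std <- beta * st_x  # penalty applies on the standardized scale
  n <- nrow(X)
  rss <- sum((y - intercept - as.vector(X %*% beta))^2)
  rss / (2 * n) + lambda * sum((1 - alpha) / 2 * b_std^2 + alpha * abs(b_std))
}

# Seeded 96 x 17 feature matrix with planted correlated pairs (r = 0.9):
# 14 independent Gaussian columns, plus noisy copies of the first three.
planted_feature_matrix <- function(seed, n = 96, r = 0.9) {
  withr::with_seed(seed, {
    Z <- matrix(rnorm(n * 14), n, 14)
    planted <- sapply(1:3, function(j) r * Z[, j] + sqrt(1 - r^2) * rnorm(n))
    X <- cbind(Z, planted)
    colnames(X) <- paste0("f", seq_len(ncol(X)))
    X
  })
}

random_labels <- function(n, p_sleep = 0.7) {
  ifelse(runif(n) < p_sleep, "sleep", "wake")
}
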