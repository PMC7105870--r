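# Anxiety prediction: feature assembly, near-zero-variance / correlation /
# VIF preprocessing, elastic-net fitting (coordinate descent, compiled), and
# the repeated nested cross-validation protocol with its
# goodness-of-fit-weighted feature-importance score.

#' Assemble the 17-column predictor table
#'
#' Joins window summaries (12 actigraphy statistics: mean/SD/CV of sleep
#' start, age-adjusted duration, awakenings, efficiency), the caregiver sleep
#' item, and age, sex (0/1), IQ, and ADOS severity, with the anxiety total as
#' response. Rows with any missing value are dropped (complete-case) and
#' counted.
#'
#' @param windows included window summaries ([build_window_summaries()]).
#' @param abi per participant-visit data.frame with `abi_sleep`.
#' @param scales per participant-visit scale table with `casi_anx`.
#' @param profiles profile table (age, sex, iq, ados_css).
#' @return list(X, y, participant_id, n_dropped); X is an N x 17 matrix.
#' @export
assemble_feature_table <- function(windows, abi, scales, profiles) {
  w <- windows[windows$included, , drop = FALSE]
  dat <- merge(w, abi, by = c("participant_id", "visit"))
  dat <- merge(dat, scales[, c("participant_id", "visit", "casi_anx")],
               by = c("participant_id", "visit"))
  dat <- merge(dat,
               profiles[, c("participant_id", "age", "sex", "iq", "ados_css")],
               by = "participant_id")
  dat$sex <- as.integer(dat$sex == "male")
  feat_cols <- c(as.vector(outer(iiv_measures, c("mean", "sd", "cv"),
                                 function(m, s) paste(m, s, sep = "_"))),
                 "abi_sleep", "age", "sex", "iq", "ados_css")
  need <- c(feat_cols, "casi_anx")
  ok <- complete.cases(dat[, need])
  n_dropped <- sum(!ok)
  dat <- dat[ok, , drop = FALSE]
  list(X = as.matrix(dat[, feat_cols]), y = dat$casi_anx,
       participant_id = dat$participant_id, n_dropped = n_dropped)
}

#' Near-zero-variance flag for one feature column
#'
#' Flagged when the fraction of unique values is below 10% of the sample
#' count AND the most-frequent to second-most-frequent value ratio exceeds 19
#' (strictly). A single-valued column is flagged (the second frequency is 0,
#' so the ratio is infinite).
#'
#' @param feature_column values of one predictor.
#' @param n_samples total sample count (defaults to the column length).
#' @return logical.
#' @export
flag_near_zero_variance <- function(feature_column,
                                    n_samples = length(feature_column)) {
  if (!length(feature_column)) stop("column must be non-empty")
  tab <- sort(table(feature_column), decreasing = TRUE)
  unique_frac <- length(tab) / n_samples
  ratio <- if (length(tab) == 1) Inf else tab[[1]] / tab[[2]]
  unique_frac < 0.10 && ratio > 19
}

#' Iteratively remove correlated predictors
#'
#' Repeatedly finds the pair with the largest absolute correlation at or
#' above the threshold and drops the member with the larger mean absolute
#' correlation to all other features (earlier column on ties), until every
#' pairwise absolute correlation is below the threshold.
#'
#' @param X numeric matrix/data.frame with >= 2 named columns.
#' @param threshold pairwise |correlation| ceiling (default 0.7).
#' @return list(kept, removed) of column names.
#' @export
remove_correlated <- function(X, threshold = 0.7) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("at least 2 features are required")
  keep <- colnames(X)
  removed <- character()
  C <- abs(cor(X))
  diag(C) <- 0
  while (ncol(C) > 1 && max(C) >= threshold) {
    pair <- which(C == max(C), arr.ind = TRUE)[1, ]
    i <- min(pair); j <- max(pair)
    mi <- mean(C[i, -i]); mj <- mean(C[j, -j])
    drop <- if (mi >= mj) i else j  # ties drop the earlier column
    removed <- c(removed, rownames(C)[drop])
    C <- C[-drop, -drop, drop = FALSE]
  }
  list(kept = rownames(C) %||% keep, removed = removed)
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j) from the least-squares regression of feature j on
#' all other features.
#'
#' @param X numeric matrix/data.frame with >= 2 named columns of full column
#'   rank (after adding an intercept).
#' @return named numeric vector of VIFs.
#' @export
compute_vif <- function(X) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 2) stop("at least 2 features are required")
  M <- cbind(1, X)
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    bad <- colnames(M)[qrM$pivot[seq.int(qrM$rank + 1, ncol(M))]]
    stop("feature matrix is rank deficient; collinear set: ",
         paste(bad, collapse = ", "))
  }
  vif <- vapply(seq_len(p), function(j) {
    fit <- lm(X[, j] ~ X[, -j, drop = FALSE])
    r2 <- summary(fit)$r.squared
    1 / (1 - r2)
  }, 0)
  setNames(vif, colnames(X))
}

#' Full preprocessing chain
#'
#' Near-zero-variance flagging, iterative decorrelation, then a VIF audit.
#' If any retained feature still has VIF at or above the threshold, the
#' largest-VIF feature is dropped and VIFs recomputed until all pass (in
#' practice the decorrelation step already guarantees this).
#'
#' @param X numeric feature matrix with named columns.
#' @param cor_threshold pairwise |correlation| ceiling (default 0.7).
#' @param vif_threshold VIF ceiling (default 10).
#' @return list(X, kept, removed_nzv, removed_cor, removed_vif, vif).
#' @export
preprocess_features <- function(X, cor_threshold = 0.7, vif_threshold = 10) {
  X <- as.matrix(X)
  nzv <- vapply(colnames(X), function(cn) flag_near_zero_variance(X[, cn]), TRUE)
  removed_nzv <- colnames(X)[nzv]
  X <- X[, !nzv, drop = FALSE]
  rc <- remove_correlated(X, cor_threshold)
  X <- X[, rc$kept, drop = FALSE]
  removed_vif <- character()
  vif <- compute_vif(X)
  while (max(vif) >= vif_threshold && ncol(X) > 2) {
    drop <- names(which.max(vif))
    removed_vif <- c(removed_vif, drop)
    X <- X[, setdiff(colnames(X), drop), drop = FALSE]
    vif <- compute_vif(X)
  }
  list(X = X, kept = colnames(X), removed_nzv = removed_nzv,
       removed_cor = rc$removed, removed_vif = removed_vif, vif = vif)
}

# ---- elastic net -----------------------------------------------------------

# 1/N-variance standardization shared by the solver wrappers.
std_fit <- function(X, y) {
  n <- nrow(X)
  xm <- colMeans(X)
  xs <- sqrt(colMeans(X^2) - xm^2)
  xs[xs == 0] <- 1
  Xs <- sweep(sweep(X, 2, xm), 2, xs, "/")
  ym <- mean(y)
  list(Xs = Xs, yc = y - ym, xm = xm, xs = xs, ym = ym, n = n)
}

#' Lambda path for the elastic net
#'
#' 100 log-spaced values from the smallest lambda that shrinks every
#' coefficient to zero (`max |x_j'y| / (N * max(alpha, 0.001))` on the
#' standardized scale) down four decades.
#'
#' @param X,y raw predictors and response.
#' @param alpha elastic-net mixing parameter in \[0, 1\].
#' @param nlambda path length (default 100).
#' @param lambda_min_ratio smallest/largest lambda (default 1e-4).
#' @return decreasing numeric vector.
#' @export
enet_lambda_path <- function(X, y, alpha, nlambda = 100,
                             lambda_min_ratio = 1e-4) {
  st <- std_fit(as.matrix(X), y)
  lmax <- max(abs(crossprod(st$Xs, st$yc))) / st$n / max(alpha, 0.001)
  if (lmax <= 0) lmax <- 1
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
}

#' Elastic-net fit at a fixed (alpha, lambda)
#'
#' Minimizes `(1/2N) sum_i (y_i - b0 - x_i'b)^2 + lambda * sum_j ((1-alpha)/2
#' b_j^2 + alpha |b_j|)` by cyclic coordinate descent, warm-started along a
#' short path from the all-zero lambda down to the requested one.
#' Standardization (1/N variance) and response centering happen internally;
#' coefficients are returned on the original scale with the transforms
#' attached.
#'
#' @param X numeric predictor matrix.
#' @param y numeric response.
#' @param alpha mixing parameter in \[0, 1\].
#' @param lambda penalty level (>= 0).
#' @param tol,maxit coordinate-descent convergence controls.
#' @return list(intercept, coefficients, selected, alpha, lambda,
#'   transforms).
#' @export
elastic_net_fit <- function(X, y, alpha, lambda, tol = 1e-10, maxit = 100000) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (lambda < 0) stop("lambda must be non-negative")
  X <- as.matrix(X)
  st <- std_fit(X, y)
  lmax <- max(abs(crossprod(st$Xs, st$yc))) / st$n / max(alpha, 0.001)
  if (lambda >= lmax && alpha > 0) {
    path <- lambda
  } else {
    lo <- max(lambda, lmax * 1e-6)
    path <- exp(seq(log(lmax), log(lo), length.out = 25))
    if (lambda < lo) path <- c(path, lambda)
  }
  B <- .cd_enet_path(st$Xs, st$yc, alpha, path, tol, maxit)
  b_std <- B[, ncol(B)]
  beta <- b_std / st$xs
  names(beta) <- colnames(X)
  intercept <- st$ym - sum(beta * st$xm)
  list(intercept = intercept, coefficients = beta,
       selected = names(beta)[beta != 0], alpha = alpha, lambda = lambda,
       transforms = list(x_center = st$xm, x_scale = st$xs,
                         y_center = st$ym))
}

#' Nested-CV configuration
#'
#' Defaults follow the full protocol: a 0-to-1 alpha grid in steps of 0.05,
#' 10-fold inner cross-validation repeated 100 times, 100 outer 70/30
#' splits, and the minimum-CV-MSE lambda rule.
#'
#' @param alpha_grid candidate mixing parameters.
#' @param n_inner_folds inner CV folds.
#' @param n_inner_reps inner CV repetitions per alpha.
#' @param n_outer_reps outer train/test splits.
#' @param train_fraction outer training fraction.
#' @param lambda_rule "min_mse" or "min_mse_plus_1se".
#' @param nlambda,lambda_min_ratio lambda path controls.
#' @param split_unit "participant" (all visits of a participant on one side)
#'   or "row".
#' @param categorical columns whose classes must appear on both sides of a
#'   split (resplit otherwise).
#' @param importance_denom denominator S of the importance sum (defaults to
#'   `n_outer_reps`).
#' @param seed integer seed governing all protocol randomness.
#' @return config list.
#' @export
enet_config <- function(alpha_grid = seq(0, 1, by = 0.05),
                        n_inner_folds = 10, n_inner_reps = 100,
                        n_outer_reps = 100, train_fraction = 0.70,
                        lambda_rule = c("min_mse", "min_mse_plus_1se"),
                        nlambda = 100, lambda_min_ratio = 1e-4,
                        split_unit = c("participant", "row"),
                        categorical = "sex", importance_denom = NULL,
                        seed = 1) {
  stopifnot(all(alpha_grid >= 0 & alpha_grid <= 1), n_inner_folds >= 2,
            train_fraction > 0, train_fraction < 1)
  list(alpha_grid = sort(alpha_grid), n_inner_folds = n_inner_folds,
       n_inner_reps = n_inner_reps, n_outer_reps = n_outer_reps,
       train_fraction = train_fraction, lambda_rule = match.arg(lambda_rule),
       nlambda = nlambda, lambda_min_ratio = lambda_min_ratio,
       split_unit = match.arg(split_unit), categorical = categorical,
       importance_denom = importance_denom %||% n_outer_reps, seed = seed)
}

#' Inner alpha/lambda selection by repeated 10-fold cross-validation
#'
#' For each alpha on the grid, runs `n_inner_reps` repetitions of K-fold CV
#' over the lambda path (fold assignments shared across alphas within a
#' repetition), records each repetition's minimum CV MSE, and averages
#' across repetitions; the alpha with the smallest averaged minimum wins
#' (smallest alpha on ties). Lambda at the winning alpha follows
#' `lambda_rule` on the repetition-averaged CV curve.
#'
#' @param X,y training data.
#' @param config see [enet_config()].
#' @param seed overrides `config$seed` (used by the outer protocol).
#' @return list(alpha, lambda, criterion, cv_curve, lambda_path).
#' @export
inner_select_alpha <- function(X, y, config = enet_config(), seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  K <- config$n_inner_folds
  if (n < 2 * K) stop("too few training rows for ", K, "-fold CV")
  seed <- seed %||% config$seed
  foldid <- with_seed(seed, {
    vapply(seq_len(config$n_inner_reps),
           function(r) sample(rep_len(seq_len(K), n)), integer(n))
  })
  crit <- numeric(length(config$alpha_grid))
  curves <- vector("list", length(config$alpha_grid))
  paths <- vector("list", length(config$alpha_grid))
  for (a in seq_along(config$alpha_grid)) {
    alpha <- config$alpha_grid[a]
    lam <- enet_lambda_path(X, y, alpha, config$nlambda,
                            config$lambda_min_ratio)
    mse <- .cd_enet_cv(X, y, alpha, lam, foldid, K)
    crit[a] <- mean(apply(mse, 2, min))
    curves[[a]] <- mse
    paths[[a]] <- lam
  }
  best <- which.min(crit)  # first minimum = smallest alpha on ties
  mse <- curves[[best]]
  lam <- paths[[best]]
  mean_curve <- rowMeans(mse)
  i_min <- which.min(mean_curve)
  lambda_star <- if (config$lambda_rule == "min_mse") {
    lam[i_min]
  } else {
    se <- sd(mse[i_min, ]) / sqrt(ncol(mse))
    max(lam[mean_curve <= mean_curve[i_min] + se])
  }
  list(alpha = config$alpha_grid[best], lambda = lambda_star,
       criterion = setNames(crit, config$alpha_grid),
       cv_curve = mean_curve, lambda_path = lam)
}

split_participants <- function(participant_id, train_fraction, X, categorical,
                               seed) {
  ids <- unique(participant_id)
  n_train <- round(train_fraction * length(ids))
  n_train <- min(max(n_train, 1), length(ids) - 1)
  # only columns that have two classes at all can constrain the split
  check_cols <- intersect(categorical, colnames(X))
  check_cols <- check_cols[vapply(check_cols,
                                  function(cc) length(unique(X[, cc])) > 1,
                                  TRUE)]
  for (attempt in 0:99) {
    train_ids <- with_seed(seed + attempt * 7919L,
                           sample(ids, n_train))
    tr <- participant_id %in% train_ids
    ok <- TRUE
    for (cc in check_cols) {
      if (length(unique(X[tr, cc])) < 2 || length(unique(X[!tr, cc])) < 2) {
        ok <- FALSE
        break
      }
    }
    if (ok) return(list(train = tr, attempts = attempt + 1))
  }
  stop("could not find a split keeping all categorical classes on both sides")
}

#' Repeated outer train/test protocol
#'
#' For each of `n_outer_reps` outer splits: 70/30 participant-level split,
#' inner alpha/lambda selection on the training part, a single refit at the
#' selected (alpha, lambda) on the full training part, prediction on the
#' held-out part, and recording of test MSE, test R-squared (about the
#' test-set mean), the F-test of the predictions against an intercept-only
#' model, and the selected-feature indicators. Splits that leave a
#' categorical covariate single-classed on either side are redrawn with the
#' next sub-seed.
#'
#' @param X,y preprocessed feature matrix and response.
#' @param participant_id ids aligning rows to participants.
#' @param config see [enet_config()].
#' @return `importance_result` list: `records` (one row per test set: s,
#'   alpha, lambda, mse, r2, f_p, f_sig, n_test), `selected` (S x p 0/1
#'   matrix), `features`, `config`.
#' @export
outer_protocol <- function(X, y, participant_id = seq_along(y),
                           config = enet_config()) {
  X <- as.matrix(X)
  p <- ncol(X)
  S <- config$n_outer_reps
  selected <- matrix(0L, S, p, dimnames = list(NULL, colnames(X)))
  records <- vector("list", S)
  for (s in seq_len(S)) {
    sub_seed <- config$seed * 10000L + s
    if (config$split_unit == "participant") {
      sp <- split_participants(participant_id, config$train_fraction, X,
                               config$categorical, sub_seed)
      tr <- sp$train
    } else {
      n <- nrow(X)
      tr <- rep(FALSE, n)
      tr[with_seed(sub_seed, sample.int(n, round(config$train_fraction * n)))] <- TRUE
    }
    sel <- inner_select_alpha(X[tr, , drop = FALSE], y[tr], config,
                              seed = sub_seed)
    fit <- elastic_net_fit(X[tr, , drop = FALSE], y[tr], sel$alpha,
                           sel$lambda)
    pred <- fit$intercept + as.vector(X[!tr, , drop = FALSE] %*%
                                        fit$coefficients)
    yte <- y[!tr]
    mse <- mean((yte - pred)^2)
    sst <- sum((yte - mean(yte))^2)
    r2 <- 1 - sum((yte - pred)^2) / sst
    if (sd(pred) > 0) {
      fsum <- summary(lm(yte ~ pred))
      fp <- unname(pf(fsum$fstatistic[1], fsum$fstatistic[2],
                      fsum$fstatistic[3], lower.tail = FALSE))
    } else {
      fp <- 1  # all-zero model: no predictive content
    }
    selected[s, ] <- as.integer(fit$coefficients != 0)
    records[[s]] <- data.frame(s = s, alpha = sel$alpha, lambda = sel$lambda,
                               mse = mse, r2 = r2, f_p = fp,
                               f_sig = as.integer(fp < 0.05),
                               n_test = length(yte))
  }
  structure(list(records = do.call(rbind, records), selected = selected,
                 features = colnames(X), config = config),
            class = "importance_result")
}

#' Goodness-of-fit-weighted feature importance
#'
#' `raw_j = sum_s c_sj * w_s / S` with `w_s = r_s * f_s`, where `c_sj`
#' indicates selection of feature j in test set s, `r_s` is the test
#' R-squared, and `f_s` indicates a significant (p < 0.05) F-test; `w_s` is
#' floored at zero so importances cannot go negative. Raw scores are
#' normalized to \[0, 1\] by the maximum; an all-zero raw vector stays zero
#' and is flagged.
#'
#' @param result an `importance_result` from [outer_protocol()].
#' @param denom denominator S (defaults to the configured
#'   `importance_denom`).
#' @return data.frame: feature, n_selected, raw, normalized; attribute
#'   `all_zero`.
#' @export
feature_importance <- function(result, denom = NULL) {
  stopifnot(inherits(result, "importance_result"))
  denom <- denom %||% result$config$importance_denom
  w <- pmax(result$records$r2, 0) * result$records$f_sig
  raw <- as.vector(crossprod(result$selected, w)) / denom
  all_zero <- all(raw == 0)
  normalized <- if (all_zero) raw else raw / max(raw)
  structure(data.frame(feature = result$features,
                       n_selected = colSums(result$selected),
                       raw = raw, normalized = normalized,
                       stringsAsFactors = FALSE),
            all_zero = all_zero)
}

#' @export
print.importance_result <- function(x, ...) {
  cat("Repeated nested-CV elastic-net protocol\n")
  cat(sprintf("  %d outer test sets over %d features\n",
              nrow(x$records), length(x$features)))
  cat(sprintf("  mean test R^2 %.3f, significant fits %d/%d\n",
              mean(x$records$r2), sum(x$records$f_sig), nrow(x$records)))
  invisible(x)
}
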