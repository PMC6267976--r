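# Independent oracles used to check solver output. These deliberately avoid
# the package's own algorithms: the maxent oracle is an exhaustive grid
# search over the feasible polytope, the permutation oracle enumerates all
# row-permutation combinations, and the ANOVA oracle is lm()/anova().

# Exhaustive grid search for the maximum-entropy distribution subject to
# trait constraints. The feasible set {p >= 0, sum p = 1, t(traits) p = target}
# is parameterized through an orthonormal null-space basis and searched with
# three nested grid refinements. `p0` must be a known feasible point (the
# problems are generated from a convex combination, so its weights serve).
oracle_maxent_grid <- function(traits, target, p0) {
  S <- nrow(traits)
  A <- rbind(t(traits), rep(1, S))
  qrA <- qr(t(A))
  d <- S - qrA$rank
  if (d == 0) {
    return(list(p = p0, entropy = entropy(p0)))
  }
  N <- qr.Q(qrA, complete = TRUE)[, (qrA$rank + 1):S, drop = FALSE]
  n_axis <- if (d == 1) 201 else 81
  entropy_cols <- function(P) {
    P <- pmax(P, 0)
    -colSums(ifelse(P > 0, P * log(P), 0))
  }
  center <- rep(0, d)
  half <- sqrt(2)          # ||p - p0|| <= sqrt(2) on the simplex
  best_u <- center; best_h <- -Inf
  for (stage in 1:3) {
    axes <- lapply(seq_len(d), function(j) {
      seq(center[j] - half, center[j] + half, length.out = n_axis)
    })
    U <- as.matrix(expand.grid(axes))
    P <- matrix(p0, S, nrow(U)) + N %*% t(U)
    feas <- colSums(P < -1e-12) == 0
    if (!any(feas)) break
    H <- entropy_cols(P[, feas, drop = FALSE])
    idx <- which.max(H)
    best_u <- U[feas, , drop = FALSE][idx, ]
    best_h <- H[idx]
    step <- 2 * half / (n_axis - 1)
    center <- best_u
    half <- 2 * step
  }
  p_best <- pmax(as.numeric(p0 + N %*% best_u), 0)
  p_best <- p_best / sum(p_best)
  list(p = p_best, entropy = best_h)
}

# Random feasible maxent problems: traits ~ N(0,1), target = convex
# combination of the trait rows (weights returned as the feasible point).
random_maxent_problem <- function(S, J) {
  tm <- matrix(stats::rnorm(S * J), S, J,
               dimnames = list(paste0("s", seq_len(S)), paste0("t", seq_len(J))))
  g <- stats::rgamma(S, 1)
  w <- g / sum(g)
  list(traits = tm, target = as.numeric(crossprod(tm, w)), w = w)
}

# Exact permutation p-value by enumerating all within-row permutation
# combinations of a 2-row matrix (6^2 = 36 for 3 species).
oracle_exhaustive_p <- function(obs, pred, statistic = "r2") {
  stat_fun <- if (statistic == "r2") fit_r2 else rmse_sqrt
  obs_stat <- stat_fun(obs, pred)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  idx <- perms(seq_len(ncol(obs)))
  stats <- c()
  for (s1 in idx) for (s2 in idx) {
    o <- rbind(obs[1, s1], obs[2, s2])
    stats <- c(stats, stat_fun(o, pred))
  }
  if (statistic == "r2") mean(stats >= obs_stat - 1e-12)
  else mean(stats <= obs_stat + 1e-12)
}

# Classical sequential two-way ANOVA F statistics (A, B, A:B).
oracle_anova_f <- function(y, a, b) {
  stats::anova(stats::lm(y ~ factor(a) * factor(b)))[["F value"]][1:3]
}

# Classical sequential two-way ANOVA sums of squares (A, B, A:B, residual).
oracle_anova_ss <- function(y, a, b) {
  stats::anova(stats::lm(y ~ factor(a) * factor(b)))[["Sum Sq"]]
}
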