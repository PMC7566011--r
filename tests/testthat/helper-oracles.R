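# Independent brute-force oracles used to cross-check every formula the
# package implements. Deliberately written with explicit loops and sum
# formulas, never calling the package's own code paths.

oracle_mean <- function(x) sum(x) / length(x)

oracle_var <- function(x) {
  m <- oracle_mean(x)
  sum((x - m)^2) / (length(x) - 1)
}

# Fisher ratio: squared mean difference over summed class variances
oracle_fisher_ratio <- function(x1, x2) {
  (oracle_mean(x1) - oracle_mean(x2))^2 / (oracle_var(x1) + oracle_var(x2))
}

# classified information index
oracle_cii <- function(x1, x2) {
  v1 <- oracle_var(x1); v2 <- oracle_var(x2)
  s1 <- sqrt(v1); s2 <- sqrt(v2)
  0.5 * abs(oracle_mean(x1) - oracle_mean(x2)) / (s1 + s2) +
    0.5 * log((v1 + v2) / (2 * s1 * s2))
}

# mid-ranks by explicit tie averaging
oracle_midrank <- function(x) {
  r <- numeric(length(x))
  for (i in seq_along(x)) {
    r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }
  r
}

# Spearman rho: Pearson correlation of mid-ranks via sum formulas
oracle_spearman <- function(a, b) {
  ra <- oracle_midrank(a); rb <- oracle_midrank(b)
  ma <- oracle_mean(ra); mb <- oracle_mean(rb)
  sum((ra - ma) * (rb - mb)) /
    sqrt(sum((ra - ma)^2) * sum((rb - mb)^2))
}

# per-tree consistency weight: agreement fraction times ensemble accuracy
oracle_tree_weight <- function(tree_lab, ensemble_lab, acc_ensemble) {
  agree <- 0
  for (j in seq_along(tree_lab)) {
    if (tree_lab[j] == ensemble_lab[j]) agree <- agree + 1
  }
  (agree / length(tree_lab)) * acc_ensemble
}

# weighted combination of per-tree importances, explicit double loop
oracle_combine <- function(fi_mat, w) {
  out <- numeric(ncol(fi_mat))
  for (j in seq_len(ncol(fi_mat))) {
    for (i in seq_len(nrow(fi_mat))) {
      out[j] <- out[j] + fi_mat[i, j] * w[i]
    }
  }
  out
}

# AUC by exhaustive positive-negative pair comparison (ties count 1/2)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == "tumor"]
  neg <- scores[labels == "normal"]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# two-sided Fisher's exact p by hypergeometric enumeration: sum the
# probabilities of all tables (fixed margins) no more likely than observed
oracle_fisher_exact <- function(a, b, c, d) {
  m <- a + b       # row 1 total
  n <- c + d       # row 2 total
  k <- a + c       # column 1 total
  lo <- max(0, k - n); hi <- min(k, m)
  p_obs <- stats::dhyper(a, m, n, k)
  tot <- 0
  for (x in lo:hi) {
    px <- stats::dhyper(x, m, n, k)
    if (px <= p_obs * (1 + 1e-7)) tot <- tot + px
  }
  min(tot, 1)
}

# k-group log-rank chi-square by the textbook formula: at each distinct
# event time, observed and expected events per group under the
# hypergeometric model, variance-covariance summed, quadratic form on the
# first k-1 groups.
oracle_logrank <- function(time, event, group) {
  group <- as.character(group)
  gs <- sort(unique(group))
  k <- length(gs)
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    d_t <- sum(event == 1 & time == t)
    for (i in seq_len(k)) {
      n_it <- sum(at_risk & group == gs[i])
      d_it <- sum(event == 1 & time == t & group == gs[i])
      O[i] <- O[i] + d_it
      E[i] <- E[i] + d_t * n_it / n_t
      for (j in seq_len(k)) {
        n_jt <- sum(at_risk & group == gs[j])
        delta <- as.numeric(i == j)
        if (n_t > 1) {
          V[i, j] <- V[i, j] + d_t * (n_it / n_t) *
            (delta - n_jt / n_t) * (n_t - d_t) / (n_t - 1)
        }
      }
    }
  }
  u <- (O - E)[-k]
  vv <- V[-k, -k, drop = FALSE]
  stat <- as.numeric(t(u) %*% solve(vv) %*% u)
  list(statistic = stat, df = k - 1,
       p = stats::pchisq(stat, df = k - 1, lower.tail = FALSE))
}

# Kaplan-Meier product-limit estimator by explicit loop
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ts))
  for (i in seq_along(ts)) {
    n_t <- sum(time >= ts[i])
    d_t <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d_t / n_t)
    out[i] <- s
  }
  data.frame(time = ts, surv = out)
}

# Fold-mean perturbation importance recomputed independently: same fold
# partition and tree learner, but accuracy bookkeeping and the fold mean
# written out explicitly.
oracle_perturbation_fi <- function(x, y, folds, gene, perturb = "mean") {
  cv <- max(folds)
  total <- 0
  for (k in seq_len(cv)) {
    tr <- which(folds != k); va <- which(folds == k)
    fit <- treeDEG:::td_fit_tree(x[tr, , drop = FALSE], y[tr])
    acc <- sum(treeDEG:::td_predict(fit, x[va, , drop = FALSE]) ==
                 y[va]) / length(va)
    xp <- x[va, , drop = FALSE]
    xp[, gene] <- sum(x[tr, gene]) / length(tr)
    accf <- sum(treeDEG:::td_predict(fit, xp) == y[va]) / length(va)
    total <- total + (acc - accf)
  }
  total / cv
}
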