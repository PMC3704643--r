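# Independent oracles used to cross-check the package implementations.
# These deliberately use different algorithms from the production code
# (matrix powers / exhaustive path counting instead of igraph's Brandes
# algorithm, explicit matrix algebra instead of lm/t.test/aov).

# Mutual-reachability equivalence classes via boolean transitive closure.
oracle_strong_components <- function(adj) {
  n <- nrow(adj)
  reach <- (adj | diag(TRUE, n))
  for (k in seq_len(n)) {
    reach <- reach | (reach %*% reach > 0)
  }
  mutual <- reach & t(reach)
  membership <- integer(n)
  lab <- 0L
  for (i in seq_len(n)) {
    if (membership[i] == 0L) {
      lab <- lab + 1L
      membership[mutual[i, ]] <- lab
    }
  }
  membership
}

# Betweenness by shortest-path counting with adjacency-matrix powers:
# sigma_kl = number of minimal-length walks (minimal walks are simple),
# sigma_kl(i) = sigma_ki * sigma_il when d(k,i) + d(i,l) = d(k,l).
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  A <- adj * 1
  diag(A) <- 0
  # dist and path counts via successive powers
  D <- matrix(Inf, n, n)
  S <- matrix(0, n, n)
  P <- diag(1, n)
  for (len in seq_len(n - 1)) {
    P <- P %*% A
    new <- is.infinite(D) & P > 0 & diag(n) == 0
    D[new] <- len
    S[new] <- P[new]
  }
  b <- numeric(n)
  for (i in seq_len(n)) {
    for (k in seq_len(n)) {
      for (l in seq_len(n)) {
        if (k == l || k == i || l == i) next
        if (is.finite(D[k, l]) && is.finite(D[k, i]) && is.finite(D[i, l]) &&
            D[k, i] + D[i, l] == D[k, l]) {
          b[i] <- b[i] + S[k, i] * S[i, l] / S[k, l]
        }
      }
    }
  }
  b
}

# Random digraph adjacency matrix (no self-loops).
random_digraph <- function(n, p = 0.3) {
  adj <- matrix(stats::runif(n * n) < p, n, n)
  diag(adj) <- FALSE
  adj
}

# All 2^(n(n-1)) digraphs on n nodes (feasible for n <= 3).
all_digraphs <- function(n) {
  off <- which(diag(n) == 0)
  m <- length(off)
  lapply(seq_len(2^m) - 1L, function(code) {
    adj <- matrix(FALSE, n, n)
    adj[off] <- bitwAnd(code, 2^(seq_len(m) - 1L)) > 0
    adj
  })
}

# OLS of y on x by explicit matrix algebra.
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  xtx_inv <- solve(t(X) %*% X)
  beta <- xtx_inv %*% t(X) %*% y
  res <- y - X %*% beta
  n <- length(y)
  sigma2 <- sum(res^2) / (n - 2)
  se <- sqrt(diag(xtx_inv) * sigma2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - sum(res^2) / tss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - 2)
  tstat <- beta[2] / se[2]
  list(slope = unname(beta[2]), se = unname(se[2]), adj_r_squared = adj_r2,
       p_value = unname(2 * stats::pt(-abs(tstat), n - 2)))
}

# Pooled-variance two-sample t statistic by the textbook formula.
oracle_ttest <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p_value = 2 * stats::pt(-abs(t), na + nb - 2))
}

# One-way ANOVA F from the sum-of-squares decomposition.
oracle_anova <- function(groups) {
  y <- unlist(groups)
  k <- length(groups); n <- length(y)
  gm <- mean(y)
  ssb <- sum(lengths(groups) * (vapply(groups, mean, numeric(1)) - gm)^2)
  ssw <- sum(unlist(lapply(groups, function(g) (g - mean(g))^2)))
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(f = f, p_value = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}
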