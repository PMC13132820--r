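# Independent brute-force / closed-form oracles used to cross-check the
# implementation. These deliberately share no code with the package
# internals.

# dense grid search over the soft-threshold level delta for the
# projection onto {||.||_2 = 1, ||.||_1 <= c}
oracle_l1l2 <- function(w, c, grid_n = 200001L) {
  s0 <- w / sqrt(sum(w^2))
  if (sum(abs(s0)) <= c) return(s0)
  deltas <- seq(0, max(abs(w)), length.out = grid_n)
  best <- s0
  best_gap <- Inf
  for (d in deltas) {
    st <- sign(w) * pmax(abs(w) - d, 0)
    n2 <- sqrt(sum(st^2))
    if (n2 == 0) next
    s <- st / n2
    gap <- abs(sum(abs(s)) - c)
    if (gap < best_gap) { best_gap <- gap; best <- s }
  }
  best
}

# tie-corrected Kruskal-Wallis H from the mid-rank formula, written out
oracle_kruskal_h <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)  # mid-ranks
  H <- 12 / (N * (N + 1)) *
    sum(tapply(seq_len(N), g, function(i) length(i) * (mean(r[i]) - (N + 1) / 2)^2))
  tie <- table(x)
  C <- 1 - sum(tie^3 - tie) / (N^3 - N)
  H / C
}

# Pearson chi-square written out from observed/expected counts
oracle_chisq <- function(tab) {
  tab <- as.matrix(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# Benjamini-Hochberg step-up, written out
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# least-squares residuals via the normal equations
oracle_residuals <- function(y, x) {
  D <- cbind(1, x)
  y - D %*% solve(t(D) %*% D, t(D) %*% y)
}

# random planted rank-1 cohort pair of bare matrices (no generator code)
toy_rank1 <- function(n, p, q, seed, noise = 0) {
  set.seed(seed)
  u <- rnorm(p); u <- u / sqrt(sum(u^2))
  v <- rnorm(q); v <- v / sqrt(sum(v^2))
  t <- rnorm(n)
  list(X = t %*% t(u) + noise * matrix(rnorm(n * p), n, p),
       Y = t %*% t(v) + noise * matrix(rnorm(n * q), n, q),
       u = u, v = v)
}

cosine <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# small cohort_matrix fixture pair built in code
fixture_blocks <- function(n = 12, seed = 1) {
  set.seed(seed)
  X <- cbind(smoker = rbinom(n, 1, 0.5),
             age = rnorm(n, 45, 10),
             education = sample(1:4, n, replace = TRUE))
  Y <- cbind(continuous_abstinence = rbinom(n, 1, 0.4),
             daily_consumption_g = rexp(n, 0.05))
  Y[Y[, 1] == 1, 2] <- 0
  list(X = cohort_matrix(X, c("binary", "continuous", "ordinal"),
                         c("pre", "pre", "within")),
       Y = cohort_matrix(Y, c("binary", "continuous"), "outcome",
                         role = "outcome"))
}
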