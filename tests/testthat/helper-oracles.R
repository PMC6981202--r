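# Independent oracles used to validate the implementation paths.

# Step-up BH by explicit sort and backward minimum.
bh_oracle <- function(p) {
  n <- length(p)
  idx <- order(p)
  ps <- p[idx]
  adj <- numeric(n)
  cur <- 1
  for (i in n:1) {
    cur <- min(cur, n * ps[i] / i)
    adj[i] <- cur
  }
  out <- numeric(n)
  out[idx] <- adj
  out
}

# Dense-grid maximization of the restricted log-likelihood, refined in
# three stages down to a 1e-8 step.  Shares no code with reml_fit().
grid_reml <- function(y, v, upper = NULL) {
  ll_grid <- function(t2) {
    V <- outer(v, t2, "+")
    W <- 1 / V
    sw <- colSums(W)
    mu <- colSums(W * y) / sw
    resid2 <- (y - rep(mu, each = length(y)))^2
    -0.5 * (colSums(log(V)) + log(sw) + colSums(W * resid2))
  }
  if (is.null(upper)) upper <- max(10 * var(y), 1e-3)
  grid <- seq(0, upper, length.out = 2001)
  step <- grid[2] - grid[1]
  best <- grid[which.max(ll_grid(grid))]
  for (s in c(step, step / 1000)) {
    grid <- seq(max(0, best - s), best + s, length.out = 2001)
    best <- grid[which.max(ll_grid(grid))]
  }
  w <- 1 / (v + best)
  list(tau2 = best, mu = sum(w * y) / sum(w))
}

# Exhaustive hypergeometric upper tail: probability that a uniformly drawn
# query of the same size overlaps the set at least as much as observed.
ora_enum <- function(query, universe, set) {
  q <- length(query)
  obs <- length(intersect(query, set))
  combos <- utils::combn(universe, q, simplify = FALSE)
  mean(vapply(combos, function(cc) length(intersect(cc, set)) >= obs,
              logical(1)))
}

# Sorted-row-means quantile normalization (valid when no ties).
qn_oracle <- function(x) {
  ref <- rowMeans(apply(x, 2, sort))
  out <- apply(x, 2, function(col) ref[rank(col)])
  dimnames(out) <- dimnames(x)
  out
}

# Two-sided t-tail by numerical integration of the density.
t_tail_p <- function(t, df) {
  2 * stats::integrate(function(x) stats::dt(x, df), abs(t), Inf)$value
}
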