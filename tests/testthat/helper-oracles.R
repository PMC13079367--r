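# Independent oracles used to check the package's closed forms and the
# contrasts engine. These deliberately avoid the code paths they verify.

# Direct evaluation of the population equation
# P(t) = P(0) (N pg)^(t/tau) s(pg)^(t/ts), with s omitted when no
# survival parameters are given.
closed_form_population <- function(N, pg, t, p0 = 1, sg = NULL, ss = NULL,
                                   ts = NULL) {
  tau <- log(N) / log(2)
  p <- p0 * (N * pg)^(t / tau)
  if (!is.null(sg)) {
    s <- ss + (sg - ss) * pg
    p <- p * s^(t / ts)
  }
  p
}

# Two-stage grid search for the germ fraction maximizing
# ln(N pg)/log2(N) + ln(s(pg))/ts over [1/N, 1] at absolute resolution
# `res`. The coarse-then-refine scheme is exact for this objective because
# it is strictly concave in pg (a sum of logs of linear functions).
grid_optimum_pg <- function(N, sg, ss, ts, res = 1e-6, coarse = 2001L) {
  obj <- function(pg) log(N * pg) / log2(N) + log(ss + (sg - ss) * pg) / ts
  lo <- 1 / N; hi <- 1
  g1 <- seq(lo, hi, length.out = coarse)
  i <- which.max(obj(g1))
  lo2 <- max(lo, g1[max(1L, i - 1L)])
  hi2 <- min(hi, g1[min(coarse, i + 1L)])
  g2 <- seq(lo2, hi2, by = res)
  if (g2[length(g2)] < hi2) g2 <- c(g2, hi2)
  g2[which.max(obj(g2))]
}

# Generalized-least-squares slope of y on x (with intercept) under the
# Brownian-motion covariance implied by the tree: the quantity the
# through-origin contrasts regression must reproduce.
gls_slope <- function(tree, x, y) {
  V <- ape::vcv(tree)
  ord <- rownames(V)
  X <- cbind(1, x[ord])
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y[ord])
  unname(beta[2])
}

# Random rooted binary tree with uniform branch lengths in (0.1, 1.1),
# strictly positive so every contrast is well defined.
random_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- tr$edge.length + 0.1
  tr
}
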