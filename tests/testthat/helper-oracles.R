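# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain lm() algebra, dense-grid quadrature and
# closed forms.

# Ezekiel-adjusted R^2 of y on a column-bound predictor set
oracle_adj_r2 <- function(y, X) {
  X <- as.matrix(X)
  r2 <- summary(lm(y ~ X))$r.squared
  n <- length(y)
  1 - (1 - r2) * (n - 1) / (n - ncol(X) - 1)
}

# brute-force three-group variation partitioning by inclusion-exclusion
# over the seven nested adjusted-R^2 regressions (x1, x2, x3 are the block
# scores)
oracle_vpa <- function(y, x1, x2, x3) {
  r1 <- oracle_adj_r2(y, cbind(x1))
  r2 <- oracle_adj_r2(y, cbind(x2))
  r3 <- oracle_adj_r2(y, cbind(x3))
  r12 <- oracle_adj_r2(y, cbind(x1, x2))
  r13 <- oracle_adj_r2(y, cbind(x1, x3))
  r23 <- oracle_adj_r2(y, cbind(x2, x3))
  r123 <- oracle_adj_r2(y, cbind(x1, x2, x3))
  a <- r123 - r23
  b <- r123 - r13
  cc <- r123 - r12
  d <- r123 - r3 - a - b
  e <- r123 - r1 - b - cc
  f <- r123 - r2 - a - cc
  g <- r123 - a - b - cc - d - e - f
  c(a, b, cc, d, e, f, g, 1 - r123)
}

# first principal component scores the same way the package defines them,
# recomputed from first principles (for VPA oracle inputs)
oracle_pc1 <- function(block) {
  p <- prcomp(as.matrix(block), center = TRUE, scale. = TRUE)
  s <- if (sum(p$rotation[, 1]) < 0) -1 else 1
  s * p$x[, 1] / p$sdev[1]
}

# dense trapezoid quadrature of f over [a, b]
oracle_quad <- function(f, a, b, n = 20001) {
  x <- seq(a, b, length.out = n)
  y <- f(x)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}
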