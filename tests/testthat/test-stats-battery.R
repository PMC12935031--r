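test_that("climate classification follows the documented thresholds and boundary convention", {
  cc <- classify_climate(c(0.32, 0.5, 0.64, 0.65, 1.0, 2.17))
  expect_equal(cc$binary, c("arid", "arid", "arid", "arid", "humid", "humid"))
  expect_equal(cc$zone, c("semi-arid", "semi-humid", "semi-humid", "humid",
                          "humid", "humid"))
  flagged <- classify_climate(0.1)
  expect_true(flagged$extreme_arid)
  expect_true(is.na(flagged$binary))
  expect_error(classify_climate(-0.5), "> 0")
})

test_that("univariate screening reports exact degenerate cases and star thresholds", {
  set.seed(2)
  x <- rnorm(40)
  d <- data.frame(g = rep(c("a", "b"), each = 20),
                  v_same = c(x[1:20], x[1:20]),
                  v_lin = NA, spr = NA)
  d$spr <- rnorm(40)
  d$v_lin <- 2 * d$spr
  out <- screen_univariate(d, "g", c("v_same", "v_lin"), targets = "spr")
  expect_equal(out$t_stat[out$variable == "v_same"], 0, tolerance = 1e-12)
  expect_equal(out$t_p[out$variable == "v_same"], 1, tolerance = 1e-12)
  expect_equal(out$r_spr[out$variable == "v_lin"], 1, tolerance = 1e-12)
  expect_equal(out$stars_spr[out$variable == "v_lin"], "***")
})

test_that("correlation stars hold their nominal null rates", {
  set.seed(5)
  n <- 40; nv <- 1000
  d <- as.data.frame(matrix(rnorm(n * nv), n))
  names(d) <- paste0("v", seq_len(nv))
  d$spr <- rnorm(n)
  d$g <- rep(c("a", "b"), each = n / 2)
  out <- screen_univariate(d, "g", paste0("v", seq_len(nv)), targets = "spr")
  stars <- out$stars_spr
  tol <- function(p) 3 * sqrt(p * (1 - p) / nv)
  expect_lt(abs(mean(stars != "") - 0.05), tol(0.05))
  expect_lt(abs(mean(stars %in% c("**", "***")) - 0.01), tol(0.01))
  expect_lt(abs(mean(stars == "***") - 0.001), tol(0.001))
})

test_that("partial correlation removes confounders and reduces to Pearson r", {
  set.seed(3)
  z <- rnorm(300)
  x <- z + rnorm(300, 0, 0.5)
  y <- z
  expect_equal(partial_correlation(x, y), cor(x, y))
  expect_lt(abs(partial_correlation(x, y, cbind(z))), 0.05)

  # orthogonal controls leave r untouched
  n <- 64
  c1 <- rep(c(1, -1), n / 2)
  x2 <- rnorm(n); y2 <- rnorm(n)
  x2 <- resid(lm(x2 ~ c1)); y2 <- resid(lm(y2 ~ c1))
  expect_equal(partial_correlation(x2, y2, cbind(c1)), cor(x2, y2),
               tolerance = 1e-9)
  expect_error(partial_correlation(x, y, cbind(z, 2 * z)), "singular")
})

test_that("rotated PCA retains by rule, rotates orthogonally and preserves explained variance", {
  set.seed(4)
  n <- 200
  f1 <- rnorm(n); f2 <- rnorm(n)
  X <- cbind(f1 + rnorm(n, 0, 0.4), f1 + rnorm(n, 0, 0.4),
             f1 + rnorm(n, 0, 0.4), f2 + rnorm(n, 0, 0.4),
             f2 + rnorm(n, 0, 0.4), f2 + rnorm(n, 0, 0.4))
  colnames(X) <- paste0("x", 1:6)
  rp <- rotated_pca(X)
  expect_equal(length(rp$retained), 2)
  blk <- (abs(rp$loadings) > 0.5)
  expect_true(all(colSums(blk) == 3))
  expect_true(all(rowSums(blk) == 1))

  expect_equal(t(rp$rotmat) %*% rp$rotmat, diag(2), tolerance = 1e-9)
  expect_equal(sum(rp$rot_var), sum(rp$prop_var[1:2]), tolerance = 1e-9)

  iso <- matrix(rnorm(200 * 8), 200)
  rpi <- rotated_pca(iso)
  # no component materially beyond the pure-noise eigenvalue edge
  mp_edge <- (1 + sqrt(8 / 200))^2
  expect_lt(max(rpi$eigenvalues), 1.1 * mp_edge)
  expect_lt(length(rpi$retained), 8)
  expect_error(rotated_pca(X[1, , drop = FALSE]), "at least 2 samples")
})

test_that("the mixed model recovers a planted component and its variance decomposition", {
  set.seed(6)
  n_site <- 12; per <- 30
  site <- rep(sprintf("s%02d", 1:n_site), each = per)
  n <- n_site * per
  d <- data.frame(site_id = site, RC1 = rnorm(n), RC2 = rnorm(n),
                  depth = rnorm(n))
  b_site <- rnorm(n_site, 0, 1.5)
  d$y <- 2 * d$RC1 + b_site[as.integer(factor(site))] + rnorm(n, 0, 1)
  fit <- fit_lmm(d, "y", c("RC1", "RC2", "depth"), "site_id")
  expect_true("RC1" %in% fit$selected)
  expect_equal(names(which.max(abs(fit$coefficients))), "RC1")
  expect_true(fit$r2m >= 0 && fit$r2m <= fit$r2c && fit$r2c <= 1)
  expect_gt(fit$r2c, fit$r2m)    # real site variance present

  # pure-noise response: nothing explains anything
  d$y0 <- rnorm(n)
  fit0 <- suppressWarnings(fit_lmm(d, "y0", c("RC1", "RC2", "depth"),
                                   "site_id"))
  expect_lt(fit0$r2m, 0.05)
})

test_that("zero site variance collapses conditional onto marginal R2", {
  set.seed(8)
  n <- 300
  d <- data.frame(site_id = rep(sprintf("s%d", 1:10), each = 30),
                  RC1 = rnorm(n))
  d$y <- 1.5 * d$RC1 + rnorm(n)
  fit <- suppressWarnings(fit_lmm(d, "y", "RC1", "site_id"))
  expect_equal(fit$r2c, fit$r2m, tolerance = 0.02)
})

test_that("variation partitioning equals the brute-force inclusion-exclusion oracle", {
  set.seed(9)
  for (rep in 1:5) {
    n <- 80
    b1 <- data.frame(u = rnorm(n), v = rnorm(n))
    b2 <- data.frame(w = rnorm(n), x = rnorm(n))
    b3 <- data.frame(z = rnorm(n))
    y <- rnorm(n) + 0.8 * b1$u - 0.5 * b2$w
    vp <- variation_partition(y, list(g1 = b1, g2 = b2, g3 = b3))
    oracle <- oracle_vpa(y, oracle_pc1(b1), oracle_pc1(b2), oracle_pc1(b3))
    expect_equal(unname(vp$fractions), oracle, tolerance = 1e-9)
    expect_equal(sum(vp$fractions), 1, tolerance = 1e-12)
  }
})

test_that("orthogonal-block VPA isolates the causal block", {
  n <- 64
  set.seed(10)
  b1 <- data.frame(p = rnorm(n))
  b2 <- data.frame(q = resid(lm(rnorm(n) ~ b1$p)))
  b3 <- data.frame(r = resid(lm(rnorm(n) ~ b1$p + b2$q)))
  y <- 2 * scale(b1$p) + rnorm(n, 0, 0.3)
  vp <- variation_partition(as.numeric(y), list(g1 = b1, g2 = b2, g3 = b3))
  expect_lt(abs(unname(vp$fractions["unique_g1"]) -
                  oracle_adj_r2(as.numeric(y), scale(b1$p))), 0.05)
  expect_lt(max(abs(vp$fractions[grep("shared", names(vp$fractions))])), 0.03)
})

test_that("VIF pruning removes collinear columns in the brute-force order", {
  set.seed(11)
  n <- 100
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  expect_equal(vif_prune(X)$removed, character(0))

  Xd <- X; Xd$dup <- Xd$a
  pr <- vif_prune(Xd)
  expect_equal(pr$removed, "a")   # largest VIF, first by column order
  expect_true("dup" %in% names(pr$X))

  base <- rnorm(n)
  Xc <- data.frame(p = base + rnorm(n, 0, 0.32),
                   q = base + rnorm(n, 0, 0.32),
                   r = base + rnorm(n, 0, 0.32))
  # brute-force replay of the removal sequence
  vif_of <- function(D) vapply(seq_along(D), function(j)
    1 / (1 - summary(lm(D[[j]] ~ ., data = D[-j]))$r.squared), numeric(1))
  D <- Xc; removed <- character()
  while (ncol(D) >= 2 && max(vif_of(D)) >= 5) {
    k <- which.max(vif_of(D)); removed <- c(removed, names(D)[k]); D <- D[-k]
  }
  expect_equal(vif_prune(Xc)$removed, removed)
})

test_that("random-forest MC cross-validation is honest on null data and finds signal", {
  set.seed(12)
  n <- 300
  X <- data.frame(matrix(rnorm(n * 5), n))
  y0 <- rnorm(n)
  null_fit <- rf_mccv(y0, X, n_rep = 15, ntree = 100, seed = 1)
  expect_lte(mean(null_fit$r2), 0.05)

  y1 <- 3 * sin(X$X1) + rnorm(n, 0, 0.3)
  sig <- rf_mccv(y1, X, n_rep = 15, ntree = 100, seed = 2)
  expect_gte(unname(sig$top_rank_freq["X1"]), 0.95)
  expect_gt(mean(sig$r2), 0.5)

  again <- rf_mccv(y1, X, n_rep = 15, ntree = 100, seed = 2)
  expect_identical(sig$r2, again$r2)
  expect_error(rf_mccv(y1[1:10], X[1:10, ], n_rep = 5), "n >= 25")
})

test_that("the composite path model satisfies its exact identities and deterministic limit", {
  set.seed(13)
  n <- 60
  tpp <- rnorm(n)
  geo <- 0.7 * tpp + rnorm(n, 0, 0.5)
  dsoc <- 0.9 * geo + rnorm(n, 0, 0.4)
  fit <- plssem_fit(list(tpp = tpp, geochem = geo, dsoc = dsoc),
                    n_boot = 200, seed = 1)
  e <- fit$effects$tpp
  expect_equal(unname(e["total"]), unname(e["direct"] + e["indirect"]),
               tolerance = 1e-12)

  # noise-free outcome equation: perfect fit, vanishing resampling spread
  dsoc0 <- 0.9 * geo
  fit0 <- suppressWarnings(plssem_fit(
    list(tpp = tpp, geochem = geo, dsoc = dsoc0), n_boot = 120, seed = 2))
  expect_equal(fit0$r2$point, 1, tolerance = 1e-9)
  # the deterministic outcome equation has zero resampling spread; only the
  # noisy tpp -> geochem link retains genuine sampling variation
  det <- fit0$paths$path %in% c("tpp_dsoc", "geochem_dsoc")
  expect_lt(max(fit0$paths$sd_boot[det]), 1e-8)
  expect_lt(fit0$r2$boot_sd, 1e-8)
  expect_error(plssem_fit(list(tpp = tpp[1:5], geochem = geo[1:5],
                               dsoc = dsoc[1:5])), ">= 8")
})
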