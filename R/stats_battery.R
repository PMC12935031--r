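#' Classify aridity-index values into climate classes
#'
#' Binary split at the hydrological transition MAP/PET = 1 (values at
#' exactly 1 are classed humid, the documented boundary convention) and
#' ternary zones with half-open intervals: semi-arid \[0.2, 0.5), semi-humid
#' \[0.5, 0.65), humid \[0.65, Inf). Values below 0.2 (extremely arid, where
#' agricultural terraces are absent) are flagged rather than classified.
#'
#' @param ai aridity index, MAP/PET (> 0).
#' @return data.frame: `ai`, `binary` ("arid"/"humid"), `zone`,
#'   `extreme_arid` flag.
#' @export
classify_climate <- function(ai) {
  stopifnot_msg(all(ai > 0), "aridity index must be > 0")
  binary <- ifelse(ai < 1, "arid", "humid")
  zone <- cut(ai, breaks = c(0.2, 0.5, 0.65, Inf), right = FALSE,
              labels = c("semi-arid", "semi-humid", "humid"))
  extreme <- ai < 0.2
  zone <- as.character(zone)
  binary[extreme] <- NA_character_
  data.frame(ai = ai, binary = binary, zone = zone, extreme_arid = extreme,
             stringsAsFactors = FALSE)
}

signif_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***",
                              ifelse(p < 0.01, "**",
                                     ifelse(p < 0.05, "*", ""))))
}

#' Univariate screening of soil variables across climate strata
#'
#' Per variable: Shapiro-Wilk normality check (on at most 5000
#' deterministically subsampled values), log-transform of skewed
#' strictly-positive variables, Welch t-test between the two strata, and
#' Pearson correlations against the target variables with significance
#' stars (* p < 0.05, ** p < 0.01, *** p < 0.001, blank above 0.05;
#' unadjusted, mirroring per-cell correlation displays).
#'
#' @param data data.frame holding `variables`, `targets` and `group`.
#' @param group name of a two-level grouping column.
#' @param variables character vector of variables to screen.
#' @param targets character vector of target columns for correlations.
#' @return data.frame with one row per variable.
#' @export
screen_univariate <- function(data, group, variables,
                              targets = c("spr")) {
  g <- factor(data[[group]])
  stopifnot_msg(nlevels(g) == 2, "grouping must have exactly two levels")
  stopifnot_msg(min(table(g)) >= 3, "need >= 3 samples per group")
  rows <- lapply(variables, function(v) {
    x <- data[[v]]
    sw <- tryCatch({
      xs <- if (length(x) > 5000) x[round(seq(1, length(x), length.out = 5000))]
            else x
      shapiro.test(xs)$p.value
    }, error = function(e) NA_real_)
    transformed <- !is.na(sw) && sw < 0.05 && all(x > 0, na.rm = TRUE)
    xt <- if (transformed) log(x) else x
    tt <- tryCatch(t.test(xt ~ g), error = function(e) NULL)
    out <- data.frame(variable = v, shapiro_p = sw,
                      log_transformed = transformed,
                      t_stat = if (is.null(tt)) NA_real_ else unname(tt$statistic),
                      t_p = if (is.null(tt)) NA_real_ else tt$p.value,
                      stringsAsFactors = FALSE)
    for (tg in targets) {
      ct <- if (sd(x, na.rm = TRUE) == 0 || sd(data[[tg]], na.rm = TRUE) == 0)
        NULL else cor.test(x, data[[tg]])
      out[[paste0("r_", tg)]] <- if (is.null(ct)) NA_real_ else unname(ct$estimate)
      out[[paste0("stars_", tg)]] <-
        signif_stars(if (is.null(ct)) NA_real_ else ct$p.value)
    }
    out
  })
  do.call(rbind, rows)
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the residuals of `x` and `y` after regressing
#' each on the control set; with no controls it equals the zero-order
#' correlation.
#'
#' @param x,y numeric vectors.
#' @param controls optional numeric matrix/data.frame of covariates.
#' @return partial correlation coefficient.
#' @export
partial_correlation <- function(x, y, controls = NULL) {
  if (is.null(controls) || NCOL(controls) == 0) return(cor(x, y))
  C <- as.matrix(controls)
  stopifnot_msg(length(x) > ncol(C) + 2,
                "need n > ncol(controls) + 2 observations")
  stopifnot_msg(qr(cbind(1, C))$rank == ncol(C) + 1,
                "singular control set (collinear controls)")
  cor(resid(lm(x ~ C)), resid(lm(y ~ C)))
}

#' Varimax-rotated principal components of soil covariates
#'
#' Correlation-matrix PCA (variables standardized internally) with
#' components retained when the eigenvalue exceeds 1 and the explained
#' proportion of variance exceeds 5 percent, followed by varimax rotation
#' of the retained loadings (Kaiser-normalized). Loadings above the
#' interpretation threshold |r| > 0.5 are flagged for naming the rotated
#' components.
#'
#' @param X samples x variables matrix or data.frame.
#' @param eigen_min,var_min retention rule (defaults 1 and 0.05).
#' @param loading_threshold interpretation threshold (default 0.5).
#' @return object of class `rotated_pca`: rotated `loadings`
#'   (correlation-scaled), `rotmat`, unrotated `eigenvalues` and
#'   `prop_var`, post-rotation `rot_var`, rotated standardized `scores`,
#'   `retained` names, and `interpretation` (logical matrix of salient
#'   loadings).
#' @export
rotated_pca <- function(X, eigen_min = 1, var_min = 0.05,
                        loading_threshold = 0.5) {
  X <- as.matrix(X)
  stopifnot_msg(nrow(X) >= 2, "need at least 2 samples")
  sds <- apply(X, 2, sd)
  stopifnot_msg(sum(sds > 0) >= 2, "need >= 2 variables with nonzero variance")
  X <- X[, sds > 0, drop = FALSE]
  Z <- scale(X)
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  prop <- ev / ncol(Z)
  keep <- which(ev > eigen_min & prop > var_min)
  if (length(keep) == 0) keep <- 1L   # degenerate: keep the first component
  L <- pc$rotation[, keep, drop = FALSE] %*% diag(pc$sdev[keep],
                                                  length(keep))
  colnames(L) <- paste0("RC", seq_along(keep))
  if (length(keep) > 1) {
    vm <- varimax(L)
    Lr <- unclass(vm$loadings)
    R <- vm$rotmat
  } else {
    Lr <- L
    R <- matrix(1, 1, 1)
  }
  S <- Z %*% pc$rotation[, keep, drop = FALSE] %*%
    diag(1 / pc$sdev[keep], length(keep))
  scores <- S %*% R
  colnames(scores) <- colnames(Lr) <- paste0("RC", seq_along(keep))
  structure(list(loadings = Lr, rotmat = R,
                 eigenvalues = ev, prop_var = prop,
                 rot_var = colSums(Lr^2) / ncol(Z),
                 scores = scores, retained = colnames(Lr),
                 interpretation = abs(Lr) > loading_threshold,
                 retention_rule = sprintf(
                   "eigenvalue > %g and variance share > %g%%",
                   eigen_min, 100 * var_min)),
            class = "rotated_pca")
}

#' @export
print.rotated_pca <- function(x, ...) {
  cat(sprintf("Rotated PCA: %d retained components (%s)\n",
              length(x$retained), x$retention_rule))
  cat(sprintf("  variance share after rotation: %s\n",
              paste(sprintf("%s %.1f%%", x$retained, 100 * x$rot_var),
                    collapse = ", ")))
  invisible(x)
}

#' Linear mixed model with stepwise fixed-effect selection
#'
#' Fits `response ~ fixed terms + (1 | random)` with a site-level random
#' intercept, selecting fixed terms by bidirectional stepwise AIC search
#' (maximum-likelihood fits). Response and candidate predictors are
#' standardized internally so coefficients read as relative importances.
#' Marginal R^2 quantifies variance explained by fixed effects alone and
#' conditional R^2 by fixed plus random effects (Gaussian
#' variance-decomposition definition). A singular random-effect fit falls
#' back to a fixed site intercept with a warning.
#'
#' @param data data.frame.
#' @param response response column name.
#' @param fixed character vector of candidate fixed-effect columns.
#' @param random grouping column for the random intercept.
#' @return object of class `lmm_result`: `selected`, standardized
#'   `coefficients`, `r2m`, `r2c`, `aic`, and the fitted `model`.
#' @export
fit_lmm <- function(data, response, fixed, random = "site_id") {
  stopifnot_msg(length(unique(data[[random]])) >= 3,
                "need >= 3 grouping levels for the random intercept")
  d <- data.frame(.y = as.numeric(scale(data[[response]])),
                  .g = factor(data[[random]]))
  for (f in fixed) d[[f]] <- as.numeric(scale(data[[f]]))

  fit_ml <- function(terms) {
    rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
    suppressMessages(suppressWarnings(
      lme4::lmer(as.formula(paste(".y ~", rhs, "+ (1 | .g)")),
                 data = d, REML = FALSE)))
  }
  current <- character()
  best_aic <- AIC(fit_ml(current))
  repeat {
    moves <- c(lapply(setdiff(fixed, current),
                      function(v) union(current, v)),
               lapply(current, function(v) setdiff(current, v)))
    if (!length(moves)) break
    aics <- vapply(moves, function(tm) AIC(fit_ml(tm)), numeric(1))
    if (min(aics) < best_aic - 1e-8) {
      current <- moves[[which.min(aics)]]
      best_aic <- min(aics)
    } else break
  }
  model <- suppressMessages(suppressWarnings(
    lme4::lmer(as.formula(paste(".y ~",
      if (length(current)) paste(current, collapse = " + ") else "1",
      "+ (1 | .g)")), data = d, REML = TRUE)))
  singular <- lme4::isSingular(model, tol = 1e-5)
  if (singular) {
    warning("singular random-effect fit; falling back to a fixed site intercept")
    fb <- lm(as.formula(paste(".y ~ .g",
      if (length(current)) paste("+", paste(current, collapse = " + ")) else "")),
      data = d)
    cf <- coef(fb)[current]
    pred_fix <- if (length(current))
      as.matrix(d[current]) %*% cf else rep(0, nrow(d))
    vf <- var(as.numeric(pred_fix))
    vg <- var(fitted(fb) - as.numeric(pred_fix))
    ve <- summary(fb)$sigma^2
    model <- fb
  } else {
    cf <- lme4::fixef(model)
    cf <- cf[setdiff(names(cf), "(Intercept)")]
    pred_fix <- if (length(cf))
      as.matrix(d[names(cf)]) %*% cf else rep(0, nrow(d))
    vf <- var(as.numeric(pred_fix))
    vc <- lme4::VarCorr(model)
    vg <- sum(vapply(vc, function(m) m[1, 1], numeric(1)))
    ve <- attr(vc, "sc")^2
  }
  r2m <- vf / (vf + vg + ve)
  r2c <- (vf + vg) / (vf + vg + ve)
  structure(list(selected = current, coefficients = cf,
                 r2m = r2m, r2c = r2c, aic = best_aic,
                 singular_fallback = singular, model = model),
            class = "lmm_result")
}

#' @export
print.lmm_result <- function(x, ...) {
  cat("Linear mixed model (standardized):\n")
  cat("  selected terms:",
      if (length(x$selected)) paste(x$selected, collapse = ", ") else "(none)",
      "\n")
  if (length(x$coefficients)) {
    cc <- sort(abs(x$coefficients), decreasing = TRUE)
    cat("  |coef| ranking:",
        paste(sprintf("%s=%.3f", names(cc), cc), collapse = ", "), "\n")
  }
  cat(sprintf("  R2m = %.3f, R2c = %.3f\n", x$r2m, x$r2c))
  invisible(x)
}

# first principal component of a standardized block, sign-aligned so the
# mean loading is positive; returns scores and explained-variance share
block_pc1 <- function(block, name = "block") {
  B <- as.matrix(block)
  if (ncol(B) == 1) {
    s <- sd(B[, 1])
    stopifnot_msg(s > 0, paste0("degenerate block (zero variance): ", name))
    return(list(scores = as.numeric(scale(B[, 1])), var_expl = 1))
  }
  sds <- apply(B, 2, sd)
  stopifnot_msg(all(sds > 0),
                paste0("degenerate block (zero-variance column): ", name))
  pc <- prcomp(B, center = TRUE, scale. = TRUE)
  sgn <- if (sum(pc$rotation[, 1]) < 0) -1 else 1
  list(scores = sgn * pc$x[, 1] / pc$sdev[1],
       var_expl = pc$sdev[1]^2 / ncol(B))
}

#' Variation partitioning among three SOC-stabilization predictor groups
#'
#' Reduces each predictor block (ligand exchange: reactive metal oxides;
#' cation bridging: exchangeable bases and pH; SOC chemistry: C:N and FTIR
#' composition ratios) to its first principal component, then partitions
#' the variance of the response into unique, pairwise-shared, triple-shared
#' and residual fractions via `vegan::varpart` (Ezekiel-adjusted R^2 over
#' the seven nested regressions). Raw fractions may be slightly negative;
#' a zero-clipped view is reported alongside, and the raw fractions sum to
#' 1 exactly.
#'
#' @param y numeric response (e.g. SPR or SOC stock density).
#' @param blocks named list of three non-empty, disjoint data.frames.
#' @return object of class `vpa_result`: `fractions` (raw, named), `clipped`,
#'   `pc1_var_expl` per block, `block_names`.
#' @export
variation_partition <- function(y, blocks) {
  stopifnot_msg(length(blocks) == 3, "exactly three predictor blocks required")
  nm <- names(blocks)
  stopifnot_msg(!is.null(nm) && all(nzchar(nm)), "blocks must be named")
  vars <- lapply(blocks, function(b) colnames(as.data.frame(b)))
  stopifnot_msg(!any(duplicated(unlist(vars))),
                "blocks must be disjoint variable sets")
  pcs <- lapply(nm, function(k) block_pc1(blocks[[k]], k))
  names(pcs) <- nm
  x1 <- pcs[[1]]$scores; x2 <- pcs[[2]]$scores; x3 <- pcs[[3]]$scores
  vp <- vegan::varpart(y, x1, x2, x3)
  ind <- vp$part$indfract$Adj.R.square
  fr <- c(ind[1], ind[2], ind[3],    # unique a, b, c
          ind[4], ind[5], ind[6],    # pairwise d (1&2), e (2&3), f (1&3)
          ind[7], ind[8])            # triple g, residual h
  names(fr) <- c(paste0("unique_", nm),
                 paste0("shared_", nm[1], "_", nm[2]),
                 paste0("shared_", nm[2], "_", nm[3]),
                 paste0("shared_", nm[1], "_", nm[3]),
                 paste0("shared_", paste(nm, collapse = "_")),
                 "residual")
  structure(list(fractions = fr, clipped = pmax(fr, 0),
                 pc1_var_expl = vapply(pcs, `[[`, numeric(1), "var_expl"),
                 block_names = nm),
            class = "vpa_result")
}

#' @export
print.vpa_result <- function(x, ...) {
  cat("Variation partitioning (adjusted R^2 fractions):\n")
  for (i in seq_along(x$fractions))
    cat(sprintf("  %-28s %8.4f\n", names(x$fractions)[i], x$fractions[i]))
  cat(sprintf("  block first-PC variance: %s\n",
              paste(sprintf("%s %.0f%%", x$block_names,
                            100 * x$pc1_var_expl), collapse = ", ")))
  invisible(x)
}

#' Iterative variance-inflation-factor pruning
#'
#' Repeatedly removes the variable with the largest VIF until all VIFs fall
#' below the threshold. VIF_j = 1/(1 - R^2_j) from regressing variable j on
#' the remaining set; ties break deterministically by column order.
#'
#' @param X numeric matrix/data.frame (>= 2 columns).
#' @param threshold VIF threshold (default 5).
#' @return list: pruned `X`, `removed` (in removal order), `vif` of the
#'   retained set.
#' @export
vif_prune <- function(X, threshold = 5) {
  X <- as.data.frame(X)
  stopifnot_msg(ncol(X) >= 2, "need >= 2 variables")
  vifs <- function(D) {
    vapply(seq_along(D), function(j) {
      r2 <- suppressWarnings(summary(lm(D[[j]] ~ ., data = D[-j]))$r.squared)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  removed <- character()
  while (ncol(X) >= 2) {
    v <- vifs(X)
    if (max(v) < threshold) break
    drop <- which.max(v)
    removed <- c(removed, names(X)[drop])
    X <- X[-drop]
  }
  list(X = X, removed = removed,
       vif = if (ncol(X) >= 2) setNames(vifs(X), names(X))
             else setNames(1, names(X)))
}

#' Random-forest Monte Carlo cross-validation
#'
#' Repeated random 4:1 train/validation splits; each repetition fits a
#' random forest (500 trees, sqrt(p) candidate variables per split) on the
#' training portion and records validation RMSE and R^2
#' (1 - SSE/SStot). Variable importance is validation-set permutation
#' importance (increase in validation MSE when the variable is permuted),
#' averaged across repetitions.
#'
#' @param y numeric response (n >= 25).
#' @param X predictor data.frame.
#' @param n_rep number of resampling repetitions (>= 2; default 100).
#' @param train_frac training fraction (default 0.8, i.e. 4:1).
#' @param ntree,mtry forest hyperparameters.
#' @param seed integer seed.
#' @return object of class `rf_mccv`: `rmse`, `r2` (length n_rep),
#'   `importance` (mean permutation importance), `importance_reps`,
#'   `top_rank_freq`.
#' @export
rf_mccv <- function(y, X, n_rep = 100, train_frac = 0.8, ntree = 500,
                    mtry = NULL, seed = NULL) {
  X <- as.data.frame(X)
  n <- length(y)
  stopifnot_msg(n >= 25, "need n >= 25 observations")
  stopifnot_msg(n_rep >= 2, "n_rep must be >= 2")
  if (is.null(mtry)) mtry <- max(1, floor(sqrt(ncol(X))))
  local_seed(seed, {
    rmse <- r2 <- numeric(n_rep)
    imp <- matrix(0, n_rep, ncol(X), dimnames = list(NULL, names(X)))
    for (k in seq_len(n_rep)) {
      tr <- sample(n, round(train_frac * n))
      va <- setdiff(seq_len(n), tr)
      rf <- randomForest::randomForest(x = X[tr, , drop = FALSE], y = y[tr],
                                       ntree = ntree, mtry = mtry)
      pred <- predict(rf, X[va, , drop = FALSE])
      sse <- sum((y[va] - pred)^2)
      rmse[k] <- sqrt(sse / length(va))
      r2[k] <- 1 - sse / sum((y[va] - mean(y[va]))^2)
      base_mse <- sse / length(va)
      for (j in seq_along(X)) {
        Xp <- X[va, , drop = FALSE]
        Xp[[j]] <- sample(Xp[[j]])
        pj <- predict(rf, Xp)
        imp[k, j] <- mean((y[va] - pj)^2) - base_mse
      }
    }
    top <- apply(imp, 1, which.max)
    structure(list(rmse = rmse, r2 = r2,
                   importance = colMeans(imp), importance_reps = imp,
                   top_rank_freq = table(factor(names(X)[top],
                                                levels = names(X))) / n_rep),
              class = "rf_mccv")
  })
}

#' @export
print.rf_mccv <- function(x, ...) {
  cat(sprintf("Random-forest MC cross-validation (%d reps):\n", length(x$r2)))
  cat(sprintf("  validation RMSE %.3f +/- %.3f, R2 %.3f +/- %.3f\n",
              mean(x$rmse), sd(x$rmse), mean(x$r2), sd(x$r2)))
  io <- sort(x$importance, decreasing = TRUE)
  cat("  permutation importance:",
      paste(sprintf("%s=%.3g", names(io), io), collapse = ", "), "\n")
  invisible(x)
}

# path coefficients among standardized composites for the fixed diagram
# tpp -> geochem, tpp -> dsoc, geochem -> dsoc
plssem_paths <- function(tpp, geo, dsoc) {
  a <- coef(lm(geo ~ tpp))[2]
  m <- lm(dsoc ~ tpp + geo)
  c(tpp_geochem = unname(a),
    tpp_dsoc = unname(coef(m)["tpp"]),
    geochem_dsoc = unname(coef(m)["geo"]),
    r2_dsoc = summary(m)$r.squared)
}

#' Composite path model of productivity, geochemistry and \eqn{\Delta}SOC
#'
#' Partial-least-squares-style structural model in composite form: each
#' indicator block is collapsed to its standardized first principal
#' component (a warning is issued when the first PC explains 75 percent or
#' less of the block variance), and the paths of the fixed diagram
#' \eqn{\Delta}TPP -> geochemistry -> \eqn{\Delta}SOC plus the direct
#' \eqn{\Delta}TPP -> \eqn{\Delta}SOC link are standardized regression
#' coefficients among composites. Coefficient stability is reported as the
#' SD over bootstrap resamples (`sd_boot`, with a sign-flip bootstrap
#' p-value) and over k-fold leave-fold-out refits (`sd_cv`). The indirect
#' effect is the product along the mediated path and the total effect is
#' direct + indirect, exactly.
#'
#' @param blocks named list: `tpp` (vector or indicator data.frame),
#'   `geochem` (vector or data.frame), `dsoc` (numeric vector).
#' @param n_boot bootstrap resamples (warning below 100).
#' @param k_fold folds for cross-validated stability (default 10, capped at
#'   n).
#' @param seed integer seed.
#' @return object of class `plssem`: `paths` data.frame, `effects`
#'   (direct/indirect/total of \eqn{\Delta}TPP, direct of geochemistry),
#'   `r2` (point, bootstrap, cv), `pc1_var_expl`.
#' @export
plssem_fit <- function(blocks, n_boot = 1000, k_fold = 10, seed = NULL) {
  stopifnot_msg(all(c("tpp", "geochem", "dsoc") %in% names(blocks)),
                "blocks must be named tpp, geochem, dsoc")
  dsoc <- as.numeric(blocks$dsoc)
  n <- length(dsoc)
  stopifnot_msg(n >= 8, "need >= 8 site-level observations")
  if (n_boot < 100) warning("n_boot < 100: bootstrap SDs will be unstable")
  k_fold <- min(k_fold, n)

  comp <- function(b, name) block_pc1(as.data.frame(b), name)
  ct <- comp(blocks$tpp, "tpp")
  cg <- comp(blocks$geochem, "geochem")
  pc1 <- c(tpp = ct$var_expl, geochem = cg$var_expl)
  if (any(pc1 <= 0.75))
    warning("first PC explains <= 75% of block variance for: ",
            paste(names(pc1)[pc1 <= 0.75], collapse = ", "))
  tpp <- as.numeric(scale(ct$scores))
  geo <- as.numeric(scale(cg$scores))
  y <- as.numeric(scale(dsoc))
  est <- plssem_paths(tpp, geo, y)

  refit <- function(rows) {
    bt <- comp(as.data.frame(blocks$tpp)[rows, , drop = FALSE], "tpp")
    bg <- comp(as.data.frame(blocks$geochem)[rows, , drop = FALSE], "geochem")
    st <- bt$scores * sign(cor(bt$scores, tpp[rows]))    # align to full fit
    sg <- bg$scores * sign(cor(bg$scores, geo[rows]))
    plssem_paths(as.numeric(scale(st)), as.numeric(scale(sg)),
                 as.numeric(scale(y[rows])))
  }
  boot <- local_seed(seed, {
    t(vapply(seq_len(n_boot), function(b) {
      repeat {
        rows <- sample(n, n, replace = TRUE)
        if (length(unique(rows)) >= 4) break
      }
      tryCatch(refit(rows), error = function(e) rep(NA_real_, 4))
    }, numeric(4)))
  })
  folds <- local_seed(child_seed(seed, 1),
                      split(sample(n), rep(seq_len(k_fold), length.out = n)))
  cv <- t(vapply(folds, function(f) {
    tryCatch(refit(setdiff(seq_len(n), f)),
             error = function(e) rep(NA_real_, 4))
  }, numeric(4)))

  pnames <- c("tpp_geochem", "tpp_dsoc", "geochem_dsoc")
  pboot <- vapply(pnames, function(p) {
    v <- boot[, p]
    v <- v[is.finite(v)]
    2 * min(mean(v > 0), mean(v < 0))
  }, numeric(1))
  paths <- data.frame(
    path = pnames, estimate = est[pnames],
    sd_boot = apply(boot[, pnames, drop = FALSE], 2, sd, na.rm = TRUE),
    sd_cv = apply(cv[, pnames, drop = FALSE], 2, sd, na.rm = TRUE),
    p_boot = pboot, row.names = NULL)
  indirect <- est[["tpp_geochem"]] * est[["geochem_dsoc"]]
  effects <- list(tpp = c(direct = est[["tpp_dsoc"]], indirect = indirect,
                          total = est[["tpp_dsoc"]] + indirect),
                  geochem = c(direct = est[["geochem_dsoc"]], indirect = 0,
                              total = est[["geochem_dsoc"]]))
  structure(list(paths = paths, effects = effects,
                 r2 = list(point = est[["r2_dsoc"]],
                           boot = mean(boot[, "r2_dsoc"], na.rm = TRUE),
                           boot_sd = sd(boot[, "r2_dsoc"], na.rm = TRUE),
                           cv = mean(cv[, "r2_dsoc"], na.rm = TRUE),
                           cv_sd = sd(cv[, "r2_dsoc"], na.rm = TRUE)),
                 pc1_var_expl = pc1, n = n),
            class = "plssem")
}

#' @export
print.plssem <- function(x, ...) {
  cat(sprintf("Composite path model (n = %d):\n", x$n))
  for (i in seq_len(nrow(x$paths)))
    cat(sprintf("  %-14s beta = %6.3f (boot SD %.3f, CV SD %.3f, p_bt %.3g)\n",
                x$paths$path[i], x$paths$estimate[i], x$paths$sd_boot[i],
                x$paths$sd_cv[i], x$paths$p_boot[i]))
  e <- x$effects$tpp
  cat(sprintf("  dTPP effects: direct %.3f, indirect %.3f, total %.3f\n",
              e["direct"], e["indirect"], e["total"]))
  cat(sprintf("  R2(dSOC) = %.3f (boot %.3f +/- %.3f, cv %.3f +/- %.3f)\n",
              x$r2$point, x$r2$boot, x$r2$boot_sd, x$r2$cv, x$r2$cv_sd))
  invisible(x)
}
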