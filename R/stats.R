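#' Nonparametric sensitivity A'
#'
#' Standard nonparametric signal-detection sensitivity: 0.5 is chance, 1 is
#' perfect. For hit rate H >= false-alarm rate F,
#' `A' = 0.5 + ((H - F) * (1 + H - F)) / (4 * H * (1 - F))`; for H < F the
#' symmetric below-chance form `0.5 - ((F - H) * (1 + F - H)) / (4 * F *
#' (1 - H))` is used. Endpoints (H = F, including 0/0) are defined by
#' continuity as 0.5.
#'
#' @param hit_rate,fa_rate probabilities in `[0, 1]` (vectorized).
#' @return A' values in `[0, 1]`.
#' @examples
#' aPrime(0.7, 0.7)  # 0.5 (chance)
#' aPrime(1, 0)      # 1 (perfect)
#' aPrime(0.8, 0.2)  # 0.875
#' @export
aPrime <- function(hit_rate, fa_rate) {
  assertProb(hit_rate, "hit_rate")
  assertProb(fa_rate, "fa_rate")
  n <- max(length(hit_rate), length(fa_rate))
  H <- rep_len(hit_rate, n)
  F_ <- rep_len(fa_rate, n)
  out <- rep(0.5, n)
  above <- H > F_
  below <- H < F_
  out[above] <- 0.5 + ((H[above] - F_[above]) * (1 + H[above] - F_[above])) /
    (4 * H[above] * (1 - F_[above]))
  out[below] <- 0.5 - ((F_[below] - H[below]) * (1 + F_[below] - H[below])) /
    (4 * F_[below] * (1 - H[below]))
  out
}

#' Fisher r-to-z transform and its inverse
#'
#' `fisherZ(r) = atanh(r)`; correlations are expected to be clipped away
#' from +/-1 beforehand (see the package's clipping rule); unclipped values
#' at or beyond +/-1 are a domain error.
#'
#' @param r correlations with `|r| < 1`.
#' @param z Fisher-z values.
#' @return transformed values.
#' @examples
#' fisherZ(0.5)          # 0.5493
#' fisherZInv(fisherZ(0.3))
#' @export
fisherZ <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE)) {
    stopf("domain error: |r| must be < 1 (apply the clipping rule first)")
  }
  atanh(r)
}

#' @rdname fisherZ
#' @export
fisherZInv <- function(z) tanh(z)

.testResult <- function(tt, d) {
  list(statistic = unname(tt$statistic), dof = unname(tt$parameter),
       p = tt$p.value, effect_size_d = d,
       ci = unname(tt$conf.int), mean = unname(tt$estimate[1]))
}

#' Paired-samples t test with effect size
#'
#' Exact paired t statistic, two-sided p, paired Cohen's d (mean difference
#' divided by the SD of the differences) and the 95% CI of the mean
#' difference.
#'
#' @param x,y paired numeric vectors of equal length (n >= 2).
#' @return list: `statistic`, `dof`, `p`, `effect_size_d`, `ci`, `mean`.
#' @export
pairedTTest <- function(x, y) {
  if (length(x) != length(y)) stopf("paired arrays must have equal length")
  if (length(x) < 2L) stopf("need n >= 2")
  d <- x - y
  if (sd(d) == 0) {
    if (all(d == 0)) {
      return(list(statistic = 0, dof = length(x) - 1L, p = 1,
                  effect_size_d = 0, ci = c(0, 0), mean = 0))
    }
    stopf("degenerate error: zero variance of paired differences")
  }
  tt <- t.test(x, y, paired = TRUE)
  .testResult(tt, mean(d) / sd(d))
}

#' One-sample t test with effect size
#'
#' @param x numeric vector (n >= 2).
#' @param mu0 null mean (default 0).
#' @return list as in [pairedTTest()].
#' @export
oneSampleTTest <- function(x, mu0 = 0) {
  if (length(x) < 2L) stopf("need n >= 2")
  if (sd(x) == 0) stopf("degenerate error: zero variance")
  tt <- t.test(x, mu = mu0)
  .testResult(tt, (mean(x) - mu0) / sd(x))
}

#' 2 x 2 repeated-measures ANOVA
#'
#' Within-subject ANOVA for a complete two-factor (2 x 2) design, one
#' observation per participant per cell: main effects and interaction with
#' F, degrees of freedom, p and partial eta squared. For two-level factors
#' each F equals the square of the corresponding paired t statistic.
#'
#' @param cell_means numeric matrix or data.frame, participants x 4 cells,
#'   columns ordered (A1B1, A1B2, A2B1, A2B2); or a long data.frame with
#'   columns `participant`, `factor_a`, `factor_b`, `value`.
#' @param factor_names names of the two factors for labeling.
#' @return data.frame with rows `factor_a`, `factor_b`, `interaction` and
#'   columns `effect`, `F`, `df1`, `df2`, `p`, `partial_eta_sq`.
#' @export
rmAnova2x2 <- function(cell_means, factor_names = c("task", "validity")) {
  if (is.data.frame(cell_means) && all(c("participant", "factor_a",
                                         "factor_b", "value") %in%
                                       names(cell_means))) {
    long <- cell_means
  } else {
    cm <- as.matrix(cell_means)
    if (ncol(cm) != 4L) stopf("expected 4 cells (2 x 2)")
    if (anyNA(cm)) stopf("incomplete-design error: missing cells")
    n <- nrow(cm)
    long <- data.frame(
      participant = factor(rep(seq_len(n), 4L)),
      factor_a = factor(rep(c(1, 1, 2, 2), each = n)),
      factor_b = factor(rep(c(1, 2, 1, 2), each = n)),
      value = as.vector(cm))
  }
  if (anyNA(long$value)) stopf("incomplete-design error: missing cells")
  long$participant <- factor(long$participant)
  long$factor_a <- factor(long$factor_a)
  long$factor_b <- factor(long$factor_b)
  tab <- table(long$participant, long$factor_a, long$factor_b)
  if (any(tab != 1L)) stopf("incomplete-design error: need one value per cell")
  fit <- aov(value ~ factor_a * factor_b +
               Error(participant / (factor_a * factor_b)), data = long)
  sm <- summary(fit)
  pick <- function(stratum, term) {
    s <- sm[[stratum]][[1]]
    i <- grep(term, trimws(rownames(s)), fixed = TRUE)
    i <- i[trimws(rownames(s))[i] == term]
    c(F = s[i, "F value"], df1 = s[i, "Df"],
      df2 = s[nrow(s), "Df"], p = s[i, "Pr(>F)"],
      ss = s[i, "Sum Sq"], sse = s[nrow(s), "Sum Sq"])
  }
  rows <- list(
    factor_a = pick("Error: participant:factor_a", "factor_a"),
    factor_b = pick("Error: participant:factor_b", "factor_b"),
    interaction = pick("Error: participant:factor_a:factor_b",
                       "factor_a:factor_b"))
  out <- do.call(rbind, lapply(names(rows), function(nm) {
    r <- rows[[nm]]
    data.frame(effect = switch(nm, factor_a = factor_names[1],
                               factor_b = factor_names[2],
                               interaction = paste(factor_names,
                                                   collapse = ":")),
               F = unname(r["F"]), df1 = unname(r["df1"]),
               df2 = unname(r["df2"]), p = unname(r["p"]),
               partial_eta_sq = unname(r["ss"] / (r["ss"] + r["sse"])),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Robust skipped correlation
#'
#' Pearson correlation after removing bivariate outliers, in four steps:
#' (1) a robust center of the point cloud via the minimum covariance
#' determinant; (2) orthogonal projection of all points onto the line
#' joining each point to the center; (3) per-projection outlier flagging by
#' the interquartile-range rule (boxplot fences at 1.5 x IQR, quartiles via
#' `stats::quantile` type 7), taking the union over projections; (4) Pearson
#' correlation on the retained points. When no point is flagged the result
#' equals the plain Pearson correlation exactly.
#'
#' @param x,y numeric vectors, `n >= 10`.
#' @param rng_seed seed for the MCD subset search (deterministic given the
#'   seed; the search is exhaustive over elemental subsets at small n).
#' @param iqr_factor fence multiplier (default 1.5).
#' @return list: `r`, `p` (two-sided, on retained n), `outliers` (indices),
#'   `n_retained`.
#' @export
skippedCorrelation <- function(x, y, rng_seed = 0L, iqr_factor = 1.5) {
  n <- length(x)
  if (length(y) != n) stopf("x and y must have equal length")
  if (n < 10L) stopf("need n >= 10 for a stable robust center")
  X <- cbind(x, y)
  center <- withSeed(childSeed(rng_seed, "mcd"), {
    ns <- if (choose(n, 3) <= 5000) "exact" else 500
    tryCatch(MASS::cov.rob(X, method = "mcd", nsamp = ns)$center,
             error = function(e) {
               # (near-)collinear clouds have a singular MCD scatter; the
               # coordinatewise median is then a robust center
               apply(X, 2, median)
             })
  })
  flagged <- rep(FALSE, n)
  for (i in seq_len(n)) {
    d <- X[i, ] - center
    nd <- sqrt(sum(d^2))
    if (nd < 1e-12) next
    proj <- as.vector((X - matrix(center, n, 2, byrow = TRUE)) %*% d) / nd
    q <- quantile(proj, c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    flagged <- flagged | proj < q[1] - iqr_factor * iqr |
      proj > q[2] + iqr_factor * iqr
  }
  keep <- !flagged
  if (sum(keep) < 3L) {
    stopf("degenerate-removal error: fewer than 3 points retained")
  }
  r <- cor(x[keep], y[keep])
  nk <- sum(keep)
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((nk - 2) / (1 - r^2))
    2 * pt(-abs(tstat), nk - 2)
  }
  list(r = r, p = p, outliers = which(flagged), n_retained = nk)
}

#' Covariate-adjusted (partial) correlation
#'
#' Correlation of the residuals of `x` and `y` after projecting out the
#' covariate (with intercept). A constant covariate falls back to the plain
#' correlation with a warning.
#'
#' @param x,y,covariate equal-length numeric vectors, `n >= 4`.
#' @return the partial correlation.
#' @export
adjustedCorrelation <- function(x, y, covariate) {
  n <- length(x)
  if (length(y) != n || length(covariate) != n) {
    stopf("x, y and covariate must have equal length")
  }
  if (n < 4L) stopf("need n >= 4")
  if (sd(covariate) == 0) {
    warning("constant covariate; returning the plain correlation")
    return(cor(x, y))
  }
  Z <- cbind(1, covariate)
  rx <- lm.fit(Z, x)$residuals
  ry <- lm.fit(Z, y)$residuals
  # a variable fully explained by the covariate has no residual variance
  if (var(rx) < 1e-20 * var(x) || var(ry) < 1e-20 * var(y)) {
    return(0)
  }
  cor(rx, ry)
}

#' Sign-flip permutation test (one-sample), with optional voxelwise FWE
#'
#' Recomputes the one-sample t statistic under random sign flips of the
#' per-participant effects. In `"single"` mode a scalar permutation p-value
#' is returned; in `"voxelwise_fwe"` mode the effects form a participants x
#' voxels matrix and the null of the maximum statistic across voxels yields
#' family-wise-error corrected voxel p-values and the FWE threshold at
#' `alpha`. p-values use the add-one rule
#' `p = (1 + #(null >= observed)) / (1 + n_perm)`.
#'
#' @param values numeric vector (length n participants) or matrix
#'   (participants x voxels).
#' @param n_perm number of permutations (default 10000).
#' @param mode `"single"` or `"voxelwise_fwe"`.
#' @param alternative `"greater"` (default, as in one-sided map inference)
#'   or `"two.sided"`.
#' @param alpha FWE level for the returned threshold (default 0.05).
#' @param rng_seed integer seed.
#' @return for `"single"`: list `statistic`, `p`. For `"voxelwise_fwe"`:
#'   list `statistic` (per voxel), `p_fwe` (per voxel), `threshold`
#'   (max-statistic null quantile at `1 - alpha`), `significant` (logical).
#' @export
signFlipPermutation <- function(values, n_perm = 10000,
                                mode = c("single", "voxelwise_fwe"),
                                alternative = c("greater", "two.sided"),
                                alpha = 0.05, rng_seed = 0L) {
  mode <- match.arg(mode)
  alternative <- match.arg(alternative)
  if (n_perm < 1) stopf("n_perm must be >= 1")
  V <- if (is.matrix(values)) values else matrix(values, ncol = 1L)
  n <- nrow(V)
  if (n < 5L) stopf("need at least 5 participants")
  tstat <- function(m, ss) {
    # ss = column sums of squares (invariant under sign flips)
    sdv <- sqrt(pmax(ss / n - m^2, 0) * n / (n - 1))
    t_ <- m / (sdv / sqrt(n))
    t_[sdv == 0] <- sign(m[sdv == 0]) * Inf
    t_
  }
  ss <- colSums(V^2)
  t_obs <- tstat(colMeans(V), ss)
  if (alternative == "two.sided") t_obs <- abs(t_obs)
  null_max <- numeric(n_perm)
  exceed <- numeric(ncol(V))
  withSeed(childSeed(rng_seed, "signflip"), {
    block <- 500L
    done <- 0L
    while (done < n_perm) {
      b <- min(block, n_perm - done)
      S <- matrix(sample(c(-1, 1), b * n, replace = TRUE), b, n)
      M <- (S %*% V) / n
      SS <- matrix(ss / n, b, ncol(V), byrow = TRUE)
      sdv <- sqrt(pmax(SS - M^2, 0) * n / (n - 1))
      Tn <- M / (sdv / sqrt(n))
      zero <- sdv == 0
      if (any(zero)) Tn[zero] <- sign(M[zero]) * Inf
      if (alternative == "two.sided") Tn <- abs(Tn)
      mx <- apply(Tn, 1L, max)
      null_max[(done + 1):(done + b)] <- mx
      if (mode == "single") {
        exceed <- exceed + colSums(Tn >= rep(t_obs, each = b))
      } else {
        exceed <- exceed + vapply(seq_along(t_obs),
                                  function(v) sum(mx >= t_obs[v]),
                                  numeric(1))
      }
      done <- done + b
    }
  })
  p <- (1 + exceed) / (1 + n_perm)
  if (mode == "single") {
    list(statistic = unname(t_obs[1]), p = unname(p[1]))
  } else {
    thr <- quantile(null_max, 1 - alpha, names = FALSE)
    list(statistic = t_obs, p_fwe = p, threshold = thr,
         significant = t_obs > thr)
  }
}
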