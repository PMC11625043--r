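#' Statistical result container
#'
#' Lightweight container shared by every test in the battery: method tag,
#' statistic, degrees of freedom (one or two), p-value, effect size (Cohen's
#' d or partial eta squared where defined) and sample sizes.
#'
#' @param method Method tag, e.g. `"welch_f"`, `"t2"`, `"jt"`.
#' @param statistic Test statistic.
#' @param df Degrees of freedom (length 1 or 2; `NA` where undefined).
#' @param p p-value.
#' @param effect Effect size (`NA` where undefined).
#' @param n Sample size(s).
#' @param extra Named list of method-specific extras.
#' @return A list of class `hemilat_stat`.
#' @export
stat_result <- function(method, statistic, df, p, effect = NA_real_,
                        n = NULL, extra = list()) {
  structure(c(list(method = method, statistic = unname(statistic),
                   df = unname(df), p = unname(p), effect = unname(effect),
                   n = n), extra),
            class = "hemilat_stat")
}

#' @export
print.hemilat_stat <- function(x, ...) {
  df <- paste(format(x$df, digits = 4), collapse = ", ")
  cat(sprintf("<%s> statistic = %.4f, df = %s, p = %.4g", x$method,
              x$statistic, df, x$p))
  if (!is.null(x$effect) && !is.na(x$effect)) cat(sprintf(", effect = %.4f", x$effect))
  cat("\n")
  invisible(x)
}

#' One-sample t test
#'
#' Two-sided t test of a mean against `mu0`, with Cohen's d
#' `(mean - mu0)/sd` as effect size. Used to ask whether a network's
#' laterality differs from zero (symmetric).
#'
#' @param x Numeric vector.
#' @param mu0 Null mean (default 0).
#' @return A `hemilat_stat` (method `"t1"`).
#' @export
one_sample_t <- function(x, mu0 = 0) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) {
    hemi_stop("hemilat_degenerate_error", "one-sample t needs n >= 2")
  }
  if (stats::sd(x) == 0) {
    hemi_stop("hemilat_degenerate_error", "one-sample t: zero variance")
  }
  tt <- stats::t.test(x, mu = mu0)
  stat_result("t1", tt$statistic, tt$parameter, tt$p.value,
              effect = (mean(x) - mu0) / stats::sd(x), n = length(x))
}

group_moments <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    hemi_stop("hemilat_value_error", "need at least 2 groups")
  }
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (any(lengths(groups) < 2L)) {
    hemi_stop("hemilat_value_error", "every group needs n >= 2")
  }
  list(groups = groups,
       m = vapply(groups, mean, numeric(1)),
       s = vapply(groups, stats::sd, numeric(1)),
       n = lengths(groups))
}

#' Levene's test for homogeneity of variance (mean-centered)
#'
#' Classic one-way F on absolute deviations from the group means; the gate
#' used to choose between classic and Welch ANOVA.
#'
#' @param groups List of numeric vectors.
#' @return A `hemilat_stat` (method `"levene"`).
#' @export
levene_test <- function(groups) {
  gm <- group_moments(groups)
  z <- lapply(gm$groups, function(g) abs(g - mean(g)))
  m <- vapply(z, mean, numeric(1))
  n <- lengths(z)
  N <- sum(n)
  k <- length(z)
  grand <- sum(n * m) / N
  ssb <- sum(n * (m - grand)^2)
  ssw <- sum(vapply(z, function(g) sum((g - mean(g))^2), numeric(1)))
  if (ssw == 0) {
    if (ssb == 0) {
      hemi_stop("hemilat_degenerate_error",
                "Levene test undefined: no dispersion in any group")
    }
    return(stat_result("levene", Inf, c(k - 1, N - k), 0, n = n))
  }
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  stat_result("levene", f, c(k - 1, N - k),
              stats::pf(f, k - 1, N - k, lower.tail = FALSE), n = n)
}

welch_f_from_moments <- function(m, s, n) {
  if (any(s == 0)) {
    hemi_stop("hemilat_degenerate_error", "Welch ANOVA: zero within-group variance")
  }
  k <- length(m)
  w <- n / s^2
  W <- sum(w)
  mw <- sum(w * m) / W
  A <- sum(w * (m - mw)^2) / (k - 1)
  B <- sum((1 - w / W)^2 / (n - 1))
  f <- A / (1 + 2 * (k - 2) * B / (k^2 - 1))
  df2 <- (k^2 - 1) / (3 * B)
  list(f = f, df1 = k - 1, df2 = df2,
       p = stats::pf(f, k - 1, df2, lower.tail = FALSE))
}

classic_f_from_moments <- function(m, s, n) {
  k <- length(m)
  N <- sum(n)
  grand <- sum(n * m) / N
  ssb <- sum(n * (m - grand)^2)
  ssw <- sum((n - 1) * s^2)
  if (ssw == 0) {
    hemi_stop("hemilat_degenerate_error", "ANOVA: zero within-group variance")
  }
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  list(f = f, df1 = k - 1, df2 = N - k,
       p = stats::pf(f, k - 1, N - k, lower.tail = FALSE),
       ssb = ssb, ssw = ssw)
}

#' One-way ANOVA from group summary statistics
#'
#' Reconstructs the classic F (between/within sums of squares) or the Welch
#' heteroscedasticity-robust F (weights `n_i/s_i^2`, Welch-Satterthwaite
#' denominator df) from per-group means, SDs and sizes. Partial eta squared
#' `SSB/(SSB + SSW)` is reported for both kinds, computed from the classic
#' sums of squares.
#'
#' @param means,sds,ns Per-group means, standard deviations and sizes.
#' @param kind `"classic"` or `"welch"`.
#' @return A `hemilat_stat` (method `"classic_f"` or `"welch_f"`).
#' @export
anova_from_summary <- function(means, sds, ns, kind = c("classic", "welch")) {
  kind <- match.arg(kind)
  if (length(means) < 2L || length(means) != length(sds) ||
      length(means) != length(ns)) {
    hemi_stop("hemilat_value_error", "need aligned summaries for >= 2 groups")
  }
  if (any(ns < 2)) hemi_stop("hemilat_value_error", "every group needs n >= 2")
  if (any(sds < 0)) hemi_stop("hemilat_value_error", "negative standard deviation")
  cl <- classic_f_from_moments(means, sds, ns)
  eta <- cl$ssb / (cl$ssb + cl$ssw)
  if (kind == "classic") {
    stat_result("classic_f", cl$f, c(cl$df1, cl$df2), cl$p, effect = eta, n = ns)
  } else {
    we <- welch_f_from_moments(means, sds, ns)
    stat_result("welch_f", we$f, c(we$df1, we$df2), we$p, effect = eta, n = ns)
  }
}

#' One-way ANOVA on raw groups
#'
#' In `auto` mode a mean-centered Levene test at `het_alpha` selects the
#' Welch F under variance heterogeneity and the classic F otherwise;
#' `force` overrides the gate. Effect size is partial eta squared from the
#' classic sums of squares in both cases.
#'
#' @param groups List of numeric vectors.
#' @param force `"auto"`, `"classic"` or `"welch"`.
#' @param het_alpha Heterogeneity gate level (default 0.05).
#' @return A `hemilat_stat` with extras `levene_p` and `variant`.
#' @export
oneway_anova <- function(groups, force = c("auto", "classic", "welch"),
                         het_alpha = 0.05) {
  force <- match.arg(force)
  gm <- group_moments(groups)
  lev_p <- NA_real_
  kind <- force
  if (force == "auto") {
    lev <- levene_test(gm$groups)
    lev_p <- lev$p
    kind <- if (lev_p < het_alpha) "welch" else "classic"
  }
  res <- anova_from_summary(gm$m, gm$s, gm$n, kind)
  res$levene_p <- lev_p
  res$variant <- kind
  res
}

#' Two-sample t test from summary statistics
#'
#' Pooled-variance or Welch two-sample t with Cohen's d (pooled SD for the
#' pooled test, root-mean variance for Welch).
#'
#' @param mean1,sd1,n1 Summary of the first group.
#' @param mean2,sd2,n2 Summary of the second group.
#' @param kind `"pooled"` or `"welch"`.
#' @return A `hemilat_stat` (method `"t2"`).
#' @export
t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                           kind = c("pooled", "welch")) {
  kind <- match.arg(kind)
  if (n1 < 2 || n2 < 2) hemi_stop("hemilat_value_error", "each group needs n >= 2")
  if (sd1 == 0 && sd2 == 0) {
    hemi_stop("hemilat_degenerate_error", "two-sample t: both variances zero")
  }
  if (kind == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    d <- (mean1 - mean2) / sqrt(sp2)
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    d <- (mean1 - mean2) / sqrt((sd1^2 + sd2^2) / 2)
  }
  t <- (mean1 - mean2) / se
  stat_result("t2", t, df, 2 * stats::pt(-abs(t), df), effect = d, n = c(n1, n2))
}

#' Pearson chi-squared test of independence
#'
#' Without continuity correction, `df = (r-1)(c-1)`; expected counts are
#' formed from the marginals and must all be positive.
#'
#' @param tab Contingency matrix of counts.
#' @return A `hemilat_stat` (method `"chi2"`).
#' @export
chi_square_independence <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(!is.finite(tab))) {
    hemi_stop("hemilat_value_error", "contingency counts must be finite and non-negative")
  }
  rs <- rowSums(tab)
  cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) {
    hemi_stop("hemilat_value_error", "zero marginal in contingency table")
  }
  E <- outer(rs, cs) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  stat_result("chi2", stat, df, stats::pchisq(stat, df, lower.tail = FALSE),
              n = sum(tab))
}

#' Games-Howell post hoc pairwise comparisons
#'
#' For each pair of groups: Welch t with Welch-Satterthwaite df, referred to
#' the studentized-range distribution via `q = t * sqrt(2)` with the total
#' number of groups as the number of means. The standard post hoc companion
#' of the Welch ANOVA under unequal variances.
#'
#' @param groups Named list of numeric vectors.
#' @return data.frame with one row per pair: `group1`, `group2`, `diff`,
#'   `statistic` (Welch t), `df`, `p`.
#' @export
games_howell <- function(groups) {
  gm <- group_moments(groups)
  k <- length(gm$groups)
  nms <- names(gm$groups) %||% paste0("g", seq_len(k))
  pairs <- utils::combn(k, 2)
  rows <- apply(pairs, 2L, function(ij) {
    i <- ij[1L]; j <- ij[2L]
    vi <- gm$s[i]^2 / gm$n[i]
    vj <- gm$s[j]^2 / gm$n[j]
    if (vi + vj == 0) {
      hemi_stop("hemilat_degenerate_error",
                "Games-Howell: zero variance in pair %s-%s", nms[i], nms[j])
    }
    t <- (gm$m[i] - gm$m[j]) / sqrt(vi + vj)
    df <- (vi + vj)^2 / (vi^2 / (gm$n[i] - 1) + vj^2 / (gm$n[j] - 1))
    p <- stats::ptukey(abs(t) * sqrt(2), nmeans = k, df = df, lower.tail = FALSE)
    data.frame(group1 = nms[i], group2 = nms[j], diff = gm$m[i] - gm$m[j],
               statistic = t, df = df, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Jonckheere-Terpstra trend test
#'
#' Tests for a monotone trend across ordered groups. `J` sums, over all
#' ordered group pairs, the Mann-Whitney counts of later-group values
#' exceeding earlier-group values (ties add 1/2); the statistic is
#' standardized with the tie-corrected null variance and referred to the
#' normal distribution, one-sided. With `alternative = "decreasing"` a
#' decreasing trend yields a negative z and a small p.
#'
#' @param groups List of >= 3 numeric vectors in hypothesized order.
#' @param alternative `"decreasing"` (default) or `"increasing"`.
#' @return A `hemilat_stat` (method `"jt"`, statistic z) with extras
#'   `J`, `mu`, `sigma2`.
#' @export
jonckheere_terpstra <- function(groups, alternative = c("decreasing", "increasing")) {
  alternative <- match.arg(alternative)
  if (!is.list(groups) || length(groups) < 3L) {
    hemi_stop("hemilat_value_error", "Jonckheere-Terpstra requires >= 3 ordered groups")
  }
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (any(lengths(groups) == 0L)) {
    hemi_stop("hemilat_value_error", "Jonckheere-Terpstra: empty group")
  }
  k <- length(groups)
  J <- 0
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      J <- J + sum(outer(groups[[i]], groups[[j]], "<")) +
        0.5 * sum(outer(groups[[i]], groups[[j]], "=="))
    }
  }
  n <- lengths(groups)
  N <- sum(n)
  tvec <- as.numeric(table(unlist(groups)))
  mu <- (N^2 - sum(n^2)) / 4
  v1 <- (N * (N - 1) * (2 * N + 5) - sum(n * (n - 1) * (2 * n + 5)) -
           sum(tvec * (tvec - 1) * (2 * tvec + 5))) / 72
  v2 <- sum(n * (n - 1) * (n - 2)) * sum(tvec * (tvec - 1) * (tvec - 2)) /
    (36 * N * (N - 1) * (N - 2))
  v3 <- sum(n * (n - 1)) * sum(tvec * (tvec - 1)) / (8 * N * (N - 1))
  sigma2 <- v1 + v2 + v3
  z <- if (sigma2 <= 0) 0 else (J - mu) / sqrt(sigma2)
  p <- if (alternative == "increasing") {
    stats::pnorm(z, lower.tail = FALSE)
  } else {
    stats::pnorm(z)
  }
  stat_result("jt", z, NA_real_, p, n = n,
              extra = list(J = J, mu = mu, sigma2 = sigma2,
                           alternative = alternative))
}

#' Partial correlation with covariate residualization
#'
#' Pearson correlation between the least-squares residuals of `x` and `y`
#' regressed on an intercept plus the covariates;
#' `t = r * sqrt((n - k - 2)/(1 - r^2))` with `df = n - k - 2`. With no
#' covariates this reduces exactly to the plain Pearson correlation.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional numeric matrix/data.frame, one row per
#'   observation.
#' @return A `hemilat_stat` (method `"partial_r"`, or `"pearson_r"` when
#'   `k = 0`).
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) hemi_stop("hemilat_shape_error", "x and y lengths differ")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (!ncol(covariates)) covariates <- NULL
  }
  k <- if (is.null(covariates)) 0L else ncol(covariates)
  if (!is.null(covariates) && nrow(covariates) != n) {
    hemi_stop("hemilat_shape_error", "covariate rows do not match observations")
  }
  if (n <= k + 2) {
    hemi_stop("hemilat_value_error", "need n > k + 2 observations")
  }
  if (k == 0L) {
    rx <- x
    ry <- y
    method <- "pearson_r"
  } else {
    X <- cbind(1, covariates)
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      hemi_stop("hemilat_collinearity_error", "rank-deficient covariate matrix")
    }
    rx <- qr.resid(qx, x)
    ry <- qr.resid(qx, y)
    method <- "partial_r"
  }
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    hemi_stop("hemilat_degenerate_error", "zero residual variance")
  }
  r <- stats::cor(rx, ry)
  df <- n - k - 2
  t <- r * sqrt(df / (1 - r^2))
  stat_result(method, r, df, 2 * stats::pt(-abs(t), df), n = n,
              extra = list(t = t, k = k))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values with monotonicity enforcement, order-preserving
#' with the input.
#'
#' @param pvalues Vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
fdr_bh <- function(pvalues) {
  if (!is.numeric(pvalues) || any(!is.finite(pvalues)) ||
      any(pvalues < 0) || any(pvalues > 1)) {
    hemi_stop("hemilat_value_error", "p-values must be finite and in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}
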