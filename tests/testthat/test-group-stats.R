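test_that("one-sample t matches the hand computation and guards degeneracy", {
  expect_equal(one_sample_t(c(-1, 0, 1))$statistic, 0)
  res <- one_sample_t(c(1, 2, 3))
  expect_equal(res$statistic, sqrt(12), tolerance = 1e-10)
  expect_equal(res$effect, 2)
  expect_equal(res$df, 2)
  expect_error(one_sample_t(1), class = "hemilat_degenerate_error")
  expect_error(one_sample_t(c(2, 2, 2)), class = "hemilat_degenerate_error")
})

test_that("Levene gate flags heteroscedastic groups and passes identical ones", {
  g <- list(c(1, 2, 3), c(1, 2, 3))
  lev <- levene_test(g)
  expect_equal(lev$statistic, 0)
  expect_gt(lev$p, 0.99)
  set.seed(8)
  hits <- vapply(1:40, function(i) {
    a <- rnorm(30, sd = 1)
    b <- rnorm(30, sd = 5)
    levene_test(list(a, b))$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  expect_error(levene_test(list(c(1, 2))), class = "hemilat_value_error")
  expect_error(levene_test(list(c(1, 1), c(1, 1))),
               class = "hemilat_degenerate_error")
})

test_that("one-way ANOVA agrees with stats::oneway.test for both variants", {
  # hand ANOVA: SSB = 16, SSW = 1.5 -> F = (16/2)/(1.5/3) = 16
  g <- list(c(1, 2), c(3, 4), c(5, 6))
  res <- oneway_anova(g, force = "classic")
  expect_equal(res$statistic, 16)
  expect_equal(res$df, c(2, 3))
  same <- list(c(1, 2, 3), c(1.5, 2, 2.5), c(1, 2, 3))
  expect_equal(oneway_anova(same, force = "classic")$statistic,
               unname(oneway.test(v ~ g, data.frame(
                 v = unlist(same), g = rep(1:3, lengths(same))),
                 var.equal = TRUE)$statistic), tolerance = 1e-10)
  set.seed(30)
  for (i in 1:10) {
    gx <- list(rnorm(8), rnorm(9, 1), rnorm(7, 0, 3))
    d <- data.frame(v = unlist(gx), g = factor(rep(1:3, lengths(gx))))
    ow_c <- oneway.test(v ~ g, d, var.equal = TRUE)
    ow_w <- oneway.test(v ~ g, d, var.equal = FALSE)
    rc <- oneway_anova(gx, force = "classic")
    rw <- oneway_anova(gx, force = "welch")
    expect_equal(rc$statistic, unname(ow_c$statistic), tolerance = 1e-10)
    expect_equal(rc$p, unname(ow_c$p.value), tolerance = 1e-10)
    expect_equal(rw$statistic, unname(ow_w$statistic), tolerance = 1e-10)
    expect_equal(rw$df[2], unname(ow_w$parameter[2]), tolerance = 1e-8)
    expect_equal(rw$p, unname(ow_w$p.value), tolerance = 1e-10)
    # raw-vs-summary oracle equivalence
    m <- vapply(gx, mean, numeric(1))
    s <- vapply(gx, sd, numeric(1))
    n <- lengths(gx)
    expect_equal(anova_from_summary(m, s, n, "classic")$statistic,
                 rc$statistic, tolerance = 1e-10)
    expect_equal(anova_from_summary(m, s, n, "welch")$statistic,
                 rw$statistic, tolerance = 1e-10)
  }
  expect_equal(oneway_anova(list(c(1, 2, 3), c(1, 2, 3)), force = "classic")$statistic, 0)
})

test_that("summary-statistic ANOVA and t reproduce the published cohort table", {
  tab <- table1_from_summary()
  get <- function(v, m) tab[tab$variable == v & tab$method == m, ]
  sis <- get("sis_threshold", "welch_f")
  expect_equal(sis$statistic, 28.217, tolerance = 0.005 * 28.217)
  expect_equal(sis$df2, 38.920, tolerance = 0.005 * 38.92)
  sin <- get("sin_threshold", "welch_f")
  expect_equal(sin$statistic, 25.070, tolerance = 0.01 * 25.07)
  ds <- get("digit_span", "classic_f")
  expect_equal(ds$statistic, 28.749, tolerance = 0.01 * 28.749)
  edu <- get("education", "t2")
  expect_equal(edu$statistic, 3.769, tolerance = 0.001 * 3.769)
  expect_equal(edu$effect, 1.112, tolerance = 1e-3)
  hear <- get("hearing", "t2")
  expect_equal(abs(hear$statistic), 0.170, tolerance = 0.01)
  gen <- get("gender", "chi2")
  expect_equal(gen$statistic, 2.174, tolerance = 1e-3)
  expect_equal(gen$df1, 2)
  # equal means -> F = 0
  expect_equal(anova_from_summary(c(1, 1, 1), c(1, 2, 3), c(5, 5, 5),
                                  "welch")$statistic, 0)
  expect_error(anova_from_summary(c(1, 2), c(0, 0), c(5, 5), "welch"),
               class = "hemilat_degenerate_error")
})

test_that("two-sample t from summaries matches t.test on the raw data", {
  set.seed(12)
  for (i in 1:8) {
    a <- rnorm(9, 1, 2)
    b <- rnorm(12)
    for (kind in c("pooled", "welch")) {
      tt <- t.test(a, b, var.equal = kind == "pooled")
      r <- t_from_summary(mean(a), sd(a), length(a), mean(b), sd(b), length(b),
                          kind = kind)
      expect_equal(r$statistic, unname(tt$statistic), tolerance = 1e-10)
      expect_equal(r$df, unname(tt$parameter), tolerance = 1e-8)
      expect_equal(r$p, tt$p.value, tolerance = 1e-10)
    }
  }
  expect_equal(t_from_summary(1, 1, 10, 1, 1, 10)$statistic, 0)
  expect_error(t_from_summary(1, 0, 5, 2, 0, 5),
               class = "hemilat_degenerate_error")
})

test_that("chi-squared matches the hand formula and chisq.test", {
  tab <- matrix(c(3, 7, 7, 3), 2, byrow = TRUE)
  expect_equal(chi_square_independence(tab)$statistic, 3.2, tolerance = 1e-12)
  g <- matrix(c(12, 12, 9, 14, 14, 9), 3, byrow = TRUE)
  res <- chi_square_independence(g)
  expect_equal(res$statistic, unname(chisq.test(g, correct = FALSE)$statistic),
               tolerance = 1e-10)
  expect_equal(res$df, 2)
  prop <- outer(c(10, 20), c(3, 7)) / 10
  expect_equal(chi_square_independence(prop)$statistic, 0)
  expect_error(chi_square_independence(matrix(c(0, 0, 1, 2), 2)),
               class = "hemilat_value_error")
})

test_that("Games-Howell matches a brute-force implementation and detects shifts", {
  two <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  gh0 <- games_howell(two)
  expect_equal(gh0$statistic, 0)
  expect_gt(gh0$p, 0.999)
  set.seed(41)
  for (i in 1:50) {
    gx <- list(a = rnorm(6 + i %% 4), b = rnorm(7, 0.5), c = rnorm(8, 0, 2))
    got <- games_howell(gx)
    want <- brute_games_howell(gx)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-8)
    expect_equal(got$df, want$df, tolerance = 1e-8)
    expect_equal(got$p, want$p, tolerance = 1e-8)
  }
  # one group shifted by 5 SDs is always detected
  set.seed(42)
  ps <- vapply(1:20, function(i) {
    gx <- list(a = rnorm(20), b = rnorm(20), c = rnorm(20, 5))
    gh <- games_howell(gx)
    max(gh$p[gh$group2 == "c" | gh$group1 == "c"])
  }, numeric(1))
  expect_true(all(ps < 0.001))
  # p-values invariant under group relabeling
  gx <- list(a = rnorm(8), b = rnorm(9, 1), c = rnorm(10, 2))
  p1 <- sort(games_howell(gx)$p)
  p2 <- sort(games_howell(gx[c(3, 1, 2)])$p)
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("Jonckheere-Terpstra matches brute-force enumeration with ties", {
  res <- jonckheere_terpstra(list(c(1, 2), c(3, 4), c(5, 6)),
                             alternative = "increasing")
  expect_equal(res$J, 12)
  expect_equal(res$mu, 6)
  expect_equal(res$sigma2, 19 / 3, tolerance = 1e-12)
  expect_equal(res$statistic, 2.38415824272, tolerance = 1e-8)

  # all-identical constants: tie-corrected variance 0 -> z defined as 0
  flat <- jonckheere_terpstra(list(c(2, 2), c(2, 2), c(2, 2)))
  expect_equal(flat$statistic, 0)

  set.seed(77)
  for (i in 1:30) {
    gx <- lapply(1:3, function(j) sample(1:6, 5 + j, replace = TRUE))
    got <- jonckheere_terpstra(gx, alternative = "increasing")
    want <- brute_jt(gx)
    expect_equal(got$J, want$J, tolerance = 1e-10)
    expect_equal(got$statistic, want$z, tolerance = 1e-8)
    # reversing the group order negates z
    rev_ <- jonckheere_terpstra(rev(gx), alternative = "increasing")
    expect_equal(rev_$statistic, -got$statistic, tolerance = 1e-10)
  }
  # decreasing alternative: decreasing data give negative z, small p
  dec <- jonckheere_terpstra(list(c(5, 6), c(3, 4), c(1, 2)),
                             alternative = "decreasing")
  expect_lt(dec$statistic, 0)
  expect_lt(dec$p, 0.05)
  expect_error(jonckheere_terpstra(list(1:3, 4:6)), class = "hemilat_value_error")
  expect_error(jonckheere_terpstra(list(1:3, numeric(0), 4:6)),
               class = "hemilat_value_error")
})

test_that("partial correlation residualizes covariates correctly", {
  set.seed(9)
  x <- rnorm(40)
  y <- rnorm(40)
  # no covariates -> plain Pearson
  expect_equal(partial_correlation(x, y)$statistic, cor(x, y), tolerance = 1e-12)
  # hand-computed 6-point instance with one covariate
  x6 <- c(1, 2, 3, 4, 5, 6)
  y6 <- c(2, 1, 4, 3, 6, 5)
  z6 <- c(1, 1, 2, 2, 3, 3)
  rx <- resid(lm(x6 ~ z6))
  ry <- resid(lm(y6 ~ z6))
  expect_equal(partial_correlation(x6, y6, cbind(z6))$statistic, cor(rx, ry),
               tolerance = 1e-10)
  # oracle: inverse-correlation-matrix formula on random instances
  for (i in 1:50) {
    n <- 15 + i %% 10
    Z <- matrix(rnorm(n * 3), n, 3)
    xr <- Z %*% c(1, -1, 0.5) + rnorm(n)
    yr <- Z %*% c(0.5, 1, -1) + rnorm(n)
    expect_equal(partial_correlation(xr, yr, Z)$statistic,
                 brute_partial_r(xr, yr, Z), tolerance = 1e-8)
  }
  # shared covariate removes a spurious correlation
  z <- rnorm(200)
  xs <- z + rnorm(200, sd = 0.05)
  ys <- z + rnorm(200, sd = 0.05)
  expect_gt(cor(xs, ys), 0.9)
  expect_lt(abs(partial_correlation(xs, ys, cbind(z))$statistic), 0.2)
  # a covariate orthogonal to x and y barely changes r
  q <- qr.resid(qr(cbind(1, x, y)), rnorm(40))
  expect_equal(partial_correlation(x, y, cbind(q))$statistic, cor(x, y),
               tolerance = 1e-10)
  expect_error(partial_correlation(x, y, cbind(x, x)),
               class = "hemilat_collinearity_error")
  expect_error(partial_correlation(1:3, 1:3, matrix(rnorm(9), 3)),
               class = "hemilat_value_error")
})

test_that("BH adjustment matches the hand step-up and is monotone", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(0.37), 0.37)
  expect_equal(fdr_bh(rep(1, 5)), rep(1, 5))
  set.seed(3)
  for (i in 1:20) {
    p <- runif(10)^2
    adj <- fdr_bh(p)
    expect_equal(adj, brute_bh(p), tolerance = 1e-12)
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
  expect_error(fdr_bh(c(0.1, 1.2)), class = "hemilat_value_error")
})
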