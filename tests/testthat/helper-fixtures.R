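# Small fixtures and independent brute-force oracles used across the suite.

# 2-pair, 4-vertex atlas: pairs p0 = (v0 L, v1 R), p1 = (v2 L, v3 R)
tiny_atlas <- function(networks = c("LAN", "LAN")) {
  as_atlas(data.frame(
    vertex_id = 0:3,
    hemisphere = c("L", "R", "L", "R"),
    pair_id = c(0L, 0L, 1L, 1L),
    network = rep(networks, each = 2L)
  ))
}

# Atlas with p pairs in a single network, vertices interleaved L/R
one_net_atlas <- function(p, network = "SMN", seed = 1L) {
  make_atlas(stats::setNames(p, network), seed = seed)
}

random_fc <- function(n, seed) {
  set.seed(seed)
  z <- matrix(stats::rnorm(n * n, sd = 0.4), n, n)
  z <- (z + t(z)) / 2
  diag(z) <- NA_real_
  z
}

# ---- brute-force oracles (kept deliberately naive) ----

brute_strength_sums <- function(fc, atlas) {
  n <- nrow(atlas)
  he <- numeric(n)
  intra <- numeric(n)
  for (i in seq_len(n)) {
    hi <- atlas$hemisphere[i]
    partner <- which(atlas$pair_id == atlas$pair_id[i] & seq_len(n) != i)
    for (j in seq_len(n)) {
      if (j == i) next
      if (atlas$hemisphere[j] == hi) {
        intra[i] <- intra[i] + fc[i, j]
      } else if (j != partner) {
        he[i] <- he[i] + fc[i, j]
      }
    }
  }
  data.frame(vertex_id = atlas$vertex_id, he = he, intra = intra)
}

brute_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# partial correlation through the inverse correlation matrix
brute_partial_r <- function(x, y, Z) {
  R <- stats::cor(cbind(x, y, Z))
  P <- solve(R)
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    val <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

brute_games_howell <- function(groups) {
  k <- length(groups)
  out <- NULL
  for (i in seq_len(k - 1)) {
    for (j in seq.int(i + 1, k)) {
      a <- groups[[i]]
      b <- groups[[j]]
      vi <- stats::var(a) / length(a)
      vj <- stats::var(b) / length(b)
      t <- (mean(a) - mean(b)) / sqrt(vi + vj)
      df <- (vi + vj)^2 / (vi^2 / (length(a) - 1) + vj^2 / (length(b) - 1))
      p <- stats::ptukey(abs(t) * sqrt(2), k, df, lower.tail = FALSE)
      out <- rbind(out, data.frame(i = i, j = j, statistic = t, df = df, p = p))
    }
  }
  out
}

# J by explicit pair enumeration, moments from first principles
brute_jt <- function(groups) {
  k <- length(groups)
  J <- 0
  for (i in seq_len(k - 1)) {
    for (j in seq.int(i + 1, k)) {
      for (x in groups[[i]]) {
        for (y in groups[[j]]) {
          J <- J + (y > x) + 0.5 * (y == x)
        }
      }
    }
  }
  n <- lengths(groups)
  N <- sum(n)
  tv <- as.numeric(table(unlist(groups)))
  mu <- (N^2 - sum(n^2)) / 4
  s2 <- (N * (N - 1) * (2 * N + 5) - sum(n * (n - 1) * (2 * n + 5)) -
           sum(tv * (tv - 1) * (2 * tv + 5))) / 72 +
    sum(n * (n - 1) * (n - 2)) * sum(tv * (tv - 1) * (tv - 2)) /
      (36 * N * (N - 1) * (N - 2)) +
    sum(n * (n - 1)) * sum(tv * (tv - 1)) / (8 * N * (N - 1))
  list(J = J, mu = mu, sigma2 = s2,
       z = if (s2 <= 0) 0 else (J - mu) / sqrt(s2))
}

# network LI by naive per-pair loop
brute_network_li <- function(limap, net, kind) {
  col <- paste0("li_", kind)
  vcol <- paste0("valid_", kind)
  vals <- c()
  for (r in seq_len(nrow(limap))) {
    if (!is.na(limap$network[r]) && limap$network[r] == net && limap[[vcol]][r]) {
      vals <- c(vals, limap[[col]][r])
    }
  }
  if (length(vals)) mean(vals) else NA_real_
}

# run the connectivity -> LI chain for one simulated subject
subject_limap <- function(atlas, plan, n_timepoints, seed) {
  ts <- simulate_timeseries(build_covariance(atlas, plan), n_timepoints, seed)
  pair_li(strength_sums(compute_fc(ts), atlas), atlas)
}
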