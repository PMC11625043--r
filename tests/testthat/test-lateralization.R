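test_that("pair LI implements (L - R)/|L + R| with the validity epsilon", {
  atlas <- tiny_atlas()
  sums <- data.frame(vertex_id = 0:3,
                     he = c(1, -3, 0.5, 0.5),
                     intra = c(0.6, 0.2, 1e-10, 1e-10))
  li <- pair_li(sums, atlas)
  expect_equal(li$li_intra[li$pair_id == 0], 0.5)      # (0.6-0.2)/0.8
  expect_equal(li$li_he[li$pair_id == 0], 2.0)         # (1-(-3))/|-2|, |LI| > 1 allowed
  expect_equal(li$li_he[li$pair_id == 1], 0)           # he_L = he_R
  expect_false(li$valid_intra[li$pair_id == 1])        # |L+R| = 2e-10 < 1e-8
  expect_true(is.na(li$li_intra[li$pair_id == 1]))
})

test_that("network LI averages valid same-network pairs only", {
  atlas <- as_atlas(data.frame(
    vertex_id = 0:7, hemisphere = rep(c("L", "R"), 4),
    pair_id = rep(0:3, each = 2),
    network = c("LAN", "LAN", "LAN", "LAN", "LAN", "DMN", "NONE", "NONE")))
  limap <- pair_li(data.frame(vertex_id = 0:7,
                              he = c(3, 1, 1, 3, 5, 1, 9, 1),
                              intra = c(0.6, 0.4, 0.7, 0.3, 1, 1, 1, 1)),
                   atlas)
  # pair 2 has mismatched networks (LAN/DMN) -> excluded; pair 3 is NONE
  expect_true(is.na(limap$network[limap$pair_id == 2]))
  out <- suppressWarnings(network_li(limap, networks = c("LAN", "DMN")))
  expect_equal(out$li_intra[out$network == "LAN"], mean(c(0.2, 0.4)))
  expect_equal(out$n_intra[out$network == "LAN"], 2L)
  expect_true(is.na(out$li_intra[out$network == "DMN"]))
  expect_warning(network_li(limap, networks = "DMN"), "no valid pairs")

  # invalid pairs excluded pairwise: {0.2, invalid, 0.4} -> 0.3 with n = 2
  limap2 <- limap
  limap2$valid_intra[limap2$pair_id == 1] <- FALSE
  limap2$li_intra[limap2$pair_id == 1] <- NA
  out2 <- suppressWarnings(network_li(limap2, networks = "LAN"))
  expect_equal(out2$li_intra, 0.2)
  expect_equal(out2$n_intra, 1L)

  # brute-force oracle over random instances
  a <- make_atlas(c(SMN = 4, LAN = 3, NONE = 2), seed = 12)
  for (seed in 1:8) {
    fc <- random_fc(nrow(a), seed + 100)
    lm_ <- pair_li(strength_sums(fc, a), a)
    out <- suppressWarnings(network_li(lm_, networks = c("SMN", "LAN")))
    for (net in c("SMN", "LAN")) {
      for (kind in c("intra", "he")) {
        expect_equal(out[[paste0("li_", kind)]][out$network == net],
                     brute_network_li(lm_, net, kind), tolerance = 1e-12)
      }
    }
  }
})

test_that("young template averages subject maps with listwise validity", {
  atlas <- tiny_atlas()
  mk <- function(li0, li1, valid1 = TRUE) {
    m <- pair_li(data.frame(vertex_id = 0:3, he = c(1, 1, 1, 1),
                            intra = c(1, 1, 1, 1)), atlas)
    m$li_intra <- c(li0, li1)
    m$li_he <- c(li0, li1)
    m$valid_intra <- c(TRUE, valid1)
    m$valid_he <- c(TRUE, valid1)
    m
  }
  t1 <- young_template(list(mk(0.1, 0.5), mk(0.3, 0.7)))
  expect_equal(t1$intra, c(0.2, 0.6))
  # identical maps -> template equals either map
  t2 <- young_template(list(mk(0.1, 0.5), mk(0.1, 0.5)))
  expect_equal(t2$intra, c(0.1, 0.5))
  # pair invalid in one subject -> dropped listwise
  t3 <- young_template(list(mk(0.1, 0.5), mk(0.3, 0.7, valid1 = FALSE)))
  expect_true(is.na(t3$intra[2]))
  expect_equal(t3$intra[1], 0.2)
  expect_error(young_template(list()), class = "hemilat_value_error")
})

test_that("alignment computes cosine similarity over shared valid pairs", {
  atlas <- one_net_atlas(2, "AUD", seed = 1)
  base <- pair_li(data.frame(vertex_id = 0:3, he = rep(1, 4), intra = rep(1, 4)),
                  atlas)
  tmpl <- young_template(list(base))
  set_li <- function(m, v) {
    m$li_intra <- v
    m$valid_intra <- TRUE
    m
  }
  tmpl$intra <- c(1, 0)
  # identical vectors -> 1; orthogonal -> 0; [1,1] vs [1,0] -> 1/sqrt(2)
  expect_equal(alignment(set_li(base, c(1, 0)), tmpl, "AUD", "intra"), 1)
  expect_equal(alignment(set_li(base, c(0, 1)), tmpl, "AUD", "intra"), 0)
  expect_equal(alignment(set_li(base, c(1, 1)), tmpl, "AUD", "intra"),
               1 / sqrt(2), tolerance = 1e-12)
  expect_error(alignment(set_li(base, c(0, 0)), tmpl, "AUD", "intra"),
               class = "hemilat_numeric_error")
  tmpl2 <- tmpl
  tmpl2$intra <- c(1, NA)
  expect_error(alignment(set_li(base, c(1, 1)), tmpl2, "AUD", "intra"),
               class = "hemilat_value_error")
})

test_that("group mean maps and map correlation behave as means and Pearson r", {
  atlas <- one_net_atlas(50, "DMN", seed = 7)
  maps <- lapply(1:3, function(s) subject_limap(atlas, symmetric_plan(), 80, 400 + s))
  gm <- group_mean_map(maps)
  i <- which(gm$valid_intra)[1]
  expect_equal(gm$li_intra[i],
               mean(vapply(maps, function(m) m$li_intra[i], numeric(1))))
  expect_equal(map_correlation(gm, gm, "intra"), 1)
  neg <- gm
  neg$li_intra <- -neg$li_intra
  expect_equal(map_correlation(gm, neg, "intra"), -1)
  # oracle: brute-force Pearson across 100 random pairs
  m1 <- subject_limap(atlas, symmetric_plan(), 80, 900)
  m2 <- subject_limap(atlas, symmetric_plan(), 80, 901)
  sel <- m1$valid_intra & m2$valid_intra
  expect_equal(map_correlation(m1, m2, "intra"),
               brute_pearson(m1$li_intra[sel], m2$li_intra[sel]),
               tolerance = 1e-12)
})

test_that("Steiger's z matches an independent evaluation and is monotone in n", {
  expect_equal(compare_dependent_correlations(0.5, 0.5, 0.3, 50)$statistic, 0)
  res <- compare_dependent_correlations(0.5, 0.3, 0.2, 100)
  expect_equal(res$statistic, 1.77833196951, tolerance = 1e-6)
  zs <- vapply(c(50, 100, 400, 1000), function(n) {
    abs(compare_dependent_correlations(0.5, 0.3, 0.2, n)$statistic)
  }, numeric(1))
  expect_true(all(diff(zs) > 0))
  expect_error(compare_dependent_correlations(1, 0.3, 0.2, 100),
               class = "hemilat_value_error")
})

test_that("hemisphere-swap negates every valid LI and alignment exactly", {
  atlas <- make_atlas(c(SMN = 5, LAN = 5, NONE = 2), seed = 21)
  swapped <- atlas
  swapped$hemisphere <- ifelse(atlas$hemisphere == "L", "R", "L")
  swapped <- as_atlas(swapped)
  plan <- lat_plan(c("SMN", "LAN", "NONE"), intra_L = 0.5, intra_R = 0.2,
                   hetero_L = 0.3, hetero_R = 0.1, homotopic = 0.2)
  for (s in 1:5) {
    ts <- simulate_timeseries(build_covariance(atlas, plan), 100, seed = 600 + s)
    fc <- compute_fc(ts)
    li_a <- pair_li(strength_sums(fc, atlas), atlas)
    li_b <- pair_li(strength_sums(fc, swapped), swapped)
    expect_identical(li_b$valid_intra, li_a$valid_intra)
    expect_identical(li_b$li_intra, -li_a$li_intra)
    expect_identical(li_b$li_he, -li_a$li_he)
    # network LIs negate, alignment negates
    na_ <- suppressWarnings(network_li(li_a, networks = c("SMN", "LAN")))
    nb_ <- suppressWarnings(network_li(li_b, networks = c("SMN", "LAN")))
    expect_equal(nb_$li_intra, -na_$li_intra, tolerance = 1e-15)
    tmpl <- young_template(list(li_a))
    expect_equal(alignment(li_b, tmpl, "SMN", "intra"),
                 -alignment(li_a, tmpl, "SMN", "intra"), tolerance = 1e-15)
  }
})

test_that("the LI map is invariant to global time-series rescaling", {
  atlas <- one_net_atlas(6, "CON", seed = 13)
  S <- build_covariance(atlas, symmetric_plan())
  ts <- simulate_timeseries(S, 90, seed = 55)
  li1 <- pair_li(strength_sums(compute_fc(ts), atlas), atlas)
  ts2 <- timeseries(ts$subject_id, ts$values * 12.5)
  li2 <- pair_li(strength_sums(compute_fc(ts2), atlas), atlas)
  expect_equal(li2$li_intra, li1$li_intra, tolerance = 1e-12)
  expect_equal(li2$li_he, li1$li_he, tolerance = 1e-12)
})
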