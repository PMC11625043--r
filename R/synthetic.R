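#' Default seed for synthetic fixtures
#' @return Integer seed.
#' @export
default_seed <- function() 20240605L

#' Lateralization plan
#'
#' Generative counterpart of the laterality quantities: per-network coupling
#' weights of the latent-factor covariance model. Each network contributes
#' one intra factor per hemisphere (loading `sqrt(intra_H)` on that
#' hemisphere's network vertices), one heterotopic factor (loadings
#' `sqrt(hetero_L)` / `sqrt(hetero_R)` on the left/right network vertices)
#' and one homotopic factor per pair (loading `sqrt(homotopic)` on both
#' members), plus independent noise with SD `noise_sd`. Nonnegative weights
#' guarantee a positive semidefinite covariance by construction.
#'
#' @param network Network label(s).
#' @param intra_L,intra_R,hetero_L,hetero_R,homotopic Nonnegative coupling
#'   weights (variance units).
#' @param noise_sd Positive noise SD (signal units).
#' @return data.frame of class `hemilat_plan`, one row per network.
#' @export
lat_plan <- function(network, intra_L = 0, intra_R = 0, hetero_L = 0,
                     hetero_R = 0, homotopic = 0, noise_sd = 1) {
  df <- data.frame(network = as.character(network),
                   intra_L = intra_L, intra_R = intra_R,
                   hetero_L = hetero_L, hetero_R = hetero_R,
                   homotopic = homotopic, noise_sd = noise_sd,
                   stringsAsFactors = FALSE)
  bad <- setdiff(unique(df$network), hemi_network_levels())
  if (length(bad)) {
    hemi_stop("hemilat_value_error", "unknown network in plan: %s",
              paste(bad, collapse = ", "))
  }
  if (anyDuplicated(df$network)) {
    hemi_stop("hemilat_value_error", "duplicated network in plan")
  }
  w <- as.matrix(df[c("intra_L", "intra_R", "hetero_L", "hetero_R", "homotopic")])
  if (any(!is.finite(w)) || any(w < 0)) {
    hemi_stop("hemilat_value_error", "coupling weights must be finite and >= 0")
  }
  if (any(df$noise_sd <= 0)) {
    hemi_stop("hemilat_value_error", "noise_sd must be > 0")
  }
  class(df) <- c("hemilat_plan", "data.frame")
  df
}

#' Hemispherically symmetric plan
#'
#' Equal left/right couplings in every network: the null condition under
#' which all laterality indices have expectation zero.
#'
#' @param networks Networks to cover.
#' @param intra,hetero,homotopic,noise_sd Shared weights.
#' @return A `hemilat_plan`.
#' @export
symmetric_plan <- function(networks = hemi_network_levels(), intra = 0.3,
                           hetero = 0.15, homotopic = 0.2, noise_sd = 1) {
  lat_plan(networks, intra_L = intra, intra_R = intra,
           hetero_L = hetero, hetero_R = hetero,
           homotopic = homotopic, noise_sd = noise_sd)
}

plan_set <- function(plan, network, ...) {
  vals <- list(...)
  i <- match(network, plan$network)
  for (f in names(vals)) plan[i, f] <- vals[[f]]
  plan
}

#' Default per-group lateralization plans
#'
#' Calibration choices emulating the study conditions: the young group (YNM)
#' carries planted asymmetries (right-lateralized intrahemispheric coupling
#' in CON, right-lateralized heterotopic coupling in LAN, a left-lateralized
#' DMN, milder asymmetries elsewhere); older non-musicians (ONM) are fully
#' symmetric (reduced lateralization); older musicians (OM) retain 80% of
#' the young asymmetry (preserved lateralization).
#'
#' @return Named list of `hemilat_plan` objects (`YNM`, `OM`, `ONM`).
#' @export
default_group_plans <- function() {
  young <- symmetric_plan()
  young <- plan_set(young, "CON", intra_L = 0.18, intra_R = 0.42)
  young <- plan_set(young, "LAN", hetero_L = 0.08, hetero_R = 0.22)
  young <- plan_set(young, "DMN", intra_L = 0.36, intra_R = 0.24)
  young <- plan_set(young, "SMN", hetero_L = 0.12, hetero_R = 0.18)
  young <- plan_set(young, "DAN", intra_L = 0.26, intra_R = 0.34)
  young <- plan_set(young, "FPN", intra_L = 0.27, intra_R = 0.33)
  young <- plan_set(young, "AUD", hetero_L = 0.13, hetero_R = 0.17)
  sym <- symmetric_plan()
  om <- young
  wcols <- c("intra_L", "intra_R", "hetero_L", "hetero_R", "homotopic")
  om[wcols] <- sym[wcols] + 0.8 * (young[wcols] - sym[wcols])
  list(YNM = young, OM = om, ONM = sym)
}

#' Generate a homotopic atlas
#'
#' Builds a bijectively paired bilateral vertex set with the requested number
#' of homotopic pairs per network; both members of a pair share the network
#' label. Pair-to-network assignment order is shuffled deterministically by
#' the seed. Defaults give 120 pairs per labeled network plus 48 unlabeled
#' (`NONE`) pairs: 888 pairs, 1,776 vertices.
#'
#' @param pairs_per_network Named counts of homotopic pairs (names from
#'   [hemi_network_levels()]), each >= 1.
#' @param seed Integer seed.
#' @return A `hemilat_atlas`.
#' @export
make_atlas <- function(pairs_per_network = c(SMN = 120, AUD = 120, LAN = 120,
                                             DAN = 120, CON = 120, FPN = 120,
                                             DMN = 120, NONE = 48),
                       seed = default_seed()) {
  if (!length(pairs_per_network)) {
    hemi_stop("hemilat_value_error", "pairs_per_network is empty")
  }
  bad <- setdiff(names(pairs_per_network), hemi_network_levels())
  if (is.null(names(pairs_per_network)) || length(bad)) {
    hemi_stop("hemilat_value_error", "pairs_per_network must be named by network")
  }
  if (any(pairs_per_network < 1)) {
    hemi_stop("hemilat_value_error", "every pair count must be >= 1")
  }
  nets <- rep(names(pairs_per_network), times = pairs_per_network)
  set.seed(seed)
  nets <- sample(nets)
  P <- length(nets)
  df <- data.frame(
    vertex_id = seq_len(2L * P) - 1L,
    hemisphere = rep(c("L", "R"), P),
    pair_id = rep(seq_len(P) - 1L, each = 2L),
    network = rep(nets, each = 2L),
    stringsAsFactors = FALSE
  )
  as_atlas(df)
}

#' Factor-model covariance for a lateralization plan
#'
#' Assembles the vertex covariance implied by the plan's latent factors (see
#' [lat_plan()]): within-hemisphere network blocks gain `intra_H +
#' hetero_H`, cross-hemisphere same-network entries gain
#' `sqrt(hetero_L * hetero_R)`, homotopic entries additionally gain the
#' homotopic weight, and the diagonal adds `noise_sd^2`. The result is
#' symmetric positive semidefinite for any nonnegative weights, and expected
#' Pearson correlations follow in closed form (see
#' [expected_correlations()]).
#'
#' @param atlas A `hemilat_atlas`.
#' @param plan A `hemilat_plan` covering every network present in the atlas.
#' @return Covariance matrix, vertices x vertices in atlas order.
#' @export
build_covariance <- function(atlas, plan) {
  if (!inherits(plan, "hemilat_plan")) plan <- lat_plan(plan$network, plan$intra_L,
    plan$intra_R, plan$hetero_L, plan$hetero_R, plan$homotopic, plan$noise_sd)
  missing_nets <- setdiff(unique(atlas$network), plan$network)
  if (length(missing_nets)) {
    hemi_stop("hemilat_value_error", "plan lacks network(s): %s",
              paste(missing_nets, collapse = ", "))
  }
  n <- nrow(atlas)
  S <- matrix(0, n, n)
  for (k in unique(atlas$network)) {
    pk <- plan[plan$network == k, , drop = FALSE]
    iL <- which(atlas$network == k & atlas$hemisphere == "L")
    iR <- which(atlas$network == k & atlas$hemisphere == "R")
    if (length(iL)) S[iL, iL] <- S[iL, iL] + pk$intra_L + pk$hetero_L
    if (length(iR)) S[iR, iR] <- S[iR, iR] + pk$intra_R + pk$hetero_R
    if (length(iL) && length(iR)) {
      cross <- sqrt(pk$hetero_L * pk$hetero_R)
      S[iL, iR] <- S[iL, iR] + cross
      S[iR, iL] <- S[iR, iL] + cross
    }
  }
  hom_w <- plan$homotopic[match(atlas$network, plan$network)]
  for (idx in split(seq_len(n), atlas$pair_id)) {
    # both members load on the pair factor; use the left member's network weight
    w <- hom_w[idx[1L]]
    S[idx[1L], idx[2L]] <- S[idx[1L], idx[2L]] + w
    S[idx[2L], idx[1L]] <- S[idx[2L], idx[1L]] + w
    S[idx[1L], idx[1L]] <- S[idx[1L], idx[1L]] + w
    S[idx[2L], idx[2L]] <- S[idx[2L], idx[2L]] + w
  }
  noise <- plan$noise_sd[match(atlas$network, plan$network)]
  diag(S) <- diag(S) + noise^2
  S
}

#' Expected Pearson correlations under a plan
#'
#' Closed-form population correlations implied by the factor model:
#' `cov2cor` of [build_covariance()], diagonal `NA`.
#'
#' @inheritParams build_covariance
#' @return Correlation matrix with `NA` diagonal.
#' @export
expected_correlations <- function(atlas, plan) {
  r <- stats::cov2cor(build_covariance(atlas, plan))
  diag(r) <- NA_real_
  r
}

# Draw n x T zero-mean Gaussian data with covariance factor A (cov = A A').
# Consumes the current RNG stream.
draw_gaussian <- function(A, n_timepoints) {
  n <- nrow(A)
  A %*% matrix(stats::rnorm(n * n_timepoints), n, n_timepoints)
}

.cov_factor_cache <- new.env(parent = emptyenv())

cov_factor <- function(cov, tol = 1e-8) {
  # repeated simulation from one covariance (replicate cohorts) is common;
  # cache the most recent factorization
  if (!is.null(.cov_factor_cache$cov) && identical(.cov_factor_cache$cov, cov)) {
    return(.cov_factor_cache$A)
  }
  eig <- eigen(cov, symmetric = TRUE)
  scale <- max(1, abs(eig$values[1L]))
  if (min(eig$values) < -tol * scale) {
    hemi_stop("hemilat_numeric_error",
              "covariance is not positive semidefinite (min eigenvalue %.3g)",
              min(eig$values))
  }
  A <- eig$vectors %*% (sqrt(pmax(eig$values, 0)) * t(eig$vectors))
  .cov_factor_cache$cov <- cov
  .cov_factor_cache$A <- A
  A
}

#' Simulate a multivariate-normal time series
#'
#' Draws `n_timepoints` zero-mean Gaussian samples with the given vertex
#' covariance (default length emulates a 750-volume resting-state run);
#' deterministic given the seed.
#'
#' @param cov Positive semidefinite covariance matrix.
#' @param n_timepoints Number of frames (default 750).
#' @param seed Integer seed.
#' @param subject_id Identifier for the returned object.
#' @return A `hemilat_ts`.
#' @export
simulate_timeseries <- function(cov, n_timepoints = 750L, seed = default_seed(),
                                subject_id = "sim") {
  A <- cov_factor(cov)
  set.seed(seed)
  timeseries(subject_id, draw_gaussian(A, n_timepoints))
}

# FD trace with exactly floor(fraction * n) frames strictly above 0.5 mm.
# Consumes the current RNG stream.
draw_fd <- function(n_timepoints, outlier_fraction) {
  fd <- pmin(stats::rlnorm(n_timepoints, meanlog = log(0.12), sdlog = 0.35), 0.49)
  n_out <- floor(outlier_fraction * n_timepoints)
  if (n_out > 0) {
    pos <- sample(n_timepoints, n_out)
    fd[pos] <- 0.5 + stats::runif(n_out, 0.02, 0.5)
  }
  fd
}

#' Simulate a framewise-displacement trace
#'
#' Baseline FD is lognormal around 0.12 mm capped below the 0.5 mm censoring
#' threshold; exactly `floor(outlier_fraction * n)` frames are planted
#' strictly above the threshold.
#'
#' @param n_timepoints Number of frames.
#' @param outlier_fraction Fraction of high-motion frames in `[0, 1]`.
#' @param seed Integer seed.
#' @return Numeric FD trace in mm.
#' @export
simulate_fd <- function(n_timepoints, outlier_fraction = 0, seed = default_seed()) {
  if (outlier_fraction < 0 || outlier_fraction > 1) {
    hemi_stop("hemilat_value_error", "outlier_fraction must be in [0, 1]")
  }
  if (n_timepoints < 1L) hemi_stop("hemilat_value_error", "need n_timepoints >= 1")
  set.seed(seed)
  draw_fd(n_timepoints, outlier_fraction)
}

#' Simulate binomial psychometric data
#'
#' Binomial trial counts from a two-parameter logistic at the standard SNR
#' levels; used to exercise threshold recovery.
#'
#' @param alpha,beta True threshold (dB) and slope scale (dB).
#' @param snr SNR levels (default `c(-12, -8, -4, 0, 4)` dB).
#' @param n_trials Trials per level.
#' @param seed Integer seed.
#' @return data.frame: `snr`, `n_trials`, `n_correct`.
#' @export
simulate_psychometric <- function(alpha, beta, snr = c(-12, -8, -4, 0, 4),
                                  n_trials = 20L, seed = default_seed()) {
  set.seed(seed)
  data.frame(snr = snr, n_trials = n_trials,
             n_correct = stats::rbinom(length(snr), n_trials,
                                       logistic2(snr, alpha, beta)))
}

#' Reference cohort summary statistics
#'
#' Published per-group means and SDs of the demographic and behavioral
#' variables in the three-group cohort the simulator emulates (24 young
#' non-musicians, 23 older musicians, 23 older non-musicians), plus the
#' fixed gender counts. These summaries parameterize the covariate
#' generator and serve as inputs to the summary-statistic test battery.
#'
#' @return data.frame: `variable`, `group`, `mean`, `sd`, `n`.
#' @export
cohort_reference_summaries <- function() {
  g <- c("YNM", "OM", "ONM")
  n <- c(YNM = 24L, OM = 23L, ONM = 23L)
  row <- function(variable, means, sds) {
    data.frame(variable = variable, group = g, mean = means, sd = sds,
               n = as.integer(n[g]), stringsAsFactors = FALSE)
  }
  out <- rbind(
    row("age", c(23.13, 64.61, 66.70), c(2.38, 3.76, 3.34)),
    row("education", c(16.50, 13.15, 9.89), c(1.67, 3.06, 2.80)),
    row("moca", c(NA, 27.91, 27.65), c(NA, 1.24, 1.37)),
    row("hearing", c(0.71, 12.33, 12.57), c(3.32, 5.42, 4.01)),
    row("sin_threshold", c(-3.99, -3.61, -1.04), c(0.59, 0.97, 1.90)),
    row("sis_threshold", c(-5.43, -4.97, -0.31), c(1.00, 1.51, 3.09)),
    row("digit_span", c(16.71, 15.09, 11.57), c(2.71, 2.27, 2.06)),
    row("stroop", c(0.18, 0.18, 0.23), c(0.12, 0.10, 0.19)),
    row("training_onset", c(NA, 11.17, NA), c(NA, 4.66, NA)),
    row("training_years", c(NA, 49.84, NA), c(NA, 8.26, NA))
  )
  rownames(out) <- NULL
  out
}

#' @rdname cohort_reference_summaries
#' @return `reference_gender_counts()`: 3x2 matrix of female/male counts by
#'   group.
#' @export
reference_gender_counts <- function() {
  m <- matrix(c(12L, 12L, 9L, 14L, 14L, 9L), nrow = 3, byrow = TRUE,
              dimnames = list(c("YNM", "OM", "ONM"), c("F", "M")))
  m
}

ref_lookup <- function(ref, variable, group, field) {
  ref[[field]][ref$variable == variable & ref$group == group]
}

#' Behavior-link specification
#'
#' Linear-Gaussian link from a subject's realized network laterality to the
#' speech thresholds: `threshold = group mean + slope * LI + covariate
#' effects + N(0, noise_sd)`. With independent covariates the planted
#' partial correlation has the closed form
#' `slope * sd(LI) / sqrt(slope^2 * var(LI) + noise_sd^2)`. The default link
#' has slope 0 (no brain-behavior association).
#'
#' @param network Target network.
#' @param kind `"intra"` or `"he"`.
#' @param slope dB per LI unit, applied to both SIN and SIS thresholds.
#' @param noise_sd Residual SD in dB; `NULL` uses each group's reference SD.
#' @param covariate_effects Named numeric vector of slopes on centered
#'   covariates (subset of the nine partial-correlation covariates).
#' @return A list of class `hemilat_link`.
#' @export
behavior_link <- function(network = "SMN", kind = c("intra", "he"), slope = 0,
                          noise_sd = NULL, covariate_effects = NULL) {
  kind <- match.arg(kind)
  if (!network %in% hemi_networks()) {
    hemi_stop("hemilat_value_error", "link network must be one of the seven labels")
  }
  if (!is.null(noise_sd) && noise_sd <= 0) {
    hemi_stop("hemilat_value_error", "noise_sd must be > 0")
  }
  structure(list(network = network, kind = kind, slope = slope,
                 noise_sd = noise_sd,
                 covariate_effects = covariate_effects %||% numeric(0)),
            class = "hemilat_link")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Simulate a full cohort
#'
#' Generates, per subject: a BOLD-like time series from the group's
#' lateralization plan, an FD trace, covariates drawn from the reference
#' group summaries (independent truncated normals; gender counts fixed at
#' the reference proportions), and SIN/SIS thresholds from the behavior
#' link. The subject's realized network laterality, motion summary and mean
#' global FC feed back into the cohort table, so planted brain-behavior
#' partial correlations are recoverable downstream. Fully deterministic
#' given the seed.
#'
#' @param atlas A `hemilat_atlas`.
#' @param group_sizes Named subject counts (default `c(YNM = 24, OM = 23,
#'   ONM = 23)`).
#' @param plans Named list of `hemilat_plan`, one per group.
#' @param link A `hemilat_link`.
#' @param n_timepoints Frames per subject (default 750).
#' @param fd_outlier_fraction Fraction of high-motion frames per subject.
#' @param seed Integer seed.
#' @return List: `cohort` (`hemilat_cohort`), `atlas`, `timeseries` (named
#'   list of `hemilat_ts`), `fd` (named list), `limaps` (named list of
#'   `hemilat_limap`), `network_li` (long data.frame), `qc` (data.frame).
#' @export
make_cohort <- function(atlas, group_sizes = c(YNM = 24L, OM = 23L, ONM = 23L),
                        plans = default_group_plans(), link = behavior_link(),
                        n_timepoints = 750L, fd_outlier_fraction = 0.02,
                        seed = default_seed()) {
  if (any(group_sizes < 2L)) {
    hemi_stop("hemilat_value_error", "every group size must be >= 2")
  }
  groups <- names(group_sizes)
  if (is.null(groups) || !all(groups %in% c("YNM", "OM", "ONM"))) {
    hemi_stop("hemilat_value_error", "group_sizes must be named YNM/OM/ONM")
  }
  if (!all(groups %in% names(plans))) {
    hemi_stop("hemilat_value_error", "plans must cover every group")
  }
  ref <- cohort_reference_summaries()
  gref <- reference_gender_counts()
  cov_centers <- c(age = 65, gender = 0.5, education = 12, hearing = 10,
                   moca = 27, digit_span = 14, stroop = 0.2, mfd = 0.13,
                   mean_global_fc = 0.15)
  rows <- list()
  ts_list <- list()
  fd_list <- list()
  limap_list <- list()
  netli_rows <- list()
  qc_rows <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    ng <- group_sizes[[g]]
    A <- cov_factor(build_covariance(atlas, plans[[g]]))
    n_f <- round(ng * gref[g, "F"] / sum(gref[g, ]))
    genders <- c(rep("F", n_f), rep("M", ng - n_f))
    for (i in seq_len(ng)) {
      sid <- sprintf("%s%02d", g, i)
      sub_seed <- (seed + 104729L * gi + 7919L * i) %% 2147483647L
      set.seed(sub_seed)
      ts <- timeseries(sid, draw_gaussian(A, n_timepoints))
      fd <- draw_fd(n_timepoints, fd_outlier_fraction)
      rnorm_ref <- function(variable) {
        m <- ref_lookup(ref, variable, g, "mean")
        s <- ref_lookup(ref, variable, g, "sd")
        if (is.na(m)) NA_real_ else stats::rnorm(1, m, s)
      }
      age <- clamp(rnorm_ref("age"), 18, 90)
      education <- clamp(rnorm_ref("education"), 0, 25)
      moca <- if (g == "YNM") NA_real_ else round(clamp(rnorm_ref("moca"), 26, 30))
      hearing <- rnorm_ref("hearing")
      digit_span <- round(clamp(rnorm_ref("digit_span"), 4, 22))
      stroop <- clamp(rnorm_ref("stroop"), 0.01, Inf)
      training_onset <- if (g == "OM") clamp(rnorm_ref("training_onset"), 3, 22) else NA_real_
      training_years <- if (g == "OM") clamp(rnorm_ref("training_years"), 32, 70) else NA_real_
      fc <- compute_fc(ts, fd = fd)
      mgfc <- mean_global_fc(fc)
      limap <- pair_li(strength_sums(fc, atlas), atlas)
      netli <- suppressWarnings(network_li(limap))
      li_col <- paste0("li_", link$kind)
      li_t <- netli[[li_col]][netli$network == link$network]
      if (is.na(li_t)) li_t <- 0
      qc <- motion_qc(fd)
      covvals <- c(age = age, gender = as.numeric(genders[i] == "M"),
                   education = education, hearing = hearing,
                   moca = ifelse(is.na(moca), cov_centers[["moca"]], moca),
                   digit_span = digit_span, stroop = stroop,
                   mfd = qc$mfd, mean_global_fc = mgfc)
      cov_term <- 0
      if (length(link$covariate_effects)) {
        ce <- link$covariate_effects
        cov_term <- sum(ce * (covvals[names(ce)] - cov_centers[names(ce)]))
      }
      thr <- function(variable) {
        mu <- ref_lookup(ref, variable, g, "mean")
        sdres <- link$noise_sd %||% ref_lookup(ref, variable, g, "sd")
        mu + link$slope * li_t + cov_term + stats::rnorm(1, 0, sdres)
      }
      sin_thr <- thr("sin_threshold")
      sis_thr <- thr("sis_threshold")
      rows[[sid]] <- data.frame(
        subject_id = sid, group = g, gender = genders[i], age = age,
        education = education, hearing = hearing, moca = moca,
        digit_span = digit_span, stroop = stroop, mfd = qc$mfd,
        mean_global_fc = mgfc, sin_threshold = sin_thr, sis_threshold = sis_thr,
        training_onset = training_onset, training_years = training_years,
        stringsAsFactors = FALSE)
      ts_list[[sid]] <- ts
      fd_list[[sid]] <- fd
      limap_list[[sid]] <- limap
      netli$subject_id <- sid
      netli_rows[[sid]] <- netli
      qc_rows[[sid]] <- cbind(data.frame(subject_id = sid), qc)
    }
  }
  list(cohort = as_cohort(do.call(rbind, rows)),
       atlas = atlas,
       timeseries = ts_list,
       fd = fd_list,
       limaps = limap_list,
       network_li = do.call(rbind, c(netli_rows, list(make.row.names = FALSE))),
       qc = do.call(rbind, c(qc_rows, list(make.row.names = FALSE))))
}
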