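#' Per-pair laterality indices
#'
#' For each homotopic pair, the laterality index `LI = (L - R) / |L + R|` is
#' computed separately for the heterotopic (`he`) and intrahemispheric
#' (`intra`) strength sums. A pair is flagged invalid for a given index when
#' `|L + R| < epsilon` (the index is undefined at a vanishing denominator);
#' invalid entries carry `NA`, not a clipped value, so network averages are
#' not biased. `|LI|` may exceed 1 when `L` and `R` have opposite signs; no
#' clipping is applied.
#'
#' @param sums data.frame from [strength_sums()].
#' @param atlas A `hemilat_atlas`.
#' @param epsilon Validity threshold on `|L + R|` (default `1e-8`).
#' @return data.frame of class `hemilat_limap`: `pair_id`, `network` (the
#'   pair's shared network label, `NA` unless both members agree and are not
#'   `NONE`), `li_intra`, `valid_intra`, `li_he`, `valid_he`.
#' @export
pair_li <- function(sums, atlas, epsilon = 1e-8) {
  if (nrow(sums) != nrow(atlas)) {
    hemi_stop("hemilat_shape_error",
              "strength sums cover %d vertices but atlas has %d",
              nrow(sums), nrow(atlas))
  }
  p <- atlas_pairs(atlas)
  iL <- match(p$left, sums$vertex_id)
  iR <- match(p$right, sums$vertex_id)
  if (anyNA(iL) || anyNA(iR)) {
    hemi_stop("hemilat_value_error", "strength sums do not cover every atlas vertex")
  }
  li_one <- function(L, R) {
    s <- abs(L + R)
    valid <- is.finite(s) & s >= epsilon
    val <- rep(NA_real_, length(L))
    val[valid] <- (L[valid] - R[valid]) / s[valid]
    list(value = val, valid = valid)
  }
  ia <- li_one(sums$intra[iL], sums$intra[iR])
  ha <- li_one(sums$he[iL], sums$he[iR])
  out <- data.frame(pair_id = p$pair_id, network = p$network,
                    li_intra = ia$value, valid_intra = ia$valid,
                    li_he = ha$value, valid_he = ha$valid,
                    stringsAsFactors = FALSE)
  class(out) <- c("hemilat_limap", "data.frame")
  out
}

#' Network-based laterality indices
#'
#' Unweighted mean of the pair-wise LI over the network-valid homotopic pairs
#' of each requested network, excluding invalid pairs pairwise per LI kind.
#' A network with zero valid pairs yields `NA` and a warning.
#'
#' @param limap A `hemilat_limap`.
#' @param networks Networks to average over (default the seven labels).
#' @return data.frame: `network`, `li_intra`, `n_intra`, `li_he`, `n_he`.
#' @export
network_li <- function(limap, networks = hemi_networks()) {
  rows <- lapply(networks, function(k) {
    sel <- !is.na(limap$network) & limap$network == k
    vi <- sel & limap$valid_intra
    vh <- sel & limap$valid_he
    ni <- sum(vi)
    nh <- sum(vh)
    if (ni == 0L || nh == 0L) {
      warning(sprintf("network %s has no valid pairs for %s", k,
                      paste(c("intra", "he")[c(ni == 0L, nh == 0L)], collapse = " and ")),
              call. = FALSE)
    }
    data.frame(network = k,
               li_intra = if (ni) mean(limap$li_intra[vi]) else NA_real_,
               n_intra = ni,
               li_he = if (nh) mean(limap$li_he[vh]) else NA_real_,
               n_he = nh,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Young-group laterality template
#'
#' Element-wise mean of the pair-wise LI across the young non-musician
#' subjects, restricted to network-valid pairs. Validity is handled listwise
#' within a network: a pair invalid in any contributing subject is dropped
#' from the template index set, so every alignment comparison uses one fixed
#' set of pairs per network.
#'
#' @param limaps List of `hemilat_limap`, one per subject.
#' @return data.frame of class `hemilat_template`: `pair_id`, `network`,
#'   `intra`, `he` (`NA` where the pair is dropped). Attribute `n_subjects`
#'   records the number of maps averaged.
#' @export
young_template <- function(limaps) {
  if (!length(limaps)) {
    hemi_stop("hemilat_value_error", "empty subject set for template")
  }
  base <- limaps[[1L]]
  np <- nrow(base)
  for (m in limaps) {
    if (nrow(m) != np || any(m$pair_id != base$pair_id)) {
      hemi_stop("hemilat_shape_error", "subject LI maps index different pairs")
    }
  }
  netok <- !is.na(base$network)
  keep_i <- netok & Reduce(`&`, lapply(limaps, function(m) m$valid_intra))
  keep_h <- netok & Reduce(`&`, lapply(limaps, function(m) m$valid_he))
  Mi <- vapply(limaps, function(m) m$li_intra, numeric(np))
  Mh <- vapply(limaps, function(m) m$li_he, numeric(np))
  if (np == 1L) {
    Mi <- matrix(Mi, nrow = 1L)
    Mh <- matrix(Mh, nrow = 1L)
  }
  intra <- ifelse(keep_i, rowMeans(Mi), NA_real_)
  he <- ifelse(keep_h, rowMeans(Mh), NA_real_)
  out <- data.frame(pair_id = base$pair_id, network = base$network,
                    intra = intra, he = he, stringsAsFactors = FALSE)
  attr(out, "n_subjects") <- length(limaps)
  class(out) <- c("hemilat_template", "data.frame")
  out
}

#' Cosine alignment of a subject's lateralization to the young template
#'
#' Cosine similarity `dot(u, v) / (|u||v|)` between a subject's pair-wise LI
#' vector and the template vector, over the pairs of one network that are
#' valid in both.
#'
#' @param limap A `hemilat_limap`.
#' @param template A `hemilat_template` from [young_template()].
#' @param network Network label.
#' @param kind `"intra"` or `"he"`.
#' @return Cosine similarity in `[-1, 1]`.
#' @export
alignment <- function(limap, template, network, kind = c("intra", "he")) {
  kind <- match.arg(kind)
  idx <- match(template$pair_id, limap$pair_id)
  if (anyNA(idx)) {
    hemi_stop("hemilat_shape_error", "subject LI map does not cover template pairs")
  }
  tv <- template[[kind]]
  lv <- limap[[paste0("li_", kind)]][idx]
  lvalid <- limap[[paste0("valid_", kind)]][idx]
  sel <- !is.na(template$network) & template$network == network &
    is.finite(tv) & lvalid
  if (sum(sel) < 2L) {
    hemi_stop("hemilat_value_error",
              "fewer than 2 shared valid pairs in network %s", network)
  }
  u <- lv[sel]
  v <- tv[sel]
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    hemi_stop("hemilat_numeric_error",
              "undefined alignment: zero-norm LI vector in network %s", network)
  }
  sum(u * v) / (nu * nv)
}

#' Alignment table over subjects and networks
#'
#' Applies [alignment()] to every subject x network x LI kind combination;
#' undefined combinations yield `NA` with a warning.
#'
#' @param limaps Named list of `hemilat_limap` (names are subject ids).
#' @param template A `hemilat_template`.
#' @param networks Networks to evaluate.
#' @return Long data.frame: `subject_id`, `network`, `align_intra`, `align_he`.
#' @export
alignment_table <- function(limaps, template, networks = hemi_networks()) {
  stopifnot(!is.null(names(limaps)))
  rows <- lapply(names(limaps), function(sid) {
    m <- limaps[[sid]]
    one <- function(net, kind) {
      tryCatch(alignment(m, template, net, kind),
               hemilat_error = function(e) {
                 warning(sprintf("subject %s, network %s (%s): %s",
                                 sid, net, kind, conditionMessage(e)), call. = FALSE)
                 NA_real_
               })
    }
    data.frame(subject_id = sid, network = networks,
               align_intra = vapply(networks, one, numeric(1), kind = "intra"),
               align_he = vapply(networks, one, numeric(1), kind = "he"),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Group-mean laterality map
#'
#' Per-pair mean LI over the subjects in which the pair is valid, with the
#' contributing subject count recorded. A pair invalid in every subject stays
#' invalid.
#'
#' @param limaps List of `hemilat_limap`.
#' @return A `hemilat_limap` of group means with extra columns
#'   `n_valid_intra`, `n_valid_he`.
#' @export
group_mean_map <- function(limaps) {
  if (!length(limaps)) hemi_stop("hemilat_value_error", "empty subject set")
  base <- limaps[[1L]]
  np <- nrow(base)
  mean_kind <- function(col, valid_col) {
    M <- vapply(limaps, function(m) m[[col]], numeric(np))
    V <- vapply(limaps, function(m) m[[valid_col]], logical(np))
    if (np == 1L) {
      M <- matrix(M, nrow = 1L)
      V <- matrix(V, nrow = 1L)
    }
    M[!V] <- 0
    nv <- rowSums(V)
    val <- ifelse(nv > 0L, rowSums(M) / nv, NA_real_)
    list(value = val, n = nv)
  }
  mi <- mean_kind("li_intra", "valid_intra")
  mh <- mean_kind("li_he", "valid_he")
  out <- data.frame(pair_id = base$pair_id, network = base$network,
                    li_intra = mi$value, valid_intra = mi$n > 0L,
                    li_he = mh$value, valid_he = mh$n > 0L,
                    n_valid_intra = mi$n, n_valid_he = mh$n,
                    stringsAsFactors = FALSE)
  class(out) <- c("hemilat_limap", "data.frame")
  out
}

#' Pearson correlation between two laterality maps
#'
#' Correlates two LI maps (e.g., group means) across the homotopic pairs
#' valid in both.
#'
#' @param mapA,mapB `hemilat_limap` objects over the same pairs.
#' @param kind `"intra"` or `"he"`.
#' @return Pearson r.
#' @export
map_correlation <- function(mapA, mapB, kind = c("intra", "he")) {
  kind <- match.arg(kind)
  if (nrow(mapA) != nrow(mapB) || any(mapA$pair_id != mapB$pair_id)) {
    hemi_stop("hemilat_shape_error", "maps index different pairs")
  }
  col <- paste0("li_", kind)
  vcol <- paste0("valid_", kind)
  sel <- mapA[[vcol]] & mapB[[vcol]]
  if (sum(sel) < 3L) {
    hemi_stop("hemilat_value_error", "fewer than 3 shared valid pairs")
  }
  u <- mapA[[col]][sel]
  v <- mapB[[col]][sel]
  if (stats::sd(u) == 0 || stats::sd(v) == 0) {
    hemi_stop("hemilat_degenerate_error", "constant map: correlation undefined")
  }
  stats::cor(u, v)
}

#' Compare two dependent correlations sharing one variable
#'
#' Steiger's z for the difference between two correlations `r1 = cor(a, x)`
#' and `r2 = cor(b, x)` that share the variable `x` (here, two group-mean
#' maps each correlated with the young-group map), with `r12 = cor(a, b)`.
#' Uses the back-transformed mean correlation in the covariance term.
#'
#' @param r1,r2 The two correlations to compare.
#' @param r12 Correlation between the two non-shared variables.
#' @param n Number of observations (homotopic pairs).
#' @return A `hemilat_stat` with the z statistic and two-sided p.
#' @export
compare_dependent_correlations <- function(r1, r2, r12, n) {
  if (any(abs(c(r1, r2, r12)) >= 1)) {
    hemi_stop("hemilat_value_error", "correlations must lie strictly inside (-1, 1)")
  }
  if (n < 4) hemi_stop("hemilat_value_error", "need n >= 4")
  z1 <- atanh(r1)
  z2 <- atanh(r2)
  rm <- tanh((z1 + z2) / 2)
  psi <- r12 * (1 - 2 * rm^2) - 0.5 * rm^2 * (1 - 2 * rm^2 - r12^2)
  cbar <- psi / (1 - rm^2)^2
  z <- (z1 - z2) * sqrt(n - 3) / sqrt(2 - 2 * cbar)
  stat_result("steiger_z", statistic = z, df = NA_real_,
              p = 2 * stats::pnorm(-abs(z)), n = n)
}
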