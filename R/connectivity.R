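#' Fisher-z functional connectivity matrix
#'
#' Pearson correlation between every pair of vertex time series, Fisher
#' r-to-z transformed (`atanh`). Correlations are clipped to
#' `+/-(1 - 1e-7)` before the transform so degenerate (perfectly correlated)
#' signals yield a large finite z rather than infinity. The diagonal is
#' undefined and set to `NA`. When a framewise-displacement trace is
#' supplied, frames with FD strictly above `fd_threshold` are censored
#' ("scrubbed") before correlation; set `scrub = FALSE` to keep all frames.
#'
#' @param ts A `hemilat_ts`.
#' @param fd Optional numeric FD trace (mm), one value per frame.
#' @param scrub Censor high-motion frames before correlation? Default `TRUE`.
#' @param fd_threshold Censoring threshold in mm (default 0.5, strict `>`).
#' @param clip Correlations are clipped to `+/- clip` before `atanh`.
#' @return Symmetric numeric matrix of Fisher-z values with `NA` diagonal.
#' @export
compute_fc <- function(ts, fd = NULL, scrub = TRUE, fd_threshold = 0.5,
                       clip = 1 - 1e-7) {
  vals <- ts$values
  if (!is.null(fd)) {
    if (length(fd) != ncol(vals)) {
      hemi_stop("hemilat_shape_error",
                "FD trace has %d frames but time series has %d",
                length(fd), ncol(vals))
    }
    if (scrub) vals <- vals[, fd <= fd_threshold, drop = FALSE]
  }
  if (ncol(vals) < 3L) {
    hemi_stop("hemilat_value_error", "fewer than 3 frames remain after censoring")
  }
  ss <- rowSums((vals - rowMeans(vals))^2)
  if (any(ss == 0)) {
    hemi_stop("hemilat_degenerate_error",
              "zero-variance signal at vertex %d", which(ss == 0)[1L] - 1L)
  }
  r <- stats::cor(t(vals))
  r <- pmin(pmax(r, -clip), clip)
  z <- atanh(r)
  diag(z) <- NA_real_
  z
}

#' Heterotopic and intrahemispheric connectivity strength sums
#'
#' For each vertex `v`, `intra(v)` is the sum of Fisher-z connectivity to all
#' other vertices in the same hemisphere (self excluded), and `he(v)` is the
#' sum to all vertices in the opposite hemisphere except the homotopic
#' partner. These are the left/right quantities entering the laterality
#' index.
#'
#' @param fc Fisher-z matrix from [compute_fc()].
#' @param atlas A `hemilat_atlas`; dimension must match `fc`.
#' @return data.frame with columns `vertex_id`, `he`, `intra`.
#' @export
strength_sums <- function(fc, atlas) {
  n <- nrow(atlas)
  if (!is.matrix(fc) || nrow(fc) != n || ncol(fc) != n) {
    hemi_stop("hemilat_shape_error",
              "FC matrix is %dx%d but atlas has %d vertices",
              NROW(fc), NCOL(fc), n)
  }
  z <- fc
  diag(z) <- 0
  if (any(!is.finite(z))) {
    hemi_stop("hemilat_value_error", "non-finite off-diagonal FC entry")
  }
  isL <- atlas$hemisphere == "L"
  partner <- integer(n)
  for (idx in split(seq_len(n), atlas$pair_id)) {
    partner[idx[1L]] <- idx[2L]
    partner[idx[2L]] <- idx[1L]
  }
  sumL <- rowSums(z[, isL, drop = FALSE])
  sumR <- rowSums(z[, !isL, drop = FALSE])
  intra <- ifelse(isL, sumL, sumR)
  he <- ifelse(isL, sumR, sumL) - z[cbind(seq_len(n), partner)]
  data.frame(vertex_id = atlas$vertex_id, he = he, intra = intra)
}

#' Mean global functional connectivity
#'
#' Mean Fisher-z connectivity over all distinct vertex pairs (the strict
#' upper triangle); used as a subject-level covariate.
#'
#' @param fc Fisher-z matrix from [compute_fc()].
#' @return Scalar mean.
#' @export
mean_global_fc <- function(fc) {
  if (!is.matrix(fc) || nrow(fc) < 2L) {
    hemi_stop("hemilat_shape_error", "FC matrix needs at least 2 vertices")
  }
  mean(fc[upper.tri(fc)])
}

#' Motion quality control
#'
#' Flags frames whose framewise displacement strictly exceeds `fd_threshold`
#' (default 0.5 mm) and excludes a subject when the flagged fraction is
#' strictly greater than `max_fraction` (default 20%). `mfd` is the mean FD
#' over all frames.
#'
#' @param fd Numeric FD trace in mm.
#' @param fd_threshold Frame-flagging threshold in mm.
#' @param max_fraction Exclusion threshold on the flagged fraction.
#' @return One-row data.frame: `n_frames`, `n_outlier_frames`,
#'   `outlier_fraction`, `excluded`, `mfd`.
#' @export
motion_qc <- function(fd, fd_threshold = 0.5, max_fraction = 0.20) {
  if (!length(fd)) hemi_stop("hemilat_value_error", "empty FD trace")
  if (any(!is.finite(fd)) || any(fd < 0)) {
    hemi_stop("hemilat_value_error", "FD values must be finite and non-negative")
  }
  n <- length(fd)
  n_out <- sum(fd > fd_threshold)
  frac <- n_out / n
  data.frame(n_frames = n, n_outlier_frames = n_out, outlier_fraction = frac,
             excluded = frac > max_fraction, mfd = mean(fd))
}
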