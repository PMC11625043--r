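#' Cortical network labels
#'
#' The seven task-relevant functional networks used throughout the package:
#' somatomotor (SMN), auditory (AUD), language (LAN), dorsal attention (DAN),
#' cingulo-opercular (CON), frontoparietal (FPN) and default-mode (DMN).
#' Vertices outside these networks carry the label `NONE`; they participate in
#' connectivity strength sums but never in network-based laterality averaging.
#'
#' @return Character vector of the seven network labels.
#' @export
hemi_networks <- function() c("SMN", "AUD", "LAN", "DAN", "CON", "FPN", "DMN")

#' @rdname hemi_networks
#' @export
hemi_network_levels <- function() c(hemi_networks(), "NONE")

#' Validate a homotopic atlas
#'
#' An atlas registers every cortical vertex with its hemisphere (`L`/`R`), its
#' homotopic partner (via a shared `pair_id`) and a network label. The pairing
#' must be a bijection: each `pair_id` occurs exactly twice, once per
#' hemisphere. Rows are canonicalized to ascending `vertex_id`, which is also
#' the row order expected of every time-series matrix.
#'
#' @param df A data.frame with columns `vertex_id` (0-based integer),
#'   `hemisphere` (`"L"` or `"R"`), `pair_id` (integer), `network`
#'   (one of [hemi_network_levels()]).
#' @return The validated atlas, a data.frame of class `hemilat_atlas`.
#' @export
as_atlas <- function(df) {
  req <- c("vertex_id", "hemisphere", "pair_id", "network")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    hemi_stop("hemilat_format_error", "atlas is missing column(s): %s",
              paste(miss, collapse = ", "))
  }
  df <- as.data.frame(df)[req]
  df$vertex_id <- suppressWarnings(as.integer(df$vertex_id))
  df$pair_id <- suppressWarnings(as.integer(df$pair_id))
  df$hemisphere <- as.character(df$hemisphere)
  df$network <- as.character(df$network)
  if (anyNA(df$vertex_id) || anyNA(df$pair_id)) {
    hemi_stop("hemilat_value_error", "atlas vertex_id/pair_id must be integers")
  }
  bad_h <- setdiff(unique(df$hemisphere), c("L", "R"))
  if (length(bad_h)) {
    hemi_stop("hemilat_value_error", "unknown hemisphere token(s): %s",
              paste(bad_h, collapse = ", "))
  }
  bad_n <- setdiff(unique(df$network), hemi_network_levels())
  if (length(bad_n)) {
    hemi_stop("hemilat_value_error", "unknown network token(s): %s",
              paste(bad_n, collapse = ", "))
  }
  if (anyDuplicated(df$vertex_id)) {
    hemi_stop("hemilat_integrity_error", "duplicated vertex_id in atlas")
  }
  tab <- table(df$pair_id)
  if (any(tab != 2L)) {
    bad <- names(tab)[tab != 2L][1L]
    hemi_stop("hemilat_integrity_error",
              "homotopic pairing is not a bijection: pair_id %s occurs %d time(s)",
              bad, tab[[bad]])
  }
  hemis <- tapply(df$hemisphere, df$pair_id, function(h) paste(sort(h), collapse = ""))
  if (any(hemis != "LR")) {
    bad <- names(hemis)[hemis != "LR"][1L]
    hemi_stop("hemilat_integrity_error",
              "pair_id %s does not have one L and one R member", bad)
  }
  df <- df[order(df$vertex_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("hemilat_atlas", "data.frame")
  df
}

#' Read / write an atlas file
#'
#' Tab-delimited UTF-8 text with one header line
#' (`vertex_id  hemisphere  pair_id  network`).
#'
#' @param path File path.
#' @return `load_atlas()` returns a validated `hemilat_atlas`.
#' @export
load_atlas <- function(path) {
  if (!file.exists(path)) {
    hemi_stop("hemilat_value_error", "atlas file not found: %s", path)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = TRUE)
  as_atlas(df)
}

#' @rdname load_atlas
#' @param atlas A `hemilat_atlas`.
#' @export
write_atlas <- function(atlas, path) {
  atlas <- as_atlas(atlas)
  utils::write.table(atlas, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# One row per homotopic pair: left/right vertex ids and the pair's network
# label, NA unless both members share the same label != NONE ("network-valid").
atlas_pairs <- function(atlas) {
  L <- atlas[atlas$hemisphere == "L", , drop = FALSE]
  R <- atlas[atlas$hemisphere == "R", , drop = FALSE]
  R <- R[match(L$pair_id, R$pair_id), , drop = FALSE]
  net <- ifelse(L$network == R$network & L$network != "NONE",
                L$network, NA_character_)
  out <- data.frame(pair_id = L$pair_id, left = L$vertex_id, right = R$vertex_id,
                    network = net, stringsAsFactors = FALSE)
  out <- out[order(out$pair_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct a BOLD-like time-series object
#'
#' @param subject_id Subject identifier.
#' @param values Numeric matrix, vertices x timepoints, rows aligned to the
#'   atlas vertex order (ascending `vertex_id`).
#' @return A list of class `hemilat_ts` with elements `subject_id`, `values`.
#' @export
timeseries <- function(subject_id, values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  dimnames(values) <- NULL
  if (any(!is.finite(values))) {
    hemi_stop("hemilat_value_error", "time series contains non-finite values")
  }
  if (ncol(values) < 3L) {
    hemi_stop("hemilat_value_error", "time series needs at least 3 timepoints")
  }
  structure(list(subject_id = as.character(subject_id), values = values),
            class = "hemilat_ts")
}

#' Read / write per-subject time series
#'
#' Two on-disk dialects share a JSON sidecar (`<subject_id>.json`) naming
#' `subject_id`, `n_vertices`, `n_timepoints` and `format`:
#' * `tsv` -- `<subject_id>.ts.tsv`, one tab-delimited row per vertex, full
#'   `%.17g` precision so text round-trips bit-for-bit;
#' * `bin` -- `<subject_id>.ts.bin`, flat little-endian float64, column-major.
#'
#' @param ts A `hemilat_ts`.
#' @param dir Output directory.
#' @param format `"tsv"` (default) or `"bin"`.
#' @return `write_timeseries()` invisibly returns the file stem.
#' @export
write_timeseries <- function(ts, dir, format = c("tsv", "bin")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- file.path(dir, ts$subject_id)
  side <- list(subject_id = ts$subject_id,
               n_vertices = nrow(ts$values),
               n_timepoints = ncol(ts$values),
               format = format, dtype = "float64",
               byte_order = "little", storage_order = "column_major")
  jsonlite::write_json(side, paste0(stem, ".json"), auto_unbox = TRUE)
  if (format == "tsv") {
    txt <- apply(ts$values, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
    writeLines(txt, paste0(stem, ".ts.tsv"))
  } else {
    con <- file(paste0(stem, ".ts.bin"), "wb")
    on.exit(close(con))
    writeBin(as.numeric(ts$values), con, size = 8L, endian = "little")
  }
  invisible(stem)
}

#' @rdname write_timeseries
#' @param path Sidecar path, data-file path or bare stem.
#' @param atlas Optional `hemilat_atlas`; when given, the vertex count must
#'   match the atlas.
#' @return `load_timeseries()` returns a `hemilat_ts`.
#' @export
load_timeseries <- function(path, atlas = NULL) {
  stem <- sub("\\.json$", "", sub("\\.ts\\.(tsv|bin)$", "", path))
  side_path <- paste0(stem, ".json")
  if (!file.exists(side_path)) {
    hemi_stop("hemilat_format_error", "missing sidecar header: %s", side_path)
  }
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  for (f in c("subject_id", "n_vertices", "n_timepoints", "format")) {
    if (is.null(side[[f]])) {
      hemi_stop("hemilat_format_error", "sidecar %s lacks field '%s'", side_path, f)
    }
  }
  nv <- as.integer(side$n_vertices)
  nt <- as.integer(side$n_timepoints)
  if (side$format == "tsv") {
    lines <- readLines(paste0(stem, ".ts.tsv"))
    if (length(lines) != nv) {
      hemi_stop("hemilat_shape_error",
                "time series file has %d rows but sidecar declares %d vertices",
                length(lines), nv)
    }
    vals <- t(vapply(strsplit(lines, "\t", fixed = TRUE),
                     function(x) as.numeric(x), numeric(nt)))
    if (nv == 1L) vals <- matrix(vals, nrow = 1L)
  } else if (side$format == "bin") {
    con <- file(paste0(stem, ".ts.bin"), "rb")
    on.exit(close(con))
    raw <- readBin(con, "numeric", n = nv * nt + 1L, size = 8L, endian = "little")
    if (length(raw) != nv * nt) {
      hemi_stop("hemilat_shape_error",
                "binary time series has %d values, expected %d", length(raw), nv * nt)
    }
    vals <- matrix(raw, nrow = nv, ncol = nt)
  } else {
    hemi_stop("hemilat_format_error", "unknown time series format '%s'", side$format)
  }
  if (!is.null(atlas) && nv != nrow(atlas)) {
    hemi_stop("hemilat_shape_error",
              "time series has %d vertices but atlas has %d", nv, nrow(atlas))
  }
  timeseries(side$subject_id, vals)
}

cohort_core_columns <- function() {
  c("subject_id", "group", "gender", "age", "education", "hearing", "moca",
    "digit_span", "stroop", "mfd", "mean_global_fc",
    "sin_threshold", "sis_threshold")
}

cohort_optional_columns <- function() c("training_onset", "training_years")

cohort_numeric_columns <- function() {
  setdiff(c(cohort_core_columns(), cohort_optional_columns()),
          c("subject_id", "group", "gender"))
}

#' Validate a cohort table
#'
#' One row per subject: group membership (`YNM` young non-musicians, `OM`
#' older musicians, `ONM` older non-musicians), demographic and motion
#' covariates, and behavioral scores (speech-in-noise/speech-in-speech
#' thresholds in dB, digit span, Stroop interference in seconds). The
#' musician-only columns `training_onset`/`training_years` are optional and
#' may be `NA` for non-musicians.
#'
#' @param df A data.frame with the cohort columns.
#' @return A validated data.frame of class `hemilat_cohort`.
#' @export
as_cohort <- function(df) {
  df <- as.data.frame(df)
  miss <- setdiff(cohort_core_columns(), names(df))
  if (length(miss)) {
    hemi_stop("hemilat_format_error", "cohort is missing column(s): %s",
              paste(miss, collapse = ", "))
  }
  for (col in cohort_optional_columns()) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
  }
  df <- df[c(cohort_core_columns(), cohort_optional_columns())]
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id)) {
    hemi_stop("hemilat_integrity_error", "duplicated subject_id in cohort")
  }
  df$group <- as.character(df$group)
  bad_g <- setdiff(unique(df$group), c("YNM", "OM", "ONM"))
  if (length(bad_g) || anyNA(df$group)) {
    hemi_stop("hemilat_value_error", "unknown group token(s): %s",
              paste(bad_g, collapse = ", "))
  }
  df$gender <- as.character(df$gender)
  bad_s <- setdiff(unique(df$gender), c("F", "M"))
  if (length(bad_s)) {
    hemi_stop("hemilat_value_error", "unknown gender token(s): %s",
              paste(bad_s, collapse = ", "))
  }
  for (col in cohort_numeric_columns()) {
    v <- df[[col]]
    if (is.character(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      introduced <- is.na(parsed) & !(is.na(v) | v %in% c("NA", ""))
      if (any(introduced)) {
        hemi_stop("hemilat_value_error", "unparseable numeric in column %s: '%s'",
                  col, v[introduced][1L])
      }
      v <- parsed
    }
    v <- as.numeric(v)
    if (any(is.infinite(v))) {
      hemi_stop("hemilat_value_error", "non-finite value in column %s", col)
    }
    df[[col]] <- v
  }
  rownames(df) <- NULL
  class(df) <- c("hemilat_cohort", "data.frame")
  df
}

#' Read / write a cohort table
#'
#' Tab-delimited text with one header line; numeric cells are written with
#' `%.17g` precision so a write/load round trip is the identity.
#'
#' @param path File path.
#' @return `load_cohort()` returns a validated `hemilat_cohort`.
#' @export
load_cohort <- function(path) {
  if (!file.exists(path)) {
    hemi_stop("hemilat_value_error", "cohort file not found: %s", path)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", na.strings = "NA")
  as_cohort(df)
}

#' @rdname load_cohort
#' @param cohort A `hemilat_cohort`.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- as_cohort(cohort)
  out <- cohort
  for (col in cohort_numeric_columns()) {
    out[[col]] <- ifelse(is.na(cohort[[col]]), NA_character_,
                         sprintf("%.17g", cohort[[col]]))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}
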