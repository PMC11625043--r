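#' Assemble a run configuration
#'
#' Collects every tunable of the end-to-end pipeline: simulation settings
#' (or input paths), motion-QC thresholds, the LI validity epsilon, the
#' variance-heterogeneity gate level, the FDR level, the template mode and
#' the partial-correlation covariate list.
#'
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @param seed Integer seed for all stochastic stages.
#' @param simulate `NULL`, or a list with any of `group_sizes`,
#'   `pairs_per_network`, `n_timepoints`, `plans`, `link`,
#'   `fd_outlier_fraction` (defaults as in [make_cohort()] /
#'   [make_atlas()]).
#' @param atlas_path,cohort_path,ts_dir,fd_dir Input paths when not
#'   simulating. FD traces (`<subject_id>.fd.tsv`, one value per line) are
#'   optional.
#' @param fd_threshold,max_fd_fraction Motion-QC thresholds (mm, fraction).
#' @param scrub Censor high-motion frames before correlation?
#' @param epsilon LI validity threshold on `|L + R|`.
#' @param het_alpha Levene gate level for Welch vs classic ANOVA.
#' @param fdr_alpha Significance level after FDR.
#' @param template_mode `"include_self"` (young subjects are aligned against
#'   the all-young template) or `"leave_one_out"`.
#' @param jt_alternative Trend direction for the Jonckheere-Terpstra test
#'   over groups ordered YNM, OM, ONM.
#' @param covariates Covariate columns residualized out of the LI-behavior
#'   partial correlations (gender is coded 0/1).
#' @return A list of class `hemilat_config`.
#' @export
run_config <- function(out_dir = NULL, seed = default_seed(),
                       simulate = list(),
                       atlas_path = NULL, cohort_path = NULL,
                       ts_dir = NULL, fd_dir = NULL,
                       fd_threshold = 0.5, max_fd_fraction = 0.20,
                       scrub = TRUE, epsilon = 1e-8,
                       het_alpha = 0.05, fdr_alpha = 0.05,
                       template_mode = c("include_self", "leave_one_out"),
                       jt_alternative = c("decreasing", "increasing"),
                       covariates = c("age", "gender", "education", "hearing",
                                      "moca", "digit_span", "stroop", "mfd",
                                      "mean_global_fc")) {
  template_mode <- match.arg(template_mode)
  jt_alternative <- match.arg(jt_alternative)
  if (max_fd_fraction < 0 || max_fd_fraction > 1) {
    hemi_stop("hemilat_value_error", "max_fd_fraction must be in [0, 1]")
  }
  if (is.null(simulate) && (is.null(atlas_path) || is.null(cohort_path) ||
                            is.null(ts_dir))) {
    hemi_stop("hemilat_value_error",
              "either simulate settings or input paths are required")
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed), simulate = simulate,
                 atlas_path = atlas_path, cohort_path = cohort_path,
                 ts_dir = ts_dir, fd_dir = fd_dir,
                 fd_threshold = fd_threshold, max_fd_fraction = max_fd_fraction,
                 scrub = scrub, epsilon = epsilon, het_alpha = het_alpha,
                 fdr_alpha = fdr_alpha, template_mode = template_mode,
                 jt_alternative = jt_alternative, covariates = covariates),
            class = "hemilat_config")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path Path to a YAML/JSON file whose keys match [run_config()]
#'   arguments.
#' @return A `hemilat_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) {
    hemi_stop("hemilat_value_error", "config file not found: %s", path)
  }
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    hemi_stop("hemilat_value_error", "unknown config key(s): %s",
              paste(unknown, collapse = ", "))
  }
  if (!is.null(raw$simulate)) {
    if (!is.null(raw$simulate$group_sizes)) {
      raw$simulate$group_sizes <- unlist(raw$simulate$group_sizes)
    }
    if (!is.null(raw$simulate$pairs_per_network)) {
      raw$simulate$pairs_per_network <- unlist(raw$simulate$pairs_per_network)
    }
  }
  do.call(run_config, raw)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  plain <- unclass(config)
  plain$out_dir <- NULL  # hash identifies the analysis, not its destination
  plain <- lapply(plain, function(x) if (is.list(x)) lapply(x, unclass) else x)
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, force = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

load_fd_trace <- function(fd_dir, subject_id) {
  if (is.null(fd_dir)) return(NULL)
  path <- file.path(fd_dir, paste0(subject_id, ".fd.tsv"))
  if (!file.exists(path)) return(NULL)
  as.numeric(readLines(path))
}

sim_defaults <- function(sim) {
  list(group_sizes = sim$group_sizes %||% c(YNM = 24L, OM = 23L, ONM = 23L),
       pairs_per_network = sim$pairs_per_network %||%
         c(SMN = 120, AUD = 120, LAN = 120, DAN = 120, CON = 120, FPN = 120,
           DMN = 120, NONE = 48),
       n_timepoints = sim$n_timepoints %||% 750L,
       plans = sim$plans %||% default_group_plans(),
       link = sim$link %||% behavior_link(),
       fd_outlier_fraction = sim$fd_outlier_fraction %||% 0.02)
}

#' Run the full lateralization pipeline
#'
#' Orchestrates simulate (or load) -> motion QC -> Fisher-z connectivity ->
#' strength sums -> pair-wise LI -> network LI -> young-template alignment
#' -> the full statistical battery. Deterministic given the configuration
#' and seed. When `out_dir` is set, writes `results_networkLI.tsv`,
#' `results_alignment.tsv`, `results_stats.json` and `run_report.json`.
#'
#' @param config A `hemilat_config` from [run_config()] or
#'   [load_run_config()].
#' @return List: `cohort`, `atlas`, `network_li`, `alignment`, `template`,
#'   `limaps`, `qc`, `stats` (long data.frame of every test), `report`.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "hemilat_config"))
  warnings_log <- character(0)
  note <- function(msg) warnings_log <<- c(warnings_log, msg)

  if (!is.null(config$simulate)) {
    sim <- sim_defaults(config$simulate)
    atlas <- make_atlas(sim$pairs_per_network, seed = config$seed)
    gen <- make_cohort(atlas, group_sizes = sim$group_sizes, plans = sim$plans,
                       link = sim$link, n_timepoints = sim$n_timepoints,
                       fd_outlier_fraction = sim$fd_outlier_fraction,
                       seed = config$seed)
    cohort <- gen$cohort
    ts_list <- gen$timeseries
    fd_list <- gen$fd
  } else {
    atlas <- load_atlas(config$atlas_path)
    cohort <- load_cohort(config$cohort_path)
    ts_list <- lapply(cohort$subject_id, function(sid) {
      load_timeseries(file.path(config$ts_dir, paste0(sid, ".json")), atlas)
    })
    names(ts_list) <- cohort$subject_id
    fd_list <- lapply(cohort$subject_id, function(sid) {
      load_fd_trace(config$fd_dir, sid)
    })
    names(fd_list) <- cohort$subject_id
  }

  # ---- motion QC ----
  qc_rows <- list()
  excluded <- character(0)
  for (sid in cohort$subject_id) {
    fd <- fd_list[[sid]]
    if (is.null(fd)) {
      qc_rows[[sid]] <- data.frame(subject_id = sid, n_frames = NA_integer_,
                                   n_outlier_frames = NA_integer_,
                                   outlier_fraction = NA_real_,
                                   excluded = FALSE, mfd = NA_real_)
      next
    }
    qc <- motion_qc(fd, config$fd_threshold, config$max_fd_fraction)
    if (qc$excluded) {
      excluded <- c(excluded, sid)
      note(sprintf("subject %s excluded: %.1f%% frames above %.2f mm FD",
                   sid, 100 * qc$outlier_fraction, config$fd_threshold))
    }
    qc_rows[[sid]] <- cbind(data.frame(subject_id = sid), qc)
  }
  qc_tab <- do.call(rbind, c(qc_rows, list(make.row.names = FALSE)))
  keep <- setdiff(cohort$subject_id, excluded)
  if (!length(keep)) {
    hemi_stop("hemilat_value_error", "all subjects excluded by motion QC")
  }
  cohort <- cohort[cohort$subject_id %in% keep, , drop = FALSE]

  # ---- connectivity and laterality ----
  limaps <- list()
  netli_rows <- list()
  for (sid in keep) {
    fc <- compute_fc(ts_list[[sid]], fd = fd_list[[sid]], scrub = config$scrub,
                     fd_threshold = config$fd_threshold)
    cohort$mean_global_fc[cohort$subject_id == sid] <- mean_global_fc(fc)
    mfd <- qc_tab$mfd[qc_tab$subject_id == sid]
    if (!is.na(mfd)) cohort$mfd[cohort$subject_id == sid] <- mfd
    limap <- pair_li(strength_sums(fc, atlas), atlas, epsilon = config$epsilon)
    limaps[[sid]] <- limap
    nl <- withCallingHandlers(
      network_li(limap),
      warning = function(w) {
        note(sprintf("subject %s: %s", sid, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    nl$subject_id <- sid
    netli_rows[[sid]] <- nl
  }
  net_tab <- do.call(rbind, c(netli_rows, list(make.row.names = FALSE)))
  net_tab <- merge(net_tab, cohort[c("subject_id", "group")], by = "subject_id",
                   sort = FALSE)

  # ---- young template and alignment ----
  ynm_ids <- cohort$subject_id[cohort$group == "YNM"]
  if (!length(ynm_ids)) {
    hemi_stop("hemilat_value_error", "no YNM subjects available for the template")
  }
  template <- young_template(limaps[ynm_ids])
  align_one <- function(sid) {
    tmpl <- if (config$template_mode == "leave_one_out" && sid %in% ynm_ids &&
                length(ynm_ids) > 1L) {
      young_template(limaps[setdiff(ynm_ids, sid)])
    } else {
      template
    }
    withCallingHandlers(
      alignment_table(limaps[sid], tmpl),
      warning = function(w) {
        note(conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }
  align_tab <- do.call(rbind, c(lapply(keep, align_one),
                                list(make.row.names = FALSE)))
  align_tab <- merge(align_tab, cohort[c("subject_id", "group")],
                     by = "subject_id", sort = FALSE)

  # ---- statistics ----
  stats_tab <- stats_battery(net_tab, align_tab, cohort, config, note)

  report <- list(
    package = "hemilat",
    version = as.character(utils::packageVersion("hemilat")),
    config_hash = config_hash(config),
    seed = config$seed,
    n_subjects = length(keep),
    n_excluded = length(excluded),
    excluded = as.list(excluded),
    group_sizes = as.list(table(cohort$group)),
    n_pairs = nrow(atlas) / 2,
    n_stat_records = nrow(stats_tab),
    warnings = as.list(warnings_log)
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_num_tsv(net_tab, file.path(config$out_dir, "results_networkLI.tsv"))
    write_num_tsv(align_tab, file.path(config$out_dir, "results_alignment.tsv"))
    jsonlite::write_json(stats_tab, file.path(config$out_dir, "results_stats.json"),
                         auto_unbox = TRUE, digits = NA, na = "null", dataframe = "rows")
    jsonlite::write_json(report, file.path(config$out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(cohort = cohort, atlas = atlas, network_li = net_tab,
       alignment = align_tab, template = template, limaps = limaps,
       qc = qc_tab, stats = stats_tab, report = report)
}

write_num_tsv <- function(df, path) {
  out <- df
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      out[[col]] <- ifelse(is.na(out[[col]]), NA_character_,
                           sprintf("%.17g", out[[col]]))
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}

stat_row <- function(analysis, kind, network, contrast, res, family) {
  df1 <- res$df[1L]
  df2 <- if (length(res$df) > 1L) res$df[2L] else NA_real_
  data.frame(analysis = analysis, kind = kind, network = network,
             contrast = contrast, method = res$method,
             statistic = res$statistic, df1 = df1, df2 = df2,
             p = res$p, p_fdr = NA_real_,
             effect = res$effect %||% NA_real_,
             family = family, stringsAsFactors = FALSE)
}

# The full inferential battery over network LIs, alignments and behavior.
stats_battery <- function(net_tab, align_tab, cohort, config, note = function(...) NULL) {
  groups_present <- intersect(c("YNM", "OM", "ONM"), unique(cohort$group))
  records <- list()
  add <- function(row) records[[length(records) + 1L]] <<- row

  pull <- function(tab, col, net, grp = NULL) {
    sel <- tab$network == net
    if (!is.null(grp)) sel <- sel & tab$group == grp
    v <- tab[[col]][sel]
    v[!is.na(v)]
  }

  for (kind in c("intra", "he")) {
    li_col <- paste0("li_", kind)
    al_col <- paste0("align_", kind)
    for (net in hemi_networks()) {
      # one-sample lateralization tests per group
      for (g in groups_present) {
        x <- pull(net_tab, li_col, net, g)
        res <- tryCatch(one_sample_t(x), hemilat_error = function(e) NULL)
        if (!is.null(res)) {
          add(stat_row("network_li_onesample", kind, net, g, res,
                       sprintf("t1|%s|%s", kind, g)))
        }
      }
      # group comparison of network LI
      gx <- lapply(groups_present, function(g) pull(net_tab, li_col, net, g))
      names(gx) <- groups_present
      if (length(gx) >= 2L && all(lengths(gx) >= 2L)) {
        res <- tryCatch(oneway_anova(gx, het_alpha = config$het_alpha),
                        hemilat_error = function(e) NULL)
        if (!is.null(res)) {
          add(stat_row("network_li_anova", kind, net, "YNM|OM|ONM", res,
                       sprintf("anova_li|%s", kind)))
          post_hoc(gx, res, function(r, contrast, family)
            add(stat_row("network_li_posthoc", kind, net, contrast, r, family)),
            kind)
        }
      }
      # group comparison + ordered trend of alignment-to-young
      ax <- lapply(groups_present, function(g) pull(align_tab, al_col, net, g))
      names(ax) <- groups_present
      if (length(ax) >= 2L && all(lengths(ax) >= 2L)) {
        res <- tryCatch(oneway_anova(ax, het_alpha = config$het_alpha),
                        hemilat_error = function(e) NULL)
        if (!is.null(res)) {
          add(stat_row("alignment_anova", kind, net, "YNM|OM|ONM", res,
                       sprintf("anova_align|%s", kind)))
          post_hoc(ax, res, function(r, contrast, family)
            add(stat_row("alignment_posthoc", kind, net, contrast, r, family)),
            paste0("align_", kind))
        }
      }
      if (length(ax) == 3L && all(lengths(ax) >= 1L)) {
        jt <- jonckheere_terpstra(ax[c("YNM", "OM", "ONM")],
                                  alternative = config$jt_alternative)
        add(stat_row("alignment_trend", kind, net, "YNM>OM>ONM", jt,
                     sprintf("jt|%s", kind)))
      } else {
        note(sprintf("network %s (%s): trend test requires >= 3 groups; skipped",
                     net, kind))
      }
    }
  }

  # brain-behavior partial correlations in the two older groups
  for (g in intersect(c("OM", "ONM"), groups_present)) {
    sub <- cohort[cohort$group == g, , drop = FALSE]
    Z0 <- covariate_matrix(sub, config$covariates)
    for (measure in c("li", "alignment")) {
      tab <- if (measure == "li") net_tab else align_tab
      col_of <- function(kind) {
        if (measure == "li") paste0("li_", kind) else paste0("align_", kind)
      }
      for (kind in c("intra", "he")) {
        for (y_col in c("sin_threshold", "sis_threshold")) {
          for (net in hemi_networks()) {
            x <- tab[[col_of(kind)]][tab$network == net & tab$group == g]
            x <- x[match(sub$subject_id, tab$subject_id[tab$network == net &
                                                          tab$group == g])]
            y <- sub[[y_col]]
            ok <- stats::complete.cases(x, y, Z0)
            res <- tryCatch(
              partial_correlation(x[ok], y[ok], Z0[ok, , drop = FALSE]),
              hemilat_error = function(e) {
                note(sprintf("partial correlation %s/%s/%s/%s in %s: %s",
                             measure, kind, net, y_col, g, conditionMessage(e)))
                NULL
              })
            if (!is.null(res)) {
              add(stat_row(paste0("behavior_", measure), kind, net,
                           paste(g, y_col, sep = "|"), res,
                           sprintf("pcor|%s|%s|%s|%s", measure, kind, g, y_col)))
            }
          }
        }
      }
    }
  }

  tab <- do.call(rbind, c(records, list(make.row.names = FALSE)))
  # BH adjustment within each 7-network family
  for (fam in unique(tab$family)) {
    idx <- which(tab$family == fam)
    tab$p_fdr[idx] <- fdr_bh(tab$p[idx])
  }
  tab
}

# Post hocs follow the ANOVA gate: Games-Howell after Welch, pairwise pooled
# t with BH-FDR after the classic F.
post_hoc <- function(gx, anova_res, emit, kind_tag) {
  gm <- group_moments(gx)
  nms <- names(gm$groups)
  if (identical(anova_res$variant, "welch") || anova_res$method == "welch_f") {
    gh <- tryCatch(games_howell(gm$groups), hemilat_error = function(e) NULL)
    if (is.null(gh)) return(invisible())
    for (r in seq_len(nrow(gh))) {
      res <- stat_result("gh", gh$statistic[r], gh$df[r], gh$p[r],
                         n = c(gm$n[gh$group1[r]], gm$n[gh$group2[r]]))
      emit(res, paste(gh$group1[r], gh$group2[r], sep = "|"),
           paste0("gh|", kind_tag))
    }
  } else {
    pairs <- utils::combn(length(gm$groups), 2)
    ps <- apply(pairs, 2L, function(ij) {
      t_from_summary(gm$m[ij[1]], gm$s[ij[1]], gm$n[ij[1]],
                     gm$m[ij[2]], gm$s[ij[2]], gm$n[ij[2]], kind = "pooled")
    })
    praw <- vapply(ps, `[[`, numeric(1), "p")
    padj <- fdr_bh(praw)
    for (c_i in seq_along(ps)) {
      res <- ps[[c_i]]
      res$p_fdr_pair <- padj[c_i]
      emit(res, paste(nms[pairs[1, c_i]], nms[pairs[2, c_i]], sep = "|"),
           paste0("pairwise_t|", kind_tag))
    }
  }
  invisible()
}

covariate_matrix <- function(cohort, covariates) {
  cols <- lapply(covariates, function(cv) {
    if (cv == "gender") as.numeric(cohort$gender == "M") else cohort[[cv]]
  })
  Z <- do.call(cbind, cols)
  colnames(Z) <- covariates
  # a covariate that is entirely missing (e.g. MoCA in a young group) or
  # constant carries no information; drop it rather than fail
  keep <- vapply(seq_len(ncol(Z)), function(j) {
    v <- Z[, j]
    sum(!is.na(v)) >= 2 && stats::sd(v, na.rm = TRUE) > 0
  }, logical(1))
  Z[, keep, drop = FALSE]
}

#' Group-difference battery on a cohort table
#'
#' The demographic/behavioral comparisons run on a raw cohort: chi-squared
#' on the gender split, pooled two-sample t between the two older groups on
#' age, education, MoCA and hearing, and gate-selected one-way ANOVA across
#' all three groups on the SIN/SIS thresholds, digit span and Stroop.
#'
#' @param cohort A `hemilat_cohort` containing all three groups.
#' @param het_alpha Levene gate level.
#' @return data.frame with one row per test.
#' @export
run_table1 <- function(cohort, het_alpha = 0.05) {
  cohort <- as_cohort(cohort)
  if (!all(c("YNM", "OM", "ONM") %in% cohort$group)) {
    hemi_stop("hemilat_value_error", "cohort must contain YNM, OM and ONM")
  }
  rows <- list()
  add <- function(variable, comparison, res) {
    rows[[length(rows) + 1L]] <<- stat_row(variable, NA_character_,
                                           NA_character_, comparison, res,
                                           family = "table1")
  }
  counts <- table(factor(cohort$group, c("YNM", "OM", "ONM")),
                  factor(cohort$gender, c("F", "M")))
  add("gender", "YNM|OM|ONM", chi_square_independence(unclass(counts)))
  om <- cohort[cohort$group == "OM", , drop = FALSE]
  onm <- cohort[cohort$group == "ONM", , drop = FALSE]
  for (v in c("age", "education", "moca", "hearing")) {
    a <- om[[v]][!is.na(om[[v]])]
    b <- onm[[v]][!is.na(onm[[v]])]
    add(v, "OM|ONM",
        t_from_summary(mean(a), stats::sd(a), length(a),
                       mean(b), stats::sd(b), length(b), kind = "pooled"))
  }
  for (v in c("sin_threshold", "sis_threshold", "digit_span", "stroop")) {
    gx <- lapply(c("YNM", "OM", "ONM"), function(g) {
      x <- cohort[[v]][cohort$group == g]
      x[!is.na(x)]
    })
    names(gx) <- c("YNM", "OM", "ONM")
    add(v, "YNM|OM|ONM", oneway_anova(gx, het_alpha = het_alpha))
  }
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  names(tab)[names(tab) == "analysis"] <- "variable"
  tab[c("variable", "contrast", "method", "statistic", "df1", "df2", "p", "effect")]
}

#' Group-difference battery from published summary statistics
#'
#' Recomputes the summary-level tests directly from per-group means, SDs and
#' sizes: chi-squared on the gender counts, pooled t between the older
#' groups, and both the classic and Welch F for each three-group variable
#' (a raw-data Levene gate is not available from summaries, so both forms
#' are reported).
#'
#' @param summaries data.frame as returned by [cohort_reference_summaries()].
#' @param gender_counts 3x2 count matrix as returned by
#'   [reference_gender_counts()].
#' @return data.frame with one row per test.
#' @export
table1_from_summary <- function(summaries = cohort_reference_summaries(),
                                gender_counts = reference_gender_counts()) {
  rows <- list()
  add <- function(variable, comparison, res) {
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, contrast = comparison, method = res$method,
      statistic = res$statistic, df1 = res$df[1L],
      df2 = if (length(res$df) > 1L) res$df[2L] else NA_real_,
      p = res$p, effect = res$effect %||% NA_real_, stringsAsFactors = FALSE)
  }
  add("gender", "YNM|OM|ONM", chi_square_independence(gender_counts))
  pick <- function(v, g, f) summaries[[f]][summaries$variable == v &
                                             summaries$group == g]
  for (v in c("age", "education", "moca", "hearing")) {
    add(v, "OM|ONM",
        t_from_summary(pick(v, "OM", "mean"), pick(v, "OM", "sd"),
                       pick(v, "OM", "n"),
                       pick(v, "ONM", "mean"), pick(v, "ONM", "sd"),
                       pick(v, "ONM", "n"), kind = "pooled"))
  }
  for (v in c("sin_threshold", "sis_threshold", "digit_span", "stroop")) {
    g <- c("YNM", "OM", "ONM")
    m <- vapply(g, pick, numeric(1), v = v, f = "mean")
    s <- vapply(g, pick, numeric(1), v = v, f = "sd")
    n <- vapply(g, pick, numeric(1), v = v, f = "n")
    add(v, "YNM|OM|ONM", anova_from_summary(m, s, n, kind = "classic"))
    add(v, "YNM|OM|ONM", anova_from_summary(m, s, n, kind = "welch"))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
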