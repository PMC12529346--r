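# End-to-end orchestration: simulate/load -> QC -> z-score -> pool ->
# select k -> cluster -> per-session metrics -> statistics -> report.

#' Pipeline configuration
#'
#' Bundles every tunable of the full analysis with its default. All
#' randomness derives from `seed`. The configuration round-trips through
#' JSON losslessly via [write_config()] / [read_config()].
#'
#' @param manifest path to a cohort manifest TSV (ignored when `simulate`
#'   is set).
#' @param out_dir output directory.
#' @param simulate optional [cohort_spec()]; when set, data are generated
#'   in memory instead of read from `manifest`.
#' @param k fixed number of states; NULL (default) scans `k_min:k_max` and
#'   takes the elbow.
#' @param k_min,k_max scan range for the cluster number.
#' @param n_replicates k-means restarts for the final fit (default 100).
#' @param scan_replicates restarts per k during the scan (default 10).
#' @param max_iter,scan_max_iter Lloyd iteration caps.
#' @param fd_threshold_mm motion QC threshold (default 0.5 mm).
#' @param alpha family-wise error rate (default 0.05).
#' @param tr_seconds repetition time (default 0.8 s).
#' @param silhouette also compute silhouettes during the scan.
#' @param literal_tp use the literal occurrences denominator for
#'   transition probabilities instead of the row-stochastic one.
#' @param zscore_per "run" or "session" standardization.
#' @param seed master seed.
#' @return list of class `cap_config`.
#' @export
cap_config <- function(manifest = NULL, out_dir = tempfile("capdyn_"),
                       simulate = NULL, k = NULL, k_min = 2, k_max = 15,
                       n_replicates = 100, scan_replicates = 10,
                       max_iter = 1000, scan_max_iter = 100,
                       fd_threshold_mm = 0.5, alpha = 0.05, tr_seconds = 0.8,
                       silhouette = FALSE, literal_tp = FALSE,
                       zscore_per = c("run", "session"), seed = 1) {
  zscore_per <- match.arg(zscore_per)
  stopifnot(k_min >= 2, k_max > k_min, n_replicates >= 1, scan_replicates >= 1,
            max_iter >= 1, fd_threshold_mm > 0, alpha > 0, alpha < 1,
            tr_seconds > 0)
  if (!is.null(k)) stopifnot(k >= 2)
  if (is.null(simulate) && is.null(manifest))
    stop("stage [input]: no manifest path and simulation disabled")
  structure(as.list(environment()), class = "cap_config")
}

#' @rdname cap_config
#' @param config a `cap_config`.
#' @param path JSON path.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$simulate <- if (!is.null(x$simulate)) "cohort_spec" else NULL  # specs carry closures; not serialized
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname cap_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$simulate <- NULL
  do.call(cap_config, x[!vapply(x, is.null, TRUE)])
}

.stage <- function(log, name, msg) {
  line <- sprintf("[%s] %s", name, msg)
  c(log, line)
}

# collapse per-run manifest rows to one row per session
.session_manifest <- function(manifest) {
  key <- !duplicated(paste(manifest$subject_id, manifest$timepoint))
  manifest[key, , drop = FALSE]
}

#' Run the full CAP analysis pipeline
#'
#' Executes every stage on a cohort (simulated or loaded from a manifest)
#' and writes all outputs under `config$out_dir`: the k-selection curve,
#' the fitted model (centroids, labels, JSON sidecar), per-session metrics
#' in long format, the statistics table with Bonferroni families, spatial
#' diagnostics, a plain-text report, and a run log with all seeds.
#' Re-running with the same config reproduces the outputs.
#'
#' @param config a [cap_config()].
#' @return (invisibly) a list with all in-memory stage products:
#'   `manifest`, `qc`, `model`, `curve`, `chosen_k`, `metric_sets`,
#'   `metrics`, `stats`, `families`, `diagnostics`, `labeling`, `out_dir`.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "cap_config"))
  t0 <- Sys.time()
  log <- sprintf("capdyn pipeline, seed = %d", config$seed)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  ## --- input stage -------------------------------------------------------
  if (!is.null(config$simulate)) {
    spec <- config$simulate
    cohort <- simulate_cohort(spec)
    manifest <- cohort$manifest
    sessions <- cohort$sessions
    parcel_table <- spec$parcel_table
    log <- .stage(log, "simulate", sprintf("%d session(s), %d parcels",
                                           length(sessions), nrow(parcel_table)))
  } else {
    if (!file.exists(config$manifest)) stop("stage [input]: manifest not found")
    manifest <- read_manifest(config$manifest)
    parcel_table <- build_parcel_table()
    sessions <- .load_sessions(manifest, parcel_table, config$tr_seconds)
    cohort <- NULL
    log <- .stage(log, "load", sprintf("%d session(s) read", length(sessions)))
  }

  ## --- motion QC ---------------------------------------------------------
  qc <- qc_mean_fd(.session_manifest(manifest), config$fd_threshold_mm)
  keep_ids <- paste(qc$retained$subject_id, qc$retained$timepoint, sep = "_")
  sessions <- sessions[names(sessions) %in% keep_ids]
  if (length(sessions) == 0) stop("stage [qc]: no sessions retained")
  log <- .stage(log, "qc", sprintf("%d retained, %d excluded session row(s)",
                                   nrow(qc$retained), nrow(qc$excluded)))

  ## --- z-score and pool --------------------------------------------------
  sessions <- lapply(sessions, zscore_session, per = config$zscore_per)
  pool <- concat_frames(sessions)
  log <- .stage(log, "pool", sprintf("%d frames pooled", nrow(pool$frames)))

  ## --- cluster number ----------------------------------------------------
  if (is.null(config$k)) {
    curve <- scan_k(pool, config$k_min, config$k_max,
                    n_replicates = config$scan_replicates,
                    max_iter = config$scan_max_iter,
                    seed = derive_seed(config$seed, 11),
                    silhouette = config$silhouette)
    chosen_k <- select_k_elbow(curve)
    log <- .stage(log, "select-k", sprintf("elbow at k = %d%s", chosen_k,
                                           if (isTRUE(attr(chosen_k, "ambiguous"))) " (ambiguous)" else ""))
  } else {
    curve <- NULL
    chosen_k <- as.integer(config$k)
    log <- .stage(log, "select-k", sprintf("fixed k = %d", chosen_k))
  }

  ## --- final clustering --------------------------------------------------
  model <- kmeans_caps(pool, as.integer(chosen_k), n_replicates = config$n_replicates,
                       max_iter = config$max_iter, seed = derive_seed(config$seed, 12))
  model <- order_states_by_network(model, parcel_table)
  labeling <- label_caps_by_network(model, parcel_table)
  log <- .stage(log, "cluster", sprintf("k = %d, objective = %.4f", model$k, model$objective))

  ## --- per-session metrics ----------------------------------------------
  tp_mode <- if (config$literal_tp) "literal" else "markov"
  metric_sets <- lapply(sessions, function(ts) {
    cap_metrics(assign_states(ts, model, pool), ts, K = model$k, tp_mode = tp_mode)
  })
  metrics <- metrics_long(metric_sets)
  log <- .stage(log, "metrics", sprintf("%d metric rows", nrow(metrics)))

  ## --- statistics --------------------------------------------------------
  stats_out <- compute_group_stats(metric_sets, .session_manifest(qc$retained),
                                   K = model$k, alpha = config$alpha)
  log <- .stage(log, "stats", sprintf("%d tests in %d families",
                                      nrow(stats_out$tests), length(stats_out$families)))

  ## --- diagnostics -------------------------------------------------------
  diagnostics <- compute_diagnostics(pool, model, metric_sets)
  log <- .stage(log, "diagnostics", "centroid similarity, frame similarity, per-state FD")

  result <- list(manifest = manifest, qc = qc, pool_size = nrow(pool$frames),
                 curve = curve, chosen_k = chosen_k, model = model,
                 labeling = labeling, metric_sets = metric_sets, metrics = metrics,
                 stats = stats_out$tests, families = stats_out$families,
                 diagnostics = diagnostics, out_dir = config$out_dir,
                 truth = if (!is.null(cohort)) cohort$truth else NULL)

  ## --- outputs -----------------------------------------------------------
  write_pipeline_outputs(result, config)
  log <- .stage(log, "write", sprintf("outputs under %s", config$out_dir))
  log <- .stage(log, "done", sprintf("elapsed %.1f s", as.numeric(Sys.time() - t0, units = "secs")))
  writeLines(log, file.path(config$out_dir, "run_log.txt"))
  invisible(result)
}

.load_sessions <- function(manifest, parcel_table, tr_seconds) {
  key <- paste(manifest$subject_id, manifest$timepoint, sep = "_")
  out <- list()
  for (sid in unique(key)) {
    rows <- manifest[key == sid, , drop = FALSE]
    rows <- rows[order(rows$run_index), , drop = FALSE]
    mats <- lapply(rows$path, read_session_matrix, parcel_table = parcel_table)
    nf <- vapply(mats, nrow, 0L)
    out[[sid]] <- roi_ts(do.call(rbind, mats),
                         subject_id = rows$subject_id[1], group = rows$group[1],
                         timepoint = rows$timepoint[1],
                         run_boundaries = cumsum(c(1L, utils::head(nf, -1))),
                         tr_seconds = tr_seconds)
  }
  out
}

#' Group and longitudinal statistics on computed CAP metrics
#'
#' Implements the full statistical plan: paired t-tests on mood scales;
#' paired t-tests on FT and MDT per state in the treatment group (each a
#' Bonferroni family of K tests); transition-probability tests restricted
#' to transitions *into* states with significant FT/MDT effects (one family
#' sized |selected| * (K - 1)); Pearson correlations of significant CAP
#' changes with percent change of significantly improved mood scores; and
#' covariate-adjusted cross-sectional comparisons (HC vs treatment baseline
#' and HC vs treatment post) for the significant metrics.
#'
#' @param metric_sets named list of `cap_metric_set` keyed
#'   "subject_timepoint".
#' @param session_manifest one-row-per-session manifest (ages, sex, moods).
#' @param K number of states.
#' @param alpha family-wise error rate.
#' @param treat_group,control_group group labels.
#' @return list: `tests` (data.frame of all [cap_test_result()] rows),
#'   `families` (list of `family_spec`).
#' @export
compute_group_stats <- function(metric_sets, session_manifest, K, alpha = 0.05,
                                treat_group = "TRD", control_group = "HC") {
  man <- session_manifest
  sid_of <- function(subject, tp) paste(subject, tp, sep = "_")
  get_metric <- function(subject, tp, what, i, j = NULL) {
    ms <- metric_sets[[sid_of(subject, tp)]]
    if (is.null(ms)) return(NA_real_)
    switch(what, ft = ms$ft[i], mdt = ms$mdt_tr[i], tp = ms$tp[i, j])
  }
  treat_subj <- unique(man$subject_id[man$group == treat_group])
  # keep only subjects with both sessions
  treat_subj <- treat_subj[vapply(treat_subj, function(s)
    all(c(sid_of(s, "baseline"), sid_of(s, "post")) %in% names(metric_sets)), TRUE)]
  ctrl_base <- man[man$group == control_group & man$timepoint == "baseline", , drop = FALSE]
  treat_base <- man[man$group == treat_group & man$timepoint == "baseline", , drop = FALSE]
  treat_post <- man[man$group == treat_group & man$timepoint == "post", , drop = FALSE]

  tests <- list()
  families <- list()
  add <- function(t) tests[[length(tests) + 1]] <<- t

  ## mood changes in the treatment group (nominal alpha)
  moods <- c("hdrs", "rrs_brooding", "rrs_reflection", "rrs_reappraisal")
  improved <- character(0)
  for (mo in moods) {
    b <- treat_base[[mo]][match(treat_subj, treat_base$subject_id)]
    p <- treat_post[[mo]][match(treat_subj, treat_post$subject_id)]
    tt <- paired_change_tests(b, p, name = paste0("mood_", mo),
                              family = "mood_change", alpha_adjusted = alpha)
    add(tt)
    if (tt$significant && tt$direction < 0) improved <- c(improved, mo)
  }

  ## longitudinal FT / MDT families (K tests each)
  sig_states <- integer(0)
  for (what in c("ft", "mdt")) {
    fam <- sprintf("%s_longitudinal", toupper(what))
    thr <- alpha / K
    for (s in seq_len(K)) {
      b <- vapply(treat_subj, get_metric, 0, tp = "baseline", what = what, i = s)
      p <- vapply(treat_subj, get_metric, 0, tp = "post", what = what, i = s)
      res <- tryCatch(
        paired_change_tests(b, p, name = sprintf("%s_state%d_%s", toupper(what), s, treat_group),
                            family = fam, alpha_adjusted = thr),
        error = function(e) NULL)
      if (!is.null(res)) {
        add(res)
        if (res$significant) sig_states <- union(sig_states, s)
      }
    }
    families[[fam]] <- bonferroni_family(numeric(0), m = K, alpha = alpha, family = fam)
  }

  ## TP family: transitions into the selected states
  tp_fam <- tp_test_family(sort(sig_states), K)
  sig_tp <- tp_fam[0, ]
  if (nrow(tp_fam) > 0) {
    thr <- alpha / nrow(tp_fam)
    families[["TP_longitudinal"]] <- bonferroni_family(numeric(0), m = nrow(tp_fam),
                                                       alpha = alpha, family = "TP_longitudinal")
    for (r in seq_len(nrow(tp_fam))) {
      i <- tp_fam$from[r]; j <- tp_fam$to[r]
      b <- vapply(treat_subj, get_metric, 0, tp = "baseline", what = "tp", i = i, j = j)
      p <- vapply(treat_subj, get_metric, 0, tp = "post", what = "tp", i = i, j = j)
      res <- tryCatch(
        paired_change_tests(b, p, name = sprintf("TP_%d_to_%d_%s", i, j, treat_group),
                            family = "TP_longitudinal", alpha_adjusted = thr),
        error = function(e) NULL)
      if (!is.null(res)) {
        add(res)
        if (res$significant) sig_tp <- rbind(sig_tp, tp_fam[r, ])
      }
    }
  }

  ## correlations of significant CAP changes with improved mood scores
  sig_metrics <- list()
  for (s in sig_states) sig_metrics[[length(sig_metrics) + 1]] <- list(what = "ft", i = s, j = NULL,
                                                                       tag = sprintf("FT_state%d", s))
  if (nrow(sig_tp) > 0) for (r in seq_len(nrow(sig_tp)))
    sig_metrics[[length(sig_metrics) + 1]] <- list(what = "tp", i = sig_tp$from[r], j = sig_tp$to[r],
                                                   tag = sprintf("TP_%d_to_%d", sig_tp$from[r], sig_tp$to[r]))
  n_corr <- length(sig_metrics) * length(improved)
  if (n_corr > 0) {
    thr <- alpha / n_corr
    families[["mood_correlation"]] <- bonferroni_family(numeric(0), m = n_corr,
                                                        alpha = alpha, family = "mood_correlation")
    for (sm in sig_metrics) {
      d <- vapply(treat_subj, function(su)
        get_metric(su, "post", sm$what, sm$i, sm$j) -
          get_metric(su, "baseline", sm$what, sm$i, sm$j), 0)
      for (mo in improved) {
        b <- treat_base[[mo]][match(treat_subj, treat_base$subject_id)]
        p <- treat_post[[mo]][match(treat_subj, treat_post$subject_id)]
        res <- tryCatch(
          correlate_change_with_mood(d, percent_change(b, p),
                                     name = sprintf("corr_%s_pct_%s", sm$tag, mo),
                                     family = "mood_correlation", alpha_adjusted = thr),
          error = function(e) NULL)
        if (!is.null(res)) add(res)
      }
    }
  }

  ## cross-sectional follow-up on significant metrics, controlling age + sex
  if (length(sig_metrics) > 0 && nrow(ctrl_base) >= 3) {
    for (tp_lab in c("baseline", "post")) {
      tman <- if (tp_lab == "baseline") treat_base else treat_post
      for (sm in sig_metrics) {
        v_c <- vapply(ctrl_base$subject_id, get_metric, 0, tp = "baseline",
                      what = sm$what, i = sm$i, j = sm$j)
        v_t <- vapply(tman$subject_id, get_metric, 0, tp = tp_lab,
                      what = sm$what, i = sm$i, j = sm$j)
        res <- tryCatch(
          adjusted_group_comparison(
            c(v_c, v_t),
            c(rep(control_group, length(v_c)), rep(treat_group, length(v_t))),
            c(ctrl_base$age, tman$age), c(ctrl_base$sex, tman$sex),
            name = sprintf("xsec_%s_%s_vs_%s", sm$tag, control_group,
                           paste0(treat_group, "_", tp_lab)),
            family = "cross_sectional", alpha_adjusted = alpha),
          error = function(e) NULL)
        if (!is.null(res)) add(res)
      }
    }
  }

  tests_df <- do.call(rbind, tests)
  rownames(tests_df) <- NULL
  list(tests = tests_df, families = families,
       significant_states = sort(sig_states), tp_family = tp_fam)
}

#' Spatial and motion diagnostics for a fitted model
#'
#' @param pool frame pool.
#' @param model fitted `cap_model`.
#' @param metric_sets per-session metric sets (for per-state FD).
#' @return list: `centroid_similarity` (k x k), `frame_similarity`
#'   (per-session mean r + per-state ANOVA across group/timepoint cells),
#'   `state_fd` (per-state FD mean/sd + ANOVA).
#' @export
compute_diagnostics <- function(pool, model, metric_sets) {
  fs <- frame_centroid_similarity(pool, model)
  cell <- function(df) ifelse(df$group == "HC", "HC", paste(df$group, df$timepoint, sep = "_"))
  fs$per_session$cell <- cell(fs$per_session)
  fs_anova <- do.call(rbind, lapply(seq_len(model$k), function(s) {
    d <- fs$per_session[fs$per_session$state == s, ]
    tryCatch(cbind(state = s, oneway_anova(d$r, d$cell, name = sprintf("frame_sim_state%d", s))),
             error = function(e) NULL)
  }))
  fd_tab <- do.call(rbind, lapply(names(metric_sets), function(id) {
    m <- metric_sets[[id]]
    data.frame(session = id, group = m$group, timepoint = m$timepoint,
               state = seq_along(m$per_state_fd_mm), fd = m$per_state_fd_mm)
  }))
  fd_summary <- NULL
  fd_anova <- NULL
  if (!all(is.na(fd_tab$fd))) {
    fd_tab$cell <- cell(fd_tab)
    fd_summary <- do.call(rbind, lapply(seq_len(model$k), function(s) {
      d <- fd_tab$fd[fd_tab$state == s]
      data.frame(state = s, mean_fd = mean(d, na.rm = TRUE), sd_fd = stats::sd(d, na.rm = TRUE))
    }))
    fd_anova <- do.call(rbind, lapply(seq_len(model$k), function(s) {
      d <- fd_tab[fd_tab$state == s & !is.na(fd_tab$fd), ]
      tryCatch(cbind(state = s, oneway_anova(d$fd, d$cell, name = sprintf("fd_state%d", s))),
               error = function(e) NULL)
    }))
  }
  list(centroid_similarity = centroid_similarity_matrix(model),
       frame_similarity = fs$per_session, frame_similarity_anova = fs_anova,
       state_fd = fd_summary, state_fd_anova = fd_anova)
}

write_pipeline_outputs <- function(result, config) {
  out <- config$out_dir
  wtsv <- function(x, f, rn = FALSE) utils::write.table(x, file.path(out, f), sep = "\t",
                                                        quote = FALSE, row.names = rn)
  if (!is.null(result$curve))
    wtsv(data.frame(k = result$curve$k_values, cvi = result$curve$cvi_scores,
                    silhouette = if (is.null(result$curve$silhouette_scores)) NA
                                 else result$curve$silhouette_scores), "k_selection_curve.tsv")
  wtsv(result$model$centroids, "centroids.tsv")
  wtsv(result$metrics, "metrics_long.tsv")
  wtsv(result$stats, "stats.tsv")
  wtsv(round(result$diagnostics$centroid_similarity, 6), "centroid_similarity.tsv", rn = TRUE)
  if (!is.null(result$diagnostics$frame_similarity_anova))
    wtsv(result$diagnostics$frame_similarity_anova, "frame_similarity_anova.tsv")
  if (!is.null(result$diagnostics$state_fd)) {
    wtsv(result$diagnostics$state_fd, "state_fd.tsv")
    wtsv(result$diagnostics$state_fd_anova, "state_fd_anova.tsv")
  }
  jsonlite::write_json(list(
    k = result$model$k, seed = result$model$seed,
    objective = result$model$objective,
    replicate_scores = result$model$replicate_scores,
    state_networks = result$model$state_networks,
    chosen_k = as.integer(result$chosen_k),
    ambiguous_elbow = isTRUE(attr(result$chosen_k, "ambiguous")),
    families = lapply(result$families, function(f) f[c("family", "m", "alpha", "threshold")])
  ), file.path(out, "model.json"), auto_unbox = TRUE, digits = NA)
  writeLines(report(result), file.path(out, "report.txt"))
  invisible(out)
}

#' Human-readable summary of a pipeline run
#'
#' Tabulates group means of the dynamics metrics, all test statistics with
#' their family thresholds (significant rows starred), and the spatial /
#' motion diagnostics.
#'
#' @param result the list returned by [run_full_pipeline()].
#' @return character vector of report lines.
#' @export
report <- function(result) {
  need_fields(result, c("model", "stats", "metric_sets"), "pipeline result")
  K <- result$model$k
  lines <- c(sprintf("CAP dynamics report: %d states", K),
             sprintf("state networks: %s", paste(result$model$state_networks, collapse = ", ")),
             "")
  cellof <- function(m) if (m$group == "HC") "HC" else paste(m$group, m$timepoint, sep = "_")
  cells <- vapply(result$metric_sets, cellof, "")
  for (cl in sort(unique(cells))) {
    sel <- result$metric_sets[cells == cl]
    ft <- rowMeans(vapply(sel, `[[`, numeric(K), "ft"))
    lines <- c(lines, sprintf("%s (n = %d sessions): mean FT  %s", cl, length(sel),
                              paste(sprintf("%.3f", ft), collapse = " ")))
  }
  lines <- c(lines, "", sprintf("%-38s %9s %7s %10s %9s %s",
                                "test", "stat", "df", "p", "alpha_adj", "sig"))
  for (i in seq_len(nrow(result$stats))) {
    s <- result$stats[i, ]
    lines <- c(lines, sprintf("%-38s %9.3f %7s %10.3g %9.4g %s",
                              s$name, s$statistic, s$df, s$p, s$alpha_adjusted,
                              if (isTRUE(s$significant)) "*" else ""))
  }
  lines
}
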