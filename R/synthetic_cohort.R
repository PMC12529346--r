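# Synthetic multi-subject cohort generator.
#
# Stands in for the restricted clinical imaging data: plants a known set of
# spatial brain states, Markov switching dynamics with group/treatment
# effects, motion traces, covariates and mood scores, so that every
# downstream stage (clustering, metrics, statistics) can be validated
# against ground truth.

canonical_state_networks <- c("Vis", "SomMot", "Default", "Limbic", "SalVentAttn", "Cont")
canonical_state_names <- c("VN/DAN", "SMN", "DMN", "vDMN", "SN", "CEN")

#' Construct planted spatial state patterns
#'
#' Each state is a whole-brain activation pattern (z-score scale) elevated
#' on one canonical network's parcels with small random texture elsewhere,
#' then standardized across parcels (mean 0, sd 1). The default six states
#' mirror a visual/dorsal-attention state (the first state also carries a
#' weaker dorsal-attention loading), somatomotor, default-mode, ventral
#' default-mode (limbic-weighted), salience, and central executive states,
#' so network labelling of fitted centroids recovers the intended name.
#'
#' @param n_states number of states; must not exceed the number of distinct
#'   cortical networks in `parcel_table`.
#' @param parcel_table parcel table from [build_parcel_table()].
#' @param seed integer seed (patterns are deterministic given it).
#' @param weight loading on the generating network before standardization.
#' @param texture sd of the background texture.
#' @return object of class `pattern_set`: list with `n_states`, `patterns`
#'   (n_states x n_parcels), `state_names`, `networks`.
#' @export
make_state_patterns <- function(n_states = 6, parcel_table = build_parcel_table(),
                                seed = 1, weight = 1.5, texture = 0.1) {
  validate_parcel_table(parcel_table)
  cortical_networks <- unique(parcel_table$network[parcel_table$source == "cortical"])
  if (n_states > length(cortical_networks))
    stop(sprintf("n_states = %d exceeds the %d distinct cortical networks available",
                 n_states, length(cortical_networks)))
  if (n_states == 6 && all(canonical_state_networks %in% cortical_networks)) {
    networks <- canonical_state_networks
    state_names <- canonical_state_names
  } else {
    networks <- cortical_networks[seq_len(n_states)]
    state_names <- networks
  }
  p <- nrow(parcel_table)
  pats <- with_seed(seed, {
    m <- matrix(stats::rnorm(n_states * p, sd = texture), n_states, p)
    for (s in seq_len(n_states)) {
      m[s, parcel_table$network == networks[s]] <- m[s, parcel_table$network == networks[s]] + weight
    }
    # the visual state of the canonical six also loads on dorsal attention
    if (identical(networks, canonical_state_networks))
      m[1, parcel_table$network == "DorsAttn"] <- m[1, parcel_table$network == "DorsAttn"] + 0.4 * weight
    m
  })
  pats <- t(scale(t(pats)))  # mean 0, sd 1 across parcels
  attr(pats, "scaled:center") <- NULL
  attr(pats, "scaled:scale") <- NULL
  cc <- stats::cor(t(pats))
  maxr <- max(abs(cc[upper.tri(cc)]), 0)
  if (n_states > 1 && maxr >= 0.8)
    stop(sprintf("pattern construction failed separation check: max |r| = %.3f", maxr))
  structure(list(n_states = n_states, patterns = pats,
                 state_names = state_names, networks = networks),
            class = "pattern_set")
}

#' Simulate one scanning session from planted states
#'
#' Each run draws a fresh Markov state chain from `markov`; frame t is the
#' active state's spatial pattern plus i.i.d. Gaussian parcel noise.
#' A framewise-displacement trace is attached (folded-normal draws,
#' independent of the state sequence; first frame of each run is 0).
#'
#' @param patterns a [make_state_patterns()] object.
#' @param markov a [markov_params()] object over the same number of states.
#' @param frames_per_run frames per run (>= 2).
#' @param n_runs number of runs in the session.
#' @param noise_sigma parcel noise sd (patterns are unit variance, so this
#'   is the noise-to-signal scale).
#' @param seed integer seed.
#' @param subject_id,group,timepoint identity stored on the session.
#' @param tr_seconds repetition time.
#' @param fd_mean,fd_sd folded-normal parameters of the FD trace (mm).
#' @param ar1 optional AR(1) coefficient for temporally correlated noise
#'   (default 0 = white noise).
#' @return list with `ts` (an [roi_ts()]) and `seq` (a [state_seq()] of the
#'   true labels).
#' @export
simulate_session <- function(patterns, markov, frames_per_run = 250, n_runs = 2,
                             noise_sigma = 1, seed = 1,
                             subject_id = "sim", group = "SIM", timepoint = "baseline",
                             tr_seconds = 0.8, fd_mean = 0.15, fd_sd = 0.17,
                             ar1 = 0) {
  stopifnot(inherits(patterns, "pattern_set"), inherits(markov, "markov_params"),
            frames_per_run >= 2, n_runs >= 1, noise_sigma >= 0, abs(ar1) < 1)
  if (nrow(markov$transition_matrix) != patterns$n_states)
    stop("markov dimension does not match number of patterns")
  p <- ncol(patterns$patterns)
  total <- frames_per_run * n_runs
  with_seed(seed, {
    labels <- unlist(lapply(seq_len(n_runs), function(r) sample_chain(markov, frames_per_run)))
    noise <- matrix(stats::rnorm(total * p, sd = noise_sigma), total, p)
    if (ar1 != 0) {
      # AR(1) within run, stationary marginal variance noise_sigma^2
      noise <- noise * sqrt(1 - ar1^2)
      for (r in seq_len(n_runs)) {
        off <- (r - 1) * frames_per_run
        noise[off + 1, ] <- noise[off + 1, ] / sqrt(1 - ar1^2)
        for (t in 2:frames_per_run)
          noise[off + t, ] <- ar1 * noise[off + t - 1, ] + noise[off + t, ]
      }
    }
    fd <- abs(stats::rnorm(total, fd_mean, fd_sd))
    boundaries <- as.integer(seq(1, total, by = frames_per_run))
    fd[boundaries] <- 0
    ts <- roi_ts(patterns$patterns[labels, , drop = FALSE] + noise,
                 subject_id = subject_id, group = group, timepoint = timepoint,
                 run_boundaries = boundaries, tr_seconds = tr_seconds,
                 fd_mm = fd, zscored = FALSE)
    list(ts = ts,
         seq = state_seq(labels, run_boundaries = boundaries, K = patterns$n_states,
                         subject_id = subject_id, group = group, timepoint = timepoint))
  })
}

#' Default group-level Markov dynamics
#'
#' Healthy controls switch uniformly between six states (self-transition
#' 0.75, stationary occupancy 1/6 each). The depressed-baseline chain tilts
#' flows toward the salience state and away from the central executive
#' state: planted stationary occupancy is +0.05 for SN and -0.05 for CEN
#' relative to controls, the collapsed-sequence transition probability
#' SN -> VN is raised (0.277 vs 0.2) and SN -> CEN lowered (0.149 vs 0.2).
#' The post-treatment chain moves 70% of the way back toward the control
#' chain, so treatment effects trend toward control patterns without fully
#' reaching them.
#'
#' @param recovery fraction of the way the post-treatment chain moves from
#'   the depressed-baseline chain toward the control chain (default 0.7).
#' @return named list of [markov_params()]: `TRD_baseline`, `TRD_post`, `HC`.
#' @export
default_group_markov <- function(recovery = 0.7) {
  K <- 6
  P_hc <- matrix(0.05, K, K); diag(P_hc) <- 0.75
  P_tb <- matrix(0, K, K)
  for (i in 1:4) {
    P_tb[i, ] <- 0.05; P_tb[i, 5] <- 0.065; P_tb[i, 6] <- 0.035; P_tb[i, i] <- 0.75
  }
  P_tb[5, ] <- c(0.065, 0.045, 0.045, 0.045, 0.765, 0.035)
  P_tb[6, ] <- c(0.05, 0.05, 0.05, 0.05, 0.065, 0.735)
  P_tp <- recovery * P_hc + (1 - recovery) * P_tb
  list(TRD_baseline = markov_params(P_tb),
       TRD_post = markov_params(P_tp),
       HC = markov_params(P_hc))
}

#' Specification of a synthetic cohort
#'
#' Defaults emulate the study design this generator stands in for:
#' 58 depressed subjects (TRD) scanned at baseline and after treatment,
#' 56 healthy controls (HC) at baseline of whom 18 are rescanned ~2 weeks
#' later with unchanged dynamics, two runs of 0.8-s TR data per session,
#' 454 parcels, and a planted correlation of -0.402 between the change in
#' salience-state occupancy and percent change in reflective rumination.
#' Ages are drawn at the reported group means (TRD 40.7 +/- 11.3,
#' HC 32.61 +/- 12); 250 frames per run is a desk-scale stand-in for the
#' full acquisition so a complete pipeline run takes minutes.
#'
#' @param n_trd,n_hc,n_hc_longitudinal group sizes.
#' @param parcel_table parcel table (drives n_rois).
#' @param n_runs,frames_per_run,tr_seconds acquisition geometry.
#' @param noise_sigma parcel noise sd (patterns are unit variance).
#' @param group_markov named list of [markov_params()] for `TRD_baseline`,
#'   `TRD_post`, `HC`.
#' @param mood_coupling_r target correlation between change in
#'   salience-state occupancy and percent-change reflection.
#' @param fd_mean,fd_sd framewise-displacement distribution (mm).
#' @param markov_concentration Dirichlet concentration for per-subject
#'   transition-row jitter (larger = less between-subject heterogeneity).
#' @param ar1 AR(1) noise coefficient (default 0, white noise).
#' @param seed master seed; all session seeds derive from it.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_trd = 58, n_hc = 56, n_hc_longitudinal = 18,
                        parcel_table = build_parcel_table(),
                        n_runs = 2, frames_per_run = 250, tr_seconds = 0.8,
                        noise_sigma = 1, group_markov = default_group_markov(),
                        mood_coupling_r = -0.402, fd_mean = 0.15, fd_sd = 0.17,
                        markov_concentration = 400, ar1 = 0, seed = 1) {
  stopifnot(n_trd > 0, n_hc > 0, n_hc_longitudinal >= 0, n_hc_longitudinal <= n_hc,
            frames_per_run >= 2, n_runs >= 1, noise_sigma >= 0,
            abs(mood_coupling_r) <= 1, markov_concentration > 0)
  need_fields(group_markov, c("TRD_baseline", "TRD_post", "HC"), "group_markov")
  structure(as.list(environment()), class = "cohort_spec")
}

# Per-subject transition jitter: each row drawn Dirichlet(c * row).
jitter_markov <- function(markov, concentration) {
  P <- markov$transition_matrix
  Q <- t(apply(P, 1, function(row) {
    g <- stats::rgamma(length(row), shape = concentration * row)
    if (sum(g) == 0) row else g / sum(g)
  }))
  markov_params(Q / rowSums(Q))
}

#' Plant mood scores coupled to salience-state occupancy change
#'
#' Percent change in reflective rumination, defined as
#' (post - baseline) / post, is generated by regressing on each subject's
#' realized change in salience-state occupancy plus a Gaussian residual
#' sized so the sample correlation equals `r` in expectation; recovering it
#' downstream is therefore a genuine estimation problem. Baseline scores are
#' drawn at the reported group means; post scores are back-solved from the
#' planted percent change. HDRS and brooding improve with treatment
#' (uncoupled to brain change); reappraisal does not change.
#'
#' @param delta_ft_sn per-subject realized change (post - baseline) in
#'   salience-state occupancy.
#' @param r target correlation with percent-change reflection.
#' @param seed integer seed.
#' @return data.frame with baseline/post HDRS and RRS subscale scores.
#' @export
plant_mood_scores <- function(delta_ft_sn, r = -0.402, seed = 1) {
  n <- length(delta_ft_sn)
  with_seed(seed, {
    mu_c <- -0.236   # mean percent change matching reported reflection means
    sigma_c <- 0.25
    d <- delta_ft_sn - mean(delta_ft_sn)
    sd_d <- if (n >= 2) stats::sd(delta_ft_sn) else 0
    beta <- if (sd_d > 0) r * sigma_c / sd_d else 0
    eps <- stats::rnorm(n, 0, sigma_c * sqrt(max(0, 1 - r^2)))
    pct_reflection <- pmin(mu_c + beta * d + eps, 0.8)
    reflection_base <- pmax(stats::rnorm(n, 11.21, 3.8), 2)
    reflection_post <- reflection_base / (1 - pct_reflection)
    hdrs_base <- pmax(stats::rnorm(n, 19, 4.76), 10)
    hdrs_post <- pmax(8.4 + 0.5 * (hdrs_base - 19) * (4.6 / 4.76) + stats::rnorm(n, 0, 4), 0)
    brood_base <- pmax(stats::rnorm(n, 13.4, 3.71), 2)
    brood_post <- pmax(9.5 + 0.6 * (brood_base - 13.4) * (3.13 / 3.71) + stats::rnorm(n, 0, 2.4), 0)
    reapp_base <- pmax(stats::rnorm(n, 13.9, 4.24), 2)
    reapp_post <- pmax(reapp_base + stats::rnorm(n, -0.5, 3), 0)
    data.frame(hdrs_baseline = hdrs_base, hdrs_post = hdrs_post,
               rrs_brooding_baseline = brood_base, rrs_brooding_post = brood_post,
               rrs_reflection_baseline = reflection_base, rrs_reflection_post = reflection_post,
               rrs_reappraisal_baseline = reapp_base, rrs_reappraisal_post = reapp_post)
  })
}

#' Simulate a full synthetic cohort
#'
#' Generates every session implied by the design: baseline + post sessions
#' for each depressed subject, one baseline session per control, and a
#' second (unchanged-dynamics) session for the longitudinal control subset.
#' Each subject-session gets its own Dirichlet-jittered transition matrix
#' around the group chain. Mood scores are planted with
#' [plant_mood_scores()] against the realized (ground-truth) change in
#' salience-state occupancy.
#'
#' @param spec a [cohort_spec()].
#' @param generate_data if FALSE, skip the parcel-level data (sessions list
#'   empty) and return only manifest + ground truth; used for fast
#'   sequence-level property checks.
#' @return list with `manifest` (one row per subject/timepoint/run),
#'   `sessions` (named list of [roi_ts()], one per subject-session, keyed
#'   `subject_timepoint`), `truth` (patterns, true sequences, per-session
#'   Markov parameters, planted mood table and occupancy changes).
#' @export
simulate_cohort <- function(spec = cohort_spec(), generate_data = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  pt <- spec$parcel_table
  patterns <- make_state_patterns(6, pt, seed = derive_seed(spec$seed, 1))
  K <- patterns$n_states

  subj <- data.frame(
    subject_id = c(sprintf("TRD%03d", seq_len(spec$n_trd)),
                   sprintf("HC%03d", seq_len(spec$n_hc))),
    group = rep(c("TRD", "HC"), c(spec$n_trd, spec$n_hc)),
    stringsAsFactors = FALSE
  )
  subj <- within(subj, {
    longitudinal <- group == "TRD" | seq_len(nrow(subj)) <= spec$n_trd + spec$n_hc_longitudinal
  })
  demo <- with_seed(derive_seed(spec$seed, 2), {
    age <- ifelse(subj$group == "TRD",
                  stats::rnorm(nrow(subj), 40.7, 11.3),
                  stats::rnorm(nrow(subj), 32.61, 12))
    age <- pmin(pmax(age, 18), 75)
    sex <- ifelse(stats::runif(nrow(subj)) < ifelse(subj$group == "TRD", 0.483, 0.564), "F", "M")
    data.frame(age = age, sex = sex, stringsAsFactors = FALSE)
  })
  subj <- cbind(subj, demo)

  # enumerate sessions: (subject, timepoint)
  ses <- rbind(
    data.frame(subject_id = subj$subject_id, group = subj$group, timepoint = "baseline",
               stringsAsFactors = FALSE),
    data.frame(subject_id = subj$subject_id[subj$longitudinal],
               group = subj$group[subj$longitudinal], timepoint = "post",
               stringsAsFactors = FALSE)
  )
  ses$session_id <- paste(ses$subject_id, ses$timepoint, sep = "_")

  sessions <- list()
  truth_seq <- list()
  truth_markov <- list()
  mean_fd <- numeric(nrow(ses))
  for (i in seq_len(nrow(ses))) {
    grp_key <- if (ses$group[i] == "HC") "HC"
               else if (ses$timepoint[i] == "baseline") "TRD_baseline" else "TRD_post"
    sseed <- derive_seed(spec$seed, 100 + i)
    mk <- with_seed(derive_seed(sseed, 1),
                    jitter_markov(spec$group_markov[[grp_key]], spec$markov_concentration))
    sim <- if (generate_data) {
      simulate_session(patterns, mk, spec$frames_per_run, spec$n_runs,
                       noise_sigma = spec$noise_sigma, seed = derive_seed(sseed, 2),
                       subject_id = ses$subject_id[i], group = ses$group[i],
                       timepoint = ses$timepoint[i], tr_seconds = spec$tr_seconds,
                       fd_mean = spec$fd_mean, fd_sd = spec$fd_sd, ar1 = spec$ar1)
    } else {
      # sequence + FD only; parcel data skipped
      total <- spec$frames_per_run * spec$n_runs
      with_seed(derive_seed(sseed, 2), {
        labels <- unlist(lapply(seq_len(spec$n_runs),
                                function(r) sample_chain(mk, spec$frames_per_run)))
        fd <- abs(stats::rnorm(total, spec$fd_mean, spec$fd_sd))
        boundaries <- as.integer(seq(1, total, by = spec$frames_per_run))
        fd[boundaries] <- 0
        list(ts = NULL, fd = fd,
             seq = state_seq(labels, run_boundaries = boundaries, K = K,
                             subject_id = ses$subject_id[i], group = ses$group[i],
                             timepoint = ses$timepoint[i]))
      })
    }
    truth_seq[[ses$session_id[i]]] <- sim$seq
    truth_markov[[ses$session_id[i]]] <- mk
    if (generate_data) {
      sessions[[ses$session_id[i]]] <- sim$ts
      mean_fd[i] <- mean(sim$ts$fd_mm)
    } else {
      mean_fd[i] <- mean(sim$fd)
    }
  }

  # realized salience-state occupancy change for depressed subjects
  trd_ids <- subj$subject_id[subj$group == "TRD"]
  sn <- which(patterns$state_names == "SN")
  ft_of <- function(sid, tp) fraction_time(truth_seq[[paste(sid, tp, sep = "_")]], K)[sn]
  delta_ft_sn <- vapply(trd_ids, function(s) ft_of(s, "post") - ft_of(s, "baseline"), 0)
  mood <- plant_mood_scores(delta_ft_sn, r = spec$mood_coupling_r,
                            seed = derive_seed(spec$seed, 3))
  mood <- cbind(data.frame(subject_id = trd_ids, stringsAsFactors = FALSE), mood)

  # manifest: one row per run; paths filled in by write_cohort()
  run_rows <- ses[rep(seq_len(nrow(ses)), each = spec$n_runs), ]
  run_rows$run_index <- rep(seq_len(spec$n_runs), nrow(ses))
  run_rows$path <- NA_character_
  run_rows$mean_fd <- rep(mean_fd, each = spec$n_runs)
  m <- merge(run_rows, subj[, c("subject_id", "age", "sex")], by = "subject_id", sort = FALSE)
  sc_cols <- c("hdrs", "rrs_brooding", "rrs_reflection", "rrs_reappraisal")
  for (col in sc_cols) m[[col]] <- NA_real_
  for (j in seq_len(nrow(mood))) {
    for (col in sc_cols) {
      base_v <- mood[[paste0(col, "_baseline")]][j]
      post_v <- mood[[paste0(col, "_post")]][j]
      sel <- m$subject_id == mood$subject_id[j]
      m[[col]][sel & m$timepoint == "baseline"] <- base_v
      m[[col]][sel & m$timepoint == "post"] <- post_v
    }
  }
  m <- m[order(match(m$subject_id, subj$subject_id), m$timepoint, m$run_index), ]
  rownames(m) <- NULL
  manifest <- m[, manifest_columns[manifest_columns %in% names(m)]]
  manifest <- cbind(manifest, m[, "session_id", drop = FALSE])

  list(manifest = manifest,
       sessions = sessions,
       truth = list(patterns = patterns,
                    sequences = truth_seq,
                    markov = truth_markov,
                    mood = mood,
                    delta_ft_sn = delta_ft_sn,
                    sn_state = sn))
}

#' Write a simulated cohort to disk
#'
#' Session matrices as per-run TSV, manifest as TSV, ground truth as JSON
#' (sequences as integer arrays) plus a patterns TSV.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return the manifest with `path` filled in, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "sessions"), recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  for (sid in names(cohort$sessions)) {
    ts <- cohort$sessions[[sid]]
    runs <- run_index_list(nrow(ts$data), ts$run_boundaries)
    for (r in seq_along(runs)) {
      path <- file.path(dir, "sessions", sprintf("%s_run%d.tsv", sid, r))
      write_session_matrix(ts$data[runs[[r]], , drop = FALSE], path)
      man$path[man$session_id == sid & man$run_index == r] <- path
    }
  }
  write_manifest(man, file.path(dir, "manifest.tsv"))
  utils::write.table(cohort$truth$patterns$patterns, file.path(dir, "true_patterns.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(lapply(cohort$truth$sequences, function(s) s$labels),
                       file.path(dir, "true_sequences.json"))
  invisible(man)
}
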