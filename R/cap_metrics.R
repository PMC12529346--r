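# Per-session dynamics metrics computed from state sequences.

#' Construct a per-session state sequence
#'
#' @param labels integer state labels, one per frame.
#' @param run_boundaries 1-based first-frame index of each run.
#' @param K number of states (default: max label).
#' @param subject_id,group,timepoint session identity.
#' @return object of class `state_seq`.
#' @export
state_seq <- function(labels, run_boundaries = 1L, K = max(labels),
                      subject_id = NA_character_, group = NA_character_,
                      timepoint = NA_character_) {
  labels <- as.integer(labels)
  if (length(labels) == 0) stop("empty label sequence")
  if (anyNA(labels) || any(labels < 1)) stop("labels must be positive integers")
  run_boundaries <- as.integer(run_boundaries)
  if (run_boundaries[1] != 1L || is.unsorted(run_boundaries, strictly = TRUE) ||
      any(run_boundaries > length(labels)))
    stop("invalid run boundaries")
  structure(list(labels = labels, run_boundaries = run_boundaries, K = as.integer(K),
                 subject_id = subject_id, group = group, timepoint = timepoint),
            class = "state_seq")
}

.check_K <- function(seq, K) {
  if (any(seq$labels > K)) stop(sprintf("label %d outside 1..%d", max(seq$labels), K))
  invisible(K)
}

.runs_of <- function(seq) {
  idx <- run_index_list(length(seq$labels), seq$run_boundaries)
  lapply(idx, function(i) seq$labels[i])
}

#' Fraction of time per state
#'
#' The proportion of a session's frames assigned to each state relative to
#' all other states (a.k.a. fractional occupancy). Unvisited states get 0.
#'
#' @param seq a [state_seq()].
#' @param K number of states.
#' @return length-K vector summing to 1.
#' @export
#' @examples
#' fraction_time(state_seq(c(1, 1, 2, 3, 3, 3)), K = 3)  # 1/3, 1/6, 1/2
fraction_time <- function(seq, K = seq$K) {
  .check_K(seq, K)
  tabulate(seq$labels, K) / length(seq$labels)
}

#' Mean dwell time per state, in TR units
#'
#' Average length of maximal uninterrupted runs of each state. Dwells never
#' span a run boundary (runs are separate acquisitions). Unvisited states
#' are NA, not 0, so they can be dropped pairwise in statistics rather than
#' biasing group means.
#'
#' @inheritParams fraction_time
#' @return length-K vector (TR units); NA for unvisited states.
#' @export
mean_dwell_time <- function(seq, K = seq$K) {
  .check_K(seq, K)
  tot <- numeric(K)
  cnt <- integer(K)
  for (lab in .runs_of(seq)) {
    r <- rle(lab)
    tot <- tot + vapply(seq_len(K), function(s) sum(r$lengths[r$values == s]), 0)
    cnt <- cnt + tabulate(r$values, K)
  }
  out <- tot / cnt
  out[cnt == 0] <- NA_real_
  out
}

#' Collapse repeated states within each run
#'
#' Merges consecutive duplicate labels (within run boundaries only), the
#' preprocessing applied before estimating transition probabilities to
#' control for the autocorrelation induced by state persistence. Idempotent.
#'
#' @param seq a [state_seq()].
#' @return a collapsed `state_seq` with updated run boundaries.
#' @export
collapse_runs <- function(seq) {
  stopifnot(inherits(seq, "state_seq"))
  pieces <- lapply(.runs_of(seq), function(lab) rle(lab)$values)
  lens <- lengths(pieces)
  state_seq(unlist(pieces),
            run_boundaries = cumsum(c(1L, utils::head(lens, -1))),
            K = seq$K, subject_id = seq$subject_id, group = seq$group,
            timepoint = seq$timepoint)
}

#' Transition probability matrix
#'
#' Estimated on the duplicate-collapsed sequence, never counting a
#' transition across a run boundary. In the default (`"markov"`) mode the
#' denominator for row A is the number of occurrences of A that have a
#' successor within their run, so every defined row is stochastic (sums
#' to 1); rows of states with no outgoing transition are NA. The
#' `"literal"` mode divides by all occurrences of A instead (the plain
#' "transitions over occurrences" reading), in which case rows need not sum
#' to 1. The diagonal is structurally 0 after collapsing.
#'
#' @param seq a [state_seq()] (collapsed internally; passing an already
#'   collapsed sequence gives the same result).
#' @param K number of states.
#' @param mode "markov" (row-stochastic, default) or "literal".
#' @return K x K matrix of transition probabilities.
#' @export
transition_probability <- function(seq, K = seq$K, mode = c("markov", "literal")) {
  mode <- match.arg(mode)
  .check_K(seq, K)
  cseq <- collapse_runs(seq)
  counts <- matrix(0L, K, K)
  n_from <- integer(K)      # occurrences with a successor
  n_occ <- integer(K)       # all occurrences
  for (lab in .runs_of(cseq)) {
    n_occ <- n_occ + tabulate(lab, K)
    if (length(lab) >= 2) {
      from <- lab[-length(lab)]
      to <- lab[-1]
      for (i in seq_along(from)) counts[from[i], to[i]] <- counts[from[i], to[i]] + 1L
      n_from <- n_from + tabulate(from, K)
    }
  }
  denom <- if (mode == "markov") n_from else n_occ
  tp <- counts / denom
  tp[denom == 0, ] <- NA_real_
  tp
}

#' Mean framewise displacement per state
#'
#' Average motion over the frames assigned to each state; used to check
#' that states are not clustered on the basis of head motion.
#'
#' @param seq a [state_seq()].
#' @param ts the matching [roi_ts()] (its `fd_mm` trace is used), or a bare
#'   numeric FD vector.
#' @param K number of states.
#' @return length-K vector; NA for unvisited states.
#' @export
per_state_fd <- function(seq, ts, K = seq$K) {
  .check_K(seq, K)
  fd <- if (inherits(ts, "roi_ts")) ts$fd_mm else as.numeric(ts)
  if (length(fd) != length(seq$labels)) stop("FD trace and label sequence differ in length")
  out <- vapply(seq_len(K), function(s) mean(fd[seq$labels == s]), 0)
  out[tabulate(seq$labels, K) == 0] <- NA_real_
  out
}

#' Static functional connectivity matrix
#'
#' Pearson correlation between all pairs of parcel time courses over the
#' whole session: the conventional static-FC summary the dynamic metrics
#' are contrasted with.
#'
#' @param ts an [roi_ts()] with >= 3 frames.
#' @return symmetric n_parcels x n_parcels correlation matrix (unit
#'   diagonal); rows/columns of zero-variance parcels are NA, with a warning.
#' @export
static_fc <- function(ts) {
  stopifnot(inherits(ts, "roi_ts"))
  if (nrow(ts$data) < 3) stop("static FC needs at least 3 frames")
  sds <- apply(ts$data, 2, stats::sd)
  if (any(sds < 1e-12)) warning(sprintf("%d zero-variance parcel(s): NA rows in FC", sum(sds < 1e-12)))
  suppressWarnings(stats::cor(ts$data))
}

#' Assign frames of a session to CAP states
#'
#' In-sample sessions (present in the model's index map) take their labels
#' from the clustering itself; otherwise each frame goes to the centroid
#' with smallest correlation distance, ties to the lowest state id.
#'
#' @param ts a z-scored [roi_ts()].
#' @param model a `cap_model` from [kmeans_caps()].
#' @param pool optional `frame_pool` the model was fitted on; if supplied
#'   and the session is found in its index map, labels are looked up.
#' @return a [state_seq()].
#' @export
assign_states <- function(ts, model, pool = NULL) {
  stopifnot(inherits(ts, "roi_ts"), inherits(model, "cap_model"))
  if (!ts$zscored) stop("session must be z-scored before state assignment")
  if (ncol(ts$data) != ncol(model$centroids)) stop("parcel space does not match model")
  labels <- NULL
  if (!is.null(pool)) {
    sel <- pool$index_map$subject_id == ts$subject_id &
      pool$index_map$timepoint == ts$timepoint
    if (sum(sel) == nrow(ts$data)) labels <- model$labels[sel]
  }
  if (is.null(labels)) {
    S <- tcrossprod(standardize_rows(ts$data), standardize_rows(model$centroids, "centroid"))
    labels <- max.col(S, ties.method = "first")
  }
  state_seq(labels, run_boundaries = ts$run_boundaries, K = model$k,
            subject_id = ts$subject_id, group = ts$group, timepoint = ts$timepoint)
}

#' All dynamics metrics for one session
#'
#' @param seq a [state_seq()].
#' @param ts optional matching [roi_ts()] for the per-state FD.
#' @param K number of states.
#' @param tp_mode passed to [transition_probability()].
#' @return list of class `cap_metric_set`: `ft`, `mdt_tr`, `tp`,
#'   `state_counts`, `per_state_fd_mm`.
#' @export
cap_metrics <- function(seq, ts = NULL, K = seq$K, tp_mode = "markov") {
  structure(list(
    subject_id = seq$subject_id, group = seq$group, timepoint = seq$timepoint,
    ft = fraction_time(seq, K),
    mdt_tr = mean_dwell_time(seq, K),
    tp = transition_probability(seq, K, mode = tp_mode),
    state_counts = tabulate(seq$labels, K),
    per_state_fd_mm = if (is.null(ts)) rep(NA_real_, K) else per_state_fd(seq, ts, K)
  ), class = "cap_metric_set")
}

#' Long-format table of metrics across sessions
#'
#' @param metric_sets list of `cap_metric_set`.
#' @return data.frame with columns subject_id, group, timepoint, metric
#'   (FT/MDT/TP/FD_state), state_from, state_to (NA unless TP), value.
#' @export
metrics_long <- function(metric_sets) {
  rows <- lapply(metric_sets, function(m) {
    K <- length(m$ft)
    base <- data.frame(subject_id = m$subject_id, group = m$group, timepoint = m$timepoint,
                       stringsAsFactors = FALSE)
    tp_idx <- which(!is.na(m$tp) | is.na(m$tp), arr.ind = TRUE)  # all cells
    rbind(
      cbind(base, metric = "FT", state_from = seq_len(K), state_to = NA_integer_, value = m$ft),
      cbind(base, metric = "MDT", state_from = seq_len(K), state_to = NA_integer_, value = m$mdt_tr),
      cbind(base, metric = "FD_state", state_from = seq_len(K), state_to = NA_integer_,
            value = m$per_state_fd_mm),
      cbind(base, metric = "TP", state_from = tp_idx[, 1], state_to = tp_idx[, 2],
            value = m$tp[tp_idx])
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
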