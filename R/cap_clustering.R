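# Frame-wise clustering of pooled BOLD frames into co-activation patterns.
#
# Distance is correlation distance d(x, y) = 1 - cor(x, y). Internally each
# frame is standardized to zero mean / unit L2 norm across parcels, which
# makes 1 - cor a monotone function of Euclidean distance, so Lloyd
# iteration with mean-then-restandardize centroid updates (spherical
# k-means) monotonically decreases the correlation-distance objective.

#' Pool frames across sessions
#'
#' Stacks all sessions' frames (in the order given) into one matrix for
#' joint clustering, with an index map recording which (subject, timepoint,
#' run, frame) each pooled row came from, so pooled labels can be split
#' back into per-session sequences.
#'
#' @param sessions list of z-scored [roi_ts()] with identical parcel order.
#' @return object of class `frame_pool`: `frames` (total x parcels),
#'   `index_map` (data.frame).
#' @export
concat_frames <- function(sessions) {
  if (length(sessions) == 0) stop("no sessions to pool")
  p <- ncol(sessions[[1]]$data)
  maps <- vector("list", length(sessions))
  for (i in seq_along(sessions)) {
    ts <- sessions[[i]]
    stopifnot(inherits(ts, "roi_ts"))
    if (!ts$zscored) stop(sprintf("session %s is not z-scored", ts$subject_id))
    if (ncol(ts$data) != p)
      stop(sprintf("mixed parcel counts: %d vs %d", ncol(ts$data), p))
    runs <- run_index_list(nrow(ts$data), ts$run_boundaries)
    maps[[i]] <- data.frame(
      subject_id = ts$subject_id, group = ts$group, timepoint = ts$timepoint,
      run_index = rep(seq_along(runs), lengths(runs)),
      frame_index = unlist(lapply(runs, seq_along)),
      stringsAsFactors = FALSE
    )
  }
  structure(list(frames = do.call(rbind, lapply(sessions, `[[`, "data")),
                 index_map = do.call(rbind, maps)),
            class = "frame_pool")
}

# One Lloyd fit from given initial centroid rows (standardized frames).
.lloyd_fit <- function(Xs, init_idx, k, max_iter, tol = 1e-10) {
  n <- nrow(Xs)
  C <- Xs[init_idx, , drop = FALSE]
  obj_prev <- Inf
  lab <- integer(n)
  reseeded <- 0L
  for (it in seq_len(max_iter)) {
    S <- tcrossprod(Xs, C)                      # frame x centroid correlations
    lab <- max.col(S, ties.method = "first")
    own <- S[cbind(seq_len(n), lab)]
    sizes <- tabulate(lab, k)
    while (any(sizes == 0)) {                   # re-seed empty cluster from farthest frame
      far <- which.min(own)
      e <- which(sizes == 0)[1]
      lab[far] <- e
      own[far] <- 1
      sizes <- tabulate(lab, k)
      reseeded <- reseeded + 1L
    }
    obj <- sum(1 - own)
    M <- rowsum(Xs, lab) / sizes
    C <- standardize_rows(M, "centroid")
    if (obj_prev - obj < tol && it > 1) break
    obj_prev <- obj
  }
  list(labels = lab, objective = obj, iterations = it, reseeded = reseeded)
}

# k-means++ style seeding under correlation distance.
.seed_kmeanspp <- function(Xs, k) {
  n <- nrow(Xs)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  dmin <- 1 - as.numeric(tcrossprod(Xs, Xs[idx[1], , drop = FALSE]))
  for (j in seq_len(k - 1)) {
    w <- pmax(dmin, 0)
    idx[j + 1] <- if (sum(w) > 0) sample.int(n, 1, prob = w) else sample.int(n, 1)
    d_new <- 1 - as.numeric(tcrossprod(Xs, Xs[idx[j + 1], , drop = FALSE]))
    dmin <- pmin(dmin, d_new)
  }
  idx
}

#' k-means clustering of pooled frames under correlation distance
#'
#' Lloyd-style iteration with distance 1 - cor(frame, centroid). The
#' algorithm is restarted `n_replicates` times from k-means++ seedings and
#' the replicate with the lowest total within-cluster correlation distance
#' is kept. Centroids are updated as the arithmetic mean of member frames;
#' an empty cluster is re-seeded from the frame farthest from its centroid.
#' Deterministic given `seed`.
#'
#' @param pool a [concat_frames()] pool (or bare numeric matrix of frames).
#' @param k number of clusters (>= 2).
#' @param n_replicates random restarts (default 100).
#' @param max_iter Lloyd iteration cap per replicate (default 1000).
#' @param seed integer seed; replicate seeds derive from it.
#' @return object of class `cap_model`: `k`, `centroids` (k x parcels, mean
#'   of member frames in z-score units), `labels`, `objective`,
#'   `replicate_scores`, `seed`, `distance = "correlation"`.
#' @export
kmeans_caps <- function(pool, k, n_replicates = 100, max_iter = 1000, seed = 1) {
  X <- if (inherits(pool, "frame_pool")) pool$frames else as.matrix(pool)
  n <- nrow(X)
  stopifnot(k >= 2, n > k, n_replicates >= 1, max_iter >= 1)
  Xs <- standardize_rows(X)
  best <- NULL
  scores <- numeric(n_replicates)
  for (rep_i in seq_len(n_replicates)) {
    fit <- with_seed(derive_seed(seed, rep_i), {
      .lloyd_fit(Xs, .seed_kmeanspp(Xs, k), k, max_iter)
    })
    scores[rep_i] <- fit$objective
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  centroids <- rowsum(X, best$labels) / tabulate(best$labels, k)
  # recompute the objective against the returned centroids so it is exactly
  # the sum over frames of correlation distance to the own centroid
  S <- tcrossprod(Xs, standardize_rows(centroids, "centroid"))
  objective <- sum(1 - S[cbind(seq_len(n), best$labels)])
  structure(list(k = as.integer(k), centroids = centroids, labels = best$labels,
                 objective = objective, replicate_scores = scores,
                 iterations = best$iterations, seed = seed,
                 distance = "correlation"),
            class = "cap_model")
}

#' @export
print.cap_model <- function(x, ...) {
  cat(sprintf("<cap_model> k = %d, %d frames, objective = %.4f (best of %d replicates)\n",
              x$k, length(x$labels), x$objective, length(x$replicate_scores)))
  invisible(x)
}

# correlations of every pooled frame with every centroid
.frame_centroid_cor <- function(pool, model) {
  X <- if (inherits(pool, "frame_pool")) pool$frames else as.matrix(pool)
  tcrossprod(standardize_rows(X), standardize_rows(model$centroids, "centroid"))
}

#' Cluster validity index
#'
#' Ratio of within-cluster to between-cluster distances: the mean
#' correlation distance from each frame to its own centroid, divided by the
#' mean distance from each frame to the centroids of all other clusters.
#' Lower is better. Near-duplicate centroids (pairwise r > 0.999) make the
#' between term degenerate; the returned value then carries attribute
#' `degenerate = TRUE`.
#'
#' @param pool the pool the model was fitted on.
#' @param model a `cap_model` with k >= 2.
#' @return scalar CVI.
#' @export
cluster_validity_index <- function(pool, model) {
  if (model$k < 2) stop("CVI undefined for k = 1 (no between-cluster term)")
  S <- .frame_centroid_cor(pool, model)
  n <- nrow(S)
  own <- S[cbind(seq_len(n), model$labels)]
  within <- mean(1 - own)
  between <- mean((rowSums(1 - S) - (1 - own)) / (model$k - 1))
  cvi <- within / between
  cc <- centroid_similarity_matrix(model)
  if (any(cc[upper.tri(cc)] > 0.999)) attr(cvi, "degenerate") <- TRUE
  cvi
}

#' Scan a range of cluster numbers
#'
#' Runs [kmeans_caps()] for each k and records the cluster validity index
#' (optionally per-cluster silhouettes). Per-k seeds derive from the base
#' seed, so the curve is reproducible.
#'
#' @param pool frame pool.
#' @param k_min,k_max inclusive scan range.
#' @param n_replicates restarts per k (scans use fewer than a final fit;
#'   default 10).
#' @param max_iter Lloyd cap per replicate.
#' @param seed base seed.
#' @param silhouette also compute mean silhouette per k (costly; frames are
#'   subsampled via `silhouette_max_frames`).
#' @param silhouette_max_frames subsample cap for silhouette computation.
#' @return object of class `k_selection_curve`: `k_values`, `cvi_scores`,
#'   optional `silhouette_scores`, `models` (list of fitted models).
#' @export
scan_k <- function(pool, k_min = 2, k_max = 15, n_replicates = 10, max_iter = 100,
                   seed = 1, silhouette = FALSE, silhouette_max_frames = 2000) {
  n <- nrow(if (inherits(pool, "frame_pool")) pool$frames else pool)
  stopifnot(k_min >= 2, k_max > k_min, k_max < n)
  ks <- seq.int(k_min, k_max)
  models <- vector("list", length(ks))
  cvi <- numeric(length(ks))
  sil <- if (silhouette) numeric(length(ks)) else NULL
  for (i in seq_along(ks)) {
    models[[i]] <- tryCatch(
      kmeans_caps(pool, ks[i], n_replicates = n_replicates, max_iter = max_iter,
                  seed = derive_seed(seed, ks[i])),
      error = function(e) stop(sprintf("k = %d: %s", ks[i], conditionMessage(e)))
    )
    cvi[i] <- as.numeric(cluster_validity_index(pool, models[[i]]))
    if (silhouette)
      sil[i] <- mean(silhouette_by_cluster(pool, models[[i]],
                                           max_frames = silhouette_max_frames,
                                           seed = derive_seed(seed, 10000 + ks[i])),
                     na.rm = TRUE)
  }
  structure(list(k_values = ks, cvi_scores = cvi, silhouette_scores = sil,
                 models = models, seed = seed),
            class = "k_selection_curve")
}

#' Select the cluster number at the elbow of the validity curve
#'
#' Fits every two-segment piecewise-linear model with the breakpoint at
#' each interior k (each segment by ordinary least squares, sharing the
#' breakpoint k), and picks the breakpoint minimizing total residual sum of
#' squares; ties break toward the smaller k. If the best two-segment fit
#' improves on a single straight line by less than 1% RSS the curve is
#' effectively straight: the smallest k is returned with an
#' "ambiguous elbow" flag.
#'
#' @param curve a `k_selection_curve` (or list with `k_values`,
#'   `cvi_scores`) covering at least 4 k values.
#' @return the chosen k (integer) with attributes `ambiguous` (logical),
#'   `rss` (per-breakpoint total RSS), `breakpoints` (candidate ks).
#' @export
select_k_elbow <- function(curve) {
  k <- curve$k_values
  y <- curve$cvi_scores
  if (length(k) < 4) stop("elbow fit needs at least 4 k values")
  rss_line <- sum(stats::lm.fit(cbind(1, k), y)$residuals^2)
  cand <- k[c(-1, -length(k))]
  rss <- vapply(cand, function(b) {
    left <- k <= b
    sum(stats::lm.fit(cbind(1, k[left]), y[left])$residuals^2) +
      sum(stats::lm.fit(cbind(1, k[!left | k == b]), y[!left | k == b])$residuals^2)
  }, 0)
  best <- which.min(rss)  # first minimum = smaller k on ties
  # a perfectly straight curve (rss ~ 0 at machine precision) has no elbow
  flat <- rss_line <= 1e-12 * sum((y - mean(y))^2)
  improvement <- if (rss_line > 0) 1 - rss[best] / rss_line else 0
  ambiguous <- flat || improvement < 0.01
  out <- if (ambiguous) k[1] else cand[best]
  structure(as.integer(out), ambiguous = ambiguous, rss = rss, breakpoints = cand)
}

#' Per-cluster mean silhouette under correlation distance
#'
#' Standard silhouette s(i) = (b - a) / max(a, b) with a(i) the mean
#' distance to the other members of i's cluster and b(i) the smallest mean
#' distance to another cluster; members of singleton clusters score 0 by
#' convention. For large pools a random subsample of frames is scored.
#'
#' @param pool frame pool.
#' @param model fitted `cap_model` (k >= 2).
#' @param max_frames subsample cap (silhouette is O(n^2) in frames).
#' @param seed subsample seed.
#' @return length-k vector of per-cluster mean silhouettes (NA if a cluster
#'   has no sampled member).
#' @export
silhouette_by_cluster <- function(pool, model, max_frames = 2000, seed = 1) {
  if (model$k < 2) stop("silhouette needs k >= 2")
  X <- if (inherits(pool, "frame_pool")) pool$frames else as.matrix(pool)
  lab <- model$labels
  n <- nrow(X)
  if (n > max_frames) {
    keep <- with_seed(seed, sort(sample.int(n, max_frames)))
    X <- X[keep, , drop = FALSE]
    lab <- lab[keep]
  }
  Xs <- standardize_rows(X)
  D <- 1 - tcrossprod(Xs)
  m <- length(lab)
  sizes <- tabulate(lab, model$k)
  # mean distance from each frame to each cluster
  sums <- t(rowsum(t(D), lab))                   # m x k: sum of distances to members of cluster
  meanD <- sweep(sums, 2, sizes, "/")
  a <- (sums[cbind(seq_len(m), lab)]) / pmax(sizes[lab] - 1, 1)
  othr <- meanD
  othr[cbind(seq_len(m), lab)] <- Inf
  b <- apply(othr, 1, min)
  s <- (b - a) / pmax(a, b)
  s[sizes[lab] == 1] <- 0
  out <- vapply(seq_len(model$k), function(cl) {
    if (sizes[cl] == 0) NA_real_ else mean(s[lab == cl])
  }, 0)
  out
}

#' Label CAP states by canonical network
#'
#' Correlates each centroid with the binary membership indicator of every
#' network in the parcel table; the best-matching network (argmax
#' correlation) names the state.
#'
#' @param model fitted `cap_model`.
#' @param parcel_table parcel table covering the model's parcels.
#' @param networks networks to test (default: all in the table).
#' @return object of class `cap_labeling`: data.frame `best` (state,
#'   network, r) and matrix `correlations` (state x network).
#' @export
label_caps_by_network <- function(model, parcel_table, networks = NULL) {
  validate_parcel_table(parcel_table)
  if (nrow(parcel_table) != ncol(model$centroids))
    stop("parcel table does not cover the model's parcels")
  ind <- network_indicators(parcel_table, networks)
  R <- stats::cor(t(model$centroids), ind)
  best <- apply(R, 1, which.max)
  structure(list(
    best = data.frame(state = seq_len(model$k),
                      network = colnames(R)[best],
                      r = R[cbind(seq_len(model$k), best)],
                      stringsAsFactors = FALSE),
    correlations = R), class = "cap_labeling")
}

#' Pairwise spatial similarity of centroids
#'
#' @param model fitted `cap_model`.
#' @return symmetric k x k Pearson correlation matrix with unit diagonal.
#' @export
centroid_similarity_matrix <- function(model) {
  stats::cor(t(model$centroids))
}

#' Per-frame similarity to the assigned centroid
#'
#' Pearson correlation of every pooled frame with its own centroid,
#' together with the pool's index map, aggregated per subject-session and
#' state for the group-representativeness ANOVA.
#'
#' @param pool frame pool the model was fitted on.
#' @param model fitted `cap_model`.
#' @return list: `per_frame` (index map + state + r), `per_session` (mean r
#'   by subject, timepoint, group, state).
#' @export
frame_centroid_similarity <- function(pool, model) {
  S <- .frame_centroid_cor(pool, model)
  r <- S[cbind(seq_len(nrow(S)), model$labels)]
  per_frame <- cbind(pool$index_map, state = model$labels, r = r)
  agg <- stats::aggregate(r ~ subject_id + group + timepoint + state,
                          data = per_frame, FUN = mean)
  list(per_frame = per_frame, per_session = agg)
}

# all permutations of 1..n (n small)
.perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))
  }))
}

#' Match two sets of centroids
#'
#' One-to-one assignment between state sets (e.g. subgroup vs pooled
#' clustering) maximizing the total pairwise centroid correlation. Exact
#' (exhaustive over permutations) for min(k) <= 8, greedy beyond. If the
#' sets differ in size, the smaller set is matched into the larger.
#'
#' @param centroids_a,centroids_b matrices (states x parcels) in the same
#'   parcel space; `cap_model`s are also accepted.
#' @return data.frame with `state_a`, `state_b`, `r`, ordered by `state_a`.
#' @export
match_clusters <- function(centroids_a, centroids_b) {
  A <- if (inherits(centroids_a, "cap_model")) centroids_a$centroids else as.matrix(centroids_a)
  B <- if (inherits(centroids_b, "cap_model")) centroids_b$centroids else as.matrix(centroids_b)
  if (ncol(A) != ncol(B)) stop("centroid sets live in different parcel spaces")
  swapped <- nrow(A) > nrow(B)
  if (swapped) { tmp <- A; A <- B; B <- tmp }
  R <- stats::cor(t(A), t(B))          # small x large
  ka <- nrow(A); kb <- nrow(B)
  if (ka <= 8 && kb <= 8) {
    pm <- .perms(kb)
    pm <- pm[, seq_len(ka), drop = FALSE]
    pm <- unique(pm)
    tot <- apply(pm, 1, function(p) sum(R[cbind(seq_len(ka), p)]))
    p_best <- pm[which.max(tot), ]
  } else {
    p_best <- integer(ka)
    avail <- rep(TRUE, kb)
    for (i in order(apply(R, 1, max), decreasing = TRUE)) {
      j <- which.max(replace(R[i, ], !avail, -Inf))
      p_best[i] <- j
      avail[j] <- FALSE
    }
  }
  out <- data.frame(state_a = seq_len(ka), state_b = p_best,
                    r = R[cbind(seq_len(ka), p_best)])
  if (swapped) out <- data.frame(state_a = out$state_b, state_b = out$state_a,
                                 r = out$r)[order(out$state_b), ]
  rownames(out) <- NULL
  out
}

#' Reorder model states to canonical network order
#'
#' Reporting order follows the canonical state inventory (visual,
#' somatomotor, default mode, ventral default mode / limbic, salience,
#' central executive); raw cluster ids are retained in the returned
#' mapping.
#'
#' @param model fitted `cap_model`.
#' @param parcel_table parcel table.
#' @return the model with reordered centroids/labels plus `state_networks`
#'   and `raw_order` fields.
#' @export
order_states_by_network <- function(model, parcel_table) {
  lab <- label_caps_by_network(model, parcel_table)
  pref <- c("Vis", "SomMot", "Default", "Limbic", "SalVentAttn", "Cont",
            "DorsAttn", "subcortical")
  ord <- order(match(lab$best$network, pref), -lab$best$r)
  model$centroids <- model$centroids[ord, , drop = FALSE]
  model$labels <- match(model$labels, ord)
  model$state_networks <- lab$best$network[ord]
  model$raw_order <- ord
  model
}
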