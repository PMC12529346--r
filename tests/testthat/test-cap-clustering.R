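test_that("frame pooling stacks sessions with an invertible index map", {
  s1 <- tiny_session(seed = 1, frames = 5, n_runs = 1)$ts_z
  s2 <- tiny_session(seed = 2, frames = 7, n_runs = 1)$ts_z
  s2$subject_id <- "other"
  pool <- concat_frames(list(a = s1, b = s2))
  expect_equal(nrow(pool$frames), 12)
  expect_equal(nrow(pool$index_map), 12)
  # splitting pooled rows by the map reproduces per-session lengths
  expect_equal(as.integer(table(pool$index_map$subject_id)[c("sim", "other")]), c(5, 7))
  expect_equal(pool$frames[6:12, ], s2$data, ignore_attr = TRUE)

  expect_error(concat_frames(list()), "no sessions")
  raw <- tiny_session(seed = 3, frames = 5, n_runs = 1)$ts
  expect_error(concat_frames(list(raw)), "not z-scored")
  s3 <- s2; s3$data <- s3$data[, 1:10]
  expect_error(concat_frames(list(s1, s3)), "mixed parcel counts")
})

test_that("k-means attains the exhaustive-partition optimum on small inputs", {
  # 8 frames: 4 noisy copies of each of two orthogonal patterns
  set.seed(5)
  base <- rbind(c(1, -1, 1, -1, 0, 0, 1, -1), c(1, 1, -1, -1, 1, -1, 0, 0))
  X <- base[rep(1:2, each = 4), ] + matrix(rnorm(64, sd = 0.05), 8)
  model <- kmeans_caps(X, 2, n_replicates = 20, max_iter = 100, seed = 1)

  # brute-force global optimum over all 2^7 - 1 = 127 bipartitions
  best_obj <- Inf; best_lab <- NULL
  for (m in 1:126) {
    lab <- as.integer(intToBits(m)[1:8]) + 1L
    if (length(unique(lab)) < 2) next
    o <- partition_objective(X, lab)
    if (o < best_obj) { best_obj <- o; best_lab <- lab }
  }
  expect_equal(model$objective, best_obj, tolerance = 1e-8)
  agree <- max(mean(model$labels == best_lab), mean(model$labels == 3L - best_lab))
  expect_equal(agree, 1)
})

test_that("clustering is deterministic, scale-invariant in assignment, and bookkept", {
  sim <- tiny_session(seed = 9, frames = 40)
  pool <- concat_frames(list(a = sim$ts_z))
  m1 <- kmeans_caps(pool, 6, n_replicates = 8, max_iter = 100, seed = 42)
  m2 <- kmeans_caps(pool, 6, n_replicates = 8, max_iter = 100, seed = 42)
  expect_identical(m1$labels, m2$labels)
  expect_identical(m1$objective, m2$objective)
  expect_length(m1$replicate_scores, 8)
  expect_true(all(tabulate(m1$labels, 6) > 0))  # no empty clusters

  # objective recomputable from returned centroids and labels
  obj <- sum(vapply(seq_len(nrow(pool$frames)), function(i)
    1 - cor(pool$frames[i, ], m1$centroids[m1$labels[i], ]), 0))
  expect_equal(m1$objective, obj, tolerance = 1e-8)

  # positive rescaling of a frame leaves its assignment unchanged
  ts2 <- sim$ts_z
  ts2$data[3, ] <- 3.7 * ts2$data[3, ]
  expect_identical(assign_states(ts2, m1)$labels[3], assign_states(sim$ts_z, m1)$labels[3])

  expect_error(kmeans_caps(rbind(rep(1, 8), rep(0:1, 4), rep(1:0, 4)), 2), "zero-variance")
})

test_that("cluster validity index is 0 for perfect clusters and orders separations", {
  # frames exactly equal to their centroids
  set.seed(2)
  a <- rnorm(12); b <- rnorm(12)
  X <- rbind(a, a, a, b, b, b)
  m <- kmeans_caps(X, 2, n_replicates = 5, max_iter = 50, seed = 1)
  expect_equal(as.numeric(cluster_validity_index(X, m)), 0, tolerance = 1e-12)

  # well-separated 20-frame configuration scores lower than a noisy merge
  sep <- rbind(matrix(rep(a, 10), 10, byrow = TRUE) + matrix(rnorm(120, sd = 0.05), 10),
               matrix(rep(b, 10), 10, byrow = TRUE) + matrix(rnorm(120, sd = 0.05), 10))
  noisy <- sep + matrix(rnorm(240, sd = 1.5), 20)
  ms <- kmeans_caps(sep, 2, n_replicates = 10, max_iter = 50, seed = 3)
  mn <- kmeans_caps(noisy, 2, n_replicates = 10, max_iter = 50, seed = 3)
  expect_lt(as.numeric(cluster_validity_index(sep, ms)),
            as.numeric(cluster_validity_index(noisy, mn)))

  # duplicate centroids flag the degenerate between-term
  md <- ms; md$centroids <- ms$centroids[c(1, 1), ]; md$labels <- rep(1:2, each = 10)
  expect_true(isTRUE(attr(cluster_validity_index(sep, md), "degenerate")))

  m1 <- ms; m1$k <- 1L
  expect_error(cluster_validity_index(sep, m1), "k = 1")
})

test_that("the elbow criterion finds constructed breakpoints and flags flat curves", {
  ks <- 2:15
  elbow6 <- ifelse(ks <= 6, 10 - 1 * (ks - 2), 10 - 4 - 0.01 * (ks - 6))
  sel <- select_k_elbow(list(k_values = ks, cvi_scores = elbow6))
  expect_equal(as.integer(sel), 6L)
  expect_false(attr(sel, "ambiguous"))

  lin <- select_k_elbow(list(k_values = ks, cvi_scores = 10 - 0.3 * ks))
  expect_equal(as.integer(lin), 2L)
  expect_true(attr(lin, "ambiguous"))

  expect_error(select_k_elbow(list(k_values = 2:4, cvi_scores = c(3, 2, 1))), "4 k values")

  # ties break toward smaller k: symmetric double elbow
  y <- c(5, 4, 3, 3, 3, 3)
  s2 <- select_k_elbow(list(k_values = 2:7, cvi_scores = y))
  expect_lte(as.integer(s2), 4L)
})

test_that("scan_k produces a reproducible curve with one score per k", {
  sim <- tiny_session(seed = 12, frames = 60)
  pool <- concat_frames(list(a = sim$ts_z))
  cur <- scan_k(pool, 2, 4, n_replicates = 3, max_iter = 50, seed = 5)
  expect_equal(cur$k_values, 2:4)
  expect_length(cur$cvi_scores, 3)
  cur2 <- scan_k(pool, 2, 4, n_replicates = 3, max_iter = 50, seed = 5)
  expect_identical(cur$cvi_scores, cur2$cvi_scores)
})

test_that("silhouettes separate tight clusters from unstructured noise", {
  set.seed(8)
  a <- rnorm(15); b <- rnorm(15)
  tight <- rbind(matrix(rep(a, 12), 12, byrow = TRUE) + matrix(rnorm(180, sd = 0.02), 12),
                 matrix(rep(b, 12), 12, byrow = TRUE) + matrix(rnorm(180, sd = 0.02), 12))
  mt <- kmeans_caps(tight, 2, n_replicates = 5, max_iter = 50, seed = 2)
  expect_true(all(silhouette_by_cluster(tight, mt) > 0.9))

  noise <- matrix(rnorm(40 * 15), 40, 15)
  mn <- kmeans_caps(noise, 4, n_replicates = 5, max_iter = 50, seed = 3)
  # random-ish labels on structureless noise: means near 0
  expect_lt(max(abs(silhouette_by_cluster(noise, mn))), 0.5)
  mt1 <- mt; mt1$k <- 1L
  expect_error(silhouette_by_cluster(tight, mt1), "k >= 2")
})

test_that("network labelling recovers generating networks and sign structure", {
  pt <- tiny_parcel_table()
  pats <- tiny_patterns()
  ind <- network_ind <- vapply(unique(pt$network), function(nw) as.numeric(pt$network == nw),
                               numeric(nrow(pt)))
  # centroid equal to a (standardized) indicator correlates 1 with it
  fake <- list(k = 2L, centroids = rbind(scale(ind[, "Vis"])[, 1], -scale(ind[, "Vis"])[, 1]))
  class(fake) <- "cap_model"
  lab <- label_caps_by_network(fake, pt)
  expect_equal(unname(lab$correlations[1, "Vis"]), 1, tolerance = 1e-12)
  expect_equal(unname(lab$correlations[2, "Vis"]), -1, tolerance = 1e-12)
  expect_equal(lab$best$network[1], "Vis")

  # synthetic patterns: argmax is the generating network
  pm <- list(k = 6L, centroids = pats$patterns); class(pm) <- "cap_model"
  labp <- label_caps_by_network(pm, pt)
  expect_equal(labp$best$network, pats$networks)
  expect_true(all(labp$correlations >= -1 & labp$correlations <= 1))

  pt_bad <- pt
  expect_error(label_caps_by_network(pm, pt, networks = c("Vis", "Nope")), "zero parcels")
})

test_that("centroid similarity matrix is an exact correlation matrix", {
  sim <- tiny_session(seed = 14, frames = 40)
  m <- kmeans_caps(concat_frames(list(a = sim$ts_z)), 3, n_replicates = 5, seed = 4)
  S <- centroid_similarity_matrix(m)
  expect_equal(diag(S), rep(1, 3), ignore_attr = TRUE)
  expect_equal(S, t(S), tolerance = 1e-12, ignore_attr = TRUE)
  # brute-force recomputation
  for (i in 1:3) for (j in 1:3)
    expect_equal(S[i, j], cor(m$centroids[i, ], m$centroids[j, ]))
  neg <- list(k = 2L, centroids = rbind(m$centroids[1, ], -m$centroids[1, ]))
  class(neg) <- "cap_model"
  expect_equal(centroid_similarity_matrix(neg)[1, 2], -1)
})

test_that("frame-centroid similarity is maximal for the assigned centroid", {
  sim <- tiny_session(seed = 15, frames = 50)
  pool <- concat_frames(list(a = sim$ts_z))
  m <- kmeans_caps(pool, 4, n_replicates = 5, seed = 6)
  fs <- frame_centroid_similarity(pool, m)
  # assignment consistency: own-centroid r is the max across centroids
  R <- cor(t(pool$frames), t(m$centroids))
  expect_equal(fs$per_frame$r, R[cbind(seq_len(nrow(R)), m$labels)])
  expect_true(all(fs$per_frame$r >= apply(R, 1, max) - 1e-12))
  # a frame equal to its centroid has r = 1
  ts3 <- roi_ts(m$centroids[c(2, 2), ], "c", "HC", "baseline", zscored = TRUE)
  p3 <- concat_frames(list(x = ts3))
  m3 <- m; m3$labels <- c(2L, 2L)
  fs3 <- frame_centroid_similarity(p3, m3)
  expect_equal(fs3$per_frame$r, c(1, 1), tolerance = 1e-12)
})

test_that("cluster matching recovers permutations and scores null matches near 0", {
  pats <- tiny_patterns()$patterns
  perm <- c(4, 1, 6, 2, 5, 3)
  mm <- match_clusters(pats, pats[perm, ])
  expect_equal(order(perm)[mm$state_a], mm$state_b)
  expect_equal(mm$r, rep(1, 6), tolerance = 1e-12)

  set.seed(10)
  r_null <- match_clusters(matrix(rnorm(6 * 400), 6), matrix(rnorm(6 * 400), 6))$r
  expect_lt(mean(abs(r_null)), 0.2)
  expect_error(match_clusters(pats, pats[, 1:10]), "parcel spaces")
})

test_that("subgroup clustering reproduces the pooled states on synthetic data", {
  spec <- cohort_spec(n_trd = 4, n_hc = 4, n_hc_longitudinal = 0,
                      parcel_table = tiny_parcel_table(), frames_per_run = 80, seed = 21)
  co <- simulate_cohort(spec)
  sessions <- lapply(co$sessions, zscore_session)
  pool_all <- concat_frames(sessions)
  trd <- sessions[grepl("^TRD", names(sessions))]
  pool_trd <- concat_frames(trd)
  m_all <- kmeans_caps(pool_all, 6, n_replicates = 10, max_iter = 100, seed = 2)
  m_trd <- kmeans_caps(pool_trd, 6, n_replicates = 10, max_iter = 100, seed = 3)
  mm <- match_clusters(m_trd, m_all)
  expect_true(all(mm$r > 0.9))
})

test_that("states reorder into canonical network order", {
  spec <- cohort_spec(n_trd = 2, n_hc = 2, n_hc_longitudinal = 0,
                      parcel_table = tiny_parcel_table(), frames_per_run = 80, seed = 31)
  co <- simulate_cohort(spec)
  pool <- concat_frames(lapply(co$sessions, zscore_session))
  m <- kmeans_caps(pool, 6, n_replicates = 10, max_iter = 100, seed = 5)
  mo <- order_states_by_network(m, spec$parcel_table)
  expect_equal(mo$state_networks,
               c("Vis", "SomMot", "Default", "Limbic", "SalVentAttn", "Cont"))
  # relabelling is consistent: frame i's centroid is unchanged
  expect_equal(mo$centroids[mo$labels[10], ], m$centroids[m$labels[10], ])
})
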