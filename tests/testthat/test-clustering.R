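test_that("similarity matrices are symmetric, zero-diagonal, non-negative", {
  pool <- planted_cluster_pool(k_states = 2, frames_per_traj = 6, n_traj = 1,
                               seed = 3)
  for (metric in c("dihedral", "rmsd")) {
    D <- similarity_matrix(pool, metric = metric)
    expect_equal(D, t(D))
    expect_true(all(diag(D) == 0))
    expect_true(all(D >= 0))
  }
  # duplicated frame -> off-diagonal zero
  co <- pool$coords[c(1, 1, 2), , , drop = FALSE]
  dup <- conformation_ensemble(co, pool$topology, "t")
  D <- similarity_matrix(dup, metric = "rmsd")
  expect_equal(D[1, 2], 0, tolerance = 1e-10)
  expect_error(similarity_matrix(subset_one <- conformation_ensemble(
    pool$coords[1, , , drop = FALSE], pool$topology)), "2 frames")
})

test_that("pairwise RMSD agrees with an independent superposition oracle", {
  skip_if_not_installed("bio3d")
  pool <- planted_cluster_pool(k_states = 2, frames_per_traj = 5, n_traj = 1,
                               seed = 4)
  sel <- which(pool$topology$atom %in% c("N", "CA", "C"))
  D <- similarity_matrix(pool, metric = "rmsd")
  for (i in 1:4) for (j in (i + 1):5) {
    a <- as.vector(t(pool$coords[i, sel, ]))
    b <- as.vector(t(pool$coords[j, sel, ]))
    oracle <- bio3d::rmsd(a, b, fit = TRUE) # reported to 3 decimals
    expect_lt(abs(D[i, j] - oracle), 5.1e-4)
  }
})

test_that("the embedding is deterministic and separates planted states", {
  skip_if_not_installed("mclust")
  pool <- planted_cluster_pool(k_states = 2, frames_per_traj = 80, n_traj = 2,
                               separation = 8, seed = 6)
  D <- similarity_matrix(pool)
  emb1 <- embed_2d(D, perplexity = 20, seed = 0)
  emb2 <- embed_2d(D, perplexity = 20, seed = 0)
  expect_identical(emb1, emb2)
  expect_error(embed_2d(D, perplexity = 200), "perplexity")

  # 2-means on the embedding recovers the planted split
  truth <- attr(pool, "state")
  km <- stats::kmeans(as.matrix(emb1[, c("x", "y")]), centers = 2, nstart = 5)
  agree <- max(mean((km$cluster == 1) == (truth == 1)),
               mean((km$cluster == 2) == (truth == 1)))
  expect_gte(agree, 0.95)

  # permuting frames and permuting back yields the same cluster structure;
  # the embedding itself is not permutation-equivariant, so agreement is
  # measured on the frames both runs assign (noise quarantined)
  perm <- withr::with_seed(1, sample(n_frames(pool)))
  shuf <- conformation_ensemble(pool$coords[perm, , , drop = FALSE],
                                pool$topology, pool$trajectory_label[perm])
  ca0 <- density_cluster(embed_2d(D, 20, 0), pool$trajectory_label)
  Ds <- similarity_matrix(shuf)
  cas <- density_cluster(embed_2d(Ds, 20, 0), shuf$trajectory_label)
  lab_back <- integer(n_frames(pool))
  lab_back[perm] <- cas$assignment$cluster
  both <- ca0$assignment$cluster != -1L & lab_back != -1L
  expect_gt(mean(both), 0.9)
  expect_gte(mclust::adjustedRandIndex(ca0$assignment$cluster[both],
                                       lab_back[both]), 0.95)
})

test_that("density clustering accounts for populations exactly", {
  # single tight blob -> one cluster holding every frame
  withr::with_seed(2, {
    blob <- tibble::tibble(frame = 1:60, x = rnorm(60, sd = 0.1),
                           y = rnorm(60, sd = 0.1))
  })
  ca <- density_cluster(blob, "t", radius = 0.5, min_points = 5)
  expect_equal(glance(ca)$n_clusters, 1)
  expect_equal(ca$populations$population[ca$populations$cluster == 1], 1)

  # two planted blobs, 70/30, noise-free populations are exact
  withr::with_seed(3, {
    two <- tibble::tibble(
      frame = 1:100,
      x = c(rnorm(70, 0, 0.05), rnorm(30, 10, 0.05)),
      y = c(rnorm(70, 0, 0.05), rnorm(30, 10, 0.05))
    )
  })
  ca2 <- density_cluster(two, "t", radius = 0.5, min_points = 5)
  expect_equal(sort(ca2$populations$population, decreasing = TRUE), c(0.7, 0.3))
  # conservation incl. noise
  expect_equal(sum(ca2$populations$population), 1)

  # per-trajectory totals equal the frame shares regardless of clustering
  traj <- rep(c("a", "b"), c(25, 75))
  ca3 <- density_cluster(two, traj, radius = 0.5, min_points = 5)
  sh <- trajectory_shares(ca3)
  expect_equal(sh$share[match(c("a", "b"), sh$trajectory)], c(0.25, 0.75))
  expect_error(density_cluster(two, "t", radius = 0), "> 0")
})

test_that("cluster medoids match exhaustive search with low-index ties", {
  pool <- planted_cluster_pool(k_states = 2, frames_per_traj = 20, n_traj = 1,
                               separation = 8, seed = 9)
  D <- similarity_matrix(pool)
  emb <- embed_2d(D, perplexity = 6, seed = 0)
  ca <- density_cluster(emb, "t")
  reps <- cluster_representatives(ca, D)
  for (i in seq_len(nrow(reps))) {
    members <- ca$assignment$frame[ca$assignment$cluster == reps$cluster[i]]
    expect_equal(reps$medoid_frame[i], oracle_medoid(D, members))
  }
  # one-frame cluster is its own medoid; exact ties go to the lowest index
  Dt <- matrix(0, 3, 3)
  Dt[1, 2] <- Dt[2, 1] <- 1; Dt[1, 3] <- Dt[3, 1] <- 1; Dt[2, 3] <- Dt[3, 2] <- 1
  ca_t <- structure(list(assignment = tibble::tibble(
    frame = 1:3, trajectory = "t", cluster = 1L, x = 0, y = 0
  )), class = "cluster_assignment")
  expect_equal(cluster_representatives(ca_t, Dt)$medoid_frame, 1L)
  ca_noise <- structure(list(assignment = tibble::tibble(
    frame = 1:3, trajectory = "t", cluster = -1L, x = 0, y = 0
  )), class = "cluster_assignment")
  expect_error(cluster_representatives(ca_noise, Dt), "no non-noise")
})

test_that("planted multi-state pools are recovered near-perfectly", {
  skip_if_not_installed("mclust")
  pool <- planted_cluster_pool(k_states = 3, frames_per_traj = 80, n_traj = 3,
                               separation = 8, seed = 10)
  D <- similarity_matrix(pool)
  ca <- density_cluster(embed_2d(D, perplexity = 30, seed = 0),
                        pool$trajectory_label)
  expect_equal(glance(ca)$n_clusters, 3)
  expect_gte(mclust::adjustedRandIndex(attr(pool, "state"),
                                       ca$assignment$cluster), 0.95)
  # equal-length pooled trajectories each hold exactly a third of the pool
  sh <- trajectory_shares(ca)
  expect_equal(sh$share, rep(1 / 3, 3))
  # a state dominated by one trajectory shows up in its cluster's split
  mix <- rbind(c(0.9, 0.1), c(0.9, 0.1), c(0.1, 0.9))
  pri <- planted_cluster_pool(k_states = 2, frames_per_traj = 60, n_traj = 3,
                              separation = 8, seed = 11, state_mix = mix)
  Dp <- similarity_matrix(pri)
  cap <- density_cluster(embed_2d(Dp, perplexity = 25, seed = 0),
                         pri$trajectory_label)
  # identify the cluster matching planted state 2 and check traj3 dominates
  st <- attr(pri, "state")
  cl2 <- names(which.max(table(cap$assignment$cluster[st == 2])))
  split2 <- cap$by_trajectory[cap$by_trajectory$cluster == as.integer(cl2), ]
  expect_equal(split2$trajectory[which.max(split2$share)], "traj3")
})
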