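# Multi-trajectory conformational clustering: pairwise similarity matrix
# over pooled frames, 2-D embedding, density grouping on the embedding,
# and per-cluster / per-trajectory population accounting.

#' Pairwise frame-similarity (distance) matrix
#'
#' Default metric: Euclidean distance between backbone-dihedral
#' sine/cosine feature vectors (superposition-free and fast; angles enter
#' through sin/cos so the 180/-180 wrap is seamless). Alternative:
#' all-pairs backbone RMSD after optimal (Kabsch) superposition.
#'
#' @param ens A `conformation_ensemble` (>= 2 frames).
#' @param metric `"dihedral"` or `"rmsd"`.
#' @param atoms Atom names used by the RMSD metric (default backbone).
#' @return Symmetric `n_frames x n_frames` matrix with zero diagonal;
#'   attribute `metric` records the choice.
#' @export
similarity_matrix <- function(ens, metric = c("dihedral", "rmsd"),
                              atoms = c("N", "CA", "C")) {
  stopifnot(inherits(ens, "conformation_ensemble"))
  metric <- match.arg(metric)
  nf <- n_frames(ens)
  if (nf < 2) abort("need at least 2 frames")
  if (metric == "dihedral") {
    dh <- dihedral_angles(ens)
    feats <- dh %>%
      filter(!is.na(.data$phi) & !is.na(.data$psi)) %>%
      arrange(.data$frame, .data$residue)
    f <- cbind(sin(feats$phi * DEG), cos(feats$phi * DEG),
               sin(feats$psi * DEG), cos(feats$psi * DEG))
    X <- matrix(t(f), nrow = nf, byrow = TRUE)
    D <- as.matrix(dist(X))
  } else {
    sel <- which(ens$topology$atom %in% atoms)
    D <- matrix(0, nf, nf)
    for (i in seq_len(nf - 1)) {
      xi <- matrix(ens$coords[i, sel, ], length(sel), 3)
      for (j in (i + 1):nf) {
        xj <- matrix(ens$coords[j, sel, ], length(sel), 3)
        D[i, j] <- D[j, i] <- kabsch_rmsd(xi, xj)
      }
    }
  }
  dimnames(D) <- NULL
  attr(D, "metric") <- metric
  D
}

#' Embed a frame-distance matrix in two dimensions
#'
#' t-SNE on the precomputed distance matrix. Stochastic only through the
#' seeded initialisation: the same `(matrix, perplexity, seed)` always
#' yields identical coordinates, and the parameters are recorded on the
#' result so downstream population statistics are reproducible.
#'
#' @param D Distance matrix from [similarity_matrix()].
#' @param perplexity t-SNE perplexity (default 30; must be well below the
#'   frame count).
#' @param seed Integer seed for the embedding initialisation.
#' @param max_iter Gradient-descent iterations (default 400).
#' @return Tibble with `frame`, `x`, `y`; attribute `params`.
#' @export
embed_2d <- function(D, perplexity = 30, seed = 0, max_iter = 400) {
  Y <- tsne_embed(as.matrix(D), perplexity = perplexity, seed = seed,
                  max_iter = max_iter)
  out <- tibble(frame = seq_len(nrow(Y)), x = Y[, 1], y = Y[, 2])
  attr(out, "params") <- list(method = "tsne", perplexity = perplexity,
                              seed = seed, max_iter = max_iter)
  out
}

# Plain density-based grouping (DBSCAN) on 2-D points.
dbscan_2d <- function(xy, eps, min_points) {
  n <- nrow(xy)
  D <- as.matrix(dist(xy))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_points
  cluster <- rep(-1L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (cluster[i] != -1L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    cluster[i] <- cl
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (!core[j]) next
      for (k in nb[[j]]) {
        if (cluster[k] == -1L) {
          cluster[k] <- cl
          queue <- c(queue, k)
        }
      }
    }
  }
  cluster
}

#' Density-based clustering of an embedding with population accounting
#'
#' Groups density-connected points of the 2-D embedding (DBSCAN-style);
#' frames in regions below the density threshold are noise (cluster -1).
#' Populations are reported overall and split by source trajectory, on the
#' pooled-frame scale: when three equal-length trajectories are pooled,
#' each trajectory's summed share is 1/3 regardless of how the clusters
#' fall.
#'
#' @param embedding Output of [embed_2d()].
#' @param trajectory Per-frame trajectory labels (e.g.
#'   `ens$trajectory_label`), recycled if length 1.
#' @param radius Neighbourhood radius; default 5% of the embedding span.
#' @param min_points Core-point threshold; default `max(5, 0.5%)` of the
#'   frame count.
#' @return Object of class `cluster_assignment`: per-frame assignment,
#'   overall populations (noise included), per-(cluster, trajectory)
#'   shares, and the parameters used.
#' @export
density_cluster <- function(embedding, trajectory = "traj1",
                            radius = NULL, min_points = NULL) {
  xy <- as.matrix(embedding[, c("x", "y")])
  n <- nrow(xy)
  trajectory <- rep_len(as.character(trajectory), n)
  if (is.null(min_points)) min_points <- max(5, ceiling(0.005 * n))
  if (is.null(radius)) {
    # 5% of the embedding span, floored at the median distance to the
    # min_points-th neighbour (the usual DBSCAN k-distance heuristic) so a
    # single diffuse state is one cluster rather than all noise
    span <- max(apply(xy, 2, function(v) diff(range(v))))
    Dxy <- as.matrix(dist(xy))
    kdist <- apply(Dxy, 1, function(row) sort(row)[min(min_points + 1, n)])
    radius <- max(0.05 * span, stats::median(kdist))
  }
  if (radius <= 0) abort("radius must be > 0")
  cluster <- dbscan_2d(xy, radius, min_points)
  assignment <- tibble(frame = embedding$frame, trajectory = trajectory,
                       cluster = cluster, x = xy[, 1], y = xy[, 2])
  populations <- assignment %>%
    count(.data$cluster, name = "n_frames") %>%
    mutate(population = .data$n_frames / n) %>%
    arrange(.data$cluster)
  by_trajectory <- assignment %>%
    count(.data$cluster, .data$trajectory, name = "n_frames") %>%
    mutate(share = .data$n_frames / n) %>%
    arrange(.data$cluster, .data$trajectory)
  structure(
    list(assignment = assignment, populations = populations,
         by_trajectory = by_trajectory,
         params = c(attr(embedding, "params") %||% list(),
                    list(radius = radius, min_points = min_points))),
    class = "cluster_assignment"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-trajectory pooled shares
#'
#' Each trajectory's total share of the pooled frames, summed over
#' clusters and noise; by construction this equals its frame share of the
#' pool whatever the clustering did.
#'
#' @param ca A `cluster_assignment`.
#' @return Tibble with `trajectory`, `share`.
#' @export
trajectory_shares <- function(ca) {
  ca$by_trajectory %>%
    group_by(.data$trajectory) %>%
    summarise(share = sum(.data$share), .groups = "drop")
}

#' Representative (medoid) frame per cluster
#'
#' The medoid minimises the summed distance to all other members of its
#' cluster (in the original frame-distance metric, not the embedding);
#' ties break deterministically to the lowest frame index.
#'
#' @param ca A `cluster_assignment`.
#' @param D Frame-distance matrix from [similarity_matrix()].
#' @return Tibble with `cluster`, `medoid_frame`, `n_frames`.
#' @export
cluster_representatives <- function(ca, D) {
  D <- as.matrix(D)
  clusters <- sort(unique(ca$assignment$cluster[ca$assignment$cluster != -1L]))
  if (!length(clusters)) abort("no non-noise clusters to represent")
  purrr::map_dfr(clusters, function(cl) {
    members <- ca$assignment$frame[ca$assignment$cluster == cl]
    sums <- rowSums(D[members, members, drop = FALSE])
    tibble(cluster = cl, medoid_frame = members[which.min(sums)],
           n_frames = length(members))
  })
}

#' Tidy a cluster assignment into its per-frame table
#' @param x A `cluster_assignment`.
#' @param ... Unused.
#' @return Per-frame tibble (`frame`, `trajectory`, `cluster`, `x`, `y`).
#' @method tidy cluster_assignment
#' @export
tidy.cluster_assignment <- function(x, ...) x$assignment

#' One-row summary of a cluster assignment
#' @param x A `cluster_assignment`.
#' @param ... Unused.
#' @return Tibble with cluster count, noise fraction and frame count.
#' @method glance cluster_assignment
#' @export
glance.cluster_assignment <- function(x, ...) {
  tibble(
    n_clusters = sum(x$populations$cluster != -1L),
    noise_fraction = sum(x$populations$population[x$populations$cluster == -1L]),
    n_frames = nrow(x$assignment)
  )
}

#' @export
print.cluster_assignment <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<cluster_assignment> %d frames, %d clusters, %.1f%% noise\n",
              g$n_frames, g$n_clusters, 100 * g$noise_fraction))
  print(x$populations)
  invisible(x)
}

#' Plot a clustered embedding
#'
#' Scatter of the 2-D embedding coloured by cluster and shaped by source
#' trajectory; noise frames in grey.
#'
#' @param object A `cluster_assignment`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cluster_assignment
#' @export
autoplot.cluster_assignment <- function(object, ...) {
  df <- object$assignment %>%
    mutate(cluster = factor(ifelse(.data$cluster == -1L, "noise", .data$cluster)))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$cluster,
                                   shape = .data$trajectory)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "embedding 1", y = "embedding 2")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
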