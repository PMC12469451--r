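# Exact (dense) t-SNE on a precomputed distance matrix. O(n^2) memory and
# time per iteration -- ample for the few thousand pooled frames this
# package clusters. Deterministic given the seed.

# Per-point conditional probabilities at a target perplexity via binary
# search on the Gaussian bandwidth.
tsne_affinities <- function(D2, perplexity, tol = 1e-5, max_tries = 50) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1
    beta_min <- -Inf; beta_max <- Inf
    di <- D2[i, -i]
    for (t in seq_len(max_tries)) {
      p <- exp(-di * beta)
      sump <- sum(p)
      if (sump == 0) p <- rep(1 / length(di), length(di)) else p <- p / sump
      H <- -sum(p[p > 0] * log(p[p > 0]))
      diff <- H - logU
      if (abs(diff) < tol) break
      if (diff > 0) { # entropy too high -> narrow kernel
        beta_min <- beta
        beta <- if (is.finite(beta_max)) (beta + beta_max) / 2 else beta * 2
      } else {
        beta_max <- beta
        beta <- if (is.finite(beta_min)) (beta + beta_min) / 2 else beta / 2
      }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, .Machine$double.xmin)
}

tsne_embed <- function(D, perplexity = 30, seed = 0, max_iter = 400,
                       eta = 200, momentum_start = 0.5, momentum_final = 0.8,
                       exaggeration = 12, exaggeration_iter = 100) {
  n <- nrow(D)
  if (3 * perplexity >= n) {
    abort("perplexity too large for the number of frames")
  }
  P <- tsne_affinities(D^2, perplexity)
  withr::with_seed(seed, {
    Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
  })
  dY <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  Pex <- P * exaggeration
  for (iter in seq_len(max_iter)) {
    Puse <- if (iter <= exaggeration_iter) Pex else P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), .Machine$double.xmin)
    L <- (Puse - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    mom <- if (iter < 250) momentum_start else momentum_final
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- mom * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
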