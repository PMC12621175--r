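# Exact t-SNE on a precomputed distance matrix. Conditional affinities use
# exp(-beta * d^2) with a per-point binary search on beta to match the
# target perplexity; gradient descent with early exaggeration and momentum.

.tsne_affinities <- function(D, perplexity, tol = 1e-5) {
  n <- nrow(D)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  D2 <- D^2
  for (i in seq_len(n)) {
    beta <- 1
    bmin <- -Inf
    bmax <- Inf
    di <- D2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) p <- rep(1e-12, length(di)) else p <- p / sp
      H <- -sum(p * log(pmax(p, 1e-12)))
      diff <- H - logU
      if (abs(diff) < tol) break
      if (diff > 0) {         # entropy too high -> sharpen
        bmin <- beta
        beta <- if (is.finite(bmax)) (beta + bmax) / 2 else beta * 2
      } else {
        bmax <- beta
        beta <- if (is.finite(bmin)) (beta + bmin) / 2 else beta / 2
      }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

.tsne_from_dist <- function(D, perplexity = 30, seed = 1, max_iter = 600,
                            eta = 200, exaggeration = 12, exag_iter = 150) {
  n <- nrow(D)
  if (n <= perplexity) stop("number of points must exceed the perplexity")
  P <- .tsne_affinities(D, perplexity)
  Y <- with_seed(seed, matrix(rnorm(n * 2, sd = 1e-4), n, 2))
  dY <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  for (iter in seq_len(max_iter)) {
    mom <- if (iter <= exag_iter) 0.5 else 0.8
    Pe <- if (iter <= exag_iter) P * exaggeration else P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- pmax(ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8),
                  0.01)
    dY <- mom * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
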