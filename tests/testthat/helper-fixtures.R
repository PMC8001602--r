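# Programmatic fixtures shared across test files.

# small synthetic scene: fast to generate, still has every structural
# ingredient (low-rank background, noise, clustered bright targets)
smallSceneConfig <- function(seed = 7, height = 96, width = 96,
                             shift = c(0.10, 0.25, 0.05),
                             distractor = FALSE) {
  syntheticSceneConfig(height = height, width = width,
    nTargetClusters = 6L, clusterRadius = c(2, 8),
    targetPrevalence = 0.035, targetColorShift = shift,
    distractor = distractor, seed = seed)
}

# rank-1 background with planted spikes; returns matrix + spike positions
plantedSpikeMatrix <- function(n = 20, m = 20, nSpikes = 2,
                               magnitude = 50, seed = 1) {
  set.seed(seed)
  P <- outer(runif(n, 0.5, 1.5), runif(m, 0.5, 1.5))
  pos <- cbind(sample(n, nSpikes), sample(m, nSpikes))
  for (i in seq_len(nSpikes)) P[pos[i, 1], pos[i, 2]] <-
    P[pos[i, 1], pos[i, 2]] + magnitude
  list(P = P, spikes = pos)
}

# independent AUC oracle: pairwise concordance with ties counted 1/2
bruteForceAuc <- function(scores, truth) {
  s <- as.vector(scores); t <- as.vector(truth)
  pos <- s[t == 1]; neg <- s[t == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# independent patch-count oracle: enumerate admissible origins directly
bruteForcePatchCount <- function(H, W, wh, ww, sy, sx) {
  n <- 0
  r <- 0
  while (r + wh <= H) {
    c <- 0
    while (c + ww <= W) {
      n <- n + 1
      c <- c + sx
    }
    r <- r + sy
  }
  n
}

numericalRank <- function(M, tol = 1e-8) {
  d <- svd(M, nu = 0, nv = 0)$d
  sum(d > tol * d[1])
}
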