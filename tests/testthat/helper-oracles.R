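# Independent brute-force oracles and small fixtures, built in code.

# Elementwise-formula Pearson correlation (no stats::cor).
bruteCor <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
  if (den == 0) 0 else num / den
}

bruteRowSim <- function(Z) {
  n <- nrow(Z)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    A[i, j] <- if (i == j) 1 else bruteCor(Z[i, ], Z[j, ])
  A
}

# Loop-based silhouette on raw pairwise distances.
bruteSilhouette <- function(X, labels) {
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(c) mean(D[i, labels == c]), numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

# Brute-force minimum normalized cut over all bipartitions.
bruteNormalizedCut <- function(W) {
  n <- nrow(W)
  deg <- rowSums(W)
  best <- NULL; bestVal <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    inA <- c(TRUE, as.logical(bitwAnd(code, 2^(0:(n - 2)))))
    if (all(inA) || !any(inA)) next
    cut <- sum(W[inA, !inA])
    val <- cut * (1 / sum(deg[inA]) + 1 / sum(deg[!inA]))
    if (val < bestVal) { bestVal <- val; best <- inA }
  }
  list(partition = best + 1L, value = bestVal)
}

# A small, fast phantom configuration for unit tests.
smallPhantomConfig <- function(nVolumes = 100L, nRuns = 2L, seed = 11L, ...)
  phantomConfig(nVolumes = as.integer(nVolumes), nRuns = as.integer(nRuns),
                seed = as.integer(seed), ...)

# Null-model species configs: one sulcus, equal presence probability.
nullSpeciesConfigs <- function(p = 0.5, nSubjects = 30L) {
  preset <- studyPreset()
  lapply(preset$species, function(cf)
    speciesConfig(species = cf@species, nSubjects = nSubjects,
                  presenceProb = c(s1 = p),
                  anchor = c(s1 = "anterior_commissure"),
                  jitterSd = cf@jitterSd, apExtent = cf@apExtent))
}

# Two disconnected k-cliques as a weight matrix.
twoCliques <- function(size = 5L, w = 1) {
  n <- 2L * size
  W <- matrix(0, n, n)
  W[seq_len(size), seq_len(size)] <- w
  W[(size + 1):n, (size + 1):n] <- w
  diag(W) <- 0
  W
}
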