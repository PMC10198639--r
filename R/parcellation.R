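## Spectral parcellation of ROI voxels by connectivity-fingerprint
## similarity: row correlation -> k-NN graph -> normalized Laplacian ->
## K-means in the spectral embedding, with silhouette-based selection of
## the number of parcels, cross-run label alignment and probability maps.

#' Row-by-row similarity of a fingerprint matrix
#'
#' Pearson correlation between the Fisher-z fingerprint rows of every pair
#' of ROI voxels. Constant rows get correlation 0 against all others (with
#' a message).
#'
#' @param fp a \linkS4class{FingerprintMatrix} or a plain numeric matrix
#'   whose rows are fingerprints.
#' @return symmetric n_roi x n_roi matrix with unit diagonal.
#' @export
rowSimilarity <- function(fp) {
  Z <- if (is(fp, "FingerprintMatrix")) fingerprintValues(fp) else fp
  if (nrow(Z) < 2L) stop("need at least 2 fingerprint rows")
  s <- apply(Z, 1, sd)
  if (any(s == 0))
    message(sum(s == 0), " constant fingerprint row(s); similarity set to 0")
  A <- .safeCrossCor(t(Z), t(Z))
  diag(A) <- 1
  A
}

#' k-nearest-neighbour similarity graph
#'
#' Keeps each row's \code{kNN} largest off-diagonal similarities, floors
#' negative weights at 0, symmetrizes by elementwise maximum and zeroes the
#' diagonal.
#'
#' @param A symmetric similarity matrix.
#' @param kNN neighbour count, \code{1 <= kNN < nrow(A)}.
#' @return a \linkS4class{SimilarityGraph}.
#' @export
knnGraph <- function(A, kNN) {
  n <- nrow(A)
  if (kNN < 1L || kNN >= n)
    stop("kNN must satisfy 1 <= kNN < ", n)
  keep <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    off <- setdiff(order(A[i, ], decreasing = TRUE), i)
    keep[i, off[seq_len(kNN)]] <- TRUE
  }
  W <- ifelse(keep, pmax(A, 0), 0)
  W <- pmax(W, t(W))  # symmetrize by elementwise maximum
  diag(W) <- 0
  if (all(W == 0))
    warning("degenerate similarity graph: all retained weights are zero")
  new("SimilarityGraph", W = W, knn = as.integer(kNN))
}

#' Default neighbour count for the k-NN graph
#'
#' @param nRoi number of ROI voxels.
#' @export
defaultKnn <- function(nRoi) max(10L, as.integer(ceiling(log2(nRoi))) + 1L)

## Connected components of a nonnegative weight matrix (simple BFS).
.graphComponents <- function(W) {
  n <- nrow(W)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(W[v, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Spectral embedding of a similarity graph
#'
#' Symmetric normalized Laplacian \code{L = I - D^{-1/2} W D^{-1/2}};
#' eigenvectors of the \code{k} smallest eigenvalues, rows normalized to
#' unit length (Ng-Jordan-Weiss). Isolated vertices (zero degree) get a
#' zero embedding row and are flagged.
#'
#' @param graph a \linkS4class{SimilarityGraph} or nonnegative weight matrix.
#' @param k number of embedding dimensions.
#' @return list with \code{embedding} (n x k), \code{eigenvalues}
#'   (ascending), \code{isolated} (logical), \code{nComponents}.
#' @export
spectralEmbedding <- function(graph, k) {
  W <- if (is(graph, "SimilarityGraph")) graphWeights(graph) else graph
  n <- nrow(W)
  if (k < 1L || k > n) stop("k must lie in 1..", n)
  deg <- rowSums(W)
  isolated <- deg == 0
  if (any(isolated))
    warning(sum(isolated), " isolated vertex(es) in the similarity graph")
  dinv <- ifelse(isolated, 0, 1 / sqrt(deg))
  L <- diag(n) - (dinv %o% dinv) * W
  nComp <- max(.graphComponents(W))
  if (nComp > 1L)
    warning("similarity graph has ", nComp, " connected components")
  e <- eigen(L, symmetric = TRUE)
  ord <- seq(n, n - k + 1)  # eigen returns decreasing eigenvalues
  U <- e$vectors[, ord, drop = FALSE]
  rn <- sqrt(rowSums(U^2))
  U <- U / ifelse(rn > 0, rn, 1)
  U[isolated, ] <- 0
  list(embedding = U, eigenvalues = rev(e$values)[seq_len(k)],
       isolated = isolated, nComponents = nComp)
}

## k-means++ center initialization (D^2 sampling).
.kppCenters <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- colSums((t(X) - X[centers[1], ])^2)
  for (j in seq_len(k - 1)) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1] <- sample.int(n, 1, prob = p)
    d2 <- pmin(d2, colSums((t(X) - X[centers[j + 1], ])^2))
  }
  X[centers, , drop = FALSE]
}

## K-means with k-means++ seeding and nInit restarts; returns the labels of
## the restart with the lowest total within-cluster sum of squares.
.kmeansPP <- function(X, k, nInit = 50L, seed = 1L) {
  withSeed(seed, {
    best <- NULL
    for (i in seq_len(nInit)) {
      centers <- .kppCenters(X, k)
      if (anyDuplicated(centers)) next
      km <- tryCatch(
        suppressWarnings(stats::kmeans(X, centers = centers, iter.max = 100L)),
        error = function(e) NULL)
      if (is.null(km)) next
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    if (is.null(best))
      stop("K-means failed for every restart (k = ", k, ")")
    as.integer(best$cluster)
  })
}

#' Spectral partition of a similarity graph
#'
#' Embeds the graph with \code{\link{spectralEmbedding}} and clusters the
#' row-normalized eigenvector matrix with K-means (k-means++ seeding,
#' \code{nInit} restarts, fixed seed).
#'
#' @param graph a \linkS4class{SimilarityGraph} or weight matrix.
#' @param k number of clusters (>= 2).
#' @param seed RNG seed for the K-means restarts.
#' @param nInit number of K-means restarts.
#' @return integer labels in 1..k with attributes \code{embedding} and
#'   \code{eigenvalues}.
#' @export
spectralPartition <- function(graph, k, seed = 1L, nInit = 50L) {
  if (k < 2L) stop("k must be >= 2")
  se <- spectralEmbedding(graph, k)
  labels <- .kmeansPP(se$embedding, k, nInit = nInit, seed = seed)
  structure(labels, embedding = se$embedding, eigenvalues = se$eigenvalues)
}

## ---- partition quality ---------------------------------------------------

#' Silhouette and variance-ratio scores of a partition
#'
#' The silhouette is the mean over points of \code{(b - a) / max(a, b)}
#' with Euclidean distances in the supplied space (a: mean within-cluster
#' distance; b: mean distance to the nearest other cluster); points in
#' singleton clusters contribute 0. The variance ratio is the
#' between-cluster dispersion divided by the within-cluster dispersion
#' (dispersions as sums of squared distances to the respective centroids).
#'
#' @param embedding n x d numeric matrix (typically the spectral embedding).
#' @param labels integer cluster labels.
#' @return named numeric: \code{silhouette}, \code{varianceRatio}.
#' @export
scorePartition <- function(embedding, labels) {
  embedding <- as.matrix(embedding)
  labels <- as.integer(labels)
  cls <- sort(unique(labels))
  if (length(cls) < 2L) stop("need at least 2 nonempty clusters")
  n <- nrow(embedding)
  D <- as.matrix(stats::dist(embedding))
  sizes <- table(factor(labels, levels = cls))
  ## mean distance from each point to each cluster
  M <- sapply(cls, function(c) rowSums(D[, labels == c, drop = FALSE]))
  sil <- numeric(n)
  for (i in seq_len(n)) {
    ci <- match(labels[i], cls)
    ni <- sizes[ci]
    if (ni == 1L) { sil[i] <- 0; next }
    a <- M[i, ci] / (ni - 1)
    b <- min(M[i, -ci] / sizes[-ci])
    sil[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mu <- colMeans(embedding)
  within <- 0; between <- 0
  for (c in cls) {
    Xc <- embedding[labels == c, , drop = FALSE]
    muc <- colMeans(Xc)
    within <- within + sum(sweep(Xc, 2, muc)^2)
    between <- between + nrow(Xc) * sum((muc - mu)^2)
  }
  c(silhouette = mean(sil),
    varianceRatio = if (within > 0) between / within else Inf)
}

## ---- model selection -----------------------------------------------------

#' Select the number of parcels by mean silhouette
#'
#' For every k in \code{kRange}, partitions the fingerprint-similarity k-NN
#' graph with \code{\link{spectralPartition}} under each seed and scores the
#' result in the spectral embedding; the chosen k maximizes the mean
#' silhouette across seeds (ties broken toward the smallest k). The
#' returned labels are those of the best-silhouette seed at the chosen k.
#'
#' @param fp a \linkS4class{FingerprintMatrix}.
#' @param kRange candidate cluster counts (subset of 2..n_roi-1). k = 1 is
#'   not evaluable under the silhouette and is not scanned.
#' @param kNN neighbour count for the graph; default
#'   \code{\link{defaultKnn}}.
#' @param seeds integer vector of K-means seeds.
#' @param nInit K-means restarts per seed.
#' @param scoreSpace \code{"embedding"} (default: the space K-means
#'   clusters in) or \code{"fingerprint"} (raw z rows) for the silhouette.
#' @return a \linkS4class{ParcellationResult}.
#' @export
selectK <- function(fp, kRange = 2:7, kNN = NULL, seeds = 1:5, nInit = 50L,
                    scoreSpace = c("embedding", "fingerprint")) {
  scoreSpace <- match.arg(scoreSpace)
  Z <- fingerprintValues(fp)
  n <- nrow(Z)
  if (!length(kRange)) stop("kRange is empty")
  kRange <- sort(unique(as.integer(kRange)))
  if (any(kRange < 2L) || any(kRange > n - 1L))
    stop("kRange must be a subset of 2..", n - 1L)
  if (is.null(kNN)) kNN <- defaultKnn(n)
  A <- rowSimilarity(fp)
  W <- knnGraph(A, kNN)

  scores <- data.frame(k = kRange, silhouette = NA_real_,
                       varianceRatio = NA_real_)
  bestLabels <- vector("list", length(kRange))
  maxEig <- NULL
  for (ki in seq_along(kRange)) {
    k <- kRange[ki]
    silBySeed <- vrBySeed <- rep(NA_real_, length(seeds))
    labsBySeed <- vector("list", length(seeds))
    for (si in seq_along(seeds)) {
      labels <- tryCatch(
        suppressWarnings(spectralPartition(W, k, seed = seeds[si],
                                           nInit = nInit)),
        error = function(e) NULL)
      if (is.null(labels) || length(unique(labels)) < 2L) next
      space <- if (scoreSpace == "embedding")
        attr(labels, "embedding") else Z
      sc <- scorePartition(space, labels)
      silBySeed[si] <- sc["silhouette"]
      vrBySeed[si] <- sc["varianceRatio"]
      labsBySeed[[si]] <- labels
      if (k == max(kRange) && is.null(maxEig))
        maxEig <- attr(labels, "eigenvalues")
    }
    scores$silhouette[ki] <- mean(silBySeed, na.rm = TRUE)
    scores$varianceRatio[ki] <- mean(vrBySeed, na.rm = TRUE)
    ok <- which(is.finite(silBySeed))
    if (length(ok))
      bestLabels[[ki]] <- labsBySeed[[ok[which.max(silBySeed[ok])]]]
  }
  if (all(!is.finite(scores$silhouette)))
    stop("no k in kRange produced a scorable partition")
  chosen <- .chooseK(scores$silhouette)
  labels <- bestLabels[[chosen]]
  new("ParcellationResult", labels = as.integer(labels),
      k = kRange[chosen], scoresByK = scores,
      eigenvalues = if (is.null(maxEig)) numeric() else maxEig,
      roiIndex = roiIndex(fp), seed = as.integer(seeds))
}

## Index of the selected k: first (smallest-k) maximum of the mean
## silhouette — exact ties break toward the smallest k.
.chooseK <- function(meanSilhouette) which.max(meanSilhouette)

## ---- cross-run alignment and probability maps ---------------------------

## Exhaustive optimal assignment maximizing the trace of a k x k overlap
## table under column permutation; exact for the k <= 8 scanned here.
.bestPermutation <- function(tab) {
  k <- nrow(tab)
  if (k > 8L) stop("exhaustive label assignment supports k <= 8")
  perms <- .allPermutations(k)
  overlaps <- vapply(perms, function(p) sum(tab[cbind(p, seq_len(k))]),
                     numeric(1))
  perms[[which.max(overlaps)]]
}

.allPermutations <- function(k) {
  if (k == 1L) return(list(1L))
  sub <- .allPermutations(k - 1L)
  out <- list()
  for (p in sub)
    for (pos in seq_len(k))
      out <- c(out, list(append(p, k, after = pos - 1L)))
  out
}

#' Align cluster labelings across runs
#'
#' The first labeling is the reference; every other labeling's labels are
#' permuted by the maximum-overlap optimal assignment on the k x k
#' contingency table against the reference.
#'
#' @param labelings list of integer label vectors over the same voxel set.
#' @param k number of clusters shared by all labelings.
#' @return list of aligned label vectors.
#' @export
alignRuns <- function(labelings, k) {
  if (!length(labelings)) stop("no labelings supplied")
  n <- length(labelings[[1]])
  for (l in labelings) {
    if (length(l) != n)
      stop("all labelings must cover the same voxel set")
    if (any(l < 1L | l > k))
      stop("labels must lie in 1..k")
  }
  ref <- factor(labelings[[1]], levels = seq_len(k))
  out <- labelings
  for (i in seq_along(labelings)[-1]) {
    tab <- table(ref, factor(labelings[[i]], levels = seq_len(k)))
    perm <- .bestPermutation(unclass(tab))  # perm[j]: new label of old j
    out[[i]] <- perm[labelings[[i]]]
  }
  out
}

#' Cluster probability maps across runs
#'
#' Per voxel, the fraction of (aligned) runs assigning it to each cluster.
#'
#' @param labelings list of aligned integer label vectors (see
#'   \code{\link{alignRuns}}).
#' @param k number of clusters.
#' @param roiIndex optional n x 3 voxel-index matrix carried along.
#' @param clusterOrder optional character names of the clusters.
#' @return a \linkS4class{ClusterProbabilityMap}.
#' @export
probabilityMaps <- function(labelings, k,
                            roiIndex = matrix(integer(), 0, 3),
                            clusterOrder = paste0("cluster", seq_len(k))) {
  if (!length(labelings)) stop("at least one labeling required")
  n <- length(labelings[[1]])
  prob <- matrix(0, n, k)
  for (l in labelings)
    prob <- prob + outer(l, seq_len(k), "==")
  prob <- prob / length(labelings)
  new("ClusterProbabilityMap", prob = prob, roiIndex = roiIndex,
      clusterOrder = clusterOrder)
}

## Permutation renumbering clusters 1..k by increasing mean world Y;
## ties broken by cluster size, then by lowest original label.
.caudorostralOrder <- function(labels, y, k) {
  meanY <- vapply(seq_len(k), function(c) mean(y[labels == c]), numeric(1))
  size <- vapply(seq_len(k), function(c) sum(labels == c), numeric(1))
  ord <- order(meanY, size, seq_len(k))
  perm <- integer(k)
  perm[ord] <- seq_len(k)  # perm[old] = new
  perm
}

#' @describeIn orderClustersCaudorostral Renumber the clusters of a
#'   parcellation 1..k by increasing mean world Y of their member voxels
#'   (1 = most caudal).
#' @export
setMethod("orderClustersCaudorostral", signature("ParcellationResult", "MaskSet"),
  function(result, masks) {
    y <- voxelWorldY(roiIndex(result), maskAffine(masks))
    perm <- .caudorostralOrder(clusterLabels(result), y, chosenK(result))
    initialize(result, labels = perm[clusterLabels(result)])
  })

#' @describeIn orderClustersCaudorostral Permute a label vector (with the
#'   voxel index rows supplied through \code{attr(result, "roiIndex")} or a
#'   plain matrix in the result list) is not supported; use the
#'   \code{ParcellationResult} method.
#' @export
setMethod("orderClustersCaudorostral", signature("integer", "MaskSet"),
  function(result, masks) {
    stop("supply a ParcellationResult; a bare label vector carries no voxel indices")
  })
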