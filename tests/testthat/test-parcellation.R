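# Spectral parcellation: similarity, k-NN graph, Laplacian embedding,
# K-means partition, scores, model selection, alignment and ordering.

test_that("row similarity matches the brute-force correlation formula", {
  set.seed(21)
  Z <- matrix(rnorm(12), 3, 4)
  A <- rowSimilarity(Z)
  expect_equal(A, bruteRowSim(Z), tolerance = 1e-12)
  expect_equal(diag(A), rep(1, 3))
  # identical rows -> 1; a row against its negation -> -1
  Z2 <- rbind(Z[1, ], Z[1, ], -Z[1, ])
  A2 <- rowSimilarity(Z2)
  expect_equal(A2[1, 2], 1)
  expect_equal(A2[1, 3], -1)
  # constant row -> similarity 0 against all others, with a message
  Z3 <- rbind(Z, rep(2, 4))
  expect_message(A3 <- rowSimilarity(Z3), "constant")
  expect_equal(A3[4, 1:3], rep(0, 3))
  expect_equal(A3[4, 4], 1)
})

test_that("knn graph keeps each row's top-k edges, floored and symmetrized", {
  A <- matrix(c(1, .9, .2, -.5,
                .9, 1, .3, .1,
                .2, .3, 1, .8,
                -.5, .1, .8, 1), 4, 4, byrow = TRUE)
  g <- knnGraph(A, 1L)
  W <- graphWeights(g)
  # brute force: top-1 per row -> edges (1,2),(2,1),(3,4),(4,3)
  expect_equal(W, matrix(c(0, .9, 0, 0,
                           .9, 0, 0, 0,
                           0, 0, 0, .8,
                           0, 0, .8, 0), 4, 4, byrow = TRUE))
  # k = n-1 on an all-positive matrix: nothing pruned
  Ap <- abs(A)
  gfull <- knnGraph(Ap, 3L)
  expected <- pmax(Ap, t(Ap)); diag(expected) <- 0
  expect_equal(graphWeights(gfull), expected)
  # all-negative similarities -> zero graph with a warning
  expect_warning(g0 <- knnGraph(-abs(A) - 0.1 + diag(1.1, 4), 2L),
                 "degenerate")
  expect_true(all(graphWeights(g0) == 0))
  expect_error(knnGraph(A, 4L), "kNN")
  expect_error(knnGraph(A, 0L), "kNN")
})

test_that("spectral partition recovers connected components", {
  W <- twoCliques(5L)
  expect_warning(spectralPartition(W, 2L, seed = 1L),
                 "connected components")
  labels <- suppressWarnings(spectralPartition(W, 2L, seed = 1L))
  comp <- rep(1:2, each = 5)
  expect_equal(mclust::adjustedRandIndex(labels, comp), 1)
  # eigenvalue count near zero equals the component count (3-block graph)
  W3 <- matrix(0, 9, 9)
  for (b in 0:2) W3[b * 3 + 1:3, b * 3 + 1:3] <- 1
  diag(W3) <- 0
  se <- suppressWarnings(spectralEmbedding(W3, 9L))
  expect_identical(sum(se$eigenvalues < 1e-8), 3L)
  expect_identical(se$nComponents, 3L)
})

test_that("spectral partition matches the brute-force best normalized cut", {
  # 10 nodes, two well-separated blocks with a weak bridge
  set.seed(33)
  W <- matrix(0, 10, 10)
  W[1:5, 1:5] <- 0.9; W[6:10, 6:10] <- 0.9
  W[5, 6] <- W[6, 5] <- 0.05
  diag(W) <- 0
  labels <- spectralPartition(W, 2L, seed = 1L)
  oracle <- bruteNormalizedCut(W)$partition
  expect_equal(mclust::adjustedRandIndex(labels, oracle), 1)
})

test_that("partition labels are equivariant under voxel permutation", {
  W <- twoCliques(6L, w = 0.8)
  set.seed(4)
  W <- W + matrix(runif(144, 0, 0.05), 12, 12)
  W <- (W + t(W)) / 2; diag(W) <- 0
  labels <- suppressWarnings(spectralPartition(W, 2L, seed = 3L))
  perm <- sample(12)
  labelsP <- suppressWarnings(spectralPartition(W[perm, perm], 2L, seed = 3L))
  expect_equal(mclust::adjustedRandIndex(labelsP, labels[perm]), 1)
  # determinism: same seed, identical labels
  expect_identical(as.integer(suppressWarnings(
    spectralPartition(W, 2L, seed = 3L))), as.integer(labels))
})

test_that("silhouette and variance ratio match brute force and conventions", {
  # two tight distant pairs -> silhouette 1
  X <- matrix(c(0, 0, 10, 10), 4, 1)
  sc <- scorePartition(X, c(1, 1, 2, 2))
  expect_equal(unname(sc["silhouette"]), 1)
  # 6-point hand set against the loop-based oracle
  set.seed(10)
  X6 <- matrix(rnorm(12), 6, 2)
  lab6 <- c(1, 1, 2, 2, 3, 3)
  sc6 <- scorePartition(X6, lab6)
  expect_equal(unname(sc6["silhouette"]), bruteSilhouette(X6, lab6),
               tolerance = 1e-12)
  # cross-check against the cluster package on the same instance
  sil <- cluster::silhouette(lab6, stats::dist(X6))
  expect_equal(unname(sc6["silhouette"]), mean(sil[, "sil_width"]),
               tolerance = 1e-12)
  # singleton cluster contributes 0
  scS <- scorePartition(X6, c(1, 1, 1, 1, 1, 2))
  silS <- cluster::silhouette(c(1, 1, 1, 1, 1, 2), stats::dist(X6))
  expect_equal(unname(scS["silhouette"]), mean(silS[, "sil_width"]),
               tolerance = 1e-12)
  # random labels on one Gaussian cloud score near zero
  sils <- vapply(1:20, function(s) {
    set.seed(s)
    X <- matrix(rnorm(60), 30, 2)
    scorePartition(X, sample(1:2, 30, replace = TRUE))["silhouette"]
  }, numeric(1))
  expect_lt(max(abs(sils)), 0.1)
  # variance ratio is nonnegative and matches a direct computation
  expect_gte(unname(sc6["varianceRatio"]), 0)
  mu <- colMeans(X6)
  wit <- sum(vapply(1:3, function(c) {
    Xc <- X6[lab6 == c, , drop = FALSE]
    sum(sweep(Xc, 2, colMeans(Xc))^2)
  }, numeric(1)))
  bet <- sum(vapply(1:3, function(c) {
    Xc <- X6[lab6 == c, , drop = FALSE]
    nrow(Xc) * sum((colMeans(Xc) - mu)^2)
  }, numeric(1)))
  expect_equal(unname(sc6["varianceRatio"]), bet / wit, tolerance = 1e-12)
})

test_that("selectK finds the planted block count and ties break small", {
  # two perfect fingerprint blocks -> chosen k = 2
  set.seed(12)
  v1 <- rnorm(30); v2 <- rnorm(30)
  Z <- rbind(matrix(rep(v1, 8), 8, byrow = TRUE) + rnorm(240, sd = .05),
             matrix(rep(v2, 8), 8, byrow = TRUE) + rnorm(240, sd = .05))
  fp <- new("FingerprintMatrix", z = Z,
            roiIndex = cbind(1:16, 1L, 1L), targetIndex = cbind(1:30, 1L, 1L))
  res <- suppressWarnings(selectK(fp, kRange = 2:5, kNN = 3L, seeds = 1:2))
  expect_identical(chosenK(res), 2L)
  expect_identical(nrow(scoreTable(res)), 4L)
  expect_true(all(scoreTable(res)$silhouette <= 1 + 1e-12))
  # exact tie in mean silhouette -> smallest k chosen
  expect_identical(sulcparc:::.chooseK(c(0.7, 0.7, 0.5)), 1L)
  expect_error(selectK(fp, kRange = integer()), "kRange")
})

test_that("label alignment maximizes overlap against exhaustive search", {
  set.seed(7)
  ref <- sample(1:3, 40, replace = TRUE)
  permuted <- c(3L, 1L, 2L)[ref]  # relabeled copy
  aligned <- alignRuns(list(ref, permuted), 3L)
  expect_identical(aligned[[2]], ref)
  # noisy labeling: alignment never decreases overlap with the reference
  noisy <- permuted
  noisy[1:8] <- sample(1:3, 8, replace = TRUE)
  alignedN <- alignRuns(list(ref, noisy), 3L)
  expect_gte(sum(alignedN[[2]] == ref), sum(noisy == ref))
  # hand 3x3 contingency: compare against explicit search over all 3!
  tab <- matrix(c(10, 2, 0,
                  1, 8, 3,
                  0, 1, 9), 3, 3, byrow = TRUE)
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  vals <- vapply(perms, function(p) sum(tab[cbind(p, 1:3)]), numeric(1))
  best <- perms[[which.max(vals)]]
  expect_identical(sulcparc:::.bestPermutation(tab), as.integer(best))
  expect_error(alignRuns(list(ref, noisy[-1]), 3L), "same voxel set")
})

test_that("probability maps count aligned runs per voxel", {
  lab <- rep(2L, 10)
  labs <- c(replicate(9, lab, simplify = FALSE),
            replicate(3, rep(1L, 10), simplify = FALSE))
  pm <- probabilityMaps(labs, 3L)
  expect_equal(clusterProbabilities(pm)[, 2], rep(0.75, 10))
  expect_equal(rowSums(clusterProbabilities(pm)), rep(1, 10))
  # identical labelings -> all probabilities 0 or 1
  pm2 <- probabilityMaps(replicate(5, lab, simplify = FALSE), 3L)
  expect_true(all(clusterProbabilities(pm2) %in% c(0, 1)))
})

test_that("clusters are renumbered caudo-rostrally and reverse with the axis", {
  cfg <- smallPhantomConfig(nVolumes = 120L, nRuns = 1L, seed = 6L)
  m <- makePhantom(cfg)
  run <- preprocessRun(simulateRun(m, cfg, 1L), m)
  fp <- fingerprintMatrix(run, m)
  res <- suppressWarnings(selectK(fp, kRange = 2:4, seeds = 1L))
  expect_identical(chosenK(res), 3L)
  ordered <- orderClustersCaudorostral(res, m)
  # planted zones are numbered caudo-rostrally already
  expect_equal(clusterLabels(ordered), zoneLabels(m))
  # already-ordered labels unchanged
  expect_identical(clusterLabels(orderClustersCaudorostral(ordered, m)),
                   clusterLabels(ordered))
  # reversing the Y axis reverses the ordering
  flipped <- m
  flipped@affine[2, ] <- -flipped@affine[2, ]
  rev <- orderClustersCaudorostral(ordered, flipped)
  expect_equal(clusterLabels(rev),
               (chosenK(res) + 1L) - clusterLabels(ordered))
})
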