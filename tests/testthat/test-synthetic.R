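# Phantom and sulcal-table generators: mask geometry, planted structure,
# reproducibility, and convergence of presence frequencies.

test_that("phantom masks are pairwise consistent by construction", {
  cfg <- smallPhantomConfig()
  m <- makePhantom(cfg)
  expect_true(all(roiMask(m) & gmMask(m) | !roiMask(m)))  # ROI inside GM
  expect_false(any(wmMask(m) & gmMask(m)))
  expect_false(any(csfMask(m) & gmMask(m)))
  for (acc in list(roiMask, gmMask, wmMask, csfMask))
    expect_gt(sum(acc(m)), 0)
  # ROI is an elongated contiguous strip along Y
  idx <- which(roiMask(m), arr.ind = TRUE)
  expect_setequal(idx[, 2], min(idx[, 2]):max(idx[, 2]))
  expect_gt(diff(range(idx[, 2])), diff(range(idx[, 1])))
  expect_gt(diff(range(idx[, 2])), diff(range(idx[, 3])))
})

test_that("zone boundaries partition the ROI into the expected zones", {
  cfg <- smallPhantomConfig()  # 2 boundaries -> 3 zones
  m <- makePhantom(cfg)
  # brute force: world Y of each ROI voxel from the affine, counted per zone
  idx <- which(roiMask(m), arr.ind = TRUE)
  y <- apply(idx, 1, function(v)
    (maskAffine(m) %*% c(v - 1, 1))[2])
  zb <- cfg@zoneBoundaries
  bruteZone <- ifelse(y < zb[1], 1L, ifelse(y < zb[2], 2L, 3L))
  expect_identical(sort(unique(zoneLabels(m))), 1:3)
  expect_true(all(table(bruteZone) > 0))
  expect_equal(as.vector(table(zoneLabels(m))), as.vector(table(bruteZone)))
  expect_equal(zoneLabels(m), bruteZone)
})

test_that("undersized grids and misplaced boundaries are rejected", {
  expect_error(makePhantom(smallPhantomConfig(gridShape = c(10L, 10L, 10L))),
               "too small")
  expect_error(makePhantom(smallPhantomConfig(zoneBoundaries = c(-100, 0))),
               "interior")
  expect_error(phantomConfig(nVolumes = 4L), "nVolumes")
  expect_error(phantomConfig(ar1 = 1), "ar1")
  expect_error(phantomConfig(zoneBoundaries = c(3, 1)), "increasing")
})

test_that("run simulation is reproducible and carries the study geometry", {
  cfg <- smallPhantomConfig(nVolumes = 40L, nRuns = 2L)
  m <- makePhantom(cfg)
  runs1 <- simulateRuns(m, cfg)
  runs2 <- simulateRuns(m, cfg)
  expect_length(runs1, 2L)
  expect_identical(runData(runs1[[2]]), runData(runs2[[2]]))
  expect_identical(runMotion(runs1[[1]]), runMotion(runs2[[1]]))
  expect_identical(dim(runData(runs1[[1]])), c(cfg@gridShape, 40L))
  expect_identical(dim(runMotion(runs1[[1]])), c(40L, 6L))
  # runs differ from each other
  expect_false(identical(runData(runs1[[1]]), runData(runs1[[2]])))
  # single-run generation matches the list path
  expect_identical(runData(simulateRun(m, cfg, 2L)), runData(runs1[[2]]))
})

test_that("with no planted signal, preprocessed ROI voxels are uncorrelated", {
  cfg <- smallPhantomConfig(nVolumes = 150L, nRuns = 1L, signalSd = 0)
  m <- makePhantom(cfg)
  # fwhm = 0: smoothing deliberately induces local spatial correlation, so
  # the pure-noise check applies to the band-passed, nuisance-cleaned data
  run <- preprocessRun(simulateRun(m, cfg, 1L), m, fwhm = 0)
  ts <- extractTimeseries(run, roiMask(m))
  z1 <- zoneLabels(m) == 1L
  C <- cor(ts[, z1])
  meanOff <- mean(C[upper.tri(C)])
  expect_lt(abs(meanOff), 0.05)
})

test_that("planted zones are recovered by the full pipeline at default SNR", {
  cfg <- smallPhantomConfig(nVolumes = 120L, nRuns = 1L, seed = 5L)
  m <- makePhantom(cfg)
  run <- preprocessRun(simulateRun(m, cfg, 1L), m)
  fp <- fingerprintMatrix(run, m)
  res <- suppressWarnings(selectK(fp, seeds = 1:2))
  ari <- mclust::adjustedRandIndex(clusterLabels(res), zoneLabels(m))
  expect_gte(ari, 0.9)
})

test_that("sulcal tables have the study shape and respect degenerate probabilities", {
  preset <- studyPreset()
  rec <- simulateSulcalTables(preset$species, preset$landmarks, seed = 2L)
  # 160 hemispheres per species
  hemis <- with(rec, tapply(paste(subject, hemisphere), species,
                            function(x) length(unique(x))))
  expect_true(all(hemis == 160L))
  # presence probability 1 -> present in 100% of records
  pm <- rec[rec$feature == "PMFS-P", ]
  expect_true(all(pm$present))
  expect_true(all(!is.na(pm$caudal_y)))
  expect_true(all(pm$caudal_y <= pm$rostral_y))
  # absent records carry no coordinates
  ab <- rec[!rec$present & rec$type == "sulcus", ]
  expect_true(all(is.na(ab$caudal_y)))
  # subject IDs shared across hemispheres
  expect_true(all(table(pm$subject) == 2L))
  # same seed, bit-identical output
  expect_identical(rec, simulateSulcalTables(preset$species,
                                             preset$landmarks, seed = 2L))
  # unknown anchor landmark is a vocabulary error
  bad <- preset$species
  bad[[1]]@anchor[] <- "genu_caudal"
  bad[[1]]@anchor["PMFS-P"] <- "not_a_landmark"
  expect_error(simulateSulcalTables(bad, preset$landmarks, seed = 1L),
               "unknown landmark")
})

test_that("simulated presence frequencies converge to the configured probability", {
  p <- 0.54; n <- 160L
  lo <- stats::qbinom(0.025, n, p); hi <- stats::qbinom(0.975, n, p)
  inCI <- vapply(seq_len(500), function(s) {
    cf <- speciesConfig(species = "macaque", nSubjects = 80L,
                        presenceProb = c(s1 = p),
                        anchor = c(s1 = "anterior_commissure"),
                        jitterSd = 1, apExtent = 60)
    rec <- simulateSulcalTables(list(cf), landmarkSet(), seed = s)
    k <- sum(rec$present)
    k >= lo && k <= hi  # exact central 95% interval of Binomial(n, p)
  }, logical(1))
  expect_gte(mean(inCI), 0.95)
})

test_that("study preset matches the acquisition and species constants", {
  preset <- studyPreset()
  ph <- preset$phantom
  expect_equal(ph@tr, 1.8)
  expect_identical(ph@nVolumes, 400L)
  expect_identical(ph@nRuns, 12L)
  expect_equal(ph@voxelSize, 1.8)
  ext <- vapply(preset$species, apExtent, numeric(1))
  expect_equal(unname(ext), c(175, 110, 85, 60))
  expect_identical(vapply(preset$species, function(s) s@nSubjects,
                          integer(1)) |> unname(), rep(80L, 4))
  # configs pass their own validity
  expect_true(validObject(ph))
  for (s in preset$species) expect_true(validObject(s))
  expect_true(validObject(preset$landmarks))
  # phantom zone boundaries sit at the macaque landmark levels
  expect_equal(ph@zoneBoundaries,
               c(landmarkY(preset$landmarks, "macaque", "genu_rostral"),
                 landmarkY(preset$landmarks, "macaque",
                           "cgs_suros_sos_junction")))
})
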