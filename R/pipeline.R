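## End-to-end orchestration: simulate -> preprocess -> fingerprint ->
## parcellate -> probability maps, and simulate tables -> morphometry,
## from a single validated config with one global seed.

.defaultPipelineConfig <- function() {
  preset <- studyPreset()
  ph <- preset$phantom
  list(
    seed = 42L,
    fmri = list(
      phantom = list(
        gridShape = as.integer(ph@gridShape), voxelSize = ph@voxelSize,
        tr = ph@tr, nVolumes = ph@nVolumes, nRuns = ph@nRuns,
        zoneBoundaries = ph@zoneBoundaries, signalSd = ph@signalSd,
        noiseSd = ph@noiseSd, ar1 = ph@ar1),
      preprocess = list(low = 0.01, high = 0.1, fwhm = 4),
      parcellation = list(kRange = 2:7, kNN = NULL, seeds = 1:5,
                          nInit = 50L)),
    morphometry = list(records = NULL, assignCandidates = NULL))
}

## Recursively check cfg against the default structure; unknown keys are
## rejected, known keys override defaults.
.mergeConfig <- function(default, cfg, path = "") {
  if (is.null(cfg)) return(default)
  unknown <- setdiff(names(cfg), names(default))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "))
  for (nm in names(cfg)) {
    if (is.list(default[[nm]]) && !is.null(names(default[[nm]])))
      default[[nm]] <- .mergeConfig(default[[nm]], cfg[[nm]],
                                    paste0(path, ".", nm))
    else default[[nm]] <- cfg[[nm]]
  }
  default
}

#' Build and validate a pipeline configuration
#'
#' Starts from the study-preset defaults and overrides them with the
#' supplied nested list or YAML file; unknown keys are rejected.
#'
#' @param config nested list, path to a YAML file, or NULL for the
#'   defaults.
#' @param seed optional override of the global seed.
#' @return validated nested configuration list.
#' @export
pipelineConfig <- function(config = NULL, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out <- .mergeConfig(.defaultPipelineConfig(), config)
  if (!is.null(seed)) out$seed <- as.integer(seed)
  out
}

.phantomFromConfig <- function(cfg, seed) {
  p <- cfg$fmri$phantom
  phantomConfig(gridShape = p$gridShape, voxelSize = p$voxelSize, tr = p$tr,
                nVolumes = p$nVolumes, nRuns = p$nRuns,
                zoneBoundaries = p$zoneBoundaries, signalSd = p$signalSd,
                noiseSd = p$noiseSd, ar1 = p$ar1, seed = seed)
}

#' Run the full rs-fMRI parcellation pipeline
#'
#' Simulates the phantom runs, preprocesses each (band-pass, nuisance
#' regression, smoothing), builds fingerprint matrices, selects the number
#' of parcels per run by mean silhouette, re-partitions every run at the
#' modal selected k, aligns labels across runs, orders clusters
#' caudo-rostrally and computes probability maps. All intermediates are
#' written eagerly under \code{outDir}; rerunning with the same seed
#' reproduces every artifact bit-identically.
#'
#' @param config see \code{\link{pipelineConfig}}.
#' @param outDir output directory.
#' @param seed global seed (overrides the config's).
#' @param verbose log each stage with its parameters.
#' @return invisibly, a list: \code{modalK}, \code{perRun} (per-run
#'   \linkS4class{ParcellationResult}s), \code{probMap}
#'   (\linkS4class{ClusterProbabilityMap}), \code{consensus} labels,
#'   \code{ariToConsensus}, \code{scores} (long per-run score table),
#'   \code{masks}.
#' @export
runFmriPipeline <- function(config = NULL, outDir = tempfile("fmri_"),
                            seed = NULL, verbose = FALSE) {
  cfg <- pipelineConfig(config, seed = seed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(cfg, file.path(outDir, "config_resolved.yaml"))
  say <- function(...) if (verbose) message(sprintf(...))

  pcfg <- .phantomFromConfig(cfg, cfg$seed)
  masks <- makePhantom(pcfg)
  writeMasks(masks, file.path(outDir, "masks"))
  say("phantom: %s grid, %d runs x %d volumes",
      paste(pcfg@gridShape, collapse = "x"), pcfg@nRuns, pcfg@nVolumes)

  pp <- cfg$fmri$preprocess
  pr <- cfg$fmri$parcellation
  runSeeds <- deriveSeeds(pcfg@seed, pcfg@nRuns)
  results <- vector("list", pcfg@nRuns)
  fps <- vector("list", pcfg@nRuns)
  for (r in seq_len(pcfg@nRuns)) {
    run <- simulateRun(masks, pcfg, runIndex = r, seed = runSeeds[r])
    writeRun(run, file.path(outDir, "runs", sprintf("run%02d", r)),
             affine = maskAffine(masks))
    say("run %d: band-pass %.3g-%.3g Hz, 8+1 confounds, FWHM %g mm",
        r, pp$low, pp$high, pp$fwhm)
    run <- preprocessRun(run, masks, low = pp$low, high = pp$high,
                         fwhm = pp$fwhm)
    writeRun(run, file.path(outDir, "runs", sprintf("run%02d_pp", r)),
             affine = maskAffine(masks))
    fp <- fingerprintMatrix(run, masks)
    writeFingerprints(fp, file.path(outDir, "fingerprints",
                                    sprintf("run%02d", r)))
    results[[r]] <- suppressWarnings(
      selectK(fp, kRange = pr$kRange, kNN = pr$kNN, seeds = pr$seeds,
              nInit = pr$nInit))
    fps[[r]] <- fp
    say("run %d: selected k = %d", r, chosenK(results[[r]]))
  }

  ks <- vapply(results, chosenK, integer(1))
  modalK <- as.integer(names(sort(table(ks), decreasing = TRUE))[1])
  say("modal selected k across runs: %d", modalK)

  ## per-run labelings at the globally selected k (shared label space)
  labelings <- lapply(fps, function(fp) {
    W <- knnGraph(rowSimilarity(fp),
                  if (is.null(pr$kNN)) defaultKnn(nrow(fingerprintValues(fp)))
                  else pr$kNN)
    as.integer(suppressWarnings(
      spectralPartition(W, modalK, seed = pr$seeds[1], nInit = pr$nInit)))
  })
  ## caudo-rostral ordering of the reference, then max-overlap alignment
  refRes <- new("ParcellationResult", labels = labelings[[1]], k = modalK,
                scoresByK = data.frame(), eigenvalues = numeric(),
                roiIndex = roiIndex(fps[[1]]),
                seed = as.integer(pr$seeds[1]))
  labelings[[1]] <- clusterLabels(orderClustersCaudorostral(refRes, masks))
  aligned <- alignRuns(labelings, modalK)
  clusterNames <- paste0("cluster", seq_len(modalK))
  if (modalK == 3L) clusterNames <- c("post", "mid", "ant")
  probMap <- probabilityMaps(aligned, modalK, roiIndex = roiIndex(fps[[1]]),
                             clusterOrder = clusterNames)
  consensus <- max.col(clusterProbabilities(probMap), ties.method = "first")
  ari <- vapply(aligned, function(l)
    mclust::adjustedRandIndex(l, consensus), numeric(1))

  ## artifacts
  writeRoiVolume(consensus, roiIndex(probMap), masks,
                 file.path(outDir, "parcels_consensus.nii"),
                 datatype = "uint8")
  for (c in seq_len(modalK))
    writeRoiVolume(clusterProbabilities(probMap)[, c], roiIndex(probMap),
                   masks, file.path(outDir, sprintf("probmap_%s.nii",
                                                    clusterNames[c])))
  scores <- do.call(rbind, lapply(seq_along(results), function(r)
    cbind(run = r, scoreTable(results[[r]]))))
  write.csv(scores, file.path(outDir, "scores.csv"), row.names = FALSE)
  probDf <- cbind(as.data.frame(roiIndex(probMap)),
                  as.data.frame(clusterProbabilities(probMap)))
  names(probDf) <- c("i", "j", "k", clusterNames)
  write.csv(probDf, file.path(outDir, "probmap_summary.csv"),
            row.names = FALSE)
  report <- list(modalK = modalK, selectedKPerRun = as.integer(ks),
                 ariToConsensus = as.numeric(ari),
                 silhouetteByK = stats::aggregate(
                   silhouette ~ k, data = scores, FUN = mean)$silhouette,
                 seed = cfg$seed)
  yaml::write_yaml(report, file.path(outDir, "report.yaml"))

  invisible(list(modalK = modalK, perRun = results, probMap = probMap,
                 consensus = consensus, ariToConsensus = ari,
                 scores = scores, masks = masks))
}

#' Run the cross-species morphometry pipeline
#'
#' Simulates (or loads) the four-species sulcal tables, then writes
#' occurrence frequencies, landmark assignments, species-effect tests and
#' post hoc pairwise contrasts as CSV tables plus a text log.
#'
#' @inheritParams runFmriPipeline
#' @return invisibly, a list: \code{records}, \code{frequencies},
#'   \code{assignments}, \code{tests} (one row per feature),
#'   \code{posthoc}.
#' @export
runMorphometryPipeline <- function(config = NULL,
                                   outDir = tempfile("morpho_"),
                                   seed = NULL, verbose = FALSE) {
  cfg <- pipelineConfig(config, seed = seed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(cfg, file.path(outDir, "config_resolved.yaml"))
  say <- function(...) if (verbose) message(sprintf(...))
  logLines <- character()

  preset <- studyPreset(seed = cfg$seed)
  landmarks <- preset$landmarks
  if (is.null(cfg$morphometry$records)) {
    records <- simulateSulcalTables(preset$species, landmarks,
                                    seed = cfg$seed)
    say("simulated %d records across %d species", nrow(records), 4L)
  } else {
    records <- readSulcalRecords(cfg$morphometry$records)
    say("loaded %d records from %s", nrow(records), cfg$morphometry$records)
  }
  writeSulcalRecords(records, file.path(outDir, "records.csv"))
  writeLandmarks(landmarks, file.path(outDir, "landmarks.csv"))

  if (!nrow(records) || !length(unique(records$feature)))
    stop("record table contains no sulcal features (empty feature column)")

  freqs <- occurrenceFrequency(records)
  write.csv(freqs, file.path(outDir, "frequencies.csv"), row.names = FALSE)

  sulci <- unique(records$feature[records$type == "sulcus"])
  assignments <- do.call(rbind, lapply(sulci, function(su) {
    rec <- records[records$feature == su & !is.na(records$caudal_y), ,
                   drop = FALSE]
    if (!nrow(rec)) return(NULL)
    a <- assignLandmark(rec, landmarks,
                        candidates = cfg$morphometry$assignCandidates)
    data.frame(feature = su, landmark = a$landmark, tie = a$tie,
               median = a$medians$median[a$medians$landmark == a$landmark])
  }))
  write.csv(assignments, file.path(outDir, "landmark_assignments.csv"),
            row.names = FALSE)

  features <- unique(records$feature)
  tests <- NULL; posthoc <- NULL
  for (ft in features) {
    rec <- records[records$feature == ft, , drop = FALSE]
    if (length(unique(rec$present)) < 2L) {
      logLines <- c(logLines, sprintf(
        "%s: presence is constant; species test skipped", ft))
      next
    }
    tr <- withCallingHandlers(
      speciesEffectTest(rec),
      warning = function(w) {
        logLines <<- c(logLines, sprintf("%s: %s", ft, conditionMessage(w)))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        logLines <<- c(logLines, sprintf("%s: %s", ft,
                                         trimws(conditionMessage(m))))
        invokeRestart("muffleMessage")
      })
    tests <- rbind(tests, data.frame(
      feature = ft, statistic = tr@statistic, numDf = tr@numDf,
      denDf = tr@denDf, p = tr@pValue, method = tr@method))
    ph <- suppressWarnings(suppressMessages(
      pairwisePosthoc(rec, species = unique(records$species))))
    posthoc <- rbind(posthoc, cbind(feature = ft, ph))
    say("%s: chisq = %.3g, NumDF = %d, p = %.3g", ft, tr@statistic,
        tr@numDf, tr@pValue)
  }
  write.csv(tests, file.path(outDir, "species_tests.csv"), row.names = FALSE)
  write.csv(posthoc, file.path(outDir, "posthoc.csv"), row.names = FALSE)
  writeLines(c(sprintf("seed: %d", cfg$seed), logLines),
             file.path(outDir, "morphometry.log"))

  invisible(list(records = records, frequencies = freqs,
                 assignments = assignments, tests = tests,
                 posthoc = posthoc))
}
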