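## Synthetic-data module: phantom fMRI runs with planted connectivity zones
## and four-species sulcal tables with known generating parameters.

#' Construct a phantom configuration
#'
#' @param gridShape integer(3), grid size in voxels.
#' @param voxelSize isotropic voxel size in mm.
#' @param tr repetition time in seconds.
#' @param nVolumes time points per run.
#' @param nRuns number of runs.
#' @param zoneBoundaries strictly increasing world-Y levels (mm) splitting
#'   the ROI into contiguous caudo-rostral zones.
#' @param signalSd,noiseSd standard deviations of planted signal and noise.
#' @param ar1 lag-1 autocorrelation of the noise, in [0, 1).
#' @param seed master seed for run generation.
#' @return a \linkS4class{PhantomConfig}.
#' @export
phantomConfig <- function(gridShape = c(24L, 28L, 20L), voxelSize = 1.8,
                          tr = 1.8, nVolumes = 400L, nRuns = 12L,
                          zoneBoundaries = c(-3.6, 9.0),
                          signalSd = 1, noiseSd = 1, ar1 = 0.3,
                          seed = 42L) {
  new("PhantomConfig", gridShape = as.integer(gridShape),
      voxelSize = voxelSize, tr = tr, nVolumes = as.integer(nVolumes),
      nRuns = as.integer(nRuns), zoneBoundaries = as.numeric(zoneBoundaries),
      signalSd = signalSd, noiseSd = noiseSd, ar1 = ar1,
      seed = as.integer(seed))
}

#' Construct a species configuration for the sulcal-table generator
#'
#' @param species species name.
#' @param nSubjects number of subjects (brains); each contributes two
#'   hemispheres.
#' @param presenceProb named numeric, per-sulcus presence probability.
#' @param junctionProb named numeric, per-junction probability.
#' @param anchor named character mapping each sulcus to the landmark
#'   anchoring its caudal extremity.
#' @param jitterSd SD (mm) of Gaussian jitter of feature Y around the anchor.
#' @param apExtent anteroposterior extent of the standard brain in mm.
#' @param hemispheres hemispheres per subject.
#' @return a \linkS4class{SpeciesConfig}.
#' @export
speciesConfig <- function(species, nSubjects, presenceProb,
                          junctionProb = numeric(), anchor,
                          jitterSd, apExtent, hemispheres = 2L) {
  new("SpeciesConfig", species = species, nSubjects = as.integer(nSubjects),
      hemispheres = as.integer(hemispheres), presenceProb = presenceProb,
      junctionProb = junctionProb, anchor = anchor, jitterSd = jitterSd,
      apExtent = apExtent)
}

## Caudo-rostral positions of the landmark vocabulary as fractions of the
## anteroposterior extent. The source study reads these off each species'
## standard-space anatomy; no numeric table is published, so these are
## synthetic values with the correct ordering, scaled per species.
.LANDMARK_FRACTIONS <- c(
  mammillary_rostral     = -0.35,
  anterior_commissure    = -0.25,
  optic_chiasma_rostral  = -0.18,
  genu_caudal            = -0.12,
  genu_rostral           = -0.06,
  rostrum_caudal         =  0.00,
  cgs_suros_sos_junction =  0.15)

#' Build a landmark table for a set of species
#'
#' Y levels are synthetic: fixed caudo-rostral fractions of each species'
#' anteroposterior extent (no numeric landmark table is published for the
#' real anatomies).
#'
#' @param apExtent named numeric, anteroposterior extent (mm) per species.
#' @return a \linkS4class{LandmarkSet}.
#' @export
landmarkSet <- function(apExtent = c(human = 175, chimpanzee = 110,
                                     baboon = 85, macaque = 60)) {
  tb <- do.call(rbind, lapply(names(apExtent), function(sp) {
    data.frame(species = sp, landmark = names(.LANDMARK_FRACTIONS),
               y = unname(.LANDMARK_FRACTIONS) * apExtent[[sp]])
  }))
  rownames(tb) <- NULL
  new("LandmarkSet", table = tb, apExtent = apExtent)
}

#' Look up a landmark's Y level for one species
#'
#' @param landmarks a \linkS4class{LandmarkSet}.
#' @param species species name.
#' @param landmark landmark name (must be in the fixed vocabulary).
#' @return Y level in mm.
#' @export
landmarkY <- function(landmarks, species, landmark) {
  tb <- landmarkTable(landmarks)
  hit <- tb$species == species & tb$landmark == landmark
  if (!any(hit))
    stop("unknown landmark '", landmark, "' for species '", species, "'")
  tb$y[hit][1]
}

## Target-network block slots (index ranges relative to a grid), one per zone.
.targetSlots <- function(gridShape) {
  ny <- gridShape[2]
  jSegs <- Filter(function(j) max(j) <= ny - 2, list(4:9, 12:17, 20:25))
  slots <- list()
  for (j in jSegs)
    slots <- c(slots, list(list(i = 4:8, j = j, k = 10:14)),
               list(list(i = 16:20, j = j, k = 10:14)))
  slots
}

.fillBox <- function(mask, i, j, k, value = TRUE) {
  mask[i, j, k] <- value
  mask
}

#' Build the phantom mask set
#'
#' Lays out, on one grid, an elongated ROI strip along the anteroposterior
#' (Y) axis inside a gray-matter slab, plus disjoint white-matter and CSF
#' compartments and one gray-matter "target network" block per ROI zone.
#' Voxel centers map to world mm via an affine centered on the grid.
#'
#' @param config a \linkS4class{PhantomConfig}.
#' @return a \linkS4class{PhantomMasks} (a \linkS4class{MaskSet} carrying the
#'   planted zone labels and target networks).
#' @export
makePhantom <- function(config) {
  validObject(config)
  g <- config@gridShape
  if (g[1] < 22L || g[2] < 16L || g[3] < 18L)
    stop("grid too small to place ROI, GM, WM and CSF compartments ",
         "(need at least 22 x 16 x 18 voxels)")
  vs <- config@voxelSize
  ## voxel center (0-based index) -> world mm, grid-centered
  affine <- diag(c(vs, vs, vs, 1))
  affine[1:3, 4] <- -(g - 1) / 2 * vs

  roi <- gm <- wm <- csf <- array(FALSE, g)
  gm  <- .fillBox(gm, 3:(g[1] - 2), 3:(g[2] - 2), 9:(g[3] - 2))
  wm  <- .fillBox(wm, 4:9, 4:9, 3:7)
  csf <- .fillBox(csf, 15:20, 4:9, 3:7)
  ic <- round(g[1] / 2)
  roi <- .fillBox(roi, (ic - 1):(ic + 1), 5:(g[2] - 2), 12:14)

  zb <- config@zoneBoundaries
  nZones <- length(zb) + 1L
  yRoi <- voxelWorldY(maskCoords(roi), affine)
  if (length(zb) && (min(zb) <= min(yRoi) || max(zb) >= max(yRoi)))
    stop("zone boundaries must be interior to the ROI's Y range [",
         round(min(yRoi), 2), ", ", round(max(yRoi), 2), "] mm")
  zone <- as.integer(findInterval(yRoi, zb) + 1L)

  slots <- .targetSlots(g)
  if (nZones > length(slots))
    stop("grid too small to place ", nZones, " target networks")
  targets <- array(0L, g)
  for (z in seq_len(nZones)) {
    s <- slots[[z]]
    targets[s$i, s$j, s$k] <- z
  }
  targets[!gm | roi] <- 0L  # safety: targets live in GM, outside the ROI

  out <- new("PhantomMasks", roi = roi, gm = gm, wm = wm, csf = csf,
             affine = affine, zoneLabels = zone, targetNetworks = targets)
  validObject(out)
  out
}

## Band-limited latent time course: sum of sinusoids with random frequencies
## in [fLow, fHigh] Hz and random phases/amplitudes, standardized to SD 1.
.latentSignal <- function(t_len, tr, fLow = 0.01, fHigh = 0.1, nComp = 6L) {
  tt <- (seq_len(t_len) - 1) * tr
  f <- runif(nComp, fLow, fHigh)
  a <- runif(nComp, 0.5, 1.5)
  ph <- runif(nComp, 0, 2 * pi)
  s <- drop(sin(outer(tt, 2 * pi * f) + rep(ph, each = t_len)) %*% a)
  as.numeric(scale(s))
}

## Slow drift: very-low-frequency sinusoids plus a linear trend, SD 1.
.slowDrift <- function(t_len, tr) {
  tt <- (seq_len(t_len) - 1) * tr
  f <- runif(2, 0.001, 0.008)
  s <- sin(2 * pi * f[1] * tt + runif(1, 0, 2 * pi)) +
       0.7 * sin(2 * pi * f[2] * tt + runif(1, 0, 2 * pi)) +
       seq(-1, 1, length.out = t_len) * runif(1, 0.3, 1)
  as.numeric(scale(s))
}

#' Simulate resting-state runs on a phantom
#'
#' Each ROI zone and its dedicated gray-matter target network share a latent
#' band-limited (0.01-0.1 Hz) time course scaled by \code{signalSd}. All
#' voxels receive AR(1)-plus-white noise, a baseline offset, and
#' motion-coupled and compartment-drift artifacts; WM and CSF compartments
#' carry strong copies of their drifts so that nuisance regression has real
#' work to do. Fully reproducible from \code{config@seed}.
#'
#' @param masks a \linkS4class{PhantomMasks} from \code{\link{makePhantom}}.
#' @param config the \linkS4class{PhantomConfig} used to build the masks.
#' @return list of \linkS4class{Run4D} objects of length \code{config@nRuns}.
#' @export
simulateRuns <- function(masks, config) {
  stopifnot(is(masks, "PhantomMasks"))
  validObject(config)
  runSeeds <- deriveSeeds(config@seed, config@nRuns)
  lapply(seq_len(config@nRuns), function(r)
    simulateRun(masks, config, runIndex = r, seed = runSeeds[r]))
}

#' Simulate a single phantom run
#'
#' @inheritParams simulateRuns
#' @param runIndex 1-based run number (used for the run identifier).
#' @param seed RNG seed for this run; defaults to the run's substream of
#'   \code{config@seed}.
#' @return a \linkS4class{Run4D}.
#' @export
simulateRun <- function(masks, config, runIndex = 1L,
                        seed = deriveSeeds(config@seed, runIndex)[runIndex]) {
  g <- config@gridShape
  t_len <- config@nVolumes
  nvox <- prod(g)
  nZones <- length(config@zoneBoundaries) + 1L
  withSeed(seed, {
    zoneSig <- lapply(seq_len(nZones), function(z)
      .latentSignal(t_len, config@tr))
    csfD <- .slowDrift(t_len, config@tr)
    wmD  <- .slowDrift(t_len, config@tr)
    motion <- matrix(rnorm(t_len * 6, sd = 0.02), t_len, 6)
    motion <- apply(motion, 2, cumsum)
    m1 <- as.numeric(scale(motion[, 1]))

    white <- matrix(rnorm(t_len * nvox,
                          sd = config@noiseSd * sqrt(1 - config@ar1^2)),
                    t_len, nvox)
    noise <- if (config@ar1 > 0)
      stats::filter(white, config@ar1, method = "recursive") else white
    mat <- matrix(100, t_len, nvox) + as.matrix(noise)

    ## global artifacts (removed downstream by nuisance regression)
    art <- config@noiseSd * (0.5 * csfD + 0.5 * wmD + 0.5 * m1)
    mat <- mat + art
    mat[, which(masks@wm)]  <- mat[, which(masks@wm)]  + 2 * config@noiseSd * wmD
    mat[, which(masks@csf)] <- mat[, which(masks@csf)] + 2 * config@noiseSd * csfD

    ## planted zone signals: ROI zones and their target networks
    roiLin <- which(masks@roi)
    for (z in seq_len(nZones)) {
      sig <- config@signalSd * zoneSig[[z]]
      vox <- c(roiLin[masks@zoneLabels == z], which(masks@targetNetworks == z))
      mat[, vox] <- mat[, vox] + sig
    }

    new("Run4D", data = array(as.vector(t(mat)), c(g, t_len)),
        tr = config@tr, motion = motion, subject = "phantom",
        hemisphere = "L", run = sprintf("run%02d", runIndex))
  })
}

#' Simulate four-species sulcal feature tables
#'
#' One record per (subject, hemisphere, sulcus): presence is Bernoulli with
#' the species' per-sulcus probability; when present, the caudal Y is the
#' anchor landmark's Y plus Gaussian jitter and the rostral Y extends
#' rostrally from it. Junction patterns are Bernoulli rows of type
#' \code{"junction"} with no Y coordinates. Subject IDs are shared across a
#' subject's two hemispheres.
#'
#' @param speciesConfigs list of \linkS4class{SpeciesConfig}.
#' @param landmarks a \linkS4class{LandmarkSet} covering every species.
#' @param seed integer RNG seed.
#' @return data.frame with columns \code{species}, \code{subject},
#'   \code{hemisphere}, \code{type} ("sulcus"/"junction"), \code{feature},
#'   \code{present}, \code{caudal_y}, \code{rostral_y}.
#' @export
simulateSulcalTables <- function(speciesConfigs, landmarks, seed = 1L) {
  for (cfg in speciesConfigs) {
    validObject(cfg)
    for (lm in cfg@anchor)
      landmarkY(landmarks, cfg@species, lm)  # errors on unknown landmark
  }
  withSeed(seed, {
    rows <- lapply(speciesConfigs, function(cfg) {
      subj <- sprintf("%s_S%03d", cfg@species, seq_len(cfg@nSubjects))
      hemi <- c("L", "R")[seq_len(cfg@hemispheres)]
      base <- expand.grid(subject = subj, hemisphere = hemi,
                          stringsAsFactors = FALSE)
      base <- base[order(base$subject, base$hemisphere), ]
      n <- nrow(base)
      sulci <- lapply(names(cfg@presenceProb), function(su) {
        present <- rbinom(n, 1, cfg@presenceProb[[su]]) == 1
        cy <- ry <- rep(NA_real_, n)
        if (any(present)) {
          anchor <- cfg@anchor[[su]]
          y0 <- landmarkY(landmarks, cfg@species, anchor)
          cy[present] <- y0 + rnorm(sum(present), 0, cfg@jitterSd)
          len <- pmax(0.02 * cfg@apExtent,
                      rnorm(sum(present), 0.12 * cfg@apExtent, cfg@jitterSd))
          ry[present] <- cy[present] + len
        }
        data.frame(species = cfg@species, subject = base$subject,
                   hemisphere = base$hemisphere, type = "sulcus",
                   feature = su, present = present,
                   caudal_y = cy, rostral_y = ry)
      })
      juncs <- lapply(names(cfg@junctionProb), function(jn) {
        data.frame(species = cfg@species, subject = base$subject,
                   hemisphere = base$hemisphere, type = "junction",
                   feature = jn,
                   present = rbinom(n, 1, cfg@junctionProb[[jn]]) == 1,
                   caudal_y = NA_real_, rostral_y = NA_real_)
      })
      do.call(rbind, c(sulci, juncs))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Default study configuration
#'
#' The acquisition-matched phantom (TR 1.8 s, 400 volumes, 12 runs, 1.8 mm
#' voxels, ~200-voxel ROI split into three caudo-rostral zones at the
#' macaque genu-rostral and CGS/SUROS/SOS-junction landmark levels) and four
#' species of 80 subjects / 160 hemispheres each with anteroposterior
#' extents 175/110/85/60 mm (human, chimpanzee, baboon, macaque). Junction
#' probabilities printed in the source data are used where available; the
#' remaining presence probabilities are synthetic.
#'
#' @param seed master seed stored in the phantom config.
#' @return list with elements \code{phantom} (\linkS4class{PhantomConfig}),
#'   \code{species} (list of four \linkS4class{SpeciesConfig}), and
#'   \code{landmarks} (\linkS4class{LandmarkSet}).
#' @export
studyPreset <- function(seed = 42L) {
  landmarks <- landmarkSet()
  ext <- apExtent(landmarks)
  zb <- c(landmarkY(landmarks, "macaque", "genu_rostral"),
          landmarkY(landmarks, "macaque", "cgs_suros_sos_junction"))
  phantom <- phantomConfig(zoneBoundaries = zb, seed = seed)

  presence <- list(  # per sulcus: human, chimpanzee, baboon, macaque
    `PMFS-P` = c(1, 1, 1, 1),
    `IPRS-S` = c(0.97, 0.98, 0.96, 0.95),
    `SPR-S`  = c(1, 1, 0.99, 0.98),
    `SFS-P`  = c(1, 0.99, 0.97, 0.62))
  junction <- list(
    `PMFS-P_detached_from_IPRS-S` = c(0.54, 0.34, 0.03, 0),
    `SPR-S_joins_SFS-P`           = c(0.99, 0.99, 0.19, 0.04))
  anchor <- c(`PMFS-P` = "optic_chiasma_rostral",
              `IPRS-S` = "anterior_commissure",
              `SPR-S`  = "mammillary_rostral",
              `SFS-P`  = "rostrum_caudal")
  speciesNames <- c("human", "chimpanzee", "baboon", "macaque")
  species <- lapply(seq_along(speciesNames), function(i) {
    sp <- speciesNames[i]
    speciesConfig(
      species = sp, nSubjects = 80L,
      presenceProb = vapply(presence, `[`, numeric(1), i),
      junctionProb = vapply(junction, `[`, numeric(1), i),
      anchor = anchor, jitterSd = 0.02 * ext[[sp]], apExtent = ext[[sp]])
  })
  names(species) <- speciesNames
  list(phantom = phantom, species = species, landmarks = landmarks)
}
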