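#' @import methods
#' @importFrom stats median rnorm runif rbinom cor sd setNames aggregate
#' @importFrom utils head combn read.delim write.csv read.csv
NULL

## Fixed vocabulary of subcortical / midline landmarks used to anchor sulcal
## features along the anteroposterior (Y) axis.
LANDMARK_VOCABULARY <- c(
  "mammillary_rostral",       # rostral limit of the mammillary body
  "anterior_commissure",
  "optic_chiasma_rostral",    # rostral limit of the optic chiasma
  "genu_caudal",              # caudal limit of the genu of the corpus callosum
  "genu_rostral",             # rostral limit of the genu
  "rostrum_caudal",           # caudal limit of the rostrum
  "cgs_suros_sos_junction"    # junction between CGS and the SUROS/SOS fork
)

#' Configuration for the synthetic fMRI phantom
#'
#' Describes the grid, acquisition timing and planted-signal structure of the
#' synthetic resting-state runs. The region of interest (ROI) is an elongated
#' strip along the world Y (anteroposterior) axis, split by
#' \code{zoneBoundaries} into contiguous caudo-rostral zones; each zone shares
#' a latent band-limited time course with one dedicated gray-matter target
#' network outside the ROI.
#'
#' @slot gridShape integer(3), grid size in voxels.
#' @slot voxelSize numeric(1), isotropic voxel size in mm.
#' @slot tr numeric(1), repetition time in seconds.
#' @slot nVolumes integer(1), time points per run (>= 8).
#' @slot nRuns integer(1), number of runs.
#' @slot zoneBoundaries numeric, strictly increasing world-Y levels (mm)
#'   interior to the ROI's Y range.
#' @slot signalSd,noiseSd numeric(1), standard deviations of the planted
#'   signal and of the stationary noise (arbitrary units).
#' @slot ar1 numeric(1) in [0, 1), lag-1 autocorrelation of the noise.
#' @slot seed integer(1), master seed for run generation.
#' @export
setClass("PhantomConfig", representation(
  gridShape = "integer", voxelSize = "numeric", tr = "numeric",
  nVolumes = "integer", nRuns = "integer", zoneBoundaries = "numeric",
  signalSd = "numeric", noiseSd = "numeric", ar1 = "numeric",
  seed = "integer"))

setValidity("PhantomConfig", function(object) {
  msg <- character()
  if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
    msg <- c(msg, "gridShape must be 3 positive integers")
  if (object@voxelSize <= 0) msg <- c(msg, "voxelSize must be positive")
  if (object@tr <= 0) msg <- c(msg, "tr must be positive")
  if (object@nVolumes < 8L) msg <- c(msg, "nVolumes must be >= 8")
  if (object@nRuns < 1L) msg <- c(msg, "nRuns must be >= 1")
  if (length(object@zoneBoundaries) &&
      any(diff(object@zoneBoundaries) <= 0))
    msg <- c(msg, "zoneBoundaries must be strictly increasing")
  if (object@signalSd < 0 || object@noiseSd < 0)
    msg <- c(msg, "signalSd and noiseSd must be >= 0")
  if (object@ar1 < 0 || object@ar1 >= 1) msg <- c(msg, "ar1 must be in [0,1)")
  if (length(msg)) msg else TRUE
})

#' Per-species configuration of the sulcal-table generator
#'
#' @slot species character(1), species name.
#' @slot nSubjects integer(1), number of subjects (brains).
#' @slot hemispheres integer(1), hemispheres per subject (2).
#' @slot presenceProb named numeric, per-sulcus presence probability in [0,1].
#' @slot junctionProb named numeric, per-junction probability in [0,1].
#' @slot anchor named character, sulcus -> landmark name anchoring the
#'   caudal extremity of that sulcus.
#' @slot jitterSd numeric(1), SD (mm) of the Gaussian jitter of feature Y
#'   around its anchor landmark.
#' @slot apExtent numeric(1), anteroposterior extent of the standard brain
#'   (mm), used to normalize Y distances.
#' @export
setClass("SpeciesConfig", representation(
  species = "character", nSubjects = "integer", hemispheres = "integer",
  presenceProb = "numeric", junctionProb = "numeric", anchor = "character",
  jitterSd = "numeric", apExtent = "numeric"))

setValidity("SpeciesConfig", function(object) {
  msg <- character()
  pr <- c(object@presenceProb, object@junctionProb)
  if (length(pr) && (any(pr < 0) || any(pr > 1)))
    msg <- c(msg, "probabilities must lie in [0, 1]")
  if (object@apExtent <= 0) msg <- c(msg, "apExtent must be > 0")
  if (object@nSubjects < 1L) msg <- c(msg, "nSubjects must be >= 1")
  if (object@jitterSd < 0) msg <- c(msg, "jitterSd must be >= 0")
  if (length(object@presenceProb) &&
      !all(names(object@anchor) %in% names(object@presenceProb)))
    msg <- c(msg, "anchor names must be a subset of presenceProb names")
  if (length(msg)) msg else TRUE
})

#' Landmark table: per-species anteroposterior levels of fixed landmarks
#'
#' @slot table data.frame with columns \code{species}, \code{landmark},
#'   \code{y} (mm, world Y, increasing rostrally).
#' @slot apExtent named numeric, anteroposterior extent (mm) per species.
#' @export
setClass("LandmarkSet", representation(
  table = "data.frame", apExtent = "numeric"))

setValidity("LandmarkSet", function(object) {
  tb <- object@table
  msg <- character()
  if (!all(c("species", "landmark", "y") %in% names(tb)))
    msg <- c(msg, "table must have columns species, landmark, y")
  else {
    bad <- setdiff(unique(tb$landmark), LANDMARK_VOCABULARY)
    if (length(bad))
      msg <- c(msg, paste0("unknown landmark name(s): ",
                           paste(bad, collapse = ", ")))
    ext <- object@apExtent[tb$species]
    if (anyNA(ext))
      msg <- c(msg, "every species in table needs an apExtent entry")
    else if (any(abs(tb$y) > ext))
      msg <- c(msg, "landmark |y| must not exceed the species apExtent")
  }
  if (length(msg)) msg else TRUE
})

#' Mask set on a common functional grid
#'
#' ROI, gray-matter, white-matter and CSF binary masks sharing one voxel grid
#' and one voxel-to-world affine. World Y (second world axis) is the
#' anteroposterior axis in mm, increasing rostrally.
#'
#' @slot roi,gm,wm,csf logical 3D arrays on the same grid.
#' @slot affine 4x4 voxel-to-world matrix (0-based voxel indices).
#' @export
setClass("MaskSet", representation(
  roi = "array", gm = "array", wm = "array", csf = "array",
  affine = "matrix"))

setValidity("MaskSet", function(object) {
  msg <- character()
  d <- dim(object@roi)
  for (s in c("gm", "wm", "csf"))
    if (!identical(dim(slot(object, s)), d))
      msg <- c(msg, "all masks must share one grid")
  if (!length(msg)) {
    if (any(object@roi & !object@gm)) msg <- c(msg, "roi must lie inside gm")
    if (any(object@wm & object@gm)) msg <- c(msg, "wm and gm must be disjoint")
    if (any(object@csf & object@gm)) msg <- c(msg, "csf and gm must be disjoint")
  }
  if (!identical(dim(object@affine), c(4L, 4L)) ||
      abs(det(object@affine)) < 1e-12)
    msg <- c(msg, "affine must be an invertible 4x4 matrix")
  if (length(msg)) msg else TRUE
})

#' Phantom mask set with planted zone structure
#'
#' A \linkS4class{MaskSet} extended with the generating truth of the phantom:
#' the caudo-rostral zone label of every ROI voxel and the gray-matter target
#' network dedicated to each zone.
#'
#' @slot zoneLabels integer, planted zone (1 = most caudal) per ROI voxel in
#'   column-major ROI order.
#' @slot targetNetworks integer 3D array; 0 outside any target network, else
#'   the zone index the block is coupled to.
#' @export
setClass("PhantomMasks", contains = "MaskSet", representation(
  zoneLabels = "integer", targetNetworks = "array"))

setValidity("PhantomMasks", function(object) {
  msg <- character()
  if (length(object@zoneLabels) != sum(object@roi))
    msg <- c(msg, "one zone label per ROI voxel required")
  if (!identical(dim(object@targetNetworks), dim(object@roi)))
    msg <- c(msg, "targetNetworks must share the mask grid")
  if (any(object@targetNetworks > 0 & !object@gm))
    msg <- c(msg, "target networks must lie in gray matter")
  if (any(object@targetNetworks > 0 & object@roi))
    msg <- c(msg, "target networks must not overlap the ROI")
  if (length(msg)) msg else TRUE
})

#' One resting-state run
#'
#' @slot data numeric 4D array (x, y, z, t), arbitrary units.
#' @slot tr numeric(1), repetition time in seconds.
#' @slot motion t x 6 matrix of head-motion parameter estimates.
#' @slot subject,hemisphere,run character(1) identifiers.
#' @export
setClass("Run4D", representation(
  data = "array", tr = "numeric", motion = "matrix",
  subject = "character", hemisphere = "character", run = "character"))

setValidity("Run4D", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 4L) msg <- c(msg, "data must be 4D")
  else {
    t_len <- dim(object@data)[4]
    if (t_len < 8L) msg <- c(msg, "at least 8 time points required")
    if (!identical(dim(object@motion), c(as.integer(t_len), 6L)))
      msg <- c(msg, "motion must be a t x 6 matrix")
  }
  if (object@tr <= 0) msg <- c(msg, "tr must be positive")
  if (length(msg)) msg else TRUE
})

#' Voxelwise connectivity fingerprint matrix
#'
#' Row i holds the Fisher-z transformed Pearson correlations between ROI
#' voxel i and every target gray-matter voxel. Row and column order follow
#' the column-major (x fastest) linear order of the respective masks.
#'
#' @slot z n_roi x m_target numeric matrix of Fisher-z values.
#' @slot roiIndex n_roi x 3 integer matrix of 1-based voxel indices.
#' @slot targetIndex m_target x 3 integer matrix of 1-based voxel indices.
#' @export
setClass("FingerprintMatrix", representation(
  z = "matrix", roiIndex = "matrix", targetIndex = "matrix"))

setValidity("FingerprintMatrix", function(object) {
  msg <- character()
  if (!all(is.finite(object@z))) msg <- c(msg, "all z entries must be finite")
  if (nrow(object@z) < 2L) msg <- c(msg, "need >= 2 ROI voxels")
  if (ncol(object@z) < 2L) msg <- c(msg, "need >= 2 target voxels")
  if (nrow(object@roiIndex) != nrow(object@z))
    msg <- c(msg, "roiIndex rows must match z rows")
  if (nrow(object@targetIndex) != ncol(object@z))
    msg <- c(msg, "targetIndex rows must match z columns")
  if (length(msg)) msg else TRUE
})

#' k-nearest-neighbour similarity graph over ROI voxels
#'
#' @slot W symmetric nonnegative weight matrix, zero diagonal, entries in
#'   [0, 1].
#' @slot knn integer(1), neighbour count used to build the graph.
#' @export
setClass("SimilarityGraph", representation(W = "matrix", knn = "integer"))

setValidity("SimilarityGraph", function(object) {
  W <- object@W
  msg <- character()
  if (nrow(W) != ncol(W)) msg <- c(msg, "W must be square")
  else {
    if (max(abs(W - t(W))) > 1e-12) msg <- c(msg, "W must be symmetric")
    if (any(diag(W) != 0)) msg <- c(msg, "W diagonal must be zero")
    if (any(W < 0) || any(W > 1 + 1e-12))
      msg <- c(msg, "weights must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Result of spectral parcellation with model selection
#'
#' @slot labels integer, cluster label in 1..k per ROI voxel.
#' @slot k integer(1), selected number of clusters.
#' @slot scoresByK data.frame with columns \code{k}, \code{silhouette},
#'   \code{varianceRatio} (means across K-means seeds).
#' @slot eigenvalues numeric, smallest Laplacian eigenvalues (ascending).
#' @slot roiIndex n x 3 integer matrix of ROI voxel indices (row order of
#'   \code{labels}).
#' @slot seed integer, K-means seeds used.
#' @export
setClass("ParcellationResult", representation(
  labels = "integer", k = "integer", scoresByK = "data.frame",
  eigenvalues = "numeric", roiIndex = "matrix", seed = "integer"))

setValidity("ParcellationResult", function(object) {
  msg <- character()
  k <- object@k
  if (length(object@labels)) {
    if (any(object@labels < 1L) || any(object@labels > k))
      msg <- c(msg, "labels must lie in 1..k")
    else if (!all(seq_len(k) %in% object@labels))
      msg <- c(msg, "every cluster in 1..k must be nonempty")
  }
  if (nrow(object@scoresByK)) {
    s <- object@scoresByK$silhouette
    if (any(is.finite(s) & (s < -1 | s > 1)))
      msg <- c(msg, "silhouette scores must lie in [-1, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Cluster probability map across runs
#'
#' @slot prob n_roi x k matrix; row i gives the fraction of runs in which ROI
#'   voxel i fell in each caudo-rostrally ordered cluster. Rows sum to 1.
#' @slot roiIndex n_roi x 3 integer matrix of ROI voxel indices.
#' @slot clusterOrder character, names of the ordered clusters (caudal first).
#' @export
setClass("ClusterProbabilityMap", representation(
  prob = "matrix", roiIndex = "matrix", clusterOrder = "character"))

setValidity("ClusterProbabilityMap", function(object) {
  p <- object@prob
  msg <- character()
  if (any(p < 0) || any(p > 1)) msg <- c(msg, "probabilities must be in [0,1]")
  if (any(abs(rowSums(p) - 1) > 1e-9)) msg <- c(msg, "rows must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Species-effect test result for one sulcal feature
#'
#' @slot statistic numeric(1), likelihood-ratio chi-square (or penalized LRT).
#' @slot numDf integer(1), number of species minus one.
#' @slot denDf character(1), "n/a" (denominator df approximations for
#'   binomial mixed models are software-specific and not reported).
#' @slot pValue numeric(1) in [0, 1].
#' @slot method character(1), tag describing the fitting route taken.
#' @export
setClass("SpeciesTestResult", representation(
  statistic = "numeric", numDf = "integer", denDf = "character",
  pValue = "numeric", method = "character"))

setValidity("SpeciesTestResult", function(object) {
  msg <- character()
  if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
    msg <- c(msg, "p-value must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "PhantomConfig", function(object) {
  cat("PhantomConfig:", paste(object@gridShape, collapse = "x"),
      "grid @", object@voxelSize, "mm;",
      object@nRuns, "runs x", object@nVolumes, "volumes, TR",
      object@tr, "s\n")
  cat("  zone boundaries (Y, mm):",
      paste(object@zoneBoundaries, collapse = ", "), "\n")
  cat("  signalSd", object@signalSd, "| noiseSd", object@noiseSd,
      "| ar1", object@ar1, "| seed", object@seed, "\n")
})

setMethod("show", "MaskSet", function(object) {
  cat(class(object), "on a", paste(dim(object@roi), collapse = "x"),
      "grid:\n  ROI", sum(object@roi), "| GM", sum(object@gm),
      "| WM", sum(object@wm), "| CSF", sum(object@csf), "voxels\n")
})

setMethod("show", "Run4D", function(object) {
  d <- dim(object@data)
  cat("Run4D", paste0("[", object@subject, "/", object@hemisphere, "/",
                      object@run, "]"),
      paste(d[1:3], collapse = "x"), "voxels x", d[4], "volumes, TR",
      object@tr, "s\n")
})

setMethod("show", "FingerprintMatrix", function(object) {
  cat("FingerprintMatrix:", nrow(object@z), "ROI voxels x",
      ncol(object@z), "gray-matter targets (Fisher z)\n")
})

setMethod("show", "ParcellationResult", function(object) {
  cat("ParcellationResult: k =", object@k, "over", length(object@labels),
      "ROI voxels\n")
  if (nrow(object@scoresByK)) {
    cat("  mean silhouette by k:\n")
    print(object@scoresByK, row.names = FALSE, digits = 3)
  }
})

setMethod("show", "SpeciesTestResult", function(object) {
  cat("Species effect on presence:", object@method, "\n")
  cat(sprintf("  chisq = %.4g, NumDF = %d, DenDF = %s, p = %.4g\n",
              object@statistic, object@numDf, object@denDf, object@pValue))
})

setMethod("show", "ClusterProbabilityMap", function(object) {
  cat("ClusterProbabilityMap:", nrow(object@prob), "voxels x",
      ncol(object@prob), "clusters (",
      paste(object@clusterOrder, collapse = ", "), ")\n")
})
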