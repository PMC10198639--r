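## File formats: NIfTI-1 for volumes and masks, TSV for motion parameters,
## CSV for sulcal/landmark tables, TSV + sidecar CSV indices for
## fingerprint matrices.

.affineToXform <- function(affine) {
  structure(affine, code = 2L)
}

#' Write / read a mask set as NIfTI-1
#'
#' Masks are stored as uint8 volumes \code{roi.nii}, \code{gm.nii},
#' \code{wm.nii}, \code{csf.nii} in \code{dir}, all carrying the voxel-to-
#' world affine in the sform.
#'
#' @param masks a \linkS4class{MaskSet}.
#' @param dir output directory (created if needed).
#' @return \code{writeMasks}: the directory, invisibly. \code{readMasks}:
#'   a \linkS4class{MaskSet}.
#' @export
writeMasks <- function(masks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("roi", "gm", "wm", "csf")) {
    img <- RNifti::asNifti(array(as.integer(slot(masks, nm)),
                                 dim(slot(masks, nm))), datatype = "uint8")
    img <- RNifti::`sform<-`(img, .affineToXform(maskAffine(masks)))
    RNifti::writeNifti(img, file.path(dir, paste0(nm, ".nii")))
  }
  invisible(dir)
}

#' @rdname writeMasks
#' @export
readMasks <- function(dir) {
  vols <- lapply(c("roi", "gm", "wm", "csf"), function(nm)
    RNifti::readNifti(file.path(dir, paste0(nm, ".nii"))))
  affine <- unclass(RNifti::xform(vols[[1]]))
  attributes(affine) <- list(dim = dim(affine))
  new("MaskSet",
      roi = array(as.vector(vols[[1]]) > 0, dim(vols[[1]])),
      gm  = array(as.vector(vols[[2]]) > 0, dim(vols[[2]])),
      wm  = array(as.vector(vols[[3]]) > 0, dim(vols[[3]])),
      csf = array(as.vector(vols[[4]]) > 0, dim(vols[[4]])),
      affine = affine)
}

#' Write / read a run as NIfTI-1 plus a motion TSV
#'
#' The 4D volume goes to \code{<prefix>.nii} (float64, TR recorded in the
#' time pixdim) and the motion parameters to \code{<prefix>_motion.tsv}
#' (6 named columns, one row per volume).
#'
#' @param run a \linkS4class{Run4D}.
#' @param prefix file path prefix.
#' @param affine optional 4x4 voxel-to-world matrix for the sform.
#' @return \code{writeRun}: the prefix, invisibly. \code{readRun}: a
#'   \linkS4class{Run4D}.
#' @export
writeRun <- function(run, prefix, affine = NULL) {
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  img <- RNifti::asNifti(runData(run), datatype = "double")
  if (!is.null(affine)) img <- RNifti::`sform<-`(img, .affineToXform(affine))
  RNifti::writeNifti(img, paste0(prefix, ".nii"))
  mot <- as.data.frame(runMotion(run))
  names(mot) <- c("trans_x", "trans_y", "trans_z",
                  "rot_x", "rot_y", "rot_z")
  writeTsv(mot, paste0(prefix, "_motion.tsv"))
  invisible(prefix)
}

#' @rdname writeRun
#' @param tr repetition time in seconds (readRun; NIfTI time units are not
#'   relied upon).
#' @param subject,hemisphere,runId identifiers for the reconstructed run.
#' @export
readRun <- function(prefix, tr, subject = "unknown", hemisphere = "L",
                    runId = basename(prefix)) {
  img <- RNifti::readNifti(paste0(prefix, ".nii"))
  mot <- as.matrix(read.delim(paste0(prefix, "_motion.tsv")))
  dimnames(mot) <- NULL
  new("Run4D", data = array(as.vector(img), dim(img)), tr = tr,
      motion = mot, subject = subject, hemisphere = hemisphere, run = runId)
}

## TSV writer with deterministic formatting (no timestamps, full precision).
writeTsv <- function(df, path) {
  utils::write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Persist / load a fingerprint matrix
#'
#' The z matrix is written as \code{<prefix>_z.tsv} (one row per ROI voxel,
#' full precision) with sidecar index tables \code{<prefix>_roi_index.csv}
#' and \code{<prefix>_target_index.csv} (1-based voxel coordinates in row /
#' column order).
#'
#' @param fp a \linkS4class{FingerprintMatrix}.
#' @param prefix file path prefix.
#' @export
writeFingerprints <- function(fp, prefix) {
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  z <- fingerprintValues(fp)
  con <- file(paste0(prefix, "_z.tsv"), "w")
  on.exit(close(con))
  utils::write.table(z, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  for (side in c("roi", "target")) {
    idx <- if (side == "roi") roiIndex(fp) else targetIndex(fp)
    colnames(idx) <- c("i", "j", "k")
    write.csv(as.data.frame(idx),
              paste0(prefix, "_", side, "_index.csv"), row.names = FALSE)
  }
  invisible(prefix)
}

#' @rdname writeFingerprints
#' @export
readFingerprints <- function(prefix) {
  z <- as.matrix(read.delim(paste0(prefix, "_z.tsv"), header = FALSE))
  dimnames(z) <- NULL
  readIdx <- function(side) {
    m <- as.matrix(read.csv(paste0(prefix, "_", side, "_index.csv")))
    dimnames(m) <- NULL
    storage.mode(m) <- "integer"
    m
  }
  new("FingerprintMatrix", z = z, roiIndex = readIdx("roi"),
      targetIndex = readIdx("target"))
}

#' Read a sulcal feature table with schema validation
#'
#' @param path CSV with header columns \code{species}, \code{subject},
#'   \code{hemisphere}, \code{type}, \code{feature}, \code{present},
#'   \code{caudal_y}, \code{rostral_y}.
#' @return validated data.frame (present coerced to logical).
#' @export
readSulcalRecords <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("species", "subject", "hemisphere", "type", "feature",
                "present", "caudal_y", "rostral_y")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("sulcal record table is missing column(s): ",
         paste(missing, collapse = ", "))
  df$present <- as.logical(df$present)
  if (anyNA(df$present)) stop("column 'present' must be logical (TRUE/FALSE)")
  bad <- df$present & df$type == "sulcus" & is.na(df$caudal_y)
  if (any(bad))
    warning(sum(bad), " present sulcus record(s) lack a caudal_y coordinate")
  if (any(!df$present & (!is.na(df$caudal_y) | !is.na(df$rostral_y))))
    stop("column 'caudal_y'/'rostral_y' must be missing for absent records")
  if (any(df$present & !is.na(df$caudal_y) & !is.na(df$rostral_y) &
            df$caudal_y > df$rostral_y))
    stop("column 'caudal_y' must not exceed 'rostral_y'")
  df
}

#' Read a landmark table
#'
#' @param path CSV with columns \code{species}, \code{landmark}, \code{y}
#'   (mm).
#' @param apExtent named numeric anteroposterior extent per species.
#' @return a \linkS4class{LandmarkSet}.
#' @export
readLandmarks <- function(path, apExtent) {
  tb <- read.csv(path, stringsAsFactors = FALSE)
  new("LandmarkSet", table = tb, apExtent = apExtent)
}

#' Write sulcal records / landmarks as CSV
#'
#' @param records data.frame of sulcal feature records.
#' @param path output CSV path.
#' @export
writeSulcalRecords <- function(records, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSulcalRecords
#' @param landmarks a \linkS4class{LandmarkSet}.
#' @export
writeLandmarks <- function(landmarks, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  write.csv(landmarkTable(landmarks), path, row.names = FALSE)
  invisible(path)
}

## Write a per-ROI-voxel vector (labels or probabilities) back into a 3D
## NIfTI volume on the mask grid.
writeRoiVolume <- function(values, roiIdx, masks, path, datatype = "double") {
  vol <- array(0, dim(roiMask(masks)))
  vol[roiIdx] <- values
  img <- RNifti::asNifti(vol, datatype = datatype)
  img <- RNifti::`sform<-`(img, .affineToXform(maskAffine(masks)))
  RNifti::writeNifti(img, path)
  invisible(path)
}
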