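## Connectivity fingerprints: voxelwise Pearson correlation of ROI voxels
## against whole-brain gray matter, Fisher z transformed.

#' Extract masked voxel time courses
#'
#' @param run a \linkS4class{Run4D}.
#' @param mask logical 3D array on the run's grid.
#' @return t x n_voxel matrix; columns follow the column-major (x fastest)
#'   linear order of the mask, values untouched.
#' @export
extractTimeseries <- function(run, mask) {
  validObject(run)
  if (!any(mask)) stop("mask is empty")
  if (!identical(dim(mask), dim(runData(run))[1:3]))
    stop("mask grid does not match the run grid")
  maskedMatrix(runData(run), mask)
}

#' Voxelwise connectivity fingerprint matrix
#'
#' Entry (i, j) is \code{atanh} of the Pearson correlation (clipped to
#' +/-(1 - eps)) between ROI voxel i and target voxel j, where the target
#' set is the gray matter minus the ROI. Zero-variance voxels contribute
#' r = 0 so degenerate time courses never poison the matrix.
#'
#' @param run a preprocessed \linkS4class{Run4D}.
#' @param masks a \linkS4class{MaskSet}.
#' @param includeRoiTargets keep ROI voxels in the target set (default
#'   FALSE: self/within-ROI correlations would trivially dominate the row
#'   similarity structure).
#' @param eps clipping margin before the Fisher transform (atanh is
#'   undefined at |r| = 1).
#' @return a \linkS4class{FingerprintMatrix}.
#' @export
fingerprintMatrix <- function(run, masks, includeRoiTargets = FALSE,
                              eps = 1e-7) {
  validObject(run); validObject(masks)
  roi <- roiMask(masks)
  target <- gmMask(masks)
  if (!includeRoiTargets) target <- target & !roi
  if (!any(target))
    stop("no target voxels: gray matter minus ROI is empty")
  X <- extractTimeseries(run, roi)
  Y <- extractTimeseries(run, target)
  r <- .safeCrossCor(X, Y)
  z <- atanh(pmin(pmax(r, -(1 - eps)), 1 - eps))
  new("FingerprintMatrix", z = z,
      roiIndex = maskCoords(roi), targetIndex = maskCoords(target))
}

## Pearson correlation between columns of X and columns of Y with the
## zero-variance convention r = 0.
.safeCrossCor <- function(X, Y) {
  n <- nrow(X)
  zs <- function(M) {
    mu <- colMeans(M)
    M <- sweep(M, 2, mu)
    s <- sqrt(colSums(M^2) / (n - 1))
    M <- sweep(M, 2, ifelse(s > 0, s, 1), "/")
    M[, s == 0] <- 0
    M
  }
  crossprod(zs(X), zs(Y)) / (n - 1)
}
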