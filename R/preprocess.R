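## Preprocessing: temporal band-pass, nuisance regression, spatial smoothing.
## Stage order (band-pass -> nuisance -> smoothing) follows the acquisition
## study's processing chain.

## ---- zero-phase Butterworth ---------------------------------------------

## Steady-state initial conditions for a direct-form-II-transposed IIR
## filter (the classic lfilter_zi construction): with state zi * x[1], a
## constant input produces the steady-state output from the first sample.
.lfilterZi <- function(b, a) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  b <- b / a[1]; a <- a / a[1]
  ## companion matrix of the monic polynomial a
  comp <- matrix(0, n - 1, n - 1)
  comp[1, ] <- -a[-1]
  if (n > 2) comp[cbind(2:(n - 1), 1:(n - 2))] <- 1
  IminusA <- diag(n - 1) - t(comp)
  B <- b[-1] - a[-1] * b[1]
  solve(IminusA, B)
}

## Direct-form-II-transposed filtering of each column of x (t x n matrix),
## vectorized across columns. zi: (order x n) initial state.
.lfilterMat <- function(b, a, x, zi = NULL) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  b <- b / a[1]; a <- a / a[1]
  t_len <- nrow(x); nc <- ncol(x)
  y <- matrix(0, t_len, nc)
  z <- if (is.null(zi)) matrix(0, n - 1, nc) else zi
  for (ti in seq_len(t_len)) {
    xt <- x[ti, ]
    yt <- b[1] * xt + z[1, ]
    if (n > 2)
      for (j in seq_len(n - 2))
        z[j, ] <- b[j + 1] * xt + z[j + 1, ] - a[j + 1] * yt
    z[n - 1, ] <- b[n] * xt - a[n] * yt
    y[ti, ] <- yt
  }
  y
}

## Zero-phase (forward-backward) filtering of columns of x with odd
## reflection padding and steady-state initial conditions, matching the
## standard filtfilt behavior.
.filtfiltMat <- function(b, a, x) {
  t_len <- nrow(x)
  padlen <- min(3L * (max(length(a), length(b)) - 1L) * 3L, t_len - 1L)
  zi <- .lfilterZi(b, a)
  ext <- rbind(
    2 * matrix(x[1, ], padlen, ncol(x), byrow = TRUE) -
      x[(padlen + 1):2, , drop = FALSE],
    x,
    2 * matrix(x[t_len, ], padlen, ncol(x), byrow = TRUE) -
      x[(t_len - 1):(t_len - padlen), , drop = FALSE])
  y <- .lfilterMat(b, a, ext, zi = outer(zi, ext[1, ]))
  y <- y[nrow(y):1, , drop = FALSE]
  y <- .lfilterMat(b, a, y, zi = outer(zi, y[1, ]))
  y <- y[nrow(y):1, , drop = FALSE]
  y[(padlen + 1):(padlen + t_len), , drop = FALSE]
}

#' Temporal band-pass filter
#'
#' Applies an order-2 Butterworth band-pass forward and backward (zero
#' phase) to every voxel time course, retaining the slowly fluctuating
#' activity between \code{low} and \code{high} Hz (defaults 0.01-0.1 Hz).
#' The DC component (including the baseline) is removed.
#'
#' @param run a \linkS4class{Run4D}.
#' @param low,high passband edges in Hz; \code{0 <= low < high < 1/(2 tr)}.
#' @return a \linkS4class{Run4D} of the same dimensions.
#' @export
bandpass <- function(run, low = 0.01, high = 0.1) {
  validObject(run)
  fs <- 1 / runTr(run)
  nyq <- fs / 2
  if (low < 0 || low >= high) stop("need 0 <= low < high")
  if (high >= nyq)
    stop("high edge (", high, " Hz) must be below the Nyquist frequency (",
         signif(nyq, 4), " Hz)")
  bf <- signal::butter(2, c(low, high) / nyq, type = "pass")
  d <- dim(runData(run))
  x <- matrix(runData(run), nrow = prod(d[1:3]))  # voxels x t
  y <- .filtfiltMat(bf$b, bf$a, t(x))
  new("Run4D", data = array(as.vector(t(y)), d), tr = runTr(run),
      motion = runMotion(run), subject = run@subject,
      hemisphere = run@hemisphere, run = run@run)
}

## ---- nuisance regression -------------------------------------------------

#' Regress out nuisance signals
#'
#' Per voxel, ordinary-least-squares residual after regressing out an
#' intercept, the six head-motion parameter estimates, and the mean CSF and
#' mean WM time courses (8 confounds plus intercept). Rank-deficient
#' confound matrices are handled by dropping dependent columns with a
#' warning.
#'
#' @param run a \linkS4class{Run4D}.
#' @param masks a \linkS4class{MaskSet} with nonempty WM and CSF masks.
#' @return a \linkS4class{Run4D} holding the residuals.
#' @export
regressNuisance <- function(run, masks) {
  validObject(run); validObject(masks)
  if (!any(wmMask(masks)) || !any(csfMask(masks)))
    stop("masks must contain at least one WM and one CSF voxel")
  d <- dim(runData(run))
  Y <- t(matrix(runData(run), nrow = prod(d[1:3])))  # t x voxels
  csfMean <- rowMeans(Y[, which(csfMask(masks)), drop = FALSE])
  wmMean  <- rowMeans(Y[, which(wmMask(masks)), drop = FALSE])
  X <- cbind(intercept = 1, runMotion(run), csf = csfMean, wm = wmMean)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    warning("confound matrix rank-deficient; dropping ",
            ncol(X) - qrX$rank, " dependent column(s)")
    qrX <- qr(X[, keep, drop = FALSE])
  }
  R <- qr.resid(qrX, Y)
  new("Run4D", data = array(as.vector(t(R)), d), tr = runTr(run),
      motion = runMotion(run), subject = run@subject,
      hemisphere = run@hemisphere, run = run@run)
}

## ---- spatial smoothing ---------------------------------------------------

## Band convolution matrix for one axis: truncated Gaussian rows normalized
## to sum 1, so spatially constant images are preserved exactly (including
## at grid edges).
.gaussBandMatrix <- function(n, sigmaVox) {
  if (sigmaVox <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigmaVox))
  g <- exp(-(-r:r)^2 / (2 * sigmaVox^2))
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- max(1, i - r):min(n, i + r)
    w <- g[j - i + r + 1]
    K[i, j] <- w / sum(w)
  }
  K
}

## Apply matrix K along the given axis of a 4D array.
.applyAlongAxis <- function(arr, K, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(seq_len(4), axis))
  a <- aperm(arr, perm)
  m <- K %*% matrix(a, nrow = d[axis])
  a <- array(m, dim(a))
  aperm(a, order(perm))
}

#' Spatial Gaussian smoothing
#'
#' Smooths every volume with a separable 3D Gaussian kernel of the given
#' full width at half maximum; \code{sigma = fwhm / (2 sqrt(2 log 2))},
#' converted to voxels via the voxel size. \code{fwhm = 0} is the identity.
#' No mask-based renormalization is applied; at grid edges the truncated
#' kernel is renormalized so constant images pass through unchanged.
#'
#' @param run a \linkS4class{Run4D}.
#' @param fwhm full width at half maximum in mm (default 4).
#' @param voxelSize voxel size in mm per axis (scalar or length 3).
#' @return a smoothed \linkS4class{Run4D}.
#' @export
smoothRun <- function(run, fwhm = 4, voxelSize = 1.8) {
  validObject(run)
  if (fwhm < 0) stop("fwhm must be >= 0")
  if (fwhm == 0) return(run)
  voxelSize <- rep(voxelSize, length.out = 3)
  sigmaVox <- (fwhm / (2 * sqrt(2 * log(2)))) / voxelSize
  arr <- runData(run)
  d <- dim(arr)
  for (axis in 1:3)
    arr <- .applyAlongAxis(arr, .gaussBandMatrix(d[axis], sigmaVox[axis]), axis)
  new("Run4D", data = arr, tr = runTr(run), motion = runMotion(run),
      subject = run@subject, hemisphere = run@hemisphere, run = run@run)
}

#' Full preprocessing chain
#'
#' Band-pass, then nuisance regression, then smoothing, in that fixed order.
#'
#' @inheritParams regressNuisance
#' @param low,high band-pass edges in Hz.
#' @param fwhm smoothing kernel FWHM in mm.
#' @param voxelSize voxel size in mm (scalar or length 3); defaults to the
#'   scale of the masks' affine.
#' @return a preprocessed \linkS4class{Run4D}.
#' @export
preprocessRun <- function(run, masks, low = 0.01, high = 0.1, fwhm = 4,
                          voxelSize = NULL) {
  if (is.null(voxelSize))
    voxelSize <- sqrt(colSums(maskAffine(masks)[1:3, 1:3]^2))
  run <- bandpass(run, low, high)
  run <- regressNuisance(run, masks)
  smoothRun(run, fwhm, voxelSize)
}
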