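## Internal helpers shared across modules.

## Derive n reproducible sub-seeds from one master seed without correlated
## streams (draws from a seeded RNG rather than arithmetic on the seed).
deriveSeeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
            suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

## Run expr with a locally seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
            suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

## World coordinates (mm) of 1-based voxel index rows (n x 3).
voxelWorld <- function(idx, affine) {
  idx <- rbind(idx)  # tolerate a single coordinate vector
  h <- cbind(idx - 1, 1)  # affine maps 0-based indices
  t(affine %*% t(h))[, 1:3, drop = FALSE]
}

## World Y (anteroposterior, mm) per voxel-index row.
voxelWorldY <- function(idx, affine) voxelWorld(idx, affine)[, 2]

## Reshape a 4D (x,y,z,t) array to a t x n_voxel matrix for a logical mask,
## columns in column-major (x fastest) mask order.
maskedMatrix <- function(data4d, mask) {
  d <- dim(data4d)
  m <- matrix(data4d, nrow = prod(d[1:3]))
  t(m[which(mask), , drop = FALSE])
}

## 1-based voxel coordinates of mask voxels, column-major order (matches
## maskedMatrix column order).
maskCoords <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  storage.mode(w) <- "integer"
  dimnames(w) <- NULL
  w
}
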