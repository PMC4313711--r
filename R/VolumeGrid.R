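#' @include AllGenerics.R
NULL

#' Construct a VolumeGrid
#'
#' @param values 3D numeric array.
#' @param spacing numeric length-3 voxel spacing in mm (recycled from a
#'   scalar).
#' @param origin world coordinate of voxel (0,0,0); defaults to placing the
#'   grid centre at the world origin.
#' @param affine optional full 4x4 voxel-to-world affine; overrides
#'   `spacing`/`origin` placement (spacing is then taken from the affine
#'   columns).
#' @return a [VolumeGrid].
#' @examples
#' g <- volumeGrid(array(0, c(10, 10, 10)), spacing = 2)
#' voxelVolume(g)
#' @export
volumeGrid <- function(values, spacing = c(1, 1, 1), origin = NULL,
                       affine = NULL) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (is.null(affine)) {
    d <- dim(values)
    if (is.null(origin)) origin <- -spacing * (d - 1) / 2
    affine <- diag(4)
    affine[1:3, 1:3] <- diag(spacing, 3L)
    affine[1:3, 4] <- origin
  } else {
    spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  }
  new("VolumeGrid", values = values, spacing = as.numeric(spacing),
      affine = affine)
}

#' @rdname spacing
#' @export
setMethod("spacing", "VolumeGrid", function(x) x@spacing)

#' @rdname voxelVolume
#' @export
setMethod("voxelVolume", "VolumeGrid",
          function(x) abs(det(x@affine[1:3, 1:3])))

#' @rdname values
#' @export
setMethod("values", "VolumeGrid", function(x) x@values)

#' @export
setMethod("dim", "VolumeGrid", function(x) dim(x@values))

setMethod("show", "VolumeGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("%s: %d x %d x %d voxels, spacing %s mm, range [%g, %g]\n",
              class(object), d[1], d[2], d[3],
              paste(signif(object@spacing, 4), collapse = " x "),
              min(object@values), max(object@values)))
  invisible(object)
})

#' @rdname binarize
#' @export
setMethod("binarize", "VolumeGrid", function(x, threshold = 0.5) {
  new("VolumeGrid", values = (x@values >= threshold) * 1,
      spacing = x@spacing, affine = x@affine)
})

#' Map 0-based voxel indices to world coordinates
#'
#' @param grid a [VolumeGrid].
#' @param ijk n-x-3 matrix (or length-3 vector) of 0-based voxel indices.
#' @return n-x-3 matrix of world mm coordinates.
#' @export
voxelToWorld <- function(grid, ijk) {
  ijk <- rbind(ijk)
  t(grid@affine[1:3, 1:3] %*% t(ijk) + grid@affine[1:3, 4])
}

#' Map world coordinates to 0-based (fractional) voxel indices
#' @inheritParams voxelToWorld
#' @param xyz n-x-3 matrix (or length-3 vector) of world mm coordinates.
#' @export
worldToVoxel <- function(grid, xyz) {
  xyz <- rbind(xyz)
  inv <- solve(grid@affine)
  t(inv[1:3, 1:3] %*% t(xyz) + inv[1:3, 4])
}

#' Trilinear interpolation at world coordinates
#'
#' Samples the volume at arbitrary world points by trilinear interpolation
#' in voxel space; points outside the grid return `outside` (default 0).
#'
#' @param grid a [VolumeGrid].
#' @param xyz n-x-3 matrix of world mm points.
#' @param outside value returned beyond the lattice (default 0).
#' @return numeric vector of sampled values.
#' @export
sampleWorld <- function(grid, xyz, outside = 0) {
  v <- worldToVoxel(grid, xyz)
  d <- dim(grid@values)
  i0 <- floor(v)
  f <- v - i0
  out <- rep(outside, nrow(v))
  # valid when all 8 corner indices are inside the lattice
  ok <- v[, 1] >= 0 & v[, 1] <= d[1] - 1 &
        v[, 2] >= 0 & v[, 2] <= d[2] - 1 &
        v[, 3] >= 0 & v[, 3] <= d[3] - 1
  if (!any(ok)) return(out)
  i0 <- pmin(pmax(i0[ok, , drop = FALSE], 0), rep(d - 2, each = sum(ok)))
  f <- v[ok, , drop = FALSE] - i0
  arr <- grid@values
  idx <- function(di, dj, dk)
    arr[cbind(i0[, 1] + 1 + di, i0[, 2] + 1 + dj, i0[, 3] + 1 + dk)]
  fx <- f[, 1]; fy <- f[, 2]; fz <- f[, 3]
  val <-
    idx(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
    idx(1, 0, 0) * fx * (1 - fy) * (1 - fz) +
    idx(0, 1, 0) * (1 - fx) * fy * (1 - fz) +
    idx(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
    idx(1, 1, 0) * fx * fy * (1 - fz) +
    idx(1, 0, 1) * fx * (1 - fy) * fz +
    idx(0, 1, 1) * (1 - fx) * fy * fz +
    idx(1, 1, 1) * fx * fy * fz
  out[ok] <- val
  out
}

#' World coordinates of every voxel centre, per axis
#'
#' For axis-aligned grids returns the x, y, z world coordinates of voxel
#' centres along each axis (used by the phantom generator). Errors on
#' oblique affines.
#' @param grid a [VolumeGrid].
#' @return list(x, y, z) of numeric vectors.
#' @keywords internal
axisCoords <- function(grid) {
  A <- grid@affine[1:3, 1:3]
  if (max(abs(A - diag(diag(A)))) > 1e-9)
    stop("grid must be axis-aligned")
  d <- dim(grid@values)
  list(x = grid@affine[1, 4] + A[1, 1] * (seq_len(d[1]) - 1),
       y = grid@affine[2, 4] + A[2, 2] * (seq_len(d[2]) - 1),
       z = grid@affine[3, 4] + A[3, 3] * (seq_len(d[3]) - 1))
}

#' Read a NIfTI volume
#'
#' @param path path to a .nii or .nii.gz file.
#' @return a [VolumeGrid] with the file's voxel-to-world affine.
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- matrix(RNifti::xform(img), 4L, 4L)
  volumeGrid(array(as.numeric(img), dim(img)[1:3]), affine = aff)
}

#' Write a volume as NIfTI-1
#'
#' @param grid a [VolumeGrid].
#' @param path output .nii or .nii.gz path.
#' @return the path, invisibly.
#' @export
writeVolume <- function(grid, path) {
  img <- RNifti::asNifti(grid@values)
  RNifti::pixdim(img) <- grid@spacing
  RNifti::sform(img) <- structure(grid@affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
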