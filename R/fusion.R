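#' @include AllClasses.R AllGenerics.R VolumeGrid.R landmarks.R
NULL

#' Construct an AffineTransform3D
#' @param linear 3x3 matrix.
#' @param translation numeric length-3.
#' @param residualRms optional RMS fit residual (mm).
#' @export
affineTransform3D <- function(linear = diag(3), translation = c(0, 0, 0),
                              residualRms = NA_real_) {
  new("AffineTransform3D", linear = linear,
      translation = as.numeric(translation),
      residualRms = as.numeric(residualRms))
}

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature("AffineTransform3D", "matrix"),
  function(transform, x)
    t(transform@linear %*% t(x) + transform@translation))

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature("AffineTransform3D", "numeric"),
  function(transform, x)
    as.numeric(transform@linear %*% x + transform@translation))

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature("AffineTransform3D", "LandmarkSet"),
  function(transform, x) {
    co <- applyTransform(transform, coords(x))
    rownames(co) <- rownames(coords(x))
    landmarkSet(coords = co)
  })

#' Invert an affine transform
#' @param transform an [AffineTransform3D].
#' @export
invertTransform <- function(transform) {
  Ainv <- solve(transform@linear)
  affineTransform3D(Ainv, -Ainv %*% transform@translation)
}

setMethod("show", "AffineTransform3D", function(object) {
  cat("AffineTransform3D (world mm -> world mm)\n")
  print(round(cbind(object@linear, object@translation), 4))
  if (!is.na(object@residualRms))
    cat("  landmark residual RMS:", signif(object@residualRms, 4), "mm\n")
  invisible(object)
})

#' Least-squares affine registration of landmark sets
#'
#' Finds the affine map T minimising the sum of squared distances
#' ||T(src_i) - dst_i||^2 over the shared landmarks. Requires at least 4
#' non-coplanar points; a coplanar or degenerate configuration is an error
#' naming the rank defect.
#'
#' @param src,dst [LandmarkSet]s (or n-x-3 point matrices with matching
#'   rows).
#' @return an [AffineTransform3D] with the RMS residual recorded.
#' @examples
#' # identity: registering a landmark set to itself
#' lm <- landmarkSet(nasion = c(0, 93, 10), inion = c(0, -93, 10),
#'                   preauricular_left = c(-76, 0, 0),
#'                   preauricular_right = c(76, 0, 0),
#'                   ac = c(0, 13, 0), pc = c(0, -13, 0))
#' registerLandmarks(lm, lm)
#' @export
registerLandmarks <- function(src, dst) {
  P <- if (is(src, "LandmarkSet")) coords(src) else as.matrix(src)
  Q <- if (is(dst, "LandmarkSet")) coords(dst) else as.matrix(dst)
  if (nrow(P) != nrow(Q)) stop("src and dst must have matching points")
  if (nrow(P) < 4) stop("at least 4 landmark pairs are required")
  X <- cbind(P, 1)
  qrX <- qr(X)
  if (qrX$rank < 4)
    stop("degenerate landmark configuration (rank ", qrX$rank,
         " < 4): points are coplanar or collinear")
  B <- qr.coef(qrX, Q)              # 4 x 3: [linear'; translation']
  fitted <- X %*% B
  rms <- sqrt(mean(rowSums((fitted - Q)^2)))
  affineTransform3D(t(B[1:3, , drop = FALSE]), B[4, ], residualRms = rms)
}

#' Registration point set from landmarks plus the scalp vertex
#'
#' The six anatomical landmarks are exactly coplanar whenever nasion and
#' inion sit on the AC-PC plane, which makes a 3D affine fit degenerate.
#' This helper appends the scalp vertex — the topmost scalp point on the
#' superior line through PC — giving a well-conditioned 7-point set.
#'
#' @param lm a [LandmarkSet].
#' @param scalpMask a [VolumeGrid] used to locate the vertex.
#' @return 7 x 3 matrix of world-mm points.
#' @export
registrationPoints <- function(lm, scalpMask) {
  frame <- buildAcpcFrame(lm, scalpMask)
  hh <- lineExtent(scalpMask, landmark(lm, "pc"), frame@eSi, step = 0.1)
  if (is.na(hh)) stop("cannot locate the scalp vertex above PC")
  vertex <- landmark(lm, "pc") + hh * frame@eSi
  rbind(coords(lm), vertex = vertex)
}

#' Resample a label volume onto a target grid through an affine map
#'
#' Nearest-neighbour pull-back: each target voxel takes the label found at
#' the source-space position t^-1(world position of the voxel). Positions
#' falling outside the atlas field of view get background (0).
#'
#' @param atlas a [LabelVolume].
#' @param transform [AffineTransform3D] mapping atlas world space to target
#'   world space.
#' @param target a [VolumeGrid] defining the output lattice.
#' @return a [LabelVolume] on the target grid with the atlas name map.
#' @export
resampleLabels <- function(atlas, transform, target) {
  d <- dim(target@values)
  ijk <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                               k = 0:(d[3] - 1)))
  world <- voxelToWorld(target, ijk)
  srcWorld <- applyTransform(invertTransform(transform), world)
  v <- round(worldToVoxel(atlas, srcWorld))
  da <- dim(atlas@values)
  ok <- v[, 1] >= 0 & v[, 1] <= da[1] - 1 &
        v[, 2] >= 0 & v[, 2] <= da[2] - 1 &
        v[, 3] >= 0 & v[, 3] <= da[3] - 1
  lab <- integer(nrow(v))
  lab[ok] <- atlas@values[v[ok, , drop = FALSE] + 1]
  new("LabelVolume", values = array(lab, d), spacing = target@spacing,
      affine = target@affine, nameMap = atlas@nameMap)
}

#' Majority-vote fusion of label volumes
#'
#' Per voxel, the most frequent label across the atlases wins; ties are
#' broken deterministically by the smallest label id. The fused name map is
#' the union of the input name maps.
#'
#' @param atlases list of [LabelVolume]s on one grid.
#' @return the fused [LabelVolume].
#' @export
majorityVote <- function(atlases) {
  if (length(atlases) < 1) stop("at least one atlas is required")
  d <- dim(atlases[[1]]@values)
  for (a in atlases)
    if (!identical(dim(a@values), d) ||
        max(abs(a@affine - atlases[[1]]@affine)) > 1e-6)
      stop("all atlases must share one grid")
  n <- prod(d)
  labs <- vapply(atlases, function(a) as.integer(a@values), integer(n))
  labs <- matrix(labs, nrow = n)
  ids <- sort(unique(as.vector(labs)))
  best <- rep(ids[1], n)
  bestCount <- integer(n)
  counts <- matrix(0L, n, length(ids))
  for (j in seq_along(ids)) counts[, j] <- rowSums(labs == ids[j])
  # ascending id order + strict '>' implements the smallest-id tie-break
  for (j in seq_along(ids)) {
    better <- counts[, j] > bestCount
    best[better] <- ids[j]
    bestCount[better] <- counts[better, j]
  }
  nm <- unlist(lapply(atlases, function(a) a@nameMap))
  nm <- nm[!duplicated(names(nm))]
  new("LabelVolume", values = array(best, d),
      spacing = atlases[[1]]@spacing, affine = atlases[[1]]@affine,
      nameMap = nm)
}

#' Read / write label volumes with a JSON name map
#'
#' @param path NIfTI path; the name map is read/written at the same path
#'   with extension `.labels.json` unless `namesPath` is given.
#' @param namesPath optional explicit JSON path.
#' @export
readLabelVolume <- function(path, namesPath = NULL) {
  if (is.null(namesPath))
    namesPath <- sub("\\.nii(\\.gz)?$", ".labels.json", path)
  g <- readVolume(path)
  nm <- unlist(jsonlite::read_json(namesPath, simplifyVector = TRUE))
  lab <- round(g@values)
  storage.mode(lab) <- "integer"
  new("LabelVolume", values = lab, spacing = g@spacing,
      affine = g@affine, nameMap = nm)
}

#' @rdname readLabelVolume
#' @param x a [LabelVolume].
#' @export
writeLabelVolume <- function(x, path, namesPath = NULL) {
  if (is.null(namesPath))
    namesPath <- sub("\\.nii(\\.gz)?$", ".labels.json", path)
  writeVolume(x, path)
  jsonlite::write_json(as.list(x@nameMap), namesPath, auto_unbox = TRUE)
  invisible(path)
}
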