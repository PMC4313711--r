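#' @include AllClasses.R VolumeGrid.R landmarks.R
NULL

#' Construct a PhantomSpec
#'
#' Default parameters describe an adolescent-sized head: a 152 x 186 x 212
#' mm scalp ellipsoid, 6 mm skull, 4 mm subarachnoid CSF gap, a brain
#' ellipsoid of semi-axes 61 x 73 x 86 mm with an interior WM ellipsoid at
#' 77% linear scale and a central CSF (ventricular/deep CSF) ellipsoid.
#' Intensity means follow T1 ordering CSF < GM < WM.
#'
#' @param scalpSemiAxes,skullThickness,csfGap,brainSemiAxes,wmFraction,ventricleSemiAxes
#'   geometry, mm (see [PhantomSpec-class]). `ventricleSemiAxes = NULL`
#'   omits the ventricle.
#' @param acOffset,pcOffset AC and PC positions on the anterior-posterior
#'   axis, mm.
#' @param landmarkElevation vertical offset of nasion/inion off the AC-PC
#'   plane, mm (0 makes all six landmarks coplanar).
#' @param intensityMeans (CSF, GM, WM) intensity means, arbitrary units.
#' @param noiseSd additive Gaussian noise sd.
#' @param voxelSpacing voxel size in mm (scalar or length 3).
#' @param seed RNG seed for the noise.
#' @return a validated [PhantomSpec].
#' @export
phantomSpec <- function(scalpSemiAxes = c(76, 93, 106),
                        skullThickness = 6, csfGap = 4,
                        brainSemiAxes = c(61, 73, 86),
                        wmFraction = 0.77,
                        ventricleSemiAxes = c(24, 29, 34),
                        acOffset = 13.2, pcOffset = -13.2,
                        landmarkElevation = 0,
                        intensityMeans = c(30, 70, 110),
                        noiseSd = 5, voxelSpacing = 2, seed = 1L) {
  if (length(voxelSpacing) == 1L) voxelSpacing <- rep(voxelSpacing, 3L)
  new("PhantomSpec", scalpSemiAxes = as.numeric(scalpSemiAxes),
      skullThickness = as.numeric(skullThickness),
      csfGap = as.numeric(csfGap),
      brainSemiAxes = as.numeric(brainSemiAxes),
      wmFraction = as.numeric(wmFraction),
      ventricleSemiAxes = as.numeric(
        if (is.null(ventricleSemiAxes)) numeric() else ventricleSemiAxes),
      acOffset = as.numeric(acOffset), pcOffset = as.numeric(pcOffset),
      landmarkElevation = as.numeric(landmarkElevation),
      intensityMeans = as.numeric(intensityMeans),
      noiseSd = as.numeric(noiseSd),
      voxelSpacing = as.numeric(voxelSpacing), seed = as.integer(seed))
}

#' Closed-form volume of an ellipsoid
#' @param semiAxes numeric length-3 semi-axes, mm.
#' @return volume in mm^3.
#' @export
ellipsoidVolume <- function(semiAxes) 4 / 3 * pi * prod(semiAxes)

# run expr with a temporary RNG seed, restoring global RNG state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# Per-voxel inside-fractions for origin-centred, axis-aligned ellipsoids.
# Each voxel is supersampled with s^3 points on a staggered (rotated-grid)
# pattern: along each axis the s^3 points take s^3 distinct stratified
# offsets, so the boundary fraction ramps in s^3 levels rather than s.
# Offsets are shared across ellipsoids within a pass, which keeps the
# counted memberships exactly nested for nested surfaces.
# coords: list(x, y, z) of voxel-centre world coordinates.
ellipsoidFractions <- function(coords, spacing, semiAxesList, subsamples = 3L) {
  s <- as.integer(subsamples)
  stopifnot(s >= 1L)
  nx <- length(coords$x); ny <- length(coords$y); nz <- length(coords$z)
  acc <- lapply(semiAxesList, function(e) array(0, c(nx, ny, nz)))
  u <- function(a, b) ((a * s + b) + 0.5) / s^2     # stratified stagger
  for (i in seq_len(s) - 1L) for (j in seq_len(s) - 1L)
    for (k in seq_len(s) - 1L) {
      ox <- ((i + u(j, k)) / s - 0.5) * spacing[1]
      oy <- ((j + u(i, k)) / s - 0.5) * spacing[2]
      oz <- ((k + u(i, j)) / s - 0.5) * spacing[3]
      for (e in seq_along(semiAxesList)) {
        a <- semiAxesList[[e]]
        qx <- ((coords$x + ox) / a[1])^2
        qy <- ((coords$y + oy) / a[2])^2
        qz <- ((coords$z + oz) / a[3])^2
        q <- outer(outer(qx, qy, "+"), qz, "+")
        acc[[e]] <- acc[[e]] + (q <= 1)
      }
    }
  lapply(acc, function(a) a / s^3)
}

# separable [1,2,1]/4 smoothing with edge replication; monotone and
# order-preserving, so nested fraction fields stay nested
smooth121 <- function(a) {
  d <- dim(a)
  for (ax in 1:3) {
    lo <- switch(ax, a[c(1, seq_len(d[1] - 1)), , ],
                 a[, c(1, seq_len(d[2] - 1)), ],
                 a[, , c(1, seq_len(d[3] - 1))])
    hi <- switch(ax, a[c(seq_len(d[1] - 1) + 1, d[1]), , ],
                 a[, c(seq_len(d[2] - 1) + 1, d[2]), ],
                 a[, , c(seq_len(d[3] - 1) + 1, d[3])])
    a <- (lo + 2 * a + hi) / 4
  }
  a
}

# octant "lobe" labels and 50-sector fine labels inside a binary brain mask
phantomParcellation <- function(coords, brainMaskArr, brainSemiAxes,
                                spacing, affine) {
  d <- dim(brainMaskArr)
  X <- array(coords$x, d)
  Y <- aperm(array(coords$y, d[c(2, 1, 3)]), c(2, 1, 3))
  Z <- aperm(array(coords$z, d[c(3, 2, 1)]), c(3, 2, 1))
  inside <- brainMaskArr >= 0.5
  lob <- array(0L, d)
  lob[inside] <- 1L + (X[inside] > 0) + 2L * (Y[inside] > 0) +
    4L * (Z[inside] > 0)
  sides <- expand.grid(x = c("left", "right"),
                       y = c("posterior", "anterior"),
                       z = c("inferior", "superior"))
  lobNames <- apply(sides, 1, paste, collapse = "_")
  names(lobNames) <- as.character(1:8)

  nAz <- 10L; nEl <- 5L
  az <- atan2(Y / brainSemiAxes[2], X / brainSemiAxes[1])
  azBin <- pmin(as.integer(floor((az + pi) / (2 * pi) * nAz)), nAz - 1L)
  elBin <- pmin(pmax(as.integer(floor((Z / brainSemiAxes[3] + 1) / 2 * nEl)),
                     0L), nEl - 1L)
  reg <- array(0L, d)
  reg[inside] <- 1L + azBin[inside] + nAz * elBin[inside]
  regIds <- as.character(seq_len(nAz * nEl))
  regNames <- sprintf("sector_el%d_az%d",
                      rep(seq_len(nEl), each = nAz), rep(seq_len(nAz), nEl))
  names(regNames) <- regIds

  list(lobes = new("LabelVolume", values = lob, spacing = spacing,
                   affine = affine, nameMap = lobNames),
       regions = new("LabelVolume", values = reg, spacing = spacing,
                     affine = affine, nameMap = regNames))
}

#' Soft (partial-volume) mask of an origin-centred ellipsoid
#'
#' Utility for building analytic test masks: a grid of per-voxel inside
#' fractions of an axis-aligned ellipsoid, optionally with the same
#' widened boundary ramp the phantom compartment masks use (recommended
#' for sub-voxel line measurements).
#'
#' @param semiAxes numeric length-3 semi-axes, mm.
#' @param spacing voxel spacing, mm (scalar or length-3).
#' @param subsamples per-axis supersampling factor.
#' @param smooth apply the [1,2,1]/4 boundary smoothing twice
#'   (default TRUE).
#' @return a [VolumeGrid] with values in [0, 1].
#' @export
ellipsoidMask <- function(semiAxes, spacing = 1, subsamples = 3L,
                          smooth = TRUE) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  dims <- 2L * as.integer(ceiling((semiAxes + 2 * spacing) / spacing))
  origin <- -spacing * (dims - 1) / 2
  aff <- diag(4); aff[1:3, 1:3] <- diag(spacing, 3L); aff[1:3, 4] <- origin
  grid0 <- volumeGrid(array(0, dims), spacing = spacing, affine = aff)
  f <- ellipsoidFractions(axisCoords(grid0), spacing, list(e = semiAxes),
                          subsamples)$e
  if (smooth) f <- smooth121(smooth121(f))
  new("VolumeGrid", values = f, spacing = spacing, affine = aff)
}

#' Analytic ground-truth measures of a phantom
#'
#' Closed-form values of the seven distance measures and the compartment
#' volumes implied by a [PhantomSpec]'s nested-ellipsoid geometry. The
#' plane-cut head volume has a closed form (half the scalp ellipsoid) only
#' when `landmarkElevation == 0`; otherwise it is reported as NA.
#'
#' @param spec a [PhantomSpec].
#' @return list with numeric vectors `morphometry` (mm) and `volumes`
#'   (mm^3).
#' @export
phantomTruth <- function(spec) {
  sa <- spec@scalpSemiAxes; ba <- spec@brainSemiAxes
  e <- spec@landmarkElevation
  bPrime <- sa[2] * sqrt(1 - (e / sa[3])^2)
  pc <- spec@pcOffset; ac <- spec@acOffset
  y0 <- (ac + pc) / 2
  morph <- c(
    brain_length = 2 * ba[2],
    brain_width = 2 * ba[1] * sqrt(1 - (y0 / ba[2])^2),
    brain_height = ba[3] * sqrt(1 - (pc / ba[2])^2),
    ac_pc_distance = ac - pc,
    head_length = 2 * bPrime,
    head_width = 2 * sa[1],
    head_height = sa[3] * sqrt(1 - (pc / sa[2])^2))
  inner <- sa - spec@skullThickness
  wmA <- spec@wmFraction * ba
  vVent <- if (length(spec@ventricleSemiAxes))
    ellipsoidVolume(spec@ventricleSemiAxes) else 0
  vols <- c(
    head_volume = if (e == 0) 2 / 3 * pi * prod(sa) else NA_real_,
    intracranial_volume = ellipsoidVolume(inner),
    brain_volume = ellipsoidVolume(ba),
    gm_total = ellipsoidVolume(ba) - ellipsoidVolume(wmA),
    wm_total = ellipsoidVolume(wmA) - vVent,
    csf_inner = vVent)
  list(morphometry = morph, volumes = vols)
}

#' Generate a synthetic head phantom
#'
#' Renders the nested-ellipsoid head described by a [PhantomSpec] onto a
#' voxel grid. Per-voxel compartment membership is computed by supersampling
#' each voxel against the analytic ellipsoid surfaces
#' (`subsamples^3` subsamples), which yields ground-truth partial-volume
#' fractions; intensity is the PVE-weighted sum of the tissue means plus
#' seeded Gaussian noise. Landmarks are placed on the analytic surfaces:
#' preauricular points at (+-a_s, 0, 0), nasion/inion on the scalp at the
#' configured elevation, AC and PC on the anterior-posterior axis.
#'
#' @param spec a [PhantomSpec].
#' @param dims optional grid dimensions; defaults to the smallest odd grid
#'   covering the scalp ellipsoid with a 2-voxel margin. A grid too small to
#'   contain the scalp is an error.
#' @param subsamples per-axis supersampling factor (default 3).
#' @return a [SubjectPhantom].
#' @examples
#' ph <- makePhantom(phantomSpec(voxelSpacing = 4, noiseSd = 0))
#' ph@truth$morphometry
#' @export
makePhantom <- function(spec, dims = NULL, subsamples = 3L) {
  validObject(spec)
  sp <- spec@voxelSpacing
  if (is.null(dims)) {
    # even dims: voxel centres straddle the coordinate planes symmetrically
    dims <- 2L * as.integer(ceiling((spec@scalpSemiAxes + 2 * sp) / sp))
  } else {
    half <- sp * (dims - 1) / 2
    if (any(half < spec@scalpSemiAxes))
      stop("grid too small to contain the scalp ellipsoid (needs half-extent ",
           paste(round(spec@scalpSemiAxes, 1), collapse = " x "), " mm)")
  }
  origin <- -sp * (dims - 1) / 2
  aff <- diag(4); aff[1:3, 1:3] <- diag(sp, 3L); aff[1:3, 4] <- origin
  grid0 <- volumeGrid(array(0, dims), spacing = sp, affine = aff)
  co <- axisCoords(grid0)

  inner <- spec@scalpSemiAxes - spec@skullThickness
  wmA <- spec@wmFraction * spec@brainSemiAxes
  ells <- list(scalp = spec@scalpSemiAxes, innerSkull = inner,
               brain = spec@brainSemiAxes, wm = wmA)
  hasVent <- length(spec@ventricleSemiAxes) == 3L
  if (hasVent) ells$vent <- spec@ventricleSemiAxes
  fr <- ellipsoidFractions(co, sp, ells, subsamples)
  fVent <- if (hasVent) fr$vent else array(0, dims)

  vg <- function(a) new("VolumeGrid", values = a, spacing = sp, affine = aff)
  # compartment masks carry a widened (2-voxel) partial-volume ramp: the
  # symmetric [1,2,1]/4 smoothing keeps the 0.5-crossing on the analytic
  # surface while making the ramp representable under trilinear sampling
  sm <- function(a) smooth121(smooth121(a))
  masks <- new("MaskSet", brain = vg(sm(fr$brain)),
               innerSkull = vg(sm(fr$innerSkull)), scalp = vg(sm(fr$scalp)))
  bm <- fr$brain >= 0.5

  # within-brain tissue fractions: normalised by the brain fraction so each
  # masked voxel's PVE sums to 1 (the convention posterior segmentation
  # produces); tissue sums over the mask then telescope to the analytic
  # compartment volumes up to the voxel-count error of the mask itself
  fB <- pmax(fr$brain, .Machine$double.eps)
  gm <- (fr$brain - fr$wm) / fB
  wm <- (fr$wm - fVent) / fB
  csf <- fVent / fB
  gm[!bm] <- 0; wm[!bm] <- 0; csf[!bm] <- 0
  truePve <- new("TissueMaps", gm = vg(gm), wm = vg(wm), csf = vg(csf),
                 brainMask = vg(bm * 1))

  m <- spec@intensityMeans   # (CSF, GM, WM)
  shell <- fr$scalp - fr$innerSkull       # skull + scalp layer
  gapCsf <- fVent + (fr$innerSkull - fr$brain)
  signal <- (fr$brain - fr$wm) * m[2] + (fr$wm - fVent) * m[3] +
    gapCsf * m[1] + shell * m[2]
  noise <- if (spec@noiseSd > 0)
    withSeed(spec@seed, array(stats::rnorm(prod(dims), 0, spec@noiseSd), dims))
  else array(0, dims)
  intensity <- vg(signal + noise)

  e <- spec@landmarkElevation
  bPrime <- spec@scalpSemiAxes[2] * sqrt(1 - (e / spec@scalpSemiAxes[3])^2)
  lms <- landmarkSet(
    nasion = c(0, bPrime, e), inion = c(0, -bPrime, e),
    preauricular_left = c(-spec@scalpSemiAxes[1], 0, 0),
    preauricular_right = c(spec@scalpSemiAxes[1], 0, 0),
    ac = c(0, spec@acOffset, 0), pc = c(0, spec@pcOffset, 0))

  parc <- phantomParcellation(co, fr$brain, spec@brainSemiAxes, sp, aff)

  new("SubjectPhantom", intensity = intensity, truePve = truePve,
      masks = masks, landmarks = lms, labels = parc$regions,
      lobes = parc$lobes, truth = phantomTruth(spec), spec = spec)
}

setMethod("show", "SubjectPhantom", function(object) {
  d <- dim(object@intensity@values)
  cat(sprintf("SubjectPhantom: %d x %d x %d voxels at %s mm\n",
              d[1], d[2], d[3],
              paste(signif(object@intensity@spacing, 3), collapse = " x ")))
  cat("  analytic brain volume:",
      format(object@truth$volumes[["brain_volume"]], big.mark = ","),
      "mm^3\n")
  invisible(object)
})
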