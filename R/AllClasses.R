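#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' VolumeGrid: a 3D scalar voxel lattice with world geometry
#'
#' The basic data model for an MRI-like volume: a 3D array of scalar values,
#' the voxel spacing in millimetres, and a 4x4 affine mapping 0-based voxel
#' indices to world coordinates (RAS, millimetres).
#'
#' @slot values 3D numeric array.
#' @slot spacing numeric length-3, voxel edge lengths in mm (all > 0).
#' @slot affine 4x4 matrix mapping 0-based voxel index (i,j,k,1) to world
#'   (x,y,z,1) in mm. Must be invertible.
#'
#' @seealso [volumeGrid()], [sampleWorld()], [voxelToWorld()]
#' @export
setClass("VolumeGrid",
  representation(values = "array", spacing = "numeric", affine = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@values)) != 3L)
      msg <- c(msg, "values must be a 3D array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 positive finite numbers")
    if (!all(dim(object@affine) == c(4L, 4L)))
      msg <- c(msg, "affine must be a 4x4 matrix")
    else if (abs(det(object@affine[1:3, 1:3])) < 1e-12)
      msg <- c(msg, "affine linear part must be invertible")
    if (length(msg)) msg else TRUE
  })

#' LandmarkSet: the six anatomical landmarks in world mm
#'
#' Holds nasion, inion, left/right preauricular points, and the anterior and
#' posterior commissures (AC, PC) as world-coordinate points (RAS, mm).
#'
#' @slot coords 6x3 numeric matrix, rows named with the canonical landmark
#'   names (see [landmarkNames()]).
#' @export
setClass("LandmarkSet",
  representation(coords = "matrix"),
  validity = function(object) {
    msg <- character()
    need <- landmarkNames()
    if (!all(dim(object@coords) == c(6L, 3L)))
      msg <- c(msg, "coords must be a 6x3 matrix")
    else {
      if (!identical(rownames(object@coords), need))
        msg <- c(msg, paste("row names must be exactly:",
                            paste(need, collapse = ", ")))
      if (any(!is.finite(object@coords)))
        msg <- c(msg, "landmark coordinates must be finite")
      else {
        if (sqrt(sum((object@coords["ac", ] - object@coords["pc", ])^2)) < 1e-9)
          msg <- c(msg, "ac and pc must be distinct points")
        d <- object@coords["preauricular_left", ] -
             object@coords["preauricular_right", ]
        if (sqrt(sum(d^2)) < 1e-9)
          msg <- c(msg, "preauricular points must be distinct")
      }
    }
    if (length(msg)) msg else TRUE
  })

#' Canonical landmark names
#' @return character vector of the six landmark names in canonical order.
#' @export
landmarkNames <- function()
  c("nasion", "inion", "preauricular_left", "preauricular_right", "ac", "pc")

#' MaskSet: nested brain / inner-skull / scalp compartment masks
#'
#' The three head-compartment masks on one grid. Values may be binary or
#' partial-volume fractions in [0,1]; the nesting invariant
#' brain <= inner_skull <= scalp must hold voxelwise.
#'
#' @slot brain,innerSkull,scalp [VolumeGrid] objects on one grid.
#' @export
setClass("MaskSet",
  representation(brain = "VolumeGrid", innerSkull = "VolumeGrid",
                 scalp = "VolumeGrid"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@brain@values)
    if (!identical(d, dim(object@innerSkull@values)) ||
        !identical(d, dim(object@scalp@values)))
      msg <- c(msg, "all masks must share one grid")
    else {
      tol <- 1e-6
      rng <- range(object@brain@values, object@innerSkull@values,
                   object@scalp@values)
      if (rng[1] < -tol || rng[2] > 1 + tol)
        msg <- c(msg, "mask values must lie in [0, 1]")
      if (any(object@brain@values > object@innerSkull@values + tol))
        msg <- c(msg, "brain mask must be nested inside inner-skull mask")
      if (any(object@innerSkull@values > object@scalp@values + tol))
        msg <- c(msg, "inner-skull mask must be nested inside scalp mask")
    }
    if (length(msg)) msg else TRUE
  })

#' TissueMaps: per-voxel partial-volume estimates for GM, WM and CSF
#'
#' Each map holds the fraction of the voxel occupied by that tissue. Inside
#' the brain mask the three fractions sum to 1 (within 1e-6); outside they
#' are all zero.
#'
#' @slot gm,wm,csf [VolumeGrid] PVE maps in [0,1].
#' @slot brainMask [VolumeGrid] binary brain mask the maps refer to.
#' @export
setClass("TissueMaps",
  representation(gm = "VolumeGrid", wm = "VolumeGrid", csf = "VolumeGrid",
                 brainMask = "VolumeGrid"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@gm@values)
    if (!identical(d, dim(object@wm@values)) ||
        !identical(d, dim(object@csf@values)) ||
        !identical(d, dim(object@brainMask@values)))
      msg <- c(msg, "gm, wm, csf and brainMask must share one grid")
    else {
      tol <- 1e-6
      v <- c(range(object@gm@values), range(object@wm@values),
             range(object@csf@values))
      if (min(v) < -tol || max(v) > 1 + tol)
        msg <- c(msg, "PVE values must lie in [0, 1]")
      m <- object@brainMask@values >= 0.5
      s <- object@gm@values + object@wm@values + object@csf@values
      if (any(abs(s[m] - 1) > 1e-6))
        msg <- c(msg, "PVE must sum to 1 inside the brain mask")
      if (any(s[!m] > 1e-6))
        msg <- c(msg, "PVE must be 0 outside the brain mask")
    }
    if (length(msg)) msg else TRUE
  })

#' LabelVolume: an integer-labelled parcellation volume
#'
#' A [VolumeGrid] whose values are non-negative integer label ids
#' (0 = background) together with a label-id -> structure-name map.
#'
#' @slot nameMap named character vector; names are label ids as strings.
#' @export
setClass("LabelVolume", contains = "VolumeGrid",
  representation(nameMap = "character"),
  validity = function(object) {
    msg <- character()
    v <- object@values
    if (any(v < 0) || any(v != round(v)))
      msg <- c(msg, "labels must be non-negative integers")
    ids <- sort(unique(as.vector(v)))
    ids <- ids[ids != 0]
    known <- suppressWarnings(as.numeric(names(object@nameMap)))
    if (length(ids) && !all(ids %in% known))
      msg <- c(msg, paste("labels missing from name map:",
                          paste(setdiff(ids, known), collapse = ", ")))
    if (length(msg)) msg else TRUE
  })

#' MixtureFit: a fitted Gaussian intensity mixture
#'
#' Result of EM fitting of a k-component Gaussian mixture to masked voxel
#' intensities. Components are stored in ascending-mean order after fitting.
#'
#' @slot means,sds,weights numeric length-k component parameters.
#' @slot loglik numeric log-likelihood trace over EM iterations.
#' @slot nIter integer iterations run.
#' @slot converged logical.
#' @slot clamped logical; TRUE if any component sd hit the variance floor.
#' @export
setClass("MixtureFit",
  representation(means = "numeric", sds = "numeric", weights = "numeric",
                 loglik = "numeric", nIter = "integer", converged = "logical",
                 clamped = "logical"),
  validity = function(object) {
    msg <- character()
    k <- length(object@means)
    if (length(object@sds) != k || length(object@weights) != k)
      msg <- c(msg, "means, sds, weights must have equal length")
    if (any(object@sds <= 0)) msg <- c(msg, "sds must be positive")
    if (abs(sum(object@weights) - 1) > 1e-6)
      msg <- c(msg, "weights must sum to 1")
    if (length(msg)) msg else TRUE
  })

#' AffineTransform3D: a world-mm to world-mm affine map
#'
#' @slot linear 3x3 invertible matrix.
#' @slot translation numeric length-3, mm.
#' @slot residualRms numeric; RMS landmark residual when estimated from
#'   point pairs, NA otherwise.
#' @export
setClass("AffineTransform3D",
  representation(linear = "matrix", translation = "numeric",
                 residualRms = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!all(dim(object@linear) == c(3L, 3L)))
      msg <- c(msg, "linear part must be 3x3")
    else if (abs(det(object@linear)) < 1e-12)
      msg <- c(msg, "linear part must be invertible")
    if (length(object@translation) != 3L)
      msg <- c(msg, "translation must have length 3")
    if (length(msg)) msg else TRUE
  })

#' AcpcFrame: the AC-PC anatomical reference frame
#'
#' Orthonormal frame derived from the landmarks: origin at the AC-PC
#' midpoint, \code{eAp} pointing anterior (PC to AC), \code{eLr} left to
#' right, \code{eSi} inferior to superior.
#'
#' @slot origin numeric length-3 world mm.
#' @slot eAp,eLr,eSi unit vectors, pairwise orthogonal within 1e-9.
#' @export
setClass("AcpcFrame",
  representation(origin = "numeric", eAp = "numeric", eLr = "numeric",
                 eSi = "numeric"),
  validity = function(object) {
    msg <- character()
    vs <- list(object@eAp, object@eLr, object@eSi)
    if (any(vapply(vs, length, 1L) != 3L) || length(object@origin) != 3L)
      msg <- c(msg, "origin and axes must have length 3")
    else {
      for (v in vs)
        if (abs(sqrt(sum(v^2)) - 1) > 1e-9)
          msg <- c(msg, "axes must be unit vectors")
      if (abs(sum(object@eAp * object@eLr)) > 1e-9 ||
          abs(sum(object@eAp * object@eSi)) > 1e-9 ||
          abs(sum(object@eLr * object@eSi)) > 1e-9)
        msg <- c(msg, "axes must be pairwise orthogonal")
      if (abs(det(cbind(object@eLr, object@eAp, object@eSi)) - 1) > 1e-6)
        msg <- c(msg, "triad (eLr, eAp, eSi) must be right-handed")
    }
    if (length(msg)) msg else TRUE
  })

#' PhantomSpec: geometric and imaging parameters of a synthetic head phantom
#'
#' Describes a head as nested ellipsoids centred at the world origin:
#' scalp > inner skull (scalp minus \code{skullThickness}) > brain, with a
#' white-matter ellipsoid (\code{wmFraction} of the brain semi-axes) and an
#' optional CSF-filled ventricle ellipsoid inside it. All lengths in mm.
#'
#' @slot scalpSemiAxes,brainSemiAxes numeric length-3 semi-axes (mm).
#' @slot skullThickness,csfGap single mm values; the brain plus csfGap must
#'   fit strictly inside the inner skull on every axis.
#' @slot wmFraction fraction in (0,1) scaling the brain semi-axes to the WM
#'   ellipsoid.
#' @slot ventricleSemiAxes numeric length-3 semi-axes of the central
#'   CSF ventricle, or length-0 for no ventricle.
#' @slot acOffset,pcOffset positions of AC and PC on the anterior-posterior
#'   (y) axis, mm; acOffset > pcOffset.
#' @slot landmarkElevation vertical (z) offset of nasion/inion off the AC-PC
#'   plane, mm.
#' @slot intensityMeans numeric length-3 (CSF, GM, WM) mean intensities,
#'   strictly increasing (T1 contrast).
#' @slot noiseSd additive Gaussian noise sd in intensity units.
#' @slot voxelSpacing numeric length-3 mm.
#' @slot seed integer RNG seed for the noise.
#' @export
setClass("PhantomSpec",
  representation(scalpSemiAxes = "numeric", skullThickness = "numeric",
                 csfGap = "numeric", brainSemiAxes = "numeric",
                 wmFraction = "numeric", ventricleSemiAxes = "numeric",
                 acOffset = "numeric", pcOffset = "numeric",
                 landmarkElevation = "numeric", intensityMeans = "numeric",
                 noiseSd = "numeric", voxelSpacing = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (any(object@scalpSemiAxes <= 0) || any(object@brainSemiAxes <= 0) ||
        any(object@voxelSpacing <= 0))
      msg <- c(msg, "semi-axes and voxel spacing must be positive")
    inner <- object@scalpSemiAxes - object@skullThickness
    if (any(inner <= 0))
      msg <- c(msg, "skull thickness exceeds a scalp semi-axis")
    if (any(object@brainSemiAxes + object@csfGap >= inner))
      msg <- c(msg,
        "brain ellipsoid plus CSF gap must fit strictly inside the inner skull")
    if (object@wmFraction <= 0 || object@wmFraction >= 1)
      msg <- c(msg, "wmFraction must lie in (0, 1)")
    if (length(object@ventricleSemiAxes) &&
        (length(object@ventricleSemiAxes) != 3L ||
         any(object@ventricleSemiAxes <= 0) ||
         any(object@ventricleSemiAxes >=
             object@wmFraction * object@brainSemiAxes)))
      msg <- c(msg, "ventricle must fit strictly inside the WM ellipsoid")
    if (length(object@intensityMeans) != 3L ||
        any(diff(object@intensityMeans) <= 0))
      msg <- c(msg,
        "intensityMeans must be strictly increasing (CSF < GM < WM)")
    if (object@acOffset <= object@pcOffset)
      msg <- c(msg, "acOffset must be anterior to (greater than) pcOffset")
    if (abs(object@landmarkElevation) >= object@scalpSemiAxes[3])
      msg <- c(msg, "landmarkElevation must be smaller than the scalp height")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' SubjectPhantom: one synthetic subject with full ground truth
#'
#' Bundles the rendered intensity volume with everything downstream stages
#' consume and the analytic truth they are checked against.
#'
#' @slot intensity [VolumeGrid] noisy T1-like intensities.
#' @slot truePve [TissueMaps] ground-truth partial-volume maps.
#' @slot masks [MaskSet] partial-volume compartment masks (use
#'   [binarize()] where a binary mask is required).
#' @slot landmarks [LandmarkSet].
#' @slot labels [LabelVolume] fine parcellation (angular sectors).
#' @slot lobes [LabelVolume] coarse octant "lobes".
#' @slot truth list with elements \code{morphometry} (the seven distance
#'   measures, mm) and \code{volumes} (analytic compartment volumes, mm^3).
#' @slot spec the generating [PhantomSpec].
#' @export
setClass("SubjectPhantom",
  representation(intensity = "VolumeGrid", truePve = "TissueMaps",
                 masks = "MaskSet", landmarks = "LandmarkSet",
                 labels = "LabelVolume", lobes = "LabelVolume",
                 truth = "list", spec = "PhantomSpec"))

#' GrowthModel: per-measure developmental trajectories for cohort simulation
#'
#' Each measure follows either a concave quadratic with a peak
#' (value(age) = peakValue - k (age - peakAge)^2, k >= 0) or a line
#' (value(age) = intercept + slope * age), plus additive group and sex
#' offsets and Gaussian residual noise.
#'
#' @slot measures named list; each element a list with fields \code{kind}
#'   ("quadratic" or "linear"), the kind's parameters, \code{groupPeakAge}
#'   and \code{groupValue} (named per-group additive offsets),
#'   \code{sexOffset} (added for male), and \code{residualSd}.
#' @slot groups character length-2 group labels.
#' @slot ageRange numeric length-2 years, default c(8, 16).
#' @export
setClass("GrowthModel",
  representation(measures = "list", groups = "character",
                 ageRange = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@groups) != 2L)
      msg <- c(msg, "exactly two groups are supported")
    if (length(object@ageRange) != 2L || diff(object@ageRange) <= 0)
      msg <- c(msg, "ageRange must be an increasing pair of years")
    for (nm in names(object@measures)) {
      m <- object@measures[[nm]]
      if (!m$kind %in% c("quadratic", "linear"))
        msg <- c(msg, paste0(nm, ": kind must be quadratic or linear"))
      if (m$kind == "quadratic" && m$curvature < 0)
        msg <- c(msg, paste0(nm, ": curvature must be >= 0 (inverted U)"))
      if (m$residualSd < 0)
        msg <- c(msg, paste0(nm, ": residualSd must be >= 0"))
    }
    if (length(msg)) msg else TRUE
  })
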