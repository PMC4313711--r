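#' @include AllClasses.R VolumeGrid.R landmarks.R
NULL

unitVec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

#' Build the AC-PC anatomical reference frame
#'
#' The frame origin is the AC-PC midpoint. `eAp` is the unit vector from PC
#' to AC (anterior); `eLr` is the preauricular left-to-right direction
#' orthogonalised against `eAp`; `eSi` completes the orthonormal triad.
#' When a scalp mask is supplied the superior direction is fixed toward the
#' side of greater mask extent (the top of the head); otherwise the cross
#' product eLr x eAp is used directly.
#'
#' @param lm a [LandmarkSet].
#' @param scalpMask optional [VolumeGrid] used to orient `eSi`.
#' @return an [AcpcFrame].
#' @export
buildAcpcFrame <- function(lm, scalpMask = NULL) {
  ac <- landmark(lm, "ac"); pc <- landmark(lm, "pc")
  eAp <- unitVec(ac - pc)
  lr <- landmark(lm, "preauricular_right") - landmark(lm, "preauricular_left")
  lrOrth <- lr - sum(lr * eAp) * eAp
  if (sqrt(sum(lrOrth^2)) < 1e-9)
    stop("AC-PC line is parallel to the preauricular axis; frame undefined")
  eLr <- unitVec(lrOrth)
  eSi <- c(eLr[2] * eAp[3] - eLr[3] * eAp[2],
           eLr[3] * eAp[1] - eLr[1] * eAp[3],
           eLr[1] * eAp[2] - eLr[2] * eAp[1])
  origin <- (ac + pc) / 2
  if (!is.null(scalpMask)) {
    up <- lineExtent(scalpMask, origin, eSi)
    dn <- lineExtent(scalpMask, origin, -eSi)
    if (!is.na(up) && !is.na(dn) && dn > up) {
      eSi <- -eSi
      eLr <- -eLr   # keep the triad right-handed
    }
  }
  new("AcpcFrame", origin = origin, eAp = eAp, eLr = eLr, eSi = eSi)
}

setMethod("show", "AcpcFrame", function(object) {
  cat("AcpcFrame\n  origin:", paste(round(object@origin, 2), collapse = ", "),
      "\n  eAp:", paste(round(object@eAp, 4), collapse = ", "),
      "\n  eLr:", paste(round(object@eLr, 4), collapse = ", "),
      "\n  eSi:", paste(round(object@eSi, 4), collapse = ", "), "\n")
  invisible(object)
})

# farthest point with mask >= 0.5 along +dir from point, or NA
lineExtent <- function(mask, point, dir, step = 0.5) {
  tmax <- lineGridRange(mask, point, dir)
  if (is.na(tmax[2]) || tmax[2] <= 0) return(NA_real_)
  ts <- seq(0, tmax[2], by = step)
  vals <- sampleWorld(mask, outer(ts, dir) + rep(point, each = length(ts)))
  hit <- which(vals >= 0.5)
  if (!length(hit)) NA_real_ else ts[max(hit)]
}

# parameter range [tmin, tmax] where the line point + t*dir lies inside the
# grid bounding box (voxel space slab test)
lineGridRange <- function(grid, point, dir) {
  inv <- solve(grid@affine)
  p <- as.numeric(inv[1:3, 1:3] %*% point + inv[1:3, 4])
  dv <- as.numeric(inv[1:3, 1:3] %*% dir)
  d <- dim(grid@values)
  tmin <- -Inf; tmax <- Inf
  for (i in 1:3) {
    if (abs(dv[i]) < 1e-12) {
      if (p[i] < 0 || p[i] > d[i] - 1) return(c(NA_real_, NA_real_))
    } else {
      t1 <- (0 - p[i]) / dv[i]; t2 <- (d[i] - 1 - p[i]) / dv[i]
      tmin <- max(tmin, min(t1, t2)); tmax <- min(tmax, max(t1, t2))
    }
  }
  if (tmin > tmax) c(NA_real_, NA_real_) else c(tmin, tmax)
}

# first/last >= 0.5 crossing along the full line through `point` with
# direction `dir`; returns c(tFirst, tLast) or NA pair
lineMaskSpan <- function(mask, point, dir, step = 0.1) {
  rng <- lineGridRange(mask, point, dir)
  if (any(is.na(rng))) return(c(NA_real_, NA_real_))
  ts <- seq(rng[1], rng[2], by = step)
  pts <- outer(ts, dir) + rep(point, each = length(ts))
  vals <- sampleWorld(mask, pts)
  hit <- which(vals >= 0.5)
  if (!length(hit)) return(c(NA_real_, NA_real_))
  c(ts[min(hit)], ts[max(hit)])
}

#' Brain length on the AC-PC line
#'
#' The line through AC and PC (extended both ways) is sampled at `step` mm
#' with trilinear interpolation of the brain mask; the length is the
#' distance between the first and last sample with value >= 0.5.
#'
#' @param brainMask a [VolumeGrid] (binary or partial-volume mask).
#' @param frame an [AcpcFrame].
#' @param step sampling step in mm (default 0.1).
#' @return length in mm.
#' @export
brainLength <- function(brainMask, frame, step = 0.1) {
  span <- lineMaskSpan(brainMask, frame@origin, frame@eAp, step)
  if (any(is.na(span))) stop("AC-PC line does not intersect the brain mask")
  span[2] - span[1]
}

#' Brain width on the line normal to AC-PC
#'
#' As [brainLength()], along the left-right direction through the frame
#' origin (the AC-PC midpoint; pass a frame built at AC or PC to move the
#' section).
#' @inheritParams brainLength
#' @export
brainWidth <- function(brainMask, frame, step = 0.1) {
  span <- lineMaskSpan(brainMask, frame@origin, frame@eLr, step)
  if (any(is.na(span))) stop("width line does not intersect the brain mask")
  span[2] - span[1]
}

#' Brain height from PC to the top of the brain
#'
#' Distance from PC to the last >= 0.5 sample along the superior direction
#' through PC.
#' @inheritParams brainLength
#' @param pc PC world coordinate (defaults to none; pass
#'   `landmark(lm, "pc")`).
#' @export
brainHeight <- function(brainMask, frame, pc, step = 0.1) {
  ext <- lineExtent(brainMask, pc, frame@eSi, step = step)
  if (is.na(ext)) stop("superior line through PC does not intersect the mask")
  ext
}

#' Head length, width and height
#'
#' Head length and width are the Euclidean landmark distances
#' nasion-inion and left-right preauricular; head height is the distance
#' from PC to the topmost scalp-mask sample along the superior direction.
#'
#' @param lm a [LandmarkSet].
#' @param scalpMask a [VolumeGrid].
#' @param frame an [AcpcFrame].
#' @param step sampling step in mm.
#' @return named numeric: head_length, head_width, head_height (mm).
#' @export
headMeasures <- function(lm, scalpMask, frame, step = 0.1) {
  hl <- sqrt(sum((landmark(lm, "nasion") - landmark(lm, "inion"))^2))
  hw <- sqrt(sum((landmark(lm, "preauricular_left") -
                  landmark(lm, "preauricular_right"))^2))
  hh <- lineExtent(scalpMask, landmark(lm, "pc"), frame@eSi, step = step)
  if (is.na(hh)) stop("superior line through PC does not intersect the scalp")
  c(head_length = hl, head_width = hw, head_height = hh)
}

#' AC-PC distance
#' @param lm a [LandmarkSet].
#' @return Euclidean distance between AC and PC, mm.
#' @export
acPcDistance <- function(lm)
  sqrt(sum((landmark(lm, "ac") - landmark(lm, "pc"))^2))

#' All seven morphometric measures
#'
#' Convenience wrapper computing brain length/width/height, AC-PC distance
#' and head length/width/height from the masks and landmarks.
#'
#' @param brainMask,scalpMask [VolumeGrid]s.
#' @param lm a [LandmarkSet].
#' @param step line-sampling step in mm.
#' @return named numeric vector of the seven measures (mm).
#' @export
morphometryRecord <- function(brainMask, scalpMask, lm, step = 0.1) {
  frame <- buildAcpcFrame(lm, scalpMask)
  c(brain_length = brainLength(brainMask, frame, step),
    brain_width = brainWidth(brainMask, frame, step),
    brain_height = brainHeight(brainMask, frame, landmark(lm, "pc"), step),
    ac_pc_distance = acPcDistance(lm),
    headMeasures(lm, scalpMask, frame, step))
}

#' Write a morphometry record as TSV
#' @param record named numeric vector (e.g. from [morphometryRecord()]).
#' @param path output TSV path.
#' @export
writeMorphometry <- function(record, path) {
  df <- as.data.frame(as.list(record), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
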