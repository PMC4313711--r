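#' @include AllClasses.R
NULL

#' Voxel spacing of a grid
#' @param x a [VolumeGrid] (or subclass).
#' @return numeric length-3 spacing in mm.
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' Volume of one voxel in mm^3
#' @param x a [VolumeGrid] (or subclass).
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))

#' Extract the raw value array
#' @param x a [VolumeGrid] (or subclass).
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' Threshold a scalar volume to a binary mask
#' @param x a [VolumeGrid].
#' @param threshold values >= threshold become 1 (default 0.5).
#' @return a [VolumeGrid] with 0/1 values.
#' @export
setGeneric("binarize", function(x, threshold = 0.5) standardGeneric("binarize"))

#' Landmark coordinates as a matrix
#' @param x a [LandmarkSet].
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' Apply a spatial transform to points or landmarks
#' @param transform an [AffineTransform3D].
#' @param x an n-x-3 point matrix, length-3 point, or [LandmarkSet].
#' @export
setGeneric("applyTransform",
           function(transform, x) standardGeneric("applyTransform"))
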