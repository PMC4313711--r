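#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a LandmarkSet
#'
#' @param nasion,inion,preauricular_left,preauricular_right,ac,pc length-3
#'   world coordinates (RAS, mm). Alternatively pass a 6x3 matrix with the
#'   canonical row names as the single argument `coords`.
#' @param coords optional 6x3 matrix, rows named as [landmarkNames()].
#' @return a [LandmarkSet].
#' @examples
#' lm <- landmarkSet(nasion = c(0, 95, 0), inion = c(0, -95, 0),
#'                   preauricular_left = c(-78, 0, 0),
#'                   preauricular_right = c(78, 0, 0),
#'                   ac = c(0, 14, 0), pc = c(0, -13, 0))
#' acPcDistance(lm)
#' @export
landmarkSet <- function(nasion, inion, preauricular_left, preauricular_right,
                        ac, pc, coords = NULL) {
  if (is.null(coords)) {
    coords <- rbind(nasion = nasion, inion = inion,
                    preauricular_left = preauricular_left,
                    preauricular_right = preauricular_right,
                    ac = ac, pc = pc)
  }
  coords <- as.matrix(coords)[landmarkNames(), , drop = FALSE]
  colnames(coords) <- c("x", "y", "z")
  new("LandmarkSet", coords = coords)
}

#' @rdname coords
#' @export
setMethod("coords", "LandmarkSet", function(x) x@coords)

#' Extract one landmark
#' @param x a [LandmarkSet].
#' @param name one of [landmarkNames()].
#' @return numeric length-3 world coordinate.
#' @export
landmark <- function(x, name) {
  name <- match.arg(name, landmarkNames())
  as.numeric(x@coords[name, ])
}

setMethod("show", "LandmarkSet", function(object) {
  cat("LandmarkSet (world mm):\n")
  print(round(object@coords, 2))
  invisible(object)
})

#' Read landmarks from JSON
#'
#' Expects a JSON object mapping landmark names to [x, y, z] world-mm
#' coordinates (RAS).
#' @param path JSON file path.
#' @return a [LandmarkSet].
#' @export
readLandmarks <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  missing <- setdiff(landmarkNames(), names(lst))
  if (length(missing))
    stop("landmark file is missing: ", paste(missing, collapse = ", "))
  landmarkSet(coords = do.call(rbind, lst[landmarkNames()]))
}

#' Write landmarks to JSON
#' @param x a [LandmarkSet].
#' @param path output JSON path.
#' @export
writeLandmarks <- function(x, path) {
  lst <- lapply(seq_len(6), function(i) as.numeric(x@coords[i, ]))
  names(lst) <- rownames(x@coords)
  jsonlite::write_json(lst, path, digits = NA)
  invisible(path)
}
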