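#' @include AllClasses.R VolumeGrid.R landmarks.R morphometry.R
NULL

#' Voxel-count volume of a binary mask
#'
#' Number of non-zero voxels times the voxel volume. Non-binary input is an
#' error; threshold soft masks explicitly with [binarize()].
#'
#' @param mask a [VolumeGrid] with values in {0, 1}.
#' @return volume in mm^3.
#' @export
maskVolume <- function(mask) {
  v <- mask@values
  if (any(v != 0 & v != 1))
    stop("mask is not binary; use binarize() first")
  sum(v) * voxelVolume(mask)
}

#' The two head-volume reference planes
#'
#' Plane A passes through the left preauricular point, the nasion and the
#' right preauricular point; plane B through the preauriculars and the
#' inion. Each is returned as a unit normal and offset with the normal
#' oriented superior (toward the scalp top), so the signed distance
#' `sum(normal * x) - offset` is >= 0 on the superior side.
#'
#' @param lm a [LandmarkSet].
#' @return list of two lists with elements `normal` and `offset`.
#' @export
cutPlanes <- function(lm) {
  frame <- buildAcpcFrame(lm)
  pl <- landmark(lm, "preauricular_left")
  pr <- landmark(lm, "preauricular_right")
  mk <- function(third) {
    u <- pr - pl; v <- third - pl
    n <- c(u[2] * v[3] - u[3] * v[2],
           u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
    if (sqrt(sum(n^2)) < 1e-9)
      stop("degenerate cut plane: ", paste(round(third, 1), collapse = ","),
           " lies on the preauricular axis")
    n <- unitVec(n)
    if (sum(n * frame@eSi) < 0) n <- -n
    list(normal = n, offset = sum(n * pl))
  }
  list(nasion = mk(landmark(lm, "nasion")),
       inion = mk(landmark(lm, "inion")))
}

#' Plane-cut head volume
#'
#' Counts scalp-mask voxels whose centres lie on the superior side of the
#' nasion and inion reference planes (see [cutPlanes()]) times the voxel
#' volume. With `rule = "both"` (default) a voxel must be above both
#' planes (the roof-shaped wedge over the preauricular axis); `"either"`
#' accepts either side.
#'
#' @param scalpMask a [VolumeGrid]; soft masks are thresholded at 0.5.
#' @param lm a [LandmarkSet].
#' @param rule "both" or "either".
#' @return volume in mm^3.
#' @export
headVolume <- function(scalpMask, lm, rule = c("both", "either")) {
  rule <- match.arg(rule)
  pls <- cutPlanes(lm)
  inMask <- which(scalpMask@values >= 0.5)
  if (!length(inMask)) return(0)
  d <- dim(scalpMask@values)
  ijk <- arrayInd(inMask, d) - 1L
  world <- voxelToWorld(scalpMask, ijk)
  sA <- world %*% pls$nasion$normal - pls$nasion$offset
  sB <- world %*% pls$inion$normal - pls$inion$offset
  above <- if (rule == "both") sA >= 0 & sB >= 0 else sA >= 0 | sB >= 0
  sum(above) * voxelVolume(scalpMask)
}

#' Partial-volume-weighted tissue volume over a region
#'
#' Sum of the PVE values over the selected voxels times the voxel volume.
#' The region may be a binary/soft mask (global volume: pass the brain
#' mask) or a [LabelVolume] with the label ids to select.
#'
#' @param maps a [TissueMaps].
#' @param tissue "gm", "wm" or "csf".
#' @param region a [VolumeGrid] mask, or a [LabelVolume].
#' @param labels label ids selected when `region` is a [LabelVolume]
#'   (default: all non-background labels). Unknown ids are an error.
#' @return volume in mm^3.
#' @export
pveVolume <- function(maps, tissue = c("gm", "wm", "csf"), region,
                      labels = NULL) {
  tissue <- match.arg(tissue)
  pve <- slot(maps, tissue)
  if (!identical(dim(region@values), dim(pve@values)))
    stop("region and PVE maps are on different grids")
  sel <- if (is(region, "LabelVolume")) {
    known <- as.numeric(names(region@nameMap))
    if (is.null(labels)) labels <- known
    bad <- setdiff(labels, known)
    if (length(bad))
      stop("unknown label id(s) ", paste(bad, collapse = ", "),
           "; known ids: ", paste(known, collapse = ", "))
    region@values %in% labels
  } else {
    region@values >= 0.5
  }
  sum(pve@values[sel]) * voxelVolume(pve)
}

#' Global, cortical, lobar and regional volume profile
#'
#' Fills the standard volume record for one subject: total GM/WM/CSF over
#' the brain mask, cortical GM/WM (union of the fine parcellation labels),
#' per-lobe GM/WM/total, and per-region GM and total volumes.
#'
#' @param maps a [TissueMaps].
#' @param fused fine-parcellation [LabelVolume] (e.g. majority-vote fused).
#' @param lobes lobar [LabelVolume].
#' @param brainMask binary [VolumeGrid].
#' @return list with `totals` (named numeric), `perLobe` and `perRegion`
#'   data.frames.
#' @export
regionalProfile <- function(maps, fused, lobes, brainMask) {
  vv <- voxelVolume(maps@gm)
  d <- dim(maps@gm@values)
  if (!identical(d, dim(fused@values)) || !identical(d, dim(lobes@values)) ||
      !identical(d, dim(brainMask@values)))
    stop("all inputs must share one grid")
  bm <- brainMask@values >= 0.5
  gm <- maps@gm@values; wm <- maps@wm@values; csf <- maps@csf@values
  totals <- c(brain_volume = sum(bm) * vv,
              gm_total = sum(gm[bm]) * vv,
              wm_total = sum(wm[bm]) * vv,
              csf_total = sum(csf[bm]) * vv)
  ctx <- fused@values > 0
  totals <- c(totals, gm_cortex = sum(gm[ctx]) * vv,
              wm_cortex = sum(wm[ctx]) * vv)

  tab <- function(lab, nameMap) {
    f <- factor(lab@values[lab@values > 0],
                levels = sort(as.numeric(names(nameMap))))
    sel <- lab@values > 0
    data.frame(
      id = as.numeric(levels(f)),
      name = as.character(nameMap[levels(f)]),
      gm = as.numeric(tapply(gm[sel], f, sum, default = 0)) * vv,
      wm = as.numeric(tapply(wm[sel], f, sum, default = 0)) * vv,
      total = as.numeric(tapply((gm + wm + csf)[sel], f, sum,
                                default = 0)) * vv,
      row.names = NULL)
  }
  list(totals = totals, perLobe = tab(lobes, lobes@nameMap),
       perRegion = tab(fused, fused@nameMap))
}

#' Region-by-age-group ratio table
#'
#' For each region, the mean volume within each age group divided by the
#' grand mean of those per-age-group means — the normalised regional
#' developmental profile. A region whose cohort volumes are flat across
#' age groups has all ratios 1.
#'
#' @param df data.frame with columns `region`, `age_group` and `volume`
#'   (one row per subject x region).
#' @return data.frame region x age_group with a `ratio` column.
#' @export
regionRatioTable <- function(df) {
  stopifnot(all(c("region", "age_group", "volume") %in% names(df)))
  agg <- stats::aggregate(volume ~ region + age_group, df, mean)
  grand <- stats::aggregate(volume ~ region, agg, mean)
  names(grand)[2] <- "grand_mean"
  out <- merge(agg, grand, by = "region")
  out$ratio <- out$volume / out$grand_mean
  out[order(out$region, out$age_group), c("region", "age_group", "ratio")]
}

#' Long-format volume table for one subject
#'
#' Flattens a [regionalProfile()] result into the long TSV layout
#' (subject, measure, region, tissue, mm3).
#' @param subjectId subject identifier.
#' @param profile result of [regionalProfile()].
#' @return data.frame.
#' @export
volumesLong <- function(subjectId, profile) {
  tot <- data.frame(subject = subjectId, measure = names(profile$totals),
                    region = "global", tissue = NA_character_,
                    mm3 = as.numeric(profile$totals))
  lb <- profile$perLobe; rg <- profile$perRegion
  lobe <- data.frame(subject = subjectId,
                     measure = rep(c("lobe_gm", "lobe_wm", "lobe_total"),
                                   each = nrow(lb)),
                     region = rep(lb$name, 3), tissue = rep(c("gm", "wm", NA),
                                                            each = nrow(lb)),
                     mm3 = c(lb$gm, lb$wm, lb$total))
  reg <- data.frame(subject = subjectId,
                    measure = rep(c("region_gm", "region_total"),
                                  each = nrow(rg)),
                    region = rep(rg$name, 2),
                    tissue = rep(c("gm", NA), each = nrow(rg)),
                    mm3 = c(rg$gm, rg$total))
  rbind(tot, lobe, reg)
}
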