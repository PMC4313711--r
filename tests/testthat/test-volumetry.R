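test_that("mask volume is voxel count times voxel volume", {
  expect_equal(maskVolume(volumeGrid(array(1, c(10, 10, 10)), 1)), 1000)
  expect_equal(maskVolume(volumeGrid(array(0, c(5, 5, 5)), 1)), 0)
  arr <- array(0, c(10, 10, 10)); arr[seq_len(117)] <- 1
  expect_equal(maskVolume(volumeGrid(arr, 2)), 117 * 8)
  expect_error(maskVolume(volumeGrid(array(0.5, c(2, 2, 2)), 1)),
               "not binary")
})

test_that("coplanar cut planes reproduce the half-ellipsoid head volume", {
  ph <- smallPhantom()    # landmark elevation 0: both planes at z = 0
  hv <- headVolume(ph@masks@scalp, ph@landmarks)
  closed <- 2 / 3 * pi * prod(ph@spec@scalpSemiAxes)
  expect_lt(abs(hv / closed - 1), 0.01)
  expect_equal(hv, unname(ph@truth$volumes["head_volume"]),
               tolerance = 0.01)
})

test_that("a scalp mask entirely below both planes yields zero", {
  ph <- smallPhantom()
  shifted <- ph@masks@scalp
  aff <- shifted@affine
  aff[3, 4] <- aff[3, 4] - 500   # push the whole head far inferior
  low <- volumeGrid(values(shifted), affine = aff)
  expect_equal(headVolume(low, ph@landmarks), 0)
})

test_that("elevated nasion cuts a wedge off the coplanar head volume", {
  phFlat <- smallPhantom()
  phUp <- makePhantom(smallSpec(landmarkElevation = 8))
  hvFlat <- headVolume(phFlat@masks@scalp, phFlat@landmarks)
  hvUp <- headVolume(phUp@masks@scalp, phUp@landmarks)
  expect_lt(hvUp, hvFlat)
  # "either plane" keeps the inter-plane wedge, so it can only be larger
  expect_gte(headVolume(phUp@masks@scalp, phUp@landmarks, rule = "either"),
             hvUp)
})

test_that("head volume matches an independent signed-distance recount", {
  # small grid, brute-force oracle recomputed from first principles
  m <- ellipsoidMask(c(24, 26, 25), spacing = 2.5, smooth = FALSE)
  lm <- landmarkSet(nasion = c(0, 25.1, 6), inion = c(0, -25.1, 0),
                    preauricular_left = c(-24, 0, 0),
                    preauricular_right = c(24, 0, 0),
                    ac = c(0, 6, 0), pc = c(0, -6, 0))
  hv <- headVolume(m, lm)
  # oracle: loop over voxels, test both plane sides directly
  d <- dim(values(m)); count <- 0
  pl <- c(-24, 0, 0); pr <- c(24, 0, 0)
  nrmOf <- function(third) {
    n <- pracma_cross <- c((pr - pl)[2] * (third - pl)[3] -
                             (pr - pl)[3] * (third - pl)[2],
                           (pr - pl)[3] * (third - pl)[1] -
                             (pr - pl)[1] * (third - pl)[3],
                           (pr - pl)[1] * (third - pl)[2] -
                             (pr - pl)[2] * (third - pl)[1])
    if (n[3] < 0) n <- -n
    n
  }
  nA <- nrmOf(c(0, 25.1, 6)); nB <- nrmOf(c(0, -25.1, 0))
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (values(m)[i, j, k] >= 0.5) {
      w <- as.numeric(voxelToWorld(m, c(i, j, k) - 1))
      if (sum(nA * (w - pl)) >= 0 && sum(nB * (w - pl)) >= 0)
        count <- count + 1
    }
  }
  expect_equal(hv, count * voxelVolume(m))
})

test_that("PVE volumes integrate fractions over the selection", {
  arr <- array(0, c(10, 10, 10)); arr[seq_len(1000)] <- 0.5
  maps <- new("TissueMaps", gm = volumeGrid(arr, 1),
              wm = volumeGrid(arr, 1),
              csf = volumeGrid(array(0, c(10, 10, 10)), 1),
              brainMask = volumeGrid(array(1, c(10, 10, 10)), 1))
  expect_equal(pveVolume(maps, "gm", maps@brainMask), 500)
  # tissue PVE volumes over the brain mask sum to the mask volume
  ph <- smallPhantom()
  bm <- ph@truePve@brainMask
  tot <- pveVolume(ph@truePve, "gm", bm) + pveVolume(ph@truePve, "wm", bm) +
    pveVolume(ph@truePve, "csf", bm)
  expect_equal(tot, maskVolume(bm), tolerance = 1e-9)
  # unknown label id fails listing the known ids
  expect_error(pveVolume(ph@truePve, "gm", ph@lobes, labels = 99),
               "known ids")
  # grid mismatch fails
  expect_error(pveVolume(maps, "gm", bm), "different grids")
})

test_that("ground-truth tissue volumes match the nested-ellipsoid forms", {
  ph <- smallPhantom1()
  bm <- ph@truePve@brainMask
  tv <- ph@truth$volumes
  expect_lt(abs(pveVolume(ph@truePve, "gm", bm) / tv[["gm_total"]] - 1), 0.01)
  expect_lt(abs(pveVolume(ph@truePve, "wm", bm) / tv[["wm_total"]] - 1), 0.01)
  expect_lt(abs(maskVolume(binarize(ph@masks@innerSkull)) /
                  tv[["intracranial_volume"]] - 1), 0.01)
  expect_lt(abs(maskVolume(binarize(ph@masks@brain)) /
                  tv[["brain_volume"]] - 1), 0.01)
})

test_that("regional volumes partition the global volumes", {
  ph <- smallPhantom()
  bm <- ph@truePve@brainMask
  prof <- regionalProfile(ph@truePve, ph@labels, ph@lobes, bm)
  # the 50 sectors partition the brain: totals add up to the global volume
  expect_equal(sum(prof$perRegion$total), unname(prof$totals["brain_volume"]),
               tolerance = 1e-9)
  expect_equal(sum(prof$perRegion$gm), unname(prof$totals["gm_total"]),
               tolerance = 1e-9)
  expect_equal(sum(prof$perLobe$total), unname(prof$totals["brain_volume"]),
               tolerance = 1e-9)
  # single-region atlas covering the whole brain: region totals = global
  one <- new("LabelVolume", values = (values(bm) >= 0.5) * 1L,
             spacing = spacing(bm), affine = bm@affine,
             nameMap = c(`1` = "whole_brain"))
  prof1 <- regionalProfile(ph@truePve, one, one, bm)
  expect_equal(prof1$perRegion$total, unname(prof1$totals["brain_volume"]))
  expect_equal(prof1$perRegion$gm, unname(prof1$totals["gm_total"]))
  # two-region left/right split of a symmetric phantom: equal halves
  lab <- array(0L, dim(values(bm)))
  co <- worldToVoxel(bm, c(0, 0, 0))   # 0-based fractional index of x = 0
  inB <- values(bm) >= 0.5
  X <- slice.index(lab, 1) - 1
  lab[inB & X < co[1]] <- 1L
  lab[inB & X >= co[1]] <- 2L
  two <- new("LabelVolume", values = lab, spacing = spacing(bm),
             affine = bm@affine, nameMap = c(`1` = "left", `2` = "right"))
  prof2 <- regionalProfile(ph@truePve, two, two, bm)
  expect_equal(prof2$perRegion$total[1], prof2$perRegion$total[2],
               tolerance = voxelVolume(bm) / prof2$totals[["brain_volume"]])
})

test_that("the ratio table is 1 for regions flat across age groups", {
  df <- expand.grid(region = c("r1", "r2"), age_group = c("8", "9-10"),
                    subject = 1:5)
  df$volume <- ifelse(df$region == "r1", 100, 50)
  rt <- regionRatioTable(df)
  expect_true(all(abs(rt$ratio - 1) < 1e-12))
  # a doubling region shows ratios 2/3 and 4/3
  df$volume[df$region == "r2" & df$age_group == "9-10"] <- 100
  rt2 <- regionRatioTable(df)
  r2 <- rt2[rt2$region == "r2", ]
  expect_equal(sort(r2$ratio), c(2 / 3, 4 / 3))
})

test_that("volumes are stable under voxel-size halving", {
  phCoarse <- makePhantom(phantomSpec(noiseSd = 0, voxelSpacing = 2))
  phFine <- makePhantom(phantomSpec(noiseSd = 0, voxelSpacing = 1))
  vols <- vapply(list(phCoarse, phFine), function(ph)
    c(brain = maskVolume(binarize(ph@masks@brain)),
      head = headVolume(ph@masks@scalp, ph@landmarks)), numeric(2))
  expect_lt(abs(vols["brain", 1] / vols["brain", 2] - 1), 0.005)
  expect_lt(abs(vols["head", 1] / vols["head", 2] - 1), 0.005)
})
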