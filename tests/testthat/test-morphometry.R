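test_that("AC-PC frame is axis-aligned for axis-aligned landmarks", {
  lm <- axisLandmarks(ac = c(0, 20, 0), pc = c(0, -10, 0))
  fr <- buildAcpcFrame(lm)
  expect_equal(fr@eAp, c(0, 1, 0), tolerance = 1e-12)
  expect_equal(fr@eLr, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(fr@eSi, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(fr@origin, c(0, 5, 0), tolerance = 1e-12)
})

test_that("the frame triad is orthonormal for arbitrary valid landmarks", {
  for (seed in 1:5) {
    rt <- randomRigid(seed)
    lm <- transformLandmarks(axisLandmarks(), rt$R, rt$t)
    fr <- buildAcpcFrame(lm)
    expect_true(validObject(fr))   # validity enforces orthonormality < 1e-9
    # rotation equivariance: the frame rotates with the landmarks
    fr0 <- buildAcpcFrame(axisLandmarks())
    expect_equal(fr@eAp, as.numeric(rt$R %*% fr0@eAp), tolerance = 1e-9)
    expect_equal(fr@eLr, as.numeric(rt$R %*% fr0@eLr), tolerance = 1e-9)
    expect_equal(fr@eSi, as.numeric(rt$R %*% fr0@eSi), tolerance = 1e-9)
  }
  # degenerate: AC-PC parallel to the preauricular axis
  bad <- landmarkSet(nasion = c(0, 90, 0), inion = c(0, -90, 0),
                     preauricular_left = c(0, -70, 0),
                     preauricular_right = c(0, 70, 0),
                     ac = c(0, 10, 0), pc = c(0, -10, 0))
  expect_error(buildAcpcFrame(bad), "frame undefined")
})

# one soft spherical mask (r = 60) reused by the chord tests
sphere60 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- ellipsoidMask(c(60, 60, 60), spacing = 1)
    cache
  }
})

test_that("brain length is the chord of the mask along the AC-PC line", {
  m <- sphere60()
  # through the centre: full diameter
  fr <- buildAcpcFrame(axisLandmarks())
  expect_equal(brainLength(m, fr), 120, tolerance = 0.2)
  # line offset 30 mm laterally: chord 2 sqrt(60^2 - 30^2)
  lmOff <- axisLandmarks(ac = c(30, 10, 0), pc = c(30, -10, 0))
  expect_equal(brainLength(m, buildAcpcFrame(lmOff)),
               2 * sqrt(60^2 - 30^2), tolerance = 0.3)
  # a line that misses the mask entirely
  lmMiss <- axisLandmarks(ac = c(100, 10, 0), pc = c(100, -10, 0))
  expect_error(brainLength(m, buildAcpcFrame(lmMiss)), "mask")
})

test_that("chords of an axis-aligned ellipsoid match the closed form", {
  m <- ellipsoidMask(c(70, 75, 55), spacing = 1)
  fr <- buildAcpcFrame(axisLandmarks())
  expect_equal(brainLength(m, fr), 150, tolerance = 0.2)   # along b = 75
  expect_equal(brainWidth(m, fr), 140, tolerance = 0.2)    # along a = 70
  expect_equal(brainHeight(m, fr, c(0, 0, 0)), 55, tolerance = 0.2)
  # translation along the AP axis leaves the width unchanged
  # (the width line re-centres at the shifted AC-PC midpoint)
  lmShift <- axisLandmarks(ac = c(0, 30, 0), pc = c(0, 10, 0))
  w <- brainWidth(m, buildAcpcFrame(lmShift))
  expect_equal(w, 2 * 70 * sqrt(1 - (20 / 75)^2), tolerance = 0.3)
})

test_that("brain height runs from PC to the top of the mask", {
  m <- sphere60()
  fr <- buildAcpcFrame(axisLandmarks())
  # PC at the centre of the sphere: height = radius
  expect_equal(brainHeight(m, fr, c(0, -10, 0)),
               sqrt(60^2 - 10^2), tolerance = 0.2)
  # PC displaced 10 mm below the centre: radius + offset
  expect_equal(brainHeight(m, fr, c(0, 0, -10)), 70, tolerance = 0.2)
})

test_that("head measures combine landmark distances and the scalp top", {
  lm <- axisLandmarks(nasion = c(0, 95, 0), inion = c(0, -95, 0),
                      paL = c(-78, 0, 0), paR = c(78, 0, 0))
  ph <- smallPhantom()
  fr <- buildAcpcFrame(lm)
  hm <- headMeasures(lm, ph@masks@scalp, fr)
  expect_equal(unname(hm["head_length"]), 190)
  expect_equal(unname(hm["head_width"]), 156)
  # scalp ellipsoid c = 42, PC on the z = 0 plane at y = -10:
  # top of scalp above PC at 42 sqrt(1 - (10/46)^2)
  expect_equal(unname(hm["head_height"]), 42 * sqrt(1 - (10 / 46)^2),
               tolerance = 0.3)
  expect_equal(acPcDistance(axisLandmarks(ac = c(0, 15, 0),
                                          pc = c(0, -12, 0))), 27)
  set.seed(2)
  u <- rnorm(3); u <- u / sqrt(sum(u^2))
  lm2 <- axisLandmarks(ac = c(1, 2, 3) + 25 * u, pc = c(1, 2, 3))
  expect_equal(acPcDistance(lm2), 25, tolerance = 1e-9)
})

test_that("all seven measures are invariant under rigid motion", {
  ph <- smallPhantom()
  base <- morphometryRecord(ph@masks@brain, ph@masks@scalp, ph@landmarks)
  for (seed in c(3, 17)) {
    rt <- randomRigid(seed)
    brainT <- transformGrid(ph@masks@brain, rt$R, rt$t)
    scalpT <- transformGrid(ph@masks@scalp, rt$R, rt$t)
    lmT <- transformLandmarks(ph@landmarks, rt$R, rt$t)
    moved <- morphometryRecord(brainT, scalpT, lmT)
    expect_lt(max(abs(moved - base)), 0.5)
  }
})

test_that("noise-free phantom measures match analytic truth within 0.5 mm", {
  ph <- smallPhantom1()   # 1 mm voxels: the sub-voxel accuracy regime
  rec <- morphometryRecord(ph@masks@brain, ph@masks@scalp, ph@landmarks)
  truth <- ph@truth$morphometry[names(rec)]
  expect_lt(max(abs(rec - truth)), 0.5)
})

test_that("measures scale linearly under uniform phantom scaling", {
  s <- 1.15
  sp <- smallSpec()
  spBig <- phantomSpec(scalpSemiAxes = sp@scalpSemiAxes * s,
                       skullThickness = sp@skullThickness * s,
                       csfGap = sp@csfGap * s,
                       brainSemiAxes = sp@brainSemiAxes * s,
                       wmFraction = sp@wmFraction,
                       ventricleSemiAxes = sp@ventricleSemiAxes * s,
                       acOffset = sp@acOffset * s, pcOffset = sp@pcOffset * s,
                       intensityMeans = sp@intensityMeans, noiseSd = 0,
                       voxelSpacing = sp@voxelSpacing)
  phBig <- makePhantom(spBig)
  ph <- smallPhantom()
  rec <- morphometryRecord(ph@masks@brain, ph@masks@scalp, ph@landmarks)
  recBig <- morphometryRecord(phBig@masks@brain, phBig@masks@scalp,
                              phBig@landmarks)
  expect_lt(max(abs(recBig - s * rec)), 0.8)
  expect_equal(unname(phBig@truth$morphometry),
               unname(s * ph@truth$morphometry), tolerance = 1e-9)
})
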