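# Small, fast phantom used across tests (noise-free unless overridden).
smallSpec <- function(...) {
  args <- list(scalpSemiAxes = c(40, 46, 42), skullThickness = 4, csfGap = 3,
               brainSemiAxes = c(28, 33, 30), wmFraction = 0.7,
               ventricleSemiAxes = c(8, 10, 9), acOffset = 6, pcOffset = -6,
               landmarkElevation = 0, intensityMeans = c(30, 70, 110),
               noiseSd = 0, voxelSpacing = 2, seed = 1L)
  over <- list(...)
  args[names(over)] <- over
  do.call(phantomSpec, args)
}

# cache the default small phantom: several test files reuse it
smallPhantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- makePhantom(smallSpec())
    cache
  }
})

# 1 mm version for the sub-voxel accuracy properties
smallPhantom1 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- makePhantom(smallSpec(voxelSpacing = 1))
    cache
  }
})

# axis-aligned landmark set centred on the origin
axisLandmarks <- function(ac = c(0, 10, 0), pc = c(0, -10, 0),
                          paL = c(-70, 0, 0), paR = c(70, 0, 0),
                          nasion = c(0, 90, 0), inion = c(0, -90, 0)) {
  landmarkSet(nasion = nasion, inion = inion, preauricular_left = paL,
              preauricular_right = paR, ac = ac, pc = pc)
}

# random rigid transform (rotation + translation), seeded
randomRigid <- function(seed) {
  set.seed(seed)
  A <- matrix(rnorm(9), 3, 3)
  Q <- qr.Q(qr(A))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  list(R = Q, t = runif(3, -20, 20))
}

# apply a rigid transform to a VolumeGrid by composing it into the affine
transformGrid <- function(grid, R, t) {
  M <- diag(4); M[1:3, 1:3] <- R; M[1:3, 4] <- t
  volumeGrid(values(grid), affine = M %*% grid@affine)
}

transformLandmarks <- function(lm, R, t) {
  co <- t(R %*% t(coords(lm)) + t)
  rownames(co) <- rownames(coords(lm))
  landmarkSet(coords = co)
}
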