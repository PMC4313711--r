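test_that("interior voxels get pure tissue PVE and exact intensity", {
  ph <- smallPhantom()
  sp <- ph@spec
  # a voxel centre deep inside the WM shell (between ventricle and WM edge)
  target <- c(0.85 * sp@wmFraction * sp@brainSemiAxes[1], 0, 0)
  v <- round(worldToVoxel(ph@intensity, target)) + 1
  expect_equal(ph@truePve@wm@values[v[1], v[2], v[3]], 1)
  expect_equal(ph@truePve@gm@values[v[1], v[2], v[3]], 0)
  expect_equal(ph@intensity@values[v[1], v[2], v[3]],
               sp@intensityMeans[3])
  # and one deep inside the GM shell
  target <- c(0, 0.97 * sp@brainSemiAxes[2], 0) * 0.98
  v <- round(worldToVoxel(ph@intensity, target)) + 1
  expect_equal(ph@truePve@gm@values[v[1], v[2], v[3]], 1)
  expect_equal(ph@intensity@values[v[1], v[2], v[3]],
               sp@intensityMeans[2])
})

test_that("supersampled voxelisation reproduces the analytic ellipsoid volume", {
  m <- ellipsoidMask(c(60, 70, 55), spacing = 1, smooth = FALSE)
  vol <- maskVolume(binarize(m))
  expect_lt(abs(vol / ellipsoidVolume(c(60, 70, 55)) - 1), 0.01)
})

test_that("zero landmark elevation puts all six landmarks on one plane", {
  ph <- smallPhantom()
  expect_equal(unname(coords(ph@landmarks)[, "z"]), rep(0, 6))
  # nonzero elevation lifts nasion/inion only
  ph2 <- makePhantom(smallSpec(landmarkElevation = 8))
  z <- coords(ph2@landmarks)[, "z"]
  expect_equal(unname(z[c("nasion", "inion")]), c(8, 8))
  expect_equal(unname(z[c("preauricular_left", "ac", "pc")]), rep(0, 3))
})

test_that("phantom generation is deterministic given spec and seed", {
  a <- makePhantom(smallSpec(noiseSd = 4, seed = 11L))
  b <- makePhantom(smallSpec(noiseSd = 4, seed = 11L))
  expect_identical(a@intensity@values, b@intensity@values)
  expect_identical(a@truePve@gm@values, b@truePve@gm@values)
  c <- makePhantom(smallSpec(noiseSd = 4, seed = 12L))
  expect_false(identical(a@intensity@values, c@intensity@values))
})

test_that("PVE conservation holds: sum 1 inside brain mask, 0 outside", {
  ph <- smallPhantom()
  s <- ph@truePve@gm@values + ph@truePve@wm@values + ph@truePve@csf@values
  m <- ph@truePve@brainMask@values >= 0.5
  expect_true(all(abs(s[m] - 1) <= 1e-6))
  expect_true(all(s[!m] == 0))
  expect_true(validObject(ph@truePve))
})

test_that("compartment masks nest: brain within inner skull within scalp", {
  ph <- smallPhantom()
  expect_true(all(ph@masks@brain@values <= ph@masks@innerSkull@values + 1e-9))
  expect_true(all(ph@masks@innerSkull@values <= ph@masks@scalp@values + 1e-9))
})

test_that("grid too small for the scalp is an explicit failure", {
  expect_error(makePhantom(smallSpec(), dims = c(20L, 20L, 20L)),
               "scalp ellipsoid")
  expect_error(phantomSpec(intensityMeans = c(70, 30, 110)),
               "strictly increasing")
  expect_error(phantomSpec(brainSemiAxes = c(70, 90, 100)),
               "inner skull")
})

test_that("noise-free cohorts reproduce the growth model exactly", {
  model <- defaultGrowthModel(residualScale = 0)
  sim <- simulateCohort(model, data.frame(group = c("CN", "US"),
                                          age = c(10, 14), n = c(4, 4)),
                        seed = 3)
  co <- sim$cohort
  for (ms in measureNames(model)) {
    expect_equal(co[[ms]],
                 evaluateGrowthModel(model, ms, co$age, co$group, co$sex),
                 tolerance = 1e-12)
  }
  # quadratic measure at its peak age equals the peak value exactly
  gm <- model@measures$gm_total
  expect_equal(evaluateGrowthModel(model, "gm_total", gm$peakAge, "CN", "F"),
               gm$peakValue)
  # linear measure: difference across 8 years equals 8 * slope
  wm <- model@measures$wm_total
  d <- evaluateGrowthModel(model, "wm_total", 16, "CN") -
       evaluateGrowthModel(model, "wm_total", 8, "CN")
  expect_equal(d, 8 * wm$slope)
  expect_error(evaluateGrowthModel(model, "no_such", 10), "known measures")
})

test_that("cohort simulation reproduces the reference demographic totals", {
  sim <- simulateCohort(defaultGrowthModel(), referenceAgeTable(), seed = 1)
  co <- sim$cohort
  expect_equal(sum(co$group == "CN"), 133)
  expect_equal(sum(co$group == "US"), 149)
  expect_equal(sum(co$group == "CN" & co$sex == "M"), 83)
  expect_true(all(co$age >= 8 & co$age < 17))
  expect_false(anyNA(co[measureNames(defaultGrowthModel())]))
  # reproducibility
  sim2 <- simulateCohort(defaultGrowthModel(), referenceAgeTable(), seed = 1)
  expect_identical(sim$cohort, sim2$cohort)
})

test_that("two-year age regrouping matches the published binning", {
  co <- data.frame(subject_id = paste0("S", 1:4), age = c(8, 9, 10, 11) + 0.5)
  rg <- regroupAges(co, "two_year")
  expect_equal(as.character(rg$age_group), c("8", "9-10", "9-10", "11-12"))
  # reference one-year rows regrouped: the 13-14 CN bin holds 21 + 18 = 39
  tab <- referenceAgeTable()
  cn <- tab[tab$group == "CN", ]
  co2 <- data.frame(subject_id = seq_len(sum(cn$n)),
                    age = rep(cn$age, cn$n) + 0.25)
  rg2 <- regroupAges(co2, "two_year")
  expect_equal(sum(rg2$age_group == "13-14"), 39)
  expect_equal(nrow(rg2), 133)
  # empty cohort keeps the schema
  empty <- regroupAges(co[0, ], "two_year")
  expect_equal(nrow(empty), 0)
  expect_s3_class(empty$age_group, "factor")
  # out-of-range age names the subject
  expect_error(regroupAges(data.frame(subject_id = "X1", age = 19), "two_year"),
               "X1")
})

test_that("derived phantom specs realise the drawn measures analytically", {
  model <- defaultGrowthModel()
  sim <- simulateCohort(model, data.frame(group = c("CN", "US"),
                                          age = c(9, 15), n = c(3, 3)),
                        seed = 8, makeSpecs = TRUE)
  for (j in seq_len(nrow(sim$cohort))) {
    tr <- phantomTruth(sim$specs[[j]])
    drawn <- unlist(sim$cohort[j, names(tr$morphometry)])
    expect_equal(unname(tr$morphometry), unname(drawn), tolerance = 1e-9)
    expect_equal(unname(tr$volumes[["gm_total"]]),
                 sim$cohort$gm_total[j], tolerance = 1e-9)
    expect_equal(unname(tr$volumes[["wm_total"]]),
                 sim$cohort$wm_total[j], tolerance = 1e-9)
  }
})
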