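umStudy <- uncertaintyModel(c(1.1, 1.5, 1.1), c(2.2, 3.2, 2.1), 3.2)

test_that("shift sampling has the requested moments and independence", {
  cfg0 <- evaluationConfig(100, 5, uncertaintyModel(c(0, 0, 0), c(0, 0, 0)),
                           seed = 4L)
  s0 <- sampleShifts(cfg0)
  expect_true(all(s0$sys == 0) && all(s0$rand == 0))

  cfg <- evaluationConfig(1e5, 2, umStudy, seed = 4L)
  s <- sampleShifts(cfg)
  for (a in 1:3) {
    seSD <- umStudy@sigmaSys[a] / sqrt(2 * 1e5)
    expect_lt(abs(sd(s$sys[, a]) - umStudy@sigmaSys[a]), 3 * seSD)
    expect_lt(abs(sd(as.vector(s$rand[, , a])) - umStudy@sigmaRand[a]),
              3 * umStudy@sigmaRand[a] / sqrt(2 * 2e5))
  }
  expect_lt(abs(cor(s$sys[, 1], s$sys[, 2])), 0.01)
  expect_lt(abs(cor(s$sys[, 2], s$sys[, 3])), 0.01)
  expect_lt(abs(cor(as.vector(s$rand[, , 1]), as.vector(s$rand[, , 3]))),
            0.01)
  # deterministic given the seed
  s2 <- sampleShifts(cfg)
  expect_identical(s$sys, s2$sys)
})

test_that("cumulative dose interpolates exactly in the analytic cases", {
  g <- doseGrid(c(12, 12, 8), spacing = c(2, 2, 2.5), origin = c(0, 0, 0))
  pts <- indexToWorld(g, as.matrix(expand.grid(3:9, 3:9, 3:5)))
  # F = 1, zero shifts: planned dose at the voxel centres exactly
  withr::with_seed(2, {
    arr <- array(runif(prod(dim3(g)), 0, 80), dim3(g))
  })
  d <- new("DoseDistribution", grid = g, dose = arr)
  expect_equal(cumulativeDose(d, c(0, 0, 0), matrix(0, 1, 3), pts),
               interpDose(d, pts), tolerance = 1e-12)
  # constant field is invariant under interior shifts
  dc <- new("DoseDistribution", grid = g, dose = array(42, dim3(g)))
  shifts <- matrix(runif(15, -1.5, 1.5), 5, 3)
  expect_equal(cumulativeDose(dc, c(1, -1, 0.5), shifts, pts),
               rep(42, nrow(pts)), tolerance = 1e-12)
  # linear field: cumulative dose = field at x + a + mean(b)
  lin <- indexToWorld(g, as.matrix(expand.grid(1:12, 1:12, 1:8)))
  dl <- new("DoseDistribution", grid = g,
            dose = array(2 + 0.3 * lin[, 1] + 0.2 * lin[, 2] - 0.1 * lin[, 3],
                         dim3(g)))
  a <- c(0.5, -0.7, 0.4)
  want <- 2 + sweep(pts, 2, a + colMeans(shifts), "+") %*% c(0.3, 0.2, -0.1)
  expect_equal(cumulativeDose(dl, a, shifts, pts), as.vector(want),
               tolerance = 1e-9)
})

test_that("DVH metrics follow the discrete definitions", {
  u <- rep(65, 10)
  expect_equal(dvhMetric(u, dvhObjective("s", "D", 60, 98, ">="))$value, 65)
  expect_equal(dvhMetric(u, dvhObjective("s", "V", 60, 50, ">="))$value, 100)
  two <- c(80, 60)
  expect_equal(dvhMetric(two, dvhObjective("s", "V", 70, 50, "<"))$value, 50)
  # 100 voxels at 1..100 Gy: D_50 is the 50th largest = 51 Gy
  expect_equal(dvhMetric(1:100, dvhObjective("s", "D", 0, 50, ">="))$value,
               51)
  expect_true(dvhMetric(two, dvhObjective("s", "V", 70, 60, "<"))$pass)
  expect_false(dvhMetric(two, dvhObjective("s", "V", 70, 40, "<"))$pass)
  expect_error(dvhMetric(numeric(0), dvhObjective("s", "D", 0, 50, ">=")),
               "empty")
})

test_that("coverage probability is exact under zero uncertainty", {
  g <- doseGrid(c(10, 10, 6), spacing = c(3, 3, 3))
  m <- array(FALSE, dim3(g)); m[4:7, 4:7, 3:4] <- TRUE
  str <- voiMask("ctv", g, m)
  passDose <- new("DoseDistribution", grid = g, dose = array(76, dim3(g)))
  failDose <- new("DoseDistribution", grid = g, dose = array(70, dim3(g)))
  cfg <- evaluationConfig(50, 3, uncertaintyModel(c(0, 0, 0), c(0, 0, 0)),
                          seed = 1L)
  obj <- dvhObjective("ctv", "D", dose = 74.1, volume = 98, comparator = ">=")
  expect_equal(coverageProbability(passDose, str, cfg, obj)@probability, 1)
  expect_equal(coverageProbability(failDose, str, cfg, obj)@probability, 0)
})

test_that("top-hat coverage matches the closed-form containment probability", {
  # 1D arrangement along LR: top-hat dose, interval target, systematic-only
  # shifts; pass iff all target centres stay inside the >= 50 Gy region,
  # whose half-width under trilinear interpolation is the voxel half-pitch
  # beyond the outer 100 Gy voxel centres.
  h <- 2
  g <- doseGrid(c(61, 5, 5), spacing = c(h, h, h), origin = c(-60, -4, -4))
  arr <- array(0, dim3(g))
  doseIdx <- 21:41                      # 100 Gy voxels
  arr[doseIdx, , ] <- 100
  dose <- new("DoseDistribution", grid = g, dose = arr)
  m <- array(FALSE, dim3(g)); m[26:36, 3, 3] <- TRUE
  target <- voiMask("t", g, m)
  Sig <- 3
  cfg <- evaluationConfig(1e4, 1,
                          uncertaintyModel(c(Sig, 0, 0), c(0, 0, 0)),
                          seed = 33L)
  obj <- dvhObjective("t", "D", dose = 50, volume = 100, comparator = ">=")
  p <- coverageProbability(dose, target, cfg, obj)@probability
  xl <- (min(doseIdx) - 1) * h - 60 - h / 2   # 50% isodose edges
  xr <- (max(doseIdx) - 1) * h - 60 + h / 2
  tl <- (26 - 1) * h - 60; tr <- (36 - 1) * h - 60
  pTheory <- pnorm((xr - tr) / Sig) - pnorm((xl - tl) / Sig)
  expect_lt(abs(p - pTheory), 3 * sqrt(pTheory * (1 - pTheory) / 1e4))
})

test_that("Monte-Carlo estimates converge (n vs 4n agreement)", {
  fxd <- tinyDoseFixture()
  g <- fxd$ph$grid
  dij <- buildDoseInfluence(g, fxd$beams, fxd$ph$masks$ctv,
                            fxd$ph$masks$external, fxd$params)
  w <- rep(1, ncol(dij@matrix))
  dose <- accumulateDose(dij, w)
  dose@dose <- dose@dose * (74.5 / mean(dose@dose[fxd$ph$masks$ctv@mask]))
  obj <- dvhObjective("ctv", "D", dose = 70, volume = 98, comparator = ">=")
  cfgA <- evaluationConfig(400, 5, umStudy, seed = 9L)
  cfgB <- evaluationConfig(1600, 5, umStudy, seed = 10L)
  pA <- coverageProbability(dose, fxd$ph$masks$ctv, cfgA, obj)@probability
  pB <- coverageProbability(dose, fxd$ph$masks$ctv, cfgB, obj)@probability
  expect_lt(abs(pA - pB),
            3 * sqrt(max(pB * (1 - pB), 0.01) / 400) + 0.02)
})

test_that("batch population sweep agrees with the reference cumulative dose", {
  g <- doseGrid(c(14, 12, 9), spacing = c(2.5, 2.5, 2.5))
  withr::with_seed(6, {
    arr <- array(runif(prod(dim3(g)), 0, 80), dim3(g))
  })
  dose <- new("DoseDistribution", grid = g, dose = arr)
  m <- array(FALSE, dim3(g)); m[5:9, 5:8, 4:6] <- TRUE
  str <- voiMask("s", g, m)
  cfg <- evaluationConfig(4, 6, umStudy, seed = 12L)
  shifts <- sampleShifts(cfg)
  pts <- voxelCenters(g, str)
  # recompute sample 3 with the public per-sample API
  ref <- cumulativeDose(dose, shifts$sys[3, ], shifts$rand[3, , ], pts)
  got <- NULL
  pop <- getFromNamespace("populationSweep", "bdptv")
  pop(dose, str, cfg, function(ds, s) if (s == 3) got <<- ds)
  expect_equal(got, ref, tolerance = 1e-10)
})

test_that("DVCM surfaces are monotone, consistent, and differences antisymmetric", {
  g <- doseGrid(c(12, 12, 8), spacing = c(3, 3, 3))
  withr::with_seed(14, {
    arr <- array(0, dim3(g))
    arr[3:10, 3:10, 2:7] <- 60 + 20 * runif(8 * 8 * 6)
  })
  dose <- new("DoseDistribution", grid = g, dose = arr)
  m <- array(FALSE, dim3(g)); m[5:8, 5:8, 3:6] <- TRUE
  str <- voiMask("s", g, m)
  cfg <- evaluationConfig(150, 4, umStudy, seed = 21L)
  edges <- seq(0, 90, by = 2)
  dv <- buildDvcm(dose, str, cfg, doseEdges = edges,
                  volumeEdges = seq(5, 100, by = 5))
  expect_true(all(diff(dv@surface) <= 1e-12))        # along dose
  expect_true(all(t(apply(dv@surface, 1, diff)) <= 1e-12))  # along volume
  expect_true(all(dv@surface >= 0 & dv@surface <= 1))

  # uniform dose, zero uncertainty: step indicator surface
  du <- new("DoseDistribution", grid = g, dose = array(55, dim3(g)))
  cfg0 <- evaluationConfig(10, 2, uncertaintyModel(c(0, 0, 0), c(0, 0, 0)),
                           seed = 2L)
  dv0 <- buildDvcm(du, str, cfg0, doseEdges = c(10, 54, 56),
                   volumeEdges = c(1, 50, 100))
  expect_equal(dv0@surface, rbind(1, 1, 0) %*% rbind(c(1, 1, 1)),
               ignore_attr = TRUE)

  # coverage probability equals the DVCM surface at the objective's bin
  cfg2 <- evaluationConfig(200, 4, umStudy, seed = 22L)
  obj <- dvhObjective("s", "V", dose = 70, volume = 40, comparator = ">=")
  p <- coverageProbability(dose, str, cfg2, obj)@probability
  dv2 <- buildDvcm(dose, str, cfg2, doseEdges = c(60, 70, 80),
                   volumeEdges = c(20, 40, 60))
  expect_equal(dv2@surface[2, 2], p, tolerance = 1e-12)

  # DVCDM: identical maps cancel; antisymmetry
  diffAB <- dvcmDifference(dv, dv)
  expect_true(all(diffAB@surface == 0))
  dvB <- buildDvcm(dose, str, cfg2, doseEdges = edges,
                   volumeEdges = seq(5, 100, by = 5))
  d1 <- dvcmDifference(dv, dvB); d2 <- dvcmDifference(dvB, dv)
  expect_equal(d1@surface, -d2@surface)
  expect_error(dvcmDifference(dv, dv2), "bin edges")
})
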