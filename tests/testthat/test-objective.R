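# single-voxel cube fixtures make the hand-evaluated examples independent of
# the per-VOI normalisation (N = 1)
oneVoxelCube <- function(labels, values = NULL) {
  g <- doseGrid(c(length(labels), 1, 1), spacing = c(2, 2, 2))
  ext <- voiMask("external", g, array(TRUE, c(length(labels), 1, 1)))
  vois <- list()
  for (nm in unique(labels[labels != "external"])) {
    m <- array(FALSE, c(length(labels), 1, 1))
    m[labels == nm, 1, 1] <- TRUE
    vois[[nm]] <- voiMask(nm, g, m)
  }
  cube <- buildExclusiveCube(vois, unique(labels[labels != "external"]), ext)
  list(grid = g, cube = cube)
}

doseOn <- function(grid, values) {
  new("DoseDistribution", grid = grid,
      dose = array(values, dim3(grid)))
}

objTab <- defaultObjectives(70)

test_that("exclusive objective reproduces the hand-evaluated voxel penalties", {
  fx <- oneVoxelCube("prostate")
  # inside the allowed band: zero
  expect_equal(evalObjectiveExclusive(doseOn(fx$grid, 78), fx$cube, objTab), 0)
  # one target voxel 1 Gy under the 74.5 Gy minimum, weight 10
  expect_equal(evalObjectiveExclusive(doseOn(fx$grid, 73.5), fx$cube, objTab),
               10)
  fr <- oneVoxelCube("rectum")
  # one rectum voxel 5 Gy over the 70 Gy maximum, weight 8
  expect_equal(evalObjectiveExclusive(doseOn(fr$grid, 75), fr$cube, objTab),
               8 * 25)
  # undefined structure errors
  fu <- oneVoxelCube("mystery")
  expect_error(evalObjectiveExclusive(doseOn(fu$grid, 10), fu$cube, objTab),
               "mystery")
})

test_that("overlap objective blends target and OAR terms per voxel", {
  fx <- oneVoxelCube("external")
  g <- fx$grid
  ovl <- function(o) list(prostate = new("OverlapMap", grid = g,
                                         values = array(o, dim3(g)),
                                         nBeams = 2L))
  # o = 0 everywhere reduces to the exclusive OAR objective
  expect_equal(evalObjectiveOverlap(doseOn(g, 72), ovl(0), fx$cube, objTab),
               evalObjectiveExclusive(doseOn(g, 72), fx$cube, objTab))
  # o = 1, dose inside the target band: zero
  expect_equal(evalObjectiveOverlap(doseOn(g, 78), ovl(1), fx$cube, objTab), 0)
  # blended voxel: o = 0.5, d = 72, target (74.5, su 10), OAR external has
  # dmax 60 so use a rectum-labelled voxel for the spec's 47.25 case
  fr <- oneVoxelCube("rectum")
  expect_equal(evalObjectiveOverlap(doseOn(fr$grid, 72),
                                    list(prostate = new("OverlapMap",
                                                        grid = fr$grid,
                                                        values = array(0.5, dim3(fr$grid)),
                                                        nBeams = 2L)),
                                    fr$cube, objTab),
               0.5 * 10 * 2.5^2 + 0.5 * 8 * 2^2)
  # summed overlap above one across targets is rejected
  objBoost <- rbind(objTab,
                    data.frame(structure = "boost", dmin = 70, su = 5,
                               dmax = 78, so = 5))
  ov6 <- new("OverlapMap", grid = g, values = array(0.6, dim(fx$cube@labels)),
             nBeams = 5L)
  two <- list(prostate = ov6, boost = ov6)
  expect_error(evalObjectiveOverlap(doseOn(g, 70), two, fx$cube, objBoost),
               "exceed")
})

test_that("overlap objective equals the exclusive objective in the binary limit", {
  fx <- tinyDoseFixture()
  g <- fx$ph$grid
  ctv <- fx$ph$masks$ctv
  oars <- fx$ph$masks[c("rectum", "bladder", "femoral_heads")]
  cube <- buildExclusiveCube(
    c(list(voiMask("prostate", g, ctv@mask)), oars),
    c("prostate", "rectum", "bladder", "femoral_heads"),
    fx$ph$masks$external)
  # binary overlap exactly equal to the cube's target voxels
  ov <- list(prostate = new("OverlapMap", grid = g,
                            values = (cube@labels ==
                                        match("prostate", cube@labelTable)) + 0,
                            nBeams = 1L))
  withr::with_seed(3, {
    for (rep in 1:3) {
      d <- doseOn(g, runif(prod(dim3(g)), 40, 90))
      for (nrm in c(TRUE, FALSE))
        expect_equal(
          evalObjectiveOverlap(d, ov, cube, objTab, normalize = nrm),
          evalObjectiveExclusive(d, cube, objTab, normalize = nrm),
          tolerance = 1e-10)
    }
  })
})

test_that("analytic gradient matches central finite differences", {
  fx <- tinyDoseFixture()
  g <- fx$ph$grid
  dij <- buildDoseInfluence(g, fx$beams, fx$ph$masks$ctv,
                            fx$ph$masks$external, fx$params)
  oars <- fx$ph$masks[c("rectum", "bladder", "femoral_heads")]
  cube <- buildExclusiveCube(
    c(list(voiMask("prostate", g, fx$ph$masks$ctv@mask)), oars),
    c("prostate", "rectum", "bladder", "femoral_heads"),
    fx$ph$masks$external)
  bm <- buildBeamMargins(fx$ph$masks$ctv, fx$beams,
                         uncertaintyModel(c(1.1, 1.5, 1.1),
                                          c(2.2, 3.2, 2.1), 3.2))
  problems <- list(
    planProblem(dij, cube, objTab),
    planProblem(dij, cube, objTab, overlaps = list(prostate = bm$overlap)))
  withr::with_seed(17, {
    for (pr in problems) {
      n <- ncol(dij@matrix)
      for (rep in 1:10) {
        w <- runif(n, 50, 120)
        gAn <- objectiveGradient(pr, w)
        picks <- sample(n, 4)
        h <- 1e-4
        for (b in picks) {
          wp <- w; wp[b] <- w[b] + h
          wm <- w; wm[b] <- w[b] - h
          gNum <- (objectiveValue(pr, wp) - objectiveValue(pr, wm)) / (2 * h)
          expect_lt(abs(gAn[b] - gNum) / (abs(gNum) + 1e-12), 1e-5)
        }
      }
    }
  })
})

test_that("weight scaling scales the gradient linearly via the penalties", {
  fx <- oneVoxelCube("prostate")
  g <- fx$grid
  M <- Matrix::sparseMatrix(i = 1, j = 1, x = 1, dims = c(1, 1))
  dij <- new("DoseInfluence", grid = g, matrix = M, voxelIndex = 1L,
             beamlets = data.frame(beam = 1, u = 0, v = 0), params = list())
  obj2 <- objTab
  obj2[obj2$structure == "prostate", c("su", "so")] <- c(30, 30)
  g1 <- objectiveGradient(planProblem(dij, fx$cube, objTab), 70)
  g3 <- objectiveGradient(planProblem(dij, fx$cube, obj2), 70)
  expect_equal(g3, 3 * g1, tolerance = 1e-12)
})

test_that("one-voxel one-beamlet problem converges to the analytic optimum", {
  fx <- oneVoxelCube("prostate")
  g <- fx$grid
  M <- Matrix::sparseMatrix(i = 1, j = 1, x = 1, dims = c(1, 1))
  dij <- new("DoseInfluence", grid = g, matrix = M, voxelIndex = 1L,
             beamlets = data.frame(beam = 1, u = 0, v = 0), params = list())
  pr <- planProblem(dij, fx$cube, objTab, prescription = 78)
  res <- optimizeFluence(pr, init = 10, tol = 1e-10, maxIter = 200)
  expect_equal(res@config$objective, 0)
  expect_gte(res@weights[1], 74.5 - 1e-6)
  expect_lte(res@weights[1], 82 + 1e-6)
  # already-optimal init returns without extra iterations
  res2 <- optimizeFluence(pr, init = res@weights, tol = 1e-10)
  expect_lte(res2@config$iterations, 1)
  expect_error(optimizeFluence(pr, init = -1), ">= 0")
})

test_that("descent is monotone, keeps weights nonnegative, and inits agree", {
  # single-beam toy problem: descent from random inits must agree closely
  fx <- tinyDoseFixture()
  g <- fx$ph$grid
  dij <- buildDoseInfluence(g, fx$beams[1], fx$ph$masks$ctv,
                            fx$ph$masks$external, fx$params)
  oars <- fx$ph$masks[c("rectum", "bladder", "femoral_heads")]
  cube <- buildExclusiveCube(
    c(list(voiMask("prostate", g, fx$ph$masks$ctv@mask)), oars),
    c("prostate", "rectum", "bladder", "femoral_heads"),
    fx$ph$masks$external)
  pr <- planProblem(dij, cube, objTab, prescription = 78)
  finals <- withr::with_seed(29, {
    vapply(1:10, function(i) {
      init <- runif(ncol(dij@matrix), 20, 150)
      res <- optimizeFluence(pr, init = init, tol = 1e-10, maxIter = 1500)
      expect_true(all(res@weights >= 0))
      expect_true(all(diff(res@trace) <= 1e-9 * pmax(res@trace[-1], 1)))
      res@config$objective
    }, numeric(1))
  })
  # convex objective: descent from different inits lands within ~1%
  expect_lt((max(finals) - min(finals)) / max(mean(finals), 1e-12), 0.01)
})
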