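# Independent brute-force oracles and shared fixtures for the test suite.

# Exhaustive 3D-PTV oracle: a voxel centre belongs to the expansion iff it
# lies within the ellipsoid-scaled clamped distance of some CTV voxel cube.
# Sweeps the whole grid once per CTV voxel; independent of the
# structuring-element dilation used by the implementation.
bfExpandPtv3D <- function(ctv, margins) {
  grid <- ctv@grid
  sp <- grid@spacing
  half <- sp / 2
  d <- dim(ctv@mask)
  ctvIdx <- which(ctv@mask, arr.ind = TRUE)
  allIdx <- as.matrix(expand.grid(1:d[1], 1:d[2], 1:d[3]))
  allC <- sweep(allIdx - 1, 2, sp, "*")
  out <- rep(FALSE, nrow(allIdx))
  for (j in seq_len(nrow(ctvIdx))) {
    u <- abs(sweep(allC, 2, (ctvIdx[j, ] - 1) * sp, "-"))
    q <- pmax(sweep(u, 2, half, "-"), 0)
    s <- rep(0, nrow(allIdx))
    for (a in 1:3) {
      s <- s + if (margins[a] > 0) (q[, a] / margins[a])^2 else
        ifelse(q[, a] > 1e-12, Inf, 0)
    }
    out <- out | (s <= 1 + 1e-12)
  }
  array(out, d)
}

# Exhaustive bdPTV oracle: the membership predicate (beam-parallel component
# within the voxel's half-extent along the beam, perpendicular component
# inside the margin ellipse) checked against every CTV voxel.
bfBuildBdptv <- function(ctv, beam, ellipse) {
  grid <- ctv@grid
  sp <- grid@spacing
  dvec <- beam@direction
  halfBeam <- sum(abs(dvec) * sp) / 2
  a1 <- ellipse$axes3D[, 1]; a2 <- ellipse$axes3D[, 2]
  m <- ellipse$semiAxes
  d <- dim(ctv@mask)
  ctvIdx <- which(ctv@mask, arr.ind = TRUE)
  allIdx <- as.matrix(expand.grid(1:d[1], 1:d[2], 1:d[3]))
  allC <- sweep(allIdx - 1, 2, sp, "*")
  out <- rep(FALSE, nrow(allIdx))
  for (j in seq_len(nrow(ctvIdx))) {
    u <- sweep(allC, 2, (ctvIdx[j, ] - 1) * sp, "-")
    tPar <- as.vector(u %*% dvec)
    w <- u - outer(tPar, dvec)
    p1 <- as.vector(w %*% a1); p2 <- as.vector(w %*% a2)
    r1 <- if (m[1] > 0) (p1 / m[1])^2 else ifelse(abs(p1) > 1e-9, Inf, 0)
    r2 <- if (m[2] > 0) (p2 / m[2])^2 else ifelse(abs(p2) > 1e-9, Inf, 0)
    out <- out | (abs(tPar) <= halfBeam + 1e-9 & r1 + r2 <= 1 + 1e-12)
  }
  array(out, d)
}

# random small CTV blob on a grid
randomBlob <- function(grid, n = 4) {
  d <- grid@dims
  mask <- array(FALSE, d)
  ctr <- matrix(rep(round(d / 2), each = n), n, 3) +
    matrix(sample(-2:2, 3 * n, replace = TRUE), n, 3)
  ctr <- pmin(pmax(ctr, 2), matrix(rep(d - 1L, each = n), n, 3))
  for (r in seq_len(n)) mask[ctr[r, 1], ctr[r, 2], ctr[r, 3]] <- TRUE
  voiMask("blob", grid, mask)
}

# tiny two-beam fixture used by dose/objective tests
tinyDoseFixture <- function(spacing = c(4, 4, 4)) {
  spec <- phantomSpec(spacing = spacing, ctvSemiAxes = c(12, 12, 12),
                      rectumRadius = 10, rectumLength = 50,
                      bladderSemiAxes = c(14, 14, 14),
                      bladderCenter = c(0, -18, 24),
                      femoralRadius = 10, femoralOffset = 34,
                      externalSemiAxes = c(55, 48), externalHeight = 80,
                      pad = 6, seed = 7L)
  ph <- generatePhantom(spec)
  iso <- colMeans(voxelCenters(ph$grid, ph$masks$ctv))
  beams <- lapply(c(0, 90), beam, isocenter = iso)
  params <- list(mu = 0.005, sigmaPenumbra = 3.2, beamletSize = c(5, 5))
  list(ph = ph, beams = beams, params = params, iso = iso)
}

# memoised coarse four-plan study + evaluation shared by acceptance tests
studyCacheEnv <- new.env(parent = emptyenv())

coarseStudy <- function() {
  if (is.null(studyCacheEnv$study)) {
    fx <- defaultStudyFixture(spacing = c(3, 3, 3))
    studyCacheEnv$study <- runPlanStudy(fx)
  }
  studyCacheEnv$study
}

coarseCoverage <- function() {
  if (is.null(studyCacheEnv$coverage)) {
    study <- coarseStudy()
    fx <- study@fixture
    cfg <- evaluationConfig(populationSize = 2000, fractions = fx$fractions,
                            uncertainty = fx$uncertainty, seed = 202654L)
    ctvObj <- dvhObjective("ctv", "D", dose = 0.95 * fx$prescription,
                           volume = 98, comparator = ">=")
    v70 <- dvhObjective("rectum", "V", dose = 70, volume = 5,
                        comparator = "<")
    res <- lapply(names(study@plans), function(nm) {
      p <- study@plans[[nm]]
      list(ctv = coverageProbability(p, study@anatomy$ctv, cfg, ctvObj),
           rectum = coverageProbability(p, study@anatomy$rectum, cfg, v70))
    })
    names(res) <- names(study@plans)
    studyCacheEnv$coverage <- res
  }
  studyCacheEnv$coverage
}
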