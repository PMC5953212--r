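#' Evaluation configuration
#'
#' @param populationSize number of simulated patients (study default 50000).
#' @param fractions number of treatment fractions F (study default 39).
#' @param uncertainty an [UncertaintyModel-class].
#' @param seed integer RNG seed.
#' @return An [EvaluationConfig-class].
#' @export
evaluationConfig <- function(populationSize = 50000, fractions = 39,
                             uncertainty, seed = 1L) {
  new("EvaluationConfig", populationSize = as.integer(populationSize),
      fractions = as.integer(fractions), uncertainty = uncertainty,
      seed = as.integer(seed))
}

#' DVH objective constructor
#'
#' @param structure structure name.
#' @param kind "D" (dose at volume) or "V" (volume at dose).
#' @param dose Gy: the d of V_d, or the dose threshold of a D objective.
#' @param volume percent: the q of D_q, or the volume threshold of a V
#'   objective.
#' @param comparator ">=", "<=", ">" or "<".
#' @return A [DVHObjective-class].
#' @examples
#' dvhObjective("ctv", "D", dose = 74.1, volume = 98, comparator = ">=")
#' dvhObjective("rectum", "V", dose = 70, volume = 5, comparator = "<")
#' @export
dvhObjective <- function(structure, kind, dose, volume, comparator) {
  new("DVHObjective", structure = structure, kind = kind, dose = dose,
      volume = volume, comparator = comparator)
}

#' Sample systematic and random setup shifts
#'
#' One systematic shift a_s per population sample from N(0, diag(Sigma^2))
#' and one random shift b_sn per sample and fraction from N(0,
#' diag(sigma_r^2)); independent across samples, fractions and axes, and
#' deterministic for a fixed seed.
#'
#' @param config an [EvaluationConfig-class].
#' @return list with `sys` (n x 3 matrix, mm) and `rand` (n x F x 3 array,
#'   mm).
#' @export
sampleShifts <- function(config) {
  n <- config@populationSize
  F <- config@fractions
  um <- config@uncertainty
  withSeed(config@seed, {
    sys <- matrix(rnorm(n * 3), n, 3)
    sys <- sweep(sys, 2, um@sigmaSys, "*")
    rand <- array(rnorm(n * F * 3), c(n, F, 3))
    for (a in 1:3) rand[, , a] <- rand[, , a] * um@sigmaRand[a]
    list(sys = sys, rand = rand)
  })
}

#' Trilinear interpolation of a dose volume
#'
#' Positions outside the grid (or whose interpolation cell leaves the grid)
#' contribute zero dose: the dose cloud vanishes outside the computed volume.
#'
#' @param dose a [DoseDistribution-class].
#' @param points numeric matrix (n x 3) of mm positions.
#' @return numeric dose values in Gy.
#' @export
interpDose <- function(dose, points) {
  grid <- dose@grid
  arr <- dose@dose
  d <- grid@dims
  f <- worldToIndex(grid, points)
  i0 <- floor(f)
  t <- f - i0
  val <- numeric(nrow(f))
  ok <- i0[, 1] >= 1 & i0[, 1] <= d[1] - 1 &
        i0[, 2] >= 1 & i0[, 2] <= d[2] - 1 &
        i0[, 3] >= 1 & i0[, 3] <= d[3] - 1
  # points exactly on the upper boundary voxel centre
  hi <- !ok & i0[, 1] >= 1 & i0[, 2] >= 1 & i0[, 3] >= 1 &
        f[, 1] <= d[1] & f[, 2] <= d[2] & f[, 3] <= d[3]
  if (any(ok)) {
    i <- i0[ok, 1]; j <- i0[ok, 2]; k <- i0[ok, 3]
    tx <- t[ok, 1]; ty <- t[ok, 2]; tz <- t[ok, 3]
    base <- ijkToLinear(grid, cbind(i, j, k))
    sx <- 1L; sy <- d[1]; sz <- d[1] * d[2]
    val[ok] <-
      arr[base] * (1 - tx) * (1 - ty) * (1 - tz) +
      arr[base + sx] * tx * (1 - ty) * (1 - tz) +
      arr[base + sy] * (1 - tx) * ty * (1 - tz) +
      arr[base + sx + sy] * tx * ty * (1 - tz) +
      arr[base + sz] * (1 - tx) * (1 - ty) * tz +
      arr[base + sx + sz] * tx * (1 - ty) * tz +
      arr[base + sy + sz] * (1 - tx) * ty * tz +
      arr[base + sx + sy + sz] * tx * ty * tz
  }
  if (any(hi)) {
    # clamp the degenerate upper-edge cell: nearest lower corner weights
    idx <- which(hi)
    ic <- pmin(i0[idx, , drop = FALSE], rep(d - 1L, each = length(idx)))
    tc <- f[idx, , drop = FALSE] - ic
    base <- ijkToLinear(grid, ic)
    sx <- 1L; sy <- d[1]; sz <- d[1] * d[2]
    val[idx] <-
      arr[base] * (1 - tc[, 1]) * (1 - tc[, 2]) * (1 - tc[, 3]) +
      arr[base + sx] * tc[, 1] * (1 - tc[, 2]) * (1 - tc[, 3]) +
      arr[base + sy] * (1 - tc[, 1]) * tc[, 2] * (1 - tc[, 3]) +
      arr[base + sx + sy] * tc[, 1] * tc[, 2] * (1 - tc[, 3]) +
      arr[base + sz] * (1 - tc[, 1]) * (1 - tc[, 2]) * tc[, 3] +
      arr[base + sx + sz] * tc[, 1] * (1 - tc[, 2]) * tc[, 3] +
      arr[base + sy + sz] * (1 - tc[, 1]) * tc[, 2] * tc[, 3] +
      arr[base + sx + sy + sz] * tc[, 1] * tc[, 2] * tc[, 3]
  }
  val
}

#' Cumulative dose over fractions for one population sample
#'
#' d_c(x) = (1/F) sum_n d(x + a + b_n), with trilinear interpolation of the
#' static planned dose (static dose cloud approximation); positions outside
#' the dose grid contribute zero dose.
#'
#' @param dose a [DoseDistribution-class].
#' @param a numeric(3), systematic shift in mm.
#' @param bList F x 3 matrix of per-fraction random shifts in mm.
#' @param points n x 3 matrix of structure voxel centres in mm.
#' @return numeric cumulative dose at each point, Gy.
#' @export
cumulativeDose <- function(dose, a, bList, points) {
  bList <- rbind(bList)
  acc <- numeric(nrow(rbind(points)))
  for (n in seq_len(nrow(bList))) {
    shift <- a + bList[n, ]
    acc <- acc + interpDose(dose, sweep(rbind(points), 2, shift, "+"))
  }
  acc / nrow(bList)
}

#' DVH metric of a structure dose vector
#'
#' V_d = 100 * #\{voxels with dose >= d\} / N (percent); D_q = the largest
#' dose level d with V_d >= q, computed from the sorted voxel doses without
#' interpolation.
#'
#' @param doses numeric voxel doses in Gy (non-empty).
#' @param objective a [DVHObjective-class].
#' @return list with `value` (Gy for D, percent for V) and `pass` (logical).
#' @export
dvhMetric <- function(doses, objective) {
  if (!length(doses)) stop("empty structure")
  if (objective@kind == "D") {
    srt <- sort(doses, decreasing = TRUE)
    value <- srt[ceiling(objective@volume / 100 * length(doses))]
    thr <- objective@dose
  } else {
    value <- 100 * sum(doses >= objective@dose) / length(doses)
    thr <- objective@volume
  }
  pass <- switch(objective@comparator,
                 ">=" = value >= thr, "<=" = value <= thr,
                 ">" = value > thr, "<" = value < thr)
  list(value = value, pass = pass)
}

# Fast population sweep: for every sample, the cumulative fractionated dose
# at the structure's voxel centres, computed with the uniform-shift trilinear
# stencil on a zero-padded copy of the dose array. perSample(ds, s) is called
# with the per-voxel cumulative dose of each sample.
populationSweep <- function(dose, structure, config, perSample) {
  grid <- dose@grid
  sp <- grid@spacing
  shifts <- sampleShifts(config)
  maxShift <- apply(abs(shifts$sys), 2, max) +
    apply(abs(shifts$rand), 3, max)
  padv <- as.integer(ceiling(maxShift / sp)) + 2L
  d <- grid@dims
  dp <- d + 2L * padv
  padded <- array(0, dp)
  padded[padv[1] + seq_len(d[1]), padv[2] + seq_len(d[2]),
         padv[3] + seq_len(d[3])] <- dose@dose
  ijk <- linearToIjk(grid, which(structure@mask))
  if (!nrow(ijk)) stop("empty structure")
  base0 <- as.numeric((ijk[, 1] + padv[1]) +
                      (ijk[, 2] + padv[2] - 1) * dp[1] +
                      (ijk[, 3] + padv[3] - 1) * dp[1] * dp[2])
  sx <- 1; sy <- dp[1]; sz <- dp[1] * dp[2]
  F <- config@fractions
  n <- config@populationSize
  for (s in seq_len(n)) {
    acc <- numeric(nrow(ijk))
    for (fr in seq_len(F)) {
      del <- (shifts$sys[s, ] + shifts$rand[s, fr, ]) / sp
      i0 <- floor(del)
      t1 <- del[1] - i0[1]; t2 <- del[2] - i0[2]; t3 <- del[3] - i0[3]
      off <- i0[1] * sx + i0[2] * sy + i0[3] * sz
      b <- base0 + off
      acc <- acc +
        padded[b] * (1 - t1) * (1 - t2) * (1 - t3) +
        padded[b + sx] * t1 * (1 - t2) * (1 - t3) +
        padded[b + sy] * (1 - t1) * t2 * (1 - t3) +
        padded[b + sx + sy] * t1 * t2 * (1 - t3) +
        padded[b + sz] * (1 - t1) * (1 - t2) * t3 +
        padded[b + sx + sz] * t1 * (1 - t2) * t3 +
        padded[b + sy + sz] * (1 - t1) * t2 * t3 +
        padded[b + sx + sy + sz] * t1 * t2 * t3
    }
    perSample(acc / F, s)
  }
  invisible(NULL)
}

#' Population probability of meeting a DVH objective
#'
#' Monte-Carlo verification under the static dose cloud approximation: for
#' each simulated patient the planned dose is shifted once by the systematic
#' error and per fraction by the random error, accumulated over F fractions
#' (trilinear interpolation), and the DVH objective evaluated; the reported
#' probability is the passing fraction of the population.
#'
#' @param plan a [PlanResult-class] or [DoseDistribution-class].
#' @param structure a [VOIMask-class].
#' @param config an [EvaluationConfig-class].
#' @param objective a [DVHObjective-class].
#' @return A [CoverageResult-class].
#' @export
coverageProbability <- function(plan, structure, config, objective) {
  dose <- if (is(plan, "PlanResult")) plan@dose else plan
  npass <- 0L
  populationSweep(dose, structure, config, function(ds, s) {
    if (dvhMetric(ds, objective)$pass) npass <<- npass + 1L
  })
  p <- npass / config@populationSize
  new("CoverageResult", objective = objective, probability = p,
      se = sqrt(p * (1 - p) / config@populationSize),
      n = config@populationSize)
}

#' Dose-volume coverage map
#'
#' Treats each sample's DVH as solid under the curve and accumulates over
#' the population: surface(d, v) is the fraction of samples with V_d >= v.
#'
#' @param plan a [PlanResult-class] or [DoseDistribution-class].
#' @param structure a [VOIMask-class].
#' @param config an [EvaluationConfig-class].
#' @param doseEdges dose bin edges in Gy (default 0.5 Gy steps to 110% of
#'   the dose maximum).
#' @param volumeEdges volume bin edges in percent (default 1% steps).
#' @return A [DVCMGrid-class].
#' @export
buildDvcm <- function(plan, structure, config, doseEdges = NULL,
                      volumeEdges = seq(1, 100, by = 1)) {
  dose <- if (is(plan, "PlanResult")) plan@dose else plan
  if (is.null(doseEdges))
    doseEdges <- seq(0, max(dose@dose) * 1.1 + 0.5, by = 0.5)
  surf <- matrix(0, length(doseEdges), length(volumeEdges))
  populationSweep(dose, structure, config, function(ds, s) {
    srt <- sort(ds)
    nGe <- length(ds) - findInterval(doseEdges - 1e-9, srt)
    vd <- 100 * nGe / length(ds)
    surf <<- surf + outer(vd, volumeEdges, ">=")
  })
  new("DVCMGrid", doseEdges = doseEdges, volumeEdges = volumeEdges,
      surface = surf / config@populationSize, signed = FALSE)
}

#' Dose-volume coverage difference map (DVCDM)
#'
#' Elementwise reference minus test; bin edges must match.
#'
#' @param reference,test [DVCMGrid-class] objects on identical bins.
#' @return A signed [DVCMGrid-class] with values in [-1, 1].
#' @export
dvcmDifference <- function(reference, test) {
  if (!isTRUE(all.equal(reference@doseEdges, test@doseEdges)) ||
      !isTRUE(all.equal(reference@volumeEdges, test@volumeEdges)))
    stop("DVCM bin edges differ")
  new("DVCMGrid", doseEdges = reference@doseEdges,
      volumeEdges = reference@volumeEdges,
      surface = reference@surface - test@surface, signed = TRUE)
}

setMethod("show", "CoverageResult", function(object) {
  o <- object@objective
  desc <- if (o@kind == "D")
    sprintf("D_%g%% %s %g Gy", o@volume, o@comparator, o@dose)
  else sprintf("V_%gGy %s %g%%", o@dose, o@comparator, o@volume)
  cat(sprintf("CoverageResult [%s, %s]: %.4f (SE %.4f, n = %d)\n",
              o@structure, desc, object@probability, object@se, object@n))
})

setMethod("show", "DVCMGrid", function(object) {
  cat(sprintf("%s: %d dose x %d volume bins, range [%.3f, %.3f]\n",
              if (object@signed) "DVCDM" else "DVCM",
              length(object@doseEdges), length(object@volumeEdges),
              min(object@surface), max(object@surface)))
})
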