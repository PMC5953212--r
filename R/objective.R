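# Piecewise-quadratic planning objectives in exclusive-VOI and
# overlap-weighted forms, their gradients, and problem assembly.

# per-label parameter lookup for an exclusive cube; errors on labels in use
# that have no objective row. With normalize = TRUE each structure's weights
# are divided by its voxel count (KonRad-style per-VOI normalisation).
labelParams <- function(cube, objectives, normalize = TRUE) {
  tab <- cube@labelTable
  row <- match(tab, objectives$structure)
  used <- sort(unique(cube@labels[cube@labels > 0L]))
  bad <- used[is.na(row[used])]
  if (length(bad))
    stop("no objective defined for structure(s): ",
         paste(tab[bad], collapse = ", "))
  scale <- if (normalize) pmax(labelCounts(cube), 1L) else rep(1, length(tab))
  list(
    su = ifelse(is.na(row), 0, ifelse(is.na(objectives$dmin[row]), 0,
                                      objectives$su[row])) / scale,
    dmin = ifelse(is.na(row), 0, ifelse(is.na(objectives$dmin[row]), 0,
                                        objectives$dmin[row])),
    so = ifelse(is.na(row), 0, objectives$so[row]) / scale,
    dmax = ifelse(is.na(row), Inf, ifelse(is.na(objectives$dmax[row]), Inf,
                                          objectives$dmax[row])))
}

#' Exclusive-VOI piecewise quadratic objective
#'
#' E = sum over target voxels of su (dmin - d)+^2 + so (d - dmax)+^2 plus
#' sum over OAR voxels of so (d - dmax)+^2, with voxel-wise parameters
#' assigned from the exclusive cube. A structure is a target iff its
#' objective row has a minimum-dose threshold. By default each structure's
#' weights are normalised by its voxel count; `normalize = FALSE` gives the
#' plain voxel sums.
#'
#' @param dose a [DoseDistribution-class].
#' @param cube an [ExclusiveVOICube-class] on the same grid.
#' @param objectives objective table (see [defaultObjectives()]).
#' @param normalize divide each structure's weights by its voxel count
#'   (default TRUE); single-voxel structures are unaffected.
#' @return objective value (Gy^2-weighted).
#' @export
evalObjectiveExclusive <- function(dose, cube, objectives, normalize = TRUE) {
  stopifnot(is(dose, "DoseDistribution"), is(cube, "ExclusiveVOICube"))
  if (!identical(dim3(dose@grid), dim3(cube@grid)))
    stop("dose and cube grids differ")
  p <- labelParams(cube, objectives, normalize)
  idx <- which(cube@labels > 0L)
  lab <- cube@labels[idx]
  d <- dose@dose[idx]
  sum(p$su[lab] * pmax(p$dmin[lab] - d, 0)^2) +
    sum(p$so[lab] * pmax(d - p$dmax[lab], 0)^2)
}

#' Overlap-weighted piecewise quadratic objective
#'
#' For every voxel k inside the external contour,
#' E_k = sum_i o_k^i E_k^i + (1 - sum_i o_k^i) E_k^OAR, where E_k^i uses the
#' target-level thresholds and weights of overlap target i and E_k^OAR uses
#' the voxel-assigned parameters of the margin-free exclusive cube. With
#' binary overlap values this reduces exactly to the exclusive-VOI form.
#'
#' @param dose a [DoseDistribution-class].
#' @param overlaps named list of [OverlapMap-class]; names refer to objective
#'   table rows carrying the target-level thresholds.
#' @param cube margin-free [ExclusiveVOICube-class] assigning the OAR-term
#'   parameters.
#' @param objectives objective table.
#' @param normalize divide OAR weights by the structure voxel count and
#'   target weights by the summed overlap fraction (the fractional target
#'   volume, equal to the voxel count in the binary limit); default TRUE.
#' @return objective value.
#' @export
evalObjectiveOverlap <- function(dose, overlaps, cube, objectives,
                                 normalize = TRUE) {
  stopifnot(is(dose, "DoseDistribution"), is(cube, "ExclusiveVOICube"))
  if (!is.list(overlaps) || is.null(names(overlaps)))
    stop("overlaps must be a named list of OverlapMap objects")
  idx <- which(cube@labels > 0L)
  lab <- cube@labels[idx]
  d <- dose@dose[idx]
  p <- labelParams(cube, objectives, normalize)
  oSum <- numeric(length(idx))
  val <- 0
  for (nm in names(overlaps)) {
    row <- match(nm, objectives$structure)
    if (is.na(row) || is.na(objectives$dmin[row]))
      stop("overlap target '", nm, "' has no target objective row")
    o <- overlaps[[nm]]@values[idx]
    sc <- if (normalize) max(sum(o), 1) else 1
    oSum <- oSum + o
    val <- val + sum(o * (objectives$su[row] / sc *
                            pmax(objectives$dmin[row] - d, 0)^2 +
                          objectives$so[row] / sc *
                            pmax(d - objectives$dmax[row], 0)^2))
  }
  if (max(oSum) > 1 + 1e-9)
    stop("summed overlap fractions exceed 1")
  val + sum((1 - oSum) * p$so[lab] * pmax(d - p$dmax[lab], 0)^2)
}

#' Assemble a fluence optimisation problem
#'
#' Precomputes per-voxel objective parameters over the dose-influence rows
#' (all voxels inside the external contour). With `overlaps = NULL` the
#' exclusive-VOI objective is used; otherwise the overlap-weighted form.
#'
#' @param dij a [DoseInfluence-class].
#' @param cube an [ExclusiveVOICube-class]; for overlap mode, the margin-free
#'   anatomy cube.
#' @param objectives objective table (see [defaultObjectives()]).
#' @param overlaps NULL or named list of [OverlapMap-class].
#' @param prescription prescription dose in Gy used to scale the default
#'   initial fluence.
#' @param normalize per-VOI voxel-count normalisation of the objective
#'   weights (default TRUE); see [evalObjectiveOverlap()].
#' @return A `PlanProblem` list with fields used by [optimizeFluence()].
#' @export
planProblem <- function(dij, cube, objectives, overlaps = NULL,
                        prescription = 78, normalize = TRUE) {
  stopifnot(is(dij, "DoseInfluence"))
  if (!identical(dim3(dij@grid), dim3(cube@grid)))
    stop("dose influence and cube grids differ")
  lab <- cube@labels[dij@voxelIndex]
  if (any(lab == 0L))
    stop("dose-influence rows must lie inside the external contour")
  p <- labelParams(cube, objectives, normalize)
  pr <- list(dij = dij, cube = cube, objectives = objectives,
             overlaps = overlaps, prescription = prescription,
             normalize = normalize,
             su = p$su[lab], dmin = p$dmin[lab],
             so = p$so[lab], dmax = p$dmax[lab])
  if (!is.null(overlaps)) {
    oSum <- numeric(length(lab))
    tg <- list()
    for (nm in names(overlaps)) {
      row <- match(nm, objectives$structure)
      if (is.na(row) || is.na(objectives$dmin[row]))
        stop("overlap target '", nm, "' has no target objective row")
      o <- overlaps[[nm]]@values[dij@voxelIndex]
      sc <- if (normalize) max(sum(o), 1) else 1
      oSum <- oSum + o
      tg[[nm]] <- list(o = o, su = objectives$su[row] / sc,
                       dmin = objectives$dmin[row],
                       so = objectives$so[row] / sc,
                       dmax = objectives$dmax[row])
    }
    if (max(oSum) > 1 + 1e-9) stop("summed overlap fractions exceed 1")
    pr$targets <- tg
    pr$oSum <- oSum
    # target mask used for initial-dose scaling: voxels with full overlap
    pr$targetRows <- which(oSum >= 1 - 1e-12)
  } else {
    pr$targetRows <- which(pr$su > 0)
  }
  if (!length(pr$targetRows)) stop("problem has no target voxels")
  class(pr) <- "PlanProblem"
  pr
}

# objective, per-voxel dose gradient and directional curvature at dose d
problemTerms <- function(pr, d, hd = NULL) {
  if (is.null(pr$overlaps)) {
    under <- pmax(pr$dmin - d, 0)
    over <- pmax(d - pr$dmax, 0)
    f <- sum(pr$su * under^2) + sum(pr$so * over^2)
    g <- -2 * pr$su * under + 2 * pr$so * over
    cvec <- pr$su * (under > 0) + pr$so * (over > 0)
  } else {
    over <- pmax(d - pr$dmax, 0)
    w <- (1 - pr$oSum) * pr$so
    f <- sum(w * over^2)
    g <- 2 * w * over
    cvec <- w * (over > 0)
    for (tg in pr$targets) {
      tu <- pmax(tg$dmin - d, 0)
      to <- pmax(d - tg$dmax, 0)
      f <- f + sum(tg$o * (tg$su * tu^2 + tg$so * to^2))
      g <- g + tg$o * (-2 * tg$su * tu + 2 * tg$so * to)
      cvec <- cvec + tg$o * (tg$su * (tu > 0) + tg$so * (to > 0))
    }
  }
  curv <- if (is.null(hd)) NULL else 2 * sum(cvec * hd^2)
  list(f = f, g = g, curv = curv)
}

#' Objective gradient with respect to beamlet weights
#'
#' Chain rule through d = Dij w: the gradient is D' g where g_k blends the
#' subgradients of the under- and overdose penalties (0 exactly at a
#' threshold kink).
#'
#' @param problem a `PlanProblem` from [planProblem()].
#' @param weights numeric fluence weights.
#' @return numeric gradient, one entry per beamlet.
#' @export
objectiveGradient <- function(problem, weights) {
  d <- as.vector(problem$dij@matrix %*% weights)
  g <- problemTerms(problem, d)$g
  as.vector(Matrix::crossprod(problem$dij@matrix, g))
}

#' Objective value at given weights
#'
#' @param problem a `PlanProblem`.
#' @param weights numeric fluence weights.
#' @return objective value.
#' @export
objectiveValue <- function(problem, weights) {
  d <- as.vector(problem$dij@matrix %*% weights)
  problemTerms(problem, d)$f
}

#' Optimise fluence weights
#'
#' Projected gradient descent with an exact quadratic line search along the
#' negative gradient (the objective is piecewise quadratic and convex) and a
#' halving safeguard; iterates are projected onto the nonnegative orthant
#' and the accepted objective trace is non-increasing. The default initial
#' fluence is uniform, scaled so the mean target dose equals the
#' prescription.
#'
#' @param problem a `PlanProblem` from [planProblem()].
#' @param init optional nonnegative initial weights.
#' @param tol relative objective-change stopping tolerance (default 1e-6).
#' @param maxIter iteration cap (default 500).
#' @param name plan label stored in the result.
#' @return A [PlanResult-class].
#' @export
optimizeFluence <- function(problem, init = NULL, tol = 1e-6, maxIter = 500,
                            name = "plan") {
  M <- problem$dij@matrix
  n <- ncol(M)
  if (is.null(init)) {
    w <- rep(1, n)
    d <- as.vector(M %*% w)
    mt <- mean(d[problem$targetRows])
    if (mt <= 0) stop("uniform fluence delivers no target dose")
    w <- w * problem$prescription / mt
  } else {
    if (any(init < 0)) stop("initial weights must be >= 0")
    w <- as.numeric(init)
  }
  d <- as.vector(M %*% w)
  terms <- problemTerms(problem, d)
  f <- terms$f
  trace <- f
  for (it in seq_len(maxIter)) {
    if (f <= 0) break
    g <- as.vector(Matrix::crossprod(M, terms$g))
    pg <- w - pmax(w - g, 0)               # projected gradient
    if (sqrt(sum(pg^2)) <= 1e-12 * (1 + sqrt(sum(w^2)))) break
    hd <- as.vector(M %*% g)
    curv <- problemTerms(problem, d, hd)$curv
    step <- if (is.finite(curv) && curv > 0) sum(g^2) / curv else 1
    ok <- FALSE
    for (ls in 1:60) {
      wNew <- pmax(w - step * g, 0)
      dNew <- as.vector(M %*% wNew)
      tNew <- problemTerms(problem, dNew)
      if (tNew$f < f * (1 - 1e-12) || tNew$f < f - 1e-12) { ok <- TRUE; break }
      step <- step / 2
    }
    if (!ok) {
      if (sqrt(sum(pg^2)) <= 1e-6 * (1 + sqrt(sum(w^2)))) break  # converged
      stop("line search failed to decrease the objective (divergence)")
    }
    rel <- (f - tNew$f) / max(f, .Machine$double.eps)
    w <- wNew; d <- dNew; terms <- tNew; f <- tNew$f
    trace <- c(trace, f)
    if (rel < tol) break
  }
  new("PlanResult", name = name, weights = w,
      dose = accumulateDose(problem$dij, w), trace = trace,
      config = list(tol = tol, maxIter = maxIter,
                    iterations = length(trace) - 1L,
                    objective = f, mode = if (is.null(problem$overlaps))
                      "exclusive" else "overlap"))
}

setMethod("show", "PlanResult", function(object) {
  cat(sprintf("PlanResult '%s': objective %.4g after %d iterations (%s mode)\n",
              object@name, object@config$objective, object@config$iterations,
              object@config$mode))
})
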