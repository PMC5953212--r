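#' Coverage coefficient alpha of the van Herk margin recipe
#'
#' The radius r such that a standard d-variate normal distribution has
#' probability `p` inside the ball of radius r, i.e. the quantile of the chi
#' distribution with d degrees of freedom. This is the coefficient that
#' scales the systematic uncertainty SD in the margin recipe: alpha = 2.50
#' for d = 3, p = 0.90.
#'
#' @param dimension 1, 2 or 3.
#' @param p population coverage probability in (0, 1); default 0.90.
#' @return numeric coefficient.
#' @examples
#' coverageAlpha(3, 0.90)  # 2.50
#' coverageAlpha(2, 0.90)  # 2.1460 = sqrt(-2 log 0.1)
#' @export
coverageAlpha <- function(dimension, p = 0.90) {
  if (!dimension %in% 1:3) stop("dimension must be 1, 2 or 3")
  if (!is.finite(p) || p <= 0 || p >= 1) stop("p must lie in (0, 1)")
  sqrt(qchisq(p, df = dimension))
}

#' Dose-level coefficient beta of the van Herk margin recipe
#'
#' One-sided standard normal quantile for the minimum dose level delivered
#' by the random-blurred penumbra: beta = 1.64 for the 95% dose level.
#'
#' @param doseLevelP dose level probability in (0, 1); default 0.95.
#' @return numeric coefficient.
#' @examples
#' penumbraBeta(0.95)  # 1.64
#' @export
penumbraBeta <- function(doseLevelP = 0.95) {
  if (!is.finite(doseLevelP) || doseLevelP <= 0 || doseLevelP >= 1)
    stop("doseLevelP must lie in (0, 1)")
  qnorm(doseLevelP)
}

#' Margin coefficients container
#'
#' @param dimension dimensionality alpha is computed for (2 for the per-beam
#'   in-plane recipe, 3 for the conventional volumetric recipe).
#' @param coverageP population coverage probability (default 0.90).
#' @param doseLevelP penumbra dose level probability (default 0.95).
#' @return A [MarginCoefficients-class].
#' @export
marginCoefficients <- function(dimension = 3, coverageP = 0.90,
                               doseLevelP = 0.95) {
  new("MarginCoefficients",
      alpha = coverageAlpha(dimension, coverageP),
      beta = penumbraBeta(doseLevelP),
      dimension = as.integer(dimension),
      coverageP = coverageP, doseLevelP = doseLevelP)
}

#' Uncertainty model constructor
#'
#' @param sigmaSys numeric(3), systematic SDs in mm along (LR, AP, SI).
#' @param sigmaRand numeric(3), random SDs in mm along (LR, AP, SI).
#' @param sigmaPenumbra penumbra SD in mm (default 3.2).
#' @return An [UncertaintyModel-class].
#' @export
uncertaintyModel <- function(sigmaSys, sigmaRand, sigmaPenumbra = 3.2) {
  new("UncertaintyModel", sigmaSys = as.numeric(sigmaSys),
      sigmaRand = as.numeric(sigmaRand),
      sigmaPenumbra = as.numeric(sigmaPenumbra))
}

#' Scalar van Herk margin
#'
#' Margin = alpha * Sigma + beta * (sqrt(sigma_r^2 + sigma_p^2) - sigma_p).
#'
#' @param alpha coverage coefficient (see [coverageAlpha()]).
#' @param Sigma systematic SD in mm.
#' @param sigmaR random SD in mm.
#' @param sigmaP penumbra SD in mm.
#' @param beta dose-level coefficient (see [penumbraBeta()]).
#' @return margin in mm; equals alpha * Sigma when sigmaR = 0.
#' @examples
#' margin1D(2.50, 1.5, 3.2, 3.2, 1.64)  # 5.92 mm
#' @export
margin1D <- function(alpha, Sigma, sigmaR, sigmaP, beta) {
  if (any(c(alpha, Sigma, sigmaR, sigmaP, beta) < 0))
    stop("all margin-recipe inputs must be >= 0")
  alpha * Sigma + beta * (sqrt(sigmaR^2 + sigmaP^2) - sigmaP)
}

#' Collapse a per-axis Gaussian onto the plane perpendicular to a beam
#'
#' Marginalises (not conditions) the trivariate zero-mean Gaussian with
#' diagonal covariance diag(sigma^2) along the beam direction: the returned
#' 2x2 covariance is B' C B where B = [e1 e2] is the beam's in-plane basis
#' ([beamPlaneBasis()]). It equals the covariance of 3D samples projected
#' onto the plane.
#'
#' @param sigma numeric(3), per-axis SDs in mm (LR, AP, SI).
#' @param beam a [Beam-class].
#' @return numeric 2x2 covariance in mm^2, in the beam's plane basis.
#' @export
collapseCovariance <- function(sigma, beam) {
  stopifnot(is(beam, "Beam"), length(sigma) == 3L)
  if (abs(sqrt(sum(beam@direction^2)) - 1) > 1e-12)
    stop("beam direction must be unit length")
  B <- beamPlaneBasis(beam)
  M <- base::t(B) %*% (diag(as.numeric(sigma)^2) %*% B)
  (M + base::t(M)) / 2
}

#' Collapsed uncertainty for a beam
#'
#' @param model an [UncertaintyModel-class].
#' @param beam a [Beam-class].
#' @return A [CollapsedUncertainty-class] with both systematic and random
#'   collapsed covariances.
#' @export
collapseUncertainty <- function(model, beam) {
  new("CollapsedUncertainty",
      planeBasis = beamPlaneBasis(beam),
      sysCov = collapseCovariance(model@sigmaSys, beam),
      randCov = collapseCovariance(model@sigmaRand, beam))
}

#' 2D margin ellipse for one beam
#'
#' Applies the margin recipe per principal axis of the collapsed systematic
#' covariance: each semi-axis is margin1D with alpha = coverageAlpha(2,
#' coverageP), Sigma = sqrt(systematic eigenvalue) and sigma_r = the SD of
#' the collapsed random covariance projected onto that principal axis. With
#' `isotropic = TRUE` the larger semi-axis is used for both (a circle).
#'
#' @param collapsed a [CollapsedUncertainty-class].
#' @param coeffs a [MarginCoefficients-class] with dimension 2.
#' @param sigmaP penumbra SD in mm.
#' @param isotropic use the maximum semi-axis for both axes.
#' @return list with `semiAxes` (mm, length 2), `axes` (2x2 in-plane principal
#'   directions, columns), `axes3D` (3x2 world directions) and `basis`.
#' @export
margins2D <- function(collapsed, coeffs, sigmaP, isotropic = FALSE) {
  stopifnot(is(collapsed, "CollapsedUncertainty"),
            is(coeffs, "MarginCoefficients"))
  if (coeffs@dimension != 2L)
    warning("margins2D expects 2D margin coefficients")
  es <- eigen(collapsed@sysCov, symmetric = TRUE)
  semi <- numeric(2)
  for (i in 1:2) {
    v <- es$vectors[, i]
    Sigma <- sqrt(max(es$values[i], 0))
    sigmaR <- sqrt(max(as.numeric(v %*% collapsed@randCov %*% v), 0))
    semi[i] <- margin1D(coeffs@alpha, Sigma, sigmaR, sigmaP, coeffs@beta)
  }
  if (isotropic) semi <- rep(max(semi), 2)
  list(semiAxes = semi, axes = es$vectors,
       axes3D = collapsed@planeBasis %*% es$vectors,
       basis = collapsed@planeBasis)
}

#' Conventional 3D PTV expansion
#'
#' Minkowski sum of the CTV voxel cubes with the axis-aligned ellipsoid of
#' the given semi-axes, rasterised by voxel-centre inclusion: a voxel belongs
#' to the PTV iff its centre lies within the ellipsoid-scaled distance 1 of
#' some CTV voxel cube (per-axis clamped distance).
#'
#' @param ctv a [VOIMask-class].
#' @param margins numeric(3), margin semi-axes in mm along (LR, AP, SI).
#' @return A [VOIMask-class] named `<ctv>_ptv3d`; always contains the CTV.
#' @export
expandPtv3D <- function(ctv, margins) {
  stopifnot(is(ctv, "VOIMask"), length(margins) == 3L)
  if (any(margins < 0)) stop("margins must be >= 0")
  sp <- ctv@grid@spacing
  half <- sp / 2
  nOff <- floor((half + margins) / sp + 1e-12)
  off <- as.matrix(expand.grid(i = -nOff[1]:nOff[1], j = -nOff[2]:nOff[2],
                               k = -nOff[3]:nOff[3]))
  u <- sweep(abs(off), 2, sp, "*")            # |centre offset| in mm
  q <- pmax(sweep(u, 2, half, "-"), 0)        # clamp to the voxel cube
  s <- rep(0, nrow(off))
  for (a in 1:3) {
    if (margins[a] > 0) s <- s + (q[, a] / margins[a])^2
    else s <- s + ifelse(q[, a] > 1e-12, Inf, 0)
  }
  keep <- off[s <= 1 + 1e-12, , drop = FALSE]
  voiMask(paste0(ctv@name, "_ptv3d"), ctv@grid,
          dilateByOffsets(ctv@mask, keep))
}

# integer voxel offsets satisfying the bdPTV membership predicate for a
# beam direction and margin ellipse
bdptvOffsets <- function(spacing, direction, semiAxes, axes3D) {
  halfBeam <- sum(abs(direction) * spacing) / 2
  # bounding box: beam-parallel extent + ellipse extent
  reach <- halfBeam + max(semiAxes)
  nOff <- floor(reach / spacing + 1e-12)
  off <- as.matrix(expand.grid(i = -nOff[1]:nOff[1], j = -nOff[2]:nOff[2],
                               k = -nOff[3]:nOff[3]))
  u <- sweep(off, 2, spacing, "*")
  tPar <- as.vector(u %*% direction)
  w <- u - outer(tPar, direction)
  p1 <- as.vector(w %*% axes3D[, 1])
  p2 <- as.vector(w %*% axes3D[, 2])
  r1 <- if (semiAxes[1] > 0) (p1 / semiAxes[1])^2 else
    ifelse(abs(p1) > 1e-9, Inf, 0)
  r2 <- if (semiAxes[2] > 0) (p2 / semiAxes[2])^2 else
    ifelse(abs(p2) > 1e-9, Inf, 0)
  keep <- abs(tPar) <= halfBeam + 1e-9 & r1 + r2 <= 1 + 1e-12
  off[keep, , drop = FALSE]
}

#' Beam-dependent PTV
#'
#' Expands every CTV voxel perpendicular to the beam only: voxel k belongs to
#' the bdPTV iff for some CTV voxel j the displacement of the voxel centres
#' has a beam-parallel component within j's half-extent along the beam and a
#' perpendicular component inside the 2D margin ellipse. The bdPTV is the
#' union of these per-voxel expansions and always contains the CTV.
#'
#' @param ctv a [VOIMask-class].
#' @param beam a [Beam-class].
#' @param ellipse margin ellipse from [margins2D()] (list with `semiAxes` and
#'   `axes3D`).
#' @return A [VOIMask-class] named `<ctv>_bdptv<gantry>`.
#' @export
buildBdptv <- function(ctv, beam, ellipse) {
  stopifnot(is(ctv, "VOIMask"), is(beam, "Beam"))
  if (any(ellipse$semiAxes < 0)) stop("ellipse semi-axes must be >= 0")
  off <- bdptvOffsets(ctv@grid@spacing, beam@direction,
                      ellipse$semiAxes, ellipse$axes3D)
  voiMask(sprintf("%s_bdptv%g", ctv@name, round(beam@gantry, 2)),
          ctv@grid, dilateByOffsets(ctv@mask, off))
}

#' Overlap map of a set of bdPTVs
#'
#' Per voxel, the number of bdPTVs containing it divided by the number of
#' beams; exactly on the lattice 0, 1/n, ..., 1 and equal to 1 on every CTV
#' voxel (all bdPTVs contain the CTV).
#'
#' @param bdptvs list of [VOIMask-class] on a shared grid.
#' @return An [OverlapMap-class].
#' @export
buildOverlapMap <- function(bdptvs) {
  if (length(bdptvs) < 1L) stop("need at least one bdPTV")
  grid <- bdptvs[[1]]@grid
  acc <- array(0, dim3(grid))
  for (b in bdptvs) {
    if (!identical(dim3(b@grid), dim3(grid)) ||
        max(abs(b@grid@spacing - grid@spacing)) > 1e-9)
      stop("bdPTVs must share one grid")
    acc <- acc + b@mask
  }
  new("OverlapMap", grid = grid, values = acc / length(bdptvs),
      nBeams = length(bdptvs))
}

#' Per-axis 3D van Herk margins for an uncertainty model
#'
#' @param model an [UncertaintyModel-class].
#' @param coeffs a [MarginCoefficients-class] (dimension 3 by default).
#' @return numeric(3) margins in mm along (LR, AP, SI).
#' @export
vanHerkMargins <- function(model, coeffs = marginCoefficients(3)) {
  vapply(1:3, function(a)
    margin1D(coeffs@alpha, model@sigmaSys[a], model@sigmaRand[a],
             model@sigmaPenumbra, coeffs@beta), numeric(1))
}

#' All bdPTVs and their overlap map for a beam arrangement
#'
#' @param ctv a [VOIMask-class].
#' @param beams list of [Beam-class].
#' @param model an [UncertaintyModel-class].
#' @param coeffs a [MarginCoefficients-class] with dimension 2.
#' @param isotropic forwarded to [margins2D()].
#' @return list with `bdptvs` (list of masks) and `overlap` (an
#'   [OverlapMap-class]).
#' @export
buildBeamMargins <- function(ctv, beams, model,
                             coeffs = marginCoefficients(2),
                             isotropic = FALSE) {
  bdptvs <- lapply(beams, function(b) {
    ell <- margins2D(collapseUncertainty(model, b), coeffs,
                     model@sigmaPenumbra, isotropic = isotropic)
    buildBdptv(ctv, b, ell)
  })
  list(bdptvs = bdptvs, overlap = buildOverlapMap(bdptvs))
}

setMethod("show", "OverlapMap", function(object) {
  cat(sprintf("OverlapMap: %d beams, %d voxels with positive overlap (%d at 1)\n",
              object@nBeams, sum(object@values > 0),
              sum(object@values >= 1 - 1e-12)))
})

setMethod("show", "UncertaintyModel", function(object) {
  cat(sprintf("UncertaintyModel (mm, LR/AP/SI): Sigma = %s; sigma_r = %s; sigma_p = %s\n",
              paste(fmtNum(object@sigmaSys, 2), collapse = "/"),
              paste(fmtNum(object@sigmaRand, 2), collapse = "/"),
              fmtNum(object@sigmaPenumbra, 2)))
})

setMethod("show", "MarginCoefficients", function(object) {
  cat(sprintf("MarginCoefficients: alpha = %.4f (d = %d, p = %.2f), beta = %.4f (p = %.2f)\n",
              object@alpha, object@dimension, object@coverageP,
              object@beta, object@doseLevelP))
})
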