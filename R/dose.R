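#' Pencil-beam beamlet dose kernel
#'
#' Separable water-equivalent photon beamlet model: exponential attenuation
#' with depth times, per lateral axis, the error-function profile of a finite
#' beamlet blurred by a Gaussian penumbra,
#' D = exp(-mu d) * prod_axis 0.5 (erf((u + a/2) / (sqrt2 sigma_p)) -
#' erf((u - a/2) / (sqrt2 sigma_p))).
#' A broad on-axis field at zero depth evaluates to 1, and the lateral
#' profile crosses 50% of the plateau at the geometric field edge u = a/2.
#'
#' @param depth radiological depth in mm (>= 0).
#' @param offAxis numeric vector or 2-column matrix of lateral distances (mm)
#'   from the beamlet axis; a matrix gives the two lateral axes.
#' @param params list with `mu` (1/mm), `sigmaPenumbra` (mm) and
#'   `beamletSize` (mm, length 2).
#' @return dose in Gy per unit fluence weight.
#' @export
beamletKernel <- function(depth, offAxis, params) {
  sp <- params$sigmaPenumbra
  if (is.null(sp) || sp <= 0) stop("sigmaPenumbra must be > 0")
  if (any(depth < 0)) stop("depth must be >= 0")
  offAxis <- rbind(offAxis)
  if (ncol(offAxis) == 1L) offAxis <- cbind(offAxis, 0)
  a <- params$beamletSize
  lat <- erfProfile(offAxis[, 1], a[1], sp) * erfProfile(offAxis[, 2], a[2], sp)
  as.vector(exp(-params$mu * depth) * lat)
}

# 0.5 * (erf((u + a/2)/(sqrt2 s)) - erf((u - a/2)/(sqrt2 s))) via pnorm
erfProfile <- function(u, a, s) {
  pnorm((u + a / 2) / s) - pnorm((u - a / 2) / s)
}

# radiological depth from the external-contour entry point, water-equivalent:
# for each point, march back along -direction in steps and sum the path
# length spent inside the external mask (nearest-voxel lookup).
rayDepths <- function(points, direction, external, step = 2) {
  grid <- external@grid
  ext <- external@mask
  d <- grid@dims
  extent <- sqrt(sum((d * grid@spacing)^2))
  m <- ceiling(extent / step)
  n <- nrow(points)
  depth <- numeric(n)
  for (s in seq_len(m)) {
    p <- points - outer(rep((s - 0.5) * step, n), direction)
    ijk <- round(worldToIndex(grid, p))
    ok <- ijk[, 1] >= 1 & ijk[, 1] <= d[1] & ijk[, 2] >= 1 & ijk[, 2] <= d[2] &
          ijk[, 3] >= 1 & ijk[, 3] <= d[3]
    if (!any(ok)) break
    idx <- ijkToLinear(grid, ijk[ok, , drop = FALSE])
    inside <- logical(n)
    inside[ok] <- ext[idx]
    depth <- depth + step * inside
  }
  depth
}

#' Build the sparse dose-influence matrix
#'
#' For each beam, a rectangular beamlet grid (default 5 x 5 mm^2 at the
#' isocenter plane, parallel beamlets) covering the aperture structure's
#' beam's-eye-view projection plus one beamlet ring. Each column holds the
#' [beamletKernel()] evaluated at every voxel centre inside the external
#' contour, with radiological depth measured from the external-contour entry
#' along the beam; entries below `pruneRel` times the column maximum are
#' dropped.
#'
#' @param grid a [DoseGrid-class].
#' @param beams list of [Beam-class].
#' @param aperture a [VOIMask-class]; the structure whose projection defines
#'   each beam's open beamlets (the PTV or bdPTV union).
#' @param external a [VOIMask-class], the external contour; rows of the
#'   matrix are its voxels.
#' @param params list: `mu` (1/mm, default 0.005), `sigmaPenumbra` (mm,
#'   default 3.2), `beamletSize` (mm pair, default c(5, 5)), `pruneRel`
#'   (default 1e-4), `depthStep` (mm, default 2).
#' @return A [DoseInfluence-class].
#' @export
buildDoseInfluence <- function(grid, beams, aperture, external,
                               params = list()) {
  stopifnot(is(aperture, "VOIMask"), is(external, "VOIMask"))
  if (!any(aperture@mask)) stop("aperture structure is empty")
  p <- modifyList(list(mu = 0.005, sigmaPenumbra = 3.2,
                       beamletSize = c(5, 5), pruneRel = 1e-4,
                       depthStep = 2), params)
  voxIdx <- which(external@mask)
  X <- indexToWorld(grid, linearToIjk(grid, voxIdx))
  apIdx <- which(aperture@mask)
  XA <- indexToWorld(grid, linearToIjk(grid, apIdx))
  a <- p$beamletSize
  cut <- a / 2 + 4 * p$sigmaPenumbra

  triplets <- vector("list", length(beams))
  blTabs <- vector("list", length(beams))
  colOffset <- 0L
  for (bi in seq_along(beams)) {
    bm <- beams[[bi]]
    B <- beamPlaneBasis(bm)
    dir <- bm@direction
    Xc <- sweep(X, 2, bm@isocenter)
    u <- as.vector(Xc %*% B[, 1]); v <- as.vector(Xc %*% B[, 2])
    XAc <- sweep(XA, 2, bm@isocenter)
    ua <- as.vector(XAc %*% B[, 1]); va <- as.vector(XAc %*% B[, 2])

    # occupied beamlet cells of the aperture projection, dilated by one cell
    iu <- round(ua / a[1]); iv <- round(va / a[2])
    occ <- unique(cbind(iu, iv))
    ring <- as.matrix(expand.grid(-1:1, -1:1))
    cells <- unique(do.call(rbind, lapply(seq_len(nrow(ring)), function(r)
      cbind(occ[, 1] + ring[r, 1], occ[, 2] + ring[r, 2]))))
    ub <- cells[, 1] * a[1]; vb <- cells[, 2] * a[2]

    depth <- rayDepths(X, dir, external, step = p$depthStep)
    att <- exp(-p$mu * depth)

    ord <- order(u)
    uSorted <- u[ord]
    ii <- integer(0); jj <- integer(0); xx <- numeric(0)
    for (b in seq_along(ub)) {
      lo <- findInterval(ub[b] - cut[1], uSorted) + 1L
      hi <- findInterval(ub[b] + cut[1], uSorted)
      if (lo > hi) next
      cand <- ord[lo:hi]
      cand <- cand[abs(v[cand] - vb[b]) <= cut[2]]
      if (!length(cand)) next
      val <- att[cand] *
        erfProfile(u[cand] - ub[b], a[1], p$sigmaPenumbra) *
        erfProfile(v[cand] - vb[b], a[2], p$sigmaPenumbra)
      keep <- val >= p$pruneRel * max(val)
      ii <- c(ii, cand[keep]); jj <- c(jj, rep(b + colOffset, sum(keep)))
      xx <- c(xx, val[keep])
    }
    triplets[[bi]] <- list(i = ii, j = jj, x = xx)
    blTabs[[bi]] <- data.frame(beam = bi, u = ub, v = vb)
    colOffset <- colOffset + length(ub)
  }
  ii <- unlist(lapply(triplets, `[[`, "i"))
  jj <- unlist(lapply(triplets, `[[`, "j"))
  xx <- unlist(lapply(triplets, `[[`, "x"))
  blTab <- do.call(rbind, blTabs)
  M <- sparseMatrix(i = ii, j = jj, x = xx,
                    dims = c(length(voxIdx), nrow(blTab)))
  nz <- Matrix::colSums(M) > 0
  M <- M[, nz, drop = FALSE]
  blTab <- blTab[nz, , drop = FALSE]
  new("DoseInfluence", grid = grid, matrix = M, voxelIndex = voxIdx,
      beamlets = blTab, params = p)
}

#' Accumulate dose from fluence weights
#'
#' Linear map dose = Dij %*% weights, placed back onto the grid (zero outside
#' the external contour rows).
#'
#' @param dij a [DoseInfluence-class].
#' @param weights nonnegative numeric, one per beamlet.
#' @return A [DoseDistribution-class].
#' @export
accumulateDose <- function(dij, weights) {
  stopifnot(is(dij, "DoseInfluence"))
  if (length(weights) != ncol(dij@matrix))
    stop("weight length must equal the number of beamlets")
  if (any(weights < 0)) stop("fluence weights must be >= 0")
  arr <- array(0, dim3(dij@grid))
  arr[dij@voxelIndex] <- as.vector(dij@matrix %*% weights)
  new("DoseDistribution", grid = dij@grid, dose = arr)
}

setMethod("show", "DoseInfluence", function(object) {
  cat(sprintf("DoseInfluence: %d voxels x %d beamlets, %d nonzeros (%d beams)\n",
              nrow(object@matrix), ncol(object@matrix),
              length(object@matrix@x), length(unique(object@beamlets$beam))))
})

setMethod("show", "DoseDistribution", function(object) {
  cat(sprintf("DoseDistribution: max %.2f Gy, mean (nonzero) %.2f Gy\n",
              max(object@dose), mean(object@dose[object@dose > 0])))
})
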