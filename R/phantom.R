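#' Specify a synthetic prostate phantom
#'
#' Parametric stand-in for a prostate IMRT case: an ellipsoidal CTV at the
#' isocenter, a posterior rectum (SI-aligned circular cylinder abutting the
#' CTV), an anterior-superior bladder ellipsoid, two lateral femoral-head
#' spheres and an elliptic-cylinder external contour. A seeded jitter of the
#' organ (not CTV) centres by ~1 mm emulates inter-case variation while
#' keeping every mask deterministic for a fixed seed.
#'
#' Defaults produce a CTV of about 38 cm^3 on the study voxel lattice of
#' 1.91 x 1.91 x 2.5 mm (LR, AP, SI).
#'
#' @param spacing numeric(3), voxel size in mm (LR, AP, SI).
#' @param ctvSemiAxes numeric(3), CTV ellipsoid semi-axes in mm.
#' @param rectumRadius,rectumLength rectum cylinder radius/length in mm.
#' @param bladderSemiAxes numeric(3), bladder ellipsoid semi-axes in mm.
#' @param bladderCenter numeric(3), bladder centre in mm (anterior-superior).
#' @param femoralRadius,femoralOffset femoral head sphere radius and lateral
#'   centre offset in mm.
#' @param externalSemiAxes numeric(2), external contour LR/AP semi-axes in mm.
#' @param externalHeight external contour SI extent in mm.
#' @param pad grid padding beyond the external contour in mm.
#' @param jitterSD SD in mm of the seeded organ-centre jitter.
#' @param seed integer seed for the jitter.
#' @return A validated `PhantomSpec` list.
#' @export
phantomSpec <- function(spacing = c(1.91, 1.91, 2.5),
                        ctvSemiAxes = c(21, 19, 23),
                        rectumRadius = 14, rectumLength = 110,
                        bladderSemiAxes = c(32, 30, 26),
                        bladderCenter = c(0, -24, 40),
                        femoralRadius = 22, femoralOffset = 62,
                        externalSemiAxes = c(100, 85),
                        externalHeight = 140,
                        pad = 8, jitterSD = 1, seed = 1L) {
  spec <- list(spacing = as.numeric(spacing),
               ctvSemiAxes = as.numeric(ctvSemiAxes),
               rectumRadius = rectumRadius, rectumLength = rectumLength,
               bladderSemiAxes = as.numeric(bladderSemiAxes),
               bladderCenter = as.numeric(bladderCenter),
               femoralRadius = femoralRadius, femoralOffset = femoralOffset,
               externalSemiAxes = as.numeric(externalSemiAxes),
               externalHeight = externalHeight, pad = pad,
               jitterSD = jitterSD, seed = as.integer(seed))
  dims <- c(spec$ctvSemiAxes, spec$rectumRadius, spec$rectumLength,
            spec$bladderSemiAxes, spec$femoralRadius,
            spec$externalSemiAxes, spec$externalHeight, spec$spacing)
  if (any(!is.finite(dims)) || any(dims <= 0))
    stop("all phantom dimensions must be positive")
  class(spec) <- "PhantomSpec"
  spec
}

# voxel-centre coordinate vectors of the phantom grid for a spec
phantomGrid <- function(spec) {
  hx <- spec$externalSemiAxes[1] + spec$pad
  hy <- spec$externalSemiAxes[2] + spec$pad
  hz <- spec$externalHeight / 2 + spec$pad
  dims <- as.integer(ceiling(2 * c(hx, hy, hz) / spec$spacing)) + 1L
  origin <- -(dims - 1) / 2 * spec$spacing
  doseGrid(dims, spec$spacing, origin)
}

#' Generate the synthetic prostate phantom
#'
#' Rasterises the structures of a [phantomSpec()] onto its grid by
#' voxel-centre inclusion. Rectum and bladder are clipped against the CTV so
#' that organs and CTV are disjoint (the rectum abuts the posterior CTV
#' surface); all organs are clipped to the external contour.
#'
#' @param spec a `PhantomSpec` from [phantomSpec()].
#' @return list with elements `grid` (a [DoseGrid-class]) and `masks` (named
#'   list of [VOIMask-class]: ctv, rectum, bladder, femoral_heads, external).
#' @examples
#' ph <- generatePhantom(phantomSpec(spacing = c(4, 4, 4)))
#' maskVolume(ph$masks$ctv)
#' @export
generatePhantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  grid <- phantomGrid(spec)
  xs <- grid@origin[1] + (seq_len(grid@dims[1]) - 1) * grid@spacing[1]
  ys <- grid@origin[2] + (seq_len(grid@dims[2]) - 1) * grid@spacing[2]
  zs <- grid@origin[3] + (seq_len(grid@dims[3]) - 1) * grid@spacing[3]

  jit <- withSeed(spec$seed,
                  matrix(rnorm(9, sd = spec$jitterSD), 3, 3))

  ellipsoid <- function(center, semi) {
    q <- outer(outer(((xs - center[1]) / semi[1])^2,
                     ((ys - center[2]) / semi[2])^2, "+"),
               ((zs - center[3]) / semi[3])^2, "+")
    q <= 1
  }
  ctv <- ellipsoid(c(0, 0, 0), spec$ctvSemiAxes)

  # rectum: posterior cylinder abutting the CTV surface (2 mm analytic
  # overlap, clipped against the CTV, keeps face adjacency under jitter)
  rc <- c(0, spec$ctvSemiAxes[2] + spec$rectumRadius - 2, 0) + c(jit[1, 1:2], 0)
  rxy <- outer(((xs - rc[1]) / spec$rectumRadius)^2,
               ((ys - rc[2]) / spec$rectumRadius)^2, "+") <= 1
  rz <- abs(zs - rc[3]) <= spec$rectumLength / 2
  rectum <- outer(rxy, rz, "&") & !ctv

  bc <- spec$bladderCenter + jit[2, ]
  bladder <- ellipsoid(bc, spec$bladderSemiAxes) & !ctv & !rectum

  fo <- spec$femoralOffset
  fem <- ellipsoid(c(-fo, 0, 0) + c(0, jit[3, 2:3]), rep(spec$femoralRadius, 3)) |
         ellipsoid(c(fo, 0, 0) + c(0, jit[3, 2:3]), rep(spec$femoralRadius, 3))

  exy <- outer((xs / spec$externalSemiAxes[1])^2,
               (ys / spec$externalSemiAxes[2])^2, "+") <= 1
  external <- outer(exy, abs(zs) <= spec$externalHeight / 2, "&")

  if (any(ctv & !external))
    stop("CTV extends outside the external contour")
  for (m in list(rectum, bladder, fem))
    if (!any(m & external))
      stop("an organ lies entirely outside the external contour / grid")

  masks <- list(
    ctv = voiMask("ctv", grid, ctv),
    rectum = voiMask("rectum", grid, rectum & external),
    bladder = voiMask("bladder", grid, bladder & external),
    femoral_heads = voiMask("femoral_heads", grid, fem & external),
    external = voiMask("external", grid, external))
  list(grid = grid, masks = masks)
}

#' Default objective table (prescription study)
#'
#' Piecewise-quadratic planning objectives for the prostate study: prostate
#' target min dose 74.5 Gy / max dose 82 Gy (weight 10), rectum max dose
#' `rectumMax` Gy (weight 8), bladder max 70 Gy (weight 6), femoral heads max
#' 50 Gy (weight 2) and external normal tissue max 60 Gy (weight 2).
#'
#' @param rectumMax rectum maximum dose objective in Gy (70, 65 or 60).
#' @return data.frame with columns structure, dmin, su, dmax, so.
#' @export
defaultObjectives <- function(rectumMax = 70) {
  data.frame(
    structure = c("prostate", "rectum", "bladder", "femoral_heads", "external"),
    dmin = c(74.5, NA, NA, NA, NA),
    su = c(10, 0, 0, 0, 0),
    dmax = c(82, rectumMax, 70, 50, 60),
    so = c(10, 8, 6, 2, 2),
    stringsAsFactors = FALSE)
}

#' Default study fixture
#'
#' The complete study conditions: the synthetic prostate phantom, the
#' uncertainty model (systematic SDs 1.1/1.5/1.1 mm and random SDs
#' 2.2/3.2/2.1 mm along LR/AP/SI; penumbra SD 3.2 mm), seven equidistant
#' coplanar 6 MV beams starting at gantry 0, a prescription of 78 Gy in 2 Gy
#' fractions (39 fractions), a default evaluation population of 50000, and
#' the default objective table.
#'
#' @param spacing numeric(3), voxel size in mm; pass an isotropic 3 mm grid
#'   for coarse desk-scale runs.
#' @param seed integer seed forwarded to the phantom generator.
#' @return list with elements phantom, uncertainty, gantryAngles,
#'   prescription, fractionDose, fractions, population, objectives,
#'   rectumMaxLevels, doseParams.
#' @examples
#' fx <- defaultStudyFixture()
#' length(fx$gantryAngles)  # 7
#' fx$fractions             # 39
#' @export
defaultStudyFixture <- function(spacing = c(1.91, 1.91, 2.5), seed = 1L) {
  list(
    phantom = phantomSpec(spacing = spacing, seed = seed),
    uncertainty = uncertaintyModel(sigmaSys = c(1.1, 1.5, 1.1),
                                   sigmaRand = c(2.2, 3.2, 2.1),
                                   sigmaPenumbra = 3.2),
    gantryAngles = (0:6) * 360 / 7,
    prescription = 78, fractionDose = 2, fractions = 39L,
    population = 50000L,
    objectives = defaultObjectives(70),
    rectumMaxLevels = c(70, 65, 60),
    doseParams = list(mu = 0.005, sigmaPenumbra = 3.2,
                      beamletSize = c(5, 5)),
    seed = as.integer(seed))
}
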