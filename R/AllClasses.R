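#' @import methods
#' @importFrom stats qnorm qchisq rnorm pnorm sd setNames
#' @importFrom utils modifyList write.csv
#' @importFrom Matrix sparseMatrix
NULL

#' DoseGrid: regular voxel lattice in patient coordinates
#'
#' Axis convention is fixed to (LR, AP, SI) with LPS-like signs: x increases
#' to the patient's left, y increases posteriorly, z increases superiorly
#' (head-first supine). `origin` is the world position of the centre of voxel
#' (1,1,1); world = origin + (index - 1) * spacing.
#'
#' @slot dims integer(3), voxels per axis.
#' @slot spacing numeric(3), voxel size in mm per axis.
#' @slot origin numeric(3), mm position of the first voxel centre.
#' @export
setClass("DoseGrid",
  representation(dims = "integer", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    if (length(object@dims) != 3L || length(object@spacing) != 3L ||
        length(object@origin) != 3L)
      return("dims, spacing and origin must each have length 3")
    if (any(object@dims < 1L)) return("all grid dimensions must be >= 1")
    if (any(!is.finite(object@spacing)) || any(object@spacing <= 0))
      return("all voxel spacings must be positive")
    if (any(!is.finite(object@origin))) return("origin must be finite")
    TRUE
  })

#' VOIMask: a named binary structure on a DoseGrid
#'
#' @slot name character, structure name.
#' @slot grid DoseGrid.
#' @slot mask logical 3D array with dim equal to the grid dims.
#' @slot allowEmpty logical, whether an all-FALSE mask is valid.
#' @export
setClass("VOIMask",
  representation(name = "character", grid = "DoseGrid", mask = "array",
                 allowEmpty = "logical"),
  prototype(allowEmpty = FALSE),
  validity = function(object) {
    if (!identical(dim(object@mask), dim3(object@grid)))
      return("mask dimensions do not match the grid")
    if (!is.logical(object@mask)) return("mask must be a logical array")
    if (!isTRUE(object@allowEmpty) && !any(object@mask))
      return(sprintf("VOI '%s' is empty (set allowEmpty = TRUE to permit)",
                     object@name))
    TRUE
  })

#' ExclusiveVOICube: one structure label per voxel
#'
#' Voxels outside the external contour carry label 0 (background); every voxel
#' inside the external contour carries the label of the highest-priority VOI
#' containing it, or the "external" (normal tissue) label.
#'
#' @slot grid DoseGrid.
#' @slot labels integer 3D array of label codes (0 = background).
#' @slot labelTable character vector; `labelTable[i]` names label code i.
#' @slot priority character, the VOI priority order used (first wins).
#' @export
setClass("ExclusiveVOICube",
  representation(grid = "DoseGrid", labels = "array",
                 labelTable = "character", priority = "character"),
  validity = function(object) {
    if (!identical(dim(object@labels), dim3(object@grid)))
      return("label cube dimensions do not match the grid")
    lab <- unique(as.vector(object@labels))
    if (any(lab < 0L) || any(lab > length(object@labelTable)))
      return("labels outside the label table range")
    TRUE
  })

#' Beam: a photon beam defined by its gantry angle
#'
#' @slot gantry numeric, gantry angle in degrees, normalised to [0, 360).
#' @slot direction numeric(3), unit vector from source towards isocenter.
#' @slot isocenter numeric(3), mm.
#' @export
setClass("Beam",
  representation(gantry = "numeric", direction = "numeric",
                 isocenter = "numeric"),
  validity = function(object) {
    if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-12)
      return("beam direction must be unit length")
    if (length(object@isocenter) != 3L) return("isocenter must have length 3")
    TRUE
  })

#' UncertaintyModel: per-axis Gaussian geometric uncertainty
#'
#' Standard deviations of the systematic (preparation) and random (execution)
#' setup errors along the (LR, AP, SI) patient axes, assumed uncorrelated,
#' plus the Gaussian penumbra SD of the photon beam.
#'
#' @slot sigmaSys numeric(3), systematic SDs (mm) per (LR, AP, SI).
#' @slot sigmaRand numeric(3), random SDs (mm) per (LR, AP, SI).
#' @slot sigmaPenumbra numeric, penumbra SD (mm).
#' @export
setClass("UncertaintyModel",
  representation(sigmaSys = "numeric", sigmaRand = "numeric",
                 sigmaPenumbra = "numeric"),
  validity = function(object) {
    if (length(object@sigmaSys) != 3L || length(object@sigmaRand) != 3L)
      return("sigmaSys and sigmaRand must have length 3 (LR, AP, SI)")
    if (any(c(object@sigmaSys, object@sigmaRand, object@sigmaPenumbra) < 0))
      return("all uncertainty SDs must be >= 0")
    TRUE
  })

#' MarginCoefficients: van Herk recipe coefficients
#'
#' `alpha` scales the systematic SD and depends on the dimensionality of the
#' bounding region (1, 2 or 3); `beta` is the one-sided normal quantile for
#' the minimum-dose level carried by the blurred penumbra.
#'
#' @slot alpha numeric, coverage coefficient.
#' @slot beta numeric, dose-level coefficient.
#' @slot dimension integer, dimensionality alpha was computed for.
#' @slot coverageP numeric, population coverage probability (default 0.90).
#' @slot doseLevelP numeric, minimum dose level probability (default 0.95).
#' @export
setClass("MarginCoefficients",
  representation(alpha = "numeric", beta = "numeric", dimension = "integer",
                 coverageP = "numeric", doseLevelP = "numeric"),
  validity = function(object) {
    if (object@alpha < 0 || object@beta < 0)
      return("alpha and beta must be >= 0")
    if (object@coverageP <= 0 || object@coverageP >= 1 ||
        object@doseLevelP <= 0 || object@doseLevelP >= 1)
      return("probabilities must lie in (0, 1)")
    TRUE
  })

#' CollapsedUncertainty: uncertainty marginalised onto a beam's-eye plane
#'
#' The trivariate setup Gaussian collapsed (marginalised) along the beam
#' direction onto the plane perpendicular to it, expressed in an orthonormal
#' in-plane basis.
#'
#' @slot planeBasis numeric 3x2 matrix; columns are the in-plane basis vectors.
#' @slot sysCov numeric 2x2, collapsed systematic covariance (mm^2).
#' @slot randCov numeric 2x2, collapsed random covariance (mm^2).
#' @export
setClass("CollapsedUncertainty",
  representation(planeBasis = "matrix", sysCov = "matrix", randCov = "matrix"),
  validity = function(object) {
    B <- object@planeBasis
    if (!identical(dim(B), c(3L, 2L))) return("planeBasis must be 3x2")
    if (max(abs(crossprod(B) - diag(2))) > 1e-9)
      return("planeBasis columns must be orthonormal")
    for (M in list(object@sysCov, object@randCov)) {
      if (max(abs(M - base::t(M))) > 1e-9) return("covariances must be symmetric")
      if (min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) < -1e-9)
        return("covariances must be positive semi-definite")
    }
    TRUE
  })

#' OverlapMap: fractional bdPTV overlap per voxel
#'
#' For each voxel the fraction of beams whose beam-dependent PTV contains it;
#' 1 on the CTV (all bdPTVs contain the CTV), 0 far from the target.
#'
#' @slot grid DoseGrid.
#' @slot values numeric 3D array in [0, 1].
#' @slot nBeams integer, number of bdPTVs summed.
#' @export
setClass("OverlapMap",
  representation(grid = "DoseGrid", values = "array", nBeams = "integer"),
  validity = function(object) {
    if (!identical(dim(object@values), dim3(object@grid)))
      return("overlap values do not match the grid")
    v <- range(object@values)
    if (v[1] < -1e-12 || v[2] > 1 + 1e-12)
      return("overlap fractions must lie in [0, 1]")
    cnt <- object@values * object@nBeams
    if (max(abs(cnt - round(cnt))) > 1e-9)
      return("overlap fractions must be multiples of 1/nBeams")
    TRUE
  })

#' DoseInfluence: sparse beamlet-to-voxel dose matrix
#'
#' Row i gives the dose (Gy per unit fluence weight) delivered to the voxel
#' with linear grid index `voxelIndex[i]`; columns are beamlets described by
#' `beamlets` (beam number, in-plane offsets u, v at the isocenter plane).
#'
#' @slot grid DoseGrid.
#' @slot matrix dgCMatrix, n_voxels x n_beamlets, nonnegative.
#' @slot voxelIndex integer, linear grid index per matrix row.
#' @slot beamlets data.frame with columns beam, u, v.
#' @slot params list, dose engine parameters used.
#' @export
setClass("DoseInfluence",
  representation(grid = "DoseGrid", matrix = "ANY", voxelIndex = "integer",
                 beamlets = "data.frame", params = "list"),
  validity = function(object) {
    if (nrow(object@matrix) != length(object@voxelIndex))
      return("matrix rows must match voxelIndex length")
    if (ncol(object@matrix) != nrow(object@beamlets))
      return("matrix columns must match the beamlet table")
    if (any(object@matrix@x < 0)) return("dose influence must be nonnegative")
    TRUE
  })

#' DoseDistribution: a dose volume in Gy on a DoseGrid
#'
#' @slot grid DoseGrid.
#' @slot dose numeric 3D array, Gy.
#' @export
setClass("DoseDistribution",
  representation(grid = "DoseGrid", dose = "array"),
  validity = function(object) {
    if (!identical(dim(object@dose), dim3(object@grid)))
      return("dose dimensions do not match the grid")
    if (any(!is.finite(object@dose))) return("dose must be finite")
    if (min(object@dose) < -1e-9) return("dose must be nonnegative")
    TRUE
  })

#' PlanResult: converged fluence weights and the resulting dose
#'
#' @slot name character, plan label (e.g. "2D_R65").
#' @slot weights numeric, nonnegative fluence weights per beamlet.
#' @slot dose DoseDistribution.
#' @slot trace numeric, objective value per accepted iterate (non-increasing).
#' @slot config list, echo of the optimisation setup.
#' @export
setClass("PlanResult",
  representation(name = "character", weights = "numeric",
                 dose = "DoseDistribution", trace = "numeric",
                 config = "list"),
  validity = function(object) {
    if (any(object@weights < 0)) return("fluence weights must be >= 0")
    if (length(object@trace) > 1 &&
        any(diff(object@trace) > 1e-9 * pmax(object@trace[-length(object@trace)], 1)))
      return("objective trace must be non-increasing")
    TRUE
  })

#' EvaluationConfig: Monte-Carlo verification settings
#'
#' @slot populationSize integer, number of simulated patients (default 50000).
#' @slot fractions integer, number of treatment fractions F (default 39).
#' @slot uncertainty UncertaintyModel.
#' @slot seed integer RNG seed.
#' @export
setClass("EvaluationConfig",
  representation(populationSize = "integer", fractions = "integer",
                 uncertainty = "UncertaintyModel", seed = "integer"),
  validity = function(object) {
    if (object@populationSize < 1L) return("populationSize must be >= 1")
    if (object@fractions < 1L) return("fractions must be >= 1")
    TRUE
  })

#' DVHObjective: a dose-volume histogram criterion
#'
#' Either D-at-volume (`kind = "D"`: dose received by at least `volume`% of
#' the structure) or V-at-dose (`kind = "V"`: percent volume receiving at
#' least `dose` Gy), compared against `threshold` with `comparator`.
#'
#' @slot structure character, structure name.
#' @slot kind character, "D" or "V".
#' @slot dose numeric, Gy (the d of V_d, or the threshold of a D objective).
#' @slot volume numeric, percent (the q of D_q, or the threshold of a V objective).
#' @slot comparator character, ">=" or "<=".
#' @export
setClass("DVHObjective",
  representation(structure = "character", kind = "character",
                 dose = "numeric", volume = "numeric", comparator = "character"),
  validity = function(object) {
    if (!object@kind %in% c("D", "V")) return("kind must be 'D' or 'V'")
    if (!object@comparator %in% c(">=", "<=", ">", "<"))
      return("comparator must be one of >=, <=, >, <")
    if (object@volume <= 0 || object@volume > 100)
      return("volume percentage must lie in (0, 100]")
    if (object@dose < 0) return("dose must be >= 0")
    TRUE
  })

#' CoverageResult: Monte-Carlo pass probability for one DVH objective
#'
#' @slot objective DVHObjective.
#' @slot probability numeric in [0, 1], fraction of the population passing.
#' @slot se numeric, binomial standard error sqrt(p(1-p)/n).
#' @slot n integer, population size used.
#' @export
setClass("CoverageResult",
  representation(objective = "DVHObjective", probability = "numeric",
                 se = "numeric", n = "integer"),
  validity = function(object) {
    if (object@probability < 0 || object@probability > 1)
      return("probability must lie in [0, 1]")
    TRUE
  })

#' DVCMGrid: dose-volume coverage map
#'
#' `surface[i, j]` is the population probability that at least `volumeEdges[j]`
#' percent of the structure receives at least `doseEdges[i]` Gy. Surfaces are
#' non-increasing along both axes. A signed difference of two DVCMs (a DVCDM)
#' uses the same container with values in [-1, 1].
#'
#' @slot doseEdges numeric, Gy.
#' @slot volumeEdges numeric, percent.
#' @slot surface numeric matrix, length(doseEdges) x length(volumeEdges).
#' @slot signed logical, TRUE for difference maps.
#' @export
setClass("DVCMGrid",
  representation(doseEdges = "numeric", volumeEdges = "numeric",
                 surface = "matrix", signed = "logical"),
  prototype(signed = FALSE),
  validity = function(object) {
    if (!identical(dim(object@surface),
                   c(length(object@doseEdges), length(object@volumeEdges))))
      return("surface dimensions must match the bin edges")
    lo <- if (isTRUE(object@signed)) -1 else 0
    if (min(object@surface) < lo - 1e-12 || max(object@surface) > 1 + 1e-12)
      return("surface values out of range")
    TRUE
  })

#' PlanStudy: the four-plan margin-comparison study
#'
#' @slot plans list of PlanResult (3D_R70, 2D_R70, 2D_R65, 2D_R60).
#' @slot anatomy list of VOIMask (phantom structures plus derived PTVs).
#' @slot overlap OverlapMap.
#' @slot dij DoseInfluence.
#' @slot fixture list, the study fixture used.
#' @export
setClass("PlanStudy",
  representation(plans = "list", anatomy = "list", overlap = "OverlapMap",
                 dij = "DoseInfluence", fixture = "list"))
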