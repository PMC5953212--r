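#' Beam direction from gantry angle
#'
#' IEC-61217-style convention for a head-first supine patient with axes
#' (x = LR left+, y = AP posterior+, z = SI superior+): at gantry 0 the source
#' is anterior and the beam travels towards the posterior, so
#' direction = (-sin g, cos g, 0). Coplanar beams have no SI component.
#'
#' @param gantryDeg gantry angle in degrees; any real value (normalised
#'   modulo 360).
#' @return unit numeric(3) source-to-isocenter direction.
#' @examples
#' gantryToDirection(0)    # c(0, 1, 0)
#' gantryToDirection(90)   # c(-1, 0, 0)
#' @export
gantryToDirection <- function(gantryDeg) {
  g <- (gantryDeg %% 360) * pi / 180
  d <- c(-sin(g), cos(g), 0)
  d[abs(d) < 1e-15] <- 0
  normalize3(d)
}

#' Create a treatment beam
#'
#' @param gantryDeg gantry angle in degrees.
#' @param isocenter numeric(3), mm; usually the target centroid.
#' @return A [Beam-class].
#' @export
beam <- function(gantryDeg, isocenter = c(0, 0, 0)) {
  new("Beam", gantry = gantryDeg %% 360,
      direction = gantryToDirection(gantryDeg),
      isocenter = as.numeric(isocenter))
}

#' Orthonormal basis of the plane perpendicular to a beam
#'
#' Deterministic construction: e1 = normalise(direction x SI-axis), falling
#' back to the LR axis when the beam is parallel to SI; e2 = direction x e1.
#' For coplanar beams e1 lies in the axial plane and e2 is (anti)parallel to
#' the SI axis.
#'
#' @param beam a [Beam-class] or unit numeric(3) direction.
#' @return numeric 3x2 matrix whose columns are the in-plane basis vectors.
#' @export
beamPlaneBasis <- function(beam) {
  d <- if (is(beam, "Beam")) beam@direction else normalize3(beam)
  ref <- c(0, 0, 1)
  e1 <- cross3(d, ref)
  if (sqrt(sum(e1^2)) < 1e-8) e1 <- cross3(d, c(1, 0, 0))
  e1 <- normalize3(e1)
  e2 <- cross3(d, e1)
  cbind(e1, e2, deparse.level = 0)
}

#' Equidistant coplanar beam arrangement
#'
#' @param n number of beams.
#' @param start first gantry angle in degrees (default 0).
#' @param isocenter numeric(3), mm.
#' @return list of [Beam-class] objects at gantry start + (0:(n-1)) * 360 / n.
#' @export
equidistantBeams <- function(n, start = 0, isocenter = c(0, 0, 0)) {
  lapply(start + (seq_len(n) - 1) * 360 / n, beam, isocenter = isocenter)
}

setMethod("show", "Beam", function(object) {
  cat(sprintf("Beam: gantry %.2f deg, direction (%s)\n", object@gantry,
              paste(fmtNum(object@direction), collapse = ", ")))
})
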