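#' Run the four-plan margin-comparison study
#'
#' Builds the phantom, the conventional 3D van Herk PTV, the per-beam bdPTVs
#' and their overlap map, one shared dose-influence matrix, and optimises
#' four plans: the 3D-margin plan (exclusive-VOI objective on the PTV cube,
#' rectum max 70 Gy) and three overlap-weighted plans with rectum max dose
#' 70, 65 and 60 Gy; all other objectives fixed.
#'
#' @param fixture study fixture from [defaultStudyFixture()].
#' @param tol,maxIter forwarded to [optimizeFluence()].
#' @param verbose print stage progress.
#' @return A [PlanStudy-class] with plans named 3D_R70, 2D_R70, 2D_R65,
#'   2D_R60.
#' @export
runPlanStudy <- function(fixture = defaultStudyFixture(), tol = 1e-5,
                         maxIter = 300, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  say("generating phantom")
  ph <- generatePhantom(fixture$phantom)
  grid <- ph$grid
  ctv <- ph$masks$ctv
  iso <- colMeans(voxelCenters(grid, ctv))
  beams <- lapply(fixture$gantryAngles, beam, isocenter = iso)
  um <- fixture$uncertainty

  say("building margins")
  m3 <- vanHerkMargins(um)
  ptv3d <- expandPtv3D(ctv, m3)
  bm <- buildBeamMargins(ctv, beams, um)
  unionBd <- Reduce(`|`, lapply(bm$bdptvs, function(m) m@mask))
  aperture <- voiMask("aperture", grid, ptv3d@mask | unionBd)

  say("building dose influence")
  dij <- buildDoseInfluence(grid, beams, aperture, ph$masks$external,
                            fixture$doseParams)

  oars <- ph$masks[c("rectum", "bladder", "femoral_heads")]
  prio <- c("prostate", "rectum", "bladder", "femoral_heads")
  cube3d <- buildExclusiveCube(
    c(list(voiMask("prostate", grid, ptv3d@mask)), oars),
    prio, ph$masks$external)
  cube2d <- buildExclusiveCube(
    c(list(voiMask("prostate", grid, ctv@mask)), oars),
    prio, ph$masks$external)

  plans <- list()
  say("optimising 3D_R70")
  pr <- planProblem(dij, cube3d, defaultObjectives(70),
                    prescription = fixture$prescription)
  plans[["3D_R70"]] <- optimizeFluence(pr, tol = tol, maxIter = maxIter,
                                       name = "3D_R70")
  for (rm in fixture$rectumMaxLevels) {
    nm <- sprintf("2D_R%d", rm)
    say("optimising %s", nm)
    pr <- planProblem(dij, cube2d, defaultObjectives(rm),
                      overlaps = list(prostate = bm$overlap),
                      prescription = fixture$prescription)
    plans[[nm]] <- optimizeFluence(pr, tol = tol, maxIter = maxIter,
                                   name = nm)
  }
  anatomy <- c(ph$masks,
               list(ptv3d = ptv3d,
                    bdptv_union = voiMask("bdptv_union", grid, unionBd)))
  anatomy <- c(anatomy, stats::setNames(bm$bdptvs, sprintf(
    "bdptv_%d", seq_along(bm$bdptvs))))
  new("PlanStudy", plans = plans, anatomy = anatomy, overlap = bm$overlap,
      dij = dij, fixture = fixture)
}

setMethod("show", "PlanStudy", function(object) {
  cat("PlanStudy with plans:", paste(names(object@plans), collapse = ", "),
      "\n")
  cat(sprintf("  3D PTV %.2f cm^3, bdPTV union %.2f cm^3\n",
              maskVolume(object@anatomy$ptv3d),
              maskVolume(object@anatomy$bdptv_union)))
})
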