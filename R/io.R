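# Volume, configuration and report I/O.
#
# Volumes are NIfTI; the package's (LR, AP, SI) axes map directly onto the
# file axes, with the grid carried in the qform (diagonal spacing + origin).

#' @importFrom RNifti asNifti writeNifti readNifti pixdim "pixdim<-" xform
NULL

gridAffine <- function(grid) {
  qf <- diag(c(grid@spacing, 1))
  qf[1:3, 4] <- grid@origin
  structure(qf, code = 2L)
}

#' Write a VOI mask as NIfTI
#'
#' @param mask a [VOIMask-class].
#' @param path output path (.nii or .nii.gz).
#' @return the path, invisibly.
#' @export
writeMask <- function(mask, path) {
  img <- asNifti(mask@mask + 0L)
  pixdim(img) <- mask@grid@spacing
  img <- RNifti::`qform<-`(img, gridAffine(mask@grid))
  writeNifti(img, path)
  invisible(path)
}

#' Read a VOI mask from NIfTI
#'
#' @param path NIfTI file written by [writeMask()].
#' @param name structure name for the mask.
#' @param allowEmpty permit an empty mask.
#' @return A [VOIMask-class].
#' @export
readMask <- function(path, name, allowEmpty = FALSE) {
  img <- readNifti(path)
  qf <- xform(img)
  grid <- doseGrid(dim(img), spacing = diag(qf)[1:3], origin = qf[1:3, 4])
  voiMask(name, grid, array(as.vector(img) > 0.5, dim(img)),
          allowEmpty = allowEmpty)
}

#' Write a dose or overlap volume as NIfTI
#'
#' @param volume a [DoseDistribution-class] or [OverlapMap-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeVolume <- function(volume, path) {
  arr <- if (is(volume, "DoseDistribution")) volume@dose else volume@values
  grid <- volume@grid
  img <- asNifti(arr)
  pixdim(img) <- grid@spacing
  img <- RNifti::`qform<-`(img, gridAffine(grid))
  writeNifti(img, path)
  invisible(path)
}

#' Write an exclusive VOI cube as NIfTI plus a JSON label map
#'
#' @param cube an [ExclusiveVOICube-class].
#' @param path NIfTI path; the sidecar `<path>.json` maps codes to names.
#' @return the path, invisibly.
#' @export
writeLabelCube <- function(cube, path) {
  img <- asNifti(cube@labels)
  pixdim(img) <- cube@grid@spacing
  img <- RNifti::`qform<-`(img, gridAffine(cube@grid))
  writeNifti(img, path)
  jsonlite::write_json(
    list(labels = stats::setNames(as.list(seq_along(cube@labelTable)),
                                  cube@labelTable),
         origin = cube@grid@origin),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# recursively reject keys absent from the reference structure
checkKeys <- function(cfg, ref, path = "") {
  if (!is.list(cfg) || is.null(names(cfg))) return(invisible(NULL))
  unknown <- setdiff(names(cfg), names(ref))
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (nm in names(cfg))
    if (is.list(cfg[[nm]]) && !is.null(names(cfg[[nm]])) &&
        is.list(ref[[nm]]))
      checkKeys(cfg[[nm]], ref[[nm]], paste0(path, nm, "."))
  invisible(NULL)
}

configTemplate <- function() {
  list(phantom = list(spacing = NULL, ctv_semiaxes = NULL,
                      rectum_radius = NULL, rectum_length = NULL,
                      bladder_semiaxes = NULL, bladder_center = NULL,
                      femoral_radius = NULL, femoral_offset = NULL,
                      external_semiaxes = NULL, external_height = NULL,
                      pad = NULL, jitter_sd = NULL, seed = NULL),
       uncertainty = list(sigma_sys = NULL, sigma_rand = NULL,
                          sigma_penumbra = NULL),
       beams = list(count = NULL, start = NULL),
       prescription = NULL, fraction_dose = NULL, fractions = NULL,
       population = NULL, rectum_max_levels = NULL,
       objectives = NULL, seed = NULL,
       dose = list(mu = NULL, beamlet_size = NULL))
}

#' Load a study configuration
#'
#' Reads a YAML study configuration, validates it against the known schema
#' (unknown keys are rejected, naming the offending key) and fills every
#' missing value with the packaged study default (see
#' [defaultStudyFixture()]).
#'
#' @param path YAML file path.
#' @return a study fixture list as returned by [defaultStudyFixture()].
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  checkKeys(cfg, configTemplate())
  defSeed <- if (!is.null(cfg$seed)) as.integer(cfg$seed) else 1L
  phSpacing <- cfg$phantom$spacing %||% c(1.91, 1.91, 2.5)
  phArgs <- list(spacing = phSpacing, seed = cfg$phantom$seed %||% defSeed)
  map <- c(ctv_semiaxes = "ctvSemiAxes", rectum_radius = "rectumRadius",
           rectum_length = "rectumLength", bladder_semiaxes = "bladderSemiAxes",
           bladder_center = "bladderCenter", femoral_radius = "femoralRadius",
           femoral_offset = "femoralOffset",
           external_semiaxes = "externalSemiAxes",
           external_height = "externalHeight", pad = "pad",
           jitter_sd = "jitterSD")
  for (k in names(map))
    if (!is.null(cfg$phantom[[k]])) phArgs[[map[[k]]]] <- cfg$phantom[[k]]
  fx <- defaultStudyFixture(spacing = phSpacing, seed = defSeed)
  fx$phantom <- do.call(phantomSpec, phArgs)
  if (!is.null(cfg$uncertainty))
    fx$uncertainty <- uncertaintyModel(
      sigmaSys = cfg$uncertainty$sigma_sys %||% c(1.1, 1.5, 1.1),
      sigmaRand = cfg$uncertainty$sigma_rand %||% c(2.2, 3.2, 2.1),
      sigmaPenumbra = cfg$uncertainty$sigma_penumbra %||% 3.2)
  nb <- cfg$beams$count %||% 7
  fx$gantryAngles <- (cfg$beams$start %||% 0) + (seq_len(nb) - 1) * 360 / nb
  fx$prescription <- cfg$prescription %||% 78
  fx$fractionDose <- cfg$fraction_dose %||% 2
  fx$fractions <- as.integer(cfg$fractions %||%
                               round(fx$prescription / fx$fractionDose))
  fx$population <- as.integer(cfg$population %||% 50000)
  fx$rectumMaxLevels <- cfg$rectum_max_levels %||% c(70, 65, 60)
  if (!is.null(cfg$objectives)) {
    fx$objectives <- do.call(rbind, lapply(cfg$objectives, function(o)
      data.frame(structure = o$structure,
                 dmin = o$dmin %||% NA_real_, su = o$su %||% 0,
                 dmax = o$dmax %||% NA_real_, so = o$so %||% 0)))
  }
  if (!is.null(cfg$dose)) {
    fx$doseParams$mu <- cfg$dose$mu %||% fx$doseParams$mu
    fx$doseParams$beamletSize <- cfg$dose$beamlet_size %||%
      fx$doseParams$beamletSize
  }
  fx$doseParams$sigmaPenumbra <- fx$uncertainty@sigmaPenumbra
  fx$seed <- defSeed
  fx
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Paper-style DVH coverage criteria for the study
#'
#' The four reporting criteria of the planning comparison: CTV D_98% >= 95%
#' of the prescription; rectum V_70Gy < 5% and V_75Gy < 2%; bladder
#' V_74Gy < 2%.
#'
#' @param prescription prescription dose in Gy (default 78).
#' @return list of [DVHObjective-class].
#' @export
studyObjectives <- function(prescription = 78) {
  list(
    dvhObjective("ctv", "D", dose = 0.95 * prescription, volume = 98,
                 comparator = ">="),
    dvhObjective("rectum", "V", dose = 70, volume = 5, comparator = "<"),
    dvhObjective("rectum", "V", dose = 75, volume = 2, comparator = "<"),
    dvhObjective("bladder", "V", dose = 74, volume = 2, comparator = "<"))
}

#' Evaluate all plans of a study against DVH coverage criteria
#'
#' @param study a [PlanStudy-class].
#' @param config an [EvaluationConfig-class].
#' @param objectives list of [DVHObjective-class]; defaults to
#'   [studyObjectives()].
#' @return data.frame with one row per (plan, objective): plan, structure,
#'   objective, probability, se, n.
#' @export
evaluateStudy <- function(study, config, objectives = NULL) {
  if (is.null(objectives))
    objectives <- studyObjectives(study@fixture$prescription)
  rows <- list()
  for (pn in names(study@plans)) {
    for (ob in objectives) {
      res <- coverageProbability(study@plans[[pn]],
                                 study@anatomy[[ob@structure]], config, ob)
      desc <- if (ob@kind == "D")
        sprintf("D_%g%% %s %g Gy", ob@volume, ob@comparator, ob@dose)
      else sprintf("V_%gGy %s %g%%", ob@dose, ob@comparator, ob@volume)
      rows[[length(rows) + 1L]] <- data.frame(
        plan = pn, structure = ob@structure, objective = desc,
        probability = res@probability, se = res@se, n = res@n)
    }
  }
  do.call(rbind, rows)
}

#' Write the study coverage report
#'
#' One CSV row per (plan, structure, objective) with the pass probability in
#' percent, formatted to two decimal places.
#'
#' @param results data.frame from [evaluateStudy()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeStudyReport <- function(results, path) {
  if (!nrow(results)) stop("no evaluated plans to report")
  out <- data.frame(plan = results$plan, structure = results$structure,
                    objective = results$objective,
                    probability_pct = sprintf("%.2f",
                                              100 * results$probability),
                    n = results$n)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write a DVCM or DVCDM as CSV
#'
#' Row names are dose bin edges (Gy), column names volume bin edges (%).
#'
#' @param dvcm a [DVCMGrid-class].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeDvcm <- function(dvcm, path) {
  m <- dvcm@surface
  rownames(m) <- dvcm@doseEdges
  colnames(m) <- dvcm@volumeEdges
  utils::write.csv(m, path, row.names = TRUE)
  invisible(path)
}
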