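#' Create a voxel grid
#'
#' The lattice geometry every volume in the package lives on. Axes follow the
#' fixed patient convention (LR, AP, SI) for a head-first supine patient:
#' x to the patient's left, y posterior, z superior.
#'
#' @param dims integer(3), number of voxels per axis.
#' @param spacing numeric(3), voxel size in mm; the study default is
#'   c(1.91, 1.91, 2.5) mm in (LR, AP, SI).
#' @param origin numeric(3), world position (mm) of the first voxel centre.
#' @return A [DoseGrid-class] object.
#' @examples
#' g <- doseGrid(c(10, 10, 4), spacing = c(1.91, 1.91, 2.5))
#' @export
doseGrid <- function(dims, spacing = c(1.91, 1.91, 2.5), origin = c(0, 0, 0)) {
  new("DoseGrid", dims = as.integer(dims), spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' World coordinates of voxel centres
#'
#' @param grid a [DoseGrid-class].
#' @param ijk integer matrix (n x 3) of 1-based voxel indices.
#' @return numeric matrix (n x 3) of mm positions.
#' @export
indexToWorld <- function(grid, ijk) {
  ijk <- rbind(ijk)
  sweep(sweep(ijk - 1, 2, grid@spacing, "*"), 2, grid@origin, "+")
}

#' Continuous (fractional) voxel indices of world points
#'
#' Inverse of [indexToWorld()]; returns fractional indices, so rounding gives
#' the containing voxel under the half-open voxel model.
#'
#' @param grid a [DoseGrid-class].
#' @param xyz numeric matrix (n x 3) of mm positions.
#' @return numeric matrix (n x 3) of 1-based fractional indices.
#' @export
worldToIndex <- function(grid, xyz) {
  xyz <- rbind(xyz)
  sweep(sweep(xyz, 2, grid@origin, "-"), 2, grid@spacing, "/") + 1
}

#' Create a VOI mask
#'
#' @param name structure name.
#' @param grid a [DoseGrid-class].
#' @param mask logical array on the grid.
#' @param allowEmpty permit an all-FALSE mask.
#' @return A [VOIMask-class].
#' @export
voiMask <- function(name, grid, mask, allowEmpty = FALSE) {
  storage.mode(mask) <- "logical"
  new("VOIMask", name = name, grid = grid, mask = mask,
      allowEmpty = allowEmpty)
}

#' Centres of the voxels inside a mask
#'
#' @param grid a [DoseGrid-class].
#' @param mask a [VOIMask-class] on the same grid.
#' @return numeric matrix (n x 3) of mm positions, in lexicographic (column
#'   major) voxel-index order; zero rows for an empty mask.
#' @export
voxelCenters <- function(grid, mask) {
  stopifnot(is(mask, "VOIMask"))
  if (!identical(dim3(grid), dim3(mask@grid)))
    stop("mask grid does not match")
  idx <- which(mask@mask)
  if (length(idx) == 0L)
    return(matrix(numeric(0), ncol = 3,
                  dimnames = list(NULL, c("LR", "AP", "SI"))))
  xyz <- indexToWorld(grid, linearToIjk(grid, idx))
  colnames(xyz) <- c("LR", "AP", "SI")
  xyz
}

#' Voxel volume of a mask in cubic centimetres
#'
#' @param mask a [VOIMask-class].
#' @return numeric, cm^3.
#' @export
maskVolume <- function(mask) {
  sum(mask@mask) * prod(mask@grid@spacing) / 1000
}

#' Build an exclusive VOI cube
#'
#' Assigns exactly one structure to each voxel inside the external contour.
#' Where VOIs overlap, the first structure in `priority` wins; voxels inside
#' the external contour belonging to no VOI receive the normal-tissue label
#' `"external"`. Voxels outside the external contour are background (label 0).
#'
#' @param vois list of [VOIMask-class] on one shared grid.
#' @param priority character, ordered VOI names (first wins); must cover every
#'   VOI in `vois`.
#' @param external a [VOIMask-class], the external patient contour.
#' @return An [ExclusiveVOICube-class].
#' @export
buildExclusiveCube <- function(vois, priority, external) {
  grid <- external@grid
  nm <- vapply(vois, function(v) v@name, character(1))
  for (v in vois)
    if (!identical(dim3(v@grid), dim3(grid)) ||
        max(abs(v@grid@spacing - grid@spacing)) > 1e-9 ||
        max(abs(v@grid@origin - grid@origin)) > 1e-9)
      stop("all VOIs must share the external contour's grid")
  missing <- setdiff(nm, priority)
  if (length(missing))
    stop("VOI(s) not in the priority list: ", paste(missing, collapse = ", "))
  priority <- c(intersect(priority, nm), "external")
  labels <- array(0L, dim3(grid))
  # paint lowest priority first so higher priorities overwrite
  labels[external@mask] <- match("external", priority)
  for (name in rev(setdiff(priority, "external"))) {
    v <- vois[[which(nm == name)]]
    labels[v@mask & external@mask] <- match(name, priority)
  }
  new("ExclusiveVOICube", grid = grid, labels = labels,
      labelTable = priority, priority = priority)
}

#' Voxel count per label of an exclusive cube
#'
#' @param cube an [ExclusiveVOICube-class].
#' @return named integer vector of voxel counts.
#' @export
labelCounts <- function(cube) {
  tab <- tabulate(cube@labels, nbins = length(cube@labelTable))
  names(tab) <- cube@labelTable
  tab
}

#' Extract one structure of an exclusive cube as a mask
#'
#' @param cube an [ExclusiveVOICube-class].
#' @param name structure name in the cube's label table.
#' @return A [VOIMask-class].
#' @export
cubeMask <- function(cube, name) {
  code <- match(name, cube@labelTable)
  if (is.na(code)) stop("no such label: ", name)
  voiMask(name, cube@grid, cube@labels == code, allowEmpty = TRUE)
}

setMethod("show", "DoseGrid", function(object) {
  cat("DoseGrid:", paste(object@dims, collapse = " x "), "voxels, spacing",
      paste(fmtNum(object@spacing, 2), collapse = "/"), "mm (LR/AP/SI)\n")
})

setMethod("show", "VOIMask", function(object) {
  cat(sprintf("VOIMask '%s': %d voxels (%.2f cm^3) on %s grid\n",
              object@name, sum(object@mask), maskVolume(object),
              paste(object@grid@dims, collapse = "x")))
})

setMethod("show", "ExclusiveVOICube", function(object) {
  cat("ExclusiveVOICube with labels:\n")
  print(labelCounts(object))
})
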