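# Hounsfield-unit tissue classification of the resampled CT and
# morphological regularisation of bone.

#' Hounsfield-unit thresholds
#'
#' Boundaries of the four-class tissue partition (air / fat / muscle / bone).
#' Intervals are half-open and lower-inclusive, so every HU value receives
#' exactly one label: air below `air_max`, fat in `[air_max, fat_max)`,
#' muscle in `[fat_max, muscle_max)`, bone at and above `muscle_max`.
#'
#' @param air_max Upper HU bound of air (default -200).
#' @param fat_max Upper HU bound of fat (default -20).
#' @param muscle_max Upper HU bound of muscle (default 150).
#' @return A list of class `sln_hu_thresholds`.
#' @export
hu_thresholds <- function(air_max = -200, fat_max = -20, muscle_max = 150) {
  if (!(air_max < fat_max && fat_max < muscle_max)) {
    stop("thresholds must satisfy air_max < fat_max < muscle_max",
         call. = FALSE)
  }
  structure(list(air_max = air_max, fat_max = fat_max,
                 muscle_max = muscle_max), class = "sln_hu_thresholds")
}

#' Tissue labels
#'
#' Integer codes of the tissue classes; the display colours mirror the
#' conventional rendering (air = black, fat = yellow, muscle = red,
#' bone = white).
#' @format Named integer vector.
#' @export
TISSUE_LABELS <- c(air = 0L, fat = 1L, muscle = 2L, bone = 3L)

#' Classify CT voxels into tissue types
#'
#' Total, deterministic partition of the CT volume into air (0), fat (1),
#' muscle (2) and bone (3) by Hounsfield thresholds.  Monotone: raising a
#' voxel's HU never lowers its label.
#'
#' @param ct A CT [sln_volume()] in Hounsfield units.
#' @param thresholds A [hu_thresholds()].
#' @return An object of class `sln_tissue_map`: list with `labels` (integer
#'   array aligned with the CT grid), `thresholds`, `spacing_mm`, `origin_mm`.
#' @export
classify_tissue <- function(ct, thresholds = hu_thresholds()) {
  stopifnot(inherits(ct, "sln_volume"))
  if (ct$modality != "CT") {
    stop("tissue classification applies to CT volumes", call. = FALSE)
  }
  if (!inherits(thresholds, "sln_hu_thresholds")) {
    thresholds <- do.call(hu_thresholds, thresholds)
  }
  cuts <- c(thresholds$air_max, thresholds$fat_max, thresholds$muscle_max)
  lab <- array(findInterval(ct$values, cuts), dim = dim(ct$values))
  storage.mode(lab) <- "integer"
  structure(list(labels = lab, thresholds = thresholds,
                 closing_radius_mm = NA_real_, spacing_mm = ct$spacing_mm,
                 origin_mm = ct$origin_mm), class = "sln_tissue_map")
}

#' @export
print.sln_tissue_map <- function(x, ...) {
  tab <- tabulate(as.vector(x$labels) + 1L, nbins = 4L)
  cat(sprintf("<sln_tissue_map> %s voxels: air %d, fat %d, muscle %d, bone %d\n",
              paste(dim(x$labels), collapse = "x"),
              tab[1], tab[2], tab[3], tab[4]))
  invisible(x)
}

# integer displacement triples of a ball of the given radius (in voxels,
# possibly anisotropic spacing)
ball_offsets <- function(radius_mm, spacing_mm) {
  r_vox <- floor(radius_mm / spacing_mm)
  g <- expand.grid(di = -r_vox[1]:r_vox[1], dj = -r_vox[2]:r_vox[2],
                   dk = -r_vox[3]:r_vox[3])
  d2 <- (g$di * spacing_mm[1])^2 + (g$dj * spacing_mm[2])^2 +
    (g$dk * spacing_mm[3])^2
  m <- as.matrix(g[d2 <= radius_mm^2, , drop = FALSE])
  storage.mode(m) <- "integer"
  m
}

#' Regularise bone by morphological closing
#'
#' Bone has no homogeneous structure on low-dose CT (trabecular gaps, marrow
#' read as soft tissue), so the binary bone mask is replaced by its
#' morphological closing (dilation then erosion with a ball structuring
#' element).  Voxels gained by the closing are relabelled bone; closing is
#' extensive, so no bone voxel is ever lost, and idempotent at fixed radius.
#'
#' @param m A [classify_tissue()] result.
#' @param radius_mm Ball radius in mm (default 3, enough to close trabecular
#'   gaps without bridging distinct bones).
#' @return The updated `sln_tissue_map`.
#' @export
close_bone <- function(m, radius_mm = 3) {
  stopifnot(inherits(m, "sln_tissue_map"))
  if (radius_mm < min(m$spacing_mm)) {
    sln_log("WARN", "closing radius ", radius_mm,
            " mm below voxel size; bone mask unchanged")
    m$closing_radius_mm <- radius_mm
    return(m)
  }
  dims <- dim(m$labels)
  bone <- as.vector(m$labels == TISSUE_LABELS[["bone"]])
  offs <- ball_offsets(radius_mm, m$spacing_mm)
  closed <- cpp_erode(cpp_dilate(bone, as.integer(dims), offs),
                      as.integer(dims), offs)
  gained <- closed & !bone
  m$labels[array(gained, dims)] <- TISSUE_LABELS[["bone"]]
  m$closing_radius_mm <- radius_mm
  sln_log("INFO", "bone closing (r = ", radius_mm, " mm): ",
          sum(gained), " voxels relabelled bone")
  m
}

#' Body mask
#'
#' The largest 26-connected non-air component with holes filled per axial
#' slice: interior air pockets (bowel gas and the like) count as inside the
#' body, the surrounding air does not.  Findings outside this mask cannot be
#' lymph nodes.
#'
#' @param m A [classify_tissue()] result.
#' @return Logical array aligned with the tissue map.
#' @export
body_mask <- function(m) {
  stopifnot(inherits(m, "sln_tissue_map"))
  dims <- dim(m$labels)
  nonair <- as.vector(m$labels != TISSUE_LABELS[["air"]])
  if (!any(nonair)) stop("no body found: tissue map is all air", call. = FALSE)
  labs <- cpp_label_components(nonair, as.integer(dims), 26L)
  largest <- which.max(tabulate(labs[labs > 0L]))
  mask <- labs == largest
  mask <- cpp_fill_holes_slices(mask, as.integer(dims))
  array(mask, dims)
}
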