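#' Construct a volume
#'
#' A `sln_volume` is the shared data model for both imaging modalities: a 3-D
#' scalar grid together with its voxel spacing, world origin and a modality
#' tag.  World coordinates follow `origin + index * spacing` with 0-based
#' voxel indices; axes are (x = left-right with patient-left at increasing x,
#' y = anterior-posterior, z = inferior-superior).  SPECT grids hold
#' reconstructed counts and are clamped to be non-negative on construction
#' (negative reconstruction artefacts carry no physical meaning); CT grids
#' hold Hounsfield units and may be negative.
#'
#' @param values Numeric 3-D array, at least 3 voxels along every axis.
#' @param spacing_mm Numeric length-3, all positive (mm per voxel).
#' @param origin_mm Numeric length-3 world position of voxel (0,0,0), in mm.
#' @param modality `"SPECT"` or `"CT"`.
#' @return An object of class `sln_volume`.
#' @export
#' @examples
#' v <- sln_volume(array(0, c(4, 4, 4)), spacing_mm = c(4, 4, 4),
#'                 modality = "SPECT")
#' dim(v$values)
sln_volume <- function(values, spacing_mm, origin_mm = c(0, 0, 0),
                       modality = c("SPECT", "CT")) {
  modality <- match.arg(modality)
  if (!is.array(values) || length(dim(values)) != 2L && length(dim(values)) != 3L) {
    stop("`values` must be a 3-D array", call. = FALSE)
  }
  if (length(dim(values)) != 3L) {
    stop(sprintf("volume must be 3-D, got %d dimensions", length(dim(values))),
         call. = FALSE)
  }
  if (any(dim(values) < 3L)) {
    stop("grid dimensions must be >= 3 in every axis", call. = FALSE)
  }
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0)) {
    stop("`spacing_mm` must be 3 positive finite numbers", call. = FALSE)
  }
  storage.mode(values) <- "double"
  if (modality == "SPECT" && any(values < 0)) {
    n_neg <- sum(values < 0)
    values[values < 0] <- 0
    sln_log("INFO", "clamped ", n_neg, " negative SPECT voxels to 0")
  }
  structure(
    list(values = values, spacing_mm = spacing_mm,
         origin_mm = as.numeric(origin_mm), modality = modality),
    class = "sln_volume"
  )
}

#' @export
print.sln_volume <- function(x, ...) {
  cat(sprintf("<sln_volume %s> %s voxels @ %s mm, origin (%s), range [%g, %g]\n",
              x$modality, paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing_mm), collapse = "x"),
              paste(format(x$origin_mm), collapse = ", "),
              min(x$values), max(x$values)))
  invisible(x)
}

#' World coordinates of voxel indices
#'
#' @param v A [sln_volume()].
#' @param idx Integer matrix (n x 3) of 0-based voxel indices, or a length-3
#'   vector.
#' @return Numeric matrix (n x 3) of world positions in mm.
#' @export
voxel_to_world <- function(v, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  sweep(sweep(idx, 2, v$spacing_mm, `*`), 2, v$origin_mm, `+`)
}

#' Read a volume from a NIfTI file
#'
#' Reads a NIfTI-1 image (`.nii` / `.nii.gz`) and wraps it in the package's
#' volume model, taking voxel spacing and origin from the header.  SPECT
#' values are clamped to be non-negative.
#'
#' @param path Path to an existing NIfTI file.
#' @param modality `"SPECT"` or `"CT"`.
#' @return A [sln_volume()].
#' @export
load_volume <- function(path, modality = c("SPECT", "CT")) {
  modality <- match.arg(modality)
  if (!file.exists(path)) {
    stop(sprintf("cannot read volume: file '%s' does not exist", path),
         call. = FALSE)
  }
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop(sprintf(
                    "failed to parse '%s' as NIfTI: %s", path,
                    conditionMessage(e)), call. = FALSE))
  d <- dim(img)
  if (length(d) != 3L) {
    stop(sprintf("expected a 3-D image, '%s' has %d dimensions",
                 path, length(d)), call. = FALSE)
  }
  sp <- RNifti::pixdim(img)
  if (length(sp) < 3L || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0)) {
    stop(sprintf("missing or invalid spacing metadata (pixdim) in '%s'", path),
         call. = FALSE)
  }
  xf <- RNifti::xform(img)
  org <- if (attr(xf, "code") > 0) as.numeric(xf[1:3, 4]) else c(0, 0, 0)
  vals <- array(as.numeric(img), dim = d)
  sln_log("INFO", "loaded ", modality, " volume ", paste(d, collapse = "x"),
          " @ ", paste(format(sp[1:3]), collapse = "x"), " mm from ", path)
  sln_volume(vals, spacing_mm = sp[1:3], origin_mm = org, modality = modality)
}

#' Write a volume to a NIfTI file
#'
#' @param v A [sln_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "sln_volume"))
  img <- RNifti::asNifti(v$values)
  RNifti::pixdim(img) <- v$spacing_mm
  m <- diag(c(v$spacing_mm, 1))
  m[1:3, 4] <- v$origin_mm
  img <- RNifti::`qform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Resampling specification
#'
#' @param target_spacing_mm Length-3 positive target spacing (default 1 mm
#'   isotropic, the common analysis grid).
#' @param interpolation_order 0 (nearest, used for label grids), 1 (linear)
#'   or 3 (cubic spline, the default for both modalities).
#' @return A list of class `sln_resample_spec`.
#' @export
resample_spec <- function(target_spacing_mm = c(1, 1, 1),
                          interpolation_order = 3L) {
  target_spacing_mm <- as.numeric(target_spacing_mm)
  if (length(target_spacing_mm) != 3L || any(target_spacing_mm <= 0)) {
    stop("`target_spacing_mm` must be 3 positive numbers", call. = FALSE)
  }
  if (!interpolation_order %in% c(0L, 1L, 3L)) {
    stop("`interpolation_order` must be 0, 1 or 3", call. = FALSE)
  }
  structure(list(target_spacing_mm = target_spacing_mm,
                 interpolation_order = as.integer(interpolation_order)),
            class = "sln_resample_spec")
}

#' Resample a volume to a target grid
#'
#' Both modalities are brought to a common grid (1 mm isotropic by default)
#' so that SPECT and CT can be analysed voxel-by-voxel.  Interpolation is a
#' separable cubic interpolating spline by default; the additional smoothing
#' this introduces is an accepted trade-off of the workflow.  SPECT output is
#' clamped to be non-negative (cubic interpolation can undershoot near sharp
#' edges).  The physical extent is preserved to within one output voxel and
#' the world origin is kept, so world coordinates are comparable before and
#' after.
#'
#' @param v A [sln_volume()].
#' @param spec A [resample_spec()].
#' @return A [sln_volume()] at the target spacing.
#' @export
resample <- function(v, spec = resample_spec()) {
  stopifnot(inherits(v, "sln_volume"))
  if (!inherits(spec, "sln_resample_spec")) spec <- do.call(resample_spec, spec)
  din <- dim(v$values)
  extent <- din * v$spacing_mm
  dout <- pmax(3L, as.integer(round(extent / spec$target_spacing_mm)))
  if (any(extent < 3 * spec$target_spacing_mm)) {
    stop("degenerate extent: target spacing does not fit >= 3 voxels per axis",
         call. = FALSE)
  }
  scale <- spec$target_spacing_mm / v$spacing_mm  # output index -> input index
  out <- cpp_resample3d(as.numeric(v$values), as.integer(din),
                        as.integer(dout), as.numeric(scale), rep(0, 3),
                        spec$interpolation_order)
  out <- array(out, dim = dout)
  if (v$modality == "SPECT") out[out < 0] <- 0
  sln_log("INFO", "resampled ", v$modality, " ",
          paste(din, collapse = "x"), " @ ",
          paste(format(v$spacing_mm), collapse = "x"), " mm -> ",
          paste(dout, collapse = "x"), " @ ",
          paste(format(spec$target_spacing_mm), collapse = "x"),
          " mm (order ", spec$interpolation_order, ")")
  sln_volume(out, spacing_mm = spec$target_spacing_mm,
             origin_mm = v$origin_mm, modality = v$modality)
}

#' Resample a volume onto the grid of a reference volume
#'
#' Brings `v` onto exactly the grid (dimensions, spacing, origin) of `ref`,
#' interpolating in world coordinates.  Used to put the resampled CT and
#' SPECT on one common lattice when their native grids cover slightly
#' different extents.
#'
#' @param v A [sln_volume()] to resample.
#' @param ref The reference [sln_volume()] supplying the target grid.
#' @param interpolation_order 0, 1 or 3 (default 3).
#' @return A [sln_volume()] with `ref`'s geometry and `v`'s modality.
#' @export
resample_to_reference <- function(v, ref, interpolation_order = 3L) {
  stopifnot(inherits(v, "sln_volume"), inherits(ref, "sln_volume"))
  dout <- dim(ref$values)
  scale <- ref$spacing_mm / v$spacing_mm
  offset <- (ref$origin_mm - v$origin_mm) / v$spacing_mm
  out <- cpp_resample3d(as.numeric(v$values), as.integer(dim(v$values)),
                        as.integer(dout), as.numeric(scale),
                        as.numeric(offset), as.integer(interpolation_order))
  out <- array(out, dim = dout)
  if (v$modality == "SPECT") out[out < 0] <- 0
  sln_volume(out, spacing_mm = ref$spacing_mm, origin_mm = ref$origin_mm,
             modality = v$modality)
}

#' Background-suppression threshold
#'
#' Semi-quantitative removal of diffuse background from the emission data:
#' every voxel below `fraction` of a reference value is set to zero.
#' Reconstructed counts are not calibrated to injected megabecquerels, so the
#' reference is semi-quantitative: by default the global maximum voxel value
#' (preserves faint true nodes while removing diffuse noise); a total-counts
#' reference is selectable.
#'
#' @param fraction Fraction in (0, 1); default 0.01 (the 1 % rule).
#' @param reference `"global_max"` (default) or `"total_counts"`.
#' @return A list of class `sln_background_threshold`.
#' @export
background_threshold <- function(fraction = 0.01,
                                 reference = c("global_max", "total_counts")) {
  reference <- match.arg(reference)
  fraction <- as.numeric(fraction)
  if (length(fraction) != 1L || !is.finite(fraction) || fraction <= 0 ||
      fraction >= 1) {
    stop("`fraction` must be a single number in (0, 1)", call. = FALSE)
  }
  structure(list(fraction = fraction, reference = reference),
            class = "sln_background_threshold")
}

#' Suppress SPECT background
#'
#' Sets every voxel with value below `fraction * reference` to zero and
#' leaves all other voxels unchanged.  Idempotent; never zeroes the global
#' maximum.  An all-zero volume is returned unchanged with a warning log
#' entry.
#'
#' @param v A SPECT [sln_volume()].
#' @param threshold A [background_threshold()].
#' @return The thresholded [sln_volume()].
#' @export
suppress_background <- function(v, threshold = background_threshold()) {
  stopifnot(inherits(v, "sln_volume"))
  if (v$modality != "SPECT") {
    stop("background suppression applies to SPECT volumes only", call. = FALSE)
  }
  if (!inherits(threshold, "sln_background_threshold")) {
    threshold <- do.call(background_threshold, threshold)
  }
  ref <- switch(threshold$reference,
                global_max = max(v$values),
                total_counts = sum(v$values))
  if (ref <= 0) {
    sln_log("WARN", "all-zero SPECT volume: background suppression skipped")
    return(v)
  }
  cut <- threshold$fraction * ref
  n_cut <- sum(v$values < cut & v$values > 0)
  v$values[v$values < cut] <- 0
  sln_log("INFO", "background suppression: reference ", threshold$reference,
          " = ", format(ref), ", cutoff ", format(cut), ", zeroed ", n_cut,
          " voxels")
  v
}
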