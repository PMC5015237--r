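# Deterministic digital phantom: paired SPECT/CT volumes with ground truth.
#
# The phantom emulates the statistical structure the detector assumes: a
# body of air/fat/muscle/bone compartments on CT; on SPECT a dominant
# extended injection depot plus small tracer-avid nodes, blurred by the
# system PSF, with optional Poisson counting noise.  It does not model
# attenuation, scatter or tomographic reconstruction.

#' Phantom specification
#'
#' All geometry is in mm on a 1 mm isotropic grid.  The default body is an
#' ellipsoid (semi-axes 42 x 34 x 60) with a 10 mm subcutaneous fat shell
#' and a muscle interior; a spine-like posterior cylinder and two femur-like
#' inferior cylinders stand in for the pelvis; an interior air sphere plays
#' bowel gas.  The injection depot is an extended sphere (radius 10 mm,
#' emulating an intradermal peritumoral depot) holding `injection_activity`
#' counts; nodes are 4 mm-radius spheres holding the given fractions of the
#' injection activity (sentinel nodes carry on the order of 0.1-2 % of the
#' depot).  A single seed fixes all randomness; independent sub-streams are
#' drawn per component (node placement, CT noise, Poisson noise, in that
#' order) so switching one component off does not perturb the others.
#'
#' @param grid_shape Integer length-3 (default `c(96, 96, 128)`).
#' @param body_semiaxes_mm Ellipsoid semi-axes (default `c(42, 34, 60)`).
#' @param fat_shell_mm Thickness of the subcutaneous fat shell (default 10).
#' @param bone_structures List of structures; each a list with `type`
#'   (`"cylinder_z"` or `"sphere"`), `center` (mm), `radius` (mm) and for
#'   cylinders `z_range`.  Default: spine + two femora.
#' @param air_pockets List of spheres (`center`, `radius`) painted as air
#'   inside the body.  Default: one bowel-gas sphere.
#' @param n_nodes Number of true nodes (default 3).
#' @param node_positions `"default"`, `"random"`, or an n x 3 matrix (mm).
#' @param node_activity_fractions Fractions of the injection activity per
#'   node, each in `[0.001, 0.02]` (default `c(0.01, 0.006, 0.003)`).
#' @param node_radius_mm Node sphere radius (default 4).
#' @param injection_position Depot centre (default `c(47.5, 34, 18)`,
#'   anterior-inferior midline).
#' @param injection_activity Total depot counts (default 1e6).
#' @param injection_radius_mm Depot radius (default 10).
#' @param psf_fwhm_mm System PSF full width at half maximum (default 8).
#' @param poisson_noise Draw Poisson counts after blurring (default FALSE).
#' @param ct_noise_sd_hu Gaussian HU noise s.d. (default 20).
#' @param decoys `"default"` (one bone-embedded, one extracorporal, one
#'   air-adjacent), `"none"`, or a data frame with columns `type`, `x_mm`,
#'   `y_mm`, `z_mm`, `fraction`.
#' @param landmark_plane_z_mm Inguinal/secondary boundary (default 64).
#' @param min_separation_mm Minimum pairwise node separation for random
#'   placement (default 26).
#' @param seed Integer master seed (default 1).
#' @return A list of class `sln_phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 128),
                         body_semiaxes_mm = c(42, 34, 60),
                         fat_shell_mm = 10,
                         bone_structures = NULL,
                         air_pockets = NULL,
                         n_nodes = 3,
                         node_positions = "default",
                         node_activity_fractions = c(0.01, 0.006, 0.003),
                         node_radius_mm = 4,
                         injection_position = c(47.5, 34, 18),
                         injection_activity = 1e6,
                         injection_radius_mm = 10,
                         psf_fwhm_mm = 8,
                         poisson_noise = FALSE,
                         ct_noise_sd_hu = 20,
                         decoys = "default",
                         landmark_plane_z_mm = 64,
                         min_separation_mm = 26,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  center <- (grid_shape - 1) / 2
  center[3] <- 64
  if (is.null(bone_structures)) {
    bone_structures <- list(
      list(type = "cylinder_z", center = c(center[1], center[2] + 18.5),
           radius = 10, z_range = c(64, grid_shape[3] - 1)),  # spine
      list(type = "cylinder_z", center = c(center[1] - 22, center[2] + 10.5),
           radius = 8, z_range = c(0, 40)),                   # right femur
      list(type = "cylinder_z", center = c(center[1] + 22, center[2] + 10.5),
           radius = 8, z_range = c(0, 40)))                   # left femur
  }
  if (is.null(air_pockets)) {
    air_pockets <- list(list(center = c(center[1], center[2] - 7.5, 80),
                             radius = 8))
  }
  frs <- node_activity_fractions
  if (length(frs) == 1L) frs <- rep(frs, n_nodes)
  if (length(frs) != n_nodes) {
    stop("need one activity fraction per node", call. = FALSE)
  }
  if (any(frs < 0.001 - 1e-12) || any(frs > 0.02 + 1e-12)) {
    stop("node activity fractions must lie in [0.001, 0.02] ",
         "(injection must dominate every node)", call. = FALSE)
  }
  if (identical(decoys, "default")) {
    decoys <- data.frame(
      type = c("bone_embedded", "extracorporal", "air_adjacent"),
      x_mm = c(center[1], 10, center[1]),
      y_mm = c(center[2] + 18.5, 10, center[2] - 7.5),
      z_mm = c(90, 30, 75),
      fraction = 0.006)
  } else if (identical(decoys, "none")) {
    decoys <- data.frame(type = character(), x_mm = numeric(),
                         y_mm = numeric(), z_mm = numeric(),
                         fraction = numeric())
  }
  structure(list(
    grid_shape = grid_shape, body_center = c(center[1], center[2], 64),
    body_semiaxes_mm = body_semiaxes_mm, fat_shell_mm = fat_shell_mm,
    bone_structures = bone_structures, air_pockets = air_pockets,
    n_nodes = as.integer(n_nodes), node_positions = node_positions,
    node_activity_fractions = frs, node_radius_mm = node_radius_mm,
    injection_position = injection_position,
    injection_activity = injection_activity,
    injection_radius_mm = injection_radius_mm,
    psf_fwhm_mm = psf_fwhm_mm, poisson_noise = isTRUE(poisson_noise),
    ct_noise_sd_hu = ct_noise_sd_hu, decoys = decoys,
    landmark_plane_z_mm = landmark_plane_z_mm,
    min_separation_mm = min_separation_mm, seed = as.integer(seed)),
    class = "sln_phantom_spec")
}

# squared normalised ellipsoid radius of world points
ellipsoid_rho2 <- function(xyz, center, semi) {
  rowSums(sweep(sweep(xyz, 2, center), 2, semi, `/`)^2)
}

phantom_coords <- function(shape) {
  list(x = (0:(shape[1] - 1)), y = (0:(shape[2] - 1)), z = (0:(shape[3] - 1)))
}

# default fixed node layout: two inguinal groin nodes + one paraaortal node
phantom_default_nodes <- function(spec) {
  cen <- spec$body_center
  pos <- rbind(c(cen[1] + 22.5, cen[2] - 5.5, 40),
               c(cen[1] - 22.5, cen[2] - 5.5, 40),
               c(cen[1], cen[2] - 3.5, 100))
  pos[seq_len(min(spec$n_nodes, 3L)), , drop = FALSE]
}

# distance of points (n x 3) to every bone structure surface (>0 outside)
phantom_bone_clearance <- function(spec, xyz) {
  cl <- rep(Inf, nrow(xyz))
  for (b in spec$bone_structures) {
    if (b$type == "cylinder_z") {
      d_rad <- sqrt((xyz[, 1] - b$center[1])^2 +
                    (xyz[, 2] - b$center[2])^2) - b$radius
      dz <- pmax(b$z_range[1] - xyz[, 3], xyz[, 3] - b$z_range[2], 0)
      d <- pmax(d_rad, dz)
    } else {
      d <- sqrt(rowSums(sweep(xyz, 2, b$center)^2)) - b$radius
    }
    cl <- pmin(cl, d)
  }
  cl
}

phantom_sample_nodes <- function(spec, rng_seed) {
  set.seed(rng_seed)
  cen <- spec$body_center; semi <- spec$body_semiaxes_mm
  inj <- matrix(spec$injection_position, ncol = 3)
  anchors <- inj
  if (nrow(spec$decoys)) {
    anchors <- rbind(anchors,
                     as.matrix(spec$decoys[, c("x_mm", "y_mm", "z_mm")]))
  }
  # rejection sampling with whole-configuration restarts: a partial layout
  # can paint itself into a corner of the (narrow) feasible region, so when
  # a node finds no room the whole configuration is resampled
  for (attempt in 1:100) {
    out <- matrix(NA_real_, 0, 3)
    tries <- 0L
    while (nrow(out) < spec$n_nodes && tries < 3000L) {
      tries <- tries + 1L
      p <- matrix(c(runif(1, cen[1] - semi[1], cen[1] + semi[1]),
                    runif(1, cen[2] - semi[2], cen[2] + semi[2]),
                    runif(1, 20, spec$grid_shape[3] - 20)), ncol = 3)
      if (ellipsoid_rho2(p, cen, semi - spec$fat_shell_mm / 2) > 0.8^2) next
      if (phantom_bone_clearance(spec, p) < 12) next
      ap_ok <- all(vapply(spec$air_pockets, function(a) {
        sqrt(sum((p - a$center)^2)) >= a$radius + 12
      }, logical(1)))
      if (!ap_ok) next
      cand <- rbind(anchors, out)
      dmin <- min(sqrt(rowSums(sweep(cand, 2, as.numeric(p))^2)))
      if (dmin < max(spec$min_separation_mm, 32)) next
      out <- rbind(out, p)
    }
    if (nrow(out) == spec$n_nodes) return(out)
  }
  stop("could not place all nodes under the separation constraints",
       call. = FALSE)
}

#' Generate a SPECT/CT phantom pair with ground truth
#'
#' Paints the CT from the compartment geometry (air -1000 HU, fat -100,
#' muscle 40, bone 700, class centres chosen well inside the segmentation
#' intervals so HU noise rarely flips labels), adds Gaussian HU noise;
#' builds the SPECT by distributing the depot and node activities over their
#' spheres, convolving with the Gaussian PSF, and optionally drawing Poisson
#' counts.  Both volumes are on the same 1 mm grid with origin 0.  The same
#' seed gives byte-identical volumes.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `sln_phantom`: `ct` and `spect`
#'   ([sln_volume()]s) and `truth` (class `sln_phantom_truth`: `nodes` data
#'   frame with position, fraction, side, region, `is_decoy`, `decoy_type`;
#'   `injection_position`; `landmark_plane_z_mm`; `midline_x_mm`).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "sln_phantom_spec"))
  set.seed(spec$seed)
  subseeds <- sample.int(2147483646L, 4L)  # placement, ct, poisson, spare
  shape <- spec$grid_shape
  cen <- spec$body_center; semi <- spec$body_semiaxes_mm
  co <- phantom_coords(shape)
  n <- prod(shape)

  # world coordinates of all voxels, one axis at a time (kept as arrays)
  X <- array(co$x, shape)
  Y <- array(rep(co$y, each = shape[1]), shape)
  Z <- array(rep(co$z, each = shape[1] * shape[2]), shape)

  rho2_out <- ((X - cen[1]) / semi[1])^2 + ((Y - cen[2]) / semi[2])^2 +
    ((Z - cen[3]) / semi[3])^2
  inner <- semi - spec$fat_shell_mm
  rho2_in <- ((X - cen[1]) / inner[1])^2 + ((Y - cen[2]) / inner[2])^2 +
    ((Z - cen[3]) / inner[3])^2

  hu <- array(-1000, shape)
  hu[rho2_out <= 1] <- -100                      # fat shell
  hu[rho2_in <= 1] <- 40                         # muscle interior
  body <- rho2_out <= 1
  for (b in spec$bone_structures) {
    m <- if (b$type == "cylinder_z") {
      (X - b$center[1])^2 + (Y - b$center[2])^2 <= b$radius^2 &
        Z >= b$z_range[1] & Z <= b$z_range[2]
    } else {
      (X - b$center[1])^2 + (Y - b$center[2])^2 + (Z - b$center[3])^2 <=
        b$radius^2
    }
    hu[m & body] <- 700
  }
  for (a in spec$air_pockets) {
    m <- (X - a$center[1])^2 + (Y - a$center[2])^2 + (Z - a$center[3])^2 <=
      a$radius^2
    hu[m] <- -1000
  }

  # node layout
  pos <- if (identical(spec$node_positions, "default")) {
    phantom_default_nodes(spec)
  } else if (identical(spec$node_positions, "random")) {
    phantom_sample_nodes(spec, subseeds[1])
  } else {
    matrix(spec$node_positions, ncol = 3)
  }
  if (nrow(pos) != spec$n_nodes) {
    stop("node position count does not match n_nodes", call. = FALSE)
  }
  rho_nodes <- ellipsoid_rho2(pos, cen, semi)
  if (any(rho_nodes > 1)) {
    stop("node position outside the phantom body", call. = FALSE)
  }

  # SPECT: uniform activity over depot and node spheres, then PSF blur
  spect <- array(0, shape)
  paint_sphere <- function(vol, center, radius, total) {
    m <- (X - center[1])^2 + (Y - center[2])^2 + (Z - center[3])^2 <= radius^2
    nv <- sum(m)
    if (nv == 0L) stop("activity sphere misses the grid", call. = FALSE)
    vol[m] <- vol[m] + total / nv
    vol
  }
  spect <- paint_sphere(spect, spec$injection_position,
                        spec$injection_radius_mm, spec$injection_activity)
  for (i in seq_len(nrow(pos))) {
    spect <- paint_sphere(spect, pos[i, ], spec$node_radius_mm,
                          spec$node_activity_fractions[i] *
                            spec$injection_activity)
  }
  if (nrow(spec$decoys)) {
    for (i in seq_len(nrow(spec$decoys))) {
      spect <- paint_sphere(spect, as.numeric(
        spec$decoys[i, c("x_mm", "y_mm", "z_mm")]), spec$node_radius_mm,
        spec$decoys$fraction[i] * spec$injection_activity)
    }
  }
  # Counting noise arises in the acquired counts; the PSF (which includes
  # the reconstruction's Gaussian post-filter) acts on top of it, so the
  # emitted volume is smooth, like reconstructed emission data.
  if (spec$poisson_noise) {
    set.seed(subseeds[3])
    spect <- array(as.numeric(rpois(n, as.numeric(spect))), shape)
  }
  sigma <- spec$psf_fwhm_mm / (2 * sqrt(2 * log(2)))
  spect <- array(cpp_gaussian_blur(as.numeric(spect), as.integer(shape),
                                   rep(sigma, 3)), shape)

  if (spec$ct_noise_sd_hu > 0) {
    set.seed(subseeds[2])
    hu <- hu + array(rnorm(n, 0, spec$ct_noise_sd_hu), shape)
  }

  midline <- cen[1]
  mk_truth <- function(p, fr, is_decoy, type) {
    if (nrow(p) == 0L) {
      return(data.frame(x_mm = numeric(), y_mm = numeric(), z_mm = numeric(),
                        fraction = numeric(), side = character(),
                        region = character(), is_decoy = logical(),
                        decoy_type = character()))
    }
    data.frame(x_mm = p[, 1], y_mm = p[, 2], z_mm = p[, 3], fraction = fr,
               side = ifelse(p[, 1] > midline, "left", "right"),
               region = ifelse(p[, 3] < spec$landmark_plane_z_mm,
                               "inguinal", "secondary"),
               is_decoy = is_decoy, decoy_type = type)
  }
  truth_nodes <- mk_truth(pos, spec$node_activity_fractions, FALSE,
                          NA_character_)
  if (nrow(spec$decoys)) {
    truth_nodes <- rbind(truth_nodes, mk_truth(
      as.matrix(spec$decoys[, c("x_mm", "y_mm", "z_mm")]),
      spec$decoys$fraction, TRUE, spec$decoys$type))
  }
  truth <- structure(list(nodes = truth_nodes,
                          injection_position = spec$injection_position,
                          landmark_plane_z_mm = spec$landmark_plane_z_mm,
                          midline_x_mm = midline),
                     class = "sln_phantom_truth")
  structure(list(
    ct = sln_volume(hu, c(1, 1, 1), c(0, 0, 0), "CT"),
    spect = sln_volume(spect, c(1, 1, 1), c(0, 0, 0), "SPECT"),
    truth = truth, spec = spec), class = "sln_phantom")
}

#' @export
print.sln_phantom <- function(x, ...) {
  cat(sprintf("<sln_phantom> %s, %d nodes + %d decoys, seed %d\n",
              paste(x$spec$grid_shape, collapse = "x"), x$spec$n_nodes,
              sum(x$truth$nodes$is_decoy), x$spec$seed))
  invisible(x)
}

#' Degrade phantom volumes to native scanner spacing
#'
#' Block-averages the 1 mm phantom pair down to the native acquisition
#' grids: SPECT to 4 mm isotropic, CT to 1 x 1 x 5 mm, so the pipeline's
#' resampling step can be exercised end to end.  Trailing partial blocks are
#' averaged over the voxels available.  Block averaging conserves counts
#' (mean x block volume = sum), and the origin is shifted to the centre of
#' the first block so world coordinates stay comparable.
#'
#' @param ct,spect 1 mm [sln_volume()]s (e.g. from [generate_phantom()]).
#' @return A list with degraded `ct` and `spect` volumes.
#' @export
degrade_to_native <- function(ct, spect) {
  stopifnot(inherits(ct, "sln_volume"), inherits(spect, "sln_volume"))
  degrade <- function(v, block) {
    out <- cpp_block_average(as.numeric(v$values), as.integer(dim(v$values)),
                             as.integer(block))
    dims <- attr(out, "outdim")
    sln_volume(array(out, dims), spacing_mm = v$spacing_mm * block,
               origin_mm = v$origin_mm + (block - 1) / 2 * v$spacing_mm,
               modality = v$modality)
  }
  list(ct = degrade(ct, c(1, 1, 5)), spect = degrade(spect, c(4, 4, 4)))
}
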