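# Hot-spot segmentation of the emission volume: local-maximum seeding with a
# moving 3x3x3 mask, descent-only region growing over the 26-neighbourhood,
# and deletion of voxels claimed by more than one seed.

# 0-based (i,j,k) triples for 1-based linear indices, as an n x 3 matrix.
lin_to_ijk <- function(lin, dims) {
  lin0 <- lin - 1L
  cbind(lin0 %% dims[1],
        (lin0 %/% dims[1]) %% dims[2],
        lin0 %/% (dims[1] * dims[2]))
}

ijk_to_lin <- function(ijk, dims) {
  ijk <- matrix(as.integer(ijk), ncol = 3)
  1L + ijk[, 1] + dims[1] * (ijk[, 2] + dims[2] * ijk[, 3])
}

# Order 0-based index triples lexicographically by (x, y, z).
lex_order <- function(ijk) order(ijk[, 1], ijk[, 2], ijk[, 3])

#' Detect hot-spot seeds
#'
#' Scans the (background-suppressed) SPECT volume with a moving 3x3x3 mask
#' and returns every positive voxel whose value is greater than or equal to
#' all of its in-bounds 26 neighbours.  On a flat plateau of equal connected
#' values, exactly one seed is returned, at the lexicographically smallest
#' (x, y, z) index of the qualifying voxels in that plateau.  Seeds are
#' sorted by descending value, ties broken lexicographically.
#'
#' @param v A SPECT [sln_volume()], at least 3 voxels per axis.
#' @return A data frame with columns `i`, `j`, `k` (0-based voxel index),
#'   `lin` (1-based linear index into the array) and `value`.
#' @export
find_seeds <- function(v) {
  stopifnot(inherits(v, "sln_volume"))
  dims <- dim(v$values)
  qual <- cpp_local_max_mask(as.numeric(v$values), as.integer(dims))
  if (!any(qual)) return(data.frame(i = integer(), j = integer(),
                                    k = integer(), lin = integer(),
                                    value = numeric()))
  # Collapse plateaus: one seed per connected equal-valued component that
  # contains at least one qualifying voxel.
  vals <- as.numeric(v$values)
  keep <- logical(length(qual))
  todo <- which(qual)
  tv <- vals[todo]
  dup_vals <- unique(tv[duplicated(tv)])
  keep[todo[!tv %in% dup_vals]] <- TRUE
  for (x in dup_vals) {
    plateau <- vals == x
    labs <- cpp_label_components(plateau, as.integer(dims), 26L)
    q_here <- todo[tv == x]
    for (lb in unique(labs[q_here])) {
      members <- q_here[labs[q_here] == lb]
      ijk <- lin_to_ijk(members, dims)
      keep[members[lex_order(ijk)[1]]] <- TRUE
    }
  }
  lin <- which(keep)
  ijk <- lin_to_ijk(lin, dims)
  value <- vals[lin]
  # descending value, ties lexicographic on (x, y, z)
  o <- order(-value, ijk[, 1], ijk[, 2], ijk[, 3])
  data.frame(i = ijk[o, 1], j = ijk[o, 2], k = ijk[o, 3],
             lin = lin[o], value = value[o])
}

#' Grow one hot-spot region from a seed
#'
#' Breadth-first descent from the seed over 26-connectivity: a neighbour `n`
#' of an accepted voxel `c` is accepted iff `value(n) <= value(c)` and
#' `value(n) > 0`.  A voxel rejected from one parent may be accepted later
#' from another, so the claim set equals the set of voxels reachable from the
#' seed by a non-increasing positive path.  Growth is independent of any
#' other seed.
#'
#' @param v A SPECT [sln_volume()].
#' @param seed_lin 1-based linear index of a seed voxel (positive value).
#' @return Integer vector of 1-based linear indices of the claim set
#'   (includes the seed).
#' @export
grow_region <- function(v, seed_lin) {
  stopifnot(inherits(v, "sln_volume"))
  seed_lin <- as.integer(seed_lin)
  if (v$values[seed_lin] <= 0) {
    stop("seed value must be positive", call. = FALSE)
  }
  cpp_grow_region(as.numeric(v$values), as.integer(dim(v$values)), seed_lin)
}

#' Segment all hot spots
#'
#' Runs [find_seeds()], grows every seed's claim set independently, deletes
#' every voxel claimed by two or more seeds ("common voxels") from all claim
#' sets, and assembles the surviving regions.  Hot spots whose claim set
#' becomes empty or loses its own seed are discarded (logged).  The resulting
#' regions are pairwise disjoint by construction; labels are assigned in
#' descending peak order starting at 1.
#'
#' @param v A background-suppressed SPECT [sln_volume()].
#' @return An object of class `sln_hotspots`: a list with
#'   \describe{
#'     \item{spots}{data frame with one row per hot spot: `label`, seed index
#'       columns `seed_i/j/k`, `seed_lin`, `peak_value`, `total_counts`,
#'       `n_voxels`, `volume_mm3`, counts-weighted `centroid_x/y/z_mm`, and
#'       `common_voxels_removed`.}
#'     \item{voxels}{list (by label) of 1-based linear indices of member
#'       voxels.}
#'     \item{label_map}{integer array of the volume's shape, 0 where no hot
#'       spot.}
#'     \item{n_common}{total number of deleted common voxels.}
#'     \item{adjacent_pairs}{number of residual 26-adjacent voxel pairs
#'       between distinct hot spots (regions are disjoint, not necessarily
#'       non-adjacent; reported rather than eroded further).}
#'   }
#' @export
segment_hotspots <- function(v) {
  stopifnot(inherits(v, "sln_volume"))
  dims <- dim(v$values)
  seeds <- find_seeds(v)
  empty <- function() {
    structure(list(
      spots = data.frame(label = integer(), seed_i = integer(),
                         seed_j = integer(), seed_k = integer(),
                         seed_lin = integer(), peak_value = numeric(),
                         total_counts = numeric(), n_voxels = integer(),
                         volume_mm3 = numeric(), centroid_x_mm = numeric(),
                         centroid_y_mm = numeric(), centroid_z_mm = numeric(),
                         common_voxels_removed = integer()),
      voxels = list(), label_map = array(0L, dims), n_common = 0L,
      adjacent_pairs = 0L, spacing_mm = v$spacing_mm,
      origin_mm = v$origin_mm, global_max = max(v$values),
      total_volume_counts = sum(v$values)), class = "sln_hotspots")
  }
  if (nrow(seeds) == 0L) return(empty())

  claims <- lapply(seeds$lin, function(s) cpp_grow_region(
    as.numeric(v$values), as.integer(dims), s))
  claim_count <- integer(prod(dims))
  for (cl in claims) claim_count[cl] <- claim_count[cl] + 1L
  common <- claim_count >= 2L
  n_common <- sum(common)
  if (n_common > 0) {
    sln_log("INFO", "deleting ", n_common, " common voxels shared by >= 2 regions")
  }

  spots <- list(); voxels <- list(); label_map <- array(0L, dims)
  lab <- 0L
  for (s in seq_len(nrow(seeds))) {
    mem <- claims[[s]]
    removed <- sum(common[mem])
    mem <- mem[!common[mem]]
    if (length(mem) == 0L || !(seeds$lin[s] %in% mem)) {
      sln_log("INFO", "discarding hot spot at seed (",
              paste(unlist(seeds[s, c("i", "j", "k")]), collapse = ","),
              "): claim set ", if (length(mem) == 0L) "empty"
              else "lost its seed", " after common-voxel deletion")
      next
    }
    lab <- lab + 1L
    ijk <- lin_to_ijk(mem, dims)
    w <- v$values[mem]
    cen <- colSums(ijk * w) / sum(w) * v$spacing_mm + v$origin_mm
    spots[[lab]] <- data.frame(
      label = lab, seed_i = seeds$i[s], seed_j = seeds$j[s],
      seed_k = seeds$k[s], seed_lin = seeds$lin[s],
      peak_value = seeds$value[s], total_counts = sum(w),
      n_voxels = length(mem), volume_mm3 = length(mem) * prod(v$spacing_mm),
      centroid_x_mm = cen[1], centroid_y_mm = cen[2], centroid_z_mm = cen[3],
      common_voxels_removed = removed)
    voxels[[lab]] <- mem
    label_map[mem] <- lab
  }
  if (lab == 0L) return(empty())
  spots <- do.call(rbind, spots)

  # residual adjacency between distinct labels (26-connectivity)
  adj <- 0L
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  nz <- which(label_map > 0L)
  if (length(nz) > 0 && lab > 1L) {
    ijk <- lin_to_ijk(nz, dims)
    for (r in seq_len(nrow(offs))) {
      nb <- sweep(ijk, 2, offs[r, ], `+`)
      ok <- nb[, 1] >= 0 & nb[, 2] >= 0 & nb[, 3] >= 0 &
        nb[, 1] < dims[1] & nb[, 2] < dims[2] & nb[, 3] < dims[3]
      if (!any(ok)) next
      nl <- ijk_to_lin(nb[ok, , drop = FALSE], dims)
      lm <- label_map[nl]
      adj <- adj + sum(lm > 0L & lm != label_map[nz[ok]])
    }
    adj <- adj %/% 2L  # each unordered pair seen twice
  }
  if (adj > 0) {
    sln_log("INFO", "residual adjacency: ", adj,
            " voxel pairs of distinct hot spots touch (not eroded)")
  }
  structure(list(spots = spots, voxels = voxels, label_map = label_map,
                 n_common = n_common, adjacent_pairs = adj,
                 spacing_mm = v$spacing_mm, origin_mm = v$origin_mm,
                 global_max = max(v$values),
                 total_volume_counts = sum(v$values)),
            class = "sln_hotspots")
}

#' @export
print.sln_hotspots <- function(x, ...) {
  cat(sprintf("<sln_hotspots> %d hot spots, %d common voxels deleted\n",
              nrow(x$spots), x$n_common))
  if (nrow(x$spots)) print(head(x$spots[, c("label", "peak_value",
                                            "total_counts", "n_voxels")], 10))
  invisible(x)
}

#' Export hot spots as JSON
#'
#' One record per hot spot: label, 0-based seed index, peak value, total
#' counts, centroid in mm and voxel count.
#'
#' @param hs An [segment_hotspots()] result.
#' @param path Optional output path; if `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
hotspots_to_json <- function(hs, path = NULL) {
  stopifnot(inherits(hs, "sln_hotspots"))
  recs <- lapply(seq_len(nrow(hs$spots)), function(r) {
    s <- hs$spots[r, ]
    list(label = s$label, seed = c(s$seed_i, s$seed_j, s$seed_k),
         peak_value = s$peak_value, total_counts = s$total_counts,
         centroid_mm = c(s$centroid_x_mm, s$centroid_y_mm, s$centroid_z_mm),
         n_voxels = s$n_voxels)
  })
  js <- jsonlite::toJSON(recs, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
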