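# Rule-based classification of segmented hot spots into "true" (candidate
# sentinel lymph node) and "false" findings from combined SPECT and CT
# features, with side / drainage-region assignment and probability-ranked
# output lists.

#' Classifier configuration
#'
#' Anatomically motivated hard criteria plus the two-term probability score.
#' A lymph node cannot lie outside the body, inside bone, or in air; it is
#' embedded in fatty and connective tissue, so the tissue composition of a
#' thin shell around each hot spot carries the CT evidence.  CT values
#' *inside* hot spots are deliberately not used: at low-dose CT resolution
#' the lymphatic tissue itself is not resolvable, so only the vicinity is
#' informative.
#'
#' @param shell_thickness_mm Thickness of the surrounding shell (default 2).
#' @param min_soft_tissue_fraction Minimum fat+muscle fraction of the shell
#'   for a true finding (default 0.5).
#' @param max_bone_fraction Maximum bone fraction of the shell (default 0.3).
#' @param max_air_fraction Maximum air fraction of the shell (default 0.3).
#' @param injection_site_mode `"auto_max_activity"` (flag the hot spot with
#'   maximal total counts) or `"given_coordinate"` (flag every spot within
#'   `injection_exclusion_radius_mm` of `injection_coordinate_mm`).
#' @param injection_exclusion_radius_mm Radius for coordinate mode
#'   (default 30).
#' @param injection_coordinate_mm World coordinate of the injection site
#'   (required in coordinate mode).
#' @param min_volume_mm3 Minimum hot-spot volume (default 8).
#' @param weight_spect,weight_ct Non-negative weights of the SPECT term
#'   (normalised peak) and CT term (shell soft-tissue fraction) of the
#'   probability score; must sum to 1 (defaults 0.5 / 0.5).
#' @param landmark_plane_z_mm Axial plane separating the inguinal territory
#'   (below, i.e. smaller z) from the secondary (parailiac / paraaortal)
#'   territory.
#' @param midline_x_mm Midline x coordinate, or `"auto"` to use the body-mask
#'   centroid.
#' @return A list of class `sln_classifier_config`.
#' @export
classifier_config <- function(shell_thickness_mm = 2,
                              min_soft_tissue_fraction = 0.5,
                              max_bone_fraction = 0.3,
                              max_air_fraction = 0.3,
                              injection_site_mode = c("auto_max_activity",
                                                      "given_coordinate"),
                              injection_exclusion_radius_mm = 30,
                              injection_coordinate_mm = NULL,
                              min_volume_mm3 = 8,
                              weight_spect = 0.5, weight_ct = 0.5,
                              landmark_plane_z_mm = 64,
                              midline_x_mm = "auto") {
  injection_site_mode <- match.arg(injection_site_mode)
  fr <- c(min_soft_tissue_fraction, max_bone_fraction, max_air_fraction)
  if (any(fr < 0) || any(fr > 1)) {
    stop("tissue fractions must lie in [0, 1]", call. = FALSE)
  }
  if (weight_spect < 0 || weight_ct < 0 ||
      abs(weight_spect + weight_ct - 1) > 1e-8) {
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  }
  if (injection_site_mode == "given_coordinate" &&
      is.null(injection_coordinate_mm)) {
    stop("injection_site_mode = 'given_coordinate' requires ",
         "`injection_coordinate_mm`", call. = FALSE)
  }
  structure(list(
    shell_thickness_mm = shell_thickness_mm,
    min_soft_tissue_fraction = min_soft_tissue_fraction,
    max_bone_fraction = max_bone_fraction,
    max_air_fraction = max_air_fraction,
    injection_site_mode = injection_site_mode,
    injection_exclusion_radius_mm = injection_exclusion_radius_mm,
    injection_coordinate_mm = injection_coordinate_mm,
    min_volume_mm3 = min_volume_mm3,
    weight_spect = weight_spect, weight_ct = weight_ct,
    landmark_plane_z_mm = landmark_plane_z_mm,
    midline_x_mm = midline_x_mm), class = "sln_classifier_config")
}

#' Tissue-context features of one hot spot
#'
#' Computes, for a single hot spot, the tissue composition of the shell
#' obtained by dilating the member voxels by `shell_thickness_mm` and
#' removing the members themselves; the inside-body fraction of the member
#' voxels; the volume; the peak value normalised by the volume's global
#' maximum; and the fraction of total volume counts.
#'
#' @param hs A [segment_hotspots()] result.
#' @param label Hot-spot label to analyse.
#' @param tissue A [classify_tissue()] result on the same grid.
#' @param body A [body_mask()] array on the same grid.
#' @param cfg A [classifier_config()] (shell thickness is taken from it).
#' @return Named list: `shell_air`, `shell_fat`, `shell_muscle`,
#'   `shell_bone` (fractions summing to 1), `inside_body`, `volume_mm3`,
#'   `norm_peak`, `counts_fraction`, `n_shell`.
#' @export
extract_features <- function(hs, label, tissue, body,
                             cfg = classifier_config()) {
  stopifnot(inherits(hs, "sln_hotspots"), inherits(tissue, "sln_tissue_map"))
  dims <- dim(tissue$labels)
  if (!identical(as.integer(dims), as.integer(dim(hs$label_map)))) {
    stop("hot spots and tissue map must share one grid", call. = FALSE)
  }
  mem <- hs$voxels[[label]]
  ijk <- lin_to_ijk(mem, dims)
  # dilate within a padded bounding box only
  r_vox <- ceiling(cfg$shell_thickness_mm / hs$spacing_mm)
  lo <- pmax(apply(ijk, 2, min) - r_vox, 0)
  hi <- pmin(apply(ijk, 2, max) + r_vox, dims - 1)
  bdim <- hi - lo + 1
  sub <- logical(prod(bdim))
  rel <- sweep(ijk, 2, lo, `-`)
  sub[1 + rel[, 1] + bdim[1] * (rel[, 2] + bdim[2] * rel[, 3])] <- TRUE
  offs <- ball_offsets(cfg$shell_thickness_mm, hs$spacing_mm)
  dil <- cpp_dilate(sub, as.integer(bdim), offs)
  shell_rel <- which(dil & !sub)
  if (length(shell_rel) == 0L) {
    stop("empty shell: hot spot fills the grid", call. = FALSE)
  }
  srel0 <- shell_rel - 1L
  sijk <- cbind(srel0 %% bdim[1], (srel0 %/% bdim[1]) %% bdim[2],
                srel0 %/% (bdim[1] * bdim[2]))
  sijk <- sweep(sijk, 2, lo, `+`)
  shell_lin <- ijk_to_lin(sijk, dims)
  slab <- tissue$labels[shell_lin]
  tab <- tabulate(slab + 1L, nbins = 4L) / length(slab)
  feat <- list(shell_air = tab[1], shell_fat = tab[2], shell_muscle = tab[3],
               shell_bone = tab[4], inside_body = mean(body[mem]),
               volume_mm3 = length(mem) * prod(hs$spacing_mm),
               norm_peak = hs$spots$peak_value[hs$spots$label == label] /
                 hs$global_max,
               counts_fraction = hs$spots$total_counts[hs$spots$label == label] /
                 hs$total_volume_counts,
               n_shell = length(shell_lin))
  feat
}

#' Detect the injection site among hot spots
#'
#' The peritumoral tracer depot dominates uptake and must never appear in
#' the candidate list.  In `auto_max_activity` mode the hot spot with the
#' maximal total counts is flagged (ties go to the lower label, i.e. the
#' higher peak, and are logged); in `given_coordinate` mode every hot spot
#' whose centroid lies within the exclusion radius of the supplied
#' coordinate is flagged.
#'
#' @param hs A [segment_hotspots()] result.
#' @param cfg A [classifier_config()].
#' @return Integer vector of flagged labels (length 0 if no spots).
#' @export
detect_injection_site <- function(hs, cfg = classifier_config()) {
  stopifnot(inherits(hs, "sln_hotspots"))
  if (nrow(hs$spots) == 0L) return(integer())
  if (cfg$injection_site_mode == "auto_max_activity") {
    tc <- hs$spots$total_counts
    top <- which(tc == max(tc))
    if (length(top) > 1L) {
      sln_log("INFO", "injection-site tie on total counts; choosing label ",
              hs$spots$label[min(top)])
    }
    return(hs$spots$label[min(top)])
  }
  if (is.null(cfg$injection_coordinate_mm)) {
    stop("injection_site_mode = 'given_coordinate' requires a coordinate",
         call. = FALSE)
  }
  cen <- as.matrix(hs$spots[, c("centroid_x_mm", "centroid_y_mm",
                                "centroid_z_mm")])
  d <- sqrt(rowSums(sweep(cen, 2, cfg$injection_coordinate_mm)^2))
  hs$spots$label[d <= cfg$injection_exclusion_radius_mm]
}

#' Classify hot spots into true and false findings
#'
#' A hot spot is a `true_finding` only if all hard criteria hold: it is not
#' the injection site; at least half its voxels lie inside the body; the
#' shell soft-tissue (fat + muscle) fraction is at least
#' `min_soft_tissue_fraction`; the shell bone and air fractions do not
#' exceed their maxima; and its volume reaches `min_volume_mm3`.  The
#' probability score combines the SPECT evidence (peak value normalised by
#' the global maximum) and the CT evidence (shell soft-tissue fraction):
#' `p = w_spect * norm_peak + w_ct * soft_fraction`, clipped to `[0, 1]`.
#' Every hot spot receives a verdict; none is dropped.
#'
#' @param hs A [segment_hotspots()] result.
#' @param tissue A [classify_tissue()] result on the same grid.
#' @param body A [body_mask()] array.
#' @param cfg A [classifier_config()].
#' @return An `sln_findings` data frame: one row per hot spot with `label`,
#'   `verdict`, `probability`, `side`, `region`, the feature columns and a
#'   semicolon-joined `reasons` string of failed rules.
#' @export
classify_findings <- function(hs, tissue, body, cfg = classifier_config()) {
  stopifnot(inherits(hs, "sln_hotspots"))
  inj <- detect_injection_site(hs, cfg)
  n <- nrow(hs$spots)
  rows <- vector("list", n)
  for (r in seq_len(n)) {
    lb <- hs$spots$label[r]
    f <- extract_features(hs, lb, tissue, body, cfg)
    soft <- f$shell_fat + f$shell_muscle
    reasons <- character()
    if (lb %in% inj) reasons <- c(reasons, "injection_site")
    if (f$inside_body < 0.5) reasons <- c(reasons, "extracorporal")
    if (soft < cfg$min_soft_tissue_fraction) {
      reasons <- c(reasons, "low_soft_tissue")
    }
    if (f$shell_bone > cfg$max_bone_fraction) reasons <- c(reasons, "in_bone")
    if (f$shell_air > cfg$max_air_fraction) reasons <- c(reasons, "in_air")
    if (f$volume_mm3 < cfg$min_volume_mm3) reasons <- c(reasons, "too_small")
    prob <- cfg$weight_spect * f$norm_peak + cfg$weight_ct * soft
    prob <- min(1, max(0, prob))
    rows[[r]] <- data.frame(
      label = lb, verdict = if (length(reasons)) "false_finding"
      else "true_finding",
      probability = prob, side = NA_character_, region = NA_character_,
      peak_value = hs$spots$peak_value[r],
      total_counts = hs$spots$total_counts[r],
      centroid_x_mm = hs$spots$centroid_x_mm[r],
      centroid_y_mm = hs$spots$centroid_y_mm[r],
      centroid_z_mm = hs$spots$centroid_z_mm[r],
      shell_air = f$shell_air, shell_fat = f$shell_fat,
      shell_muscle = f$shell_muscle, shell_bone = f$shell_bone,
      inside_body = f$inside_body, volume_mm3 = f$volume_mm3,
      norm_peak = f$norm_peak, counts_fraction = f$counts_fraction,
      reasons = paste(reasons, collapse = ";"))
  }
  out <- if (n) do.call(rbind, rows) else data.frame()
  class(out) <- c("sln_findings", "data.frame")
  out
}

#' Assign side and drainage region
#'
#' Side is `left` iff the centroid x exceeds the midline (patient-left at
#' increasing x); an exact tie goes to `right` and is logged.  Region is
#' `inguinal` iff the centroid z lies below the landmark plane, else
#' `secondary` (parailiac / paraaortal).  The automatic midline is the
#' body-mask centroid x in world coordinates.
#'
#' @param findings An `sln_findings` frame from [classify_findings()].
#' @param body A [body_mask()] array (used for the automatic midline).
#' @param cfg A [classifier_config()].
#' @param spacing_mm,origin_mm Grid geometry of `body` (defaults 1 mm / 0).
#' @return The findings with `side` and `region` filled in.
#' @export
assign_side_region <- function(findings, body, cfg = classifier_config(),
                               spacing_mm = c(1, 1, 1),
                               origin_mm = c(0, 0, 0)) {
  if (nrow(findings) == 0L) return(findings)
  midline <- cfg$midline_x_mm
  if (identical(midline, "auto")) {
    ijk <- lin_to_ijk(which(body), dim(body))
    midline <- mean(ijk[, 1]) * spacing_mm[1] + origin_mm[1]
    sln_log("INFO", "auto midline x = ", format(midline), " mm")
  }
  ties <- findings$centroid_x_mm == midline
  if (any(ties)) {
    sln_log("INFO", sum(ties), " centroid(s) exactly on the midline: ",
            "assigned right")
  }
  findings$side <- ifelse(findings$centroid_x_mm > midline, "left", "right")
  findings$region <- ifelse(findings$centroid_z_mm < cfg$landmark_plane_z_mm,
                            "inguinal", "secondary")
  findings
}

#' Rank findings into the true and false lists
#'
#' The true list is sorted by descending probability (best candidate first);
#' the false list by ascending probability (most confidently false first).
#' Ties break by descending peak value, then by label.  Every finding
#' appears in exactly one list.
#'
#' @param findings An `sln_findings` frame.
#' @return A list of class `sln_ranked` with elements `true` and `false`
#'   (both `sln_findings` frames).
#' @export
rank_findings <- function(findings) {
  tr <- findings[findings$verdict == "true_finding", , drop = FALSE]
  fa <- findings[findings$verdict == "false_finding", , drop = FALSE]
  if (nrow(tr)) {
    tr <- tr[order(-tr$probability, -tr$peak_value, tr$label), , drop = FALSE]
  }
  if (nrow(fa)) {
    fa <- fa[order(fa$probability, -fa$peak_value, fa$label), , drop = FALSE]
  }
  rownames(tr) <- NULL; rownames(fa) <- NULL
  structure(list(true = tr, false = fa), class = "sln_ranked")
}

#' @export
print.sln_ranked <- function(x, ...) {
  cat(sprintf("<sln_ranked> %d true, %d false findings\n",
              nrow(x$true), nrow(x$false)))
  invisible(x)
}

#' Apply expert corrections to the ranked lists
#'
#' Findings the expert judges to be on the wrong list are moved to the other
#' one.  A move from the true to the false list is a false-positive
#' correction (the program over-called); false to true is a false-negative
#' correction.  Moving a finding to the list it is already on is a no-op
#' with a warning; unknown labels are an error.
#'
#' @param ranked An [rank_findings()] result.
#' @param moves Data frame with columns `label` and `to` (`"true"` or
#'   `"false"`), applied in row order.
#' @return A list: `ranked` (re-sorted lists), `n_fp_corrections`,
#'   `n_fn_corrections`, `n_moves`.
#' @export
apply_expert_corrections <- function(ranked, moves) {
  stopifnot(inherits(ranked, "sln_ranked"))
  tr <- ranked$true; fa <- ranked$false
  n_fp <- 0L; n_fn <- 0L; n_moves <- 0L
  if (nrow(moves)) {
    for (r in seq_len(nrow(moves))) {
      lb <- moves$label[r]; to <- moves$to[r]
      in_true <- lb %in% tr$label; in_false <- lb %in% fa$label
      if (!in_true && !in_false) {
        stop(sprintf("unknown finding label %s in corrections", lb),
             call. = FALSE)
      }
      if ((to == "true" && in_true) || (to == "false" && in_false)) {
        sln_log("WARN", "label ", lb, " already on the ", to,
                " list: move ignored")
        next
      }
      n_moves <- n_moves + 1L
      if (to == "false") {        # true -> false: FP correction
        row <- tr[tr$label == lb, , drop = FALSE]
        tr <- tr[tr$label != lb, , drop = FALSE]
        row$verdict <- "false_finding"
        fa <- rbind(fa, row)
        n_fp <- n_fp + 1L
      } else {                    # false -> true: FN correction
        row <- fa[fa$label == lb, , drop = FALSE]
        fa <- fa[fa$label != lb, , drop = FALSE]
        row$verdict <- "true_finding"
        tr <- rbind(tr, row)
        n_fn <- n_fn + 1L
      }
    }
  }
  out <- rank_findings(rbind(tr, fa))
  list(ranked = out, n_fp_corrections = n_fp, n_fn_corrections = n_fn,
       n_moves = n_moves)
}

#' Export ranked findings as JSON
#'
#' Two arrays, `"true"` and `"false"`, mirroring the on-screen candidate
#' lists; each record carries verdict, probability, side, region, features
#' and fired rules.
#'
#' @param ranked An [rank_findings()] result.
#' @param path Optional output path.
#' @param provenance Optional named list appended under `"provenance"`.
#' @return The JSON string (invisibly when written).
#' @export
findings_to_json <- function(ranked, path = NULL, provenance = NULL) {
  stopifnot(inherits(ranked, "sln_ranked"))
  obj <- list(true = ranked$true, false = ranked$false)
  if (!is.null(provenance)) obj$provenance <- provenance
  js <- jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
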