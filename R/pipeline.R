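# Run configuration and the wired pipeline: detect, correct, stats, eval,
# phantom.  JSON is the machine interface; plain-text tables are for humans.

#' Default run configuration
#'
#' Nested list of every tunable of the pipeline, fully defaulted.  YAML
#' configs are validated against this structure; unknown keys are rejected.
#'
#' @return Nested named list.
#' @export
default_run_config <- function() {
  list(
    input = list(spect_path = NULL, ct_path = NULL),
    output = list(findings_json = NULL, label_map_nifti = NULL,
                  tissue_map_nifti = NULL),
    resample = list(target_spacing_mm = c(1, 1, 1), interpolation_order = 3L),
    background = list(fraction = 0.01, reference = "global_max",
                      apply = "after_resample"),
    tissue = list(air_max = -200, fat_max = -20, muscle_max = 150,
                  closing_radius_mm = 3),
    classifier = list(shell_thickness_mm = 2, min_soft_tissue_fraction = 0.5,
                      max_bone_fraction = 0.3, max_air_fraction = 0.3,
                      injection_site_mode = "auto_max_activity",
                      injection_exclusion_radius_mm = 30,
                      injection_coordinate_mm = NULL, min_volume_mm3 = 8,
                      weight_spect = 0.5, weight_ct = 0.5,
                      landmark_plane_z_mm = 64, midline_x_mm = "auto"),
    match = list(max_centroid_distance_mm = 10),
    log_level = "WARN")
}

check_config_keys <- function(cfg, ref, path = "") {
  bad <- setdiff(names(cfg), names(ref))
  if (length(bad)) {
    stop(sprintf("unknown config key(s): %s",
                 paste0(path, bad, collapse = ", ")), call. = FALSE)
  }
  for (nm in names(cfg)) {
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])) && is.list(cfg[[nm]])) {
      check_config_keys(cfg[[nm]], ref[[nm]], paste0(path, nm, "."))
    }
  }
  invisible(TRUE)
}

merge_config <- function(base, upd) {
  for (nm in names(upd)) {
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]])) &&
        is.list(upd[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], upd[[nm]])
    } else {
      base[[nm]] <- upd[[nm]]
    }
  }
  base
}

#' Load a run configuration
#'
#' Merges a YAML file and/or an override list over [default_run_config()].
#' Unknown keys anywhere in the hierarchy are an error.
#'
#' @param path Optional YAML file.
#' @param overrides Optional named nested list applied last.
#' @return The validated configuration list.
#' @export
load_run_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop(sprintf("config file '%s' not found", path), call. = FALSE)
    }
    y <- yaml::read_yaml(path)
    check_config_keys(y, cfg)
    cfg <- merge_config(cfg, y)
  }
  if (!is.null(overrides)) {
    check_config_keys(overrides, cfg)
    cfg <- merge_config(cfg, overrides)
  }
  cfg
}

# hash of the analysis parameters (I/O paths excluded: two runs of the same
# analysis on the same data must report the same hash)
config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(cfg[setdiff(names(cfg), c("input", "output"))]), f)
  unname(tools::md5sum(f))
}

#' Run the detection pipeline
#'
#' Executes the full chain on a SPECT/CT pair: resample both modalities to
#' the 1 mm analysis grid (the CT is put onto the SPECT reference lattice),
#' suppress the SPECT background (before or after resampling per config),
#' segment hot spots, classify CT tissue, regularise bone, build the body
#' mask, classify the hot spots, assign side and region, and rank the
#' findings.  Optionally writes the findings JSON (with a provenance block:
#' config hash and package version) and label maps.
#'
#' @param cfg A configuration from [load_run_config()]; alternatively pass
#'   `spect` and `ct` volumes directly (paths in the config are then
#'   ignored).
#' @param spect,ct Optional [sln_volume()]s overriding the config paths.
#' @return A list of class `sln_detect_result`: `ranked`, `findings`,
#'   `hotspots`, `tissue`, `body`, `config`, `provenance`.
#' @export
run_detect <- function(cfg = load_run_config(), spect = NULL, ct = NULL) {
  old <- options(slndetect.log_level = cfg$log_level)
  on.exit(options(old))
  if (is.null(spect)) {
    if (is.null(cfg$input$spect_path)) {
      stop("config error: input.spect_path missing", call. = FALSE)
    }
    spect <- load_volume(cfg$input$spect_path, "SPECT")
  }
  if (is.null(ct)) {
    if (is.null(cfg$input$ct_path)) {
      stop("config error: input.ct_path missing", call. = FALSE)
    }
    ct <- load_volume(cfg$input$ct_path, "CT")
  }
  thr <- background_threshold(cfg$background$fraction,
                              cfg$background$reference)
  if (identical(cfg$background$apply, "before_resample")) {
    spect <- suppress_background(spect, thr)
  }
  rs <- resample_spec(cfg$resample$target_spacing_mm,
                      cfg$resample$interpolation_order)
  spect <- resample(spect, rs)
  ct <- resample_to_reference(ct, spect, cfg$resample$interpolation_order)
  if (!identical(cfg$background$apply, "before_resample")) {
    spect <- suppress_background(spect, thr)
  }

  hs <- segment_hotspots(spect)
  tissue <- classify_tissue(ct, hu_thresholds(cfg$tissue$air_max,
                                              cfg$tissue$fat_max,
                                              cfg$tissue$muscle_max))
  tissue <- close_bone(tissue, cfg$tissue$closing_radius_mm)
  body <- body_mask(tissue)
  ccfg <- do.call(classifier_config, cfg$classifier)
  findings <- classify_findings(hs, tissue, body, ccfg)
  findings <- assign_side_region(findings, body, ccfg,
                                 spacing_mm = spect$spacing_mm,
                                 origin_mm = spect$origin_mm)
  ranked <- rank_findings(findings)

  prov <- list(config_hash = config_hash(cfg),
               package = "slndetect",
               version = as.character(utils::packageVersion("slndetect")))
  if (!is.null(cfg$output$findings_json)) {
    findings_to_json(ranked, cfg$output$findings_json, provenance = prov)
  }
  if (!is.null(cfg$output$label_map_nifti)) {
    lm <- sln_volume(array(as.numeric(hs$label_map), dim(hs$label_map)),
                     spect$spacing_mm, spect$origin_mm, "SPECT")
    write_volume(lm, cfg$output$label_map_nifti)
  }
  if (!is.null(cfg$output$tissue_map_nifti)) {
    tm <- sln_volume(array(as.numeric(tissue$labels), dim(tissue$labels)),
                     ct$spacing_mm, ct$origin_mm, "CT")
    write_volume(tm, cfg$output$tissue_map_nifti)
  }
  structure(list(ranked = ranked, findings = findings, hotspots = hs,
                 tissue = tissue, body = body, config = cfg,
                 provenance = prov), class = "sln_detect_result")
}

#' @export
print.sln_detect_result <- function(x, ...) {
  cat(sprintf("<sln_detect_result> %d hot spots -> %d true / %d false findings\n",
              nrow(x$findings), nrow(x$ranked$true), nrow(x$ranked$false)))
  invisible(x)
}

#' Read findings JSON back into ranked lists
#'
#' @param path Findings JSON written by [findings_to_json()] / [run_detect()].
#' @return An `sln_ranked` list.
#' @export
read_findings <- function(path) {
  obj <- jsonlite::fromJSON(path)
  as_frame <- function(df) {
    if (is.null(df) || length(df) == 0L) {
      return(data.frame(label = integer(), verdict = character(),
                        probability = numeric()))
    }
    df
  }
  structure(list(true = as_frame(obj$true), false = as_frame(obj$false)),
            class = "sln_ranked")
}

#' Read a crosstab from CSV
#'
#' Expects columns `a`, `b`, `c`, `d`; an empty field, `NA` or `"unknown"`
#' in `d` marks the cell unavailable.
#'
#' @param path CSV path.
#' @return A [confusion_counts()].
#' @export
read_crosstab_csv <- function(path) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop(sprintf(
                   "cannot parse crosstab '%s': %s", path,
                   conditionMessage(e)), call. = FALSE))
  need <- c("a", "b", "c", "d")
  if (!all(need %in% names(df)) || nrow(df) < 1L) {
    stop(sprintf("malformed crosstab '%s': need columns a,b,c,d", path),
         call. = FALSE)
  }
  d <- df$d[1]
  if (is.character(d)) d <- if (d %in% c("", "unknown", "NA")) NA else
    as.numeric(d)
  confusion_counts(df$a[1], df$b[1], df$c[1], d)
}

#' Crosstab report from a counts file or two findings files
#'
#' @param counts_csv Path to a crosstab CSV (see [read_crosstab_csv()]); or
#' @param program_json,corrected_json Paths to two findings JSON files to
#'   crosstab against each other.
#' @return A list with `counts`, `rates` and `report` (text lines).
#' @export
run_stats <- function(counts_csv = NULL, program_json = NULL,
                      corrected_json = NULL) {
  cc <- if (!is.null(counts_csv)) {
    read_crosstab_csv(counts_csv)
  } else if (!is.null(program_json) && !is.null(corrected_json)) {
    crosstab_from_lists(read_findings(program_json),
                        read_findings(corrected_json))
  } else {
    stop("provide counts_csv or both findings files", call. = FALSE)
  }
  list(counts = cc, rates = rates(cc),
       report = render_crosstab(cc, "Assessment crosstab"))
}

#' Apply a corrections file to a findings file
#'
#' @param findings_json Findings JSON path.
#' @param moves_csv CSV with columns `label`, `to` ("true"/"false").
#' @param out_json Optional output path for the corrected lists.
#' @return The [apply_expert_corrections()] result.
#' @export
run_correct <- function(findings_json, moves_csv, out_json = NULL) {
  ranked <- read_findings(findings_json)
  moves <- utils::read.csv(moves_csv, stringsAsFactors = FALSE)
  res <- apply_expert_corrections(ranked, moves)
  if (!is.null(out_json)) findings_to_json(res$ranked, out_json)
  res
}

#' Evaluate findings against phantom ground truth
#'
#' @param ranked An `sln_ranked` (or findings JSON path).
#' @param truth A `sln_phantom_truth` (or truth JSON path).
#' @param spec A [match_spec()].
#' @return The [match_to_truth()] result plus `rates`.
#' @export
run_eval <- function(ranked, truth, spec = match_spec()) {
  if (is.character(ranked)) ranked <- read_findings(ranked)
  if (is.character(truth)) truth <- read_phantom_truth(truth)
  m <- match_to_truth(ranked, truth, spec)
  c(m, list(rates = rates(m$counts)))
}

#' Write and read phantom ground truth as JSON
#'
#' @param truth An `sln_phantom_truth`.
#' @param path JSON path.
#' @return `path` (write) or the truth object (read).
#' @export
write_phantom_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sln_phantom_truth"))
  writeLines(jsonlite::toJSON(unclass(truth), dataframe = "rows",
                              auto_unbox = TRUE, digits = NA, pretty = TRUE),
             path)
  invisible(path)
}

#' @rdname write_phantom_truth
#' @export
read_phantom_truth <- function(path) {
  obj <- jsonlite::fromJSON(path)
  obj$injection_position <- as.numeric(obj$injection_position)
  structure(obj, class = "sln_phantom_truth")
}

#' Generate a phantom study to disk
#'
#' Writes the CT and SPECT NIfTI pair (1 mm grid; optionally also the
#' native-resolution degraded pair) plus the ground-truth JSON.
#'
#' @param out_dir Output directory (created if needed).
#' @param spec A [phantom_spec()].
#' @param native Also write the degraded native-spacing pair (default TRUE).
#' @return Invisibly, the `sln_phantom` object.
#' @export
run_phantom <- function(out_dir, spec = phantom_spec(), native = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ph <- generate_phantom(spec)
  write_volume(ph$ct, file.path(out_dir, "ct_1mm.nii.gz"))
  write_volume(ph$spect, file.path(out_dir, "spect_1mm.nii.gz"))
  if (native) {
    deg <- degrade_to_native(ph$ct, ph$spect)
    write_volume(deg$ct, file.path(out_dir, "ct_native.nii.gz"))
    write_volume(deg$spect, file.path(out_dir, "spect_native.nii.gz"))
  }
  write_phantom_truth(ph$truth, file.path(out_dir, "truth.json"))
  invisible(ph)
}
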