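# File formats, configuration parsing and the end-to-end pipeline.
#
# Array-grid format: a CSV of voxel indices and values (columns ix, iy, iz,
# value) plus a JSON sidecar <path>.json recording dimensions, voxel size,
# axis conventions and, for tissue grids, the label legend. CSV dialect
# throughout: UTF-8, comma separator, header row, '.' decimal point.

#' Write a 3-D array to the array-grid format
#'
#' @param arr Numeric or integer 3-D array.
#' @param path Output CSV path; the sidecar is written to `<path>.json`.
#' @param voxel_size Voxel edge (cm), recorded in the sidecar.
#' @param legend Optional named integer vector mapping labels to codes
#'   (for tissue grids).
#' @param extra Optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_grid <- function(arr, path, voxel_size, legend = NULL, extra = NULL) {
  stopifnot(length(dim(arr)) == 3)
  d <- dim(arr)
  idx <- arrayInd(seq_along(arr), d)
  df <- data.frame(ix = idx[, 1], iy = idx[, 2], iz = idx[, 3],
                   value = as.vector(arr))
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(dim = d, voxel_size_cm = voxel_size,
               axes = list(x = "left-right (column index ix)",
                           y = "posterior-anterior (row index iy)",
                           z = "depth from surface (layer index iz)"),
               format = "bnctplan array-grid v1")
  if (!is.null(legend)) meta$legend <- as.list(legend)
  if (!is.null(extra)) meta <- c(meta, extra)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an array-grid file
#'
#' @param path CSV path written by [write_grid()].
#' @return List with `array` and the sidecar `meta`.
#' @export
read_grid <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path)
  d <- as.integer(meta$dim)
  arr <- array(NA_real_, dim = d)
  arr[cbind(df$ix, df$iy, df$iz)] <- df$value
  list(array = arr, meta = meta)
}

#' Write a phantom to the array-grid format
#'
#' @param phantom A [make_head_phantom()] object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_phantom <- function(phantom, path) {
  stopifnot(inherits(phantom, "phantom"))
  write_grid(phantom$tissue, path, phantom$voxel_size,
             legend = .tissue_legend,
             extra = list(case_id = phantom$case_id))
  invisible(path)
}

# default run configuration (all values reproduce the standard study setup)
.default_config <- function() {
  list(
    phantom = list(case = "wide_disk", voxel_size_cm = 0.5,
                   lateral_extent_cm = 20, depth_cm = 10,
                   skin_thickness_cm = 0.5),
    beam = list(intensity = 0.45, profile_sigma_cm = 4.25,
                gamma_fraction = 0.05),
    tissues = list(blood_boron_ppm = 24, tumor_blood_ratio = 3.5,
                   skin_blood_ratio = 1.0, brain_blood_ratio = 1.0),
    optimizer = list(thicknesses_cm = c(2, 3, 4, 5), ratios = c(2, 3, 4, 5),
                     allow_ratio_one = FALSE),
    output = list(dir = "bnctplan-results")
  )
}

# recursive strict merge: every user key must exist in the defaults
.merge_strict <- function(defaults, user, path = character(0)) {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop("config section '", paste(path, collapse = "."),
                           "' must be a mapping")
  for (key in names(user)) {
    full <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults)) stop("unknown config key: ", full)
    if (is.list(defaults[[key]])) {
      defaults[[key]] <- .merge_strict(defaults[[key]], user[[key]],
                                       c(path, key))
    } else {
      val <- user[[key]]
      if (is.list(val)) val <- unlist(val)
      if (!is.null(dim(val))) stop("config key ", full, " must be scalar/vector")
      defaults[[key]] <- val
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration and applies the defaults, which reproduce
#' the standard study settings (24 ppm blood boron, T/B 3.5, S/B 1.0,
#' LiF-PE thicknesses 2-5 cm, time ratios 1:2-1:5, 0.5-cm voxels). Parsing
#' is strict: unknown keys are rejected by name, as are out-of-range
#' values. An empty file yields the all-defaults configuration. Key names
#' carry explicit unit suffixes (`_cm`, `_ppm`).
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A validated configuration list of class `run_config`.
#' @export
load_config <- function(path = NULL) {
  user <- if (is.null(path)) NULL else yaml::read_yaml(path)
  cfg <- .merge_strict(.default_config(), user)

  chk_pos <- function(value, key) {
    if (any(!is.finite(value)) || any(value <= 0)) {
      stop("config key ", key, " must be positive (got ",
           paste(value, collapse = ", "), ")")
    }
  }
  if (!cfg$phantom$case %in% c("wide_disk", "small_rect", "asymmetric")) {
    stop("config key phantom.case must be one of wide_disk, small_rect, asymmetric")
  }
  chk_pos(cfg$phantom$voxel_size_cm, "phantom.voxel_size_cm")
  chk_pos(cfg$phantom$lateral_extent_cm, "phantom.lateral_extent_cm")
  chk_pos(cfg$phantom$depth_cm, "phantom.depth_cm")
  chk_pos(cfg$beam$profile_sigma_cm, "beam.profile_sigma_cm")
  if (cfg$beam$intensity < 0) stop("config key beam.intensity must be >= 0")
  chk_pos(cfg$tissues$blood_boron_ppm, "tissues.blood_boron_ppm")
  chk_pos(cfg$tissues$tumor_blood_ratio, "tissues.tumor_blood_ratio")
  chk_pos(cfg$tissues$skin_blood_ratio, "tissues.skin_blood_ratio")
  chk_pos(cfg$tissues$brain_blood_ratio, "tissues.brain_blood_ratio")
  chk_pos(cfg$optimizer$thicknesses_cm, "optimizer.thicknesses_cm")
  r <- cfg$optimizer$ratios
  if (any(abs(r - round(r)) > 1e-9)) {
    stop("config key optimizer.ratios must hold integers")
  }
  low <- if (isTRUE(cfg$optimizer$allow_ratio_one)) 1 else 2
  if (any(r < low)) {
    stop("config key optimizer.ratios: ratio r must be >= ", low,
         " (1:1 requires optimizer.allow_ratio_one: true)")
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Run the full planning pipeline
#'
#' Chains phantom construction, catalog enumeration, exhaustive candidate
#' evaluation, baseline computation and best-plan selection, and writes a
#' deterministic artifact tree to the output directory:
#' `phantom.csv` (+ sidecar), `catalog.json`, `candidates.csv`,
#' `best_plan.json`, `scatter.csv` (minimum tumor dose vs HI per candidate
#' with the best plan and baseline flagged), `dvh/` (cumulative DVH CSVs
#' for the baseline and best plans) and `run.log`.
#'
#' @param config A [load_config()] object (default: all defaults).
#' @param out_dir Output directory (default from the config).
#' @param quiet Suppress progress output.
#' @return The [select_best()] result, invisibly.
#' @export
run_all <- function(config = load_config(), out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- out_dir %||% config$output$dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "dvh"), showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)

  grid <- build_aperture_grid()
  phantom <- make_head_phantom(config$phantom$case,
                               voxel_size = config$phantom$voxel_size_cm,
                               lateral_extent = config$phantom$lateral_extent_cm,
                               depth = config$phantom$depth_cm,
                               skin_thickness = config$phantom$skin_thickness_cm)
  beam <- beam_model(epithermal_intensity = config$beam$intensity,
                     profile_sigma_cm = config$beam$profile_sigma_cm,
                     gamma_fraction = config$beam$gamma_fraction)
  tissues <- tissue_model(blood_boron_ppm = config$tissues$blood_boron_ppm,
                          tumor_blood_ratio = config$tissues$tumor_blood_ratio,
                          skin_blood_ratio = config$tissues$skin_blood_ratio,
                          brain_blood_ratio = config$tissues$brain_blood_ratio)
  catalog <- build_catalog(grid, config$optimizer$thicknesses_cm)

  say("stage phantom: ", phantom$case_id, " at ", phantom$voxel_size, " cm")
  write_phantom(phantom, file.path(out_dir, "phantom.csv"))
  say("stage catalog: ", nrow(catalog$configs), " configurations")
  write_catalog_json(catalog, file.path(out_dir, "catalog.json"))

  say("stage optimize: ", nrow(catalog$configs), " x ",
      length(config$optimizer$ratios), " candidates")
  result <- tryCatch(
    optimize_plan(phantom, beam, tissues, grid, catalog,
                  ratios = config$optimizer$ratios),
    error = function(e) stop("stage optimize failed: ", conditionMessage(e)))
  cands <- result$candidates
  utils::write.csv(cands, file.path(out_dir, "candidates.csv"),
                   row.names = FALSE)

  scatter <- cands[, c("config_id", "ratio", "d_min_tumor", "HI")]
  scatter$flag <- ifelse(
    cands$config_id == result$best$config_id & cands$ratio == result$best$ratio,
    "best", "")
  base_row <- data.frame(config_id = "IF-A", ratio = NA_integer_,
                         d_min_tumor = result$baseline$d_min_tumor,
                         HI = result$baseline$HI, flag = "baseline")
  utils::write.csv(rbind(scatter, base_row),
                   file.path(out_dir, "scatter.csv"), row.names = FALSE)

  best_plan <- plan_doses(if_a_pattern(),
                          shape_to_pattern(catalog$shapes[[result$best$shape_id]],
                                           result$best$thickness_cm),
                          result$best$ratio, phantom, beam, tissues, grid)
  base_plan <- plan_doses(if_a_pattern(), NULL, NULL, phantom, beam,
                          tissues, grid)
  utils::write.csv(best_plan$tumor_dvh$curve,
                   file.path(out_dir, "dvh", "best_tumor_dvh.csv"),
                   row.names = FALSE)
  utils::write.csv(base_plan$tumor_dvh$curve,
                   file.path(out_dir, "dvh", "baseline_tumor_dvh.csv"),
                   row.names = FALSE)

  summary <- list(
    pattern_id = result$best$config_id, ratio = result$best$ratio,
    time_min = result$best$time_min,
    limiting_tissue = result$best$limiting_tissue,
    d_min_tumor = result$best$d_min_tumor, HI = result$best$HI,
    baseline = list(time_min = result$baseline$time_min,
                    d_min_tumor = result$baseline$d_min_tumor,
                    HI = result$baseline$HI,
                    limiting_tissue = result$baseline$limiting_tissue),
    improvement_d_min_percent = 100 *
      (result$best$d_min_tumor - result$baseline$d_min_tumor) /
      result$baseline$d_min_tumor,
    improvement_hi_percent = as.numeric(
      improvement_percent(result$baseline$HI, result$best$HI)),
    dvh_path = "dvh/best_tumor_dvh.csv")
  jsonlite::write_json(summary, file.path(out_dir, "best_plan.json"),
                       auto_unbox = TRUE, digits = NA)

  log_lines <- c(
    paste0("bnctplan ", as.character(utils::packageVersion("bnctplan"))),
    paste0("R ", R.version.string),
    "config:",
    utils::capture.output(utils::str(unclass(config), give.attr = FALSE)),
    sprintf("selected pattern: %s", result$best$config_id),
    sprintf("selected time ratio: 1:%d", result$best$ratio),
    sprintf("minimum tumor dose: %.6g Gy-eq", result$best$d_min_tumor),
    sprintf("homogeneity index: %.6g", result$best$HI))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  say("done: ", out_dir)
  invisible(result)
}
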