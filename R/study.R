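#' Study design grid
#'
#' Enumerates the lesion-measurement instances of a study: every
#' combination of lesion, scanner, dose and repetition.
#'
#' @param scanners character vector of scanner labels.
#' @param doses dose levels in mGy.
#' @param repetitions number of repeated scans per condition.
#' @param lesions lesion ids included.
#' @param base_seed study base seed.
#' @return data frame, one row per lesion-measurement instance, with the
#'   per-condition seed.
#' @export
study_grid <- function(scanners = c("EIDCT", "PCCT"),
                       doses = c(20.4, 9.8, 4.9, 2.4, 1.6),
                       repetitions = 3, lesions = 1:6, base_seed = 101L) {
  specs <- lesion_specs()
  specs <- specs[specs$lesion_id %in% lesions, , drop = FALSE]
  g <- expand.grid(lesion_id = specs$lesion_id, dose_mGy = doses,
                   scanner = scanners, repetition = seq_len(repetitions),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- merge(g, specs[, c("lesion_id", "lesion_type", "size_class",
                          "phantom_id")], by = "lesion_id")
  g$scanner_idx <- match(g$scanner, scanners)
  g$dose_idx <- match(g$dose_mGy, doses)
  g$seed <- condition_seed(base_seed, g$scanner_idx, g$dose_idx,
                           g$repetition, g$phantom_id)
  g <- g[order(g$scanner_idx, g$dose_idx, g$repetition, g$lesion_id), ]
  rownames(g) <- NULL
  g
}

#' Study configuration
#'
#' Collects every tunable of the pipeline; the defaults reproduce the
#' reference design exactly: doses {20.4, 9.8, 4.9, 2.4, 1.6} mGy, two
#' scanner models, three repetitions, six lesions, 0.5 x 0.5 x 1.0 mm
#' voxels, 8 mm ROIs on three central slices, 25 HU feature bins, 95%
#' PCA variance retention, 5% significance level.
#'
#' @param base_seed integer; drives every random stream in the study.
#' @param scanners,doses,repetitions,lesions design grid.
#' @param spacing voxel spacing (mm).
#' @param materials a [material_table()].
#' @param noise_points calibration points, see [noise_calibration_points()].
#' @param texture phantom texture parameters (HU SDs and scales, mm).
#' @param noise_corr_mm noise correlation length (mm).
#' @param bin_width radiomics bin width (HU).
#' @param variance_threshold PCA cumulative-variance rule.
#' @param alpha significance level.
#' @return list of class `study_config`.
#' @export
study_config <- function(base_seed = 101L,
                         scanners = c("EIDCT", "PCCT"),
                         doses = c(20.4, 9.8, 4.9, 2.4, 1.6),
                         repetitions = 3,
                         lesions = 1:6,
                         spacing = c(0.5, 0.5, 1),
                         materials = material_table(),
                         noise_points = noise_calibration_points(),
                         texture = list(parenchyma_sd = 20, lesion_sd = 15,
                                        corr_mm = 2, highpass_mm = 8),
                         noise_corr_mm = 1,
                         bin_width = 25,
                         variance_threshold = 0.95,
                         alpha = 0.05) {
  structure(list(base_seed = as.integer(base_seed), scanners = scanners,
                 doses = doses, repetitions = repetitions, lesions = lesions,
                 spacing = spacing, materials = materials,
                 noise_points = noise_points, texture = texture,
                 noise_corr_mm = noise_corr_mm, bin_width = bin_width,
                 variance_threshold = variance_threshold, alpha = alpha),
            class = "study_config")
}

#' Fit the per-scanner noise models of a configuration
#' @param config a [study_config()].
#' @return named list of [fit_noise_model()] results.
#' @export
config_noise_models <- function(config) {
  out <- lapply(config$scanners, function(sc) {
    pts <- config$noise_points[config$noise_points$scanner == sc,
                               c("dose_mGy", "sigma_hu")]
    fit_noise_model(pts)
  })
  names(out) <- config$scanners
  out
}

#' Write a volume or mask as NIfTI-1
#'
#' @param x a [ct_volume()] or [ct_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_volume <- function(x, path) {
  img <- RNifti::asNifti(x$data)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path NIfTI file.
#' @param scanner,dose_mGy,repetition optional metadata to attach.
#' @return a [ct_volume()].
#' @export
read_volume <- function(path, scanner = NA_character_, dose_mGy = NA_real_,
                        repetition = NA_integer_) {
  img <- RNifti::readNifti(path)
  ct_volume(array(as.numeric(img), dim = dim(img)),
            spacing = RNifti::pixdim(img)[1:3], scanner = scanner,
            dose_mGy = dose_mGy, repetition = repetition)
}

#' Generate a study to disk
#'
#' Rasterizes the phantoms, simulates every (scanner, dose, repetition,
#' phantom) acquisition and writes volume/mask NIfTI pairs plus a
#' lesion-level manifest CSV.  Existing files are kept (the run is
#' resumable and seeds are derived, not sequential).
#'
#' @param config a [study_config()].
#' @param out_dir writable output directory.
#' @return the manifest data frame (written to `manifest.csv`), one row
#'   per lesion-measurement instance with file paths and seeds.
#' @export
generate_study <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) stop("output directory not writable")
  grid <- study_grid(config$scanners, config$doses, config$repetitions,
                     config$lesions, config$base_seed)
  specs <- phantom_specs(lesion_specs()[lesion_specs()$lesion_id %in%
                                          config$lesions, ])
  models <- config_noise_models(config)
  manifest <- list()
  for (spec in specs) {
    pid <- spec$phantom_id
    mask_path <- file.path(out_dir, sprintf("phantom%d_mask.nii.gz", pid))
    for (sc_i in seq_along(config$scanners)) {
      sc <- config$scanners[sc_i]
      truth <- rasterize_phantom(spec, config$materials, sc,
                                 spacing = config$spacing,
                                 texture = config$texture,
                                 seed = condition_seed(config$base_seed,
                                                       phantom_id = pid))
      if (!file.exists(mask_path)) write_volume(truth$mask, mask_path)
      rois <- place_rois(truth$mask, spec)
      for (d_i in seq_along(config$doses)) {
        for (rep_i in seq_len(config$repetitions)) {
          seed <- condition_seed(config$base_seed, sc_i, d_i, rep_i, pid)
          vol_path <- file.path(out_dir,
                                sprintf("phantom%d_%s_d%02d_r%d.nii.gz",
                                        pid, sc, d_i, rep_i))
          if (!file.exists(vol_path)) {
            vol <- simulate_scan(truth$volume, truth$mask, models[[sc]],
                                 sc, config$doses[d_i], rep_i, seed,
                                 rois = rois, corr_mm = config$noise_corr_mm)
            write_volume(vol, vol_path)
          }
          les <- spec$lesions
          manifest[[length(manifest) + 1]] <- data.frame(
            lesion_id = les$lesion_id, lesion_type = les$lesion_type,
            size_class = les$size_class, scanner = sc,
            dose_mGy = config$doses[d_i], repetition = rep_i, seed = seed,
            volume_path = vol_path, mask_path = mask_path,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  manifest <- do.call(rbind, manifest)
  manifest <- manifest[order(manifest$scanner, manifest$dose_mGy,
                             manifest$repetition, manifest$lesion_id), ]
  rownames(manifest) <- NULL
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Import external volume/mask pairs
#'
#' Builds a manifest in the [generate_study()] schema from existing NIfTI
#' volume and mask files so downstream stages run unchanged.
#'
#' @param volumes character vector of volume paths.
#' @param masks character vector of mask paths (recycled if length 1).
#' @param labels data frame with one row per volume: `lesion_id`,
#'   `lesion_type`, `size_class`, `scanner`, `dose_mGy`, `repetition`.
#' @return manifest data frame.
#' @export
import_external <- function(volumes, masks, labels) {
  if (length(masks) == 1) masks <- rep(masks, length(volumes))
  stopifnot(length(volumes) == length(masks),
            nrow(labels) == length(volumes))
  for (i in seq_along(volumes)) {
    if (!file.exists(volumes[i]))
      stop("missing volume: ", volumes[i], call. = FALSE)
    if (!file.exists(masks[i]))
      stop("missing mask for instance ", i, " (", masks[i], ")",
           call. = FALSE)
    v <- RNifti::readNifti(volumes[i])
    m <- RNifti::readNifti(masks[i])
    if (any(abs(RNifti::pixdim(v)[1:3] - RNifti::pixdim(m)[1:3]) > 1e-6))
      stop("spacing mismatch between volume and mask for instance ", i,
           call. = FALSE)
  }
  cbind(labels,
        data.frame(seed = NA_integer_, volume_path = volumes,
                   mask_path = masks, stringsAsFactors = FALSE))
}

#' Write a study configuration to a structured text file
#'
#' Serializes every field of a [study_config()] (design grid, material
#' table, noise calibration points, texture, extractor and analysis
#' settings) as JSON, round-trippable with [read_study_config()].
#'
#' @param config a [study_config()].
#' @param path output path (`.json`).
#' @return the path, invisibly.
#' @export
write_study_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' Read a study configuration file
#'
#' @param path a file written by [write_study_config()].
#' @return a [study_config()].
#' @export
read_study_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  study_config(base_seed = raw$base_seed, scanners = raw$scanners,
               doses = raw$doses, repetitions = raw$repetitions,
               lesions = raw$lesions, spacing = raw$spacing,
               materials = as.data.frame(raw$materials),
               noise_points = as.data.frame(raw$noise_points),
               texture = raw$texture, noise_corr_mm = raw$noise_corr_mm,
               bin_width = raw$bin_width,
               variance_threshold = raw$variance_threshold,
               alpha = raw$alpha)
}
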