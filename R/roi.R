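#' Voxel indices covered by a circular ROI
#'
#' Voxels whose centres lie within the ROI disc on the given slice
#' (single-slice 2D disc; half-open grid convention with centred axes).
#'
#' @param roi one row of a [place_rois()] table.
#' @param dims volume dimensions.
#' @param spacing voxel spacing (mm).
#' @return integer vector of linear voxel indices.
#' @export
roi_voxel_indices <- function(roi, dims, spacing) {
  ax <- grid_axes(dims, spacing)
  dx <- ax[[1]] - roi$cx
  dy <- ax[[2]] - roi$cy
  d2 <- outer(dx^2, dy^2, "+")
  sel2d <- which(d2 <= roi$radius_mm^2)
  (roi$slice - 1) * dims[1] * dims[2] + sel2d
}

#' Place measurement ROIs on a phantom
#'
#' Deterministic surrogate for manual ROI placement in homogeneous regions:
#' per central slice, one ROI inside each lesion (for part-solid lesions,
#' inside the homogeneous ground-glass shell), one in the parenchyma
#' adjacent to each lesion (radially outward along the sector bisector),
#' and — for the phantom flagged with `include_water_roi` — one in the
#' solid-water ring.  ROI centres maximize clearance from region
#' boundaries; the default 8 mm diameter is shrunk (with a warning, never
#' below 4 mm) where a region is too thin.
#'
#' @param mask a [ct_mask()] from [rasterize_phantom()].
#' @param spec the matching element of [phantom_specs()].
#' @param diameter_mm nominal ROI diameter (default 8).
#' @param n_slices number of central slices (default 3).
#' @return data frame with one row per ROI: `phantom_id`, `lesion_id`,
#'   `roi_kind`, `label`, `material`, `slice`, `cx`, `cy`, `radius_mm`.
#' @export
place_rois <- function(mask, spec, diameter_mm = 8, n_slices = 3) {
  dims <- dim(mask$data)
  mid <- as.integer(ceiling(dims[3] / 2))
  slices <- mid + seq_len(n_slices) - 1L - (n_slices - 1L) %/% 2L
  stopifnot(all(slices >= 1 & slices <= dims[3]))
  rho0 <- diameter_mm / 2
  out <- list()
  add <- function(kind, lesion_id, material, label, cx, cy, radius) {
    if (radius < rho0 - 1e-9)
      warning(sprintf("ROI (%s, lesion %s) shrunk to %.1f mm diameter",
                      kind, lesion_id, 2 * radius), call. = FALSE)
    radius <- max(radius, 2)
    for (sl in slices)
      out[[length(out) + 1]] <<- data.frame(
        phantom_id = spec$phantom_id, lesion_id = lesion_id, roi_kind = kind,
        label = label, material = material, slice = sl, cx = cx, cy = cy,
        radius_mm = radius, stringsAsFactors = FALSE)
  }
  r_phantom <- spec$diameter / 2
  for (i in seq_len(nrow(spec$lesions))) {
    les <- spec$lesions[i, ]
    axes <- lesion_axes(les, spec$height)
    theta <- les$sector_angle * pi / 180
    ur <- c(cos(theta), sin(theta))
    ut <- c(-sin(theta), cos(theta))
    d <- spec$lesion_center_radius
    cx <- d * ur[1]; cy <- d * ur[2]
    if (les$lesion_type == "part_solid") {
      # homogeneous shell: worst-case (largest) core over both scanner models
      mt <- material_table()
      s_core <- max(vapply(unique(mt$scanner), function(sc) {
        part_solid_core_fraction(les$mean_intensity,
                                 material_hu(mt, sc, "solid"),
                                 material_hu(mt, sc, "part_solid"))^(1 / 3)
      }, numeric(1)))
      m <- unname((1 + s_core) / 2 * axes["a"])
      rho <- min(rho0, 0.9 * (1 - s_core) / 2 * axes["a"],
                 0.9 * axes["b"] * sqrt(1 - (m / axes["a"])^2))
      add("lesion", les$lesion_id, les$lesion_type, 10L + les$lesion_id,
          cx + m * ut[1], cy + m * ut[2], rho)
    } else {
      rho <- min(rho0, 0.8 * axes["b"])
      add("lesion", les$lesion_id, les$lesion_type, 10L + les$lesion_id,
          cx, cy, rho)
    }
    # adjacent parenchyma, radially outward
    gap_out <- unname(r_phantom - (d + axes["b"]))
    rho_bg <- min(rho0, (gap_out - 4) / 2)
    pos <- unname(d + axes["b"] + rho_bg + min(3, gap_out - 2 * rho_bg - 1))
    add("parenchyma", les$lesion_id, "lung_parenchyma", 1L,
        pos * ur[1], pos * ur[2], rho_bg)
  }
  if (isTRUE(spec$include_water_roi)) {
    rw <- (r_phantom + spec$ring_outer_diameter / 2) / 2
    add("water", NA_integer_, "water", 2L, rw, 0, rho0)
  }
  rois <- do.call(rbind, out)
  rownames(rois) <- NULL
  rois
}

#' Measure mean and SD of HU values in an ROI
#'
#' Sample statistics (denominator n - 1) over voxels whose centres lie
#' within the ROI disc on its slice.
#'
#' @param volume a [ct_volume()].
#' @param roi one row of a [place_rois()] table.
#' @return data frame row with the ROI labels plus `mean`, `sd`, `n_voxels`.
#' @export
measure_roi <- function(volume, roi) {
  idx <- roi_voxel_indices(roi, dim(volume$data), volume$spacing)
  if (!length(idx)) stop("empty ROI", call. = FALSE)
  vals <- volume$data[idx]
  cbind(roi,
        data.frame(mean = mean(vals), sd = if (length(vals) > 1) sd(vals) else 0,
                   n_voxels = length(vals),
                   scanner = volume$scanner, dose_mGy = volume$dose_mGy,
                   repetition = volume$repetition, stringsAsFactors = FALSE))
}

#' Measure a table of ROIs against a volume
#'
#' @param volume a [ct_volume()].
#' @param rois a [place_rois()] table.
#' @param index_cache optional precomputed list of voxel index vectors.
#' @return data frame with one row per ROI.
#' @export
measure_rois <- function(volume, rois, index_cache = NULL) {
  dims <- dim(volume$data)
  if (is.null(index_cache))
    index_cache <- lapply(seq_len(nrow(rois)), function(i)
      roi_voxel_indices(rois[i, ], dims, volume$spacing))
  stats <- vapply(index_cache, function(ix) {
    v <- volume$data[ix]
    c(mean(v), sd(v), length(v))
  }, numeric(3))
  cbind(rois,
        data.frame(mean = stats[1, ], sd = stats[2, ], n_voxels = stats[3, ],
                   scanner = volume$scanner, dose_mGy = volume$dose_mGy,
                   repetition = volume$repetition, stringsAsFactors = FALSE))
}

#' Pool per-material HU statistics over ROI measurements
#'
#' Pooled mean of ROI means and its standard error (SD of ROI means over
#' the square root of their count), across lesion sizes, slices, doses and
#' repetitions.
#'
#' @param measurements a [measure_rois()] table (any subset).
#' @param material material name to pool.
#' @return one-row data frame `material`, `mean_hu`, `se_hu`, `n_rois`;
#'   `se_hu` is 0 with attribute `single_roi = TRUE` when only one ROI
#'   is available.
#' @export
pool_material_stats <- function(measurements, material) {
  m <- measurements[measurements$material == material, , drop = FALSE]
  if (!nrow(m)) stop("no measurements for material '", material, "'")
  mu <- mean(m$mean)
  se <- if (nrow(m) > 1) sd(m$mean) / sqrt(nrow(m)) else 0
  out <- data.frame(material = material, mean_hu = mu, se_hu = se,
                    n_rois = nrow(m), stringsAsFactors = FALSE)
  if (nrow(m) == 1) attr(out, "single_roi") <- TRUE
  out
}

#' Contrast-to-noise ratio of a lesion against its background
#'
#' `CNR = (mu_lesion - mu_background) / sd_lesion`, signed; magnitudes are
#' taken at the reporting level.
#'
#' @param lesion,background single ROI measurement rows (lesion and its
#'   paired parenchyma ROI).
#' @return scalar CNR; `NaN` with a warning when the lesion SD is zero.
#' @export
compute_cnr <- function(lesion, background) {
  if (lesion$sd == 0) {
    warning("undefined CNR: lesion ROI SD is zero", call. = FALSE)
    return(NaN)
  }
  (lesion$mean - background$mean) / lesion$sd
}

#' Coefficient of variation
#'
#' Absolute ratio of the standard deviation to the mean.
#'
#' @param values numeric vector.
#' @return non-negative scalar; carries attribute `unstable = TRUE` when
#'   the mean is within one SD of zero (ratio regime is unstable).
#' @export
coefficient_of_variation <- function(values) {
  m <- mean(values)
  if (m == 0) stop("coefficient of variation undefined for zero mean")
  cov <- abs(sd(values) / m)
  if (abs(m) < sd(values)) attr(cov, "unstable") <- TRUE
  cov
}

#' Percent change between scanners
#'
#' `100 * (reference - comparison) / reference` for reductions;
#' `100 * (comparison - reference) / reference` for increases.
#'
#' @param reference,comparison numeric values (reference must be nonzero).
#' @param type `"reduction"` or `"increase"`.
#' @return percent change (not rounded; reports round to one decimal).
#' @export
percent_change <- function(reference, comparison,
                           type = c("reduction", "increase")) {
  type <- match.arg(type)
  if (any(reference == 0)) stop("zero reference in percent change")
  if (type == "reduction") 100 * (reference - comparison) / reference
  else 100 * (comparison - reference) / reference
}
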