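#' Per-scanner material attenuation table
#'
#' Mean Hounsfield units for the five materials of interest
#' (lung parenchyma, ground-glass, part-solid, solid, solid water) for the
#' energy-integrating (EIDCT) and photon-counting (PCCT) scanner models.
#' Defaults are the pooled measurements the simulator is calibrated to.
#' Attenuation ordering lung parenchyma < ground-glass < part-solid <
#' solid < water is validated.
#'
#' @param values optional data frame with columns `scanner`, `material`,
#'   `mean_hu` to override the defaults.
#' @return data frame with columns `scanner`, `material`, `mean_hu`.
#' @export
material_table <- function(values = NULL) {
  if (is.null(values)) {
    values <- data.frame(
      scanner = rep(c("EIDCT", "PCCT"), each = 5),
      material = rep(c("lung_parenchyma", "ground_glass", "part_solid",
                       "solid", "water"), 2),
      mean_hu = c(-873.9, -723.7, -660.9, -22.9, -2.9,
                  -871.5, -750.1, -662.8, -41.8, -12.7),
      stringsAsFactors = FALSE
    )
  }
  required <- c("lung_parenchyma", "ground_glass", "part_solid", "solid",
                "water")
  for (sc in unique(values$scanner)) {
    v <- values[values$scanner == sc, ]
    if (!all(required %in% v$material))
      stop("material table for ", sc, " is missing materials", call. = FALSE)
    hu <- v$mean_hu[match(required, v$material)]
    if (any(diff(hu) <= 0))
      stop("material HU ordering violated for ", sc, call. = FALSE)
  }
  values
}

#' Look up a material HU value
#' @param materials a [material_table()].
#' @param scanner scanner label.
#' @param material material name.
#' @return scalar HU.
#' @export
material_hu <- function(materials, scanner, material) {
  hit <- materials$mean_hu[materials$scanner == scanner &
                             materials$material == material]
  if (length(hit) != 1)
    stop("unknown material '", material, "' for scanner '", scanner, "'",
         call. = FALSE)
  hit
}

#' Per-dose noise calibration points
#'
#' Mean lung-parenchyma image noise (HU) at the five study dose levels for
#' both scanner models; these points drive [fit_noise_model()].
#'
#' @return data frame with columns `scanner`, `dose_mGy`, `sigma_hu`.
#' @export
noise_calibration_points <- function() {
  data.frame(
    scanner = rep(c("EIDCT", "PCCT"), each = 5),
    dose_mGy = rep(c(1.6, 2.4, 4.9, 9.8, 20.4), 2),
    sigma_hu = c(134.4, 117.2, 88.2, 65.9, 47.2,
                 116.9, 103.5, 76.8, 57.9, 45.8),
    stringsAsFactors = FALSE
  )
}

#' Canonical lesion specifications
#'
#' The six study lesions: type (solid, part-solid, ground-glass), size class,
#' maximum 3D diameter (mm) and target mean intensity (HU), with their
#' phantom assignment and angular sector.  Lesions 1-4 occupy quarter
#' sectors of phantom 1; lesions 5-6 occupy half sectors of phantom 2.
#'
#' @return data frame, one row per lesion.
#' @export
lesion_specs <- function() {
  specs <- data.frame(
    lesion_id = 1:6,
    lesion_type = c("part_solid", "part_solid", "solid", "solid",
                    "ground_glass", "ground_glass"),
    size_class = c("small", "large", "small", "large", "small", "large"),
    max_3d_diameter = c(36.2, 62.8, 23.5, 43.1, 22.9, 48.6),
    mean_intensity = c(-560.9, -614.6, -164.8, -94.8, -747.4, -734.6),
    sector = c("quarter", "quarter", "quarter", "quarter", "half", "half"),
    phantom_id = c(1L, 1L, 1L, 1L, 2L, 2L),
    sector_angle = c(135, 45, 315, 225, 270, 90),
    stringsAsFactors = FALSE
  )
  stopifnot(all(specs$max_3d_diameter > 0))
  specs
}

#' Phantom geometry specifications
#'
#' Two cylindrical phantoms: phantom 1 (diameter 200 mm, height 32 mm,
#' four lesions) and phantom 2 (diameter 150 mm, height 40 mm, two lesions,
#' extended by a water-equivalent ring).  Both sit inside a solid-water
#' outer ring (230 mm assembly diameter) emulating the body-sized holder.
#'
#' @param lesions a [lesion_specs()] table (possibly subset).
#' @return list of phantom spec lists with elements `phantom_id`, `diameter`,
#'   `height`, `ring_outer_diameter`, `lesion_center_radius`, `lesions`
#'   (rows of `lesions`), `include_water_roi`.
#' @export
phantom_specs <- function(lesions = lesion_specs()) {
  make <- function(id, diameter, height, d_center, water_roi) {
    les <- lesions[lesions$phantom_id == id, , drop = FALSE]
    list(phantom_id = id, diameter = diameter, height = height,
         ring_outer_diameter = 230, lesion_center_radius = d_center,
         lesions = les, include_water_roi = water_roi)
  }
  specs <- list(make(1L, 200, 32, 58, TRUE), make(2L, 150, 40, 37.5, FALSE))
  specs[vapply(specs, function(s) nrow(s$lesions) > 0, logical(1))]
}

#' In-plane semi-axes of a lesion ellipsoid
#'
#' Lesions are rendered as ellipsoids whose largest (tangential, in-plane)
#' semi-axis equals half the maximum 3D diameter; the radial in-plane
#' semi-axis is 0.75 of that, and the axial semi-axis is capped by the
#' phantom height.
#'
#' @param lesion one row of [lesion_specs()].
#' @param height phantom height in mm.
#' @return named numeric: `a` (tangential), `b` (radial), `c` (axial), mm.
#' @export
lesion_axes <- function(lesion, height) {
  a <- lesion$max_3d_diameter / 2
  b <- 0.75 * a
  c_ax <- min(0.45 * a, height / 2 - 3)
  c(a = a, b = b, c = c_ax)
}
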