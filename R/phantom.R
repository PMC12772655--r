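#' Construct an image volume object
#'
#' A light container for a 3D HU grid with voxel spacing and scan metadata.
#'
#' @param data 3D numeric array (HU).
#' @param spacing voxel spacing (x, y, z) in mm.
#' @param origin physical position of the first voxel centre, mm.
#' @param scanner,dose_mGy,repetition,seed scan metadata (optional).
#' @return object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing, origin = c(0, 0, 0), scanner = NA_character_,
                      dose_mGy = NA_real_, repetition = NA_integer_,
                      seed = NA_integer_) {
  stopifnot(length(dim(data)) == 3, all(spacing > 0), all(is.finite(spacing)))
  if (any(dim(data) < 3)) stop("volume must be at least 3 voxels per axis")
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), scanner = scanner,
                 dose_mGy = dose_mGy, repetition = repetition, seed = seed),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s  spacing %s mm  scanner=%s dose=%s rep=%s\n",
              paste(dim(x$data), collapse = "x"),
              paste(x$spacing, collapse = "x"), x$scanner,
              x$dose_mGy, x$repetition))
  invisible(x)
}

#' Construct a label mask aligned with a volume
#'
#' @param data 3D integer array of region labels.
#' @param spacing voxel spacing (mm).
#' @param legend named integer vector mapping label value to region name.
#' @return object of class `ct_mask`.
#' @export
ct_mask <- function(data, spacing, legend) {
  stopifnot(length(dim(data)) == 3)
  structure(list(data = data, spacing = as.numeric(spacing), legend = legend),
            class = "ct_mask")
}

#' Voxel-centre coordinate axes of a phantom grid
#' @keywords internal
grid_axes <- function(dims, spacing) {
  lapply(1:3, function(ax) (seq_len(dims[ax]) - (dims[ax] + 1) / 2) * spacing[ax])
}

#' Band-limited random texture field
#'
#' Smoothed white noise, optionally high-pass filtered (difference of
#' Gaussians) so that structure below a given scale carries all the power;
#' normalized to unit standard deviation.
#'
#' @param dims grid dimensions.
#' @param spacing voxel spacing, mm.
#' @param corr_mm correlation length (mm); the Gaussian smoothing kernel
#'   SD is half this value.
#' @param highpass_mm if finite, remove structure smoother than this scale.
#' @param seed integer seed.
#' @return 3D array with unit SD and zero mean.
#' @export
texture_field <- function(dims, spacing, corr_mm = 2, highpass_mm = 8,
                          seed = 1L) {
  w <- with_seed(seed, array(rnorm(prod(dims)), dim = dims))
  s1 <- corr_mm / 2 / spacing
  f <- cpp_sep_gauss3d(as.numeric(w), as.integer(dims), as.numeric(s1))
  if (is.finite(highpass_mm) && highpass_mm > 0) {
    s2 <- highpass_mm / 2 / spacing
    f <- f - cpp_sep_gauss3d(f, as.integer(dims), as.numeric(s2))
  }
  f <- f - mean(f)
  f <- f / sd(f)
  array(f, dim = dims)
}

#' Part-solid core volume fraction
#'
#' Volume fraction of the dense (solid-material) core needed for the
#' lesion mask mean to equal the target intensity when the shell is
#' rendered at the part-solid material value (the HU that ROIs placed in
#' the homogeneous part of such lesions measure).
#'
#' @param target target lesion mean HU.
#' @param hu_solid,hu_shell solid-core and shell material HU.
#' @return fraction in (0, 1).
#' @export
part_solid_core_fraction <- function(target, hu_solid, hu_shell) {
  f <- (target - hu_shell) / (hu_solid - hu_shell)
  if (!is.finite(f) || f <= 0 || f >= 1)
    stop("part-solid core fraction out of range; check material table",
         call. = FALSE)
  f
}

#' Rasterize a digital lung phantom
#'
#' Renders a noise-free phantom volume and its ground-truth label mask.
#' The cylinder interior is lung parenchyma with low-amplitude band-passed
#' texture; each lesion is an ellipsoid at its sector centroid rendered at
#' its target mean HU (part-solid lesions as a solid-HU core inside a
#' shell at the part-solid material HU, core fraction solved so the mask
#' mean matches the lesion specification); the
#' surrounding ring is solid water; outside is air at -1000 HU.
#' Lesion mask means are mean-matched exactly to the lesion specification.
#'
#' @param spec one element of [phantom_specs()].
#' @param materials a [material_table()].
#' @param scanner scanner label ("EIDCT" or "PCCT").
#' @param spacing voxel spacing (x, y, z) mm; default `c(0.5, 0.5, 1)`.
#' @param texture list with `parenchyma_sd`, `lesion_sd` (HU), `corr_mm`,
#'   `highpass_mm`; set the SDs to 0 for piecewise-constant output.
#' @param seed texture seed (shared across scanners so both scanner models
#'   image the "same" phantom pattern).
#' @return list with elements `volume` (a [ct_volume()]) and `mask`
#'   (a [ct_mask()]); lesion labels are `10 + lesion_id`.
#' @export
rasterize_phantom <- function(spec, materials, scanner,
                              spacing = c(0.5, 0.5, 1),
                              texture = list(parenchyma_sd = 20,
                                             lesion_sd = 15,
                                             corr_mm = 2, highpass_mm = 8),
                              seed = 1L) {
  stopifnot(all(spacing > 0))
  r_phantom <- spec$diameter / 2
  r_outer <- spec$ring_outer_diameter / 2
  fov <- 2 * r_outer + 10 # 5 mm air margin
  dims <- c(ceiling(fov / spacing[1]), ceiling(fov / spacing[2]),
            max(3L, round(spec$height / spacing[3])))
  ax <- grid_axes(dims, spacing)
  x <- ax[[1]]; y <- ax[[2]]; z <- ax[[3]]
  r2 <- outer(x^2, y^2, "+") # nx x ny

  hu_par <- material_hu(materials, scanner, "lung_parenchyma")
  hu_wat <- material_hu(materials, scanner, "water")
  hu_sol <- material_hu(materials, scanner, "solid")
  hu_shell <- material_hu(materials, scanner, "part_solid")

  in_cyl2d <- r2 <= r_phantom^2
  in_ring2d <- r2 > r_phantom^2 & r2 <= r_outer^2

  vol <- array(-1000, dim = dims)
  lab <- array(0L, dim = dims)
  cyl_idx <- which(in_cyl2d)
  ring_idx <- which(in_ring2d)
  nxy <- dims[1] * dims[2]
  for (k in seq_len(dims[3])) {
    off <- (k - 1) * nxy
    vol[off + cyl_idx] <- hu_par
    vol[off + ring_idx] <- hu_wat
    lab[off + cyl_idx] <- 1L
    lab[off + ring_idx] <- 2L
  }

  tex_amp_par <- if (is.null(texture$parenchyma_sd)) 0 else texture$parenchyma_sd
  tex_amp_les <- if (is.null(texture$lesion_sd)) 0 else texture$lesion_sd
  tex <- NULL
  if (tex_amp_par > 0 || tex_amp_les > 0) {
    tex <- texture_field(dims, spacing, corr_mm = texture$corr_mm,
                         highpass_mm = texture$highpass_mm, seed = seed)
  }
  if (tex_amp_par > 0) {
    par_mask <- lab == 1L
    vol[par_mask] <- vol[par_mask] + tex_amp_par * tex[par_mask]
  }

  for (i in seq_len(nrow(spec$lesions))) {
    les <- spec$lesions[i, ]
    axes <- lesion_axes(les, spec$height)
    validate_lesion_geometry(les, axes, spec)
    theta <- les$sector_angle * pi / 180
    cx <- spec$lesion_center_radius * cos(theta)
    cy <- spec$lesion_center_radius * sin(theta)
    ur <- c(cos(theta), sin(theta))    # radial unit vector
    ut <- c(-sin(theta), cos(theta))   # tangential unit vector
    # bounding box in grid indices
    half <- max(axes["a"], axes["b"])
    xi <- which(x >= cx - half & x <= cx + half)
    yi <- which(y >= cy - half & y <= cy + half)
    zi <- which(abs(z) <= axes["c"])
    dxm <- outer(x[xi] - cx, rep(1, length(yi)))
    dym <- outer(rep(1, length(xi)), y[yi] - cy)
    tco <- dxm * ut[1] + dym * ut[2]
    rco <- dxm * ur[1] + dym * ur[2]
    e2d <- (tco / axes["a"])^2 + (rco / axes["b"])^2
    lab_val <- 10L + les$lesion_id
    core_scale <- NA_real_
    if (les$lesion_type == "part_solid") {
      f <- part_solid_core_fraction(les$mean_intensity, hu_sol, hu_shell)
      core_scale <- f^(1 / 3)
    }
    sel_all <- integer(0)
    for (k in zi) {
      zterm <- (z[k] / axes["c"])^2
      inside <- which(e2d + zterm <= 1)
      if (!length(inside)) next
      gidx <- (k - 1) * nxy +
        (rep(xi, times = length(yi))[inside] - 1) +
        (rep(yi, each = length(xi))[inside] - 1) * dims[1] + 1
      lab[gidx] <- lab_val
      if (les$lesion_type == "part_solid") {
        in_core <- (e2d[inside] + zterm) <= core_scale^2
        vol[gidx] <- ifelse(in_core, hu_sol, hu_shell)
      } else {
        vol[gidx] <- les$mean_intensity
      }
      sel_all <- c(sel_all, gidx)
    }
    if (tex_amp_les > 0) {
      t_l <- tex[sel_all]
      vol[sel_all] <- vol[sel_all] + tex_amp_les * (t_l - mean(t_l))
    }
    # exact mean matching to the lesion specification
    vol[sel_all] <- vol[sel_all] + (les$mean_intensity - mean(vol[sel_all]))
  }

  legend <- c(air = 0L, lung_parenchyma = 1L, water = 2L)
  if (nrow(spec$lesions) > 0)
    legend <- c(legend, setNames(10L + spec$lesions$lesion_id,
                                 paste0("lesion_", spec$lesions$lesion_id)))
  list(volume = ct_volume(vol, spacing, scanner = scanner, seed = seed),
       mask = ct_mask(lab, spacing, legend))
}

#' Check that a lesion ellipsoid fits inside its sector
#' @keywords internal
validate_lesion_geometry <- function(les, axes, spec) {
  r_phantom <- spec$diameter / 2
  d <- spec$lesion_center_radius
  half_angle <- if (les$sector == "quarter") pi / 4 else pi / 2
  if (d + axes["b"] > r_phantom - 2)
    stop("lesion ", les$lesion_id, " exceeds phantom radius", call. = FALSE)
  if (axes["a"] >= d || asin(axes["a"] / d) > half_angle)
    stop("lesion ", les$lesion_id, " larger than its sector", call. = FALSE)
  if (axes["c"] <= 0 || 2 * axes["c"] > spec$height)
    stop("lesion ", les$lesion_id, " exceeds phantom height", call. = FALSE)
  invisible(TRUE)
}
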