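#' Fixed-bin-width gray-level discretization
#'
#' Assigns every in-mask voxel an integer gray level
#' `floor((HU - min) / bin_width) + 1`, with bin edges anchored at the
#' in-mask minimum.
#'
#' @param volume a [ct_volume()] or 3D array.
#' @param mask logical/integer 3D array (nonzero = in mask) or [ct_mask()].
#' @param bin_width bin width in HU (default 25).
#' @return object of class `discretized_roi`: list with `levels` (3D
#'   integer array, 0 outside mask), `ng`, `bin_width`, `spacing`,
#'   `n_voxels`, `degenerate` (single level).
#' @export
discretize <- function(volume, mask, bin_width = 25) {
  stopifnot(bin_width > 0)
  arr <- if (inherits(volume, "ct_volume")) volume$data else volume
  spacing <- if (inherits(volume, "ct_volume")) volume$spacing else c(1, 1, 1)
  m <- if (inherits(mask, "ct_mask")) mask$data != 0 else mask != 0
  stopifnot(identical(dim(arr), dim(m)))
  if (!any(m)) stop("empty mask", call. = FALSE)
  lev <- array(0L, dim = dim(arr))
  vals <- arr[m]
  lev[m] <- as.integer(floor((vals - min(vals)) / bin_width)) + 1L
  ng <- max(lev)
  structure(list(levels = lev, ng = ng, bin_width = bin_width,
                 spacing = spacing, n_voxels = sum(m),
                 degenerate = ng == 1L),
            class = "discretized_roi")
}

#' The 13 unique 3D direction offsets at distance 1
#' @return integer matrix, one offset per row.
#' @export
direction_offsets_13 <- function() {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] == 0), ]
  keep <- apply(offs, 1, function(o) {
    o[3] > 0 || (o[3] == 0 && (o[2] > 0 || (o[2] == 0 && o[1] > 0)))
  })
  unname(offs[keep, , drop = FALSE])
}

#' First-order intensity features
#'
#' The 18 first-order features on in-mask voxel intensities: energy, total
#' energy (voxel-volume scaled), entropy and uniformity (on the
#' fixed-bin-width histogram), minimum, 10th/90th percentiles, maximum,
#' mean, median, interquartile range, range, mean absolute deviation,
#' robust MAD (10-90 percentile subset), RMS, skewness, kurtosis
#' (non-excess), variance (population).
#'
#' @param volume a [ct_volume()] or 3D array.
#' @param mask mask array or [ct_mask()].
#' @param bin_width histogram bin width for entropy/uniformity (HU).
#' @return named numeric vector of 18 features.
#' @export
first_order_features <- function(volume, mask, bin_width = 25) {
  arr <- if (inherits(volume, "ct_volume")) volume$data else volume
  spacing <- if (inherits(volume, "ct_volume")) volume$spacing else c(1, 1, 1)
  m <- if (inherits(mask, "ct_mask")) mask$data != 0 else mask != 0
  x <- arr[m]
  n <- length(x)
  if (n < 1) stop("empty mask", call. = FALSE)
  vx <- prod(spacing)
  p <- tabulate(as.integer(floor((x - min(x)) / bin_width)) + 1L)
  p <- p[p > 0] / n
  q <- quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE, type = 7)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  sub <- x[x >= q[1] & x <= q[5]]
  skew <- if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((x - mu)^4) / m2^2 else 0
  c(Energy = sum(x^2),
    TotalEnergy = vx * sum(x^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(x),
    `10Percentile` = q[1],
    `90Percentile` = q[5],
    Maximum = max(x),
    Mean = mu,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(sub - mean(sub))),
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = skew,
    Kurtosis = kurt,
    Variance = m2,
    Uniformity = sum(p^2))
}

#' Mesh- and moment-based shape features
#'
#' The 14 shape features of a binary lesion mask: mesh volume and surface
#' area from a marching-tetrahedra iso-surface of the lightly smoothed
#' mask indicator (0.5 level), voxel volume, surface/volume ratio,
#' sphericity, maximum 3D diameter and per-plane maximum 2D diameters
#' (largest pairwise surface-voxel distances), principal axis lengths from
#' second-moment eigenvalues, elongation and flatness.
#'
#' @param mask mask array or [ct_mask()] (nonzero = lesion).
#' @param spacing voxel spacing (mm); taken from the mask if available.
#' @return named numeric vector of 14 features.
#' @export
shape_features <- function(mask, spacing = NULL) {
  m <- if (inherits(mask, "ct_mask")) mask$data != 0 else mask != 0
  if (is.null(spacing))
    spacing <- if (inherits(mask, "ct_mask")) mask$spacing else c(1, 1, 1)
  idx <- which(m, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0) stop("empty mask", call. = FALSE)
  vx <- prod(spacing)
  voxvol <- n * vx

  # crop with 2-voxel pad, smooth the indicator, extract iso-surface
  lo <- pmax(apply(idx, 2, min) - 2L, 1L)
  hi <- pmin(apply(idx, 2, max) + 2L, dim(m))
  sub <- m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  dims <- dim(sub)
  f <- array(as.numeric(sub), dim = dims)
  if (n > 1) {
    sig <- 0.5 / spacing # 0.5 mm smoothing
    f <- array(cpp_sep_gauss3d(as.numeric(f), as.integer(dims),
                               as.numeric(sig)), dim = dims)
  }
  av <- cpp_mesh_area_volume(as.numeric(f), as.integer(dims),
                             as.numeric(spacing), 0.5)
  area <- av[1]; meshvol <- av[2]
  if (n < 8 || meshvol <= 0 || area <= 0) {
    # voxel-based fallback for degenerate masks
    meshvol <- voxvol
    area <- surface_area_voxel(m, spacing)
    warning("degenerate mask: voxel-based shape fallback", call. = FALSE)
  }
  sphericity <- (pi^(1 / 3)) * (6 * meshvol)^(2 / 3) / area

  pts <- surface_voxel_points(m, spacing)
  max3d <- cpp_max_pairdist(extreme_points(pts))
  max2d <- function(keep) {
    # largest in-plane diameter over slices of the dropped axis
    drop_ax <- setdiff(1:3, keep)
    best <- 0
    for (v in unique(pts[, drop_ax])) {
      sl <- pts[pts[, drop_ax] == v, keep, drop = FALSE]
      if (nrow(sl) >= 2)
        best <- max(best, cpp_max_pairdist(extreme_points(sl)))
    }
    best
  }
  # physical coordinates of all mask voxels for the moment tensor
  phys <- sweep(idx, 2, spacing, "*")
  ctr <- colMeans(phys)
  cen <- sweep(phys, 2, ctr, "-")
  ev <- if (n > 1) sort(eigen(crossprod(cen) / n, symmetric = TRUE,
                              only.values = TRUE)$values,
                        decreasing = TRUE) else c(0, 0, 0)
  ev <- pmax(ev, 0)
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2]); least <- 4 * sqrt(ev[3])
  c(MeshVolume = meshvol,
    VoxelVolume = voxvol,
    SurfaceArea = area,
    SurfaceVolumeRatio = area / meshvol,
    Sphericity = sphericity,
    Maximum3DDiameter = max3d,
    Maximum2DDiameterSlice = max2d(c(1, 2)),
    Maximum2DDiameterColumn = max2d(c(1, 3)),
    Maximum2DDiameterRow = max2d(c(2, 3)),
    MajorAxisLength = major,
    MinorAxisLength = minor,
    LeastAxisLength = least,
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0)
}

# physical coordinates of surface voxels (those with an exposed 6-face)
surface_voxel_points <- function(m, spacing) {
  d <- dim(m)
  pad <- array(FALSE, dim = d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  inner <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  nb <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  surf <- inner & !nb
  if (!any(surf)) surf <- inner
  idx <- which(surf, arr.ind = TRUE)
  sweep(idx, 2, spacing, "*")
}

# reduce a point set to per-column extremes along the first axis; the
# reduced set contains every convex-hull vertex, so pairwise maxima are
# preserved exactly
extreme_points <- function(pts) {
  if (nrow(pts) <= 2) return(pts)
  key <- apply(pts[, -1, drop = FALSE], 1, paste, collapse = "_")
  keep <- unlist(lapply(split(seq_len(nrow(pts)), key), function(ii) {
    v <- pts[ii, 1]
    unique(c(ii[which.min(v)], ii[which.max(v)]))
  }), use.names = FALSE)
  pts[keep, , drop = FALSE]
}

surface_area_voxel <- function(m, spacing) {
  d <- dim(m)
  pad <- array(FALSE, dim = d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  faces <- 0
  fa <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
          spacing[1] * spacing[2])
  sh <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
             c(0, 0, 1), c(0, 0, -1))
  total <- 0
  for (s in sh) {
    nb <- pad[(2:(d[1] + 1)) + s[1], (2:(d[2] + 1)) + s[2],
              (2:(d[3] + 1)) + s[3], drop = FALSE]
    dim(nb) <- d
    total <- total + sum(m & !nb) * fa[which(s != 0)]
  }
  total
}
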