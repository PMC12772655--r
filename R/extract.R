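#' Extract the full 107-feature radiomics vector
#'
#' 18 first-order + 14 shape + 24 GLCM + 16 GLRLM + 16 GLSZM + 14 GLDM +
#' 5 NGTDM features for one lesion measurement.  Feature names are
#' `<family>_<FeatureName>` and stable across runs.
#'
#' @param volume a [ct_volume()] (or 3D array with `spacing` given through
#'   a `ct_volume`).
#' @param mask binary mask (array or [ct_mask()]) selecting the lesion.
#' @param bin_width discretization bin width in HU (default 25).
#' @param shape optional precomputed [shape_features()] vector (the mask
#'   is identical across doses/repetitions, so shape can be cached).
#' @return named numeric vector of exactly 107 finite values.
#' @export
extract_all <- function(volume, mask, bin_width = 25, shape = NULL) {
  arr <- if (inherits(volume, "ct_volume")) volume$data else volume
  spacing <- if (inherits(volume, "ct_volume")) volume$spacing else c(1, 1, 1)
  m <- if (inherits(mask, "ct_mask")) mask$data != 0 else mask != 0
  if (!identical(dim(arr), dim(m)))
    stop("volume and mask are not aligned", call. = FALSE)
  # crop to the mask bounding box (plus 1 voxel) for texture speed
  idx <- which(m, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - 1L, 1L)
  hi <- pmin(apply(idx, 2, max) + 1L, dim(m))
  sub_v <- arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  sub_m <- m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]

  run_family <- function(name, fn) {
    out <- tryCatch(fn(), error = function(e)
      stop("feature family '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    out
  }
  vol_obj <- ct_volume(sub_v, spacing)
  fo <- run_family("firstorder", function()
    first_order_features(vol_obj, sub_m, bin_width = bin_width))
  sh <- if (is.null(shape)) run_family("shape", function()
    shape_features(sub_m, spacing)) else shape
  d <- discretize(vol_obj, sub_m, bin_width = bin_width)
  glcm <- run_family("glcm", function() glcm_features(d))
  glrlm <- run_family("glrlm", function() glrlm_features(d))
  glszm <- run_family("glszm", function() glszm_features(d))
  gldm <- run_family("gldm", function() gldm_features(d))
  ngtdm <- run_family("ngtdm", function() ngtdm_features(d))
  out <- c(setNames(fo, paste0("firstorder_", names(fo))),
           setNames(sh, paste0("shape_", names(sh))),
           setNames(glcm, paste0("glcm_", names(glcm))),
           setNames(glrlm, paste0("glrlm_", names(glrlm))),
           setNames(glszm, paste0("glszm_", names(glszm))),
           setNames(gldm, paste0("gldm_", names(gldm))),
           setNames(ngtdm, paste0("ngtdm_", names(ngtdm))))
  stopifnot(length(out) == 107)
  if (any(!is.finite(out)))
    stop("non-finite features: ",
         paste(names(out)[!is.finite(out)], collapse = ", "), call. = FALSE)
  out
}

#' Feature-family cardinalities of the extractor
#' @return named integer vector (18/14/24/16/16/14/5).
#' @export
feature_group_sizes <- function() {
  c(firstorder = 18L, shape = 14L, glcm = 24L, glrlm = 16L, glszm = 16L,
    gldm = 14L, ngtdm = 5L)
}
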