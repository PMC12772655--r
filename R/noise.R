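#' Fit a dose-dependent noise model
#'
#' Fits `sigma^2(D) = a / D + b` (quantum term plus electronic-noise floor)
#' to per-dose noise calibration points.  The fit minimizes the worst-case
#' relative deviation of `sigma(D)` from the calibration points (Chebyshev
#' criterion), started from the ordinary least-squares solution on
#' `sigma^2`; on exactly consistent inputs the OLS start is already exact
#' and is returned unchanged.
#'
#' @param dose_sigma_pairs data frame or matrix with columns dose (mGy) and
#'   sigma (HU).
#' @return object of class `noise_model`: list with `a` (HU^2 mGy), `b`
#'   (HU^2), `calibration` (input points with fitted values and relative
#'   residuals).
#' @export
fit_noise_model <- function(dose_sigma_pairs) {
  d <- as.numeric(dose_sigma_pairs[[1]])
  s <- as.numeric(dose_sigma_pairs[[2]])
  if (length(unique(d)) < 2) stop("need at least 2 distinct doses")
  if (any(d <= 0) || any(s <= 0)) stop("doses and sigmas must be positive")
  fit0 <- lm(I(s^2) ~ I(1 / d))
  a0 <- max(coef(fit0)[2], 1e-8)
  b0 <- max(coef(fit0)[1], 0)
  pred0 <- sqrt(pmax(a0 / d + b0, 0))
  worst <- function(p) {
    if (p[1] <= 0 || p[2] < 0) return(Inf)
    max(abs(sqrt(p[1] / d + p[2]) / s - 1))
  }
  if (worst(c(a0, b0)) > 1e-9 && length(d) > 2) {
    opt <- optim(c(a0, b0), worst, method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 20000))
    opt <- optim(opt$par, worst, method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 20000))
    a0 <- opt$par[1]; b0 <- opt$par[2]
  }
  fitted <- sqrt(a0 / d + b0)
  structure(list(a = unname(a0), b = unname(b0),
                 calibration = data.frame(dose_mGy = d, sigma_hu = s,
                                          fitted_sigma = fitted,
                                          rel_residual = fitted / s - 1)),
            class = "noise_model")
}

#' Evaluate a noise model
#' @param model a [fit_noise_model()] result.
#' @param dose dose in mGy (vectorized).
#' @return sigma in HU.
#' @export
noise_sigma <- function(model, dose) {
  stopifnot(inherits(model, "noise_model"), all(dose > 0))
  sqrt(model$a / dose + model$b)
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("<noise_model> sigma^2(D) = %.1f/D + %.1f  (max |rel resid| %.2f%%)\n",
              x$a, x$b, 100 * max(abs(x$calibration$rel_residual))))
  invisible(x)
}

#' Simulate a noisy CT acquisition
#'
#' Adds a zero-mean correlated Gaussian noise field to a noise-free truth
#' volume.  The field is white noise smoothed to the requested correlation
#' length and rescaled so that the *image* noise — the SD measured in the
#' reference parenchyma ROIs — matches the model's `sigma(dose)`: the
#' injected variance is `sigma(dose)^2` minus the ROI-scale variance the
#' truth texture already contributes.  Deterministic given the seed.
#'
#' @param truth a [ct_volume()] (noise-free).
#' @param mask matching [ct_mask()].
#' @param model a [fit_noise_model()] result.
#' @param scanner,dose,repetition condition labels; `dose` sets the target.
#' @param seed integer seed for the noise field.
#' @param rois optional ROI table from [place_rois()]; its parenchyma rows
#'   are used to calibrate the ROI-scale SD.  If `NULL`, the field is
#'   rescaled to the target SD globally.
#' @param corr_mm noise correlation length (mm), default 1.
#' @return a [ct_volume()] with noise added.
#' @export
simulate_scan <- function(truth, mask, model, scanner, dose, repetition,
                          seed, rois = NULL, corr_mm = 1) {
  stopifnot(inherits(truth, "ct_volume"), dose > 0)
  if (!is.null(mask) && !identical(dim(truth$data), dim(mask$data)))
    stop("volume and mask grids do not match", call. = FALSE)
  dims <- dim(truth$data)
  target <- noise_sigma(model, dose)

  roi_idx <- NULL
  if (!is.null(rois)) {
    par_rois <- rois[rois$roi_kind == "parenchyma", , drop = FALSE]
    if (nrow(par_rois) > 0)
      roi_idx <- lapply(seq_len(nrow(par_rois)), function(i)
        roi_voxel_indices(par_rois[i, ], dims, truth$spacing))
  }
  sigma_tex <- 0
  if (!is.null(roi_idx))
    sigma_tex <- mean(vapply(roi_idx, function(ix) sd(truth$data[ix]),
                             numeric(1)))
  target_noise <- sqrt(max(target^2 - sigma_tex^2, 0))
  if (target_noise <= 0) {
    out <- truth
    out$scanner <- scanner; out$dose_mGy <- dose
    out$repetition <- repetition; out$seed <- seed
    return(out)
  }
  field <- with_seed(seed, array(rnorm(prod(dims)), dim = dims))
  sig_vox <- corr_mm / 2 / truth$spacing
  field <- array(cpp_sep_gauss3d(as.numeric(field), as.integer(dims),
                                 as.numeric(sig_vox)), dim = dims)
  field <- field - mean(field)
  scale_ref <- if (!is.null(roi_idx)) {
    mean(vapply(roi_idx, function(ix) sd(field[ix]), numeric(1)))
  } else {
    sd(field)
  }
  field <- field * (target_noise / scale_ref)
  out <- truth
  out$data <- truth$data + field
  out$scanner <- scanner; out$dose_mGy <- dose
  out$repetition <- repetition; out$seed <- seed
  out
}
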