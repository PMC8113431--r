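#' Scanner calibration surrogate
#'
#' Collects the knobs of the acquisition/reconstruction emulation: the count
#' sensitivity (expected counts per SUV unit per minute per voxel), the
#' intrinsic point-spread FWHM, and the monotone map from the regularization
#' strength beta to the additional smoothing it buys. Penalized iterative
#' reconstruction is emulated, not implemented: larger beta means a wider
#' effective Gaussian kernel, which reproduces the qualitative
#' noise/resolution trade-off the method exercises.
#'
#' @param sensitivity expected counts per SUV unit per minute per voxel
#'   (> 0). The default (1.5) is calibrated so that the emulated 1-min
#'   image set shows a clinically realistic liver COV of roughly 10% after
#'   reconstruction; no absolute count calibration is available, so only
#'   noise orderings are meaningful.
#' @param psf_fwhm_mm intrinsic point-spread FWHM in mm.
#' @param beta_fwhm non-decreasing function mapping beta to extra Gaussian
#'   FWHM in mm; default `2 + beta / 250`.
#' @return a `scanner_calib` list.
#' @export
scanner_calib <- function(sensitivity = 1.5,
                          psf_fwhm_mm = 4.0,
                          beta_fwhm = function(beta) 2 + beta / 250) {
  stopifnot(sensitivity > 0, psf_fwhm_mm >= 0, is.function(beta_fwhm))
  probe <- beta_fwhm(c(100, 200, 300, 500, 700))
  if (any(diff(probe) < 0)) {
    stop("`beta_fwhm` must be non-decreasing in beta", call. = FALSE)
  }
  structure(list(sensitivity = sensitivity, psf_fwhm_mm = psf_fwhm_mm,
                 beta_fwhm = beta_fwhm),
            class = "scanner_calib")
}

count_volume <- function(counts, voxel_size, duration_min, sensitivity) {
  stopifnot(duration_min >= 0, all(counts >= 0))
  out <- pet_volume(counts, voxel_size, units = "counts")
  attr(out, "duration_min") <- duration_min
  attr(out, "sensitivity") <- sensitivity
  out
}

#' @rdname simulate_frame
#' @export
frame_duration <- function(frame) attr(frame, "duration_min")

#' Simulate one acquisition frame
#'
#' Each voxel's count is an independent Poisson draw with mean
#' `activity x duration x sensitivity` — a statistical stand-in for the
#' scanner acquisition. Identical inputs and seed give identical output.
#'
#' @param act activity volume in SUV units (from [build_phantom()]).
#' @param duration frame duration in minutes (>= 0).
#' @param calib a [scanner_calib()].
#' @param seed integer seed.
#' @return a count volume (`pet_volume` in counts, with `duration_min` and
#'   `sensitivity` attributes).
#' @export
simulate_frame <- function(act, duration, calib, seed) {
  stopifnot(inherits(act, "pet_volume"), inherits(calib, "scanner_calib"))
  if (duration < 0) stop("`duration` must be >= 0", call. = FALSE)
  lam <- as.numeric(act) * duration * calib$sensitivity
  counts <- withr::with_seed(seed, stats::rpois(length(lam), lam))
  count_volume(array(counts, dim(act)), voxel_size(act), duration,
               calib$sensitivity)
}

#' Split one frame into equal sub-frames
#'
#' Emulates list-mode sub-interval reconstruction: each voxel's counts are
#' partitioned across `n_intervals` intervals by a multinomial draw with
#' equal probabilities, so the per-voxel sum over the sub-frames equals the
#' parent frame exactly and each sub-frame has duration
#' `duration / n_intervals`. Sub-frames from one parent are therefore
#' negatively correlated at fixed total, as sub-intervals of one real
#' acquisition are.
#'
#' @param frame a count volume from [simulate_frame()].
#' @param n_intervals number of equal intervals (>= 1).
#' @param seed integer seed.
#' @return list of `n_intervals` count volumes.
#' @export
split_frame <- function(frame, n_intervals, seed) {
  stopifnot(inherits(frame, "pet_volume"))
  if (n_intervals < 1) stop("`n_intervals` must be >= 1", call. = FALSE)
  n_intervals <- as.integer(n_intervals)
  if (n_intervals == 1L) return(list(frame))
  dur <- frame_duration(frame) / n_intervals
  sens <- attr(frame, "sensitivity")
  withr::with_seed(seed, {
    rem <- as.integer(frame)
    out <- vector("list", n_intervals)
    for (i in seq_len(n_intervals - 1L)) {
      xi <- stats::rbinom(length(rem), rem, 1 / (n_intervals - i + 1))
      rem <- rem - xi
      out[[i]] <- count_volume(array(xi, dim(frame)), voxel_size(frame),
                               dur, sens)
    }
    out[[n_intervals]] <- count_volume(array(rem, dim(frame)),
                                       voxel_size(frame), dur, sens)
    out
  })
}

#' Extract a shorter sub-frame by binomial thinning
#'
#' Emulates reconstructing the first `duration` minutes of a longer
#' list-mode frame: each count is kept independently with probability
#' `duration / frame_duration(frame)`.
#'
#' @inheritParams split_frame
#' @param duration target duration in minutes, in `(0, frame duration]`.
#' @return a count volume.
#' @export
subframe <- function(frame, duration, seed) {
  p <- duration / frame_duration(frame)
  if (p <= 0 || p > 1) {
    stop("`duration` must be in (0, parent frame duration]", call. = FALSE)
  }
  if (p == 1) return(frame)
  counts <- withr::with_seed(
    seed, stats::rbinom(length(frame), as.integer(frame), p))
  count_volume(array(counts, dim(frame)), voxel_size(frame), duration,
               attr(frame, "sensitivity"))
}

#' Emulate a regularized reconstruction
#'
#' Converts counts back to activity concentration
#' (`counts / (duration x sensitivity)`), applies Gaussian smoothing whose
#' FWHM combines the intrinsic PSF with the beta-mapped regularization
#' smoothing in quadrature, and scales to SUV by the standard convention.
#' The smoother uses half-sample symmetric boundaries with a normalized
#' kernel, so a constant field is a fixed point and the voxel sum is
#' conserved.
#'
#' @inheritParams split_frame
#' @param beta regularization-strength surrogate (maps to smoothing FWHM via
#'   the calibration).
#' @param calib a [scanner_calib()].
#' @param weight_kg,injected_MBq subject body weight and injected activity
#'   used for the SUV scaling.
#' @return a `pet_volume` in SUV units, same shape as the input frame.
#' @export
emulate_reconstruction <- function(frame, beta, calib,
                                   weight_kg = 70, injected_MBq = 280) {
  stopifnot(inherits(frame, "pet_volume"), inherits(calib, "scanner_calib"))
  dur <- frame_duration(frame)
  sens <- attr(frame, "sensitivity") %||% calib$sensitivity
  if (is.null(dur) || dur <= 0) {
    stop("frame duration must be positive", call. = FALSE)
  }
  if (sens <= 0) stop("sensitivity must be positive", call. = FALSE)
  conc_suv <- as.numeric(frame) / (dur * sens)
  fwhm <- sqrt(calib$psf_fwhm_mm^2 + calib$beta_fwhm(beta)^2)
  sm <- smooth_gaussian(array(conc_suv, dim(frame)), voxel_size(frame), fwhm)
  # express as kBq/mL for the given subject, then convert back to SUV
  conc_kbq <- sm * injected_MBq / weight_kg
  suv <- suv_convert(pet_volume(conc_kbq, voxel_size(frame), "kBq/mL"),
                     weight_kg = weight_kg, injected_MBq = injected_MBq)
  attr(suv, "beta") <- beta
  attr(suv, "duration_min") <- dur
  suv
}

#' Separable Gaussian smoothing with mass-conserving boundaries
#'
#' @param values 3D array.
#' @param voxel_size mm per voxel along (row, col, slice).
#' @param fwhm_mm isotropic full width at half maximum in mm.
#' @return smoothed array of the same shape.
#' @export
smooth_gaussian <- function(values, voxel_size, fwhm_mm) {
  d <- dim(values)
  stopifnot(length(d) == 3L, fwhm_mm >= 0)
  if (fwhm_mm == 0) return(values)
  sigma_vox <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / voxel_size
  array(gauss_smooth3d(as.numeric(values), as.integer(d), sigma_vox), d)
}
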