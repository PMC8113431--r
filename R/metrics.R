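#' Convert activity concentration to SUV
#'
#' Standard uptake value with the universal convention
#' `SUV = concentration (kBq/mL) x body weight (kg) / injected activity
#' (MBq)` (1 g/mL tissue density, no decay correction): a subject injected
#' at exactly 4 MBq/kg with uniformly distributed tracer has SUV 1.0.
#'
#' @param concentration volume (or array) in kBq/mL.
#' @param weight_kg body weight in kg (> 0).
#' @param injected_MBq injected activity in MBq (> 0).
#' @return the volume in SUV units.
#' @export
suv_convert <- function(concentration, weight_kg, injected_MBq) {
  if (weight_kg <= 0) stop("`weight_kg` must be positive", call. = FALSE)
  if (injected_MBq <= 0) stop("`injected_MBq` must be positive", call. = FALSE)
  vals <- unclass(concentration) * weight_kg / injected_MBq
  if (inherits(concentration, "pet_volume")) {
    pet_volume(vals, voxel_size(concentration), units = "SUV")
  } else {
    vals
  }
}

# normalize a VOI (logical array or linear/array indices) to linear indices
voi_indices <- function(voi, dims) {
  if (is.logical(voi)) {
    idx <- which(voi)
  } else if (is.matrix(voi) && ncol(voi) == 3L) {
    idx <- voi[, 1] + dims[1] * (voi[, 2] - 1L) +
      dims[1] * dims[2] * (voi[, 3] - 1L)
  } else {
    idx <- as.integer(voi)
  }
  if (length(idx) == 0L) stop("VOI is empty", call. = FALSE)
  if (any(idx < 1L) || any(idx > prod(dims))) {
    stop("VOI indices fall outside the volume", call. = FALSE)
  }
  idx
}

#' Lesion SUV metrics
#'
#' `suv_max()` is the maximum voxel value within the VOI. `suv_peak()` is
#' the maximum, over candidate sphere centres inside the VOI, of the mean
#' voxel value within a 1 cm3 sphere (radius ~6.2 mm, rasterized by
#' voxel-centre inclusion); by construction `suv_peak() <= suv_max()` never
#' fails on the same VOI... the mean of a region cannot exceed its maximum.
#'
#' @param volume a `pet_volume` (or 3D array) in SUV units.
#' @param voi lesion VOI: logical mask, linear voxel indices, or an
#'   `n x 3` matrix of voxel coordinates.
#' @return a single SUV value.
#' @export
suv_max <- function(volume, voi) {
  max(unclass(volume)[voi_indices(voi, dim(volume))])
}

#' @rdname suv_max
#' @param voxel_size mm per voxel (taken from the volume when available).
#' @param center_on `"max_mean"` (default: sphere centred to maximize the
#'   sphere mean over all candidate centres in the VOI) or `"suvmax"`
#'   (sphere centred on the hottest voxel).
#' @param sphere_volume_mm3 sphere volume (default 1 cm3 = 1000 mm3).
#' @export
suv_peak <- function(volume, voi,
                     voxel_size = attr(volume, "voxel_size"),
                     center_on = c("max_mean", "suvmax"),
                     sphere_volume_mm3 = 1000) {
  center_on <- match.arg(center_on)
  d <- dim(volume)
  vs <- voxel_size %||% c(2.7, 2.7, 2.8)
  idx <- voi_indices(voi, d)
  x <- unclass(volume)

  r_mm <- (3 * sphere_volume_mm3 / (4 * pi))^(1 / 3)
  rr <- ceiling(r_mm / vs)
  off <- as.matrix(expand.grid(i = -rr[1]:rr[1], j = -rr[2]:rr[2],
                               k = -rr[3]:rr[3]))
  off <- off[rowSums(sweep(off, 2, vs, `*`)^2) <= r_mm^2, , drop = FALSE]

  centers <- arrayInd(idx, d)
  if (center_on == "suvmax") {
    centers <- centers[which.max(x[idx]), , drop = FALSE]
  }
  best <- -Inf
  for (ci in seq_len(nrow(centers))) {
    pts <- sweep(off, 2, centers[ci, ], `+`)
    if (any(pts < 1L) || any(pts[, 1] > d[1]) || any(pts[, 2] > d[2]) ||
        any(pts[, 3] > d[3])) {
      next  # sphere would leave the volume at this candidate
    }
    m <- mean(x[pts[, 1] + d[1] * (pts[, 2] - 1L) +
                  d[1] * d[2] * (pts[, 3] - 1L)])
    if (m > best) best <- m
  }
  if (!is.finite(best)) {
    stop("the 1 cm3 sphere exceeds the volume bounds for every candidate ",
         "centre", call. = FALSE)
  }
  best
}

#' Liver ROI set for the noise protocol
#'
#' Three circular ROIs of 6 cm diameter on transaxial slices `i`, `i + 2`
#' and `i + 4` (one slice in between), defined once per subject on the
#' reference image set and copied unchanged to the others.
#'
#' @param center in-plane circle centre, voxel coordinates `(row, col)`.
#' @param start_slice slice index of the first circle.
#' @param diameter_mm circle diameter (default 60 mm).
#' @return a `liver_roi_set`.
#' @export
liver_roi_set <- function(center, start_slice, diameter_mm = 60) {
  stopifnot(length(center) == 2L, start_slice >= 1, diameter_mm > 0)
  structure(list(center = as.numeric(center),
                 slices = as.integer(start_slice) + c(0L, 2L, 4L),
                 diameter_mm = diameter_mm),
            class = "liver_roi_set")
}

#' @rdname liver_roi_set
#' @param phantom an activity volume from [build_phantom()]; the ROI set is
#'   centred on the liver mask's centroid.
#' @export
liver_rois_from_phantom <- function(phantom) {
  masks <- phantom_masks(phantom)
  if (is.null(masks$liver)) stop("phantom has no liver mask", call. = FALSE)
  co <- arrayInd(masks$liver, dim(phantom))
  ctr <- round(colMeans(co))
  liver_roi_set(ctr[1:2], ctr[3] - 2L)
}

#' Liver coefficient of variation
#'
#' For each of the three circles the COV is the ratio of the voxel-value
#' standard deviation (population form) to the mean; the three measurements
#' are averaged. Voxel centres strictly inside the circle diameter are
#' included. COV is an objective noise measure: lower is less noise.
#'
#' @param volume a `pet_volume` in SUV units.
#' @param rois a [liver_roi_set()].
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return the averaged COV (dimensionless, >= 0).
#' @export
cov_liver <- function(volume, rois, sd_type = c("population", "sample")) {
  stopifnot(inherits(rois, "liver_roi_set"))
  sd_type <- match.arg(sd_type)
  d <- dim(volume)
  vs <- voxel_size(volume) %||% c(2.7, 2.7, 2.8)
  r <- rois$diameter_mm / 2
  di <- (seq_len(d[1]) - rois$center[1]) * vs[1]
  dj <- (seq_len(d[2]) - rois$center[2]) * vs[2]
  inside <- outer(di^2, dj^2, `+`) < r^2
  if (!any(inside)) stop("ROI circle covers no voxels", call. = FALSE)
  if (any(rois$slices < 1L) || any(rois$slices > d[3])) {
    stop("ROI slices fall outside the volume", call. = FALSE)
  }
  x <- unclass(volume)
  covs <- vapply(rois$slices, function(z) {
    v <- x[, , z][inside]
    m <- mean(v)
    if (m <= 0) {
      stop("degenerate ROI: non-positive mean on slice ", z, call. = FALSE)
    }
    s <- if (sd_type == "population") {
      sqrt(mean((v - m)^2))
    } else {
      stats::sd(v)
    }
    s / m
  }, 1.0)
  mean(covs)
}

#' Per-subject quantitative metrics across image sets
#'
#' Computes SUVmax and SUVpeak for every lesion VOI and the liver COV, for
#' each image set, with the VOIs/ROIs defined once and applied unchanged to
#' all sets. One row per (image set, lesion).
#'
#' @param image_sets named list of `pet_volume`s (the image-set labels).
#' @param lesion_vois named list of lesion VOIs (see [suv_max()]).
#' @param rois a [liver_roi_set()].
#' @param subject subject identifier stamped on every row.
#' @return a tibble with columns `subject`, `image_set`, `lesion`,
#'   `suv_max`, `suv_peak`, `cov` (COV is subject-level: constant within an
#'   image set).
#' @export
evaluate_image_sets <- function(image_sets, lesion_vois, rois,
                                subject = "subject_1") {
  stopifnot(length(image_sets) >= 1, !is.null(names(image_sets)),
            length(lesion_vois) >= 1)
  if (is.null(names(lesion_vois))) {
    names(lesion_vois) <- paste0("lesion_", seq_along(lesion_vois))
  }
  purrr::map_dfr(names(image_sets), function(set) {
    vol <- image_sets[[set]]
    cov <- cov_liver(vol, rois)
    purrr::map_dfr(names(lesion_vois), function(les) {
      tibble::tibble(subject = subject, image_set = set, lesion = les,
                     suv_max = suv_max(vol, lesion_vois[[les]]),
                     suv_peak = suv_peak(vol, lesion_vois[[les]]),
                     cov = cov)
    })
  })
}

#' Automated lesion-preservation check
#'
#' Stands in for a reader's side-by-side review of enhanced images: verifies
#' on phantom ground truth that every known lesion remains a hotspot after
#' denoising (lesion SUVmax above a contrast factor times the local
#' background) and that no new hotspot appears in the background.
#'
#' @param input,denoised the image before and after enhancement.
#' @param masks named list of voxel-index masks from [phantom_masks()]
#'   (`liver`, `lesion_*`).
#' @param contrast_factor minimum lesion-to-background SUVmax ratio.
#' @return list with `lesions` (tibble: lesion, suv_max before/after,
#'   relative change, `preserved`) and `hotspot_added` (logical).
#' @export
check_lesion_preservation <- function(input, denoised, masks,
                                      contrast_factor = 1.3) {
  les_names <- grep("^lesion_", names(masks), value = TRUE)
  stopifnot(length(les_names) >= 1)
  all_idx <- unlist(masks, use.names = FALSE)
  bg <- stats::median(unclass(denoised)[-all_idx])
  lesions <- purrr::map_dfr(les_names, function(nm) {
    before <- suv_max(input, masks[[nm]])
    after <- suv_max(denoised, masks[[nm]])
    tibble::tibble(lesion = nm, suv_max_before = before,
                   suv_max_after = after,
                   rel_change = (after - before) / before,
                   preserved = after > contrast_factor * bg)
  })
  out_max_before <- max(unclass(input)[-all_idx])
  out_max_after <- max(unclass(denoised)[-all_idx])
  list(lesions = lesions,
       hotspot_added = out_max_after > max(1.1 * out_max_before,
                                           contrast_factor * bg))
}
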