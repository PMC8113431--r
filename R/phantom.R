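#' Phantom geometry specifications
#'
#' A whole-body-like digital phantom is a uniform soft-tissue background, a
#' large ellipsoidal "liver" compartment, and a set of focal spherical
#' hotspots ("lesions") spanning a range of uptake values. All levels are in
#' SUV units; the phantom is the noiseless ground truth from which count
#' frames are simulated.
#'
#' @param center lesion centre in voxel coordinates `(row, col, slice)`.
#' @param diameter_mm lesion diameter in mm (> 0).
#' @param suv lesion uptake in SUV; must exceed the background (hotspot
#'   convention).
#' @return `lesion_spec()` and `phantom_spec()` return validated lists used
#'   by [build_phantom()].
#' @export
lesion_spec <- function(center, diameter_mm, suv) {
  stopifnot(length(center) == 3L, diameter_mm > 0, suv >= 0)
  structure(list(center = as.numeric(center),
                 diameter_mm = as.numeric(diameter_mm),
                 suv = as.numeric(suv)),
            class = "lesion_spec")
}

#' @rdname lesion_spec
#' @param shape grid shape `(rows, cols, slices)`.
#' @param voxel_size mm per voxel along (row, col, slice).
#' @param background_suv uniform soft-tissue uptake level (SUV).
#' @param liver `NULL` or a list with `center` (voxel coords), `semi_axes_mm`
#'   (length 3, mm) and `suv`.
#' @param lesions list of [lesion_spec()] objects.
#' @param seed integer seed recorded with the spec (used by the random
#'   generator helpers; `build_phantom()` itself is deterministic).
#' @export
phantom_spec <- function(shape = c(128L, 128L, 71L),
                         voxel_size = c(2.7, 2.7, 2.8),
                         background_suv = 0.7,
                         liver = default_liver(shape),
                         lesions = list(),
                         seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 1), background_suv >= 0)
  if (!is.null(liver)) {
    stopifnot(is.list(liver), length(liver$center) == 3L,
              length(liver$semi_axes_mm) == 3L,
              all(liver$semi_axes_mm > 0), liver$suv >= 0)
  }
  for (l in lesions) {
    stopifnot(inherits(l, "lesion_spec"))
    if (l$suv <= background_suv) {
      stop("lesion SUV (", l$suv, ") must exceed the background (",
           background_suv, "): hotspot convention", call. = FALSE)
    }
  }
  structure(list(shape = as.integer(shape),
                 voxel_size = as.numeric(voxel_size),
                 background_suv = background_suv,
                 liver = liver, lesions = lesions,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @rdname lesion_spec
#' @param voxel_size mm per voxel along (row, col, slice).
#' @export
default_liver <- function(shape = c(128L, 128L, 71L),
                          voxel_size = c(2.7, 2.7, 2.8)) {
  extent_mm <- shape * voxel_size
  # anatomical liver size, shrunk on small desk-scale grids so the ellipsoid
  # always clears the field of view
  list(center = c(round(shape[1] * 0.40), round(shape[2] * 0.50),
                  round(shape[3] * 0.50)),
       semi_axes_mm = pmin(c(55, 45, 42),
                           c(0.28, 0.28, 0.30) * extent_mm),
       suv = 2.0)
}

#' Random phantom specification
#'
#' Draws a phantom with the default background/liver and `n_lesions`
#' spherical hotspots with true SUV uniform in `suv_range` and diameter
#' uniform in `diameter_range_mm`, placed in the background compartment
#' (outside the liver, inside the grid, pairwise disjoint).
#'
#' @inheritParams phantom_spec
#' @param seed integer seed; the draw is a pure function of it.
#' @param n_lesions number of hotspots.
#' @param suv_range,diameter_range_mm uniform sampling ranges.
#' @return a [phantom_spec()].
#' @export
random_phantom_spec <- function(seed, shape = c(128L, 128L, 71L),
                                voxel_size = c(2.7, 2.7, 2.8),
                                background_suv = 0.7,
                                n_lesions = 3L,
                                suv_range = c(2, 8),
                                diameter_range_mm = c(10, 25)) {
  liver <- default_liver(shape, voxel_size)
  withr::with_seed(seed, {
    lesions <- list()
    tries <- 0L
    while (length(lesions) < n_lesions && tries < 2000L) {
      tries <- tries + 1L
      dia <- stats::runif(1, diameter_range_mm[1], diameter_range_mm[2])
      suv <- stats::runif(1, suv_range[1], suv_range[2])
      r_vox <- (dia / 2) / voxel_size
      ctr <- c(stats::runif(1, 1 + r_vox[1] + 3, shape[1] - r_vox[1] - 3),
               stats::runif(1, 1 + r_vox[2] + 3, shape[2] - r_vox[2] - 3),
               stats::runif(1, 1 + r_vox[3] + 3, shape[3] - r_vox[3] - 3))
      cand <- lesion_spec(ctr, dia, suv)
      if (.lesion_clear(cand, liver, lesions, voxel_size)) {
        lesions <- c(lesions, list(cand))
      }
    }
    if (length(lesions) < n_lesions) {
      stop("could not place ", n_lesions, " disjoint lesions", call. = FALSE)
    }
    phantom_spec(shape, voxel_size, background_suv, liver, lesions, seed)
  })
}

# margin-checked separation from the liver ellipsoid and other lesions
.lesion_clear <- function(cand, liver, lesions, voxel_size, margin_mm = 8) {
  r <- cand$diameter_mm / 2
  if (!is.null(liver)) {
    d_mm <- (cand$center - liver$center) * voxel_size
    # conservative: normalized ellipsoid distance with lesion radius added
    if (sqrt(sum((d_mm / (liver$semi_axes_mm + r + margin_mm))^2)) < 1) {
      return(FALSE)
    }
  }
  for (l in lesions) {
    d_mm <- sqrt(sum(((cand$center - l$center) * voxel_size)^2))
    if (d_mm < r + l$diameter_mm / 2 + margin_mm) return(FALSE)
  }
  TRUE
}

#' Read / write phantom specifications as JSON
#'
#' A structured plain-text representation of a [phantom_spec()], so phantom
#' geometries can be version-controlled and passed to the command-line
#' tools.
#'
#' @param spec a [phantom_spec()].
#' @param path file path (`.json`).
#' @return `read_phantom_spec()` returns a [phantom_spec()];
#'   `write_phantom_spec()` returns `path` invisibly.
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  payload <- unclass(spec)
  payload$lesions <- lapply(spec$lesions, unclass)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  phantom_spec(shape = p$shape, voxel_size = p$voxel_size,
               background_suv = p$background_suv,
               liver = if (is.null(p$liver)) NULL else
                 list(center = p$liver$center,
                      semi_axes_mm = p$liver$semi_axes_mm,
                      suv = p$liver$suv),
               lesions = lapply(p$lesions, function(l) {
                 lesion_spec(l$center, l$diameter_mm, l$suv)
               }),
               seed = p$seed)
}

#' Rasterize a phantom specification into an activity volume
#'
#' Paints the background, liver and lesions onto the voxel grid (voxel-centre
#' inclusion for ellipsoid and spheres) and returns the ground-truth activity
#' map in SUV units together with named masks for the liver and each lesion.
#'
#' @param spec a [phantom_spec()].
#' @return a `pet_volume` with attribute `masks`: a named list of linear
#'   voxel index vectors (`liver`, `lesion_1`, ...) matching the painted
#'   regions exactly.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape; vs <- spec$voxel_size
  vals <- array(spec$background_suv, shape)
  masks <- list()

  grid_mm <- function(axis) (seq_len(shape[axis]) - 1) * vs[axis]
  gx <- grid_mm(1); gy <- grid_mm(2); gz <- grid_mm(3)

  if (!is.null(spec$liver)) {
    c_mm <- (spec$liver$center - 1) * vs
    a <- spec$liver$semi_axes_mm
    ex <- ((gx - c_mm[1]) / a[1])^2
    ey <- ((gy - c_mm[2]) / a[2])^2
    ez <- ((gz - c_mm[3]) / a[3])^2
    inside <- outer(outer(ex, ey, `+`), ez, `+`) <= 1
    if (inside[1, 1, 1] || any(inside[c(1, shape[1]), , ]) ||
        any(inside[, c(1, shape[2]), ]) || any(inside[, , c(1, shape[3])])) {
      stop("liver ellipsoid touches the grid boundary", call. = FALSE)
    }
    idx <- which(inside)
    vals[idx] <- spec$liver$suv
    masks$liver <- idx
  }

  for (i in seq_along(spec$lesions)) {
    l <- spec$lesions[[i]]
    c_mm <- (l$center - 1) * vs
    r <- l$diameter_mm / 2
    if (any(c_mm - r < 0) || any(c_mm + r > (shape - 1) * vs)) {
      stop("lesion ", i, " extends outside the grid", call. = FALSE)
    }
    dx <- (gx - c_mm[1])^2
    dy <- (gy - c_mm[2])^2
    dz <- (gz - c_mm[3])^2
    idx <- which(outer(outer(dx, dy, `+`), dz, `+`) <= r^2)
    if (length(idx) == 0L) {
      stop("lesion ", i, " covers no voxel centres", call. = FALSE)
    }
    for (m in masks) {
      if (any(idx %in% m)) {
        stop("lesion ", i, " overlaps another painted region; masks must ",
             "be disjoint", call. = FALSE)
      }
    }
    vals[idx] <- l$suv
    masks[[paste0("lesion_", i)]] <- idx
  }

  out <- pet_volume(vals, vs, units = "SUV")
  attr(out, "masks") <- masks
  attr(out, "spec") <- spec
  out
}

#' @rdname build_phantom
#' @param x an activity volume from `build_phantom()`.
#' @export
phantom_masks <- function(x) attr(x, "masks")
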