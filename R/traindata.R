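#' Crop to the centremost slices
#'
#' Keeps the `keep` centremost contiguous slices. When the number of slices
#' to discard is odd, one more slice is removed from the end than from the
#' start (a fixed, documented convention): a 71-slice volume keeps 0-based
#' slices 10..60.
#'
#' @param volume a `pet_volume` (or plain 3D array).
#' @param keep number of slices to retain (default 50).
#' @return the cropped volume.
#' @export
crop_central <- function(volume, keep = 50L) {
  d <- dim(volume)
  if (d[3] < keep) {
    stop("volume has ", d[3], " slices, fewer than keep = ", keep,
         call. = FALSE)
  }
  drop <- d[3] - keep
  from <- floor(drop / 2) + 1L
  out <- volume[, , from:(from + keep - 1L), drop = FALSE]
  if (inherits(volume, "pet_volume")) {
    out <- pet_volume(out, voxel_size(volume), attr(volume, "units"))
  }
  out
}

#' Partition a volume into fixed-depth slice blocks
#'
#' Divides the slices into contiguous, non-overlapping blocks of `depth`
#' slices in order; concatenating the blocks reproduces the input exactly.
#'
#' @inheritParams crop_central
#' @param depth slices per block (must divide the slice count).
#' @return list of blocks; each carries a 0-based `subset_index` attribute.
#' @export
partition_subsets <- function(volume, depth = 5L) {
  d <- dim(volume)
  if (d[3] %% depth != 0L) {
    stop("slice count ", d[3], " is not divisible by depth ", depth,
         call. = FALSE)
  }
  n <- d[3] %/% depth
  lapply(seq_len(n) - 1L, function(i) {
    blk <- volume[, , (i * depth + 1L):((i + 1L) * depth), drop = FALSE]
    if (inherits(volume, "pet_volume")) {
      blk <- pet_volume(blk, voxel_size(volume), attr(volume, "units"))
    }
    attr(blk, "subset_index") <- i
    blk
  })
}

#' In-plane geometric transforms for augmentation
#'
#' Augmentation is geometric and strictly transaxial: a uniform scale, a
#' shear, and independent flips along the two in-plane axes, resampled back
#' onto the original grid with bilinear interpolation (edge-replicated
#' sampling outside the grid). The same transform object can be applied to a
#' noisy volume and to its clean counterpart so the pair stays spatially
#' consistent.
#'
#' @param scale uniform in-plane scale factor.
#' @param shear in-plane shear coefficient.
#' @param flip_row,flip_col logical flips along the two in-plane axes.
#' @return an `inplane_transform` list.
#' @export
inplane_transform <- function(scale = 1, shear = 0,
                              flip_row = FALSE, flip_col = FALSE) {
  stopifnot(is.finite(scale), scale > 0, is.finite(shear))
  structure(list(scale = scale, shear = shear,
                 flip_row = isTRUE(flip_row), flip_col = isTRUE(flip_col)),
            class = "inplane_transform")
}

#' @rdname inplane_transform
#' @param n number of transforms to draw.
#' @param scale_range,shear_range uniform sampling ranges.
#' @param flip_prob probability of each flip.
#' @param seed integer seed.
#' @export
draw_transforms <- function(n, scale_range = c(0.9, 1.1),
                            shear_range = c(-0.1, 0.1),
                            flip_prob = 0.5, seed = 1L) {
  stopifnot(n >= 0, scale_range[1] > 0, scale_range[1] <= scale_range[2],
            shear_range[1] <= shear_range[2],
            flip_prob >= 0, flip_prob <= 1)
  if (n == 0L) return(list())
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      inplane_transform(
        scale = stats::runif(1, scale_range[1], scale_range[2]),
        shear = stats::runif(1, shear_range[1], shear_range[2]),
        flip_row = stats::runif(1) < flip_prob,
        flip_col = stats::runif(1) < flip_prob)
    })
  })
}

#' @rdname inplane_transform
#' @param volume a `pet_volume` or 3D array.
#' @param tf an `inplane_transform`.
#' @export
apply_transform <- function(volume, tf) {
  stopifnot(inherits(tf, "inplane_transform"))
  d <- dim(volume)
  a <- tf$scale * matrix(c(1, 0, tf$shear, 1), 2, 2)
  a <- a %*% diag(c(if (tf$flip_row) -1 else 1, if (tf$flip_col) -1 else 1))
  ainv <- solve(a)
  c1 <- (d[1] + 1) / 2; c2 <- (d[2] + 1) / 2
  g <- expand.grid(i = seq_len(d[1]) - c1, j = seq_len(d[2]) - c2)
  src <- ainv %*% rbind(g$i, g$j)
  sx <- pmin(pmax(src[1, ] + c1, 1), d[1])
  sy <- pmin(pmax(src[2, ] + c2, 1), d[2])
  x0 <- pmin(floor(sx), d[1] - 1L); y0 <- pmin(floor(sy), d[2] - 1L)
  wx <- sx - x0; wy <- sy - y0
  out <- array(0, d)
  for (z in seq_len(d[3])) {
    sl <- volume[, , z]
    v00 <- sl[cbind(x0, y0)];     v10 <- sl[cbind(x0 + 1L, y0)]
    v01 <- sl[cbind(x0, y0 + 1L)]; v11 <- sl[cbind(x0 + 1L, y0 + 1L)]
    out[, , z] <- (1 - wx) * (1 - wy) * v00 + wx * (1 - wy) * v10 +
      (1 - wx) * wy * v01 + wx * wy * v11
  }
  if (inherits(volume, "pet_volume")) {
    out <- pet_volume(out, voxel_size(volume), attr(volume, "units"))
  }
  out
}

#' @rdname inplane_transform
#' @param n_samples number of augmented samples to generate.
#' @param transforms optional list of transforms to apply instead of drawing
#'   new ones (used to replay a noisy volume's transforms on its clean
#'   counterpart).
#' @param ... passed to [draw_transforms()].
#' @export
augment <- function(volume, n_samples = 5L, seed = 1L, transforms = NULL,
                    ...) {
  if (is.null(transforms)) {
    transforms <- draw_transforms(n_samples, seed = seed, ...)
  }
  out <- lapply(transforms, function(tf) apply_transform(volume, tf))
  attr(out, "transforms") <- transforms
  out
}

#' Training-pair bookkeeping manifest
#'
#' Enumerates the full provenance grid of training pairs — subsets x sources
#' x reconstructions x samples (original + augmented) — without
#' materializing any voxel data, and shuffles it with a seeded permutation.
#' The row count is exactly
#' `subsets_per_volume * n_sources * n_recons_per_source * (1 + n_aug)`.
#'
#' @param n_sources number of training subjects.
#' @param n_recons_per_source short-duration reconstructions per subject.
#' @param n_aug augmented samples per reconstruction (in addition to the
#'   original).
#' @param subsets_per_volume 5-slice blocks per cropped volume.
#' @param seed permutation seed (`NULL` keeps grid order).
#' @return a tibble with columns `pair_id`, `source`, `recon`, `subset`,
#'   `sample`.
#' @examples
#' nrow(pair_manifest(72, 4, 5))  # 17280
#' @export
pair_manifest <- function(n_sources, n_recons_per_source, n_aug = 5L,
                          subsets_per_volume = 10L, seed = NULL) {
  stopifnot(n_sources >= 0, n_recons_per_source >= 0, n_aug >= 0,
            subsets_per_volume >= 1)
  if (n_sources == 0L || n_recons_per_source == 0L) {
    return(tibble::tibble(pair_id = integer(), source = integer(),
                          recon = integer(), subset = integer(),
                          sample = character()))
  }
  m <- tidyr::expand_grid(
    source = seq_len(n_sources),
    recon = seq_len(n_recons_per_source),
    sample = c("original",
               if (n_aug > 0) paste0("sample_", seq_len(n_aug))),
    subset = seq_len(subsets_per_volume) - 1L)
  if (!is.null(seed)) {
    m <- withr::with_seed(seed, m[sample.int(nrow(m)), ])
  }
  dplyr::mutate(m, pair_id = dplyr::row_number(), .before = 1)
}

#' Assemble training pairs from reconstructed volumes
#'
#' For each source subject this crops the clean (long-acquisition) and each
#' noisy (short-acquisition) reconstruction to the centremost slices, draws
#' the augmentation transforms per reconstruction, applies each transform
#' identically to the noisy volume and its clean counterpart, partitions
#' both into aligned 5-slice subsets, and returns the shuffled pair set.
#'
#' @param sources list of sources; each a list with elements `id`, `clean`
#'   (a `pet_volume`) and `noisy` (list of `pet_volume`s of the same
#'   anatomy).
#' @param n_aug augmented samples per reconstruction.
#' @param keep centremost slices to retain before partitioning.
#' @param depth slices per subset block.
#' @param seed integer seed for transforms and the final shuffle.
#' @param ... augmentation parameter ranges, passed to [draw_transforms()].
#' @return a tibble: the [pair_manifest()] columns plus list-columns `noisy`
#'   and `clean` holding aligned `rows x cols x depth` arrays.
#' @export
build_pairs <- function(sources, n_aug = 5L, keep = 50L, depth = 5L,
                        seed = 1L, ...) {
  if (length(sources) == 0L) {
    return(dplyr::mutate(pair_manifest(0, 0), noisy = list(), clean = list()))
  }
  rows <- list()
  for (si in seq_along(sources)) {
    src <- sources[[si]]
    clean <- crop_central(src$clean, keep)
    for (ri in seq_along(src$noisy)) {
      noisy <- crop_central(src$noisy[[ri]], keep)
      if (!identical(dim(noisy), dim(clean))) {
        stop("source ", si, " recon ", ri, ": noisy and clean volumes are ",
             "not aligned (", paste(dim(noisy), collapse = "x"), " vs ",
             paste(dim(clean), collapse = "x"), ")", call. = FALSE)
      }
      tfs <- c(list(NULL),
               draw_transforms(n_aug, seed = seed + 7919L * si + 104729L * ri,
                               ...))
      for (ti in seq_along(tfs)) {
        nv <- if (is.null(tfs[[ti]])) noisy else apply_transform(noisy, tfs[[ti]])
        cv <- if (is.null(tfs[[ti]])) clean else apply_transform(clean, tfs[[ti]])
        nb <- partition_subsets(nv, depth)
        cb <- partition_subsets(cv, depth)
        tag <- if (ti == 1L) "original" else paste0("sample_", ti - 1L)
        for (bi in seq_along(nb)) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            source = src$id %||% si, recon = ri, sample = tag,
            subset = bi - 1L,
            noisy = list(unclass(nb[[bi]])), clean = list(unclass(cb[[bi]])))
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- withr::with_seed(seed, out[sample.int(nrow(out)), ])
  dplyr::mutate(out, pair_id = dplyr::row_number(), .before = 1)
}
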