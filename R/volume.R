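#' 3D PET volume container
#'
#' A thin S3 wrapper around a numeric 3D array `[row, col, slice]` carrying
#' the voxel size in millimetres. All simulation, reconstruction and metric
#' functions in the package operate on `pet_volume` objects. The default
#' geometry matches a clinical whole-body FDG protocol: 2.7 x 2.7 mm
#' in-plane pixels and 2.8 mm slice thickness.
#'
#' @param values numeric 3D array (or object coercible to one).
#' @param voxel_size numeric length-3, mm per voxel along (row, col, slice).
#' @param units unit label for the voxel values (e.g. `"SUV"`, `"counts"`,
#'   `"kBq/mL"`).
#' @return A `pet_volume`: the array with `voxel_size` and `units` attributes.
#' @examples
#' v <- pet_volume(array(1, c(8, 8, 5)))
#' voxel_size(v)
#' @export
pet_volume <- function(values, voxel_size = c(2.7, 2.7, 2.8), units = "SUV") {
  values <- unclass(values)
  if (length(dim(values)) != 3L) {
    stop("`values` must be a 3D array (got ", length(dim(values)),
         " dimensions)", call. = FALSE)
  }
  stopifnot(is.numeric(voxel_size), length(voxel_size) == 3L,
            all(voxel_size > 0))
  structure(values,
            voxel_size = as.numeric(voxel_size),
            units = units,
            class = "pet_volume")
}

#' @rdname pet_volume
#' @param x a `pet_volume`.
#' @export
voxel_size <- function(x) attr(x, "voxel_size")

#' @rdname pet_volume
#' @export
n_slices <- function(x) dim(x)[3L]

#' @export
print.pet_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<pet_volume> %d x %d x %d voxels (%s), %.2f x %.2f x %.2f mm\n",
              d[1], d[2], d[3], attr(x, "units") %||% "?",
              voxel_size(x)[1], voxel_size(x)[2], voxel_size(x)[3]))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x), max(x)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rebuild a volume with new values, keeping geometry/metadata
with_values <- function(vol, values, units = attr(vol, "units")) {
  pet_volume(array(values, dim(vol)), voxel_size(vol), units)
}

#' Read / write volumes as NIfTI
#'
#' Lossless round-trip of voxel values and voxel geometry through NIfTI-1,
#' the canonical on-disk format for all volumes produced by the package.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume()` returns a `pet_volume`; `write_volume()` returns
#'   `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' write_volume(pet_volume(array(rnorm(320), c(8, 8, 5))), f)
#' v <- read_volume(f)
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) {
    stop("expected a 3D volume, but NIfTI header field `dim` describes ",
         length(d), " dimensions", call. = FALSE)
  }
  px <- RNifti::pixdim(img)
  if (length(px) < 3L || any(!is.finite(px[1:3])) || any(px[1:3] <= 0)) {
    stop("malformed NIfTI header: field `pixdim` is not a positive ",
         "3-vector", call. = FALSE)
  }
  pet_volume(array(as.numeric(img), d), px[1:3])
}

#' Write / read named masks as one integer-label volume
#'
#' Encodes a list of voxel-index masks as a single co-registered NIfTI with
#' integer labels 1, 2, ... in list order (0 = background); the label/name
#' correspondence travels in a JSON sidecar next to the image.
#'
#' @param masks named list of linear voxel-index vectors (e.g.
#'   [phantom_masks()]).
#' @param dims volume dimensions.
#' @param voxel_size mm per voxel.
#' @param path output path (`.nii` / `.nii.gz`); the sidecar replaces the
#'   extension with `.labels.json`.
#' @return `path`, invisibly.
#' @export
write_masks <- function(masks, dims, voxel_size, path) {
  lab <- array(0L, dims)
  for (i in seq_along(masks)) lab[masks[[i]]] <- i
  write_volume(pet_volume(lab, voxel_size, units = "label"), path)
  side <- sub("\\.nii(\\.gz)?$", ".labels.json", path)
  jsonlite::write_json(as.list(stats::setNames(seq_along(masks),
                                               names(masks))),
                       side, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_masks
#' @export
read_masks <- function(path) {
  lab <- read_volume(path)
  side <- sub("\\.nii(\\.gz)?$", ".labels.json", path)
  ids <- jsonlite::read_json(side, simplifyVector = TRUE)
  out <- lapply(ids, function(i) which(as.integer(lab) == i))
  names(out) <- names(ids)
  out
}

#' @rdname read_volume
#' @param volume a `pet_volume`.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "pet_volume"))
  img <- RNifti::asNifti(array(as.numeric(volume), dim(volume)))
  RNifti::pixdim(img) <- voxel_size(volume)
  RNifti::writeNifti(img, path)
  invisible(path)
}
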