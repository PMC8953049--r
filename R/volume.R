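#' Voxel volume container
#'
#' A `volume_grid` is the package's universal image carrier: a 3D numeric
#' array together with its voxel spacing in millimetres and an explicit unit
#' tag. Activity volumes carry `"Bq_per_mL"`, SUV-converted volumes carry
#' `"SUV_g_per_mL"`, and stress-rest subtraction images carry `"difference"`
#' (the only unit for which negative voxels are permitted).
#'
#' @param values 3D numeric array of voxel values. Must be finite; must be
#'   non-negative unless `unit = "difference"`.
#' @param voxel_size_mm positive numeric voxel edge lengths in mm; a scalar
#'   is recycled to the three axes. Default 1.4 mm isotropic.
#' @param unit one of `"Bq_per_mL"`, `"SUV_g_per_mL"`, `"difference"`.
#' @return An object of class `volume_grid`.
#' @seealso [voi_mask()], [read_volume()], [write_volume()]
#' @export
volume_grid <- function(values, voxel_size_mm = 1.4,
                        unit = c("Bq_per_mL", "SUV_g_per_mL", "difference")) {
  unit <- match.arg(unit)
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("'values' must be a 3D array", call. = FALSE)
  if (!all(is.finite(values)))
    stop("volume contains non-finite values", call. = FALSE)
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("'voxel_size_mm' must be a positive scalar or triple", call. = FALSE)
  if (unit != "difference" && any(values < 0))
    stop("negative voxel values are only valid in a 'difference' volume",
         call. = FALSE)
  structure(list(values = values, voxel_size_mm = voxel_size_mm, unit = unit),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume_grid> %d x %d x %d voxels, %.3g x %.3g x %.3g mm, unit %s\n",
              d[1], d[2], d[3],
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3],
              x$unit))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$values)

#' Binary volume-of-interest mask
#'
#' A `voi_mask` is a binary 3D mask congruent with a [volume_grid()]. It
#' replaces the study's manual voxel-by-voxel delineation of the left
#' ventricular myocardium or whole brain: segmentations enter the pipeline
#' as mask volumes sharing the grid of the image they index.
#'
#' @param values 3D logical/0-1 array.
#' @param reference optional `volume_grid` whose geometry the mask must
#'   match; a shape or spacing mismatch is an error (no resampling is ever
#'   performed).
#' @param voxel_size_mm spacing, taken from `reference` when given.
#' @return An object of class `voi_mask` holding a logical array.
#' @export
voi_mask <- function(values, reference = NULL, voxel_size_mm = 1.4) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("mask must be a 3D array", call. = FALSE)
  if (!all(values %in% c(0, 1, TRUE, FALSE)))
    stop("mask must be binary (0/1)", call. = FALSE)
  storage.mode(values) <- "logical"
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "volume_grid"))
    check_congruent(dim(values), dim(reference$values),
                    what = "mask vs reference volume")
    voxel_size_mm <- reference$voxel_size_mm
  }
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  structure(list(values = values, voxel_size_mm = as.numeric(voxel_size_mm)),
            class = "voi_mask")
}

#' @export
print.voi_mask <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voi_mask> %d x %d x %d voxels, %d selected\n",
              d[1], d[2], d[3], sum(x$values)))
  invisible(x)
}

#' @export
dim.voi_mask <- function(x) dim(x$values)

check_congruent <- function(da, db, what = "volumes") {
  if (!identical(as.integer(da), as.integer(db)))
    stop(sprintf("geometry error: %s differ in shape (%s vs %s)", what,
                 paste(da, collapse = "x"), paste(db, collapse = "x")),
         call. = FALSE)
  invisible(TRUE)
}

check_mask <- function(mask, v = NULL, require_nonempty = TRUE) {
  stopifnot(inherits(mask, "voi_mask"))
  if (!is.null(v)) check_congruent(dim(mask$values), dim(v$values),
                                   what = "mask vs volume")
  if (require_nonempty && !any(mask$values))
    stop("validation error: mask is empty", call. = FALSE)
  invisible(TRUE)
}

#' Acquisition metadata for SUV conversion
#'
#' Holds the quantities entering the SUV formula: injected dose, body
#' weight, the injection-to-scan delay used for decay correction, and the
#' isotope half-life (default 109.77 min for fluorine-18).
#'
#' @param dose_bq injected dose in Bq (> 0).
#' @param weight_kg body weight in kg (> 0).
#' @param delay_min minutes from injection to scan start (>= 0); with the
#'   default 0 no decay correction is applied.
#' @param half_life_min isotope half-life in minutes (> 0).
#' @return An object of class `acquisition_meta`.
#' @export
acquisition_meta <- function(dose_bq, weight_kg, delay_min = 0,
                             half_life_min = 109.77) {
  if (!is.numeric(dose_bq) || dose_bq <= 0)
    stop("'dose_bq' must be > 0", call. = FALSE)
  if (!is.numeric(weight_kg) || weight_kg <= 0)
    stop("'weight_kg' must be > 0", call. = FALSE)
  if (!is.numeric(delay_min) || delay_min < 0)
    stop("validation error: 'delay_min' must be >= 0", call. = FALSE)
  if (!is.numeric(half_life_min) || half_life_min <= 0)
    stop("'half_life_min' must be > 0", call. = FALSE)
  structure(list(dose_bq = dose_bq, weight_kg = weight_kg,
                 delay_min = delay_min, half_life_min = half_life_min),
            class = "acquisition_meta")
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", "", path) |> paste0(".json")
}

#' Read and write voxel volumes as NIfTI-1
#'
#' Volumes are stored as NIfTI-1 (`.nii` / `.nii.gz`) with the voxel
#' spacing in the header; the unit tag travels in a small JSON sidecar
#' next to the image (same basename, `.json` extension). `read_volume()`
#' falls back to `unit` when no sidecar exists.
#'
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @param unit default unit tag when no sidecar is found.
#' @return `read_volume()` returns a [volume_grid()]; `write_volume()`
#'   invisibly returns `path`.
#' @export
read_volume <- function(path, unit = "Bq_per_mL") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  # the header stores spacing in float32; the sidecar keeps it exact
  spacing <- as.numeric(RNifti::pixdim(img))
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(meta$unit)) unit <- meta$unit
    if (!is.null(meta$voxel_size_mm)) spacing <- meta$voxel_size_mm
  }
  volume_grid(array(as.numeric(img), dim = dim(img)),
              voxel_size_mm = spacing, unit = unit)
}

#' @rdname read_volume
#' @param v a [volume_grid()] to write.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "volume_grid"))
  img <- RNifti::asNifti(v$values)
  RNifti::pixdim(img) <- v$voxel_size_mm
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(unit = v$unit, voxel_size_mm = v$voxel_size_mm),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write VOI masks as NIfTI-1
#'
#' Masks are 0/1 NIfTI volumes on the same grid as their reference volume;
#' `read_mask()` enforces shape congruence against `reference` (no
#' resampling is performed).
#'
#' @param path NIfTI file path.
#' @param reference the [volume_grid()] the mask indexes.
#' @return `read_mask()` returns a [voi_mask()].
#' @export
read_mask <- function(path, reference) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  voi_mask(array(as.numeric(img) != 0, dim = dim(img)),
           reference = reference)
}

#' @rdname read_mask
#' @param mask a [voi_mask()] to write.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "voi_mask"))
  img <- RNifti::asNifti(array(as.numeric(mask$values), dim(mask$values)))
  RNifti::pixdim(img) <- mask$voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read and write acquisition metadata as JSON
#'
#' @param path JSON file path.
#' @return `read_acquisition_meta()` returns an [acquisition_meta()].
#' @export
read_acquisition_meta <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  acquisition_meta(dose_bq = m$dose_bq, weight_kg = m$weight_kg,
                   delay_min = m$delay_min %||% 0,
                   half_life_min = m$half_life_min %||% 109.77)
}

#' @rdname read_acquisition_meta
#' @param meta an [acquisition_meta()] to write.
#' @export
write_acquisition_meta <- function(meta, path) {
  stopifnot(inherits(meta, "acquisition_meta"))
  jsonlite::write_json(unclass(meta), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write RGB stain photographs as PNG
#'
#' @param path PNG file path.
#' @return `read_stain_image()` returns an H x W x 3 numeric array in
#'   \[0, 1\].
#' @export
read_stain_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 3L))
  img[, , 1:3, drop = FALSE]
}

#' @rdname read_stain_image
#' @param image H x W x 3 numeric array in \[0, 1\].
#' @export
write_stain_image <- function(image, path) {
  png::writePNG(image, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
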