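#' Radioactive decay correction factor
#'
#' Correction factor C decay-correcting a measured activity back to
#' injection time: `C = 2^(delay / half_life)`, so `C = 1` at zero delay
#' and `C = 2` after one half-life. For fluorine-18 the half-life is
#' 109.77 min.
#'
#' @param delay_min minutes from injection to scan (>= 0).
#' @param half_life_min isotope half-life in minutes (> 0).
#' @return the scalar factor C >= 1.
#' @export
decay_factor <- function(delay_min, half_life_min = 109.77) {
  if (!is.numeric(delay_min) || any(delay_min < 0))
    stop("validation error: 'delay_min' must be >= 0", call. = FALSE)
  if (half_life_min <= 0) stop("'half_life_min' must be > 0", call. = FALSE)
  2^(delay_min / half_life_min)
}

#' Convert an activity volume to standardized uptake values
#'
#' Applies the SUV conversion voxelwise:
#' `SUV (g/mL) = activity (Bq/mL) * C * weight (kg) / dose (Bq) * 1000 (g/kg)`,
#' with C the decay correction from [decay_factor()] evaluated at the
#' metadata's injection-to-scan delay. A voxel holding the uniformly
#' distributed dose, `dose / (weight * 1000)` Bq/mL, maps to SUV = C.
#'
#' @param v a [volume_grid()] in Bq/mL.
#' @param meta an [acquisition_meta()].
#' @return a [volume_grid()] with unit `"SUV_g_per_mL"`.
#' @export
to_suv <- function(v, meta) {
  stopifnot(inherits(v, "volume_grid"), inherits(meta, "acquisition_meta"))
  if (v$unit != "Bq_per_mL")
    stop("unit error: SUV conversion requires a Bq/mL volume, got ", v$unit,
         call. = FALSE)
  C <- decay_factor(meta$delay_min, meta$half_life_min)
  factor <- C * meta$weight_kg / meta$dose_bq * 1000
  volume_grid(v$values * factor, voxel_size_mm = v$voxel_size_mm,
              unit = "SUV_g_per_mL")
}

#' Total activity inside a volume of interest
#'
#' Sums the voxel values under the mask and reports the masked mean, voxel
#' count and physical volume. The vasodilation pipeline consumes the raw
#' masked sum — the per-VOI "activity" that one row of the stress/rest
#' tables is built from.
#'
#' @param v a [volume_grid()].
#' @param mask a nonempty [voi_mask()] congruent with `v`.
#' @return list with `sum`, `mean`, `voxel_count`, `volume_mL`
#'   (`voxel_count` times the voxel volume in mL).
#' @export
voi_total <- function(v, mask) {
  stopifnot(inherits(v, "volume_grid"))
  check_mask(mask, v)
  vals <- v$values[mask$values]
  list(sum = sum(vals), mean = mean(vals), voxel_count = length(vals),
       volume_mL = length(vals) * prod(v$voxel_size_mm) / 1000)
}

#' Histogram of masked voxel values
#'
#' Bins the voxel values under a VOI mask, in the volume's own unit
#' (Bq/mL, SUV, or a stress-rest difference). Default binning is 64
#' equal-width bins spanning the masked min-max; explicit strictly
#' increasing `breaks` covering the data range may be supplied instead.
#' Counts always sum to the number of masked voxels.
#'
#' @param v a [volume_grid()].
#' @param mask a nonempty [voi_mask()] congruent with `v`.
#' @param n_bins number of equal-width bins (ignored when `breaks` given).
#' @param breaks optional strictly increasing bin-edge vector.
#' @return An object of class `activity_histogram`: list with `bin_edges`,
#'   `counts`, `unit`.
#' @export
activity_histogram <- function(v, mask, n_bins = 64, breaks = NULL) {
  stopifnot(inherits(v, "volume_grid"))
  check_mask(mask, v)
  vals <- v$values[mask$values]
  if (is.null(breaks)) {
    rng <- range(vals)
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)   # degenerate: one value
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  } else {
    if (any(diff(breaks) <= 0))
      stop("validation error: bin edges must be strictly increasing",
           call. = FALSE)
    if (min(vals) < breaks[1] || max(vals) > breaks[length(breaks)])
      stop("validation error: bin edges do not cover the data range",
           call. = FALSE)
  }
  counts <- hist(vals, breaks = breaks, plot = FALSE,
                 include.lowest = TRUE, right = TRUE)$counts
  structure(list(bin_edges = breaks, counts = counts, unit = v$unit),
            class = "activity_histogram")
}

#' @export
print.activity_histogram <- function(x, ...) {
  cat(sprintf("<activity_histogram> %d bins over [%.4g, %.4g] (%s), %d voxels\n",
              length(x$counts), x$bin_edges[1],
              x$bin_edges[length(x$bin_edges)], x$unit, sum(x$counts)))
  invisible(x)
}

#' Export a histogram as CSV
#'
#' One row per bin: `bin_start, bin_end, count`.
#'
#' @param h an [activity_histogram()].
#' @param path output CSV path.
#' @export
write_histogram_csv <- function(h, path) {
  stopifnot(inherits(h, "activity_histogram"))
  n <- length(h$counts)
  utils::write.csv(data.frame(bin_start = h$bin_edges[seq_len(n)],
                              bin_end = h$bin_edges[seq_len(n) + 1],
                              count = h$counts),
                   path, row.names = FALSE)
  invisible(path)
}
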