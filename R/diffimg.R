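#' Rigid co-registration by mask-centroid alignment
#'
#' Translates the moving volume (and its mask) by the integer voxel shift
#' that brings the moving mask's centroid onto the fixed mask's centroid;
#' the sub-voxel remainder is discarded. Volumes acquired on the same
#' scanner in the same session differ essentially by a small translation,
#' and an integer shift introduces no interpolation into the subsequent
#' voxelwise subtraction.
#'
#' @param moving,fixed [volume_grid()]s on congruent grids.
#' @param moving_mask,fixed_mask nonempty [voi_mask()]s for the two
#'   volumes.
#' @return list with `volume` and `mask` (the shifted moving pair, zero /
#'   FALSE filled at the trailing edge) and `shift`, the integer voxel
#'   displacement applied.
#' @export
register_rigid <- function(moving, moving_mask, fixed, fixed_mask) {
  stopifnot(inherits(moving, "volume_grid"), inherits(fixed, "volume_grid"))
  check_mask(moving_mask, moving)
  check_mask(fixed_mask, fixed)
  check_congruent(dim(moving$values), dim(fixed$values))
  centroid <- function(m) {
    idx <- which(m$values, arr.ind = TRUE)
    colMeans(idx)
  }
  shift <- round(centroid(fixed_mask) - centroid(moving_mask))
  list(volume = volume_grid(translate_array(moving$values, shift, fill = 0),
                            voxel_size_mm = moving$voxel_size_mm,
                            unit = moving$unit),
       mask = voi_mask(translate_array(moving_mask$values, shift,
                                       fill = FALSE),
                       voxel_size_mm = moving_mask$voxel_size_mm),
       shift = as.integer(shift))
}

# Integer translation with constant fill; shift[k] > 0 moves content toward
# higher indices along axis k.
translate_array <- function(a, shift, fill = 0) {
  d <- dim(a)
  out <- array(fill, dim = d)
  src <- dst <- vector("list", 3L)
  for (k in 1:3) {
    s <- shift[k]
    if (abs(s) >= d[k]) return(out)
    src[[k]] <- if (s >= 0) seq_len(d[k] - s) else seq(1 - s, d[k])
    dst[[k]] <- if (s >= 0) seq(1 + s, d[k]) else seq_len(d[k] + s)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Clipped stress-rest difference image
#'
#' Voxelwise `max(stress - rest, 0)` inside the mask, zero outside.
#' Negative differences arise mainly from partial-volume averaging against
#' the adjacent high-activity chamber blood pool and are set to zero rather
#' than excluded, so the mask voxel count is unchanged.
#'
#' @param stress,rest co-registered [volume_grid()]s on congruent grids and
#'   in the same unit.
#' @param mask a nonempty [voi_mask()].
#' @return a [volume_grid()] with unit `"difference"`.
#' @export
clipped_difference <- function(stress, rest, mask) {
  stopifnot(inherits(stress, "volume_grid"), inherits(rest, "volume_grid"))
  check_congruent(dim(stress$values), dim(rest$values))
  check_mask(mask, stress)
  if (stress$unit != rest$unit)
    stop("unit error: stress and rest volumes are in different units",
         call. = FALSE)
  diff <- pmax(stress$values - rest$values, 0)
  diff[!mask$values] <- 0
  volume_grid(diff, voxel_size_mm = stress$voxel_size_mm, unit = "difference")
}

#' Construct a vasodilation result from summed activities
#'
#' Bundles the per-VOI stress sum, rest sum, clipped-difference sum and the
#' increased ratio `100 * clipped_diff_sum / rest_sum` — the vasodilation
#' statistic: the percentage of the resting blood-pool signal recruited
#' under pharmacological stress. One such result is one row of a
#' stress/rest activity table.
#'
#' @param stress_sum,rest_sum,clipped_diff_sum masked activity sums;
#'   `rest_sum` must be > 0 and `clipped_diff_sum` >= 0.
#' @return An object of class `vasodilation_result`.
#' @export
vasodilation_result <- function(stress_sum, rest_sum, clipped_diff_sum) {
  if (rest_sum <= 0)
    stop("undefined-ratio error: rest activity sum must be > 0",
         call. = FALSE)
  if (clipped_diff_sum < 0)
    stop("clipped difference sum must be >= 0", call. = FALSE)
  structure(list(stress_sum = stress_sum, rest_sum = rest_sum,
                 clipped_diff_sum = clipped_diff_sum,
                 increased_ratio_pct = 100 * clipped_diff_sum / rest_sum),
            class = "vasodilation_result")
}

#' @export
print.vasodilation_result <- function(x, ...) {
  cat(sprintf(paste0("<vasodilation_result> stress %.2f, rest %.2f, ",
                     "clipped difference %.2f, increased ratio %.2f%%\n"),
              x$stress_sum, x$rest_sum, x$clipped_diff_sum,
              x$increased_ratio_pct))
  invisible(x)
}

#' Vasodilation increased ratio from co-registered volumes
#'
#' Computes the masked stress and rest activity sums, the clipped
#' pixelwise stress-rest difference sum, and the increased ratio
#' `100 * sum(max(stress - rest, 0)) / sum(rest)` over the mask. Inputs
#' must already be co-registered (see [register_rigid()]).
#'
#' On an ideal blood-pool image pair whose tissue signal is uniformly
#' multiplied by `1 + d` under stress, the increased ratio recovers
#' `100 * d` exactly; negative clipping makes the estimator's noise bias
#' non-negative.
#'
#' @inheritParams clipped_difference
#' @return a [vasodilation_result()].
#' @export
increased_ratio <- function(stress, rest, mask) {
  diff <- clipped_difference(stress, rest, mask)
  vasodilation_result(stress_sum = sum(stress$values[mask$values]),
                      rest_sum = sum(rest$values[mask$values]),
                      clipped_diff_sum = sum(diff$values[mask$values]))
}
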