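#' Two-threshold Otsu stratification of a value distribution
#'
#' Histogram-based three-class Otsu thresholding: the values are binned
#' into `n_bins` equal-width bins and the pair of cut points maximizing
#' the between-class variance
#' `sum_k w_k (mu_k - mu)^2` over the three classes is found by exhaustive
#' search over all bin-pair splits (O(n_bins^2), exact and deterministic;
#' ties broken toward the lowest threshold pair). Because binning is
#' min-max equal-width, the induced class assignment is invariant under
#' affine rescaling of the values.
#'
#' @param values numeric vector with at least 3 distinct values.
#' @param n_bins number of histogram bins (default 64).
#' @return numeric `c(t_low_med, t_med_high)`: bin-edge thresholds with
#'   `t_low_med < t_med_high`. Class rule: low `value <= t_low_med`,
#'   medium `t_low_med < value <= t_med_high`, high above.
#' @export
otsu_two_thresholds <- function(values, n_bins = 64) {
  values <- as.numeric(values)
  if (length(unique(values)) < 3L)
    stop("degenerate input: need at least 3 distinct values for a ",
         "three-class split", call. = FALSE)
  rng <- range(values)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- hist(values, breaks = edges, plot = FALSE,
                 include.lowest = TRUE, right = TRUE)$counts
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  p <- counts / sum(counts)
  cw <- cumsum(p)               # class weight up to bin i
  cm <- cumsum(p * mids)        # partial first moment
  total_mean <- cm[n_bins]
  best <- c(NA, NA); best_var <- -Inf
  for (i in seq_len(n_bins - 2)) {
    w1 <- cw[i]; m1 <- cm[i]
    for (j in seq(i + 1, n_bins - 1)) {
      w2 <- cw[j] - w1; w3 <- 1 - cw[j]
      m2 <- cm[j] - m1; m3 <- total_mean - cm[j]
      v <- 0
      if (w1 > 0) v <- v + m1^2 / w1
      if (w2 > 0) v <- v + m2^2 / w2
      if (w3 > 0) v <- v + m3^2 / w3
      # v = sum w_k mu_k^2; between-class variance differs from it by the
      # constant total_mean^2, so maximizing v is equivalent
      if (v > best_var + 1e-12) {
        best_var <- v
        best <- c(i, j)
      }
    }
  }
  c(t_low_med = edges[best[1] + 1], t_med_high = edges[best[2] + 1])
}

#' Classify values against a two-threshold stratification
#'
#' @param values numeric vector.
#' @param thresholds `c(t_low_med, t_med_high)` as returned by
#'   [otsu_two_thresholds()].
#' @return integer vector: 1 = low, 2 = medium, 3 = high.
#' @export
classify_three <- function(values, thresholds) {
  if (thresholds[1] >= thresholds[2])
    stop("thresholds must satisfy t_low_med < t_med_high", call. = FALSE)
  1L + (values > thresholds[1]) + (values > thresholds[2])
}

#' Stratify a masked short-axis slice into perfusion classes
#'
#' Labels every masked voxel of one short-axis slice (a plane perpendicular
#' to the declared long axis, grid axis 3) as low, medium or high tracer
#' activity. With blood-pool imaging these classes read as perfusion
#' strata: the low class marks candidate infarct.
#'
#' @param v a [volume_grid()].
#' @param mask a [voi_mask()] congruent with `v`.
#' @param slice_index index along grid axis 3.
#' @param thresholds `c(t_low_med, t_med_high)`; when `NULL`, Otsu
#'   thresholds are computed from this slice's masked values.
#' @param n_bins histogram bins for the Otsu search.
#' @return list with `labels` (integer matrix, `NA` outside the mask),
#'   `thresholds`, and `counts` (named low/medium/high).
#' @export
stratify_slice <- function(v, mask, slice_index, thresholds = NULL,
                           n_bins = 64) {
  stopifnot(inherits(v, "volume_grid"))
  check_mask(mask, v, require_nonempty = FALSE)
  d <- dim(v$values)
  if (slice_index < 1 || slice_index > d[3])
    stop("slice index out of range", call. = FALSE)
  m2 <- mask$values[, , slice_index]
  if (!any(m2))
    stop("validation error: slice does not intersect the mask", call. = FALSE)
  vals <- v$values[, , slice_index][m2]
  if (is.null(thresholds)) thresholds <- otsu_two_thresholds(vals, n_bins)
  cls <- classify_three(vals, thresholds)
  labels <- matrix(NA_integer_, d[1], d[2])
  labels[m2] <- cls
  counts <- c(low = sum(cls == 1L), medium = sum(cls == 2L),
              high = sum(cls == 3L))
  list(labels = labels, thresholds = thresholds, counts = counts)
}

#' Infarct size of a short-axis slice from PET stratification
#'
#' Three-class stratification of the masked slice (Otsu by default, or a
#' manual threshold override) followed by the infarct fraction: the low
#' class is counted as infarcted muscle and the medium and high classes as
#' viable, so `infarct_pct = 100 * low / (low + medium + high)`.
#'
#' @inheritParams stratify_slice
#' @param thresholds optional manual override of the two Otsu thresholds,
#'   standing in for expert fine adjustment.
#' @return An object of class `slice_infarct_estimate`: list with
#'   `thresholds`, `counts`, `infarct_pct`, `slice_index`.
#' @export
infarct_percentage <- function(v, mask, slice_index, thresholds = NULL,
                               n_bins = 64) {
  s <- stratify_slice(v, mask, slice_index, thresholds = thresholds,
                      n_bins = n_bins)
  total <- sum(s$counts)
  if (total == 0)
    stop("validation error: no masked voxels in slice", call. = FALSE)
  structure(list(thresholds = s$thresholds, counts = s$counts,
                 infarct_pct = 100 * s$counts[["low"]] / total,
                 slice_index = slice_index),
            class = "slice_infarct_estimate")
}

#' @export
print.slice_infarct_estimate <- function(x, ...) {
  cat(sprintf(paste0("<slice_infarct_estimate> slice %d: low/med/high = ",
                     "%d/%d/%d, infarct %.2f%%\n"),
              x$slice_index, x$counts[["low"]], x$counts[["medium"]],
              x$counts[["high"]], x$infarct_pct))
  invisible(x)
}

#' Voxel-weighted whole-VOI infarct estimate
#'
#' Convenience aggregate over every short-axis slice intersecting the
#' mask: per-slice estimates are combined weighted by slice voxel count,
#' equivalent to pooling the per-slice low/viable counts.
#'
#' @inheritParams infarct_percentage
#' @return list with `per_slice` (list of `slice_infarct_estimate`) and
#'   `infarct_pct`, the pooled percentage.
#' @export
lv_infarct_summary <- function(v, mask, thresholds = NULL, n_bins = 64) {
  slices <- which(apply(mask$values, 3, any))
  per_slice <- lapply(slices, function(k)
    infarct_percentage(v, mask, k, thresholds = thresholds, n_bins = n_bins))
  low <- sum(vapply(per_slice, function(e) e$counts[["low"]], numeric(1)))
  total <- sum(vapply(per_slice, function(e) sum(e$counts), numeric(1)))
  list(per_slice = per_slice, infarct_pct = 100 * low / total)
}

#' Color thresholds for TTC stain segmentation
#'
#' Hue-saturation-lightness boxes separating dark-red viable myocardium,
#' tan infarct, and the white background of a tetrazolium stain
#' photograph. Hue in degrees \[0, 360); saturation and lightness in
#' \[0, 1\] (HSL). Defaults suit a standard TTC preparation but are
#' exposed because stain intensity varies between preparations.
#'
#' @param viable_hue_deg two hue intervals (reddish), given as a 2-column
#'   matrix of `c(lo, hi)` rows.
#' @param viable_sat_min minimum saturation of viable tissue.
#' @param infarct_hue_deg tan hue interval `c(lo, hi)`.
#' @param infarct_sat range `c(lo, hi)` of infarct saturation.
#' @param background_lightness_min lightness above which a pixel is
#'   background.
#' @return list of class `stain_color_config`.
#' @export
stain_color_config <- function(viable_hue_deg = rbind(c(330, 360), c(0, 20)),
                               viable_sat_min = 0.4,
                               infarct_hue_deg = c(20, 60),
                               infarct_sat = c(0.1, 0.5),
                               background_lightness_min = 0.9) {
  structure(list(viable_hue_deg = viable_hue_deg,
                 viable_sat_min = viable_sat_min,
                 infarct_hue_deg = infarct_hue_deg,
                 infarct_sat = infarct_sat,
                 background_lightness_min = background_lightness_min),
            class = "stain_color_config")
}

# RGB (H x W x 3 in [0,1]) -> hue (deg), saturation, lightness (HSL).
rgb_to_hsl <- function(image) {
  r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  l <- (mx + mn) / 2
  delta <- mx - mn
  s <- ifelse(delta == 0, 0, delta / (1 - abs(2 * l - 1)))
  h <- matrix(0, nrow(r), ncol(r))
  nz <- delta > 0
  hr <- nz & mx == r
  hg <- nz & !hr & mx == g
  hb <- nz & !hr & !hg
  h[hr] <- 60 * (((g[hr] - b[hr]) / delta[hr]) %% 6)
  h[hg] <- 60 * ((b[hg] - r[hg]) / delta[hg] + 2)
  h[hb] <- 60 * ((r[hb] - g[hb]) / delta[hb] + 4)
  list(h = h, s = s, l = l)
}

#' Infarct size from a TTC stain photograph
#'
#' Segments a tetrazolium-stained heart-slice photograph by color: the
#' white background is removed by a lightness threshold, then tissue
#' pixels are split into dark-red viable and tan infarct classes by the
#' hue-saturation boxes of a [stain_color_config()]. The infarct
#' percentage is the infarct pixel count over all classified tissue
#' pixels.
#'
#' @param image H x W x 3 RGB array in \[0, 1\].
#' @param config a [stain_color_config()].
#' @return An object of class `stain_segmentation`: list with
#'   `viable_mask`, `infarct_mask` (logical matrices), `n_unclassified`,
#'   and `infarct_pct`.
#' @export
stain_infarct <- function(image, config = stain_color_config()) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] >= 3L)
  hsl <- rgb_to_hsl(image[, , 1:3, drop = FALSE])
  tissue <- hsl$l < config$background_lightness_min
  if (!any(tissue))
    stop("validation error: no tissue pixels after background removal",
         call. = FALSE)
  in_hue <- function(h, box) h >= box[1] & h <= box[2]
  viable_hue <- Reduce(`|`, lapply(seq_len(nrow(config$viable_hue_deg)),
                                   function(i) in_hue(hsl$h,
                                     config$viable_hue_deg[i, ])))
  viable <- tissue & viable_hue & hsl$s > config$viable_sat_min
  infarct <- tissue & !viable & in_hue(hsl$h, config$infarct_hue_deg) &
    hsl$s >= config$infarct_sat[1] & hsl$s <= config$infarct_sat[2]
  n_classified <- sum(viable) + sum(infarct)
  if (n_classified == 0)
    stop("validation error: no tissue pixels matched either color class",
         call. = FALSE)
  structure(list(viable_mask = viable, infarct_mask = infarct,
                 n_unclassified = sum(tissue) - n_classified,
                 infarct_pct = 100 * sum(infarct) / n_classified),
            class = "stain_segmentation")
}

#' @export
print.stain_segmentation <- function(x, ...) {
  cat(sprintf(paste0("<stain_segmentation> viable %d px, infarct %d px ",
                     "(%d unclassified), infarct %.2f%%\n"),
              sum(x$viable_mask), sum(x$infarct_mask), x$n_unclassified,
              x$infarct_pct))
  invisible(x)
}
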