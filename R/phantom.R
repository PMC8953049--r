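#' Specification of a synthetic blood-pool PET phantom
#'
#' Declares the geometry, signal model and degradation model of the
#' digital phantoms used to validate the pipeline. The signal model is the
#' blood-pool model of labeled-erythrocyte imaging: the chamber blood pool
#' carries `blood_activity` (Bq/mL), while tissue carries only its vascular
#' fraction of that activity, `vascular_fraction * blood_activity`.
#' Pharmacological vasodilation multiplies the tissue vascular signal by
#' `1 + vasodilation_delta` (the chamber is unchanged); an optional infarct
#' wedge scales the tissue signal down inside a contiguous angular sector.
#' Degradations are an isotropic Gaussian point-spread blur (partial-volume
#' effect) followed by per-voxel Poisson count noise.
#'
#' @param grid_shape integer triple of voxel counts. Default `c(64, 64, 64)`.
#' @param voxel_size_mm isotropic voxel edge in mm. Default 1.4.
#' @param blood_activity blood-pool activity in Bq/mL.
#' @param vascular_fraction tissue vascular volume fraction in \[0, 1\].
#' @param vasodilation_delta fractional vasodilatory increase (>= 0) of the
#'   tissue vascular signal under stress; 0.5 means +50%.
#' @param infarct `NULL`, or `list(extent_deg =, scale =)`: a wedge of
#'   angular extent `extent_deg` degrees (in (0, 360]) about the long axis
#'   whose tissue signal is multiplied by `scale` in \[0, 1\].
#' @param psf_sigma_mm Gaussian point-spread sigma in mm (>= 0; 0 = no
#'   blur). Default 0.6, a sub-voxel value typical of small-animal PET
#'   intrinsic resolution.
#' @param noise `"none"` or `"poisson"`.
#' @param dwell_scale counts per (Bq/mL) per voxel for the Poisson model:
#'   counts are drawn as Poisson(activity * dwell_scale) and rescaled back
#'   to Bq/mL. Default 1 (high-count regime).
#' @param n_gates number of cardiac gate bins (>= 1). Default 4.
#' @param seed integer seed; every random draw flows from it, so phantoms
#'   are bit-reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64), voxel_size_mm = 1.4,
                         blood_activity = 20000, vascular_fraction = 0.1,
                         vasodilation_delta = 0, infarct = NULL,
                         psf_sigma_mm = 0.6,
                         noise = c("none", "poisson"), dwell_scale = 1,
                         n_gates = 4, seed = 1) {
  noise <- match.arg(noise)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape <= 0))
    stop("'grid_shape' must be a positive integer triple", call. = FALSE)
  if (voxel_size_mm <= 0) stop("'voxel_size_mm' must be > 0", call. = FALSE)
  if (blood_activity < 0) stop("'blood_activity' must be >= 0", call. = FALSE)
  if (vascular_fraction < 0 || vascular_fraction > 1)
    stop("'vascular_fraction' must lie in [0, 1]", call. = FALSE)
  if (vasodilation_delta < 0)
    stop("'vasodilation_delta' must be >= 0", call. = FALSE)
  if (!is.null(infarct)) {
    if (is.null(infarct$extent_deg) || is.null(infarct$scale))
      stop("'infarct' needs fields 'extent_deg' and 'scale'", call. = FALSE)
    if (infarct$extent_deg <= 0 || infarct$extent_deg > 360)
      stop("infarct wedge extent must lie in (0, 360] degrees", call. = FALSE)
    if (infarct$scale < 0 || infarct$scale > 1)
      stop("infarct activity scale must lie in [0, 1]", call. = FALSE)
  }
  if (psf_sigma_mm < 0) stop("'psf_sigma_mm' must be >= 0", call. = FALSE)
  if (dwell_scale <= 0) stop("'dwell_scale' must be > 0", call. = FALSE)
  if (n_gates < 1) stop("'n_gates' must be >= 1", call. = FALSE)
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 blood_activity = blood_activity,
                 vascular_fraction = vascular_fraction,
                 vasodilation_delta = vasodilation_delta, infarct = infarct,
                 psf_sigma_mm = psf_sigma_mm, noise = noise,
                 dwell_scale = dwell_scale, n_gates = as.integer(n_gates),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Physical voxel-centre coordinates (mm) relative to the grid centre.
grid_coords <- function(shape, vox) {
  lapply(1:3, function(k) (seq_len(shape[k]) - (shape[k] + 1) / 2) * vox)
}

# Shell-thickness modulation per gate: the cavity radius is scaled by a
# per-gate factor; gate 1 (largest cavity, thinnest wall) stands for
# diastole, mid-cycle gates stand for systole.
gate_cavity_factors <- function(n_gates) {
  if (n_gates == 1L) return(1)
  phase <- (seq_len(n_gates) - 1) / n_gates            # 0 = diastole
  1 - 0.2 * (1 - cos(2 * pi * phase)) / 2              # in [0.8, 1]
}

# Region masks for the LV geometry: axis-aligned ellipsoidal shell (long
# axis = grid axis 3) around an ellipsoidal blood-pool cavity.
lv_regions <- function(spec, cavity_factor = 1) {
  shape <- spec$grid_shape
  half_mm <- shape * spec$voxel_size_mm / 2
  co <- grid_coords(shape, spec$voxel_size_mm)
  out_ax <- c(0.55, 0.55, 0.75) * half_mm   # outer semi-axes, mm
  cav_ax <- c(0.35, 0.35, 0.55) * half_mm * cavity_factor
  qx_o <- (co[[1]] / out_ax[1])^2; qy_o <- (co[[2]] / out_ax[2])^2
  qz_o <- (co[[3]] / out_ax[3])^2
  qx_c <- (co[[1]] / cav_ax[1])^2; qy_c <- (co[[2]] / cav_ax[2])^2
  qz_c <- (co[[3]] / cav_ax[3])^2
  outer_q <- outer(outer(qx_o, qy_o, `+`), qz_o, `+`)
  cav_q <- outer(outer(qx_c, qy_c, `+`), qz_c, `+`)
  chamber <- cav_q <= 1
  shell <- (outer_q <= 1) & !chamber
  list(shell = shell, chamber = chamber)
}

# Wedge membership: azimuth about the long axis within +/- extent/2 of 0.
wedge_mask <- function(shape, vox, extent_deg) {
  co <- grid_coords(shape, vox)
  theta <- outer(co[[1]], co[[2]], function(x, y) atan2(y, x)) * 180 / pi
  in_wedge2d <- abs(theta) <= extent_deg / 2
  array(rep(in_wedge2d, shape[3]), dim = shape)
}

tissue_signal <- function(spec, mode) {
  s <- spec$vascular_fraction * spec$blood_activity
  if (mode == "stress") s <- s * (1 + spec$vasodilation_delta)
  s
}

degrade <- function(values, spec) {
  if (spec$psf_sigma_mm > 0)
    values <- gaussian_blur3d(values, spec$psf_sigma_mm, spec$voxel_size_mm)
  if (spec$noise == "poisson") {
    counts <- stats::rpois(length(values), values * spec$dwell_scale)
    values <- array(counts / spec$dwell_scale, dim = dim(values))
  }
  values
}

#' Generate a gated left-ventricle blood-pool phantom
#'
#' Builds a cardiac-gated rest or stress phantom: an ellipsoidal
#' myocardial shell (signal = vascular fraction of blood activity, times
#' the vasodilation multiplier under stress, times the infarct scale inside
#' the wedge) around a blood-pool chamber at full blood activity. Gates
#' differ only by a prescribed shell-thickness modulation; gate 1 is the
#' diastolic (thinnest-wall, largest-cavity) state on which quantification
#' is performed. The noiseless, blur-free construction is exactly
#' piecewise-constant; blur and Poisson noise are applied per gate when
#' requested, all randomness flowing from `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @param mode `"rest"` or `"stress"`.
#' @return An object of class `gated_phantom`: list with `gates` (list of
#'   [volume_grid()]), `myocardium_mask` and `chamber_mask`
#'   ([voi_mask()]s of the diastolic state), `diastolic_gate_index`, and
#'   `truth` (the spec plus the exact per-region values).
#' @export
make_lv_phantom <- function(spec, mode = c("rest", "stress")) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "phantom_spec"))
  factors <- gate_cavity_factors(spec$n_gates)
  shell_value <- tissue_signal(spec, mode)
  wedge <- if (!is.null(spec$infarct))
    wedge_mask(spec$grid_shape, spec$voxel_size_mm, spec$infarct$extent_deg)
  dia <- lv_regions(spec, cavity_factor = max(factors))
  if (!is.null(spec$infarct) && !any(dia$shell & wedge))
    stop("infarct wedge does not intersect the myocardial shell",
         call. = FALSE)
  gates <- withr::with_seed(spec$seed, lapply(factors, function(f) {
    reg <- lv_regions(spec, cavity_factor = f)
    vals <- array(0, dim = spec$grid_shape)
    vals[reg$shell] <- shell_value
    if (!is.null(spec$infarct))
      vals[reg$shell & wedge] <- shell_value * spec$infarct$scale
    vals[reg$chamber] <- spec$blood_activity
    volume_grid(degrade(vals, spec), voxel_size_mm = spec$voxel_size_mm,
                unit = "Bq_per_mL")
  }))
  truth <- c(unclass(spec),
             list(mode = mode, shell_value = shell_value,
                  infarct_value = if (!is.null(spec$infarct))
                    shell_value * spec$infarct$scale))
  structure(list(gates = gates,
                 myocardium_mask = voi_mask(dia$shell,
                                            voxel_size_mm = spec$voxel_size_mm),
                 chamber_mask = voi_mask(dia$chamber,
                                         voxel_size_mm = spec$voxel_size_mm),
                 diastolic_gate_index = which.max(factors),
                 truth = truth),
            class = "gated_phantom")
}

#' @export
print.gated_phantom <- function(x, ...) {
  cat(sprintf("<gated_phantom> %d gates, %d myocardial voxels, mode %s\n",
              length(x$gates), sum(x$myocardium_mask$values), x$truth$mode))
  invisible(x)
}

#' Generate a whole-brain blood-pool phantom
#'
#' A filled axis-aligned ellipsoid whose uniform signal is the vascular
#' fraction of blood activity, multiplied by `1 + vasodilation_delta` under
#' stress — the cerebrovascular analogue of [make_lv_phantom()] with no
#' chamber and no gating.
#'
#' @inheritParams make_lv_phantom
#' @return list with `volume` (a [volume_grid()]), `mask` (a [voi_mask()]),
#'   and `truth`.
#' @export
make_brain_phantom <- function(spec, mode = c("rest", "stress")) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$grid_shape
  half_mm <- shape * spec$voxel_size_mm / 2
  co <- grid_coords(shape, spec$voxel_size_mm)
  ax <- c(0.6, 0.6, 0.7) * half_mm
  q <- outer(outer((co[[1]] / ax[1])^2, (co[[2]] / ax[2])^2, `+`),
             (co[[3]] / ax[3])^2, `+`)
  brain <- q <= 1
  value <- tissue_signal(spec, mode)
  vals <- array(0, dim = shape)
  vals[brain] <- value
  vol <- withr::with_seed(spec$seed,
    volume_grid(degrade(vals, spec), voxel_size_mm = spec$voxel_size_mm,
                unit = "Bq_per_mL"))
  list(volume = vol,
       mask = voi_mask(brain, voxel_size_mm = spec$voxel_size_mm),
       truth = c(unclass(spec), list(mode = mode, brain_value = value)))
}

#' Separable 3D Gaussian blur
#'
#' Isotropic Gaussian point-spread convolution in physical units, applied
#' as three successive 1D convolutions with a kernel truncated at 4 sigma
#' and zero padding at the grid edge. Interior activity is conserved; only
#' mass blurred across the boundary is lost.
#'
#' @param values 3D numeric array.
#' @param sigma_mm Gaussian sigma in mm.
#' @param voxel_size_mm voxel edge in mm.
#' @return blurred array of the same shape.
#' @export
gaussian_blur3d <- function(values, sigma_mm, voxel_size_mm) {
  if (sigma_mm == 0) return(values)
  sigma_vox <- sigma_mm / voxel_size_mm
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- stats::dnorm(-r:r, sd = sigma_vox)
  k <- k / sum(k)
  d <- dim(values)
  for (axis in 1:3) {
    n <- d[axis]
    band <- outer(seq_len(n), seq_len(n),
                  function(i, j) ifelse(abs(i - j) <= r, k[abs(i - j) + r + 1], 0))
    perm <- c(axis, setdiff(1:3, axis))
    x <- aperm(values, perm)
    xm <- matrix(x, nrow = n)
    y <- band %*% xm
    values <- aperm(array(y, dim = d[perm]), order(perm))
  }
  values
}

#' Generate a synthetic TTC-stained heart-slice photograph
#'
#' Renders the annular cross-section of a tetrazolium-stained myocardial
#' slice on a white background: viable tissue dark red, an angular infarct
#' wedge tan, with seeded per-pixel color jitter. The ground-truth label
#' mask is returned alongside, so stain segmentation can be validated
#' against known wedge fractions.
#'
#' @param wedge_fraction fraction of the annulus rendered as infarct, in
#'   \[0, 1\].
#' @param image_size image edge in pixels (square image).
#' @param viable_color,infarct_color RGB triples in \[0, 1\].
#' @param inner_frac,outer_frac annulus radii as fractions of the half
#'   image edge; `0 <= inner_frac < outer_frac` required.
#' @param jitter_sd standard deviation of the Gaussian RGB jitter (0 for an
#'   exact two-color image).
#' @param seed integer seed; a fixed seed reproduces the image
#'   byte-identically.
#' @return list with `image` (H x W x 3 array in \[0, 1\]) and `truth`
#'   (integer matrix: 0 background, 1 viable, 2 infarct).
#' @export
make_ttc_image <- function(wedge_fraction, image_size = 256,
                           viable_color = c(0.55, 0.08, 0.10),
                           infarct_color = c(0.82, 0.71, 0.55),
                           inner_frac = 0.18, outer_frac = 0.42,
                           jitter_sd = 0.01, seed = 1) {
  if (wedge_fraction < 0 || wedge_fraction > 1)
    stop("'wedge_fraction' must lie in [0, 1]", call. = FALSE)
  if (inner_frac < 0 || inner_frac >= outer_frac || outer_frac <= 0)
    stop("degenerate annulus: need 0 <= inner_frac < outer_frac", call. = FALSE)
  n <- as.integer(image_size)
  cc <- (seq_len(n) - (n + 1) / 2) / (n / 2)
  r2 <- outer(cc^2, cc^2, `+`)
  annulus <- r2 >= inner_frac^2 & r2 <= outer_frac^2
  theta <- outer(cc, cc, function(x, y) atan2(y, x)) * 180 / pi
  wedge <- annulus & (abs(theta) <= wedge_fraction * 180)
  truth <- matrix(0L, n, n)
  truth[annulus] <- 1L
  truth[wedge] <- 2L
  img <- array(1, dim = c(n, n, 3))
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[truth == 1L] <- viable_color[ch]
    plane[truth == 2L] <- infarct_color[ch]
    img[, , ch] <- plane
  }
  if (jitter_sd > 0) {
    img <- withr::with_seed(seed, {
      jit <- array(stats::rnorm(length(img), sd = jitter_sd), dim = dim(img))
      jit[rep(truth == 0L, 3)] <- 0       # background stays clean white
      pmin(pmax(img + jit, 0), 1)
    })
  }
  list(image = img, truth = truth)
}

#' Write a phantom to disk with its provenance sidecar
#'
#' Writes the diastolic gate and both masks as NIfTI plus a JSON sidecar
#' recording the full [phantom_spec()], so any phantom on disk can be
#' regenerated exactly.
#'
#' @param phantom a `gated_phantom`.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return invisibly, the paths written.
#' @export
write_phantom <- function(phantom, dir, prefix = "phantom") {
  stopifnot(inherits(phantom, "gated_phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    volume = file.path(dir, paste0(prefix, "_diastole.nii.gz")),
    myocardium = file.path(dir, paste0(prefix, "_myocardium.nii.gz")),
    chamber = file.path(dir, paste0(prefix, "_chamber.nii.gz")),
    spec = file.path(dir, paste0(prefix, "_spec.json")))
  write_volume(phantom$gates[[phantom$diastolic_gate_index]], paths["volume"])
  write_mask(phantom$myocardium_mask, paths["myocardium"])
  write_mask(phantom$chamber_mask, paths["chamber"])
  jsonlite::write_json(phantom$truth, paths["spec"], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}
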