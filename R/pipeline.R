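#' Run a stress/rest vasodilation phantom study end to end
#'
#' For each subject: generate a rest and a stress phantom (noise drawn
#' independently per condition from the subject's seed), co-register the
#' stress volume to the rest volume by mask centroids, compute the clipped
#' stress-rest difference and the increased ratio, and finish with the
#' exact paired signed-rank test of the stress vs rest activity sums. The
#' per-subject table has the standard stress/rest column layout (stress
#' sum, rest sum, clipped difference sum, increased ratio). Identical
#' configuration and seeds reproduce the table exactly.
#'
#' @param organ `"lv"` (gated shell phantom, diastolic gate quantified) or
#'   `"brain"` (filled ellipsoid).
#' @param deltas numeric vector of per-subject vasodilation deltas (one
#'   subject per element).
#' @param base_spec a [phantom_spec()] providing every other phantom
#'   parameter.
#' @param seeds integer vector of unique per-subject seeds (defaults to
#'   `seq_along(deltas)`); the stress acquisition of subject i uses
#'   `seeds[i] + 1000003L` so rest and stress noise are independent.
#' @param out_csv optional path; when given the subject table is written
#'   as CSV.
#' @return list with `table` (data frame: `subject`, `delta`,
#'   `stress_sum`, `rest_sum`, `clipped_diff_sum`, `increased_ratio_pct`),
#'   `test` (a `rank_test_result`), and `summary` (`mean_se` of the
#'   ratios).
#' @export
run_vasodilation_study <- function(organ = c("lv", "brain"), deltas,
                                   base_spec = phantom_spec(),
                                   seeds = seq_along(deltas),
                                   out_csv = NULL) {
  organ <- match.arg(organ)
  stopifnot(length(deltas) >= 1, length(seeds) == length(deltas))
  if (anyDuplicated(seeds)) stop("per-subject seeds must be unique",
                                 call. = FALSE)
  rows <- lapply(seq_along(deltas), function(i) {
    spec_of <- function(delta, seed) {
      s <- base_spec
      s$vasodilation_delta <- delta
      s$seed <- as.integer(seed)
      s
    }
    rest_spec <- spec_of(0, seeds[i])
    stress_spec <- spec_of(deltas[i], seeds[i] + 1000003L)
    if (organ == "lv") {
      rest <- make_lv_phantom(rest_spec, "rest")
      stress <- make_lv_phantom(stress_spec, "stress")
      rest_v <- rest$gates[[rest$diastolic_gate_index]]
      stress_v <- stress$gates[[stress$diastolic_gate_index]]
      rest_m <- rest$myocardium_mask
      stress_m <- stress$myocardium_mask
    } else {
      rest <- make_brain_phantom(rest_spec, "rest")
      stress <- make_brain_phantom(stress_spec, "stress")
      rest_v <- rest$volume; stress_v <- stress$volume
      rest_m <- rest$mask; stress_m <- stress$mask
    }
    reg <- register_rigid(stress_v, stress_m, rest_v, rest_m)
    res <- increased_ratio(reg$volume, rest_v, rest_m)
    data.frame(subject = i, delta = deltas[i], stress_sum = res$stress_sum,
               rest_sum = res$rest_sum,
               clipped_diff_sum = res$clipped_diff_sum,
               increased_ratio_pct = res$increased_ratio_pct)
  })
  table <- do.call(rbind, rows)
  test <- signed_rank_exact(table$stress_sum, table$rest_sum)
  summary <- if (nrow(table) >= 2) mean_se(table$increased_ratio_pct)
  if (!is.null(out_csv)) utils::write.csv(table, out_csv, row.names = FALSE)
  list(table = table, test = test, summary = summary)
}

#' Run a myocardial infarction phantom study end to end
#'
#' For each subject: generate an LV phantom carrying an infarct wedge,
#' size the infarct on the mid short-axis slice by three-class Otsu
#' stratification of the diastolic gate, render the matched synthetic TTC
#' stain image with the same wedge fraction and size the infarct by color
#' thresholding, then summarize both methods as mean +/- SE.
#'
#' @param wedge_fractions per-subject infarct wedge fractions of the
#'   annulus/shell, in \[0, 1\] (wedge angular extent =
#'   `360 * wedge_fraction` degrees).
#' @param infarct_scale residual activity scale inside the wedge
#'   (default 0, a complete perfusion defect).
#' @param base_spec a [phantom_spec()]; its `infarct` field is overridden
#'   per subject.
#' @param seeds unique per-subject integer seeds.
#' @param stain_jitter_sd RGB jitter of the synthetic stain images.
#' @param out_csv optional CSV path for the subject table.
#' @return list with `table` (`subject`, `wedge_fraction`,
#'   `pet_infarct_pct`, `stain_infarct_pct`), and `summary` (per-method
#'   `mean_se`, when n >= 2).
#' @export
run_infarct_study <- function(wedge_fractions, infarct_scale = 0,
                              base_spec = phantom_spec(),
                              seeds = seq_along(wedge_fractions),
                              stain_jitter_sd = 0.01, out_csv = NULL) {
  stopifnot(length(wedge_fractions) >= 1,
            length(seeds) == length(wedge_fractions))
  if (anyDuplicated(seeds)) stop("per-subject seeds must be unique",
                                 call. = FALSE)
  rows <- lapply(seq_along(wedge_fractions), function(i) {
    s <- base_spec
    s$infarct <- list(extent_deg = 360 * wedge_fractions[i],
                      scale = infarct_scale)
    s$seed <- as.integer(seeds[i])
    ph <- make_lv_phantom(s, "rest")
    v <- ph$gates[[ph$diastolic_gate_index]]
    mid <- round(dim(v$values)[3] / 2)
    pet <- infarct_percentage(v, ph$myocardium_mask, mid)
    ttc <- make_ttc_image(wedge_fractions[i], seed = seeds[i],
                          jitter_sd = stain_jitter_sd)
    stain <- stain_infarct(ttc$image)
    data.frame(subject = i, wedge_fraction = wedge_fractions[i],
               pet_infarct_pct = pet$infarct_pct,
               stain_infarct_pct = stain$infarct_pct)
  })
  table <- do.call(rbind, rows)
  summary <- if (nrow(table) >= 2)
    list(pet = mean_se(table$pet_infarct_pct),
         stain = mean_se(table$stain_infarct_pct))
  if (!is.null(out_csv)) utils::write.csv(table, out_csv, row.names = FALSE)
  list(table = table, summary = summary)
}
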