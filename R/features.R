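# Feature extraction from a landmarked ADC profile.
#
# The feature vector holds, in order: gradient 1 over A-B (edema rise), the
# mean / SD / median of plateau 1 (B-C, perilesional edema), gradient 2 over
# C-D (edema-to-ring fall, signed, negative when ADC falls), gradient 3 over
# D-E (ring-to-core rise), and the mean / SD / median of plateau 2 (E-F, the
# lesion core). The seven-predictor subset drops the two means and keeps the
# three gradients plus the median and SD of each plateau.

#' Two-point gradient along a profile
#'
#' `(value[j] - value[i]) / (position[j] - position[i])` — an endpoint
#' two-point slope, no fitting. Gradients are signed: a falling segment has a
#' negative gradient.
#'
#' @param profile An [adc_profile()].
#' @param i,j Indices with `i < j`.
#' @param units `"per_px"` (default) or `"per_mm"`.
#' @return Gradient in ADC units per pixel (or per mm).
#' @export
adc_gradient <- function(profile, i, j, units = c("per_px", "per_mm")) {
  stopifnot(inherits(profile, "adc_profile"))
  units <- match.arg(units)
  n <- length(profile$values)
  if (i == j) stopf("degenerate gradient: i == j (%d)", i)
  if (i > j) stopf("gradient endpoints must satisfy i < j")
  if (i < 1L || j > n) stopf("gradient indices out of range [1, %d]", n)
  pos <- if (units == "per_px") profile$positions_px else profile$positions_mm
  (profile$values[j] - profile$values[i]) / (pos[j] - pos[i])
}

#' Summary statistics over an inclusive profile segment
#'
#' @param profile An [adc_profile()].
#' @param i,j Segment endpoints (inclusive), `j - i >= 2`.
#' @return Named numeric: `mean`, `std` (sample SD, denominator n-1),
#'   `median`.
#' @export
segment_stats <- function(profile, i, j) {
  stopifnot(inherits(profile, "adc_profile"))
  if (j - i < 2L) stopf("segment [%d, %d] too short: need >= 3 samples", i, j)
  if (i < 1L || j > length(profile$values))
    stopf("segment indices out of range")
  x <- profile$values[i:j]
  c(mean = mean(x), std = stats::sd(x), median = stats::median(x))
}

#' Extract the feature vector from a landmarked profile
#'
#' @param profile An [adc_profile()].
#' @param landmarks A [profile_landmarks()] valid for the profile.
#' @param feature_set `"nine"` (default; the full vector) or `"seven"` (drops
#'   `mean_E` and `mean_T`, the seven-predictor subset used for the
#'   classifiers; the dropped entries are returned as `NA`).
#' @param units Gradient units, `"per_px"` (default) or `"per_mm"`.
#' @param gradient_mode `"signed"` (default) or `"magnitude"` (absolute
#'   slopes, the way boxplot summaries aggregate them).
#' @return Named numeric vector with the nine feature names (see
#'   [read_features_csv()] for the ordering contract).
#' @export
extract_features <- function(profile, landmarks,
                             feature_set = c("nine", "seven"),
                             units = c("per_px", "per_mm"),
                             gradient_mode = c("signed", "magnitude")) {
  stopifnot(inherits(profile, "adc_profile"),
            inherits(landmarks, "profile_landmarks"))
  feature_set <- match.arg(feature_set)
  units <- match.arg(units)
  gradient_mode <- match.arg(gradient_mode)
  if (landmarks$f > length(profile$values))
    stopf("landmarks extend beyond the profile")
  g1 <- adc_gradient(profile, landmarks$a, landmarks$b, units)
  g2 <- adc_gradient(profile, landmarks$c, landmarks$d, units)
  g3 <- adc_gradient(profile, landmarks$d, landmarks$e, units)
  if (gradient_mode == "magnitude") { g1 <- abs(g1); g2 <- abs(g2); g3 <- abs(g3) }
  p1 <- segment_stats(profile, landmarks$b, landmarks$c)
  p2 <- segment_stats(profile, landmarks$e, landmarks$f)
  fv <- c(grad_E_rise = g1, mean_E = p1[["mean"]], std_E = p1[["std"]],
          median_E = p1[["median"]], grad_E_fall = g2, grad_T_rise = g3,
          mean_T = p2[["mean"]], std_T = p2[["std"]],
          median_T = p2[["median"]])
  if (feature_set == "seven") fv[c("mean_E", "mean_T")] <- NA_real_
  fv
}

#' Names of the active feature columns for a feature set
#'
#' @param feature_set `"nine"` or `"seven"`.
#' @return Character vector of feature column names.
#' @export
feature_names <- function(feature_set = c("nine", "seven")) {
  feature_set <- match.arg(feature_set)
  if (feature_set == "nine") FEATURE_COLUMNS
  else setdiff(FEATURE_COLUMNS, c("mean_E", "mean_T"))
}
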