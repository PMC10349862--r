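# Landmark placement on a cross-sectional ADC profile.
#
# Six points divide the profile into the segments used downstream:
#   A  onset of the perilesional edema elevation
#   B  start of the edema plateau (plateau 1)
#   C  end of the edema plateau, where ADC starts to fall toward the ring
#   D  ring minimum (most intense restriction between edema and core)
#   E  start of the core plateau (plateau 2)
#   F  last profile sample (lesion center)
# In the clinical workflow these are placed by a radiologist; the automatic
# detector here is an explicit heuristic stand-in used for synthetic data and
# as a starting point for manual correction. Manual annotations always win
# when both are supplied.

#' Construct profile landmarks
#'
#' @param a,b,c,d,e,f Integer 1-based indices into an [adc_profile()],
#'   strictly increasing. Segments `a..b`, `c..d`, `d..e` must hold at least 2
#'   samples; the plateau segments `b..c` and `e..f` at least 3 (so a median
#'   and a standard deviation are well defined).
#' @param method `"manual"` or `"auto"`.
#' @return An object of class `profile_landmarks`.
#' @export
profile_landmarks <- function(a, b, c, d, e, f, method = "manual") {
  idx <- stats::setNames(as.numeric(c(a, b, c, d, e, f)),
                         c("a", "b", "c", "d", "e", "f"))
  if (any(!is.finite(idx)) || any(idx != round(idx)))
    stopf("landmark indices must be integers")
  idx[] <- as.integer(round(idx))
  if (idx["a"] < 1L) stopf("landmark 'a' must be >= 1")
  if (any(diff(idx) <= 0L))
    stopf("landmarks must satisfy a < b < c < d < e < f (violated at '%s')",
          names(idx)[which(diff(idx) <= 0L)[1] + 1L])
  if (idx["c"] - idx["b"] < 2L)
    stopf("plateau 1 (b..c) needs >= 3 samples")
  if (idx["f"] - idx["e"] < 2L)
    stopf("plateau 2 (e..f) needs >= 3 samples")
  structure(list(a = idx[["a"]], b = idx[["b"]], c = idx[["c"]],
                 d = idx[["d"]], e = idx[["e"]], f = idx[["f"]],
                 method = match.arg(method, c("manual", "auto"))),
            class = "profile_landmarks")
}

#' @export
print.profile_landmarks <- function(x, ...) {
  cat(sprintf("profile landmarks (%s): A=%d B=%d C=%d D=%d E=%d F=%d\n",
              x$method, x$a, x$b, x$c, x$d, x$e, x$f))
  invisible(x)
}

landmark_indices <- function(lm) c(lm$a, lm$b, lm$c, lm$d, lm$e, lm$f)

#' Detector parameters
#'
#' Tunables of the automatic landmark detector. Slopes are estimated on a
#' moving-average-smoothed profile as central differences over half the
#' smoothing window; a ramp is a sustained run of slope magnitude above
#' `rise_slope_threshold`, a plateau a sustained run below
#' `plateau_slope_threshold`. Defaults recover the default noise-free phantom
#' exactly and are declared configuration, not clinical ground truth.
#'
#' @param smoothing_window Odd integer >= 3; default 5.
#' @param rise_slope_threshold ADC units per pixel; default 15.
#' @param plateau_slope_threshold ADC units per pixel; default 8.
#' @param min_plateau_len Minimum sustained run length in samples; default 3.
#' @return An object of class `detector_params`.
#' @export
detector_params <- function(smoothing_window = 5L, rise_slope_threshold = 15,
                            plateau_slope_threshold = 8, min_plateau_len = 3L) {
  smoothing_window <- as.integer(smoothing_window)
  if (smoothing_window < 3L || smoothing_window %% 2L == 0L)
    stopf("'smoothing_window' must be an odd integer >= 3")
  check_scalar(rise_slope_threshold, "rise_slope_threshold", positive = TRUE)
  check_scalar(plateau_slope_threshold, "plateau_slope_threshold", positive = TRUE)
  if (min_plateau_len < 1L) stopf("'min_plateau_len' must be >= 1")
  structure(list(smoothing_window = smoothing_window,
                 rise_slope_threshold = rise_slope_threshold,
                 plateau_slope_threshold = plateau_slope_threshold,
                 min_plateau_len = as.integer(min_plateau_len)),
            class = "detector_params")
}

# Central-difference slope of a series over half-width h (per sample step);
# NA at the h edge samples.
central_slope <- function(s, h) {
  n <- length(s)
  out <- rep(NA_real_, n)
  idx <- (h + 1L):(n - h)
  out[idx] <- (s[idx + h] - s[idx - h]) / (2 * h)
  out
}

# All runs of at least `minlen` consecutive TRUE within [from, to]; runs
# separated by gaps of <= `gap` are merged. Returns a list of c(start, end).
find_runs <- function(flag, from = 1L, to = length(flag), minlen = 2L,
                      gap = 0L) {
  flag[is.na(flag)] <- FALSE
  idx <- which(flag)
  idx <- idx[idx >= from & idx <= to]
  if (!length(idx)) return(list())
  splits <- cumsum(c(1L, diff(idx) > gap + 1L))
  out <- list()
  for (g in unique(splits)) {
    run <- idx[splits == g]
    if (length(run) >= minlen)
      out[[length(out) + 1L]] <- c(run[1], run[length(run)])
  }
  out
}

# The run with the largest amplitude `sign * (s[end] - s[start])`; noise can
# produce short spurious threshold crossings, but only a true ramp moves the
# smoothed profile by a large amount.
pick_run <- function(runs, s, sign = 1) {
  if (!length(runs)) return(NULL)
  amp <- vapply(runs, function(r) sign * (s[r[2]] - s[r[1]]), 1)
  runs[[which.max(amp)]]
}

# Least-squares line v ~ pos over index range; returns c(intercept, slope).
fit_line <- function(pos, val, idx) {
  if (length(idx) < 2L) return(NULL)
  ft <- stats::lm.fit(cbind(1, pos[idx]), val[idx])
  ft$coefficients
}

# Index whose position is nearest the intersection of line (a0 + a1*x) with
# the horizontal level `lev`.
intersect_index <- function(pos, line, lev) {
  if (is.null(line) || abs(line[2]) < 1e-12) return(NA_integer_)
  x <- (lev - line[1]) / line[2]
  which.min(abs(pos - x))
}

detect_fail <- function(point, why) {
  stopf("landmark detection failed at point %s: %s", point, why)
}

#' Automatically place landmarks A-F on a profile
#'
#' Two-stage heuristic. The coarse stage thresholds slopes of the smoothed
#' profile to locate the edema rise, the fall toward the ring, and (when
#' present) the rise into the core. The refinement stage estimates the
#' background, edema-plateau and core-plateau levels from raw-sample medians,
#' fits least-squares lines to the interior of each ramp, and places A, B, C
#' and E at the line/level intersections; D is the earliest raw-value minimum
#' within the detected fall region, as the ring minimum is a raw-profile
#' feature. On noise-free piecewise-linear profiles the intersections recover
#' the construction breakpoints exactly.
#'
#' @param profile An [adc_profile()] with at least 15 samples.
#' @param params A [detector_params()].
#' @return A [profile_landmarks()] with `method = "auto"`.
#' @export
detect_landmarks <- function(profile, params = detector_params()) {
  stopifnot(inherits(profile, "adc_profile"))
  v <- profile$values
  pos <- profile$positions_px
  n <- length(v)
  if (n < 15L) stopf("profile too short for detection (%d < 15 samples)", n)
  step <- stats::median(diff(pos))
  w <- params$smoothing_window
  hw <- w %/% 2L
  h <- max(1L, hw)
  s <- moving_average(v, w)
  slope <- central_slope(s, h) / step
  rise_thr <- params$rise_slope_threshold
  plat_thr <- params$plateau_slope_threshold
  minrun <- max(2L, params$min_plateau_len - 1L)
  trim0 <- h + hw

  fit_ramp <- function(run, direction, min_pts = 5L) {
    # threshold runs overshoot the true ramp by a slope-dependent number of
    # samples (smoothing smear); on noise-free data the overshoot is exposed
    # by the fit residuals, so accept the smallest trim whose interior is
    # collinear to machine precision
    best <- NULL; best_n <- 0L
    for (lt in 0:trim0) for (rt in 0:trim0) {
      lo <- run[1] + lt; hi <- run[2] - rt
      np <- hi - lo + 1L
      if (np < 3L || np <= best_n) next
      line <- fit_line(pos, v, lo:hi)
      resid <- v[lo:hi] - (line[1] + line[2] * pos[lo:hi])
      if (sqrt(mean(resid^2)) <= 1e-6 * (1 + max(abs(v[lo:hi]))) &&
          is.finite(line[2]) && direction * line[2] > 0) {
        best <- line; best_n <- np
      }
    }
    if (!is.null(best)) return(best)
    # noisy data: trim as far as possible while keeping min_pts samples
    trim <- trim0
    while (trim > 0L && (run[2] - trim) - (run[1] + trim) + 1L < min_pts)
      trim <- trim - 1L
    idx <- seq.int(run[1] + trim, run[2] - trim)
    if (length(idx) < 2L) return(NULL)
    line <- fit_line(pos, v, idx)
    if (is.null(line) || !is.finite(line[2]) || direction * line[2] <= 0) {
      # degenerate noisy fit: fall back to the run-amplitude slope through
      # the run midpoint (never triggered on noise-free ramps)
      beta <- (s[run[2]] - s[run[1]]) / (pos[run[2]] - pos[run[1]])
      if (!is.finite(beta) || direction * beta <= 0) return(NULL)
      mid_x <- mean(pos[run[1]:run[2]]); mid_y <- mean(s[run[1]:run[2]])
      line <- c(mid_y - beta * mid_x, beta)
    }
    line
  }

  # --- coarse stage ---------------------------------------------------------
  # the edema-to-ring fall is the largest sustained descent; the edema rise
  # is the largest ascent before it, the core rise (if any) the largest
  # ascent after it
  all_rises <- find_runs(slope >= rise_thr, minlen = minrun, gap = 1L)
  if (!length(all_rises))
    detect_fail("A", "no sustained rise above rise_slope_threshold")
  fall <- pick_run(find_runs(slope <= -rise_thr, minlen = minrun, gap = 2L),
                   s, sign = -1)
  if (is.null(fall))
    detect_fail("C", "no sustained fall toward the ring")
  rise1 <- pick_run(find_runs(slope >= rise_thr, to = fall[1] - 1L,
                              minlen = minrun, gap = 1L), s)
  if (is.null(rise1))
    detect_fail("A", "no sustained rise above rise_slope_threshold before the fall")
  rise3 <- pick_run(find_runs(slope >= rise_thr, from = fall[2] + 1L,
                              minlen = minrun, gap = 1L), s)

  # --- level estimates ------------------------------------------------------
  bg_hi <- rise1[1] - h
  if (bg_hi < 1L) detect_fail("A", "no background run-in before the rise")
  bg_level <- stats::median(v[1:bg_hi])
  p1_lo <- rise1[2] + 2L; p1_hi <- fall[1] - 2L
  if (p1_lo > p1_hi) { p1_lo <- rise1[2]; p1_hi <- fall[1] }
  if (p1_lo > p1_hi) detect_fail("B", "no samples between rise and fall")
  p1_idx <- p1_lo:p1_hi
  p1_level <- stats::median(v[p1_idx])
  tail_lo <- max(fall[2] + 1L, n - max(params$min_plateau_len,
                                       (n - fall[2]) %/% 2L) + 1L)
  tail_lo <- min(tail_lo, n - 2L)
  p2_level <- stats::median(v[tail_lo:n])

  # --- refinement -----------------------------------------------------------
  line1 <- fit_ramp(rise1, 1)
  if (is.null(line1)) detect_fail("A", "no usable edema-rise ramp")
  a <- intersect_index(pos, line1, bg_level)
  b <- intersect_index(pos, line1, p1_level)
  line2 <- fit_ramp(fall, -1)
  if (is.null(line2)) detect_fail("C", "no usable edema-to-ring fall")
  cc <- intersect_index(pos, line2, p1_level)
  if (is.na(a)) detect_fail("A", "degenerate ramp fit (zero slope)")
  a <- max(a, 1L)
  # intersections can disorder under heavy noise; fall back to the coarse
  # run boundaries, which sit just inside the plateau
  if (is.na(b) || b <= a) b <- min(max(a + 1L, rise1[2]), n - 4L)
  if (is.na(cc) || cc < b + 2L) cc <- max(b + 2L, fall[1] - 1L)
  if (cc >= n - 3L) detect_fail("C", "no room for the ring and core after C")

  d_hi <- min(max(fall[2], cc) + 2L, n - 1L)
  d_lo <- max(cc + 1L, fall[1])
  if (d_lo > d_hi) detect_fail("D", "empty search window after C")
  d_window <- d_lo:d_hi
  d <- d_window[which.min(v[d_window])]          # earliest index on ties

  e <- NA_integer_
  if (!is.null(rise3)) {
    line3 <- fit_ramp(rise3, 1)
    if (!is.null(line3) && line3[2] > 1e-12)
      e <- intersect_index(pos, line3, p2_level)
  }
  if (is.na(e)) {
    # weak core rise (core barely above the ring): fit a short line from D to
    # the first smoothed-by-3 sample reaching the core plateau level
    s3 <- moving_average(v, 3L)
    noise_est <- stats::mad(v[tail_lo:n], constant = 1.4826)
    delta <- max((p2_level - v[d]) / 4, noise_est, .Machine$double.eps)
    k <- which(s3 >= p2_level - delta & seq_len(n) > d)
    k <- if (length(k)) max(d + 2L, min(k[1], n - 3L)) else d + 2L
    line3 <- fit_line(pos, v, seq.int(d, min(k, n)))
    e <- if (!is.null(line3) && line3[2] > 1e-12)
      intersect_index(pos, line3, p2_level) else d + 2L
  }
  e <- min(max(e, d + 1L), n - 2L)

  lm <- try(profile_landmarks(a, b, cc, d, e, n, method = "auto"),
            silent = TRUE)
  if (inherits(lm, "try-error"))
    detect_fail("ordering", conditionMessage(attr(lm, "condition")))
  lm
}

#' Validate landmarks against a profile
#'
#' Hard errors only on ordering/length violations (checked by
#' [profile_landmarks()] and against the profile length); expected-dynamics
#' checks — the ring minimum D lying below the edema plateau median and at or
#' below the value at E — produce soft warnings in the report, since real
#' lesions may deviate (abscesses occasionally show GBM-like high core ADC and
#' vice versa).
#'
#' @param profile An [adc_profile()].
#' @param landmarks A [profile_landmarks()].
#' @return Data frame report with columns `check`, `level`, `detail`;
#'   zero rows when clean.
#' @export
validate_landmarks <- function(profile, landmarks) {
  stopifnot(inherits(profile, "adc_profile"),
            inherits(landmarks, "profile_landmarks"))
  v <- profile$values
  if (landmarks$f > length(v))
    stopf("landmark 'f' (%d) beyond profile length %d", landmarks$f, length(v))
  out <- list()
  warn <- function(check, detail)
    out[[length(out) + 1L]] <<- data.frame(check = check, level = "warning",
                                           detail = detail,
                                           stringsAsFactors = FALSE)
  p1_med <- stats::median(v[landmarks$b:landmarks$c])
  if (!(v[landmarks$d] < p1_med))
    warn("d_below_plateau1",
         sprintf("value at D (%.1f) not below plateau-1 median (%.1f)",
                 v[landmarks$d], p1_med))
  if (!(v[landmarks$d] <= v[landmarks$e]))
    warn("d_below_e",
         sprintf("value at D (%.1f) above value at E (%.1f)",
                 v[landmarks$d], v[landmarks$e]))
  if (!length(out))
    return(data.frame(check = character(), level = character(),
                      detail = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
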