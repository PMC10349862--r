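# Line-of-interest sampling: the 1-D ADC profile along a user-drawn line.

#' Construct a line of interest
#'
#' A line of interest (LOI) runs from a peripheral point A, placed in
#' normal-looking tissue outside the perilesional edema, to a point F in the
#' lesion center, crossing every lesion compartment. Points on the line are
#' `A + t * u` with `u = (F - A) / ||F - A||` and `t` the arc length in pixels.
#'
#' @param point_A,point_F Continuous 0-based (row, col) coordinates.
#' @param subject_id,loi_id Identifiers carried through to profiles/features.
#' @return An object of class `loi`.
#' @export
loi <- function(point_A, point_F, subject_id = "s1", loi_id = "loi1") {
  point_A <- as.numeric(point_A); point_F <- as.numeric(point_F)
  if (length(point_A) != 2L || length(point_F) != 2L ||
      any(!is.finite(c(point_A, point_F))))
    stopf("LOI endpoints must be finite (row, col) pairs")
  if (sqrt(sum((point_F - point_A)^2)) < 1e-9)
    stopf("LOI endpoints must be distinct")
  structure(list(point_A = point_A, point_F = point_F,
                 subject_id = as.character(subject_id),
                 loi_id = as.character(loi_id)),
            class = "loi")
}

loi_length <- function(l) sqrt(sum((l$point_F - l$point_A)^2))

#' Construct an ADC profile
#'
#' Arc-length positions (pixel units, starting at 0 at point A) with the
#' interpolated ADC values along one LOI.
#'
#' @param positions_px Strictly increasing arc lengths from A, starting at 0.
#' @param values ADC values at those positions (paper units).
#' @param mean_spacing_mm Mean in-plane pixel spacing used to derive
#'   `positions_mm`.
#' @param subject_id,loi_id Identifiers.
#' @return An object of class `adc_profile`.
#' @export
adc_profile <- function(positions_px, values, mean_spacing_mm = 0.8,
                        subject_id = "s1", loi_id = "loi1") {
  positions_px <- as.numeric(positions_px); values <- as.numeric(values)
  if (length(positions_px) != length(values) || length(values) < 2L)
    stopf("profile needs matching positions/values of length >= 2")
  if (any(diff(positions_px) <= 0))
    stopf("profile positions must be strictly increasing")
  structure(list(positions_px = positions_px,
                 positions_mm = positions_px * mean_spacing_mm,
                 values = values,
                 mean_spacing_mm = mean_spacing_mm,
                 subject_id = as.character(subject_id),
                 loi_id = as.character(loi_id)),
            class = "adc_profile")
}

#' @export
print.adc_profile <- function(x, ...) {
  cat(sprintf("ADC profile '%s' (%s): %d samples over %.1f px, values [%.0f, %.0f]\n",
              x$loi_id, x$subject_id, length(x$values),
              max(x$positions_px), min(x$values), max(x$values)))
  invisible(x)
}

#' Plot an ADC profile with optional landmarks
#'
#' @param x An `adc_profile`.
#' @param landmarks Optional [profile_landmarks()] to annotate.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.adc_profile <- function(x, landmarks = NULL, ...) {
  graphics::plot(x$positions_px, x$values, type = "l",
                 xlab = "arc length [px]", ylab = "ADC [paper units]", ...)
  if (!is.null(landmarks)) {
    idx <- unlist(landmarks[c("a", "b", "c", "d", "e", "f")])
    graphics::points(x$positions_px[idx], x$values[idx], pch = 19,
                     col = "firebrick")
    graphics::text(x$positions_px[idx], x$values[idx],
                   labels = LETTERS[1:6], pos = 3, col = "firebrick")
  }
  invisible(x)
}

# Bilinear interpolation of map values at continuous 0-based (row, col)
# points. Points must lie within [0, nrow-1] x [0, ncol-1] (tiny tolerance for
# floating-point edge cases). Returns the interpolated values; as a side
# effect records which points touch the exclusion mask in attr "masked".
bilinear_sample <- function(map, rows, cols) {
  vals <- map$values
  nr <- nrow(vals); nc <- ncol(vals)
  eps <- 1e-9
  if (any(rows < -eps | rows > nr - 1 + eps | cols < -eps | cols > nc - 1 + eps))
    stopf("sample point outside image bounds")
  rows <- pmin(pmax(rows, 0), nr - 1)
  cols <- pmin(pmax(cols, 0), nc - 1)
  r0 <- pmin(floor(rows), nr - 2); c0 <- pmin(floor(cols), nc - 2)
  fr <- rows - r0; fc <- cols - c0
  i00 <- cbind(r0 + 1, c0 + 1); i01 <- cbind(r0 + 1, c0 + 2)
  i10 <- cbind(r0 + 2, c0 + 1); i11 <- cbind(r0 + 2, c0 + 2)
  out <- (1 - fr) * (1 - fc) * vals[i00] + (1 - fr) * fc * vals[i01] +
    fr * (1 - fc) * vals[i10] + fr * fc * vals[i11]
  if (!is.null(map$exclusion_mask)) {
    m <- map$exclusion_mask
    touched <- m[i00] | m[i01] | m[i10] | m[i11]
    attr(out, "masked") <- touched
  }
  out
}

#' Sample ADC values along a line of interest
#'
#' Samples the map at arc lengths `t = 0, step, 2*step, ..., ||F - A||` (the
#' endpoint is always included), bilinearly interpolating each value from the
#' four surrounding pixel centers. The LOI is a single interpolated ray of
#' 1-pixel width; an optional band average (perpendicular mean over `band_px`
#' rays spaced 1 px apart) is available but off by default.
#'
#' @param map An [adc_map()].
#' @param l A [loi()].
#' @param step_px Positive sampling step in pixels (default 1).
#' @param band_px Odd integer band width in pixels; 1 (default) = single ray.
#' @return An [adc_profile()]. If the ray touches the exclusion mask a warning
#'   lists the offending arc-length positions.
#' @export
sample_loi <- function(map, l, step_px = 1.0, band_px = 1L) {
  stopifnot(inherits(map, "adc_map"), inherits(l, "loi"))
  check_scalar(step_px, "step_px", positive = TRUE)
  len <- loi_length(l)
  n_steps <- floor(len / step_px + 1e-9)
  t <- (0:n_steps) * step_px
  if (len - t[length(t)] > 1e-9) t <- c(t, len)
  u <- (l$point_F - l$point_A) / len
  rows <- l$point_A[1] + t * u[1]
  cols <- l$point_A[2] + t * u[2]
  if (band_px > 1L) {
    if (band_px %% 2L == 0L) stopf("'band_px' must be odd")
    perp <- c(-u[2], u[1])
    offs <- seq(-(band_px %/% 2L), band_px %/% 2L)
    acc <- 0; masked <- FALSE
    for (o in offs) {
      v <- bilinear_sample(map, rows + o * perp[1], cols + o * perp[2])
      masked <- masked | (attr(v, "masked") %||% FALSE)
      acc <- acc + as.numeric(v)
    }
    values <- acc / length(offs)
    attr(values, "masked") <- masked
  } else {
    values <- bilinear_sample(map, rows, cols)
  }
  masked <- attr(values, "masked")
  if (!is.null(masked) && any(masked))
    warning(sprintf("LOI '%s' crosses the exclusion mask at arc positions: %s",
                    l$loi_id, paste(signif(t[masked], 4), collapse = ", ")))
  adc_profile(t, as.numeric(values),
              mean_spacing_mm = mean(map$pixel_spacing_mm),
              subject_id = l$subject_id, loi_id = l$loi_id)
}

#' Validate lines of interest against a map
#'
#' Report-only checks mirroring how LOIs are placed in practice: samples must
#' stay inside the image, must avoid excluded regions (ventricles, bone), and
#' two LOIs of one subject must not be (anti-)parallel duplicates — two
#' contralaterally oriented LOIs cross the same tissue twice.
#'
#' @param map An [adc_map()].
#' @param lois A single [loi()] or list of them (one subject).
#' @param contralateral_tol_deg LOI pairs whose directions are within this
#'   angle of anti-parallel (180 degrees apart) are flagged; default 10.
#' @return A data frame report with columns `loi_id`, `issue`, `detail`
#'   (zero rows when everything is clean).
#' @export
validate_loi <- function(map, lois, contralateral_tol_deg = 10) {
  if (inherits(lois, "loi")) lois <- list(lois)
  issues <- list()
  add <- function(id, issue, detail)
    issues[[length(issues) + 1L]] <<- data.frame(
      loi_id = id, issue = issue, detail = detail, stringsAsFactors = FALSE)
  for (l in lois) {
    prof <- tryCatch(withCallingHandlers(
      sample_loi(map, l),
      warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) e)
    if (inherits(prof, "error")) {
      add(l$loi_id, "out_of_bounds", conditionMessage(prof))
      next
    }
    if (!is.null(map$exclusion_mask)) {
      len <- loi_length(l)
      u <- (l$point_F - l$point_A) / len
      t <- prof$positions_px
      v <- bilinear_sample(map, l$point_A[1] + t * u[1],
                           l$point_A[2] + t * u[2])
      masked <- attr(v, "masked")
      if (!is.null(masked) && any(masked)) {
        runs <- rle(masked)
        ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
        iv <- paste(sprintf("[%.1f, %.1f]", t[starts[runs$values]],
                            t[ends[runs$values]]), collapse = " ")
        add(l$loi_id, "mask_crossing",
            sprintf("arc-length interval(s) %s px", iv))
      }
    }
  }
  if (length(lois) > 1L) {
    dirs <- lapply(lois, function(l) (l$point_F - l$point_A) / loi_length(l))
    for (i in seq_along(lois)) for (j in seq_along(lois)) {
      if (j <= i) next
      ang <- acos(pmin(pmax(sum(dirs[[i]] * dirs[[j]]), -1), 1)) * 180 / pi
      if (ang >= 180 - contralateral_tol_deg)
        add(lois[[j]]$loi_id, "contralateral",
            sprintf("anti-parallel with '%s' (%.1f deg apart)",
                    lois[[i]]$loi_id, ang))
    }
  }
  if (!length(issues))
    return(data.frame(loi_id = character(), issue = character(),
                      detail = character(), stringsAsFactors = FALSE))
  do.call(rbind, issues)
}
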