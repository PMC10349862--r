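# Synthetic ring-enhancing-lesion phantom.
#
# The radial model has four levels: a normal-parenchyma background plateau,
# an elevated perilesional-edema plateau, a ring minimum (the thin enhancing
# ring is represented only by this minimum; it is too thin on clinical ADC
# maps for a broad analysis), and a core plateau — high for GBM-like lesions
# (necrosis, free diffusion), low for abscess-like lesions (viscous pus,
# restricted diffusion). Transitions are linear ramps so ground-truth
# gradients are analytic; noise is additive Gaussian truncated at zero.

#' Compartment specification for one synthetic lesion profile
#'
#' @param background_level Normal-parenchyma ADC plateau (paper units;
#'   brain parenchyma sits around 700-750).
#' @param edema_level Perilesional-edema plateau; must exceed the background
#'   (vasogenic edema elevates ADC).
#' @param ring_min_level Ring minimum; must lie below both the edema and the
#'   core level (D is a local minimum).
#' @param core_level Core plateau.
#' @param seg_lengths Five positive integers (each >= 3): sample counts of
#'   the pre-edema run-in, gradient 1 (edema rise), plateau 1, the combined
#'   gradient-2 / ring / gradient-3 span, and plateau 2.
#' @param transition_smoothness Non-negative moving-average width applied to
#'   the noise-free curve (0 = sharp piecewise-linear transitions, the
#'   default).
#' @param noise_sd Additive Gaussian noise SD (paper units), truncated so
#'   values stay non-negative.
#' @return An object of class `compartment_spec`.
#' @export
compartment_spec <- function(background_level = 725, edema_level = 1400,
                             ring_min_level = 600, core_level = 1900,
                             seg_lengths = c(12L, 15L, 30L, 35L, 25L),
                             transition_smoothness = 0, noise_sd = 50) {
  for (nm in c("background_level", "edema_level", "ring_min_level",
               "core_level"))
    check_scalar(get(nm), nm, positive = TRUE)
  if (edema_level <= background_level)
    stopf("invalid spec: edema_level must exceed background_level")
  if (ring_min_level >= edema_level)
    stopf("invalid spec: ring_min_level must lie below edema_level")
  if (ring_min_level >= core_level)
    stopf("invalid spec: ring_min_level must lie below core_level")
  seg_lengths <- as.integer(seg_lengths)
  if (length(seg_lengths) != 5L || any(seg_lengths < 3L))
    stopf("invalid spec: seg_lengths must be 5 integers, each >= 3")
  check_scalar(transition_smoothness, "transition_smoothness", nonneg = TRUE)
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  structure(list(background_level = background_level,
                 edema_level = edema_level,
                 ring_min_level = ring_min_level, core_level = core_level,
                 seg_lengths = seg_lengths,
                 transition_smoothness = transition_smoothness,
                 noise_sd = noise_sd),
            class = "compartment_spec")
}

#' Default class specifications
#'
#' Configuration, not clinical ground truth: the background matches the
#' normal-parenchyma range (around 700-750), and the ordering of the plateau
#' levels matches the reported class differences (GBM edema and core medians
#' above the abscess ones); magnitudes are otherwise free choices.
#'
#' @param noise_sd Noise SD passed through; default 50.
#' @return A `compartment_spec`.
#' @export
default_gbm_spec <- function(noise_sd = 50) {
  compartment_spec(background_level = 725, edema_level = 1400,
                   ring_min_level = 600, core_level = 1900,
                   noise_sd = noise_sd)
}

#' @rdname default_gbm_spec
#' @export
default_abscess_spec <- function(noise_sd = 50) {
  compartment_spec(background_level = 725, edema_level = 1150,
                   ring_min_level = 550, core_level = 650,
                   noise_sd = noise_sd)
}

# Landmark indices implied by a spec's seg_lengths (1-based, step-1 grid).
spec_landmark_indices <- function(spec) {
  s <- spec$seg_lengths
  a <- s[1]; b <- a + s[2]; cc <- b + s[3]
  fall <- min(max(2L, as.integer(round(s[4] * 0.5))), s[4] - 1L)
  d <- cc + fall; e <- cc + s[4]; f <- e + s[5]
  c(a = a, b = b, c = cc, d = d, e = e, f = f)
}

# Noise-free piecewise-linear curve on the 1..f index grid.
spec_curve <- function(spec) {
  li <- spec_landmark_indices(spec)
  v <- numeric(li["f"])
  v[1:li["a"]] <- spec$background_level
  ramp <- function(i0, i1, y0, y1)
    y0 + (y1 - y0) * (seq.int(i0, i1) - i0) / (i1 - i0)
  v[li["a"]:li["b"]] <- ramp(li["a"], li["b"], spec$background_level,
                             spec$edema_level)
  v[li["b"]:li["c"]] <- spec$edema_level
  v[li["c"]:li["d"]] <- ramp(li["c"], li["d"], spec$edema_level,
                             spec$ring_min_level)
  v[li["d"]:li["e"]] <- ramp(li["d"], li["e"], spec$ring_min_level,
                             spec$core_level)
  v[li["e"]:li["f"]] <- spec$core_level
  if (spec$transition_smoothness > 0)
    v <- moving_average(v, as.integer(spec$transition_smoothness))
  list(values = v, landmarks = li)
}

truth_features <- function(curve) {
  li <- curve$landmarks
  prof <- adc_profile(seq_along(curve$values) - 1, curve$values)
  lm <- profile_landmarks(li["a"], li["b"], li["c"], li["d"], li["e"],
                          li["f"], method = "manual")
  extract_features(prof, lm)
}

#' Generate one synthetic lesion profile
#'
#' Builds the noise-free piecewise curve for `spec`, records its construction
#' breakpoints and noise-free features as ground truth, then adds truncated
#' Gaussian noise.
#'
#' @param spec A [compartment_spec()].
#' @param label `"GBM"` or `"ABSCESS"` (carried into the ground truth).
#' @param seed Optional integer seed for the noise draw; `NULL` uses the
#'   current RNG stream.
#' @param subject_id,loi_id Identifiers.
#' @return List with elements `profile` (an [adc_profile()]) and `truth`
#'   (list: `landmarks`, `true_features`, `class_label`, `clean_values`).
#' @export
generate_profile <- function(spec, label = c("GBM", "ABSCESS"), seed = NULL,
                             subject_id = "s1", loi_id = "loi1") {
  stopifnot(inherits(spec, "compartment_spec"))
  label <- match.arg(label)
  curve <- spec_curve(spec)
  draw <- function() {
    v <- curve$values
    if (spec$noise_sd > 0)
      v <- pmax(v + stats::rnorm(length(v), 0, spec$noise_sd), 0)
    v
  }
  noisy <- if (is.null(seed)) draw() else with_seed(seed, draw())
  li <- curve$landmarks
  truth <- list(
    landmarks = profile_landmarks(li["a"], li["b"], li["c"], li["d"],
                                  li["e"], li["f"], method = "manual"),
    true_features = truth_features(curve),
    class_label = label,
    clean_values = curve$values)
  list(profile = adc_profile(seq_along(noisy) - 1, noisy,
                             subject_id = subject_id, loi_id = loi_id),
       truth = truth)
}

# Piecewise-linear radial level function: value at radius r (px) from the
# lesion center, given breakpoint radii (decreasing outward positions
# core < ring < edema_inner < edema_outer < lesion_outer) and the levels.
radial_levels <- function(spec, radii) {
  r_core <- radii[1]; r_ring <- radii[2]; r_ein <- radii[3]
  r_eout <- radii[4]; r_a <- radii[5]
  function(r) {
    out <- numeric(length(r))
    out[r <= r_core] <- spec$core_level
    i <- r > r_core & r <= r_ring
    out[i] <- spec$ring_min_level + (spec$core_level - spec$ring_min_level) *
      (r_ring - r[i]) / (r_ring - r_core)
    i <- r > r_ring & r <= r_ein
    out[i] <- spec$edema_level + (spec$ring_min_level - spec$edema_level) *
      (r[i] - r_ein) / (r_ring - r_ein)
    i <- r > r_ein & r <= r_eout
    out[i] <- spec$edema_level
    i <- r > r_eout & r <= r_a
    out[i] <- spec$background_level +
      (spec$edema_level - spec$background_level) * (r_a - r[i]) / (r_a - r_eout)
    out[r > r_a] <- spec$background_level
    out
  }
}

#' Generate a 2-D radially symmetric lesion map with LOIs and ground truth
#'
#' Embeds the radial compartment model in an image so the LOI sampler can be
#' exercised end to end. Each returned LOI runs from just outside the edema
#' to the lesion center, at distinct angles spread over less than a half
#' turn so that no pair is contralateral. Along every LOI, the analytic
#' (noise-free) profile and its construction breakpoints are returned as
#' ground truth.
#'
#' @param spec A [compartment_spec()]; levels and `noise_sd` are used, the
#'   lesion geometry comes from `radii`/`run_in_px`.
#' @param label `"GBM"` or `"ABSCESS"`.
#' @param image_shape `(rows, cols)`; default `c(101, 101)`.
#' @param center Lesion center, 0-based (row, col); default image center.
#' @param radii Increasing breakpoint radii in px: core-plateau edge (E),
#'   ring minimum (D), edema-plateau inner edge (C), edema-plateau outer
#'   edge (B), edema onset (A). Default `c(6, 10, 16, 26, 34)`.
#' @param run_in_px Background run-in outside the edema onset; default 6.
#' @param n_lois Number of LOIs; default 5.
#' @param angles_deg Optional LOI angles; default evenly spaced over
#'   `[0, 160)` degrees.
#' @param seed Optional seed for the pixel noise.
#' @param subject_id Identifier stamped on the LOIs.
#' @return List with `map` (an [adc_map()]), `lois` (list of [loi()]), and
#'   `truths` (per-LOI list: `landmarks`, `true_features`, `class_label`,
#'   `clean_values` — the analytic profile along that LOI).
#' @export
generate_map <- function(spec, label = c("GBM", "ABSCESS"),
                         image_shape = c(101L, 101L), center = NULL,
                         radii = c(6, 10, 16, 26, 34), run_in_px = 6,
                         n_lois = 5L, angles_deg = NULL, seed = NULL,
                         subject_id = "s1") {
  stopifnot(inherits(spec, "compartment_spec"))
  label <- match.arg(label)
  if (length(radii) != 5L || any(diff(radii) <= 0))
    stopf("'radii' must be 5 strictly increasing breakpoint radii")
  image_shape <- as.integer(image_shape)
  center <- center %||% ((image_shape - 1) / 2)
  r_start <- radii[5] + run_in_px
  if (center[1] - r_start < 0 || center[1] + r_start > image_shape[1] - 1 ||
      center[2] - r_start < 0 || center[2] + r_start > image_shape[2] - 1)
    stopf("lesion (radius %.1f px incl. run-in) does not fit inside the image",
          r_start)
  lv <- radial_levels(spec, radii)
  rows <- matrix(rep(0:(image_shape[1] - 1L), image_shape[2]),
                 nrow = image_shape[1])
  cols <- matrix(rep(0:(image_shape[2] - 1L), each = image_shape[1]),
                 nrow = image_shape[1])
  rr <- sqrt((rows - center[1])^2 + (cols - center[2])^2)
  vals <- matrix(lv(as.numeric(rr)), nrow = image_shape[1])
  draw <- function() {
    if (spec$noise_sd > 0)
      pmax(vals + matrix(stats::rnorm(length(vals), 0, spec$noise_sd),
                         nrow = nrow(vals)), 0)
    else vals
  }
  noisy <- if (is.null(seed)) draw() else with_seed(seed, draw())
  map <- adc_map(noisy, source_id = sprintf("phantom:%s", subject_id))

  if (!is.null(angles_deg)) n_lois <- length(angles_deg)
  angles_deg <- angles_deg %||% (seq.int(0L, n_lois - 1L) * (160 / n_lois))
  # analytic profile along any radial LOI: position t in [0, r_start],
  # radius r = r_start - t
  t_grid <- 0:r_start
  clean_prof <- lv(r_start - t_grid)
  li <- c(a = run_in_px + 1L,
          b = run_in_px + (radii[5] - radii[4]) + 1L,
          c = run_in_px + (radii[5] - radii[3]) + 1L,
          d = run_in_px + (radii[5] - radii[2]) + 1L,
          e = run_in_px + (radii[5] - radii[1]) + 1L,
          f = length(t_grid))
  lms <- profile_landmarks(li["a"], li["b"], li["c"], li["d"], li["e"],
                           li["f"], method = "manual")
  tf <- extract_features(adc_profile(t_grid, clean_prof), lms)
  lois <- vector("list", n_lois)
  truths <- vector("list", n_lois)
  for (k in seq_len(n_lois)) {
    th <- angles_deg[k] * pi / 180
    pa <- center + r_start * c(sin(th), cos(th))
    lois[[k]] <- loi(pa, center, subject_id = subject_id,
                     loi_id = sprintf("loi%d", k))
    truths[[k]] <- list(landmarks = lms, true_features = tf,
                        class_label = label, clean_values = clean_prof)
  }
  list(map = map, lois = lois, truths = truths)
}

#' Cohort specification
#'
#' @param n_gbm,n_abscess Subject counts per class (`n_gbm + n_abscess >= 1`).
#' @param lois_per_subject LOIs (profiles) per subject; default 5.
#' @param gbm_spec,abscess_spec Per-class [compartment_spec()]s.
#' @param subject_jitter_sd SD of the per-subject Gaussian jitter added to
#'   the four compartment levels, so subjects differ; default 40.
#' @param gradient_mean,gradient_sd Length-3 numerics: means and SDs of the
#'   per-LOI ramp-slope draws (edema rise, edema-to-ring fall magnitude,
#'   ring-to-core rise), shared by both classes so that gradient features are
#'   drawn from identical distributions (the class difference lives in the
#'   plateau levels, matching the reported significance pattern).
#' @param seed Root seed for the cohort.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_gbm = 26L, n_abscess = 14L, lois_per_subject = 5L,
                        gbm_spec = default_gbm_spec(),
                        abscess_spec = default_abscess_spec(),
                        subject_jitter_sd = 40,
                        gradient_mean = c(45, 60, 50),
                        gradient_sd = c(6, 8, 8), seed = 1L) {
  n_gbm <- as.integer(n_gbm); n_abscess <- as.integer(n_abscess)
  if (n_gbm < 0L || n_abscess < 0L || n_gbm + n_abscess < 1L)
    stopf("need n_gbm >= 0, n_abscess >= 0 and at least one subject")
  if (lois_per_subject < 1L) stopf("'lois_per_subject' must be >= 1")
  stopifnot(inherits(gbm_spec, "compartment_spec"),
            inherits(abscess_spec, "compartment_spec"))
  check_scalar(subject_jitter_sd, "subject_jitter_sd", nonneg = TRUE)
  if (length(gradient_mean) != 3L || length(gradient_sd) != 3L)
    stopf("'gradient_mean' and 'gradient_sd' must have length 3")
  structure(list(n_gbm = n_gbm, n_abscess = n_abscess,
                 lois_per_subject = as.integer(lois_per_subject),
                 gbm_spec = gbm_spec, abscess_spec = abscess_spec,
                 subject_jitter_sd = subject_jitter_sd,
                 gradient_mean = gradient_mean, gradient_sd = gradient_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Per-LOI lesion geometry: draw the three ramp slopes from the class-shared
# distributions and derive integer ramp lengths; realized plateau levels
# absorb the rounding so the noise-free gradients equal the drawn slopes
# exactly for both classes.
realize_loi_spec <- function(base, levels, cs) {
  g <- stats::rnorm(3L, cs$gradient_mean, cs$gradient_sd)
  g <- pmin(pmax(g, 20), 150)
  d1 <- max(levels["edema"] - levels["background"], 60)
  len1 <- max(3L, as.integer(round(d1 / g[1])))
  edema <- levels["background"] + g[1] * len1
  d2 <- max(edema - levels["ring"], 60)
  len_fall <- max(2L, as.integer(round(d2 / g[2])))
  ring <- edema - g[2] * len_fall
  d3 <- max(levels["core"] - ring, 40)
  # floor the ring-to-core span: a two-point gradient over a very short span
  # inherits a large, class-specific noise variance, which would leak class
  # information through a feature that is drawn class-independently
  len_rise <- max(6L, as.integer(round(d3 / g[3])))
  core <- ring + g[3] * len_rise
  spec <- compartment_spec(
    background_level = unname(levels["background"]),
    edema_level = unname(edema),
    ring_min_level = unname(ring), core_level = unname(core),
    seg_lengths = c(base$seg_lengths[1], len1, base$seg_lengths[3],
                    len_fall + len_rise, base$seg_lengths[5]),
    transition_smoothness = base$transition_smoothness,
    noise_sd = base$noise_sd)
  # force the fall/rise split at exactly len_fall
  spec$fall_override <- len_fall
  spec
}

spec_landmark_indices_cohort <- function(spec) {
  li <- spec_landmark_indices(spec)
  if (!is.null(spec$fall_override)) {
    li["d"] <- li["c"] + spec$fall_override
  }
  li
}

#' Generate a labeled synthetic cohort
#'
#' Subjects get per-subject level jitter; each LOI gets per-LOI ramp slopes
#' drawn from class-shared distributions and independent sampling noise.
#' Features are extracted from the noisy profile at the ground-truth
#' landmarks. Identical seed, identical cohort.
#'
#' @param cs A [cohort_spec()].
#' @return An object of class `rel_cohort`: a data frame of labeled samples
#'   (columns `subject_id`, `loi_id`, `label` and the nine features) with the
#'   raw profiles and ground truths attached as attributes `profiles` and
#'   `truths` (named by `subject_id/loi_id`).
#' @export
generate_cohort <- function(cs) {
  stopifnot(inherits(cs, "cohort_spec"))
  n_total <- cs$n_gbm + cs$n_abscess
  labels <- c(rep("GBM", cs$n_gbm), rep("ABSCESS", cs$n_abscess))
  subject_ids <- sprintf("%s%02d", ifelse(labels == "GBM", "g", "a"),
                         c(seq_len(cs$n_gbm), seq_len(cs$n_abscess)))
  rows <- vector("list", n_total * cs$lois_per_subject)
  profiles <- list(); truths <- list()
  with_seed(derive_seed(cs$seed, "phantom"), {
    for (si in seq_len(n_total)) {
      base <- if (labels[si] == "GBM") cs$gbm_spec else cs$abscess_spec
      jit <- stats::rnorm(4L, 0, cs$subject_jitter_sd)
      levels <- c(background = base$background_level + jit[1],
                  edema = base$edema_level + jit[2],
                  ring = base$ring_min_level + jit[3],
                  core = base$core_level + jit[4])
      levels <- pmax(levels, 50)
      for (k in seq_len(cs$lois_per_subject)) {
        lspec <- realize_loi_spec(base, levels, cs)
        li <- spec_landmark_indices_cohort(lspec)
        curve_v <- spec_curve_at(lspec, li)
        noisy <- if (lspec$noise_sd > 0)
          pmax(curve_v + stats::rnorm(length(curve_v), 0, lspec$noise_sd), 0)
        else curve_v
        loi_id <- sprintf("loi%d", k)
        prof <- adc_profile(seq_along(noisy) - 1, noisy,
                            subject_id = subject_ids[si], loi_id = loi_id)
        lms <- profile_landmarks(li["a"], li["b"], li["c"], li["d"],
                                 li["e"], li["f"], method = "manual")
        fv <- extract_features(prof, lms)
        key <- paste(subject_ids[si], loi_id, sep = "/")
        profiles[[key]] <- prof
        truths[[key]] <- list(
          landmarks = lms,
          true_features = extract_features(
            adc_profile(seq_along(curve_v) - 1, curve_v), lms),
          class_label = labels[si], clean_values = curve_v)
        rows[[(si - 1L) * cs$lois_per_subject + k]] <- data.frame(
          subject_id = subject_ids[si], loi_id = loi_id, label = labels[si],
          t(fv), stringsAsFactors = FALSE)
      }
    }
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  structure(df, profiles = profiles, truths = truths,
            class = c("rel_cohort", "data.frame"))
}

# Noise-free curve honoring an explicit fall/rise split.
spec_curve_at <- function(spec, li) {
  v <- numeric(li[["f"]])
  ramp <- function(i0, i1, y0, y1)
    y0 + (y1 - y0) * (seq.int(i0, i1) - i0) / (i1 - i0)
  v[1:li[["a"]]] <- spec$background_level
  v[li[["a"]]:li[["b"]]] <- ramp(li[["a"]], li[["b"]], spec$background_level,
                                 spec$edema_level)
  v[li[["b"]]:li[["c"]]] <- spec$edema_level
  v[li[["c"]]:li[["d"]]] <- ramp(li[["c"]], li[["d"]], spec$edema_level,
                                 spec$ring_min_level)
  v[li[["d"]]:li[["e"]]] <- ramp(li[["d"]], li[["e"]], spec$ring_min_level,
                                 spec$core_level)
  v[li[["e"]]:li[["f"]]] <- spec$core_level
  if (spec$transition_smoothness > 0)
    v <- moving_average(v, as.integer(spec$transition_smoothness))
  v
}

#' @export
print.rel_cohort <- function(x, ...) {
  cat(sprintf("synthetic REL cohort: %d samples (%d GBM, %d ABSCESS lines), %d subjects\n",
              nrow(x), sum(x$label == "GBM"), sum(x$label == "ABSCESS"),
              length(unique(x$subject_id))))
  invisible(x)
}
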