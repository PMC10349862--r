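test_that("compartment spec validation names the violated invariant", {
  expect_error(compartment_spec(edema_level = 700, background_level = 725),
               "edema_level")
  expect_error(compartment_spec(ring_min_level = 1500), "ring_min_level")
  expect_error(compartment_spec(core_level = 500, ring_min_level = 600),
               "ring_min_level")
  expect_error(compartment_spec(seg_lengths = c(2, 15, 30, 35, 25)),
               "seg_lengths")
  expect_error(compartment_spec(noise_sd = -1), "noise_sd")
})

test_that("noise-free profiles reproduce the construction exactly", {
  gp <- generate_profile(default_gbm_spec(noise_sd = 0), "GBM")
  lm <- gp$truth$landmarks
  # plateau-1 median is exactly the edema level
  expect_identical(median(gp$profile$values[lm$b:lm$c]), 1400)
  # D is the global minimum of the C..E span
  seg <- gp$profile$values[lm$c:lm$e]
  expect_equal(which.min(seg) + lm$c - 1L, lm$d)
  expect_equal(min(seg), 600)
  # noise-free feature recovery at ground-truth landmarks
  fv <- extract_features(gp$profile, lm)
  expect_lt(max(abs(fv - gp$truth$true_features)), 1e-9)
})

test_that("plateau noise has the configured spread", {
  spec <- default_gbm_spec(noise_sd = 50)
  vals <- unlist(lapply(1:200, function(i) {
    gp <- generate_profile(spec, "GBM", seed = 1000 + i)
    lm <- gp$truth$landmarks
    gp$profile$values[lm$b:lm$c] - 1400
  }))
  expect_gt(sd(vals), 50 * 0.8)
  expect_lt(sd(vals), 50 * 1.2)
})

test_that("profile and cohort generation are deterministic under a seed", {
  p1 <- generate_profile(default_gbm_spec(), "GBM", seed = 7)
  p2 <- generate_profile(default_gbm_spec(), "GBM", seed = 7)
  expect_identical(p1$profile$values, p2$profile$values)
  c1 <- generate_cohort(cohort_spec(n_gbm = 3, n_abscess = 3, seed = 5))
  c2 <- generate_cohort(cohort_spec(n_gbm = 3, n_abscess = 3, seed = 5))
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  c3 <- generate_cohort(cohort_spec(n_gbm = 3, n_abscess = 3, seed = 6))
  expect_false(identical(c1$median_E, c3$median_E))
})

test_that("cohort design, labels and ground-truth invariants hold", {
  co <- generate_cohort(cohort_spec(seed = 11))
  expect_equal(nrow(co), 200)
  expect_equal(sum(co$label == "GBM"), 130)
  expect_equal(anyDuplicated(co[c("subject_id", "loi_id")]), 0L)
  one <- generate_cohort(cohort_spec(n_gbm = 1, n_abscess = 0,
                                     lois_per_subject = 1, seed = 1))
  expect_equal(nrow(one), 1L)
  expect_equal(one$label, "GBM")
  truths <- attr(co, "truths")
  for (tr in truths[seq(1, length(truths), by = 10)]) {
    idx <- unlist(tr$landmarks[c("a", "b", "c", "d", "e", "f")])
    expect_true(all(diff(idx) > 0))
    # noise-free features recovered from the clean curve
    prof <- adc_profile(seq_along(tr$clean_values) - 1, tr$clean_values)
    expect_lt(max(abs(extract_features(prof, tr$landmarks) -
                      tr$true_features)), 1e-9)
  }
})

test_that("plateau medians separate by class while gradients are drawn alike", {
  co <- generate_cohort(cohort_spec(seed = 21))
  med_g <- median(co$median_E[co$label == "GBM"])
  med_a <- median(co$median_E[co$label == "ABSCESS"])
  expect_gt(med_g, med_a)
  expect_gt(median(co$median_T[co$label == "GBM"]),
            median(co$median_T[co$label == "ABSCESS"]))
  # the noise-free gradient draws come from class-shared distributions
  tf <- t(sapply(attr(co, "truths"), function(x) x$true_features))
  labs <- sapply(attr(co, "truths"), function(x) x$class_label)
  for (g in c("grad_E_rise", "grad_E_fall", "grad_T_rise")) {
    expect_lt(abs(mean(tf[labs == "GBM", g]) - mean(tf[labs == "ABSCESS", g])),
              3)
  }
})

test_that("radial maps are consistent with the 1-D profile model", {
  gm <- generate_map(default_gbm_spec(noise_sd = 0), "GBM", seed = 1)
  # plateau-2 median sampled from any LOI reproduces the core level exactly
  for (k in c(1, 3, 5)) {
    prof <- sample_loi(gm$map, gm$lois[[k]])
    lm <- gm$truths[[k]]$landmarks
    expect_identical(median(prof$values[lm$e:lm$f]), 1900)
  }
  # analytic ground-truth profiles are identical across angles
  expect_lt(max(abs(gm$truths[[1]]$clean_values - gm$truths[[4]]$clean_values)),
            1e-6)
  # rotating a LOI by 90 degrees leaves raster-sampled features unchanged
  base <- generate_map(default_gbm_spec(noise_sd = 0), "GBM",
                       angles_deg = c(20, 110))
  f1 <- extract_features(sample_loi(base$map, base$lois[[1]]),
                         base$truths[[1]]$landmarks)
  f2 <- extract_features(sample_loi(base$map, base$lois[[2]]),
                         base$truths[[2]]$landmarks)
  expect_lt(max(abs(f1 - f2)), 1e-6)
})

test_that("map generation rejects lesions that do not fit", {
  expect_error(generate_map(default_gbm_spec(), "GBM",
                            image_shape = c(60, 60)), "fit")
  expect_error(generate_map(default_gbm_spec(), "GBM",
                            radii = c(10, 6, 16, 26, 34)), "increasing")
})
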