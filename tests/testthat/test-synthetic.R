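test_that("generators are deterministic given a seed", {
  s <- the_sched()
  spec <- effect_spec(planted_beta = c(cs = 0.2), n_voxels = 20)
  expect_identical(unclass(generate_patterns(s, spec, seed = 7)),
                   unclass(generate_patterns(s, spec, seed = 7)))
  pm <- generate_patterns(s, spec, seed = 7)
  expect_identical(unclass(generate_bold(s, pm, noise_sd = 1, seed = 3)),
                   unclass(generate_bold(s, pm, noise_sd = 1, seed = 3)))
  expect_identical(generate_pupil(s, pupil_sim_spec(), seed = 5)$diameter,
                   generate_pupil(s, pupil_sim_spec(), seed = 5)$diameter)
  # generators do not disturb the caller's RNG stream
  set.seed(99); a <- rnorm(1)
  set.seed(99); invisible(generate_patterns(s, spec, seed = 1)); b <- rnorm(1)
  expect_identical(a, b)
})

test_that("a null planting yields near-zero mean similarity", {
  s <- the_sched()
  spec <- effect_spec(planted_beta = numeric(0), n_voxels = 400,
                      condition_pattern_corr = 0)
  zs <- sapply(1:20, function(k) {
    mean(similarity_vector(compute_rsm(
      generate_patterns(s, spec, seed = k), s)))
  })
  se <- sd(zs) / sqrt(length(zs))
  expect_lt(abs(mean(zs)), 3 * se + 1e-3)
})

test_that("a planted category weight is recovered as the within-between contrast", {
  s <- the_sched()
  tset <- the_tset()
  w <- 0.25
  spec <- effect_spec(planted_beta = c(category = w), n_voxels = 300,
                      condition_pattern_corr = 0)
  catv <- as.numeric(lower_triangle(tset$category))
  # Monte-Carlo oracle: average within/between contrast across simulated RSMs
  diffs <- sapply(1:30, function(k) {
    z <- similarity_vector(compute_rsm(generate_patterns(s, spec,
                                                         tset = tset,
                                                         seed = 200 + k), s))
    mean(z[catv == 1]) - mean(z[catv == 0])
  })
  # planted on the Fisher-z scale of the transformed template (1 -> 0.999)
  expect_equal(mean(diffs), w * 0.999, tolerance = 0.05)
})

test_that("impossible planted structures are rejected naming the weight", {
  s <- the_sched()
  expect_error(generate_patterns(s, effect_spec(planted_beta = c(cs = -40),
                                                n_voxels = 10), seed = 1),
               "non-positive-semidefinite.*cs")
})

test_that("effect_spec validates its fields", {
  expect_error(effect_spec(snr = 0))
  expect_error(effect_spec(n_voxels = 1))
  expect_error(effect_spec(planted_beta = 0.3), "named")
  expect_error(generate_patterns(the_sched(),
                                 effect_spec(planted_beta = c(nope = 0.1)),
                                 seed = 1),
               "not in template set")
})

test_that("pupil traces have event-locked responses and blink gaps", {
  s <- the_sched()
  spec <- pupil_sim_spec(sampling_hz = 50, cs_effect_mm = 0.4,
                         blink_rate_hz = 0)
  tr <- generate_pupil(s, spec, seed = 3)
  expect_false(anyNA(tr$diameter))
  expect_equal(attr(tr, "sampling_hz"), 50)
  # CS+ windows dilate more than CS- windows on average
  ev <- event_table(s, "chosen_option")
  peaks <- sapply(seq_len(nrow(ev)), function(k) {
    max(tr$diameter[tr$time_s >= ev$onset_s[k] &
                      tr$time_s <= ev$onset_s[k] + 2.5])
  })
  expect_gt(mean(peaks[ev$cs == "CSplus"]), mean(peaks[ev$cs == "CSminus"]))
  withblinks <- generate_pupil(s, pupil_sim_spec(sampling_hz = 50), seed = 4)
  expect_gt(sum(is.na(withblinks$diameter)), 0)
  expect_error(pupil_sim_spec(blink_rate_hz = 10,
                              blink_dur_ms = c(mean = 200, sd = 10)),
               "100%")
})

test_that("a strongly planted pupil effect is detected across subjects", {
  sched <- the_sched()
  spec <- pupil_sim_spec(sampling_hz = 50, cs_effect_mm = 0.5)
  means <- do.call(rbind, lapply(1:8, function(sj) {
    tr <- generate_pupil(sched, spec, seed = 300 + sj,
                         subject_id = paste0("s", sj))
    pupil_pipeline(tr, sched)$cs_means
  }))
  res <- condition_contrast(means)
  expect_gt(res$t, 0)
  expect_lt(res$p, 0.05)
})
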