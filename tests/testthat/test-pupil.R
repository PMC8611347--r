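make_trace <- function(d, fs = 250) {
  structure(data.frame(time_s = (seq_along(d) - 1) / fs, diameter = d),
            sampling_hz = fs, subject_id = "s1",
            class = c("pupil_trace", "data.frame"))
}

test_that("deblink widens gaps by 100 ms and interpolates linearly", {
  fs <- 250
  d <- rep(5, 1000)
  d[401:410] <- NA  # 40 ms gap
  tr <- deblink(make_trace(d, fs))
  expect_false(anyNA(tr$diameter))
  expect_equal(tr$diameter, rep(5, 1000))  # flat fill between equal values
  rep_ <- attr(tr, "blink_report")
  expect_equal(rep_$treated_ms, 240)  # 40 ms + 100 ms each side
  mask <- attr(tr, "missing_mask")
  expect_equal(sum(mask), 60L)
  expect_equal(range(which(mask)), c(376L, 435L))
  # linear gap between a and b reproduces the exact line
  x <- seq(0, 1, length.out = 1000) * 2 + 3
  xx <- x; xx[301:340] <- NA
  tr2 <- deblink(make_trace(xx, fs))
  expect_lt(max(abs(tr2$diameter - x)), 1e-12)
})

test_that("deblink leaves valid samples outside widened segments untouched", {
  set.seed(31)
  d <- rnorm(2000, 4, 0.1)
  d[500:520] <- NA
  tr <- deblink(make_trace(d))
  mask <- attr(tr, "missing_mask")
  expect_identical(tr$diameter[!mask], d[!mask])
  # boundary gap has no neighbour and stays missing
  d2 <- rnorm(500, 4, 0.1); d2[1:30] <- NA
  tr2 <- deblink(make_trace(d2))
  expect_true(anyNA(tr2$diameter[1:30]))
  expect_error(deblink(make_trace(rep(NA_real_, 100))), "all samples")
})

test_that("trial_response measures baseline-corrected peaks", {
  fs <- 250
  t <- seq(0, 40, by = 1 / fs)
  d <- rep(3, length(t))
  ev <- data.frame(onset_s = c(10, 30), trial = 1:2,
                   partner = "intentional", cs = c("CSplus", "CSminus"))
  flat <- trial_response(deblink(make_trace(d, fs)), ev)
  expect_equal(flat$response, c(0, 0))
  expect_equal(flat$baseline, c(3, 3))
  # a bump of amplitude A on a flat baseline returns A
  A <- 0.8
  bump <- d + A * exp(-((t - 11)^2) / 0.1) * (t > 10 & t < 12.5)
  r <- trial_response(deblink(make_trace(bump, fs)), ev)
  expect_equal(r$response[1], A, tolerance = 0.01)
  expect_equal(r$response[2], 0)
  # fully missing baseline (not repairable, e.g. trace edge) is flagged
  dmiss <- d; dmiss[t >= 29.4] <- NA
  dmiss[t > 30.2] <- 3
  rm_ <- trial_response(make_trace(dmiss, fs), ev)
  expect_true(rm_$baseline_missing[2])
  expect_error(trial_response(deblink(make_trace(d, fs)),
                              data.frame(onset_s = 39.9, trial = 1,
                                         partner = "x", cs = "CSplus")),
               "outside the trace")
})

test_that("qc_impute discards, imputes, and excludes participants", {
  resp <- data.frame(trial = 1:13, partner = "intentional", cs = "CSplus",
                     baseline = 3, response = as.numeric(1:13),
                     missing_fraction = 0, baseline_missing = FALSE)
  # clean input passes through unchanged
  clean <- qc_impute(resp)
  expect_false(clean$excluded)
  expect_equal(clean$responses$response, resp$response)
  expect_false(any(clean$responses$imputed))
  # 5/13 discarded (38%) excludes the participant
  bad <- resp
  bad$missing_fraction[1:5] <- 0.8
  out <- qc_impute(bad)
  expect_true(out$excluded)
  expect_equal(out$report$n_discarded, 5L)
  # 4/13 (31%) does not exclude
  ok <- resp; ok$missing_fraction[1:4] <- 0.8
  expect_false(qc_impute(ok)$excluded)
  # a discarded trial between neighbours 2 and 4 imputes their midpoint
  mid <- data.frame(trial = 1:3, partner = "intentional", cs = "CSplus",
                    baseline = 3, response = c(2, 99, 4),
                    missing_fraction = c(0, 0.9, 0), baseline_missing = FALSE)
  m <- qc_impute(mid)
  expect_equal(m$responses$response[2], 3)
  expect_true(m$responses$imputed[2])
  # endpoint rule: nearest valid value
  endp <- mid; endp$missing_fraction <- c(0.9, 0, 0); endp$response <- c(99, 2, 4)
  expect_equal(qc_impute(endp)$responses$response[1], 2)
})

test_that("condition_contrast is a paired t-test on subject means", {
  df <- data.frame(subject_id = rep(paste0("s", 1:6), each = 2),
                   cs = rep(c("CSplus", "CSminus"), 6),
                   response = c(1.2, 1.0, 0.8, 0.9, 1.1, 0.9,
                                1.0, 1.0, 1.3, 1.1, 0.9, 1.0))
  res <- condition_contrast(df)
  diffs <- df$response[df$cs == "CSplus"] - df$response[df$cs == "CSminus"]
  expect_equal(res$t, mean(diffs) / (sd(diffs) / sqrt(6)), tolerance = 1e-12)
  expect_equal(res$d, mean(diffs) / sd(diffs), tolerance = 1e-12)
  same <- df; same$response <- rep(1, 12)
  expect_error(condition_contrast(same), "zero variance")
  expect_error(condition_contrast(df[1:2, ]), "at least 2")
})

test_that("the pipeline is deterministic and reports per-condition QC", {
  s <- the_sched()
  tr <- generate_pupil(s, pupil_sim_spec(sampling_hz = 50), seed = 8)
  p1 <- pupil_pipeline(tr, s)
  p2 <- pupil_pipeline(tr, s)
  expect_identical(p1, p2)
  expect_equal(nrow(p1$qc), 4L)
  expect_equal(sum(p1$qc$n_trials), 52L)
  expect_equal(nrow(p1$condition_means), 4L)
})
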