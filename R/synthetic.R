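# Synthetic subject-level data with planted, known template weights, so
# every downstream stage is testable by parameter recovery.

#' Planted-effect specification for synthetic voxel patterns
#'
#' Effects are planted on the Fisher-z similarity scale, the scale the
#' template regression operates on, so recovery targets are exact: the
#' expected Fisher-z RSM over target trials is
#' `atanh(condition_pattern_corr) + sum(planted_beta * template_z)`.
#'
#' @param planted_beta Named numeric vector of template weights (names must
#'   be a subset of the emulated template set's names). Empty = global null.
#' @param snr Ratio of shared (structured) to independent voxel-noise
#'   variance; must be > 0.
#' @param n_voxels Number of voxels per pattern (>= 2). Sampling error of
#'   the realized RSM scales as 1/sqrt(n_voxels).
#' @param condition_pattern_corr Baseline correlation between trial patterns
#'   regardless of condition (intercept of the planted model, on the
#'   correlation scale).
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(planted_beta = numeric(0), snr = 1,
                        n_voxels = 200L, condition_pattern_corr = 0.1) {
  stopifnot(snr > 0, n_voxels >= 2L,
            abs(condition_pattern_corr) < 1)
  if (length(planted_beta) && is.null(names(planted_beta)))
    stop("planted_beta must be a named vector of template weights",
         call. = FALSE)
  structure(list(planted_beta = planted_beta, snr = snr,
                 n_voxels = as.integer(n_voxels),
                 condition_pattern_corr = condition_pattern_corr),
            class = "effect_spec")
}

# Target correlation matrix over target trials implied by a planted spec.
.planted_cor <- function(spec, tset) {
  extra <- setdiff(names(spec$planted_beta), names(tset))
  if (length(extra))
    stop("planted_beta names not in template set: ",
         paste(extra, collapse = ", "), call. = FALSE)
  n <- nrow(attr(tset, "trial_order"))
  Z <- matrix(atanh(spec$condition_pattern_corr), n, n)
  for (nm in names(spec$planted_beta)) {
    Tz <- fisher_z(unclass(tset[[nm]]))
    Z <- Z + spec$planted_beta[[nm]] * Tz
  }
  C <- tanh(Z)
  diag(C) <- 1
  C
}

#' Generate synthetic single-trial voxel patterns
#'
#' Target-trial patterns are drawn as a shared component with the planted
#' correlation structure (via an eigendecomposition square root) plus
#' independent voxel noise scaled by `1/snr`; the construction compensates
#' for the noise so the expected correlation between target trials equals
#' the planted value regardless of `snr`. Filler trials receive pure noise
#' patterns of matching variance.
#'
#' @param schedule A `trial_schedule`.
#' @param spec An [effect_spec()].
#' @param tset The `template_set` the planted weights refer to; defaults to
#'   the phase's chosen-option set.
#' @param seed Integer seed (deterministic output).
#' @param roi_name,subject_id Metadata labels.
#' @return A [pattern_matrix()] covering all trials of the schedule.
#' @export
generate_patterns <- function(schedule, spec = effect_spec(),
                              tset = NULL, seed = 0L,
                              roi_name = "roi", subject_id = "sub") {
  stopifnot(inherits(schedule, "trial_schedule"),
            inherits(spec, "effect_spec"))
  phase <- attr(schedule, "phase")
  if (is.null(tset)) {
    tset <- assemble_templates(
      phase, "chosen_option",
      if (phase == "threat") "learning" else "extinction_decay",
      schedule = schedule)
  }
  C <- .planted_cor(spec, tset)
  n <- nrow(C)
  # total covariance (1 + 1/snr) * C = shared part + (1/snr) I
  S_shared <- (1 + 1 / spec$snr) * C
  diag(S_shared) <- 1
  eg <- eigen(S_shared, symmetric = TRUE)
  if (min(eg$values) < -1e-8) {
    worst <- names(spec$planted_beta)[which.max(abs(spec$planted_beta))]
    stop("planted weights imply a non-positive-semidefinite correlation ",
         "structure (min eigenvalue ", format(min(eg$values)),
         "); offending weight: ", worst, call. = FALSE)
  }
  L <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), n)

  tord <- attr(tset, "trial_order")
  V <- spec$n_voxels
  with_local_seed(seed, {
    Xt <- L %*% matrix(stats::rnorm(n * V), n, V) +
      sqrt(1 / spec$snr) * matrix(stats::rnorm(n * V), n, V)
    full <- matrix(stats::rnorm(nrow(schedule) * V,
                                sd = sqrt(1 + 1 / spec$snr)),
                   nrow(schedule), V)
    full[match(tord$trial, schedule$trial), ] <- Xt
    pattern_matrix(full, trials = schedule$trial, roi_name = roi_name,
                   subject_id = subject_id, period = attr(tset, "period"))
  })
}

#' Generate a synthetic BOLD timeseries from trial patterns
#'
#' Each trial's pattern enters the timeseries through its HRF-convolved
#' boxcar regressor (the modelled period), plus white Gaussian noise.
#'
#' @param schedule A `trial_schedule`.
#' @param patterns A [pattern_matrix()] with one row per schedule trial.
#' @param tr_s Repetition time in seconds (default 2).
#' @param noise_sd White-noise standard deviation.
#' @param hrf_params Optional [canonical_hrf()] parameters.
#' @param ar1 Optional AR(1) coefficient for temporally autocorrelated noise
#'   (default 0 = white); the long fixed ITI of the design exists precisely
#'   to decouple consecutive trials from such autocorrelation.
#' @param seed Integer seed.
#' @return Time x voxel matrix of class `voxel_timeseries` with attributes
#'   `tr_s` and `period`.
#' @export
generate_bold <- function(schedule, patterns, tr_s = 2, noise_sd = 1,
                          hrf_params = NULL, ar1 = 0, seed = 0L) {
  stopifnot(inherits(schedule, "trial_schedule"),
            inherits(patterns, "pattern_matrix"), tr_s > 0)
  if (nrow(patterns) != nrow(schedule))
    stop("pattern trial count (", nrow(patterns),
         ") does not match schedule trial count (", nrow(schedule), ")",
         call. = FALSE)
  period <- attr(patterns, "period")
  n_frames <- .default_n_frames(schedule, tr_s)
  ev <- event_table(schedule, period)
  R <- .event_regressors(ev$onset_s, ev$duration_s, tr_s, n_frames,
                         hrf_params)
  signal <- R %*% unclass(patterns)
  noise <- with_local_seed(seed, {
    e <- matrix(stats::rnorm(length(signal), sd = noise_sd),
                nrow(signal), ncol(signal))
    if (ar1 != 0) e <- apply(e, 2L, function(x)
      as.numeric(stats::filter(x, ar1, method = "recursive")))
    e
  })
  structure(signal + noise, tr_s = tr_s, period = period,
            class = c("voxel_timeseries", "matrix", "array"))
}

#' Pupil trace simulation settings
#'
#' @param sampling_hz Sampling rate in Hz (250 in the recorded data).
#' @param baseline_mm Mean pupil diameter in mm.
#' @param response_amp_mm Mean event-locked dilation amplitude (mm).
#' @param cs_effect_mm Planted CS+ minus CS- peak difference in mm (0 =
#'   null).
#' @param blink_rate_hz Expected blink frequency (per second).
#' @param blink_dur_ms Mean and sd of blink duration in ms.
#' @param noise_sd_mm Sample-to-sample noise sd (mm); slow drift of the same
#'   scale is added as smoothed noise.
#' @return Object of class `pupil_sim_spec`.
#' @export
pupil_sim_spec <- function(sampling_hz = 250, baseline_mm = 3,
                           response_amp_mm = 0.3, cs_effect_mm = 0,
                           blink_rate_hz = 0.2,
                           blink_dur_ms = c(mean = 150, sd = 50),
                           noise_sd_mm = 0.05) {
  stopifnot(sampling_hz > 0, all(blink_dur_ms >= 0), noise_sd_mm >= 0)
  expected_missing <- blink_rate_hz * (blink_dur_ms[["mean"]] / 1000)
  if (expected_missing >= 1)
    stop("blink parameters imply >= 100% missing samples", call. = FALSE)
  structure(list(sampling_hz = sampling_hz, baseline_mm = baseline_mm,
                 response_amp_mm = response_amp_mm,
                 cs_effect_mm = cs_effect_mm, blink_rate_hz = blink_rate_hz,
                 blink_dur_ms = blink_dur_ms, noise_sd_mm = noise_sd_mm),
            class = "pupil_sim_spec")
}

# Smooth dilation kernel peaking ~1.2 s after event onset, unit peak.
.pupil_kernel <- function(t_s, peak_s = 1.2) {
  k <- (t_s / peak_s)^2 * exp(2 * (1 - t_s / peak_s))
  k[t_s < 0] <- 0
  k
}

#' Generate a synthetic pupil trace for one subject
#'
#' Continuous diameter trace at `sampling_hz` covering the schedule, with an
#' event-locked dilation response at each trial's CS (chosen-option) onset
#' whose amplitude is `response_amp_mm` plus `cs_effect_mm` on CS+ trials,
#' slow drift plus white measurement noise, and blink gaps (NA runs) drawn
#' as a Poisson process.
#'
#' @param schedule A `trial_schedule`.
#' @param spec A [pupil_sim_spec()].
#' @param seed Integer seed.
#' @param subject_id Metadata label.
#' @return Data.frame of class `pupil_trace` with columns `time_s`,
#'   `diameter` (NA during blinks) and attributes `sampling_hz`,
#'   `subject_id`.
#' @export
generate_pupil <- function(schedule, spec = pupil_sim_spec(), seed = 0L,
                           subject_id = "sub") {
  stopifnot(inherits(schedule, "trial_schedule"),
            inherits(spec, "pupil_sim_spec"))
  fs <- spec$sampling_hz
  cfg <- attr(schedule, "config")
  total_s <- max(schedule$onset_s) + cfg$trial_dur_s + cfg$iti_s
  t <- seq(0, total_s, by = 1 / fs)
  ev <- event_table(schedule, "chosen_option")

  with_local_seed(seed, {
    d <- rep(spec$baseline_mm, length(t))
    amps <- spec$response_amp_mm +
      spec$cs_effect_mm * (ev$cs == "CSplus") +
      stats::rnorm(nrow(ev), sd = spec$response_amp_mm / 3)
    for (k in seq_len(nrow(ev))) {
      i0 <- floor(ev$onset_s[k] * fs) + 1L
      idx <- i0:min(i0 + as.integer(4 * fs), length(t))
      d[idx] <- d[idx] + amps[k] * .pupil_kernel(t[idx] - ev$onset_s[k])
    }
    # slow drift: heavily smoothed noise, plus white measurement noise
    drift <- stats::filter(stats::rnorm(length(t), sd = spec$noise_sd_mm),
                           rep(1 / fs, fs), circular = TRUE)
    d <- d + as.numeric(drift) + stats::rnorm(length(t),
                                              sd = spec$noise_sd_mm)
    n_blinks <- stats::rpois(1, spec$blink_rate_hz * total_s)
    if (n_blinks > 0) {
      onsets <- stats::runif(n_blinks, 0, total_s)
      durs <- pmax(stats::rnorm(n_blinks, spec$blink_dur_ms[["mean"]],
                                spec$blink_dur_ms[["sd"]]), 20) / 1000
      for (b in seq_len(n_blinks)) {
        i0 <- floor(onsets[b] * fs) + 1L
        i1 <- min(i0 + as.integer(durs[b] * fs), length(t))
        d[i0:i1] <- NA_real_
      }
    }
    structure(data.frame(time_s = t, diameter = d),
              sampling_hz = fs, subject_id = subject_id,
              class = c("pupil_trace", "data.frame"))
  })
}
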