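# Single-trial ("least-squares-all") GLM: one HRF-convolved regressor per
# trial in a single model, plus US and nuisance regressors; OLS per voxel.

#' Canonical double-gamma haemodynamic response function
#'
#' Difference of two gamma densities (response peak ~5 s, undershoot ~15 s,
#' undershoot ratio 1/6), scaled to unit peak amplitude. The response is 0
#' at t = 0 and has decayed to under 1% of peak by 30 s.
#'
#' @param t_s Time in seconds, `t_s >= 0`.
#' @param params Named list of shape/rate parameters `a1`, `b1` (response),
#'   `a2`, `b2` (undershoot) and undershoot ratio `c`.
#' @return HRF amplitude at `t_s` (unit peak).
#' @export
canonical_hrf <- function(t_s, params = list(a1 = 6, b1 = 1, a2 = 16,
                                             b2 = 1, c = 1 / 6)) {
  if (any(t_s < 0)) stop("HRF is defined for t >= 0", call. = FALSE)
  raw <- function(t) {
    stats::dgamma(t, shape = params$a1, rate = params$b1) -
      params$c * stats::dgamma(t, shape = params$a2, rate = params$b2)
  }
  peak <- max(raw(seq(0, 30, by = 0.01)))
  raw(t_s) / peak
}

# Cumulative HRF as an interpolating function; the convolution of a boxcar
# [onset, onset+dur] with the HRF is CH(t-onset) - CH(t-onset-dur).
.hrf_cumfun <- function(params = NULL, span_s = 40, dt = 0.01) {
  grid <- seq(0, span_s, by = dt)
  h <- if (is.null(params)) canonical_hrf(grid) else canonical_hrf(grid, params)
  ch <- cumsum(h) * dt
  stats::approxfun(grid, ch, yleft = 0, yright = ch[length(ch)])
}

# frames x events matrix of HRF-convolved boxcar regressors sampled at the
# TR grid.
.event_regressors <- function(onsets, durations, tr_s, n_frames,
                              hrf_params = NULL) {
  CH <- .hrf_cumfun(hrf_params)
  t_frames <- (seq_len(n_frames) - 1) * tr_s
  durations <- rep_len(durations, length(onsets))
  out <- vapply(seq_along(onsets), function(k) {
    CH(pmax(t_frames - onsets[k], 0)) -
      CH(pmax(t_frames - onsets[k] - durations[k], 0))
  }, numeric(n_frames))
  matrix(out, nrow = n_frames)
}

.default_n_frames <- function(schedule, tr_s, pad_s = 24) {
  cfg <- attr(schedule, "config")
  total <- max(schedule$onset_s) + cfg$trial_dur_s + cfg$iti_s + pad_s
  as.integer(ceiling(total / tr_s))
}

#' Discrete-cosine drift basis
#'
#' Optional low-frequency drift regressors (DCT-II basis, excluding the
#' constant term), off by default in [build_design()].
#'
#' @param n_frames Number of timepoints.
#' @param n_basis Number of cosine regressors.
#' @return n_frames x n_basis matrix.
#' @export
drift_basis <- function(n_frames, n_basis) {
  t <- seq_len(n_frames) - 1
  out <- vapply(seq_len(n_basis), function(k) {
    cos(pi * (2 * t + 1) * k / (2 * n_frames))
  }, numeric(n_frames))
  matrix(out, nrow = n_frames,
         dimnames = list(NULL, paste0("drift_", seq_len(n_basis))))
}

#' Build the single-trial GLM design matrix
#'
#' One HRF-convolved boxcar regressor per trial (all trials of the phase),
#' starting at the period's onset with the period's duration, plus a shock
#' (US) regressor when the schedule contains reinforced trials, plus any
#' supplied nuisance columns, an optional drift basis, and an intercept.
#'
#' @param schedule A `trial_schedule`.
#' @param period Within-trial period to model (`"early_anticipation"` or
#'   `"chosen_option"`, both 3 s; `"choice"` is 1 s).
#' @param tr_s Repetition time in seconds (default 2).
#' @param nuisance Optional numeric matrix of nuisance regressors with
#'   `n_frames` rows (e.g. motion parameters).
#' @param n_drift Number of discrete-cosine drift regressors (default 0).
#' @param n_frames Number of timepoints; defaults to covering the phase.
#' @param hrf_params Optional [canonical_hrf()] parameter list.
#' @return Design matrix of class `glm_design` with column labels and
#'   attributes `trials` (schedule trial per trial column), `trial_cols`,
#'   `period`, `tr_s`.
#' @export
build_design <- function(schedule,
                         period = c("chosen_option", "early_anticipation",
                                    "choice"),
                         tr_s = 2, nuisance = NULL, n_drift = 0L,
                         n_frames = NULL, hrf_params = NULL) {
  stopifnot(inherits(schedule, "trial_schedule"), tr_s > 0)
  period <- match.arg(period)
  if (is.null(n_frames)) n_frames <- .default_n_frames(schedule, tr_s)
  ev <- event_table(schedule, period)
  X_tr <- .event_regressors(ev$onset_s, ev$duration_s, tr_s, n_frames,
                            hrf_params)
  colnames(X_tr) <- sprintf("trial_%02d", ev$trial)
  parts <- list(X_tr)
  us <- us_events(schedule)
  if (nrow(us) > 0) {
    us_col <- rowSums(.event_regressors(us$onset_s, us$duration_s, tr_s,
                                        n_frames, hrf_params))
    parts <- c(parts, list(us = matrix(us_col, ncol = 1,
                                       dimnames = list(NULL, "us"))))
  }
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != n_frames)
      stop("nuisance matrix has ", nrow(nuisance), " rows; expected ",
           n_frames, call. = FALSE)
    if (is.null(colnames(nuisance)))
      colnames(nuisance) <- paste0("nuis_", seq_len(ncol(nuisance)))
    parts <- c(parts, list(nuisance))
  }
  if (n_drift > 0L) parts <- c(parts, list(drift_basis(n_frames, n_drift)))
  parts <- c(parts, list(intercept = matrix(1, n_frames, 1,
                                            dimnames = list(NULL, "intercept"))))
  X <- do.call(cbind, parts)

  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  structure(X, trials = ev$trial, trial_cols = seq_len(ncol(X_tr)),
            period = period, tr_s = tr_s,
            class = c("glm_design", "matrix", "array"))
}

#' Fit single-trial betas by ordinary least squares
#'
#' Per-voxel OLS on the full design; returns the trial columns' estimates as
#' a [pattern_matrix()] tagged with trial metadata. Nuisance, US, drift and
#' intercept coefficients are estimated jointly but not returned.
#'
#' @param ts Numeric time x voxel matrix (a `voxel_timeseries`).
#' @param design A `glm_design` from [build_design()] with `nrow(ts)` rows.
#' @param roi_name,subject_id Metadata for the returned pattern matrix.
#' @return A [pattern_matrix()] (trials x voxels) with attribute
#'   `residual_sd` (per-voxel residual standard deviation).
#' @export
fit_betas <- function(ts, design, roi_name = "roi", subject_id = "sub") {
  stopifnot(inherits(design, "glm_design"))
  Y <- as.matrix(ts)
  if (any(!is.finite(Y)))
    stop("timeseries contains missing or non-finite values", call. = FALSE)
  if (nrow(Y) != nrow(design))
    stop("timeseries has ", nrow(Y), " rows but design has ", nrow(design),
         call. = FALSE)
  qx <- qr(unclass(design))
  B <- qr.coef(qx, Y)
  resid <- qr.resid(qx, Y)
  rdf <- nrow(Y) - ncol(design)
  res_sd <- sqrt(colSums(resid^2) / rdf)
  pm <- pattern_matrix(B[attr(design, "trial_cols"), , drop = FALSE],
                       trials = attr(design, "trials"),
                       roi_name = roi_name, subject_id = subject_id,
                       period = attr(design, "period"))
  attr(pm, "residual_sd") <- res_sd
  pm
}

#' One-call single-trial GLM
#'
#' Builds the design for the timeseries at hand and fits it.
#'
#' @inheritParams fit_betas
#' @inheritParams build_design
#' @param ... Passed to [build_design()].
#' @return A [pattern_matrix()].
#' @export
trial_glm <- function(ts, schedule, period = "chosen_option",
                      tr_s = attr(ts, "tr_s") %||% 2,
                      roi_name = "roi", subject_id = "sub", ...) {
  design <- build_design(schedule, period = period, tr_s = tr_s,
                         n_frames = nrow(ts), ...)
  fit_betas(ts, design, roi_name = roi_name, subject_id = subject_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
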