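# Pupillometry preprocessing: blink repair, baseline correction, peak
# extraction, trial/participant QC and the CS+ vs CS- contrast.

.runs_of_na <- function(x) {
  r <- rle(is.na(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Blink repair by widening and linear interpolation
#'
#' Samples within 100 ms before and after each missing segment are deemed
#' unreliable; each widened segment is replaced by the linear trend between
#' the nearest valid neighbours. Segments touching the trace boundary have
#' no neighbour on one side and remain missing.
#'
#' @param trace A `pupil_trace` (columns `time_s`, `diameter`).
#' @param pad_ms Widening margin in ms (default 100).
#' @return The trace with interpolated `diameter`, plus attributes
#'   `missing_mask` (logical; TRUE where samples were missing or widened,
#'   i.e. the pre-interpolation mask) and `blink_report` (one row per
#'   segment: sample range and treated duration in ms).
#' @export
deblink <- function(trace, pad_ms = 100) {
  stopifnot(inherits(trace, "pupil_trace"))
  fs <- attr(trace, "sampling_hz")
  d <- trace$diameter
  n <- length(d)
  if (all(is.na(d))) stop("all samples missing", call. = FALSE)
  segs <- .runs_of_na(d)
  pad <- as.integer(round(pad_ms / 1000 * fs))
  mask <- rep(FALSE, n)
  if (nrow(segs)) {
    segs$wstart <- pmax(segs$start - pad, 1L)
    segs$wend <- pmin(segs$end + pad, n)
    for (k in seq_len(nrow(segs))) mask[segs$wstart[k]:segs$wend[k]] <- TRUE
    segs$treated_ms <- (segs$wend - segs$wstart + 1L) / fs * 1000
  }
  dd <- d
  dd[mask] <- NA_real_
  valid <- which(!is.na(dd))
  if (length(valid) >= 2L) {
    interp <- stats::approx(valid, dd[valid], xout = seq_len(n),
                            method = "linear", rule = 1)$y
    fill <- mask & !is.na(interp)
    dd[fill] <- interp[fill]
  }
  out <- trace
  out$diameter <- dd
  attr(out, "missing_mask") <- mask
  attr(out, "blink_report") <- segs
  out
}

#' Per-trial baseline-corrected peak responses
#'
#' For each event: baseline = mean diameter over the 500 ms preceding the
#' onset; response = maximum over the 2.5 s window from the onset, minus the
#' baseline. The missing fraction is evaluated on the pre-interpolation
#' mask over the response window (set `missing_window = "trial"` to use the
#' whole trial).
#'
#' @param trace A deblinked `pupil_trace` (from [deblink()]).
#' @param events Data.frame with columns `onset_s`, `trial`, `partner`,
#'   `cs` (e.g. the chosen-option [event_table()]).
#' @param baseline_s Baseline window length before onset (default 0.5).
#' @param window_s Response window length from onset (default 2.5).
#' @param missing_window `"response"` (default) or `"trial"` (onset to next
#'   onset).
#' @return Data.frame with one row per event: `trial`, `partner`, `cs`,
#'   `baseline`, `response`, `missing_fraction`, `baseline_missing`.
#' @export
trial_response <- function(trace, events, baseline_s = 0.5, window_s = 2.5,
                           missing_window = c("response", "trial")) {
  stopifnot(inherits(trace, "pupil_trace"))
  missing_window <- match.arg(missing_window)
  mask <- attr(trace, "missing_mask")
  if (is.null(mask)) mask <- is.na(trace$diameter)
  t <- trace$time_s
  d <- trace$diameter
  if (any(events$onset_s - baseline_s < t[1L]) ||
      any(events$onset_s + window_s > t[length(t)]))
    stop("event window outside the trace", call. = FALSE)
  spacing <- if (nrow(events) > 1L) min(diff(events$onset_s)) else window_s
  rows <- lapply(seq_len(nrow(events)), function(k) {
    on <- events$onset_s[k]
    ib <- which(t >= on - baseline_s & t < on)
    iw <- which(t >= on & t <= on + window_s)
    im <- if (missing_window == "response") iw else
      which(t >= on & t < on + spacing)
    baseline_missing <- all(is.na(d[ib]))
    baseline <- if (baseline_missing) NA_real_ else mean(d[ib], na.rm = TRUE)
    peak <- if (all(is.na(d[iw]))) NA_real_ else max(d[iw], na.rm = TRUE)
    data.frame(trial = events$trial[k], partner = events$partner[k],
               cs = events$cs[k], baseline = baseline,
               response = peak - baseline,
               missing_fraction = mean(mask[im]),
               baseline_missing = baseline_missing,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Trial QC, imputation and participant exclusion
#'
#' Trials with more than `max_missing` missing samples (after blink
#' widening), or with no usable baseline, are discarded and replaced by the
#' linear trend between the preceding and following trial of the same
#' condition (nearest valid value at the condition's ends). A participant is
#' excluded when the discarded fraction of any condition exceeds
#' `max_discard` (more than 33% of trials of any condition).
#'
#' @param responses Per-trial data.frame from [trial_response()].
#' @param max_missing Per-trial missing-fraction threshold (default 0.5).
#' @param max_discard Per-condition discard-fraction threshold for
#'   participant exclusion (default 1/3).
#' @return List: `responses` (with `discarded` and `imputed` flags and
#'   imputed values), `excluded` (logical), `report` (per-condition counts).
#' @export
qc_impute <- function(responses, max_missing = 0.5, max_discard = 1 / 3) {
  resp <- responses
  resp$discarded <- resp$missing_fraction > max_missing |
    resp$baseline_missing | is.na(resp$response)
  resp$imputed <- FALSE
  key <- paste(resp$partner, resp$cs)
  for (cond in unique(key)) {
    idx <- which(key == cond)
    idx <- idx[order(resp$trial[idx])]
    bad <- resp$discarded[idx]
    if (any(bad)) {
      ok <- which(!bad)
      if (length(ok) == 0L)
        stop("condition ", cond, " has no valid trials to impute from",
             call. = FALSE)
      filled <- stats::approx(ok, resp$response[idx[ok]],
                              xout = seq_along(idx), method = "linear",
                              rule = 2)$y
      resp$response[idx[bad]] <- filled[bad]
      resp$imputed[idx[bad]] <- TRUE
    }
  }
  report <- do.call(rbind, lapply(split(resp, key), function(g) {
    data.frame(partner = g$partner[1L], cs = g$cs[1L],
               n_trials = nrow(g), n_discarded = sum(g$discarded),
               discard_fraction = mean(g$discarded),
               stringsAsFactors = FALSE)
  }))
  rownames(report) <- NULL
  list(responses = resp,
       excluded = any(report$discard_fraction > max_discard),
       report = report)
}

#' Paired CS+ vs CS- contrast across subjects
#'
#' Two-sided paired t-test on per-subject mean responses.
#'
#' @param subject_means Data.frame with columns `subject_id`, `cs`
#'   (`"CSplus"`/`"CSminus"`), `response` (one mean per subject x CS).
#' @return List `t`, `df`, `p`, `d` (Cohen's d of the paired differences),
#'   `mean_diff`, `n`.
#' @export
condition_contrast <- function(subject_means) {
  wide <- stats::reshape(subject_means[, c("subject_id", "cs", "response")],
                         idvar = "subject_id", timevar = "cs",
                         direction = "wide")
  plus <- wide$response.CSplus
  minus <- wide$response.CSminus
  if (anyNA(plus) || anyNA(minus))
    stop("each subject needs both CS+ and CS- means", call. = FALSE)
  if (length(plus) < 2L) stop("need at least 2 subjects", call. = FALSE)
  diffs <- plus - minus
  s <- stats::sd(diffs)
  if (!is.finite(s) || s == 0)
    stop("zero variance of paired differences", call. = FALSE)
  tt <- stats::t.test(plus, minus, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       d = mean(diffs) / s, mean_diff = mean(diffs), n = length(diffs))
}

#' Full per-subject pupil pipeline
#'
#' Deblink, per-trial baseline-corrected peaks on the chosen-option (CS
#' presentation) events, QC and imputation, then per-condition means.
#'
#' @param trace A raw `pupil_trace`.
#' @param schedule The `trial_schedule`.
#' @param ... Passed to [qc_impute()].
#' @return List: `condition_means` (data.frame `subject_id`, `partner`,
#'   `cs`, `response`), `cs_means` (collapsed over partner), `excluded`,
#'   `qc` report.
#' @export
pupil_pipeline <- function(trace, schedule, ...) {
  db <- deblink(trace)
  ev <- event_table(schedule, "chosen_option")
  resp <- trial_response(db, ev)
  qc <- qc_impute(resp, ...)
  r <- qc$responses
  agg <- stats::aggregate(response ~ partner + cs, data = r, FUN = mean)
  agg <- cbind(subject_id = attr(trace, "subject_id"), agg)
  cs_agg <- stats::aggregate(response ~ cs, data = r, FUN = mean)
  cs_agg <- cbind(subject_id = attr(trace, "subject_id"), cs_agg)
  list(condition_means = agg, cs_means = cs_agg,
       excluded = qc$excluded, qc = qc$report)
}
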