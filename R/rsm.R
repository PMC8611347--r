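# Shared pair indexer: row-major lower triangle (i > j), excluding the
# diagonal. Templates and RSMs must use the identical ordering.
pair_index <- function(n) {
  stopifnot(n >= 2L)
  i <- rep(seq(2L, n), times = seq(2L, n) - 1L)
  j <- unlist(lapply(seq(2L, n), function(k) seq_len(k - 1L)), use.names = FALSE)
  data.frame(i = i, j = j)
}

#' Z-score a single-trial voxel pattern
#'
#' Standardizes one trial's pattern across voxels to mean 0, standard
#' deviation 1, the normalization applied to single-trial parameter
#' estimates before computing pattern correlations.
#'
#' @param x Numeric vector (one trial's voxel pattern), length >= 2.
#' @param label Optional trial label used in error messages.
#' @return Standardized numeric vector.
#' @export
zscore_pattern <- function(x, label = NULL) {
  if (length(x) < 2L) stop("pattern needs at least 2 voxels", call. = FALSE)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("zero-variance pattern",
         if (!is.null(label)) paste0(" (trial ", label, ")") else "",
         call. = FALSE)
  (x - mean(x)) / s
}

#' Single-trial pattern matrix
#'
#' Container for per-trial voxel patterns (trials x voxels) of one subject,
#' ROI and within-trial period, with a per-row link to schedule trials.
#'
#' @param betas Numeric matrix, trials x voxels.
#' @param trials Integer vector of schedule trial numbers, one per row.
#' @param roi_name,subject_id,period Metadata labels.
#' @return Matrix of class `pattern_matrix`.
#' @export
pattern_matrix <- function(betas, trials, roi_name = "roi",
                           subject_id = "sub", period = "chosen_option") {
  betas <- as.matrix(betas)
  if (nrow(betas) != length(trials))
    stop("row count (", nrow(betas), ") does not match trial count (",
         length(trials), ")", call. = FALSE)
  if (any(!is.finite(betas)))
    stop("pattern matrix contains non-finite values", call. = FALSE)
  structure(betas, trials = as.integer(trials), roi_name = roi_name,
            subject_id = subject_id, period = period,
            class = c("pattern_matrix", "matrix", "array"))
}

#' Trial-by-trial representational similarity matrix over target trials
#'
#' Z-scores each target trial's pattern across voxels and computes all
#' pairwise Pearson correlations, with rows/columns in the condition-grouped
#' target order (conditions in fixed order, chronological within condition).
#'
#' @param patterns A [pattern_matrix()] covering (at least) all target trials
#'   of `schedule`.
#' @param schedule The `trial_schedule` the patterns were estimated on.
#' @return Correlation matrix of class `rsm` (n_target x n_target) with
#'   attributes `trial_order`, `roi_name`, `subject_id`, `phase`, `period`.
#' @export
compute_rsm <- function(patterns, schedule) {
  stopifnot(inherits(patterns, "pattern_matrix"),
            inherits(schedule, "trial_schedule"))
  tord <- target_order(schedule)
  ptrials <- attr(patterns, "trials")
  rows <- match(tord$trial, ptrials)
  if (anyNA(rows))
    stop("patterns are missing target trials: ",
         paste(tord$trial[is.na(rows)], collapse = ", "), call. = FALSE)
  X <- patterns[rows, , drop = FALSE]
  Z <- t(vapply(seq_len(nrow(X)),
                function(r) zscore_pattern(X[r, ], label = tord$trial[r]),
                numeric(ncol(X))))
  R <- stats::cor(t(Z))
  R[R > 1] <- 1; R[R < -1] <- -1
  diag(R) <- 1
  labs <- paste(abbreviate(tord$partner, 5), tord$cs, tord$cond_pos, sep = ".")
  dimnames(R) <- list(labs, labs)
  structure(R, trial_order = tord,
            roi_name = attr(patterns, "roi_name"),
            subject_id = attr(patterns, "subject_id"),
            phase = attr(schedule, "phase"),
            period = attr(patterns, "period"),
            class = c("rsm", "matrix", "array"))
}

#' Fisher z-transform with the infinity replacement rule
#'
#' Applies `atanh` elementwise; perfect correlations transform to +/-Inf and
#' are replaced by +/-0.999 after the transformation (signed by default; set
#' `signed = FALSE` to replace both with +0.999).
#'
#' @param values Numeric values in `[-1, 1]`.
#' @param signed Preserve the sign of the replaced infinities (default TRUE).
#' @return Transformed values, same shape as the input.
#' @export
fisher_z <- function(values, signed = TRUE) {
  v <- values
  bad <- !is.na(v) & abs(v) > 1
  if (any(bad))
    stop("correlation values outside [-1, 1]: ",
         paste(utils::head(v[bad], 3L), collapse = ", "), call. = FALSE)
  z <- atanh(v)
  inf <- !is.na(z) & is.infinite(z)
  z[inf] <- if (signed) sign(z[inf]) * 0.999 else 0.999
  z
}

#' Lower-triangle vector of an RSM
#'
#' Extracts the below-diagonal entries in the shared row-major pair order
#' (i > j); the diagonal is never used in the regression.
#'
#' @param rsm Square symmetric matrix (an `rsm` or a template matrix).
#' @return Numeric vector of length n(n-1)/2 with attribute `pair_index`.
#' @export
lower_triangle <- function(rsm) {
  m <- unclass(rsm)
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (max(abs(m - t(m))) > 1e-10)
    stop("matrix is not symmetric (max asymmetry ",
         format(max(abs(m - t(m)))), ")", call. = FALSE)
  pi <- pair_index(nrow(m))
  structure(m[cbind(pi$i, pi$j)], pair_index = pi)
}

#' Fisher-transformed similarity vector of an RSM
#'
#' Convenience composition of [lower_triangle()] and [fisher_z()]: the
#' per-subject response vector of the template regression.
#'
#' @inheritParams lower_triangle
#' @inheritParams fisher_z
#' @return Numeric vector of Fisher-z similarities with `pair_index`.
#' @export
similarity_vector <- function(rsm, signed = TRUE) {
  lt <- lower_triangle(rsm)
  structure(fisher_z(lt, signed = signed),
            pair_index = attr(lt, "pair_index"))
}

#' @export
print.rsm <- function(x, ...) {
  cat(sprintf("<rsm> %dx%d | subject=%s roi=%s phase=%s period=%s\n",
              nrow(x), ncol(x), attr(x, "subject_id"), attr(x, "roi_name"),
              attr(x, "phase"), attr(x, "period")))
  invisible(x)
}
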