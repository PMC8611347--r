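# Consecutive-trial correlation analysis: within-condition superdiagonal of
# the RSM and a 2x2 repeated-measures ANOVA on the per-condition means.

#' Consecutive-trial Fisher-z correlations per condition
#'
#' Extracts, for each condition's within-block chronological order, the
#' correlations between consecutive target trials (1-2, 2-3, ...; the
#' (i, j+1) superdiagonal of the condition's block) and Fisher-transforms
#' them.
#'
#' @param rsm An `rsm` from [compute_rsm()].
#' @return Data.frame with columns `partner`, `cs`, `pair` (1..k-1), `z`;
#'   k-1 rows per condition.
#' @export
consecutive_series <- function(rsm) {
  stopifnot(inherits(rsm, "rsm"))
  tord <- attr(rsm, "trial_order")
  cond <- conditions()
  out <- list()
  for (ci in seq_len(nrow(cond))) {
    idx <- which(tord$partner == cond$partner[ci] & tord$cs == cond$cs[ci])
    idx <- idx[order(tord$cond_pos[idx])]
    k <- length(idx)
    if (k < 2L)
      stop("condition ", cond$partner[ci], "/", cond$cs[ci],
           " has fewer than 2 target trials", call. = FALSE)
    r <- rsm[cbind(idx[-1L], idx[-k])]
    out[[ci]] <- data.frame(partner = cond$partner[ci], cs = cond$cs[ci],
                            pair = seq_len(k - 1L), z = fisher_z(r),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "subject_id") <- attr(rsm, "subject_id")
  attr(res, "roi_name") <- attr(rsm, "roi_name")
  res
}

#' 2x2 repeated-measures ANOVA on per-condition means
#'
#' Within-subject ANOVA with factors CS type (2) and intentionality (2):
#' main effects and interaction, each on (1, n-1) degrees of freedom, with
#' partial eta squared = SS_effect / (SS_effect + SS_error).
#'
#' @param cells Data.frame with columns `subject_id`, `partner`, `cs`,
#'   `value`: one value per subject x condition (complete cells).
#' @return Data.frame with one row per effect (`cs`, `intentionality`,
#'   `interaction`): `F`, `df1`, `df2`, `p`, `partial_eta_sq`.
#' @export
rm_anova_2x2 <- function(cells) {
  needed <- c("subject_id", "partner", "cs", "value")
  if (!all(needed %in% names(cells)))
    stop("cells must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  tab <- table(cells$subject_id, paste(cells$partner, cells$cs))
  if (any(tab != 1L) || ncol(tab) != 4L)
    stop("incomplete cells: each subject needs exactly one value per ",
         "condition", call. = FALSE)
  n <- nrow(tab)
  if (n < 2L) stop("need at least 2 subjects", call. = FALSE)

  d <- data.frame(subject = factor(cells$subject_id),
                  cs = factor(cells$cs),
                  partner = factor(cells$partner),
                  value = cells$value)
  fit <- stats::aov(value ~ cs * partner + Error(subject / (cs * partner)),
                    data = d)
  sm <- summary(fit)
  # scale-relative floor: strata whose entire SS is numerical noise are
  # degenerate (constant cells within subjects) and report F = 0
  ss_floor <- 1e-12 * (stats::var(d$value) * (nrow(d) - 1L) + 1e-300)
  grab <- function(stratum, term) {
    tt <- sm[[paste0("Error: ", stratum)]][[1L]]
    row <- trimws(rownames(tt)) == term
    err <- trimws(rownames(tt)) == "Residuals"
    ss_eff <- tt[row, "Sum Sq"]; ss_err <- tt[err, "Sum Sq"]
    if (!is.finite(ss_eff) || ss_eff + ss_err < ss_floor)
      return(data.frame(F = 0, df1 = tt[row, "Df"], df2 = tt[err, "Df"],
                        p = 1, partial_eta_sq = 0))
    data.frame(F = tt[row, "F value"],
               df1 = tt[row, "Df"], df2 = tt[err, "Df"],
               p = tt[row, "Pr(>F)"],
               partial_eta_sq = ss_eff / (ss_eff + ss_err))
  }
  out <- rbind(cs = grab("subject:cs", "cs"),
               intentionality = grab("subject:partner", "partner"),
               interaction = grab("subject:cs:partner", "cs:partner"))
  out <- cbind(effect = c("cs", "intentionality", "interaction"), out)
  rownames(out) <- NULL
  # constant cells within every subject give 0/0; report F = 0
  zero <- !is.finite(out$F)
  out$F[zero] <- 0
  out$p[zero] <- 1
  out$partial_eta_sq[zero] <- 0
  out
}

#' Consecutive-trial analysis for a cohort across ROIs
#'
#' Per subject and ROI, averages the Fisher-z consecutive correlations
#' within each condition, runs the 2x2 repeated-measures ANOVA per ROI, and
#' applies BH-FDR across ROIs within each effect family.
#'
#' @param cohort Nested list `cohort[[subject]][[roi]]` of
#'   [pattern_matrix()] objects.
#' @param schedule The `trial_schedule`.
#' @param q FDR threshold.
#' @return Data.frame with one row per (roi, effect), including `p_fdr` and
#'   `rejected`; per-subject condition means in attribute `cell_means`.
#' @export
consecutive_analysis <- function(cohort, schedule, q = 0.05) {
  rois <- names(cohort[[1L]])
  subjects <- names(cohort) %||% paste0("sub", seq_along(cohort))
  cells_all <- list()
  res <- list()
  for (r in rois) {
    cells <- do.call(rbind, lapply(seq_along(cohort), function(s) {
      rsm <- compute_rsm(cohort[[s]][[r]], schedule)
      ser <- consecutive_series(rsm)
      agg <- stats::aggregate(z ~ partner + cs, data = ser, FUN = mean)
      data.frame(subject_id = subjects[s], partner = agg$partner,
                 cs = agg$cs, value = agg$z, stringsAsFactors = FALSE)
    }))
    an <- rm_anova_2x2(cells)
    an <- cbind(roi = r, an)
    res[[r]] <- an
    cells_all[[r]] <- cells
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out <- do.call(rbind, lapply(split(out, out$effect), fdr_correct, q = q))
  out <- out[order(out$roi, out$effect), ]
  rownames(out) <- NULL
  structure(out, cell_means = cells_all)
}
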