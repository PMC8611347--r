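# Per-subject template regression on Fisher-z similarity vectors and group
# inference with Benjamini-Hochberg FDR across ROIs.

#' Fit the template regression for one subject and ROI
#'
#' Regresses a Fisher-z similarity vector on the Fisher-transformed template
#' predictors plus an intercept:
#' `z(i,j) = beta0 + sum_n beta_n * template_n(i,j) + eps(i,j)`.
#'
#' @param sim Numeric similarity vector from [similarity_vector()] (length
#'   n_pairs, shared pair ordering).
#' @param tset A `template_set` on the same trial ordering.
#' @param estimator `"ols"` (default) or `"robust"` (M-estimation via
#'   [MASS::rlm()]).
#' @param transform_templates Fisher-transform the template predictors like
#'   the data (default TRUE).
#' @param subject_id,roi_name Metadata labels.
#' @return Object of class `subject_fit`: `beta0`, named `betas`, per-
#'   coefficient `t_stats`, `residual_sd`, `fitted`, `residuals`.
#' @export
fit_subject <- function(sim, tset, estimator = c("ols", "robust"),
                        transform_templates = TRUE,
                        subject_id = attr(sim, "subject_id") %||% "sub",
                        roi_name = attr(sim, "roi_name") %||% "roi") {
  estimator <- match.arg(estimator)
  P <- template_predictors(tset, transform = transform_templates)
  y <- as.numeric(sim)
  if (length(y) != nrow(P))
    stop("similarity vector length (", length(y),
         ") does not match template pair count (", nrow(P), ")",
         call. = FALSE)
  X <- cbind("(Intercept)" = 1, P)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("collinear templates: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (estimator == "ols") {
    coefs <- qr.coef(qx, y)
    res <- qr.resid(qx, y)
    rdf <- length(y) - ncol(X)
    sigma2 <- sum(res^2) / rdf
    XtXinv <- chol2inv(chol(crossprod(X)))
    se <- sqrt(sigma2 * diag(XtXinv))
    tv <- coefs / se
    fitted <- y - res
    residual_sd <- sqrt(sigma2)
  } else {
    rf <- MASS::rlm(X, y, maxit = 100)
    sm <- summary(rf)$coefficients
    coefs <- stats::setNames(sm[, "Value"], colnames(X))
    tv <- stats::setNames(sm[, "t value"], colnames(X))
    res <- stats::residuals(rf)
    fitted <- stats::fitted(rf)
    residual_sd <- summary(rf)$sigma
  }
  structure(list(subject_id = subject_id, roi_name = roi_name,
                 beta0 = unname(coefs[1L]),
                 betas = coefs[-1L], t_stats = tv[-1L],
                 residual_sd = residual_sd,
                 fitted = fitted, residuals = res,
                 estimator = estimator,
                 hypothesis_set = attr(tset, "hypothesis_set")),
            class = "subject_fit")
}

#' @export
print.subject_fit <- function(x, ...) {
  cat(sprintf("<subject_fit> %s/%s (%s): beta0=%.3f\n", x$subject_id,
              x$roi_name, x$estimator, x$beta0))
  print(round(rbind(beta = x$betas, t = x$t_stats), 3))
  invisible(x)
}

#' One-sample group test on a coefficient's per-subject estimates
#'
#' Two-sided one-sample t-test of the subjects' beta estimates against zero,
#' with Cohen's d = mean/sd.
#'
#' @param fits List of `subject_fit` objects (>= 2 subjects).
#' @param coefficient Template name.
#' @return List with `coefficient`, `n`, `mean_beta`, `t`, `df`, `p`, `d`.
#' @export
group_test <- function(fits, coefficient) {
  betas <- vapply(fits, function(f) {
    if (!coefficient %in% names(f$betas))
      stop("coefficient '", coefficient, "' not in subject fit for ",
           f$subject_id, call. = FALSE)
    f$betas[[coefficient]]
  }, numeric(1))
  if (length(betas) < 2L)
    stop("group test needs at least 2 subjects", call. = FALSE)
  s <- stats::sd(betas)
  if (!is.finite(s) || s == 0)
    stop("zero variance across subjects for '", coefficient, "'",
         call. = FALSE)
  tt <- stats::t.test(betas, mu = 0)
  list(coefficient = coefficient, n = length(betas),
       mean_beta = mean(betas),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, d = mean(betas) / s)
}

#' Benjamini-Hochberg FDR correction over a model's test family
#'
#' The family is all (ROI x template-coefficient) tests of one model; the
#' intercept is excluded. With the default 12-region chosen-option registry
#' and 5 templates the family has 60 tests.
#'
#' @param results Data.frame with a `p` column (one row per test).
#' @param q FDR threshold (default 0.05).
#' @return `results` with columns `p_fdr` (BH step-up adjusted p) and
#'   `rejected` appended.
#' @export
fdr_correct <- function(results, q = 0.05) {
  if (!is.data.frame(results) || !"p" %in% names(results))
    stop("results must be a data.frame with a 'p' column", call. = FALSE)
  if (nrow(results) == 0L) stop("empty test family", call. = FALSE)
  stopifnot(q > 0, q < 1)
  results$p_fdr <- stats::p.adjust(results$p, method = "BH")
  results$rejected <- results$p_fdr <= q
  results
}

#' Run the full model for a cohort: RSM, regression, group inference
#'
#' For each subject and ROI: condition-grouped RSM over target trials,
#' Fisher-z lower triangle, per-subject template regression; then per (ROI,
#' coefficient) a one-sample group t-test, and BH-FDR across the whole
#' model family.
#'
#' @param cohort Nested list: `cohort[[subject]][[roi]]` is a
#'   [pattern_matrix()].
#' @param schedule The `trial_schedule` the patterns were estimated on.
#' @param period,hypothesis_set Passed to [assemble_templates()] (phase is
#'   taken from the schedule).
#' @param estimator Passed to [fit_subject()].
#' @param q FDR threshold.
#' @return Data.frame of class `group_result` with one row per (ROI,
#'   coefficient): `model`, `roi`, `coefficient`, `n`, `beta_mean`, `t`,
#'   `df`, `p`, `p_fdr`, `d`, `rejected`; subject fits in attribute
#'   `subject_fits`.
#' @export
run_model <- function(cohort, schedule, period = "chosen_option",
                      hypothesis_set = "learning",
                      estimator = "ols", q = 0.05) {
  phase <- attr(schedule, "phase")
  tset <- assemble_templates(phase, period, hypothesis_set,
                             schedule = schedule)
  rois <- names(cohort[[1L]])
  subjects <- names(cohort) %||% paste0("sub", seq_along(cohort))
  fits <- list()
  for (r in rois) {
    fits[[r]] <- lapply(seq_along(cohort), function(s) {
      pm <- cohort[[s]][[r]]
      if (is.null(pm))
        stop("subject ", subjects[s], " lacks patterns for ROI ", r,
             call. = FALSE)
      rsm <- compute_rsm(pm, schedule)
      fit_subject(similarity_vector(rsm), tset, estimator = estimator,
                  subject_id = subjects[s], roi_name = r)
    })
  }
  rows <- list()
  model_id <- paste(phase, period, attr(tset, "hypothesis_set"), sep = "/")
  for (r in rois) {
    for (cf in names(tset)) {
      g <- group_test(fits[[r]], cf)
      rows[[length(rows) + 1L]] <- data.frame(
        model = model_id, roi = r, coefficient = cf, n = g$n,
        beta_mean = g$mean_beta, t = g$t, df = g$df, p = g$p, d = g$d,
        stringsAsFactors = FALSE)
    }
  }
  res <- fdr_correct(do.call(rbind, rows), q = q)
  res <- res[, c("model", "roi", "coefficient", "n", "beta_mean", "t",
                 "df", "p", "p_fdr", "d", "rejected")]
  structure(res, subject_fits = fits, q = q,
            class = c("group_result", "data.frame"))
}
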