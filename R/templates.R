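# Template regression matrices: hypothesis-shaped predictors with the same
# dimensions and trial ordering as the RSM. All entries in [0, 1], symmetric,
# zero diagonal (the diagonal is never used).

.blank_template <- function(tord, name) {
  n <- nrow(tord)
  m <- matrix(0, n, n)
  labs <- paste(abbreviate(tord$partner, 5), tord$cs, tord$cond_pos, sep = ".")
  dimnames(m) <- list(labs, labs)
  structure(m, name = name, trial_order = tord,
            class = c("rsa_template", "matrix", "array"))
}

#' Condition selectors for template construction
#'
#' Returns a predicate over the target-order rows, selecting trials by
#' partner and/or CS type.
#'
#' @param partner Optional `"intentional"` or `"unintentional"`.
#' @param cs Optional `"CSplus"` or `"CSminus"`.
#' @return Function mapping a target-order data.frame to a logical vector.
#' @export
cond_is <- function(partner = NULL, cs = NULL) {
  force(partner); force(cs)
  function(tord) {
    keep <- rep(TRUE, nrow(tord))
    if (!is.null(partner)) keep <- keep & tord$partner == partner
    if (!is.null(cs)) keep <- keep & tord$cs == cs
    keep
  }
}

#' Category-information template
#'
#' Entry (i, j) = 1 when trials i and j presented the same stimulus: the
#' same CS image for the chosen-option period, the same partner's face for
#' the early-anticipation period. Models the similarity of repeated
#' presentations of one stimulus, regardless of experimental manipulation.
#'
#' @param schedule A `trial_schedule`.
#' @param period `"chosen_option"` (4 CS images) or `"early_anticipation"`
#'   (2 faces).
#' @return An `rsa_template` matrix.
#' @export
category_template <- function(schedule,
                              period = c("chosen_option",
                                         "early_anticipation")) {
  period <- match.arg(period)
  tord <- target_order(schedule)
  key <- if (period == "chosen_option") {
    paste(tord$partner, tord$cs)
  } else {
    tord$partner
  }
  m <- .blank_template(tord, "category")
  same <- outer(key, key, "==") * 1
  diag(same) <- 0
  m[] <- same
  m
}

#' Membership (block) template
#'
#' Entry (i, j) = 1 when BOTH trials belong to the selected subset (e.g.
#' both intentional, or both CS+), 0 elsewhere. Mixed pairs are 0.
#'
#' @param schedule A `trial_schedule`.
#' @param selector A predicate from [cond_is()].
#' @param name Template name.
#' @return An `rsa_template` matrix.
#' @export
membership_template <- function(schedule, selector, name = "membership") {
  tord <- target_order(schedule)
  keep <- selector(tord)
  if (!any(keep)) stop("selector selects no target trials", call. = FALSE)
  m <- .blank_template(tord, name)
  v <- outer(keep, keep, "&") * 1
  diag(v) <- 0
  m[] <- v
  m
}

#' Learning / extinction ramp template
#'
#' Within the selected trials (ordered chronologically), pair (i, j) takes a
#' linear ramp value determined by the pair's position; entries outside the
#' selected set are 0. An increasing ramp rises from exactly 0 at the
#' earliest eligible pair to exactly 1 at the latest pair, modelling the
#' gradual build-up of a condition-specific representation over learning; a
#' decreasing ramp is its reflection (1 down to 0), modelling decay of a
#' learned representation during extinction.
#'
#' @param schedule A `trial_schedule`.
#' @param selector Predicate from [cond_is()] selecting the ramped trials
#'   (typically one condition's targets, or one partner's face trials).
#' @param start_trial Within-block ordinal at which the ramp starts; pairs
#'   whose earlier member precedes it are 0 (habituation exclusion). Default
#'   2 for threat-phase learning ramps; use 1 for extinction decay.
#' @param direction `"increase"` or `"decrease"`.
#' @param pair_rule How a pair's position is computed: `"min"` (default; a
#'   pair is only as learned as its earlier trial) or `"mean"`.
#' @param name Template name.
#' @return An `rsa_template` matrix.
#' @export
ramp_template <- function(schedule, selector, start_trial = 2L,
                          direction = c("increase", "decrease"),
                          pair_rule = c("min", "mean"),
                          name = "ramp") {
  direction <- match.arg(direction)
  pair_rule <- match.arg(pair_rule)
  tord <- target_order(schedule)
  keep <- which(selector(tord))
  if (!length(keep)) stop("selector selects no target trials", call. = FALSE)
  k <- length(keep)
  if (start_trial > k - 1L)
    stop("start_trial (", start_trial, ") beyond block length (", k, ")",
         call. = FALSE)
  # chronological position within the selected set
  pos <- integer(nrow(tord))
  pos[keep] <- rank(tord$trial[keep])

  m <- .blank_template(tord, name)
  pi <- pair_index(nrow(tord))
  ii <- pi$i; jj <- pi$j
  inset <- pos[ii] > 0 & pos[jj] > 0
  val <- numeric(length(ii))
  if (pair_rule == "min") {
    u <- pmin(pos[ii], pos[jj])
    lo <- start_trial; hi <- k - 1L
  } else {
    u <- (pos[ii] + pos[jj]) / 2
    lo <- start_trial + 0.5; hi <- k - 0.5
  }
  eligible <- inset & u >= lo
  f <- if (hi > lo) (u - lo) / (hi - lo) else rep(1, length(u))
  if (direction == "decrease") f <- 1 - f
  val[eligible] <- f[eligible]
  m[cbind(ii, jj)[eligible, , drop = FALSE]] <- val[eligible]
  m[cbind(jj, ii)[eligible, , drop = FALSE]] <- val[eligible]
  m
}

#' Assemble the template set for one phase, period and hypothesis set
#'
#' Builds the ordered, named set of template regression matrices used to
#' model the RSM of one phase x period:
#'
#' * `chosen_option` / threat `learning`: category, intentionality, CS, and
#'   increasing CS+intentional and CS+unintentional ramps (5 templates;
#'   ramps start at within-block trial 2, excluding the habituation trials
#'   where the CS-shock contingency was still unknown).
#' * `chosen_option` / extinction `extinction_decay`: the decreasing-ramp
#'   analogue (decay of the learned representation over all 7 trials).
#' * `chosen_option` / extinction `extinction_resistance`: the
#'   CS+intentional block stays constant at 1 while CS+unintentional decays.
#' * `chosen_option` / extinction `extinction_relearning`: threat-style
#'   increasing ramps (novel safety learning).
#' * `early_anticipation` (either phase): category (face), intentionality,
#'   and increasing intentional / unintentional face ramps (4 templates).
#'
#' @param phase `"threat"` or `"extinction"`.
#' @param period `"chosen_option"` or `"early_anticipation"`.
#' @param hypothesis_set One of `"learning"`, `"extinction_decay"`,
#'   `"extinction_resistance"`, `"extinction_relearning"`. Ignored for the
#'   early-anticipation period, which always uses the face set.
#' @param schedule A `trial_schedule`.
#' @param pair_rule Passed to [ramp_template()].
#' @param warn_r Warn when any two Fisher-transformed predictors correlate
#'   above this threshold in absolute value (default 0.95).
#' @return A `template_set`: named list of `rsa_template` matrices with
#'   attributes `phase`, `period`, `hypothesis_set`, `trial_order`.
#' @export
assemble_templates <- function(phase = c("threat", "extinction"),
                               period = c("chosen_option",
                                          "early_anticipation"),
                               hypothesis_set = c("learning",
                                                  "extinction_decay",
                                                  "extinction_resistance",
                                                  "extinction_relearning"),
                               schedule = build_schedule(phase),
                               pair_rule = c("min", "mean"),
                               warn_r = 0.95) {
  phase <- match.arg(phase)
  period <- match.arg(period)
  hypothesis_set <- match.arg(hypothesis_set)
  pair_rule <- match.arg(pair_rule)

  if (period == "early_anticipation") {
    hypothesis_set <- "learning"
    tpl <- list(
      category = category_template(schedule, "early_anticipation"),
      intentionality = membership_template(
        schedule, cond_is(partner = "intentional"), "intentionality"),
      intentional_face = ramp_template(
        schedule, cond_is(partner = "intentional"), start_trial = 2L,
        direction = "increase", pair_rule = pair_rule,
        name = "intentional_face"),
      unintentional_face = ramp_template(
        schedule, cond_is(partner = "unintentional"), start_trial = 2L,
        direction = "increase", pair_rule = pair_rule,
        name = "unintentional_face")
    )
  } else {
    if (phase == "threat" && hypothesis_set != "learning")
      stop("threat-phase chosen-option models use hypothesis_set = 'learning'",
           call. = FALSE)
    if (phase == "extinction" && hypothesis_set == "learning")
      stop("extinction chosen-option models use one of the extinction ",
           "hypothesis sets", call. = FALSE)
    base <- list(
      category = category_template(schedule, "chosen_option"),
      intentionality = membership_template(
        schedule, cond_is(partner = "intentional"), "intentionality"),
      cs = membership_template(schedule, cond_is(cs = "CSplus"), "cs")
    )
    sel_int <- cond_is(partner = "intentional", cs = "CSplus")
    sel_unint <- cond_is(partner = "unintentional", cs = "CSplus")
    extra <- switch(
      hypothesis_set,
      learning = list(
        csplus_intentional = ramp_template(schedule, sel_int, 2L, "increase",
                                           pair_rule, "csplus_intentional"),
        csplus_unintentional = ramp_template(schedule, sel_unint, 2L,
                                             "increase", pair_rule,
                                             "csplus_unintentional")),
      extinction_decay = list(
        csplus_intentional = ramp_template(schedule, sel_int, 1L, "decrease",
                                           pair_rule, "csplus_intentional"),
        csplus_unintentional = ramp_template(schedule, sel_unint, 1L,
                                             "decrease", pair_rule,
                                             "csplus_unintentional")),
      extinction_resistance = list(
        csplus_intentional = membership_template(schedule, sel_int,
                                                 "csplus_intentional"),
        csplus_unintentional = ramp_template(schedule, sel_unint, 1L,
                                             "decrease", pair_rule,
                                             "csplus_unintentional")),
      extinction_relearning = list(
        csplus_intentional = ramp_template(schedule, sel_int, 2L, "increase",
                                           pair_rule, "csplus_intentional"),
        csplus_unintentional = ramp_template(schedule, sel_unint, 2L,
                                             "increase", pair_rule,
                                             "csplus_unintentional"))
    )
    tpl <- c(base, extra)
  }

  tset <- structure(tpl, phase = phase, period = period,
                    hypothesis_set = hypothesis_set,
                    trial_order = target_order(schedule),
                    class = "template_set")
  P <- template_predictors(tset)
  cm <- suppressWarnings(stats::cor(P))
  cm[upper.tri(cm, diag = TRUE)] <- 0
  if (any(abs(cm) > warn_r, na.rm = TRUE)) {
    w <- which(abs(cm) > warn_r, arr.ind = TRUE)
    warning("highly correlated predictors: ",
            paste(sprintf("%s~%s (r=%.3f)", colnames(P)[w[, 2]],
                          rownames(cm)[w[, 1]], cm[w]), collapse = ", "),
            call. = FALSE)
  }
  tset
}

#' Predictor matrix of a template set
#'
#' Stacks each template's lower-triangle vector (shared pair ordering) into
#' the columns of the regression design, Fisher-transforming them exactly
#' like the data by default.
#'
#' @param tset A `template_set`.
#' @param transform Fisher-transform the template values (default TRUE, the
#'   treatment applied to the data; FALSE for sensitivity analysis).
#' @return Numeric matrix, n_pairs x n_templates, with template names as
#'   column names.
#' @export
template_predictors <- function(tset, transform = TRUE) {
  stopifnot(inherits(tset, "template_set"))
  cols <- lapply(tset, function(m) {
    v <- lower_triangle(m)
    if (transform) fisher_z(v) else as.numeric(v)
  })
  P <- do.call(cbind, cols)
  colnames(P) <- names(tset)
  P
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("<template_set> phase=%s period=%s set=%s (%d templates: %s)\n",
              attr(x, "phase"), attr(x, "period"), attr(x, "hypothesis_set"),
              length(x), paste(names(x), collapse = ", ")))
  invisible(x)
}
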