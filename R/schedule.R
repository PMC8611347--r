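#' @keywords internal
"_PACKAGE"

# Within-trial period layout (seconds from trial onset) and durations.
.PERIODS <- data.frame(
  period   = c("early_anticipation", "choice", "chosen_option"),
  offset_s = c(0, 3, 4),
  dur_s    = c(3, 1, 3),
  stringsAsFactors = FALSE
)

.TRIAL_DUR_S <- 7
.ITI_S <- 13
.SHOCK_DELAY_S <- 2.8

#' The four experimental conditions
#'
#' The paradigm crosses two interaction partners (one believed to deliver
#' shocks intentionally, one unintentionally) with two conditioned stimuli
#' (CS+, sometimes followed by shock; CS-, never followed by shock).
#'
#' @return A data.frame with columns `partner` and `cs`, one row per
#'   condition, in the fixed condition-grouped order used for RSM layout.
#' @export
conditions <- function() {
  data.frame(
    partner = rep(c("intentional", "unintentional"), each = 2),
    cs      = rep(c("CSplus", "CSminus"), times = 2),
    stringsAsFactors = FALSE
  )
}

.condition_key <- function(partner, cs) paste(partner, cs, sep = "/")

#' Schedule configuration
#'
#' Defaults reproduce the study design: per partner 26 trials (13 CS+,
#' 13 CS-), 6 of the 13 CS+ trials reinforced (46%), and 7 target trials per
#' condition. Targets are laid out in 7 rounds of 4 (one per condition, fixed
#' order) separated by filler blocks of 4 (one per condition), which makes
#' consecutive same-condition targets equidistant. All reinforced trials are
#' CS+ fillers. The layout requires `cs_per_partner = 2 * targets_per_condition
#' - 1` so that the filler blocks fill the gaps exactly.
#'
#' @param targets_per_condition Number of analysis-eligible (target) trials
#'   per condition. Default 7.
#' @param cs_per_partner Number of CS+ trials (and, equally, CS- trials) per
#'   partner. Default 13.
#' @param reinforced_per_partner Number of reinforced CS+ trials per partner
#'   (all of them fillers). Default 6.
#' @param trial_dur_s,iti_s Trial duration and fixed inter-trial interval in
#'   seconds. Defaults 7 and 13 (consecutive onsets 20 s apart).
#' @param stimulus_map Named character vector mapping each condition
#'   (`"partner/cs"`) to a CS image identifier, plus each partner to a face
#'   identifier. Defaults to a fixed counterbalancing assignment.
#' @return An object of class `schedule_config`.
#' @export
schedule_config <- function(targets_per_condition = 7L,
                            cs_per_partner = 13L,
                            reinforced_per_partner = 6L,
                            trial_dur_s = .TRIAL_DUR_S,
                            iti_s = .ITI_S,
                            stimulus_map = NULL) {
  if (is.null(stimulus_map)) {
    cond <- conditions()
    stimulus_map <- c(
      stats::setNames(paste0("cs_img_", seq_len(nrow(cond))),
                      .condition_key(cond$partner, cond$cs)),
      intentional = "face_intentional",
      unintentional = "face_unintentional"
    )
  }
  cfg <- structure(
    list(
      targets_per_condition = as.integer(targets_per_condition),
      cs_per_partner = as.integer(cs_per_partner),
      reinforced_per_partner = as.integer(reinforced_per_partner),
      trial_dur_s = trial_dur_s,
      iti_s = iti_s,
      stimulus_map = stimulus_map
    ),
    class = "schedule_config"
  )
  validate_schedule_config(cfg)
  cfg
}

validate_schedule_config <- function(cfg) {
  k <- cfg$targets_per_condition
  ncs <- cfg$cs_per_partner
  if (k < 2L) stop("targets_per_condition must be at least 2", call. = FALSE)
  if (ncs != 2L * k - 1L) {
    stop("inconsistent counts: cs_per_partner (", ncs,
         ") must equal 2 * targets_per_condition - 1 (", 2L * k - 1L,
         ") for the equidistant target/filler block layout", call. = FALSE)
  }
  n_cs_fillers <- ncs - k
  if (cfg$reinforced_per_partner > n_cs_fillers) {
    stop("reinforced count per partner (", cfg$reinforced_per_partner,
         ") exceeds available CS+ filler trials (", n_cs_fillers,
         "); targets are never reinforced", call. = FALSE)
  }
  if (cfg$reinforced_per_partner < 0L)
    stop("reinforced_per_partner must be non-negative", call. = FALSE)
  invisible(cfg)
}

# Run expr with a transient RNG state so generators are seed-deterministic
# without disturbing the caller's stream.
with_local_seed <- function(seed, expr) {
  # force the seed before snapshotting the caller's RNG state, so a seed
  # expression that itself draws from the RNG still advances the stream
  seed <- as.integer(seed)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Build a trial schedule for one experimental phase
#'
#' Constructs the full ordered trial list for the threat-learning or
#' extinction phase: alternating blocks of 4 target trials (one per
#' condition, fixed order across participants) and 4 filler trials (one per
#' condition, order randomized by `seed`). All reinforced trials are CS+
#' fillers in the threat phase; the extinction phase has no reinforcement.
#'
#' @param phase `"threat"` or `"extinction"`.
#' @param config A [schedule_config()].
#' @param seed Integer seed controlling filler order within filler blocks
#'   only; the target order is fixed.
#' @return A data.frame of class `trial_schedule` with one row per trial and
#'   columns `trial` (1-based), `onset_s`, `partner`, `cs`, `stimulus_id`,
#'   `face_id`, `role`, `reinforced`, `shock_onset_s`, plus attributes
#'   `phase`, `config` and `target_order`.
#' @export
build_schedule <- function(phase = c("threat", "extinction"),
                           config = schedule_config(),
                           seed = 0L) {
  phase <- match.arg(phase)
  validate_schedule_config(config)
  cond <- conditions()
  k <- config$targets_per_condition
  n_fill_rounds <- k - 1L

  # one target round = one target per condition, fixed order
  target_rounds <- lapply(seq_len(k), function(r) {
    data.frame(partner = cond$partner, cs = cond$cs, role = "target",
               stringsAsFactors = FALSE)
  })
  filler_rounds <- with_local_seed(seed, {
    lapply(seq_len(n_fill_rounds), function(r) {
      ord <- sample.int(nrow(cond))
      data.frame(partner = cond$partner[ord], cs = cond$cs[ord],
                 role = "filler", stringsAsFactors = FALSE)
    })
  })

  rounds <- vector("list", k + n_fill_rounds)
  rounds[seq(1L, by = 2L, length.out = k)] <- target_rounds
  if (n_fill_rounds > 0L)
    rounds[seq(2L, by = 2L, length.out = n_fill_rounds)] <- filler_rounds
  trials <- do.call(rbind, rounds)
  n <- nrow(trials)
  trials$trial <- seq_len(n)
  trials$onset_s <- (trials$trial - 1L) * (config$trial_dur_s + config$iti_s)

  # reinforcement: CS+ fillers only, threat phase only
  trials$reinforced <- FALSE
  if (phase == "threat") {
    for (p in unique(cond$partner)) {
      idx <- which(trials$partner == p & trials$cs == "CSplus" &
                     trials$role == "filler")
      take <- idx[seq_len(min(config$reinforced_per_partner, length(idx)))]
      trials$reinforced[take] <- TRUE
    }
  }
  chosen_onset <- trials$onset_s + .PERIODS$offset_s[.PERIODS$period == "chosen_option"]
  trials$shock_onset_s <- ifelse(trials$reinforced,
                                 chosen_onset + .SHOCK_DELAY_S, NA_real_)

  smap <- config$stimulus_map
  trials$stimulus_id <- unname(smap[.condition_key(trials$partner, trials$cs)])
  trials$face_id <- unname(smap[trials$partner])

  trials <- trials[, c("trial", "onset_s", "partner", "cs", "stimulus_id",
                       "face_id", "role", "reinforced", "shock_onset_s")]
  rownames(trials) <- NULL

  sched <- structure(trials,
                     phase = phase,
                     config = config,
                     class = c("trial_schedule", "data.frame"))
  attr(sched, "target_order") <- .make_target_order(sched)
  validate_schedule(sched)
  sched
}

# Condition-grouped target ordering used by RSMs and templates: conditions in
# the fixed conditions() order, trials chronological within condition.
.make_target_order <- function(sched) {
  cond <- conditions()
  rows <- lapply(seq_len(nrow(cond)), function(i) {
    idx <- which(sched$role == "target" &
                   sched$partner == cond$partner[i] &
                   sched$cs == cond$cs[i])
    idx <- idx[order(sched$onset_s[idx])]
    data.frame(trial = sched$trial[idx],
               partner = cond$partner[i], cs = cond$cs[i],
               cond_pos = seq_along(idx), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Condition-grouped target-trial ordering of a schedule
#'
#' @param schedule A `trial_schedule`.
#' @return Data.frame with columns `trial`, `partner`, `cs`, `cond_pos`
#'   (chronological position 1..k within the condition), in the row/column
#'   order used by RSMs and templates.
#' @export
target_order <- function(schedule) {
  stopifnot(inherits(schedule, "trial_schedule"))
  attr(schedule, "target_order")
}

#' @export
print.trial_schedule <- function(x, ...) {
  cat(sprintf("<trial_schedule> phase=%s, %d trials (%d targets, %d reinforced)\n",
              attr(x, "phase"), nrow(x), sum(x$role == "target"),
              sum(x$reinforced)))
  NextMethod()
}

validate_schedule <- function(sched) {
  phase <- attr(sched, "phase")
  cfg <- attr(sched, "config")
  if (any(sched$reinforced & sched$cs != "CSplus"))
    stop("reinforced trial with CS- stimulus", call. = FALSE)
  if (any(sched$reinforced & sched$role == "target"))
    stop("reinforced target trial: targets must be non-reinforced", call. = FALSE)
  if (phase == "extinction" && any(sched$reinforced))
    stop("extinction phase must have no reinforced trials", call. = FALSE)
  d <- diff(sched$onset_s)
  if (length(d) && any(abs(d - (cfg$trial_dur_s + cfg$iti_s)) > 1e-9))
    stop("trial onsets are not equally spaced", call. = FALSE)
  tord <- attr(sched, "target_order")
  if (nrow(tord) != 4L * cfg$targets_per_condition)
    stop("wrong number of target trials", call. = FALSE)
  invisible(sched)
}

#' Per-trial event table for one within-trial period
#'
#' @param schedule A `trial_schedule`.
#' @param period One of `"early_anticipation"` (3 s), `"choice"` (1 s),
#'   `"chosen_option"` (3 s).
#' @return Data.frame with one event per trial: `onset_s`, `duration_s`,
#'   `trial`, `partner`, `cs`, `role`, `reinforced`.
#' @export
event_table <- function(schedule,
                        period = c("early_anticipation", "choice",
                                   "chosen_option")) {
  stopifnot(inherits(schedule, "trial_schedule"))
  period <- match.arg(period)
  p <- .PERIODS[.PERIODS$period == period, ]
  data.frame(
    onset_s = schedule$onset_s + p$offset_s,
    duration_s = p$dur_s,
    trial = schedule$trial,
    partner = schedule$partner,
    cs = schedule$cs,
    role = schedule$role,
    reinforced = schedule$reinforced,
    stringsAsFactors = FALSE
  )
}

#' Shock (US) events of a schedule
#'
#' Shocks are delivered 2.8 s after chosen-option onset on reinforced trials
#' and last 200 ms.
#'
#' @param schedule A `trial_schedule`.
#' @return Data.frame with `onset_s`, `duration_s`, `trial` (possibly empty).
#' @export
us_events <- function(schedule) {
  stopifnot(inherits(schedule, "trial_schedule"))
  idx <- which(schedule$reinforced)
  data.frame(onset_s = schedule$shock_onset_s[idx],
             duration_s = rep(0.2, length(idx)),
             trial = schedule$trial[idx])
}

#' Write / read a schedule as a BIDS-events-like TSV
#'
#' @param schedule A `trial_schedule`.
#' @param path Output file path.
#' @return `write_events` returns `path` invisibly; `read_events` returns a
#'   `trial_schedule` (target ordering reconstructed from the table).
#' @export
write_events <- function(schedule, path) {
  stopifnot(inherits(schedule, "trial_schedule"))
  df <- as.data.frame(schedule)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @param phase Phase label of the events being read.
#' @param config The `schedule_config` the events were generated under.
#' @export
read_events <- function(path, phase = c("threat", "extinction"),
                        config = schedule_config()) {
  phase <- match.arg(phase)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("trial", "onset_s", "partner", "cs", "role", "reinforced")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("events file lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  sched <- structure(df, phase = phase, config = config,
                     class = c("trial_schedule", "data.frame"))
  attr(sched, "target_order") <- .make_target_order(sched)
  validate_schedule(sched)
  sched
}
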