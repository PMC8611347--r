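# ROI registry, run configuration, and delimited-table IO. In synthetic
# mode ROI "masks" are voxel-count declarations; geometric NIfTI masks are
# an ingestion concern outside this package's scope.

#' Default ROI registry
#'
#' Threat-learning regions (ACC, amygdala, insula, hippocampus, vmPFC) and
#' mentalizing regions (left/right TPJ, dmPFC, anterior/posterior STS), plus
#' IFG and ITG; the FFA is added only for the early-anticipation period
#' (face viewing). The chosen-option registry has 12 regions, giving the
#' 60-test family with 5 templates.
#'
#' @param period `"chosen_option"` or `"early_anticipation"`.
#' @return Character vector of ROI names.
#' @export
roi_registry <- function(period = c("chosen_option", "early_anticipation")) {
  period <- match.arg(period)
  base <- c("ACC", "amygdala", "insula", "hippocampus", "vmPFC",
            "lTPJ", "rTPJ", "dmPFC", "arSTS", "prSTS", "IFG", "ITG")
  if (period == "early_anticipation") c(base, "FFA") else base
}

#' Spherical mask definitions for STS regions
#'
#' The two STS regions are defined as bilateral 5 mm spheres at published
#' coordinates (MNI); all other registry regions come from an anatomical
#' atlas in ingestion mode.
#'
#' @return Data.frame with `roi`, `hemisphere`, `x`, `y`, `z`, `radius_mm`.
#' @export
roi_spheres <- function() {
  data.frame(
    roi = c("arSTS", "arSTS", "prSTS", "prSTS"),
    hemisphere = c("left", "right", "left", "right"),
    x = c(-46, 50, 22, 46),
    y = c(-6, -4, 44, -40),
    z = c(-26, -34, 36, -2),
    radius_mm = 5,
    stringsAsFactors = FALSE
  )
}

#' Load a run configuration from YAML
#'
#' Missing keys fall back to the defaults of the study design: threat
#' phase, chosen-option period, learning hypothesis set, OLS estimator,
#' q = 0.05, the default ROI registry, seed 0.
#'
#' @param path Optional YAML file path; NULL returns the defaults.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(path = NULL) {
  cfg <- list(phase = "threat", period = "chosen_option",
              hypothesis_set = "learning", estimator = "ols", q = 0.05,
              seed = 0L, n_subjects = 26L, n_voxels = 200L, snr = 1,
              roi_registry = NULL)
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg[names(user)] <- user
  }
  if (is.null(cfg$roi_registry)) cfg$roi_registry <- roi_registry(cfg$period)
  if (cfg$q <= 0 || cfg$q >= 1) stop("q must be in (0, 1)", call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Write / read a pattern matrix as a TSV with a JSON sidecar
#'
#' @param pm A [pattern_matrix()].
#' @param path TSV path; metadata goes to `<path>.json`.
#' @return `write_pattern_matrix` returns `path` invisibly;
#'   `read_pattern_matrix` returns a [pattern_matrix()].
#' @export
write_pattern_matrix <- function(pm, path) {
  stopifnot(inherits(pm, "pattern_matrix"))
  utils::write.table(unclass(pm), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  meta <- list(trials = attr(pm, "trials"), roi_name = attr(pm, "roi_name"),
               subject_id = attr(pm, "subject_id"),
               period = attr(pm, "period"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_pattern_matrix
#' @export
read_pattern_matrix <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side))
    stop("missing sidecar metadata file: ", side, call. = FALSE)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(m) <- NULL
  if (nrow(m) != length(meta$trials))
    stop("pattern table has ", nrow(m), " rows but sidecar lists ",
         length(meta$trials), " trials", call. = FALSE)
  pattern_matrix(m, trials = meta$trials, roi_name = meta$roi_name,
                 subject_id = meta$subject_id, period = meta$period)
}

#' Write / read an RSM as a square delimited table
#'
#' The header row carries the condition-grouped trial labels; subject/ROI
#' metadata goes to a JSON sidecar.
#'
#' @param rsm An `rsm`.
#' @param path TSV path.
#' @export
write_rsm <- function(rsm, path) {
  stopifnot(inherits(rsm, "rsm"))
  utils::write.table(unclass(rsm), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  tord <- attr(rsm, "trial_order")
  meta <- list(trial_order = tord, roi_name = attr(rsm, "roi_name"),
               subject_id = attr(rsm, "subject_id"),
               phase = attr(rsm, "phase"), period = attr(rsm, "period"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_rsm
#' @export
read_rsm <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side))
    stop("missing sidecar metadata file: ", side, call. = FALSE)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   check.names = FALSE))
  rownames(m) <- colnames(m)
  structure(m, trial_order = as.data.frame(meta$trial_order),
            roi_name = meta$roi_name, subject_id = meta$subject_id,
            phase = meta$phase, period = meta$period,
            class = c("rsm", "matrix", "array"))
}

#' Write / read a pupil trace as a two-column text table
#'
#' Missing samples are written as `NaN`.
#'
#' @param trace A `pupil_trace`.
#' @param path Output path.
#' @export
write_pupil_trace <- function(trace, path) {
  stopifnot(inherits(trace, "pupil_trace"))
  df <- data.frame(time_s = trace$time_s,
                   diameter = ifelse(is.na(trace$diameter), NaN,
                                     trace$diameter))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pupil_trace
#' @param subject_id Subject label for the trace being read.
#' @export
read_pupil_trace <- function(path, subject_id = "sub") {
  df <- utils::read.delim(path)
  if (!all(c("time_s", "diameter") %in% names(df)))
    stop("pupil trace file needs columns time_s and diameter", call. = FALSE)
  dt <- diff(df$time_s)
  if (any(dt <= 0)) stop("time_s must be strictly increasing", call. = FALSE)
  if (max(dt) - min(dt) > 1e-6)
    stop("sampling interval is not constant", call. = FALSE)
  df$diameter[is.nan(df$diameter)] <- NA_real_
  structure(df, sampling_hz = 1 / stats::median(dt), subject_id = subject_id,
            class = c("pupil_trace", "data.frame"))
}

#' Write a results table as TSV
#'
#' @param table A data.frame (e.g. a `group_result`).
#' @param path Output path.
#' @export
write_results <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Heatmap of an RSM or template matrix
#'
#' @param m An `rsm` or `rsa_template`.
#' @param main Plot title.
#' @param zlim Colour range.
#' @export
plot_rsm <- function(m, main = NULL, zlim = NULL) {
  x <- unclass(m)
  n <- nrow(x)
  if (is.null(zlim)) zlim <- range(x)
  if (is.null(main))
    main <- attr(m, "name") %||% paste(attr(m, "roi_name"),
                                       attr(m, "period"))
  pal <- grDevices::hcl.colors(64, "Blue-Red 3")
  graphics::image(seq_len(n), seq_len(n), t(x[n:1, ]), zlim = zlim,
                  col = pal, axes = FALSE, xlab = "", ylab = "",
                  main = main)
  tord <- attr(m, "trial_order")
  if (!is.null(tord)) {
    brk <- which(diff(as.integer(factor(paste(tord$partner, tord$cs)))) != 0)
    graphics::abline(v = brk + 0.5, h = n - brk + 0.5, col = "grey30")
  }
  invisible(m)
}

#' Gallery of a template set's matrices
#'
#' @param tset A `template_set`.
#' @export
plot_template_set <- function(tset) {
  stopifnot(inherits(tset, "template_set"))
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(tset)),
                       mar = c(1, 1, 2, 1))
  on.exit(graphics::par(old))
  for (nm in names(tset)) plot_rsm(tset[[nm]], main = nm, zlim = c(0, 1))
  invisible(tset)
}
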