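# Shared fixtures, built in code. Schedules and template sets are
# deterministic, so build them once per test run.

the_sched <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_schedule("threat", seed = 1L)
    cache
  }
})

the_ext_sched <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_schedule("extinction", seed = 1L)
    cache
  }
})

the_tset <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- assemble_templates("threat", "chosen_option", "learning",
                                   schedule = the_sched())
    cache
  }
})

# Small synthetic cohort: subjects x ROIs of pattern matrices.
make_cohort <- function(n_subjects, rois, spec, schedule = the_sched(),
                        tset = the_tset(), seed = 100L) {
  cohort <- lapply(seq_len(n_subjects), function(s) {
    pats <- lapply(seq_along(rois), function(r) {
      generate_patterns(schedule, spec, tset = tset,
                        seed = seed + 97L * s + r,
                        roi_name = rois[r],
                        subject_id = sprintf("sub%02d", s))
    })
    stats::setNames(pats, rois)
  })
  stats::setNames(cohort, sprintf("sub%02d", seq_len(n_subjects)))
}

# Independent brute-force Pearson correlation (naive double loop).
naive_pearson_rsm <- function(X) {
  n <- nrow(X)
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      xi <- X[i, ]; xj <- X[j, ]
      out[i, j] <- sum((xi - mean(xi)) * (xj - mean(xj))) /
        sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
    }
  }
  out
}

# Independent BH step-up oracle by exhaustive rule application.
bh_oracle <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  k <- 0L
  for (i in seq_len(m)) if (p[ord[i]] <= i / m * q) k <- i
  rejected <- logical(m)
  if (k > 0L) rejected[ord[seq_len(k)]] <- TRUE
  # adjusted p: cummin from the top of m*p_(i)/i
  adj_sorted <- rev(cummin(rev(p[ord] * m / seq_len(m))))
  adj <- numeric(m)
  adj[ord] <- pmin(adj_sorted, 1)
  list(rejected = rejected, p_adj = adj)
}

# Independent 2x2 within-subject ANOVA via per-subject contrasts (for
# one-df effects, F is the squared paired t of the contrast).
rm_anova_oracle <- function(cells) {
  key <- paste(cells$partner, cells$cs)
  wide <- stats::reshape(data.frame(subject_id = cells$subject_id,
                                    key = key, value = cells$value),
                         idvar = "subject_id", timevar = "key",
                         direction = "wide")
  y <- as.matrix(wide[, -1L])
  colnames(y) <- sub("^value\\.", "", colnames(y))
  ip <- y[, "intentional CSplus"]; im <- y[, "intentional CSminus"]
  up <- y[, "unintentional CSplus"]; um <- y[, "unintentional CSminus"]
  n <- nrow(y)
  fstat <- function(contrast) {
    tval <- mean(contrast) / (stats::sd(contrast) / sqrt(n))
    f <- tval^2
    list(F = f, p = stats::pf(f, 1, n - 1, lower.tail = FALSE),
         peta = f / (f + (n - 1)))
  }
  list(cs = fstat((ip + up) / 2 - (im + um) / 2),
       intentionality = fstat((ip + im) / 2 - (up + um) / 2),
       interaction = fstat((ip - im) - (up - um)))
}
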