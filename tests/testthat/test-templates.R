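test_that("template sets have the documented composition", {
  tset <- the_tset()
  expect_length(tset, 5L)
  expect_named(tset, c("category", "intentionality", "cs",
                       "csplus_intentional", "csplus_unintentional"))
  ea <- assemble_templates("threat", "early_anticipation",
                           schedule = the_sched())
  expect_length(ea, 4L)
  expect_named(ea, c("category", "intentionality", "intentional_face",
                     "unintentional_face"))
  # extinction sets exist and are 5 templates each
  for (hs in c("extinction_decay", "extinction_resistance",
               "extinction_relearning")) {
    ts <- assemble_templates("extinction", "chosen_option", hs,
                             schedule = the_ext_sched())
    expect_length(ts, 5L)
  }
  expect_error(assemble_templates("threat", "chosen_option",
                                  "extinction_decay",
                                  schedule = the_sched()),
               "learning")
  expect_error(assemble_templates("extinction", "chosen_option", "learning",
                                  schedule = the_ext_sched()),
               "extinction")
})

test_that("binary template one-counts match the combinatorial oracles", {
  tset <- the_tset()
  expect_equal(sum(lower_triangle(tset$category) == 1), 4 * choose(7, 2))   # 84
  expect_equal(sum(lower_triangle(tset$intentionality) == 1), choose(14, 2)) # 91
  expect_equal(sum(lower_triangle(tset$cs) == 1), choose(14, 2))             # 91
  ea <- assemble_templates("threat", "early_anticipation",
                           schedule = the_sched())
  expect_equal(sum(lower_triangle(ea$category) == 1), 2 * choose(14, 2))    # 182
  # mixed-condition pairs are zero
  to <- target_order(the_sched())
  i <- which(to$partner == "intentional")[1]
  j <- which(to$partner == "unintentional")[1]
  expect_equal(tset$intentionality[i, j], 0)
  # all-trials selector fills every off-diagonal entry
  allm <- membership_template(the_sched(), cond_is(), "all")
  expect_true(all(lower_triangle(allm) == 1))
  expect_error(membership_template(the_sched(),
                                   function(tord) rep(FALSE, nrow(tord))),
               "no target trials")
})

test_that("every template is symmetric, zero-diagonal, and within [0, 1]", {
  combos <- list(
    the_tset(),
    assemble_templates("threat", "early_anticipation",
                       schedule = the_sched()),
    assemble_templates("extinction", "chosen_option", "extinction_decay",
                       schedule = the_ext_sched()),
    assemble_templates("extinction", "chosen_option",
                       "extinction_resistance",
                       schedule = the_ext_sched()),
    assemble_templates("extinction", "chosen_option",
                       "extinction_relearning",
                       schedule = the_ext_sched())
  )
  for (tset in combos) {
    for (nm in names(tset)) {
      m <- unclass(tset[[nm]])
      expect_equal(m, t(m))
      expect_equal(unname(diag(m)), rep(0, nrow(m)))
      expect_true(all(m >= 0 & m <= 1))
    }
    # no two templates in a set are identical
    for (a in seq_along(tset)) for (b in seq_len(a - 1L))
      expect_gt(max(abs(unclass(tset[[a]]) - unclass(tset[[b]]))), 0)
  }
})

test_that("ramps hit their endpoints exactly and reflect correctly", {
  s <- the_sched()
  sel <- cond_is(partner = "intentional", cs = "CSplus")
  inc <- ramp_template(s, sel, start_trial = 2, direction = "increase")
  to <- target_order(s)
  blk <- which(sel(to))
  pos <- rank(to$trial[blk])
  ord <- blk[order(pos)]
  # earliest eligible pair (positions 2,3) is exactly 0; latest (6,7) is 1
  expect_equal(inc[ord[3], ord[2]], 0)
  expect_equal(inc[ord[7], ord[6]], 1)
  # pairs involving a pre-start trial are 0
  expect_equal(inc[ord[5], ord[1]], 0)
  # pair value depends on the earlier trial of the pair (min rule)
  expect_equal(inc[ord[7], ord[4]], inc[ord[5], ord[4]])
  dec <- ramp_template(s, sel, start_trial = 1, direction = "decrease")
  inc1 <- ramp_template(s, sel, start_trial = 1, direction = "increase")
  within <- outer(seq_len(28) %in% blk, seq_len(28) %in% blk, "&")
  diag(within) <- FALSE
  expect_equal(unclass(dec)[within], 1 - unclass(inc1)[within])
  expect_equal(dec[ord[2], ord[1]], 1)
  expect_equal(dec[ord[7], ord[6]], 0)
  # mean pair-position rule also hits the endpoints
  incm <- ramp_template(s, sel, 2, "increase", pair_rule = "mean")
  expect_equal(incm[ord[3], ord[2]], 0)
  expect_equal(incm[ord[7], ord[6]], 1)
  expect_error(ramp_template(s, sel, start_trial = 7), "beyond block length")
})

test_that("templates and similarity vectors share one pair ordering", {
  s <- the_sched()
  tset <- the_tset()
  P <- template_predictors(tset, transform = FALSE)
  pm <- generate_patterns(s, effect_spec(n_voxels = 30), seed = 8)
  v <- similarity_vector(compute_rsm(pm, s))
  expect_equal(nrow(P), length(v))
  pi_t <- attr(lower_triangle(tset$category), "pair_index")
  pi_v <- attr(v, "pair_index")
  expect_identical(pi_t, pi_v)
})

test_that("template predictors are Fisher-transformed like the data", {
  tset <- the_tset()
  P <- template_predictors(tset)
  raw <- template_predictors(tset, transform = FALSE)
  expect_equal(max(P), 0.999)         # entries of 1 clamp to 0.999
  expect_equal(P[raw == 0], rep(0, sum(raw == 0)))
  mid <- raw > 0 & raw < 1
  expect_equal(P[mid], atanh(raw[mid]))
})

test_that("assemble warns on excessive predictor correlation only when asked", {
  expect_silent(assemble_templates("threat", "chosen_option", "learning",
                                   schedule = the_sched()))
  expect_warning(assemble_templates("threat", "chosen_option", "learning",
                                    schedule = the_sched(), warn_r = 0.2),
                 "correlated predictors")
})
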