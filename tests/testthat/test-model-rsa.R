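test_that("fit_subject exactly recovers a noiseless linear construction", {
  tset <- the_tset()
  P <- template_predictors(tset)
  sim <- 0.3 + 0.5 * P[, "cs"]
  fit <- fit_subject(sim, tset)
  expect_equal(fit$beta0, 0.3, tolerance = 1e-10)
  expect_equal(unname(fit$betas[["cs"]]), 0.5, tolerance = 1e-10)
  others <- setdiff(names(fit$betas), "cs")
  expect_equal(unname(fit$betas[others]), rep(0, length(others)),
               tolerance = 1e-10)
})

test_that("fit_subject equals the normal-equation oracle on random data", {
  tset <- the_tset()
  P <- template_predictors(tset)
  X <- cbind(1, P)
  set.seed(77)
  for (k in 1:10) {
    y <- rnorm(nrow(P))
    fit <- fit_subject(y, tset)
    oracle <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(unname(c(fit$beta0, fit$betas)), as.numeric(oracle),
                 tolerance = 1e-10)
    # t-statistics match the textbook OLS formula
    res <- y - X %*% oracle
    sig2 <- sum(res^2) / (nrow(X) - ncol(X))
    se <- sqrt(sig2 * diag(solve(t(X) %*% X)))
    expect_equal(unname(fit$t_stats),
                 unname((as.numeric(oracle) / se)[-1]), tolerance = 1e-8)
  }
})

test_that("noise orthogonal to the design leaves coefficients unchanged", {
  tset <- the_tset()
  P <- template_predictors(tset)
  X <- cbind(1, P)
  set.seed(42)
  y <- 0.2 + P %*% runif(ncol(P), -0.3, 0.3) + rnorm(nrow(P), sd = 0.1)
  noise <- rnorm(nrow(P))
  orth <- noise - X %*% solve(t(X) %*% X, t(X) %*% noise)
  f1 <- fit_subject(as.numeric(y), tset)
  f2 <- fit_subject(as.numeric(y + orth), tset)
  expect_equal(f1$betas, f2$betas, tolerance = 1e-10)
  expect_equal(f1$beta0, f2$beta0, tolerance = 1e-10)
})

test_that("fit_subject rejects bad input and names collinear templates", {
  tset <- the_tset()
  expect_error(fit_subject(rnorm(100), tset), "does not match")
  dup <- tset
  dup$cs_copy <- dup$cs
  attr(dup, "class") <- "template_set"
  expect_error(fit_subject(rnorm(378), dup), "collinear.*cs_copy")
})

test_that("the robust estimator agrees with OLS on clean data", {
  tset <- the_tset()
  P <- template_predictors(tset)
  sim <- as.numeric(0.1 + 0.4 * P[, "cs"] + rnorm(nrow(P), sd = 0.01))
  f_ols <- fit_subject(sim, tset, estimator = "ols")
  f_rob <- fit_subject(sim, tset, estimator = "robust")
  expect_equal(f_rob$betas, f_ols$betas, tolerance = 0.01)
})

test_that("group_test is a one-sample t-test of subject betas", {
  mk <- function(b) structure(list(subject_id = "s", roi_name = "r",
                                   beta0 = 0, betas = c(cs = b),
                                   t_stats = c(cs = 0)),
                              class = "subject_fit")
  fits <- lapply(c(-0.2, 0.2, -0.1, 0.1), mk)
  g <- group_test(fits, "cs")
  expect_equal(g$t, 0, tolerance = 1e-12)
  expect_equal(g$p, 1, tolerance = 1e-12)
  b <- c(0.1, 0.3, 0.2, 0.25, 0.15)
  g2 <- group_test(lapply(b, mk), "cs")
  expect_equal(g2$t, mean(b) / (sd(b) / sqrt(length(b))), tolerance = 1e-12)
  expect_equal(g2$d, mean(b) / sd(b), tolerance = 1e-12)
  expect_error(group_test(list(mk(1)), "cs"), "at least 2")
  expect_error(group_test(lapply(c(1, 1, 1), mk), "cs"), "zero variance")
})

test_that("fdr_correct matches the step-up oracle", {
  set.seed(123)
  for (k in 1:50) {
    p <- runif(sample(5:80, 1))^sample(1:3, 1)
    res <- fdr_correct(data.frame(p = p), q = 0.05)
    oracle <- bh_oracle(p, 0.05)
    expect_equal(res$p_fdr, oracle$p_adj, tolerance = 1e-12)
    expect_equal(res$rejected, oracle$rejected)
    expect_true(all(res$p_fdr >= res$p))
  }
  allp <- data.frame(p = rep(0.01, 6))
  expect_true(all(fdr_correct(allp, 0.05)$rejected))
  expect_error(fdr_correct(data.frame(p = numeric(0))), "empty")
  ex <- fdr_correct(data.frame(p = c(0.01, 0.02, 0.04, 0.05)), 0.05)
  expect_equal(ex$p_fdr, bh_oracle(c(0.01, 0.02, 0.04, 0.05), 0.05)$p_adj)
})

test_that("run_model recovers a planted effect in the right ROI only", {
  s <- the_sched()
  tset <- the_tset()
  rois <- c("insula", "ACC", "vmPFC")
  cohort <- lapply(1:8, function(sj) {
    pats <- lapply(rois, function(r) {
      spec <- if (r == "insula")
        effect_spec(planted_beta = c(cs = 0.3), snr = 2, n_voxels = 150)
      else effect_spec(snr = 2, n_voxels = 150)
      generate_patterns(s, spec, tset = tset, seed = 1000 + 31 * sj +
                          match(r, rois),
                        roi_name = r, subject_id = paste0("s", sj))
    })
    stats::setNames(pats, rois)
  })
  res <- run_model(cohort, s)
  expect_s3_class(res, "group_result")
  expect_equal(nrow(res), length(rois) * 5L)
  hit <- res[res$roi == "insula" & res$coefficient == "cs", ]
  expect_true(hit$rejected)
  expect_gt(hit$beta_mean, 0)
  # determinism: identical cohort gives identical tables
  res2 <- run_model(cohort, s)
  expect_equal(as.data.frame(res), as.data.frame(res2))
})
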