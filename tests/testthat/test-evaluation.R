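test_that("leave-one-out reproduces noiseless reference trajectories exactly", {
  for (pars in list(c(0.6, 5, 3), c(0.3, 2.2, 1.4), c(1, 4, 2))) {
    s <- make_ref_series(pars[1], pars[2], pars[3], F0 = 0.25, U0 = 0.85)
    loo <- loo_evaluate(s)
    expect_equal(loo$left_out_index, 2:6)
    expect_true(all(loo$ok))
    expect_lt(max(loo$abs_error_F, loo$abs_error_U), 1e-6)
  }
  expect_error(loo_evaluate(make_ref_series(n_points = 5L)), "7-point")
})

test_that("leave-one-out errors sit near the injected noise floor and beat the baseline", {
  cfg <- synth_config(25, seed = 77, noise_sd = 0.05)
  coh <- generate_cohort(cfg)
  loo <- loo_cohort(coh)
  expect_true(all(loo$ok))
  expect_true(all(loo$abs_error_F >= 0 & loo$abs_error_F <= 1))
  mF <- mean(loo$abs_error_F)
  mU <- mean(loo$abs_error_U)
  # function errors bracket the target-noise scale
  expect_gt(mF, 0.5 * 0.05)
  expect_lt(mF, 3 * 0.05)
  # use errors are compressed through the logistic, so only bounded above
  expect_lt(mU, 3 * 0.05)
  rb <- randomized_baseline(coh, seed = 78)
  expect_gt(mean(rb$abs_error_F), mF)
  expect_gt(mean(rb$abs_error_U), mU)
  # summary table: one row per error type, columns 4..20 months plus average
  smry <- loo_summary(loo)
  expect_equal(names(smry),
               c("error", "4_months", "8_months", "12_months", "16_months",
                 "20_months", "average"))
  expect_equal(smry$average[1], mF)
})

test_that("the randomized baseline is seed-reproducible and null on identical subjects", {
  cfg <- synth_config(10, seed = 111)
  coh <- generate_cohort(cfg)
  b1 <- randomized_baseline(coh, seed = 5)
  b2 <- randomized_baseline(coh, seed = 5)
  expect_identical(b1, b2)
  b3 <- randomized_baseline(coh, seed = 6)
  expect_false(identical(b1$donor_id, b3$donor_id))
  # clones of one subject: every cross-prediction is exact
  s <- make_ref_series()
  clones <- cohort(lapply(1:4, function(i) {
    subject_series(paste0("C", i), "immediate", "post", s$times, s$F, s$U)
  }))
  b0 <- randomized_baseline(clones, seed = 1)
  expect_equal(max(b0$abs_error_F, b0$abs_error_U), 0)
  expect_error(randomized_baseline(cohort(list(s)), seed = 1), "at least 2")
})

test_that("degenerate paired comparisons collapse to t = 0 / p = 1 or p = 0", {
  mk_fits <- function(bvals) {
    series <- lapply(seq_along(bvals), function(i) {
      make_ref_series(0.6, bvals[i], 1.4, F0 = 0.3, U0 = 0.6,
                      n_points = 4L, id = sprintf("S%d", i))
    })
    fit_cohort(cohort(series), candidate_ids = c("F1_weighted", "U_sig_lag"))
  }
  pre <- mk_fits(c(2, 2.5, 3, 3.5))
  te0 <- therapy_effect(pre, pre, cutoffs = c(a = Inf, b = Inf, c = Inf))
  expect_equal(te0$t_stat, rep(0, 3))
  expect_equal(te0$p_two_tailed, rep(1, 3))
  expect_equal(te0$n_pairs, rep(4L, 3))
})

test_that("a therapy-induced confidence shift is picked out of a delayed cohort", {
  shift_hat <- matrix(NA_real_, 3, 3)
  p_b <- numeric(3)
  for (r in 1:3) {
    cfg <- synth_config(45, "delayed", therapy_shift = 1.5, seed = 9000 + r)
    coh <- generate_cohort(cfg)
    pre <- cohort(unclass(coh)[vapply(coh, function(s) s$phase == "pre",
                                      logical(1))])
    post <- cohort(unclass(coh)[vapply(coh, function(s) s$phase == "post",
                                       logical(1))])
    # shared prior means across phases keep the paired contrast clean
    priors <- list(F1_weighted = pooled_prior_means(coh, "F1_weighted"),
                   U_sig_lag = pooled_prior_means(coh, "U_sig_lag"))
    pf <- fit_cohort(pre, candidate_ids = c("F1_weighted", "U_sig_lag"),
                     priors = priors)
    qf <- fit_cohort(post, candidate_ids = c("F1_weighted", "U_sig_lag"),
                     priors = priors)
    te <- therapy_effect(pf, qf)
    i <- match(c("a", "b", "c"), te$parameter)
    shift_hat[r, ] <- (te$mean_after - te$mean_before)[i]
    p_b[r] <- te$p_two_tailed[i[2]]
  }
  # the confidence slope moves by about the injected amount ...
  expect_true(all(p_b < 0.05))
  expect_true(all(shift_hat[, 2] > 1))
  # ... and dwarfs any drift in the other two parameters
  expect_true(all(shift_hat[, 2] > 4 * abs(shift_hat[, 1])))
  expect_true(all(shift_hat[, 2] > 4 * abs(shift_hat[, 3])))
})

test_that("use trends are classified by the lenient slope test", {
  tt <- seq(0, 24, by = 4)
  expect_equal(classify_use_trend(0.2 + 0.02 * tt, tt), "increase")
  expect_equal(classify_use_trend(0.9 - 0.02 * tt, tt), "decrease")
  expect_equal(classify_use_trend(rep(0.5, 7), tt), "no_change")
  set.seed(121)
  noisy_flat <- 0.5 + rnorm(7, 0, 0.001)
  # invariance to affine rescaling of time
  for (U in list(0.2 + 0.02 * tt + rnorm(7, 0, 0.01), noisy_flat)) {
    expect_equal(classify_use_trend(U, tt), classify_use_trend(U, 3 * tt + 7))
  }
  expect_error(classify_use_trend(c(0.1, 0.2), c(0, 4)), "3 paired")
  expect_error(classify_use_trend(rep(0.5, 5), rep(2, 5)), "zero variance")
})

test_that("noisy archetypal trajectories mostly land in their own trend category", {
  set.seed(131)
  tt <- seq(0, 24, by = 4)
  hits <- c(increase = 0, decrease = 0, no_change = 0)
  n_rep <- 40
  for (r in 1:n_rep) {
    hits["increase"] <- hits["increase"] +
      (classify_use_trend(0.3 + 0.015 * tt + rnorm(7, 0, 0.05), tt) == "increase")
    hits["decrease"] <- hits["decrease"] +
      (classify_use_trend(0.8 - 0.015 * tt + rnorm(7, 0, 0.05), tt) == "decrease")
    hits["no_change"] <- hits["no_change"] +
      (classify_use_trend(0.5 + rnorm(7, 0, 0.05), tt) == "no_change")
  }
  expect_true(all(hits / n_rep > 0.6))
})

test_that("the low-function subgroup filter keeps only poorly functioning subjects", {
  cfg <- synth_config(30, seed = 141)
  coh <- generate_cohort(cfg)
  sub <- low_function_subgroup(coh, threshold = 0.5)
  expect_true(all(vapply(sub, function(s) s$F[1] < 0.5, logical(1))))
  expect_true(length(sub) < length(coh))
})
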