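test_that("the reference function model linearises increments on the use-function gap", {
  s <- subject_series("X", "immediate", "post", c(0, 4),
                      F = c(0.2, 0.4), U = c(0.6, 0.3))
  p <- build_regression("F1_weighted", s)
  expect_equal(p$y, 0.2)
  expect_equal(unname(p$Phi[, 1]), 0.4)
  expect_equal(p$L, 1)
  expect_equal(p$M, 1)
})

test_that("sigmoid use targets are logits with boundary clipping", {
  s <- subject_series("X", "immediate", "post", c(0, 4, 8),
                      F = c(0.2, 0.4, 0.6), U = c(0.6, 0.5, 1.0))
  p <- build_regression("U_sig_lag", s, logit_eps = 1e-4)
  expect_equal(p$y[1], 0)                      # logit(0.5)
  expect_equal(p$y[2], qlogis(1 - 1e-4))       # clipped boundary
  expect_equal(unname(p$Phi[, 1]), c(0.2, 0.4))  # lagged function
  expect_equal(unname(p$Phi[, 2]), c(-1, -1))  # so coefficients are (b, c)
  # lag-0 variant reads current function
  p0 <- build_regression("U_sig_t", s)
  expect_equal(unname(p0$Phi[, 1]), c(0.4, 0.6))
  expect_error(build_regression("U_sig_lag", s, logit_eps = 0.7), "logit_eps")
})

test_that("a series of L + 1 points yields L usable transitions for every candidate", {
  s <- make_ref_series(n_points = 7L)
  for (id in candidate_models()$id) {
    expect_equal(build_regression(id, s)$L, 6)
  }
  s4 <- make_ref_series(n_points = 4L)
  expect_equal(build_regression("F1_weighted", s4)$L, 3)
  expect_error(build_regression("F1_weighted",
                                structure(list(F = 0.5, U = 0.5),
                                          class = "subject_series")),
               "too short")
})

test_that("least squares matches the normal-equations oracle", {
  set.seed(21)
  for (r in 1:20) {
    p <- random_problem()
    w <- ml_fit(p)
    oracle <- solve(crossprod(p$Phi), crossprod(p$Phi, p$y))
    expect_equal(w, as.numeric(oracle), tolerance = 1e-10)
  }
  # scalar case: w = sum(phi y) / sum(phi^2)
  p1 <- random_problem(M = 1)
  expect_equal(ml_fit(p1), sum(p1$Phi * p1$y) / sum(p1$Phi^2), tolerance = 1e-12)
  # noiseless data return the generating coefficients exactly
  Phi <- cbind(c(1, 2, 3, 4), c(1, 1, 1, 1))
  w0 <- c(0.3, -0.2)
  p0 <- random_problem(L = 4, M = 2)
  p0$Phi <- Phi
  p0$y <- as.numeric(Phi %*% w0)
  expect_equal(ml_fit(p0), w0, tolerance = 1e-12)
})

test_that("the iterated evidence equals the closed-form Gaussian marginal", {
  set.seed(31)
  for (r in 1:200) {
    p <- random_problem()
    prior <- prior_spec(rnorm(p$M), prior_precision0 = 1e-11)
    fit <- evidence_fit(p, prior)
    oracle <- log_evidence_oracle(p, fit$prior_precision, fit$noise_precision,
                                  prior$m0)
    expect_equal(fit$log_evidence, oracle, tolerance = 1e-8)
  }
})

test_that("the evidence oracle reduces to the scalar Gaussian for L = M = 1", {
  p <- random_problem(L = 1, M = 1)
  alpha <- 0.7
  beta <- 2.3
  m0 <- 0.4
  v <- 1 / beta + p$Phi[1, 1]^2 / alpha
  expect_equal(log_evidence_oracle(p, alpha, beta, m0),
               dnorm(p$y, p$Phi[1, 1] * m0, sqrt(v), log = TRUE))
  # y placed at the marginal mean maximises the oracle over y
  p2 <- p
  p2$y <- as.numeric(p$Phi %*% m0)
  expect_gt(log_evidence_oracle(p2, alpha, beta, m0),
            log_evidence_oracle(p, alpha, beta, m0) - 1e-12)
})

test_that("a vanishing prior precision recovers the least-squares solution", {
  set.seed(41)
  for (r in 1:10) {
    p <- random_problem(L = 8)
    prior <- prior_spec(rnorm(p$M), prior_precision0 = 1e-15,
                        noise_precision0 = 1)
    fit <- evidence_fit(p, prior, update_hyperparams = FALSE)
    expect_equal(fit$mN, ml_fit(p), tolerance = 1e-8)
  }
})

test_that("posterior precision is exactly alpha I + beta Phi'Phi and shrinkage is monotone", {
  set.seed(51)
  p <- random_problem(L = 8, M = 2)
  m0 <- c(1, -1)
  dists <- vapply(10^seq(-4, 4), function(alpha) {
    fit <- evidence_fit(p, prior_spec(m0, prior_precision0 = alpha,
                                      noise_precision0 = 1),
                        update_hyperparams = FALSE)
    expect_equal(fit$SN_precision,
                 alpha * diag(2) + 1 * crossprod(p$Phi), tolerance = 1e-12)
    sqrt(sum((fit$mN - m0)^2))
  }, numeric(1))
  expect_true(all(diff(dists) <= 1e-12))
})

test_that("effective degrees of freedom stay within [0, M]", {
  set.seed(61)
  for (r in 1:20) {
    p <- random_problem()
    fit <- evidence_fit(p, prior_spec(rnorm(p$M)))
    expect_gte(fit$effective_dof, 0)
    expect_lte(fit$effective_dof, p$M + 1e-9)
  }
})

test_that("noiseless data stop the hyperparameter iteration at a flagged state with exact coefficients", {
  s <- make_ref_series(a = 0.6)
  p <- build_regression("F1_weighted", s)
  fit <- evidence_fit(p, prior_spec(1))
  expect_equal(fit$mN, 0.6, tolerance = 1e-8)
  expect_false(fit$converged)
})

test_that("pooled prior means follow the cohort except the reference model pinned at 1", {
  expect_equal(pooled_prior_means(cohort(list(make_ref_series())),
                                  "F1_weighted")$m0, 1)
  # noiseless cohort generated with b = 3, c = 2: pooled logit regression
  series <- lapply(1:4, function(i) {
    make_ref_series(a = 0.5, b = 3, c = 2, F0 = 0.1 + 0.2 * i,
                    U0 = 0.9 - 0.15 * i, id = paste0("S", i))
  })
  pr <- pooled_prior_means(cohort(series), "U_sig_lag")
  expect_equal(pr$m0, c(3, 2), tolerance = 1e-6)
  # single-subject cohort: identical to that subject's own least squares
  one <- cohort(series[1])
  expect_equal(pooled_prior_means(one, "U_sig_t")$m0,
               ml_fit(build_regression("U_sig_t", series[[1]])))
  expect_error(pooled_prior_means(cohort(list()), "U_sig_lag"), "empty")
})

test_that("hyperparameter defaults encode the almost-flat prior", {
  pr <- prior_spec(1)
  expect_equal(pr$prior_precision0, 1e-11)
  expect_equal(pr$noise_precision0, 1e-8)
  expect_error(prior_spec(1, prior_precision0 = -1), "positive")
})

test_that("model ranking is unchanged for smaller prior-precision initialisations", {
  cfg <- synth_config(8, seed = 71)
  coh <- generate_cohort(cfg)
  ids <- c("F1_weighted", "F1_fw", "F1_uw")
  verdicts <- lapply(c(1e-11, 1e-13), function(a0) {
    fits <- fit_cohort(coh, candidate_ids = ids, prior_precision0 = a0)
    rbind(compare_candidates(fits, "F1_weighted", "F1_fw")$verdict,
          compare_candidates(fits, "F1_weighted", "F1_uw")$verdict)
  })
  expect_equal(verdicts[[1]], verdicts[[2]])
})
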