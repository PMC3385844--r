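test_that("cohort generation is fully reproducible from the seed", {
  cfg <- synth_config(6, seed = 171)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_cohort(c1, f1)
  write_cohort(c2, f2)
  expect_identical(readLines(f1), readLines(f2))
  c3 <- generate_cohort(synth_config(6, seed = 172))
  expect_false(identical(as.data.frame(c1), as.data.frame(c3)))
})

test_that("generated values respect scales, schedules and truncation bounds", {
  cfg <- synth_config(20, seed = 181, noise_sd = 0.15)
  coh <- generate_cohort(cfg)
  df <- as.data.frame(coh)
  expect_true(all(df$F >= 0 & df$F <= 1 & df$U >= 0 & df$U <= 1))
  expect_true(all(vapply(coh, function(s) length(s$F), integer(1)) == 7L))
  pars <- attr(coh, "true_params")
  expect_true(all(pars$a >= 0 & pars$a <= 1))
  expect_true(all(pars$b >= 0))
  # delayed group: 4 + 4 schedule
  del <- generate_cohort(synth_config(5, "delayed", seed = 182))
  expect_length(del, 10)
  expect_true(all(vapply(del, function(s) length(s$F), integer(1)) == 4L))
  expect_setequal(vapply(del, function(s) s$phase, character(1)),
                  c("pre", "post"))
})

test_that("zero-variance configurations pin every subject at the medians", {
  cfg <- synth_config(4, seed = 191,
                      param_dists = list(a = c(0.64, 0, 0, 1),
                                         b = c(2.2, 0, 0, Inf),
                                         c = c(1.4, 0, -Inf, Inf)))
  pars <- attr(generate_cohort(cfg), "true_params")
  expect_equal(pars$a, rep(0.64, 4))
  expect_equal(pars$b, rep(2.2, 4))
  expect_equal(pars$c, rep(1.4, 4))
  expect_error(synth_config(4, seed = 1,
                            param_dists = list(a = c(2, 0, 0, 1),
                                               b = c(2.2, 0, 0, Inf),
                                               c = c(1.4, 0, -Inf, Inf))) |>
                 generate_cohort(), "outside bounds")
})

test_that("an empty truncation region is rejected", {
  cfg <- synth_config(4, seed = 1,
                      param_dists = list(a = c(-50, 0.1, 0, 1),
                                         b = c(2.2, 1, 0, Inf),
                                         c = c(1.4, 1, -Inf, Inf)))
  expect_error(generate_cohort(cfg), "empty truncation")
})

test_that("noise-free cohorts satisfy the generating equations exactly", {
  for (ids in list(c("F1_weighted", "U_sig_lag"), c("F2_fw_const", "U_lin_t"),
                   c("F3_fw_uw_const", "U_sig_t"))) {
    cfg <- synth_config(3, seed = 201, function_id = ids[1], use_id = ids[2],
                        noise_sd = 0)
    coh <- generate_cohort(cfg)
    pars <- attr(coh, "true_params")
    fun_np <- candidate_models()$n_params[candidate_models()$id == ids[1]]
    for (i in seq_along(coh)) {
      pf <- build_regression(ids[1], coh[[i]])
      pu <- build_regression(ids[2], coh[[i]])
      wf <- as.numeric(pars[i, 1 + seq_len(fun_np)])
      wu <- as.numeric(pars[i, 1 + fun_np + seq_len(ncol(pu$Phi))])
      expect_lt(max(abs(pf$y - pf$Phi %*% wf)), 1e-10)
      expect_lt(max(abs(pu$y - pu$Phi %*% wu)), 1e-10)
    }
  }
})

test_that("sampled parameter medians converge to the configured centres", {
  cfg <- synth_config(10000, seed = 211)
  set.seed(cfg$seed)
  pars <- sample_subject_params(cfg)
  # truncation shifts the a median slightly up from the untruncated centre
  expect_lt(abs(median(pars$a) - 0.64), 0.02)
  expect_lt(abs(median(pars$b) - 2.20), 0.04)
  expect_lt(abs(median(pars$c) - 1.40), 0.04)
})

test_that("raw-visit back-fill round-trips through the transform layer", {
  cfg <- synth_config(4, seed = 221)
  coh <- generate_cohort(cfg)
  visits <- synthesize_raw_visits(coh)
  expect_true(all(visits$wmft_seconds > 0 & visits$wmft_seconds <= 1800))
  aou <- as.matrix(visits[, sprintf("aou_%02d", 1:30)])
  expect_true(all(aou * 2 == round(aou * 2)))
  back <- assemble_cohort(visits, "immediate",
                          ref = list(neglog_min = -log(1800),
                                     neglog_max = -log(5)))
  expect_equal(length(back), length(coh))
  for (i in seq_along(coh)) {
    expect_equal(back[[i]]$F, unname(coh[[i]]$F), tolerance = 1e-9)
    expect_lt(max(abs(back[[i]]$U - coh[[i]]$U)), 1 / 400)
  }
})

test_that("the surrogate study recovers the reference pair at small scale", {
  st <- surrogate_study(candidate_ids = c("F1_weighted", "U_sig_lag"),
                        n_subjects = 25L, seed = 400L)
  use_rows <- st$per[st$per$gen_id == "U_sig_lag", ]
  expect_true(all(use_rows$won))
  fun_rows <- st$per[st$per$gen_id == "F1_weighted" &
                       st$per$alt_id %in% c("F1_fw", "F1_uw"), ]
  expect_true(all(fun_rows$won))
  rec <- st$recovery
  expect_true(all(abs(rec$bias[rec$param == "a"]) < 0.15))
  expect_true(all(rec$coverage >= 0 & rec$coverage <= 1))
})

test_that("noise-free surrogate fits recover the generating parameters almost exactly", {
  st <- surrogate_study(candidate_ids = "U_sig_lag", n_subjects = 10L,
                        noise_sd = 0, seed = 500L, apply_filter = FALSE)
  expect_true(all(abs(st$recovery$bias) < 1e-3))
})
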