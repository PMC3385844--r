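# Fixtures are built in code: noiseless series from the coupled reference
# map, and small synthetic cohorts.

make_ref_series <- function(a = 0.6, b = 5, c = 3, F0 = 0.3, U0 = 0.7,
                            n_points = 7L, id = "S1") {
  tr <- simulate_trajectory(model_params(a, b, c), F0 = F0, U0 = U0,
                            n_steps = n_points - 1L)
  subject_series(id, "immediate", "post", tr$time, tr$F, tr$U)
}

random_problem <- function(L = NULL, M = NULL) {
  if (is.null(L)) L <- sample(3:10, 1)
  if (is.null(M)) M <- sample(1:3, 1)
  Phi <- matrix(rnorm(L * M), L, M)
  w <- rnorm(M)
  y <- as.numeric(Phi %*% w + rnorm(L, 0, 0.3))
  structure(list(y = y, Phi = Phi, candidate_id = "F1_weighted", L = L, M = M,
                 t_target = seq_len(L) + 1L, needs_prev = TRUE,
                 logit_eps = 1e-4, log_jac_rows = rep(0, L)),
            class = "regression_problem")
}
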