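# Bayesian evidence-maximisation regression: each candidate update rule is
# linearised into y = Phi w + eps with iid Gaussian noise (precision beta)
# and an iid Gaussian prior w ~ N(m0, 1/alpha I); the two hyperparameters
# are tuned by maximising the (closed-form) marginal likelihood.

#' Linearise a candidate model into a regression problem
#'
#' Each transition between consecutive grid points contributes one row, so a
#' series of `n` points yields `L = n - 1` rows. The reference function
#' model regresses the increment `F(t) - F(t-1)` on `U(t-1) - F(t-1)`
#' (single parameter `a`); the other function rows regress `F(t)` on their
#' raw regressors. Sigmoid use rows regress `logit(U(t))` on
#' `(F(lag), -1)` so the coefficients are `(b, c)`; linear use rows regress
#' `U(t)` on `(F(lag), 1)`. `U` values at 0 or 1 (common for the Motor
#' Activity Log) are clipped to `(logit_eps, 1 - logit_eps)` before the
#' logit.
#'
#' @param candidate_id A candidate id (see [candidate_models()]).
#' @param series A `subject_series` (length >= 2).
#' @param logit_eps Clipping bound for the logit transform, in (0, 0.5).
#' @return Object of class `regression_problem`: list with `y`, `Phi`,
#'   `candidate_id`, `L`, `M`, `t_target` (index of each row's target
#'   point) and `needs_prev` (whether rows also consume the preceding
#'   point).
#' @export
build_regression <- function(candidate_id, series, logit_eps = 1e-4) {
  info <- candidate_info(candidate_id)
  F <- series$F
  U <- series$U
  n <- length(F)
  if (n < 2L) stop("series too short: need at least 2 points")
  if (logit_eps <= 0 || logit_eps >= 0.5) stop("'logit_eps' must be in (0, 0.5)")
  if (any(U < 0 | U > 1)) stop("'U' must lie in [0, 1]")
  tt <- 2:n
  log_jac_rows <- rep(0, n - 1L)
  if (info$target == "function") {
    Fp <- F[tt - 1L]
    Up <- U[tt - 1L]
    y <- switch(candidate_id, F1_weighted = F[tt] - Fp, F[tt])
    Phi <- switch(candidate_id,
                  F1_fw = cbind(F_prev = Fp),
                  F1_uw = cbind(U_prev = Up),
                  F1_weighted = cbind(dUF = Up - Fp),
                  F2_fw_const = cbind(F_prev = Fp, const = 1),
                  F2_uw_const = cbind(U_prev = Up, const = 1),
                  F2_fw_uw = cbind(F_prev = Fp, U_prev = Up),
                  F3_fw_uw_const = cbind(F_prev = Fp, U_prev = Up, const = 1))
    needs_prev <- TRUE
  } else {
    Farg <- if (info$lag == 0L) F[tt] else F[tt - 1L]
    if (info$link == "sigmoid") {
      Uc <- pmin(1 - logit_eps, pmax(logit_eps, U[tt]))
      y <- qlogis(Uc)
      Phi <- cbind(F_arg = Farg, neg_const = -1)
      # log |d logit(U)/dU|: puts the evidence on the scale of the observed
      # use values, so Bayes factors against linear-link candidates compare
      # densities of the same data
      log_jac_rows <- -log(Uc * (1 - Uc))
    } else {
      y <- U[tt]
      Phi <- cbind(F_arg = Farg, const = 1)
    }
    needs_prev <- info$lag == 1L
  }
  if (any(!is.finite(Phi)) || any(!is.finite(y))) {
    stop("non-finite entries in the regression problem")
  }
  structure(list(y = as.numeric(y), Phi = Phi, candidate_id = candidate_id,
                 L = length(y), M = ncol(Phi), t_target = tt,
                 needs_prev = needs_prev, logit_eps = logit_eps,
                 log_jac_rows = log_jac_rows),
            class = "regression_problem")
}

#' Drop the regression rows that consume a held-out point
#'
#' Removes every row whose target point, or (for lagged candidates) whose
#' preceding point, is among `drop_t`. Used by the leave-one-out protocol.
#'
#' @param problem A `regression_problem`.
#' @param drop_t Integer indices (1-based over the series) to hold out.
#' @return The reduced `regression_problem`.
#' @export
drop_rows <- function(problem, drop_t) {
  hit <- problem$t_target %in% drop_t
  if (problem$needs_prev) hit <- hit | (problem$t_target - 1L) %in% drop_t
  keep <- !hit
  out <- problem
  out$y <- problem$y[keep]
  out$Phi <- problem$Phi[keep, , drop = FALSE]
  out$t_target <- problem$t_target[keep]
  out$log_jac_rows <- problem$log_jac_rows[keep]
  out$L <- sum(keep)
  out
}

#' Merge regression problems from several subjects into one pooled problem
#'
#' @param problems List of `regression_problem`s for the same candidate.
#' @return One `regression_problem` with the rows stacked.
#' @export
pool_problems <- function(problems) {
  ids <- unique(vapply(problems, function(p) p$candidate_id, character(1)))
  if (length(ids) != 1L) stop("cannot pool problems of different candidates")
  out <- problems[[1]]
  out$y <- unlist(lapply(problems, function(p) p$y), use.names = FALSE)
  out$Phi <- do.call(rbind, lapply(problems, function(p) p$Phi))
  out$t_target <- unlist(lapply(problems, function(p) p$t_target))
  out$log_jac_rows <- unlist(lapply(problems, function(p) p$log_jac_rows))
  out$L <- length(out$y)
  out
}

#' Maximum-likelihood (least-squares) fit of a regression problem
#'
#' The frequentist solution, used for the pooled prior means and as an
#' independent check of the flat-prior limit of [evidence_fit()]. A
#' rank-deficient design falls back to the minimum-norm solution and is
#' flagged via the `rank_deficient` attribute.
#'
#' @param problem A `regression_problem`.
#' @return Numeric coefficient vector of length `M`.
#' @export
ml_fit <- function(problem) {
  qrP <- qr(problem$Phi)
  if (qrP$rank < problem$M) {
    sv <- svd(problem$Phi)
    pos <- sv$d > max(sv$d) * 1e-12
    w <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% problem$y) / sv$d[pos])
    w <- as.numeric(w)
    attr(w, "rank_deficient") <- TRUE
    return(w)
  }
  as.numeric(qr.coef(qrP, problem$y))
}

#' Specify the Gaussian prior and hyperparameter initialisation
#'
#' The prior over the `M` coefficients is iid Gaussian with mean `m0` and
#' precision `prior_precision0` (alpha); the noise precision is
#' `noise_precision0` (beta). The defaults encode an almost-flat prior with
#' alpha/beta = 1e-3: alpha = 1e-11, beta = 1e-8.
#'
#' @param m0 Prior mean vector.
#' @param prior_precision0,noise_precision0 Positive initial hyperparameters.
#' @return Object of class `prior_spec`.
#' @export
prior_spec <- function(m0, prior_precision0 = 1e-11,
                       noise_precision0 = prior_precision0 / 1e-3) {
  if (prior_precision0 <= 0 || noise_precision0 <= 0) {
    stop("precisions must be positive")
  }
  structure(list(m0 = as.numeric(m0), prior_precision0 = prior_precision0,
                 noise_precision0 = noise_precision0),
            class = "prior_spec")
}

# Posterior at fixed hyperparameters: precision A = alpha I + beta Phi'Phi,
# mean mN = A^-1 (beta Phi'y + alpha m0).
.posterior_at <- function(PtP, Pty, m0, alpha, beta, M) {
  A <- alpha * diag(M) + beta * PtP
  mN <- solve(A, beta * Pty + alpha * m0)
  list(A = A, mN = as.numeric(mN))
}

# Log marginal likelihood in the quadratic-expansion form
# (M/2) log alpha + (L/2) log beta - E(mN) - (1/2) log|A| - (L/2) log 2pi,
# exact for the linear-Gaussian model.
.log_evidence_terms <- function(problem, alpha, beta, m0, mN, A) {
  r2 <- sum((problem$y - problem$Phi %*% mN)^2)
  d2 <- sum((mN - m0)^2)
  terms <- c(fit = -beta / 2 * r2,
             regularisation = -alpha / 2 * d2,
             log_det = -0.5 * determinant(A, logarithm = TRUE)$modulus[[1]],
             const = problem$M / 2 * log(alpha) + problem$L / 2 * log(beta) -
               problem$L / 2 * log(2 * pi))
  list(terms = terms, value = sum(terms), r2 = r2, d2 = d2)
}

#' Fit a regression problem by Bayesian evidence maximisation
#'
#' Alternates between (i) the posterior mean/precision at the current
#' hyperparameters and (ii) the evidence-maximising hyperparameter updates
#' `alpha <- gamma / ||mN - m0||^2` and
#' `beta <- (L - gamma) / ||y - Phi mN||^2`, where the effective number of
#' well-determined parameters is `gamma = sum(lambda_i / (alpha + lambda_i))`
#' over the eigenvalues `lambda_i` of `beta Phi'Phi`. Iterates until the
#' relative change of both hyperparameters drops below `tol`. Degenerate
#' updates (zero residual or posterior mean equal to the prior mean) stop
#' the iteration at the last finite state with `converged = FALSE`, which
#' mirrors the poorly-converging subjects one sees with very short series.
#'
#' @param problem A `regression_problem`.
#' @param prior A [prior_spec()].
#' @param tol Relative convergence tolerance on both hyperparameters.
#' @param max_iter Maximum number of update sweeps.
#' @param update_hyperparams If `FALSE`, compute the posterior and evidence
#'   once at the initial hyperparameters (used e.g. to expose the flat-prior
#'   frequentist limit).
#' @return Object of class `posterior_fit`: posterior mean `mN`, posterior
#'   precision `SN_precision`, per-parameter `posterior_sd`, converged
#'   hyperparameters `prior_precision` and `noise_precision`,
#'   `log_evidence` with its additive breakdown `log_evidence_terms`,
#'   `effective_dof`, `n_iter`, `converged` and bookkeeping fields.
#' @export
evidence_fit <- function(problem, prior, tol = 1e-6, max_iter = 500L,
                         update_hyperparams = TRUE) {
  stopifnot(inherits(problem, "regression_problem"), inherits(prior, "prior_spec"))
  m0 <- prior$m0
  if (length(m0) != problem$M) stop("prior mean length must equal M")
  alpha <- prior$prior_precision0
  beta <- prior$noise_precision0
  PtP <- crossprod(problem$Phi)
  Pty <- crossprod(problem$Phi, problem$y)
  lam0 <- eigen(PtP, symmetric = TRUE, only.values = TRUE)$values
  lam0[lam0 < 0] <- 0
  converged <- FALSE
  degenerate <- FALSE
  n_iter <- 0L
  if (update_hyperparams) {
    for (it in seq_len(max_iter)) {
      n_iter <- it
      post <- .posterior_at(PtP, Pty, m0, alpha, beta, problem$M)
      lam <- beta * lam0
      gamma <- sum(lam / (alpha + lam))
      d2 <- sum((post$mN - m0)^2)
      r2 <- sum((problem$y - problem$Phi %*% post$mN)^2)
      if (d2 < 1e-300 || r2 < 1e-24 || gamma >= problem$L) {
        degenerate <- TRUE
        break
      }
      alpha_new <- gamma / d2
      beta_new <- (problem$L - gamma) / r2
      if (!is.finite(alpha_new) || !is.finite(beta_new) ||
          alpha_new <= 0 || beta_new <= 0) {
        degenerate <- TRUE
        break
      }
      rel <- max(abs(alpha_new - alpha) / alpha, abs(beta_new - beta) / beta)
      alpha <- alpha_new
      beta <- beta_new
      if (rel < tol) {
        converged <- TRUE
        break
      }
    }
  }
  post <- .posterior_at(PtP, Pty, m0, alpha, beta, problem$M)
  lam <- beta * lam0
  gamma <- sum(lam / (alpha + lam))
  ev <- .log_evidence_terms(problem, alpha, beta, m0, post$mN, post$A)
  SN <- solve(post$A)
  structure(list(candidate_id = problem$candidate_id,
                 param_names = candidate_param_names(problem$candidate_id),
                 mN = post$mN, SN_precision = post$A,
                 posterior_sd = sqrt(pmax(0, diag(SN))),
                 prior_precision = alpha, noise_precision = beta,
                 log_evidence = ev$value, log_evidence_terms = ev$terms,
                 effective_dof = gamma, n_iter = n_iter,
                 converged = converged || !update_hyperparams,
                 degenerate = degenerate,
                 log_jacobian = sum(problem$log_jac_rows),
                 L = problem$L, M = problem$M, m0 = m0,
                 logit_eps = problem$logit_eps),
            class = "posterior_fit")
}

#' @export
print.posterior_fit <- function(x, ...) {
  cat(sprintf("<posterior_fit> %s: log evidence %.3f (%s, %d iter)\n",
              x$candidate_id, x$log_evidence,
              if (x$converged) "converged" else "not converged", x$n_iter))
  print(data.frame(param = x$param_names, mean = round(x$mN, 4),
                   sd = signif(x$posterior_sd, 4)))
  invisible(x)
}

#' Closed-form Gaussian marginal log-likelihood (independent oracle)
#'
#' With iid Gaussian noise of precision `noise_precision` and an iid
#' Gaussian prior `N(m0, prior_precision^-1 I)`, the marginal distribution
#' of the targets is exactly
#' `N(Phi m0, noise_precision^-1 I + prior_precision^-1 Phi Phi')`. This
#' evaluates its log density directly (via an eigendecomposition of the
#' covariance), independently of the expansion used by [evidence_fit()].
#'
#' @param problem A `regression_problem`.
#' @param prior_precision,noise_precision Positive precisions.
#' @param m0 Prior mean vector.
#' @return The marginal log-likelihood of `problem$y`.
#' @export
log_evidence_oracle <- function(problem, prior_precision, noise_precision, m0) {
  if (prior_precision <= 0 || noise_precision <= 0) {
    stop("precisions must be positive")
  }
  L <- problem$L
  C <- diag(L) / noise_precision +
    tcrossprod(problem$Phi) / prior_precision
  eC <- eigen(C, symmetric = TRUE)
  if (any(eC$values <= 0)) stop("singular marginal covariance")
  d <- problem$y - as.numeric(problem$Phi %*% m0)
  z <- crossprod(eC$vectors, d)
  -0.5 * (L * log(2 * pi) + sum(log(eC$values)) + sum(z^2 / eC$values))
}

#' Pooled prior means for a candidate
#'
#' The prior mean for each candidate is the maximum-likelihood solution of
#' all transitions of the cohort stacked into one regression -- except the
#' reference weighted-average function model, whose prior mean is fixed
#' at 1.
#'
#' @param x A `cohort`.
#' @param candidate_id Candidate id.
#' @param logit_eps Passed to [build_regression()].
#' @param ... Passed to [prior_spec()] (hyperparameter initialisation).
#' @return A [prior_spec()].
#' @export
pooled_prior_means <- function(x, candidate_id, logit_eps = 1e-4, ...) {
  if (length(x) == 0L) stop("empty cohort")
  if (candidate_id == "F1_weighted") return(prior_spec(m0 = 1, ...))
  problems <- lapply(unclass(x), function(s) {
    build_regression(candidate_id, s, logit_eps = logit_eps)
  })
  prior_spec(m0 = ml_fit(pool_problems(problems)), ...)
}

#' Fit candidates across a cohort
#'
#' Fits each requested candidate to every series of the cohort with
#' [evidence_fit()], using cohort-pooled prior means (unless priors are
#' supplied).
#'
#' @param x A `cohort`.
#' @param candidate_ids Candidate ids to fit (default: the full family).
#' @param priors Optional named list of [prior_spec()]s keyed by candidate
#'   id; missing entries are computed with [pooled_prior_means()].
#' @param logit_eps,tol,max_iter Passed down to [build_regression()] and
#'   [evidence_fit()].
#' @param prior_precision0,noise_precision0 Hyperparameter initialisation
#'   used when computing pooled priors.
#' @return Object of class `cohort_fits`: a list with `fits` (nested list
#'   `fits[[series key]][[candidate id]]` of `posterior_fit`s), `keys`
#'   (data frame mapping keys to subject/group/phase) and `priors`.
#' @export
fit_cohort <- function(x, candidate_ids = candidate_models()$id, priors = NULL,
                       logit_eps = 1e-4, tol = 1e-6, max_iter = 500L,
                       prior_precision0 = 1e-11,
                       noise_precision0 = prior_precision0 / 1e-3) {
  stopifnot(inherits(x, "cohort"))
  if (is.null(priors)) priors <- list()
  for (id in candidate_ids) {
    if (is.null(priors[[id]])) {
      priors[[id]] <- pooled_prior_means(x, id, logit_eps = logit_eps,
                                         prior_precision0 = prior_precision0,
                                         noise_precision0 = noise_precision0)
    }
  }
  keys <- data.frame(
    key = vapply(unclass(x), function(s) paste(s$subject_id, s$phase, sep = "|"),
                 character(1)),
    subject_id = vapply(unclass(x), function(s) s$subject_id, character(1)),
    group = vapply(unclass(x), function(s) s$group, character(1)),
    phase = vapply(unclass(x), function(s) s$phase, character(1)),
    stringsAsFactors = FALSE)
  if (anyDuplicated(keys$key)) stop("duplicate subject/phase in cohort")
  fits <- vector("list", length(x))
  names(fits) <- keys$key
  for (i in seq_along(x)) {
    s <- x[[i]]
    fits[[i]] <- setNames(lapply(candidate_ids, function(id) {
      evidence_fit(build_regression(id, s, logit_eps = logit_eps),
                   priors[[id]], tol = tol, max_iter = max_iter)
    }), candidate_ids)
  }
  structure(list(fits = fits, keys = keys, priors = priors,
                 candidate_ids = candidate_ids),
            class = "cohort_fits")
}

#' Flatten cohort fits to one row per parameter
#'
#' @param fits A `cohort_fits` object.
#' @return Data frame with columns `subject_id`, `group`, `phase`,
#'   `candidate_id`, `param`, `mean`, `sd`, `log_evidence`, `converged`,
#'   `n_iter`, `prior_precision`, `noise_precision`.
#' @export
fits_table <- function(fits) {
  stopifnot(inherits(fits, "cohort_fits"))
  rows <- list()
  for (i in seq_len(nrow(fits$keys))) {
    for (id in fits$candidate_ids) {
      f <- fits$fits[[i]][[id]]
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = fits$keys$subject_id[i], group = fits$keys$group[i],
        phase = fits$keys$phase[i], candidate_id = id, param = f$param_names,
        mean = f$mN, sd = f$posterior_sd, log_evidence = f$log_evidence,
        converged = f$converged, n_iter = f$n_iter,
        prior_precision = f$prior_precision,
        noise_precision = f$noise_precision, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
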