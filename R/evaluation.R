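# Predictive evaluation: leave-one-out trajectory prediction with a
# randomized between-subject baseline, the before/after-therapy parameter
# comparison, and the use-trend classification.

#' Leave-one-out prediction errors for one 7-point series
#'
#' For each interior index `k` in 2..6 the coupled model is refitted on the
#' remaining six points (regression rows consuming the held-out point are
#' dropped), then simulated forward from the observed first point; the
#' absolute differences between simulated and observed function and use at
#' index `k` are the prediction errors. The first and last points are never
#' held out: they anchor the initial and final state.
#'
#' @param series A 7-point `subject_series`.
#' @param function_id,use_id Candidate pair to evaluate (default: the
#'   reference pair).
#' @param function_prior,use_prior [prior_spec()]s; when `NULL`, the
#'   function prior mean defaults to 1 (reference model) or the series'
#'   least-squares fit, and likewise for use.
#' @param logit_eps Passed to [build_regression()].
#' @return Data frame with columns `subject_id`, `left_out_index`,
#'   `abs_error_F`, `abs_error_U`, `ok` (fit success flag).
#' @export
loo_evaluate <- function(series, function_id = "F1_weighted",
                         use_id = "U_sig_lag",
                         function_prior = NULL, use_prior = NULL,
                         logit_eps = 1e-4) {
  if (length(series$F) != 7L) stop("leave-one-out needs a 7-point series")
  fp_full <- build_regression(function_id, series, logit_eps = logit_eps)
  up_full <- build_regression(use_id, series, logit_eps = logit_eps)
  if (is.null(function_prior)) {
    m0 <- if (function_id == "F1_weighted") 1 else ml_fit(fp_full)
    function_prior <- prior_spec(m0)
  }
  if (is.null(use_prior)) use_prior <- prior_spec(ml_fit(up_full))
  lag0 <- candidate_info(use_id)$lag == 0L
  rows <- list()
  for (k in 2:6) {
    ff <- tryCatch(evidence_fit(drop_rows(fp_full, k), function_prior),
                   error = function(e) NULL)
    uf <- tryCatch(evidence_fit(drop_rows(up_full, k), use_prior),
                   error = function(e) NULL)
    if (is.null(ff) || is.null(uf)) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = series$subject_id, left_out_index = k,
        abs_error_F = NA_real_, abs_error_U = NA_real_, ok = FALSE,
        stringsAsFactors = FALSE)
      next
    }
    sim <- simulate_trajectory(F0 = series$F[1], U0 = series$U[1],
                               n_steps = 6L,
                               function_id = function_id, use_id = use_id,
                               function_params = ff$mN, use_params = uf$mN)
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = series$subject_id, left_out_index = k,
      abs_error_F = abs(sim$F[k] - series$F[k]),
      abs_error_U = abs(sim$U[k] - series$U[k]), ok = TRUE,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Leave-one-out evaluation across a cohort
#'
#' Prior means are pooled once over the whole cohort and reused for every
#' reduced fit.
#'
#' @param x A `cohort` of 7-point series.
#' @param function_id,use_id Candidate pair.
#' @param logit_eps Passed down.
#' @return Data frame of [loo_evaluate()] rows for all subjects.
#' @export
loo_cohort <- function(x, function_id = "F1_weighted", use_id = "U_sig_lag",
                       logit_eps = 1e-4) {
  fprior <- pooled_prior_means(x, function_id, logit_eps = logit_eps)
  uprior <- pooled_prior_means(x, use_id, logit_eps = logit_eps)
  out <- do.call(rbind, lapply(unclass(x), function(s) {
    loo_evaluate(s, function_id, use_id, fprior, uprior, logit_eps)
  }))
  rownames(out) <- NULL
  out
}

#' Summarise leave-one-out errors by held-out time point
#'
#' @param loo Data frame from [loo_cohort()] or [loo_evaluate()].
#' @return Data frame with one row per error type (function, use) and one
#'   column per held-out index (labelled by months), plus the average.
#' @export
loo_summary <- function(loo) {
  loo <- loo[loo$ok, , drop = FALSE]
  ks <- sort(unique(loo$left_out_index))
  mk <- function(v) {
    m <- vapply(ks, function(k) mean(v[loo$left_out_index == k]), numeric(1))
    c(m, average = mean(v))
  }
  out <- rbind(mk(loo$abs_error_F), mk(loo$abs_error_U))
  colnames(out) <- c(sprintf("%d_months", 4 * (ks - 1)), "average")
  data.frame(error = c("abs_error_F", "abs_error_U"), out, check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Randomized between-subject prediction baseline
#'
#' For every subject and interior index, the "prediction" is the value of a
#' uniformly drawn other subject at that index. Quantifies how much of the
#' model's accuracy is just shared group structure.
#'
#' @param x A `cohort` of equally long series (at least 2 subjects).
#' @param seed Integer seed; the draw is fully reproducible.
#' @return Data frame with `subject_id`, `left_out_index`, `abs_error_F`,
#'   `abs_error_U`, `donor_id`.
#' @export
randomized_baseline <- function(x, seed) {
  if (length(x) < 2L) stop("the baseline needs at least 2 subjects")
  lens <- vapply(unclass(x), function(s) length(s$F), integer(1))
  if (length(unique(lens)) != 1L) stop("all series must have equal length")
  set.seed(seed)
  n <- lens[1]
  ks <- 2:(n - 1L)
  rows <- list()
  for (i in seq_along(x)) {
    for (k in ks) {
      j <- sample(setdiff(seq_along(x), i), 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = x[[i]]$subject_id, left_out_index = k,
        abs_error_F = abs(x[[j]]$F[k] - x[[i]]$F[k]),
        abs_error_U = abs(x[[j]]$U[k] - x[[i]]$U[k]),
        donor_id = x[[j]]$subject_id, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Before/after-therapy comparison of model parameters
#'
#' Pairs each subject's pre- and post-therapy posterior means, keeps (per
#' parameter) the subjects whose fits pass the posterior-width convergence
#' filter in both phases, and runs a classical two-tailed paired t-test.
#'
#' @param pre_fits,post_fits `cohort_fits` for the pre- and post-therapy
#'   phases, fitted with the same candidates.
#' @param candidate_ids Candidates whose parameters to compare (default:
#'   the reference pair, i.e. parameters a, b, c).
#' @param cutoffs Named numeric vector of per-parameter sd cut-offs (e.g.
#'   `c(a = 0.316, b = 6.38, c = 3.67)`), or `"auto"` to derive them from
#'   the spread of the posterior means across both phases.
#' @return Data frame with one row per parameter: `n_pairs`,
#'   `mean_before`, `se_before`, `mean_after`, `se_after`, `t_stat`,
#'   `p_two_tailed`.
#' @export
therapy_effect <- function(pre_fits, post_fits,
                           candidate_ids = c("F1_weighted", "U_sig_lag"),
                           cutoffs = "auto") {
  stopifnot(inherits(pre_fits, "cohort_fits"), inherits(post_fits, "cohort_fits"))
  pre <- fits_table(pre_fits)
  post <- fits_table(post_fits)
  pre <- pre[pre$candidate_id %in% candidate_ids, ]
  post <- post[post$candidate_id %in% candidate_ids, ]
  params <- unique(pre$param)
  rows <- list()
  for (p in params) {
    a <- pre[pre$param == p, ]
    b <- post[post$param == p, ]
    m <- merge(a[, c("subject_id", "mean", "sd")],
               b[, c("subject_id", "mean", "sd")],
               by = "subject_id", suffixes = c("_pre", "_post"))
    if (identical(cutoffs, "auto")) {
      cut_p <- sd(c(m$mean_pre, m$mean_post))
    } else {
      if (is.null(names(cutoffs)) || !(p %in% names(cutoffs))) {
        stop("'cutoffs' must be named with an entry per parameter")
      }
      cut_p <- cutoffs[[p]]
    }
    m <- m[m$sd_pre < cut_p & m$sd_post < cut_p, , drop = FALSE]
    if (nrow(m) < 2L) stop("fewer than 2 convergent pairs for parameter ", p)
    d <- m$mean_post - m$mean_pre
    if (sd(d) < 1e-14) {
      # degenerate pairing: no within-pair variance
      tt <- list(statistic = if (abs(mean(d)) < 1e-14) 0 else Inf * sign(mean(d)),
                 p.value = if (abs(mean(d)) < 1e-14) 1 else 0)
    } else {
      tt <- t.test(m$mean_post, m$mean_pre, paired = TRUE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = p, n_pairs = nrow(m),
      mean_before = mean(m$mean_pre),
      se_before = sd(m$mean_pre) / sqrt(nrow(m)),
      mean_after = mean(m$mean_post),
      se_after = sd(m$mean_post) / sqrt(nrow(m)),
      t_stat = unname(tt$statistic), p_two_tailed = tt$p.value,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify the long-term trend of an arm-use series
#'
#' Ordinary least-squares slope of use against time, with a lenient
#' significance criterion (default p < 0.25) deciding whether use
#' increased, decreased or did not change over the follow-up.
#'
#' @param U Use values (at least 3).
#' @param times Measurement times (any affine scale).
#' @param p_threshold Slope p-value threshold.
#' @return One of `"increase"`, `"decrease"`, `"no_change"`.
#' @export
classify_use_trend <- function(U, times, p_threshold = 0.25) {
  if (length(U) < 3L || length(times) != length(U)) {
    stop("need at least 3 paired points")
  }
  if (sd(times) < 1e-12) stop("zero variance in 'times'")
  fit <- lm(U ~ times)
  slope <- coef(fit)[[2]]
  if (sqrt(mean(fit$residuals^2)) < 1e-10) {
    # exact linear data: the t-test is degenerate, decide on the slope alone
    if (abs(slope) < 1e-10) return("no_change")
    return(if (slope > 0) "increase" else "decrease")
  }
  p <- summary(fit)$coefficients[2, 4]
  if (is.na(p) || p >= p_threshold) return("no_change")
  if (slope > 0) "increase" else "decrease"
}
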