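# Model comparison: per-subject Bayes factors, group-level positive
# evidence ratios, the posterior-sd convergence filter, and the
# initialisation sensitivity scan.

#' Bayes factor between two fitted candidates
#'
#' `BF = exp(log evidence ref - log evidence alt)`. Following the standard
#' evidence scale, `BF >= 3` counts as positive (substantial) evidence for
#' the reference candidate, `BF <= 1/3` for the alternative; anything in
#' between is inconclusive.
#'
#' When a sigmoid-link use candidate meets a linear-link one, the sigmoid
#' fit's evidence (computed for the logit-transformed targets) is corrected
#' by the log Jacobian of the logit so that both evidences are densities of
#' the same observed use values; within a link the correction cancels.
#'
#' @param fit_ref,fit_alt `posterior_fit`s of two candidates for the same
#'   series and the same target variable.
#' @param subject_id Optional identifier carried into the outcome.
#' @return One-row data frame with columns `subject_id`, `ref_id`,
#'   `alt_id`, `log_bf`, `bf`, `verdict` (`"ref_positive"`,
#'   `"alt_positive"` or `"inconclusive"`).
#' @export
bayes_factor <- function(fit_ref, fit_alt, subject_id = NA_character_) {
  tr <- candidate_info(fit_ref$candidate_id)$target
  ta <- candidate_info(fit_alt$candidate_id)$target
  if (tr != ta) stop("cannot compare candidates with different targets")
  log_bf <- (fit_ref$log_evidence + fit_ref$log_jacobian) -
    (fit_alt$log_evidence + fit_alt$log_jacobian)
  if (!is.finite(log_bf)) {
    verdict <- "inconclusive"
    bf <- NA_real_
  } else {
    bf <- exp(log_bf)
    # decide on the log scale so that a factor of exactly 3 counts as
    # positive evidence despite floating-point rounding of exp()
    verdict <- if (log_bf >= log(3) - 1e-12) "ref_positive"
    else if (log_bf <= -log(3) + 1e-12) "alt_positive"
    else "inconclusive"
  }
  data.frame(subject_id = subject_id, ref_id = fit_ref$candidate_id,
             alt_id = fit_alt$candidate_id, log_bf = log_bf, bf = bf,
             verdict = verdict, stringsAsFactors = FALSE)
}

#' Compare two candidates across a fitted cohort
#'
#' @param fits A `cohort_fits` object (see [fit_cohort()]).
#' @param ref_id,alt_id Candidate ids present in `fits`.
#' @return Data frame of [bayes_factor()] outcomes, one row per series.
#' @export
compare_candidates <- function(fits, ref_id, alt_id) {
  stopifnot(inherits(fits, "cohort_fits"))
  out <- do.call(rbind, lapply(seq_len(nrow(fits$keys)), function(i) {
    bayes_factor(fits$fits[[i]][[ref_id]], fits$fits[[i]][[alt_id]],
                 subject_id = fits$keys$subject_id[i])
  }))
  rownames(out) <- NULL
  out
}

#' Positive evidence ratio of a set of pairwise comparisons
#'
#' Group-level tally `x : y` of the subjects with positive evidence
#' (`BF >= 3`) for the reference and for the alternative candidate; the
#' remaining `N - (x + y)` subjects are undecided.
#'
#' @param outcomes Data frame of [bayes_factor()] outcomes, one per
#'   subject.
#' @return One-row data frame with `ref_id`, `alt_id`, `x`, `y`,
#'   `undecided`, `N` and a formatted `ratio` string.
#' @export
positive_evidence_ratio <- function(outcomes) {
  if (anyDuplicated(outcomes$subject_id)) {
    stop("duplicate subjects in comparison outcomes")
  }
  x <- sum(outcomes$verdict == "ref_positive")
  y <- sum(outcomes$verdict == "alt_positive")
  N <- nrow(outcomes)
  data.frame(ref_id = outcomes$ref_id[1], alt_id = outcomes$alt_id[1],
             x = x, y = y, undecided = N - x - y, N = N,
             ratio = sprintf("%d:%d", x, y), stringsAsFactors = FALSE)
}

#' Positive-evidence-ratio table of a reference against its whole family
#'
#' @param fits A `cohort_fits`.
#' @param ref_id Reference candidate.
#' @param alt_ids Alternatives (default: every other fitted candidate with
#'   the same target).
#' @return Data frame with one [positive_evidence_ratio()] row per
#'   alternative.
#' @export
per_table <- function(fits, ref_id, alt_ids = NULL) {
  if (is.null(alt_ids)) {
    tgt <- candidate_info(ref_id)$target
    fam <- candidate_models(tgt)$id
    alt_ids <- setdiff(intersect(fam, fits$candidate_ids), ref_id)
  }
  out <- do.call(rbind, lapply(alt_ids, function(aid) {
    positive_evidence_ratio(compare_candidates(fits, ref_id, aid))
  }))
  rownames(out) <- NULL
  out
}

#' Filter fits by posterior-width convergence
#'
#' With very short series, evidence maximisation sometimes leaves the
#' parameter posterior nearly flat. A fit counts as well converged when
#' every posterior standard deviation is below its cut-off; under
#' `cutoffs = "auto"` the cut-off for each parameter is the standard
#' deviation, across subjects, of that parameter's posterior means (a flat
#' posterior is wider than the between-subject spread of the estimates).
#'
#' @param fits List of `posterior_fit`s for the same candidate (or a
#'   `cohort_fits` restricted via `candidate_id`).
#' @param cutoffs `"auto"`, or a numeric vector of per-parameter cut-offs.
#' @param candidate_id Required when `fits` is a `cohort_fits`.
#' @return List with `kept` (the retained fits), `keep` (logical vector),
#'   and `cutoffs` (the cut-offs used).
#' @export
convergence_filter <- function(fits, cutoffs = "auto", candidate_id = NULL) {
  if (inherits(fits, "cohort_fits")) {
    if (is.null(candidate_id)) stop("supply 'candidate_id' for cohort_fits input")
    fits <- lapply(fits$fits, function(ff) ff[[candidate_id]])
  }
  ids <- unique(vapply(fits, function(f) f$candidate_id, character(1)))
  if (length(ids) != 1L) stop("all fits must be for the same candidate")
  sds <- do.call(rbind, lapply(fits, function(f) f$posterior_sd))
  means <- do.call(rbind, lapply(fits, function(f) f$mN))
  if (identical(cutoffs, "auto")) {
    if (length(fits) < 2L) stop("'auto' cut-offs need at least 2 fits")
    cutoffs <- apply(means, 2L, sd)
  }
  if (length(cutoffs) != ncol(sds)) {
    stop("need one cut-off per parameter")
  }
  keep <- apply(sds, 1L, function(s) all(s < cutoffs))
  list(kept = fits[keep], keep = keep,
       cutoffs = setNames(as.numeric(cutoffs),
                          fits[[1]]$param_names))
}

#' Sensitivity of the model ranking to the noise-precision initialisation
#'
#' Refits the cohort over a grid of initial noise precisions (beta) and
#' reports, per competitor, the group median of the log Bayes factor of the
#' reference candidate. Medians are used because non-converged fits can
#' produce extreme evidence values; optionally those fits are excluded.
#'
#' @param x A `cohort`.
#' @param ref_id Reference candidate.
#' @param alt_ids Competitors (default: rest of the reference's family).
#' @param noise_precision0_grid Positive grid of initial noise precisions.
#' @param prior_precision0 Initial prior precision (alpha), fixed across
#'   the scan.
#' @param exclude_nonconverged Drop series whose ref or alt fit did not
#'   converge before taking the median.
#' @param ... Passed to [fit_cohort()].
#' @return Data frame with `noise_precision0`, `alt_id`, `median_log_bf`,
#'   `n_used`.
#' @export
sensitivity_scan <- function(x, ref_id, alt_ids = NULL,
                             noise_precision0_grid = 10^seq(-8, -3),
                             prior_precision0 = 1e-11,
                             exclude_nonconverged = TRUE, ...) {
  if (any(noise_precision0_grid <= 0)) stop("grid must be positive")
  if (is.null(alt_ids)) {
    fam <- candidate_models(candidate_info(ref_id)$target)$id
    alt_ids <- setdiff(fam, ref_id)
  }
  rows <- list()
  for (b0 in noise_precision0_grid) {
    fits <- fit_cohort(x, candidate_ids = c(ref_id, alt_ids),
                       prior_precision0 = prior_precision0,
                       noise_precision0 = b0, ...)
    for (aid in alt_ids) {
      cmp <- compare_candidates(fits, ref_id, aid)
      use <- rep(TRUE, nrow(cmp))
      if (exclude_nonconverged) {
        conv <- vapply(seq_len(nrow(fits$keys)), function(i) {
          fits$fits[[i]][[ref_id]]$converged && fits$fits[[i]][[aid]]$converged
        }, logical(1))
        if (any(conv)) use <- conv
      }
      rows[[length(rows) + 1L]] <- data.frame(
        noise_precision0 = b0, alt_id = aid,
        median_log_bf = median(cmp$log_bf[use]), n_used = sum(use),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
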