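# Score transforms: WMFT time -> normalised function, MAL AOU items ->
# normalised use, and series assembly on the trial visit schedule.

#' Visit labels of the measurement schedule
#'
#' Nine visits: pre/post the two-week therapy window at randomisation
#' (`Pre1`, `Post1`), follow-ups at 4 and 8 months, pre/post the delayed
#' therapy window at one year (`Pre2`, `Post2`), and follow-ups at 16, 20
#' and 24 months.
#'
#' @return Character vector of the nine visit labels, in schedule order.
#' @export
visit_labels <- function() {
  c("Pre1", "Post1", "M4", "M8", "Pre2", "Post2", "M16", "M20", "M24")
}

#' Convert a WMFT time score to normalised arm function
#'
#' The Wolf Motor Function Test time score (seconds, summed over 15 tasks,
#' 120 s charged per failed task) is long-tailed; the negated natural
#' logarithm is taken so that a good (fast) score maps to high function, then
#' the value is scaled to \[0, 1\] by the dataset-wide range of the negated
#' log scores.
#'
#' @param wmft_seconds Positive time score(s) in seconds, at most 1800
#'   (15 tasks x 120 s cap).
#' @param ref_neglog_min,ref_neglog_max Dataset-wide minimum and maximum of
#'   `-log(wmft_seconds)`; the normalisation reference range.
#' @param clamp If `TRUE`, values falling outside the reference range are
#'   clamped to \[0, 1\] instead of raising an error.
#' @return Normalised function score(s) in \[0, 1\]; 1 = excellent function.
#' @seealso [function_to_wmft()] for the inverse, [aou_to_use()].
#' @export
wmft_to_function <- function(wmft_seconds, ref_neglog_min, ref_neglog_max,
                             clamp = FALSE) {
  if (!is.numeric(wmft_seconds) || any(!is.finite(wmft_seconds))) {
    stop("'wmft_seconds' must be finite numeric")
  }
  if (any(wmft_seconds <= 0)) stop("WMFT time scores must be positive")
  if (any(wmft_seconds > 15 * 120 + 1e-9)) {
    stop("WMFT time score exceeds the 15 x 120 s maximum")
  }
  if (!(ref_neglog_min < ref_neglog_max)) {
    stop("'ref_neglog_min' must be smaller than 'ref_neglog_max'")
  }
  f <- (-log(wmft_seconds) - ref_neglog_min) / (ref_neglog_max - ref_neglog_min)
  out_of_range <- f < -1e-12 | f > 1 + 1e-12
  if (any(out_of_range)) {
    if (clamp) f <- pmin(1, pmax(0, f))
    else stop("WMFT score outside the normalisation reference range; ",
              "set clamp = TRUE to clip")
  }
  pmin(1, pmax(0, f))
}

#' Invert the function normalisation back to a WMFT time score
#'
#' @param f Normalised function score(s) in \[0, 1\].
#' @inheritParams wmft_to_function
#' @return WMFT time score(s) in seconds.
#' @export
function_to_wmft <- function(f, ref_neglog_min, ref_neglog_max) {
  if (any(f < -1e-12 | f > 1 + 1e-12)) stop("'f' must lie in [0, 1]")
  exp(-(f * (ref_neglog_max - ref_neglog_min) + ref_neglog_min))
}

#' Convert MAL AOU item ratings to normalised arm use
#'
#' The Motor Activity Log Amount of Use rates spontaneous use of the paretic
#' arm over 30 activities of daily living, each from 0 (no use) to 5
#' (normal) in 0.5 steps. Use is the item mean rescaled to \[0, 1\].
#'
#' @param items Numeric vector of 30 ratings, or a matrix with 30 columns
#'   (one row per assessment).
#' @return Normalised use in \[0, 1\] (one value per assessment).
#' @export
aou_to_use <- function(items) {
  if (is.matrix(items) || is.data.frame(items)) {
    items <- as.matrix(items)
    if (ncol(items) != 30L) stop("AOU assessments must have exactly 30 items")
    return(apply(items, 1L, aou_to_use))
  }
  if (length(items) != 30L) stop("AOU assessments must have exactly 30 items")
  if (any(!is.finite(items)) || any(items < 0 | items > 5)) {
    stop("AOU ratings must lie in [0, 5]")
  }
  if (any(abs(items * 2 - round(items * 2)) > 1e-9)) {
    stop("AOU ratings must be on the 0.5 grid")
  }
  mean(items) / 5
}

#' Synthesise a 30-item AOU rating vector with a given mean use
#'
#' Inverse of [aou_to_use()] up to the granularity of the 0.5 rating grid:
#' the returned items lie on the grid and their normalised mean is within
#' 1/600 of `u`.
#'
#' @param u Normalised use in \[0, 1\].
#' @return Numeric vector of 30 ratings on the 0.5 grid.
#' @export
use_to_aou <- function(u) {
  if (length(u) != 1L || !is.finite(u) || u < 0 || u > 1) {
    stop("'u' must be a single value in [0, 1]")
  }
  # total of doubled ratings is an integer in 0..300
  k <- round(u * 300)
  items2 <- rep(k %/% 30L, 30L)
  rem <- k %% 30L
  if (rem > 0L) items2[seq_len(rem)] <- items2[seq_len(rem)] + 1L
  items2 / 2
}

#' Construct a subject series
#'
#' A `subject_series` holds one subject's normalised function `F` and use
#' `U` trajectories on the 4-month analysis grid, together with the group
#' and therapy phase.
#'
#' @param subject_id Identifier string.
#' @param group `"immediate"` or `"delayed"`.
#' @param phase `"post"` (after therapy) or `"pre"` (delayed group only).
#' @param times Months since the first retained point; strictly increasing
#'   with step 4.
#' @param F,U Numeric vectors in \[0, 1\], same length as `times`.
#' @return An object of class `subject_series`.
#' @export
subject_series <- function(subject_id, group = c("immediate", "delayed"),
                           phase = c("post", "pre"), times, F, U) {
  group <- match.arg(group)
  phase <- match.arg(phase)
  n <- length(times)
  if (length(F) != n || length(U) != n) {
    stop("'times', 'F' and 'U' must have equal length")
  }
  if (n < 2L) stop("a subject series needs at least 2 points")
  if (any(!is.finite(F)) || any(F < -1e-12 | F > 1 + 1e-12)) {
    stop("'F' must lie in [0, 1]")
  }
  if (any(!is.finite(U)) || any(U < -1e-12 | U > 1 + 1e-12)) {
    stop("'U' must lie in [0, 1]")
  }
  if (any(abs(diff(times) - 4) > 1e-9)) {
    stop("'times' must increase in steps of 4 months")
  }
  if (group == "immediate" && phase == "pre") {
    stop("the immediate group has no pre-therapy series")
  }
  structure(
    list(subject_id = as.character(subject_id), group = group, phase = phase,
         times = as.numeric(times),
         F = pmin(1, pmax(0, as.numeric(F))),
         U = pmin(1, pmax(0, as.numeric(U)))),
    class = "subject_series")
}

#' @export
print.subject_series <- function(x, ...) {
  cat(sprintf("<subject_series> %s (%s, %s): %d points over %g months\n",
              x$subject_id, x$group, x$phase, length(x$times),
              max(x$times) - min(x$times)))
  print(data.frame(time = x$times, F = round(x$F, 4), U = round(x$U, 4)))
  invisible(x)
}

#' Dataset-wide normalisation range of negated log WMFT scores
#'
#' @param wmft_seconds All WMFT time scores entering the analysis.
#' @return Named list with `neglog_min` and `neglog_max`.
#' @export
neglog_range <- function(wmft_seconds) {
  v <- -log(wmft_seconds)
  if (any(!is.finite(v))) stop("WMFT time scores must be positive and finite")
  list(neglog_min = min(v), neglog_max = max(v))
}

#' Assemble one subject's analysis series from raw visits
#'
#' Applies the normalisation and schedule rules: for the immediate group the
#' randomisation baseline `Pre1` is dropped and the one-year pair
#' `Pre2`/`Post2` (which brackets no therapy for this group) is averaged,
#' giving 7 points spaced 4 months. For the delayed group the pair
#' `Pre1`/`Post1` is averaged, giving a 4-point pre-therapy series
#' (`mean(Pre1, Post1)`, `M4`, `M8`, `Pre2`) and a 4-point post-therapy
#' series (`Post2`, `M16`, `M20`, `M24`). Averaging is done on the
#' normalised values.
#'
#' @param visits Data frame for one subject with columns `visit`,
#'   `wmft_seconds` and 30 AOU item columns `aou_01` ... `aou_30` (or a
#'   single pre-normalised `use` column).
#' @param group `"immediate"` or `"delayed"`.
#' @param ref Normalisation reference, as returned by [neglog_range()].
#' @param subject_id Identifier; defaults to `visits$subject_id[1]`.
#' @param clamp Passed to [wmft_to_function()].
#' @return A `subject_series` (immediate group) or a list with elements
#'   `pre` and `post` (delayed group).
#' @export
assemble_series <- function(visits, group = c("immediate", "delayed"), ref,
                            subject_id = NULL, clamp = FALSE) {
  group <- match.arg(group)
  if (is.null(subject_id)) subject_id <- as.character(visits$subject_id[1])
  labs <- visit_labels()
  missing <- setdiff(labs, visits$visit)
  if (length(missing) > 0L) {
    stop(sprintf("subject %s excluded: missing visit(s) %s",
                 subject_id, paste(missing, collapse = ", ")))
  }
  visits <- visits[match(labs, visits$visit), , drop = FALSE]
  f <- wmft_to_function(visits$wmft_seconds, ref$neglog_min, ref$neglog_max,
                        clamp = clamp)
  if ("use" %in% names(visits)) {
    u <- visits$use
  } else {
    aou_cols <- sprintf("aou_%02d", 1:30)
    if (!all(aou_cols %in% names(visits))) {
      stop("visits need either a 'use' column or aou_01..aou_30 item columns")
    }
    u <- aou_to_use(visits[, aou_cols])
  }
  names(f) <- names(u) <- labs
  if (group == "immediate") {
    keep <- c("Post1", "M4", "M8", "M16", "M20", "M24")
    F7 <- c(f["Post1"], f["M4"], f["M8"], mean(f[c("Pre2", "Post2")]),
            f[c("M16", "M20", "M24")])
    U7 <- c(u["Post1"], u["M4"], u["M8"], mean(u[c("Pre2", "Post2")]),
            u[c("M16", "M20", "M24")])
    subject_series(subject_id, "immediate", "post",
                   times = seq(0, 24, by = 4), F = F7, U = U7)
  } else {
    Fpre <- c(mean(f[c("Pre1", "Post1")]), f[c("M4", "M8", "Pre2")])
    Upre <- c(mean(u[c("Pre1", "Post1")]), u[c("M4", "M8", "Pre2")])
    Fpost <- f[c("Post2", "M16", "M20", "M24")]
    Upost <- u[c("Post2", "M16", "M20", "M24")]
    list(pre = subject_series(subject_id, "delayed", "pre",
                              times = seq(0, 12, by = 4), F = Fpre, U = Upre),
         post = subject_series(subject_id, "delayed", "post",
                               times = seq(0, 12, by = 4), F = Fpost, U = Upost))
  }
}

#' Assemble a whole cohort from a raw visit table
#'
#' Subjects without a full visit complement are excluded with a message;
#' only complete cases enter the analysis.
#'
#' @param visits Data frame with a `subject_id` column plus the columns
#'   described in [assemble_series()].
#' @param group Group label applied to every subject, or a named vector
#'   mapping subject id to group.
#' @param ref Normalisation reference; defaults to the range over all rows.
#' @param clamp Passed to [wmft_to_function()].
#' @return A `cohort` object (list of `subject_series` with the
#'   normalisation range attached as an attribute).
#' @export
assemble_cohort <- function(visits, group = "immediate", ref = NULL,
                            clamp = FALSE) {
  if (is.null(ref)) ref <- neglog_range(visits$wmft_seconds)
  ids <- unique(as.character(visits$subject_id))
  series <- list()
  for (id in ids) {
    g <- if (length(group) > 1L) unname(group[[id]]) else group
    sub <- visits[visits$subject_id == id, , drop = FALSE]
    res <- tryCatch(assemble_series(sub, g, ref, subject_id = id, clamp = clamp),
                    error = function(e) {
                      message(conditionMessage(e))
                      NULL
                    })
    if (is.null(res)) next
    if (inherits(res, "subject_series")) {
      series[[length(series) + 1L]] <- res
    } else {
      series[[length(series) + 1L]] <- res$pre
      series[[length(series) + 1L]] <- res$post
    }
  }
  cohort(series, neglog_min = ref$neglog_min, neglog_max = ref$neglog_max)
}

#' Construct a cohort from a list of subject series
#'
#' @param series List of `subject_series` objects.
#' @param neglog_min,neglog_max Optional normalisation reference range kept
#'   with the cohort for raw-score provenance.
#' @param ... Further attributes (e.g. the generating configuration of a
#'   synthetic cohort).
#' @return An object of class `cohort`.
#' @export
cohort <- function(series, neglog_min = NULL, neglog_max = NULL, ...) {
  if (!all(vapply(series, inherits, logical(1), "subject_series"))) {
    stop("'series' must be a list of subject_series objects")
  }
  structure(series, class = "cohort",
            neglog_min = neglog_min, neglog_max = neglog_max, ...)
}

#' @export
print.cohort <- function(x, ...) {
  kinds <- table(vapply(x, function(s) paste(s$group, s$phase), character(1)))
  cat(sprintf("<cohort> %d series, %d subjects (%s)\n", length(x),
              length(unique(vapply(x, function(s) s$subject_id, character(1)))),
              paste(sprintf("%s x %d", names(kinds), kinds), collapse = ", ")))
  invisible(x)
}

#' Keep the medium-to-low-function subgroup of a cohort
#'
#' Subjects whose initial normalised function is below a threshold; used to
#' check that model selection does not hinge on the high-function subjects
#' for whom function and use are strongly correlated.
#'
#' @param x A `cohort`.
#' @param threshold Keep series with `F[1] < threshold` (default 0.5).
#' @return The filtered `cohort`.
#' @export
low_function_subgroup <- function(x, threshold = 0.5) {
  keep <- vapply(x, function(s) s$F[1] < threshold, logical(1))
  cohort(unclass(x)[keep],
         neglog_min = attr(x, "neglog_min"), neglog_max = attr(x, "neglog_max"))
}

#' @export
as.data.frame.cohort <- function(x, ...) {
  do.call(rbind, lapply(unclass(x), function(s) {
    data.frame(subject_id = s$subject_id, group = s$group, phase = s$phase,
               time_months = s$times, F = s$F, U = s$U,
               stringsAsFactors = FALSE)
  }))
}
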