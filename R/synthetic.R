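# Synthetic cohorts: surrogate subjects generated from the candidate
# dynamics with Gaussian noise injected on the regression targets, on the
# clinical visit schedules (7 post-therapy points for the immediate group,
# 4 + 4 around the delayed therapy window).

rtruncnorm1 <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd < 0) stop("'sd' must be non-negative")
  if (sd == 0) {
    if (mean < lo || mean > hi) stop("degenerate distribution outside bounds")
    return(rep(mean, n))
  }
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  if (phi <= plo) stop("empty truncation region")
  qnorm(runif(n, plo, phi), mean, sd)
}

# Generating distributions, one row per parameter: mean, sd, lower, upper.
# The reference triple is centred on the cohort medians reported for the
# fitted model (a 0.64, b 2.20, c 1.40); the remaining candidates get
# distributions chosen to keep trajectories inside [0, 1] with realistic
# spread (synthetic choices, see the methods vignette).
.default_dists <- list(
  F1_fw = list(w = c(0.95, 0.03, 0, 1)),
  F1_uw = list(w = c(0.85, 0.08, 0, 1)),
  F1_weighted = list(a = c(0.64, 0.2, 0, 1)),
  F2_fw_const = list(w = c(0.80, 0.08, 0, 1), k = c(0.10, 0.04, 0, Inf)),
  F2_uw_const = list(w = c(0.70, 0.10, 0, 1), k = c(0.12, 0.05, 0, Inf)),
  F2_fw_uw = list(w1 = c(0.50, 0.10, 0, 1), w2 = c(0.35, 0.10, 0, 1)),
  F3_fw_uw_const = list(w1 = c(0.45, 0.10, 0, 1), w2 = c(0.30, 0.08, 0, 1),
                        k = c(0.08, 0.04, 0, Inf)),
  U_lin_t = list(w = c(0.60, 0.15, 0, 1), k = c(0.15, 0.08, 0, Inf)),
  U_lin_lag = list(w = c(0.60, 0.15, 0, 1), k = c(0.15, 0.08, 0, Inf)),
  U_sig_t = list(b = c(2.20, 1.0, 0, Inf), c = c(1.40, 1.0, -Inf, Inf)),
  U_sig_lag = list(b = c(2.20, 1.0, 0, Inf), c = c(1.40, 1.0, -Inf, Inf)))

#' Configuration of a synthetic cohort
#'
#' Defines the generating candidate pair, the per-subject parameter
#' distributions (independent truncated normals), the target-space noise
#' level, the initial-state distribution and the measurement schedule. The
#' reference-pair defaults centre the parameters on the cohort medians of
#' the fitted model: `a ~ N(0.64, 0.2)` truncated to \[0, 1\],
#' `b ~ N(2.20, 1.0)` truncated to non-negative, `c ~ N(1.40, 1.0)`.
#'
#' @param n_subjects Number of subjects.
#' @param group `"immediate"` (7-point post-therapy series) or `"delayed"`
#'   (4 pre- + 4 post-therapy points).
#' @param function_id,use_id Generating candidates (default: reference
#'   pair).
#' @param param_dists Named list of `c(mean, sd, lower, upper)` vectors,
#'   one per generating parameter; `NULL` uses the built-in defaults for
#'   the chosen candidates.
#' @param therapy_shift Additive change applied to the first use-model
#'   parameter (the confidence slope) in the delayed post-therapy phase.
#' @param noise_sd Standard deviation of the Gaussian noise added to the
#'   regression targets (function values; logit of use for sigmoid
#'   candidates).
#' @param noise_space `"target"` (matches the fitted likelihood) or
#'   `"observation"` (noise added to F and U directly).
#' @param init_range Range of the uniform initial-state distribution for
#'   `F0` and `U0`.
#' @param seed Mandatory integer seed.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_subjects, group = c("immediate", "delayed"),
                         function_id = "F1_weighted", use_id = "U_sig_lag",
                         param_dists = NULL, therapy_shift = 0,
                         noise_sd = 0.05,
                         noise_space = c("target", "observation"),
                         init_range = c(0.1, 0.9), seed) {
  group <- match.arg(group)
  noise_space <- match.arg(noise_space)
  if (missing(seed) || is.null(seed)) stop("'seed' is mandatory")
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  if (is.null(param_dists)) {
    param_dists <- c(.default_dists[[function_id]], .default_dists[[use_id]])
  }
  fun_np <- candidate_info(function_id)$n_params
  use_np <- candidate_info(use_id)$n_params
  if (length(param_dists) != fun_np + use_np) {
    stop("'param_dists' must have one entry per generating parameter")
  }
  structure(list(n_subjects = as.integer(n_subjects), group = group,
                 function_id = function_id, use_id = use_id,
                 param_dists = param_dists, therapy_shift = therapy_shift,
                 noise_sd = noise_sd, noise_space = noise_space,
                 init_range = init_range, seed = as.integer(seed)),
            class = "synth_config")
}

#' Draw per-subject generating parameters
#'
#' One independent truncated-normal draw per configured parameter per
#' subject. Uses the current RNG state; [generate_cohort()] seeds it from
#' the configuration.
#'
#' @param config A [synth_config()].
#' @param n Number of subjects (default from the configuration).
#' @return Data frame, one row per subject, one column per parameter.
#' @export
sample_subject_params <- function(config, n = config$n_subjects) {
  cols <- lapply(config$param_dists, function(d) {
    rtruncnorm1(n, d[1], d[2], d[3], d[4])
  })
  as.data.frame(cols, optional = TRUE)
}

# One noisy series. Noise enters the regression targets: the next F gets
# additive noise (then clipped to [0, 1]); for sigmoid use candidates the
# noise is added to the linear predictor b F - c before the logistic, for
# linear candidates to U itself (clipped).
.simulate_noisy <- function(function_id, fp, use_id, up, F0, U0, n_points,
                            noise_sd, noise_space) {
  lag0 <- candidate_info(use_id)$lag == 0L
  sig <- candidate_info(use_id)$link == "sigmoid"
  F <- numeric(n_points)
  U <- numeric(n_points)
  F[1] <- F0
  U[1] <- U0
  for (t in 2:n_points) {
    fmu <- function_step(function_id, fp, F[t - 1L], U[t - 1L])
    if (noise_space == "target") {
      F[t] <- min(1, max(0, fmu + rnorm(1, 0, noise_sd)))
      Farg <- if (lag0) F[t] else F[t - 1L]
      if (sig) {
        U[t] <- plogis(up[1] * Farg - up[2] + rnorm(1, 0, noise_sd))
      } else {
        U[t] <- min(1, max(0, up[1] * Farg + up[2] + rnorm(1, 0, noise_sd)))
      }
    } else {
      F[t] <- min(1, max(0, fmu + rnorm(1, 0, noise_sd)))
      Farg <- if (lag0) F[t] else F[t - 1L]
      U[t] <- min(1, max(0, use_step(use_id, up, Farg) + rnorm(1, 0, noise_sd)))
    }
  }
  list(F = F, U = U)
}

#' Generate a synthetic cohort
#'
#' Draws per-subject parameters and initial states, iterates the generating
#' candidate pair with target-space Gaussian noise, and assembles the
#' series on the configured schedule. For the delayed group the
#' post-therapy phase continues from the end of the pre-therapy phase with
#' the therapy shift applied to the confidence slope. The true generating
#' parameters are attached as the `true_params` attribute.
#'
#' @param config A [synth_config()].
#' @return A `cohort`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  pars <- sample_subject_params(config, n)
  fun_np <- candidate_info(config$function_id)$n_params
  F0 <- runif(n, config$init_range[1], config$init_range[2])
  U0 <- runif(n, config$init_range[1], config$init_range[2])
  series <- list()
  for (i in seq_len(n)) {
    id <- sprintf("S%03d", i)
    fp <- as.numeric(pars[i, seq_len(fun_np)])
    up <- as.numeric(pars[i, -seq_len(fun_np)])
    if (config$group == "immediate") {
      tr <- .simulate_noisy(config$function_id, fp, config$use_id, up,
                            F0[i], U0[i], 7L, config$noise_sd,
                            config$noise_space)
      series[[length(series) + 1L]] <-
        subject_series(id, "immediate", "post", seq(0, 24, by = 4),
                       tr$F, tr$U)
    } else {
      pre <- .simulate_noisy(config$function_id, fp, config$use_id, up,
                             F0[i], U0[i], 4L, config$noise_sd,
                             config$noise_space)
      up_post <- up
      up_post[1] <- up_post[1] + config$therapy_shift
      # the post-therapy series continues from the pre-therapy endpoint
      post0 <- .simulate_noisy(config$function_id, fp, config$use_id, up_post,
                               pre$F[4], pre$U[4], 5L, config$noise_sd,
                               config$noise_space)
      series[[length(series) + 1L]] <-
        subject_series(id, "delayed", "pre", seq(0, 12, by = 4), pre$F, pre$U)
      series[[length(series) + 1L]] <-
        subject_series(id, "delayed", "post", seq(0, 12, by = 4),
                       post0$F[2:5], post0$U[2:5])
    }
  }
  true_params <- cbind(subject_id = sprintf("S%03d", seq_len(n)), pars,
                       F0 = F0, U0 = U0, stringsAsFactors = FALSE)
  cohort(series, config = config, true_params = true_params)
}

#' Back-fill raw visit records consistent with a normalised cohort
#'
#' Synthesises WMFT time scores and 30-item AOU ratings whose transforms
#' reproduce each series (averaged visit pairs are filled with the shared
#' averaged value). Intended for round-trip testing of the transform and
#' assembly layer; the file names and docs of anything derived from this
#' should mark it as synthetic.
#'
#' @param x A `cohort`.
#' @param ref_neglog_min,ref_neglog_max Normalisation range used to invert
#'   the function transform (defaults: 5 s .. 1800 s).
#' @return Data frame of visits (`subject_id`, `visit`, `wmft_seconds`,
#'   `aou_01` .. `aou_30`) suitable for [assemble_cohort()].
#' @export
synthesize_raw_visits <- function(x, ref_neglog_min = -log(1800),
                                  ref_neglog_max = -log(5)) {
  rows <- list()
  ids <- unique(vapply(unclass(x), function(s) s$subject_id, character(1)))
  for (id in ids) {
    ss <- unclass(x)[vapply(unclass(x), function(s) s$subject_id == id,
                            logical(1))]
    grp <- ss[[1]]$group
    if (grp == "immediate") {
      s <- ss[[1]]
      vals <- rbind(F = s$F, U = s$U)
      per_visit <- list(Pre1 = vals[, 1], Post1 = vals[, 1], M4 = vals[, 2],
                        M8 = vals[, 3], Pre2 = vals[, 4], Post2 = vals[, 4],
                        M16 = vals[, 5], M20 = vals[, 6], M24 = vals[, 7])
    } else {
      phases <- vapply(ss, function(s) s$phase, character(1))
      pre <- ss[phases == "pre"][[1]]
      post <- ss[phases == "post"][[1]]
      per_visit <- list(Pre1 = c(pre$F[1], pre$U[1]),
                        Post1 = c(pre$F[1], pre$U[1]),
                        M4 = c(pre$F[2], pre$U[2]),
                        M8 = c(pre$F[3], pre$U[3]),
                        Pre2 = c(pre$F[4], pre$U[4]),
                        Post2 = c(post$F[1], post$U[1]),
                        M16 = c(post$F[2], post$U[2]),
                        M20 = c(post$F[3], post$U[3]),
                        M24 = c(post$F[4], post$U[4]))
    }
    for (v in names(per_visit)) {
      f <- per_visit[[v]][1]
      u <- per_visit[[v]][2]
      items <- use_to_aou(u)
      row <- data.frame(subject_id = id, visit = v,
                        wmft_seconds = function_to_wmft(f, ref_neglog_min,
                                                        ref_neglog_max),
                        stringsAsFactors = FALSE)
      row[sprintf("aou_%02d", 1:30)] <- as.list(items)
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Model- and parameter-recovery study on surrogate cohorts
#'
#' For each generating candidate: simulate a cohort from it (paired with
#' the reference candidate of the other variable), fit its whole family,
#' tabulate the positive evidence ratio of the generating candidate against
#' every competitor, and summarise recovery of the generating parameters
#' (bias, RMSE, coverage of +/- 2 posterior-sd intervals). Recovery
#' summaries are reported after the posterior-width convergence filter,
#' matching how parameter distributions are reported for real cohorts.
#'
#' @param candidate_ids Generating candidates to study (default: all 11).
#' @param n_subjects,noise_sd Cohort size and target-noise level per
#'   generating candidate.
#' @param seed Base seed; candidate `i` uses `seed + i`.
#' @param apply_filter Apply [convergence_filter()] before the recovery
#'   summaries.
#' @return List with data frames `per` (columns `gen_id`, `alt_id`, `x`,
#'   `y`, `undecided`, `N`, `won`) and `recovery` (columns `gen_id`,
#'   `param`, `n_used`, `bias`, `rmse`, `coverage`).
#' @export
surrogate_study <- function(candidate_ids = candidate_models()$id,
                            n_subjects = 50L, noise_sd = 0.05, seed = 1L,
                            apply_filter = TRUE) {
  per_rows <- list()
  rec_rows <- list()
  for (i in seq_along(candidate_ids)) {
    gid <- candidate_ids[i]
    info <- candidate_info(gid)
    cfg <- if (info$target == "function") {
      synth_config(n_subjects, "immediate", function_id = gid,
                   use_id = "U_sig_lag", noise_sd = noise_sd, seed = seed + i)
    } else {
      synth_config(n_subjects, "immediate", function_id = "F1_weighted",
                   use_id = gid, noise_sd = noise_sd, seed = seed + i)
    }
    coh <- generate_cohort(cfg)
    fam <- candidate_models(info$target)$id
    fits <- fit_cohort(coh, candidate_ids = fam)
    per <- per_table(fits, gid)
    per_rows[[length(per_rows) + 1L]] <-
      cbind(gen_id = gid, per[, c("alt_id", "x", "y", "undecided", "N")],
            won = per$x > per$y, stringsAsFactors = FALSE)
    # recovery of the generating parameters from the generating candidate fit
    gfits <- lapply(fits$fits, function(ff) ff[[gid]])
    keep <- rep(TRUE, length(gfits))
    if (apply_filter && length(gfits) >= 2L) {
      keep <- convergence_filter(gfits)$keep
    }
    true <- attr(coh, "true_params")
    fun_np <- candidate_info(cfg$function_id)$n_params
    pcols <- if (info$target == "function") seq_len(fun_np)
    else fun_np + seq_len(candidate_info(cfg$use_id)$n_params)
    pnames <- candidate_param_names(gid)
    for (j in seq_along(pnames)) {
      est <- vapply(gfits, function(f) f$mN[j], numeric(1))
      sds <- vapply(gfits, function(f) f$posterior_sd[j], numeric(1))
      tru <- true[[names(true)[1 + pcols[j]]]]
      err <- (est - tru)[keep]
      cov <- mean((abs(est - tru) <= 2 * sds)[keep])
      rec_rows[[length(rec_rows) + 1L]] <- data.frame(
        gen_id = gid, param = pnames[j], n_used = sum(keep),
        bias = mean(err), rmse = sqrt(mean(err^2)), coverage = cov,
        stringsAsFactors = FALSE)
    }
  }
  list(per = do.call(rbind, per_rows), recovery = do.call(rbind, rec_rows))
}
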