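# Candidate model family: seven update rules for arm function and four for
# arm use, including the coupled reference pair, plus forward simulation.

.fun_ids <- c("F1_fw", "F1_uw", "F1_weighted", "F2_fw_const", "F2_uw_const",
              "F2_fw_uw", "F3_fw_uw_const")
.use_ids <- c("U_lin_t", "U_lin_lag", "U_sig_t", "U_sig_lag")

.candidates <- data.frame(
  id = c(.fun_ids, .use_ids),
  target = c(rep("function", 7L), rep("use", 4L)),
  link = c(rep("linear", 7L), "linear", "linear", "sigmoid", "sigmoid"),
  lag = c(rep(1L, 7L), 0L, 1L, 0L, 1L),
  n_params = c(1L, 1L, 1L, 2L, 2L, 2L, 3L, 2L, 2L, 2L, 2L),
  reference = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE,
                FALSE, FALSE, FALSE, TRUE),
  params = c("w", "w", "a", "w,k", "w,k", "w1,w2", "w1,w2,k",
             "w,k", "w,k", "b,c", "b,c"),
  formula = c("w F(t-1)", "w U(t-1)", "(1-a) F(t-1) + a U(t-1)",
              "w F(t-1) + k", "w U(t-1) + k", "w1 F(t-1) + w2 U(t-1)",
              "w1 F(t-1) + w2 U(t-1) + k",
              "w F(t) + k", "w F(t-1) + k",
              "sigma(b F(t) - c)", "sigma(b F(t-1) - c)"),
  stringsAsFactors = FALSE)

#' The candidate model family
#'
#' Seven update rules for arm function `F(t)` (combinations of previous
#' function, previous use and a constant, with 1 to 3 free parameters) and
#' four for arm use `U(t)` (linear or sigmoidal in current or previous
#' function). The reference pair is the 1-parameter weighted-average
#' function rule and the sigmoid-of-lagged-function use rule.
#'
#' @param target `"all"`, `"function"` or `"use"`.
#' @return Data frame with columns `id`, `target`, `link`, `lag`,
#'   `n_params`, `reference`, `params` (comma-separated parameter names)
#'   and `formula`.
#' @export
candidate_models <- function(target = c("all", "function", "use")) {
  target <- match.arg(target)
  if (target == "all") .candidates
  else .candidates[.candidates$target == target, , drop = FALSE]
}

candidate_info <- function(id) {
  i <- match(id, .candidates$id)
  if (is.na(i)) stop("unknown candidate model id: ", id)
  as.list(.candidates[i, ])
}

candidate_param_names <- function(id) {
  strsplit(candidate_info(id)$params, ",", fixed = TRUE)[[1]]
}

check_params <- function(info, params) {
  p <- as.numeric(params)
  if (length(p) != info$n_params) {
    stop(sprintf("model %s takes %d parameter(s), got %d",
                 info$id, info$n_params, length(p)))
  }
  p
}

#' Reference model parameters
#'
#' Bundles the three parameters of the coupled reference model: the use
#' effect rate `a` (so `1 - a` is the per-step decay of function), the
#' confidence slope `b` of the sigmoidal decision rule, and the competition
#' bias `c` absorbing the (constant) function of the non-affected arm.
#'
#' @param a,b,c Numeric scalars. The interpretable regime is `a` in
#'   \[0, 1\]; values outside it are accepted but flagged via the
#'   `interpretable` attribute (fits can land there).
#' @return Object of class `model_params`.
#' @export
model_params <- function(a, b, c) {
  stopifnot(is.finite(a), is.finite(b), is.finite(c))
  structure(list(a = a, b = b, c = c), class = "model_params",
            interpretable = (a >= 0 && a <= 1))
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<model_params> a = %.4g, b = %.4g, c = %.4g%s\n", x$a, x$b, x$c,
              if (attr(x, "interpretable")) "" else "  [a outside [0, 1]]"))
  invisible(x)
}

#' One step of a function update rule
#'
#' @param model_id Candidate id with target `"function"` (see
#'   [candidate_models()]).
#' @param params Parameter vector of the length the candidate requires.
#' @param F_prev,U_prev Previous function and use (vectors recycle).
#' @return Updated function value(s).
#' @export
function_step <- function(model_id, params, F_prev, U_prev = NULL) {
  info <- candidate_info(model_id)
  if (info$target != "function") stop(model_id, " is not a function model")
  p <- check_params(info, params)
  needs_u <- model_id %in% c("F1_uw", "F1_weighted", "F2_uw_const",
                             "F2_fw_uw", "F3_fw_uw_const")
  if (needs_u && is.null(U_prev)) stop(model_id, " requires U_prev")
  switch(model_id,
         F1_fw = p[1] * F_prev,
         F1_uw = p[1] * U_prev,
         F1_weighted = (1 - p[1]) * F_prev + p[1] * U_prev,
         F2_fw_const = p[1] * F_prev + p[2],
         F2_uw_const = p[1] * U_prev + p[2],
         F2_fw_uw = p[1] * F_prev + p[2] * U_prev,
         F3_fw_uw_const = p[1] * F_prev + p[2] * U_prev + p[3])
}

#' One step of a use update rule
#'
#' @param model_id Candidate id with target `"use"`.
#' @param params Parameter vector (`(w, k)` for linear rows, `(b, c)` for
#'   sigmoid rows).
#' @param F_arg Function value entering the rule: `F(t)` for lag-0
#'   candidates, `F(t-1)` for lag-1 candidates.
#' @return Updated use value(s); sigmoid rows stay in (0, 1).
#' @export
use_step <- function(model_id, params, F_arg) {
  info <- candidate_info(model_id)
  if (info$target != "use") stop(model_id, " is not a use model")
  p <- check_params(info, params)
  if (info$link == "sigmoid") plogis(p[1] * F_arg - p[2])
  else p[1] * F_arg + p[2]
}

#' Simulate the coupled function--use map
#'
#' Iterates the function rule and the use rule from an initial state. With
#' the reference pair and `a` in \[0, 1\] the trajectory is confined to
#' \[0, 1\] in both variables. Lag-0 use rules read the function value just
#' computed at the current step; lag-1 rules read the previous one.
#'
#' @param params A [model_params()] object (reference pair), or `NULL` when
#'   passing `function_params`/`use_params` explicitly.
#' @param F0,U0 Initial state.
#' @param n_steps Number of 4-month steps (>= 1).
#' @param function_id,use_id Candidate ids (default: the reference pair).
#' @param function_params,use_params Explicit parameter vectors overriding
#'   `params`.
#' @param hold_use Optional fixed value for `U` (degenerate hook: with
#'   `hold_use = 0` function decays geometrically with factor `1 - a`).
#' @return Data frame with columns `step` (0-based), `time` (months),
#'   `F`, `U`.
#' @export
simulate_trajectory <- function(params = NULL, F0, U0, n_steps,
                                function_id = "F1_weighted",
                                use_id = "U_sig_lag",
                                function_params = NULL, use_params = NULL,
                                hold_use = NULL) {
  if (n_steps < 1L) stop("'n_steps' must be at least 1")
  if (is.null(function_params)) {
    if (is.null(params)) stop("provide 'params' or explicit parameter vectors")
    function_params <- params$a
  }
  if (is.null(use_params)) {
    if (is.null(params)) stop("provide 'params' or explicit parameter vectors")
    use_params <- c(params$b, params$c)
  }
  lag0 <- candidate_info(use_id)$lag == 0L
  F <- numeric(n_steps + 1L)
  U <- numeric(n_steps + 1L)
  F[1] <- F0
  U[1] <- if (is.null(hold_use)) U0 else hold_use
  for (t in seq_len(n_steps)) {
    F[t + 1L] <- function_step(function_id, function_params, F[t], U[t])
    U[t + 1L] <- if (is.null(hold_use)) {
      use_step(use_id, use_params, if (lag0) F[t + 1L] else F[t])
    } else hold_use
  }
  data.frame(step = 0:n_steps, time = 4 * (0:n_steps), F = F, U = U)
}
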