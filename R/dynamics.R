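# Dynamics of the coupled reference map: fixed points and their stability,
# saddle-node limit points, and one-parameter bifurcation diagrams.
#
# Fixed points satisfy sigma(b F* - c) = F* (and U* = F*: with the
# single-parameter function rule, function and use coincide at steady
# state). The Jacobian of the coupled map at a fixed point is
# [[1 - a, a], [b U*(1 - U*), 0]]; a fold (limit point) occurs where the
# sigmoid branch is tangent to the identity, i.e. b sigma'(b F - c) = 1,
# which at a fixed point reduces to b F (1 - F) = 1.

#' Fixed points of the coupled reference map
#'
#' Locates all roots of `g(F) = sigma(b F - c) - F` on \[0, 1\] by a dense
#' sign-change scan refined with bisection, and classifies each by the
#' spectral radius of the coupled-map Jacobian. The fixed-point set depends
#' only on `(b, c)`; `a` affects stability and transients only.
#'
#' @param params A [model_params()], or anything with `$a`, `$b`, `$c`.
#' @param tol Root tolerance.
#' @param grid_n Scan resolution (>= 1000).
#' @return Data frame with columns `F_star`, `U_star`, `spectral_radius`,
#'   `stability` (`"stable"`, `"unstable"` or `"neutral"`).
#' @export
fixed_points <- function(params, tol = 1e-10, grid_n = 2000L) {
  a <- params$a
  b <- params$b
  c <- params$c
  if (a <= 0 || a > 1) stop("'a' must lie in (0, 1] for stability analysis")
  g <- function(F) plogis(b * F - c) - F
  xs <- seq(0, 1, length.out = max(1000L, grid_n))
  gs <- g(xs)
  n <- length(xs)
  hits <- which(gs[-n] == 0 | gs[-n] * gs[-1L] < 0)
  roots <- vapply(hits, function(i) {
    if (gs[i] == 0) xs[i] else uniroot(g, c(xs[i], xs[i + 1L]), tol = tol)$root
  }, numeric(1))
  if (gs[n] == 0) roots <- c(roots, 1)
  roots <- sort(roots)
  if (length(roots) > 1L) {
    roots <- roots[c(TRUE, diff(roots) > 50 * max(tol, 1e-9))]
  }
  out <- do.call(rbind, lapply(roots, function(Fs) {
    Us <- plogis(b * Fs - c)
    J <- rbind(c(1 - a, a), c(b * Us * (1 - Us), 0))
    rho <- max(Mod(eigen(J, only.values = TRUE)$values))
    data.frame(F_star = Fs, U_star = Us, spectral_radius = rho,
               stability = if (abs(rho - 1) < 1e-6) "neutral"
               else if (rho < 1) "stable" else "unstable",
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Fold branch: at a tangency, F(1 - F) = 1/b (requires b >= 4) and
# c = b F - logit(F). `upper` selects the F > 1/2 branch.
.fold_c_of_b <- function(b, upper) {
  disc <- sqrt(pmax(0, 1 - 4 / b))
  F <- (1 + (if (upper) disc else -disc)) / 2
  list(F = F, c = b * F - qlogis(F))
}

#' Saddle-node limit points of the map for a fixed bias
#'
#' Solves the tangency system `sigma(b F - c) = F`,
#' `b sigma'(b F - c) = 1` by one-dimensional continuation along the two
#' analytic fold branches `F = (1 +/- sqrt(1 - 4/b)) / 2`,
#' `c = b F - logit(F)` (the branches exist only for `b >= 4` and merge in
#' a cusp at `b = 4`, `c = 2`, `F = 1/2`, forced by the sigmoid's maximal
#' slope of 1/4). For a given `c` the fold locations in `b` are found by a
#' sign-change scan plus root refinement on each branch.
#'
#' @param c Competition bias at which to locate folds.
#' @param b_range Positive range of confidence slopes to search.
#' @param tol Root tolerance in `b`.
#' @param grid_n Scan resolution along `b`.
#' @return Data frame with columns `b_lp`, `c_lp`, `F_lp`, `branch`
#'   (`"low"`/`"high"` state at the fold); zero rows when no fold exists in
#'   range.
#' @export
limit_points <- function(c, b_range = c(1, 60), tol = 1e-9, grid_n = 4000L) {
  if (any(b_range <= 0)) stop("'b_range' must be positive")
  lo <- max(4, min(b_range))
  hi <- max(b_range)
  out <- list()
  if (hi >= 4) {
    # degenerate cusp: both branches meet at b = 4, c = 2
    if (abs(c - 2) < 1e-12 && lo <= 4) {
      return(data.frame(b_lp = 4, c_lp = 2, F_lp = 0.5, branch = "cusp",
                        stringsAsFactors = FALSE))
    }
    bs <- seq(lo + 1e-12, hi, length.out = grid_n)
    for (upper in c(FALSE, TRUE)) {
      h <- function(b) .fold_c_of_b(b, upper)$c - c
      hs <- h(bs)
      for (i in seq_len(length(bs) - 1L)) {
        if (hs[i] == 0) {
          b_lp <- bs[i]
        } else if (sign(hs[i]) * sign(hs[i + 1L]) < 0) {
          b_lp <- uniroot(h, c(bs[i], bs[i + 1L]), tol = tol)$root
        } else {
          next
        }
        br <- .fold_c_of_b(b_lp, upper)
        out[[length(out) + 1L]] <- data.frame(
          b_lp = b_lp, c_lp = c, F_lp = br$F,
          branch = if (upper) "high" else "low", stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(b_lp = numeric(0), c_lp = numeric(0), F_lp = numeric(0),
                      branch = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, out)
  out <- out[order(out$b_lp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Asymptotic state of the coupled map by forward simulation
#'
#' Iterates until the state moves less than `tol` per step or the horizon
#' is reached (recovery time constants can exceed the two-year observation
#' window, so the horizon is long).
#'
#' @param params A [model_params()].
#' @param F0,U0 Initial state.
#' @param max_steps Simulation horizon.
#' @param tol Per-step convergence tolerance.
#' @return Named list with `F`, `U` and `converged`.
#' @export
asymptotic_state <- function(params, F0, U0, max_steps = 10000L, tol = 1e-10) {
  F <- F0
  U <- U0
  converged <- FALSE
  for (i in seq_len(max_steps)) {
    Fn <- (1 - params$a) * F + params$a * U
    Un <- plogis(params$b * F - params$c)
    if (abs(Fn - F) < tol && abs(Un - U) < tol) {
      F <- Fn
      U <- Un
      converged <- TRUE
      break
    }
    F <- Fn
    U <- Un
  }
  list(F = F, U = U, converged = converged)
}

#' Bifurcation diagram of asymptotic arm function over the confidence slope
#'
#' Tabulates the fixed-point branches (with stability) over a grid of
#' confidence slopes `b`, for one or more values of the competition bias
#' `c`. Optionally adds the asymptotic function reached by forward
#' simulation from a low and a high initial state, which land on the stable
#' branches and, in a bistable window, on two different ones.
#'
#' @param c_values Competition-bias values (one curve per value).
#' @param b_grid Grid of confidence slopes.
#' @param a Use-effect rate (affects stability and simulation, not the
#'   branch locations).
#' @param simulate If `TRUE`, append columns `F_low`/`F_high` from forward
#'   simulation at `F0 = U0 = 0.05` and `0.95`.
#' @param ... Passed to [fixed_points()].
#' @return Data frame with columns `c`, `b`, `F_star`, `stability` (one
#'   row per branch) and, with `simulate`, the asymptotic columns.
#' @export
bifurcation_diagram <- function(c_values, b_grid, a = 0.6, simulate = FALSE,
                                ...) {
  rows <- list()
  for (cv in c_values) {
    for (b in b_grid) {
      fp <- fixed_points(model_params(a, b, cv), ...)
      block <- data.frame(c = cv, b = b, F_star = fp$F_star,
                          stability = fp$stability, stringsAsFactors = FALSE)
      if (simulate) {
        block$F_low <- asymptotic_state(model_params(a, b, cv), 0.05, 0.05)$F
        block$F_high <- asymptotic_state(model_params(a, b, cv), 0.95, 0.95)$F
      }
      rows[[length(rows) + 1L]] <- block
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
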