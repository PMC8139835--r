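#' Full state at gate steady state for a given voltage
#'
#' @param p A `v1r_params` object.
#' @param V Membrane voltage (mV).
#' @param s_frozen Value imposed on the slow-inactivation gate when it is
#'   treated as a frozen parameter of the fast subsystem; defaults to its
#'   steady state when slow inactivation is enabled, 1 otherwise.
#' @return Named numeric state vector `(V, m, h, mp, s, n, hA)`.
#' @export
steady_state_at <- function(p, V, s_frozen = NULL) {
  g <- p$gates
  s <- if (!is.null(s_frozen)) s_frozen
       else if (p$include_slow_inactivation) gate_steady_state(g$s, V) else 1
  c(V = V,
    m = gate_steady_state(g$m, V),
    h = gate_steady_state(g$h, V),
    mp = gate_steady_state(g$mp, V),
    s = s,
    n = gate_steady_state(g$n, V),
    hA = gate_steady_state(g$hA, V))
}

#' Right-hand side of the model equations
#'
#' Membrane equation
#' \deqn{C_{in} dV/dt = G_{in}(V_r - V) + G_{Nat} m^3 h (E_{Na} - V) +
#'   G_{Nap} m_p^3 s (E_{Na} - V) + G_{Kdr} n^3 (E_K - V) +
#'   G_A m_{A\infty}(V) h_A (E_K - V) + I}
#' with first-order gate relaxation \eqn{dx/dt = (x_\infty(V) - x)/\tau_x}.
#' The A-current activation is algebraic (instantaneous); the slow
#' inactivation gate is frozen at its current value unless
#' `include_slow_inactivation` is set.
#'
#' @param state Named state vector as returned by [steady_state_at()].
#' @param p A `v1r_params` object.
#' @return Named vector of time derivatives (mV/ms and 1/ms).
#' @export
model_rhs <- function(state, p) {
  if (any(!is.finite(state))) stop("non-finite state")
  V <- state[["V"]]; m <- state[["m"]]; h <- state[["h"]]
  mp <- state[["mp"]]; s <- state[["s"]]; n <- state[["n"]]
  hA <- state[["hA"]]
  g <- p$gates
  GA <- if (p$include_IA) p$GA else 0
  mAinf <- gate_steady_state(g$mA, V)
  dV <- (p$Gin * (p$Vr - V) +
         p$GNat * m^3 * h * (p$ENa - V) +
         p$GNap * mp^3 * s * (p$ENa - V) +
         p$GKdr * n^3 * (p$EK - V) +
         GA * mAinf * hA * (p$EK - V) +
         p$I) / p$Cin
  ds <- if (p$include_slow_inactivation)
          (gate_steady_state(g$s, V) - s) / g$s$tau else 0
  dhA <- if (p$include_IA)
           (gate_steady_state(g$hA, V) - hA) / g$hA$tau else 0
  c(V = dV,
    m = (gate_steady_state(g$m, V) - m) / g$m$tau,
    h = (gate_steady_state(g$h, V) - h) / tau_h(V, p$tau_h_coef),
    mp = (gate_steady_state(g$mp, V) - mp) / g$mp$tau,
    s = ds,
    n = (gate_steady_state(g$n, V) - n) / g$n$tau,
    hA = dhA)
}

#' Steady-state current balance (scalar reduction)
#'
#' Membrane current balance with every gate at its voltage steady state;
#' zeros of this function are the fixed points of the model. Equals
#' `Cin * model_rhs()[V]` when the state is set by [steady_state_at()].
#'
#' @inheritParams steady_state_at
#' @param V Voltage (mV), vectorized.
#' @return Net current (pA), vectorized over `V`.
#' @export
steady_state_current <- function(p, V, s_frozen = NULL) {
  g <- p$gates
  s <- if (!is.null(s_frozen)) s_frozen
       else if (p$include_slow_inactivation) gate_steady_state(g$s, V) else 1
  GA <- if (p$include_IA) p$GA else 0
  p$Gin * (p$Vr - V) +
    p$GNat * gate_steady_state(g$m, V)^3 * gate_steady_state(g$h, V) * (p$ENa - V) +
    p$GNap * gate_steady_state(g$mp, V)^3 * s * (p$ENa - V) +
    p$GKdr * gate_steady_state(g$n, V)^3 * (p$EK - V) +
    GA * gate_steady_state(g$mA, V) * gate_steady_state(g$hA, V) * (p$EK - V) +
    p$I
}

#' Numerical Jacobian of the model at a state
#'
#' Central finite differences with step 1e-6 on each dynamical variable. The
#' instantaneous gate mA and any disabled gate contribute no dynamical
#' dimension; the returned matrix covers the active variables only.
#'
#' @inheritParams model_rhs
#' @return Square matrix over the active variables (row/col names attached).
#' @export
model_jacobian <- function(state, p) {
  vars <- active_vars(p)
  J <- matrix(0, length(vars), length(vars), dimnames = list(vars, vars))
  e <- 1e-6
  for (j in seq_along(vars)) {
    xp <- state; xm <- state
    xp[vars[j]] <- xp[vars[j]] + e
    xm[vars[j]] <- xm[vars[j]] - e
    J[, j] <- (model_rhs(xp, p)[vars] - model_rhs(xm, p)[vars]) / (2 * e)
  }
  J
}

active_vars <- function(p) {
  vars <- c("V", "m", "h", "mp", "n")
  if (p$include_slow_inactivation) vars <- c(vars, "s")
  if (p$include_IA) vars <- c(vars, "hA")
  vars
}

#' Locate all fixed points and their stability
#'
#' Roots of the steady-state current balance are bracketed on a dense voltage
#' grid and refined by bisection; stability comes from the eigenvalues of the
#' numerically differenced Jacobian. With slow inactivation enabled the gate s
#' is frozen (fast-subsystem fixed points), at `s_frozen` if supplied.
#'
#' @inheritParams steady_state_at
#' @param V_range Voltage bracket searched (mV).
#' @param n_grid Grid points used for root bracketing.
#' @param tol Voltage tolerance of the bisection (mV).
#' @param marginal_tol Eigenvalue real parts smaller than this in magnitude
#'   are flagged marginal.
#' @return Data frame with one row per fixed point: `V`, `stable`, `marginal`,
#'   `max_re` (largest eigenvalue real part), `max_re_complex` (largest real
#'   part over the complex-conjugate pairs, `NA` if all eigenvalues are real);
#'   the full states and eigenvalue sets are attached as attributes `states`
#'   and `eigen`.
#' @export
find_fixed_points <- function(p, V_range = c(-100, 40), n_grid = 2001,
                              tol = 1e-6, s_frozen = NULL, marginal_tol = 1e-9) {
  if (p$include_slow_inactivation && is.null(s_frozen))
    s_frozen <- 1  # fast subsystem: slow gate treated as frozen parameter
  Vg <- seq(V_range[1], V_range[2], length.out = n_grid)
  f <- steady_state_current(p, Vg, s_frozen = s_frozen)
  roots <- numeric(0)
  sgn <- sign(f)
  for (i in which(sgn[-1] * sgn[-length(sgn)] < 0)) {
    r <- tryCatch(
      stats::uniroot(function(v) steady_state_current(p, v, s_frozen = s_frozen),
                     c(Vg[i], Vg[i + 1]), tol = tol)$root,
      error = function(e) {
        warning("root refinement failed in [", Vg[i], ", ", Vg[i + 1], "] mV: ",
                conditionMessage(e))
        NA_real_
      })
    roots <- c(roots, r)
  }
  roots <- c(roots, Vg[sgn == 0])
  roots <- sort(roots[is.finite(roots)])
  states <- lapply(roots, function(v) steady_state_at(p, v, s_frozen = s_frozen))
  eigs <- lapply(states, function(x)
    eigen(model_jacobian(x, p), only.values = TRUE)$values)
  max_re <- vapply(eigs, function(ev) max(Re(ev)), numeric(1))
  max_re_c <- vapply(eigs, function(ev) {
    cv <- ev[abs(Im(ev)) > 1e-8]
    if (length(cv)) max(Re(cv)) else NA_real_
  }, numeric(1))
  out <- data.frame(V = roots, stable = max_re < 0,
                    marginal = abs(max_re) < marginal_tol,
                    max_re = max_re, max_re_complex = max_re_c)
  attr(out, "states") <- states
  attr(out, "eigen") <- eigs
  out
}

#' Fixed-point branch along a parameter sweep
#'
#' Sweeps one of `I`, `GNap`, `GKdr` over a grid and records every fixed point
#' with its stability; the branch is S-shaped (a fold pair, with a coexistence
#' window of three roots) exactly where three roots are reported.
#'
#' @param p A `v1r_params` object.
#' @param sweep Parameter name: `"I"`, `"GNap"` or `"GKdr"`.
#' @param range Length-2 numeric sweep range.
#' @param n Number of grid points.
#' @return Data frame `(param, value, V, stable)`, one row per (sweep value,
#'   fixed point); attribute `n_roots` gives the root count per sweep value.
#' @export
iv_fixed_point_curve <- function(p, sweep = c("I", "GNap", "GKdr"),
                                 range, n = 201) {
  sweep <- match.arg(sweep)
  if (missing(range) || length(range) != 2 || diff(range) <= 0)
    stop("a nonempty sweep range is required")
  vals <- seq(range[1], range[2], length.out = n)
  rows <- lapply(vals, function(v) {
    p[[sweep]] <- v
    fp <- find_fixed_points(p)
    data.frame(param = sweep, value = v, V = fp$V, stable = fp$stable)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_roots") <- vapply(rows, nrow, integer(1))
  out
}
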