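# Bifurcation analysis: Hopf points by eigenvalue bisection on fixed-point
# branches, folds of limit cycles by attractor-following continuation, firing
# rates on the stable cycle, two-parameter activity maps, and the
# quiescence/plateau bistability region.

#' Simulate the autonomous model at constant injected current
#'
#' @param p A `v1r_params` object (`p$I` is the injected current).
#' @param x0 Initial state (named vector over `(V, m, h, mp, s, n, hA)`).
#' @param t_total Simulated time (ms).
#' @param dt Integration step (ms).
#' @param record_every Output thinning.
#' @return A `v1r_trace`.
#' @export
simulate_autonomous <- function(p, x0, t_total, dt = 0.01, record_every = 10L) {
  seg <- matrix(c(t_total, p$I, p$I), 1)
  raw <- rcpp_integrate(.param_vec(p), seg, 0L, dt, as.numeric(x0),
                        as.integer(record_every))
  structure(data.frame(t = raw$t, V = raw$V, cmd = raw$cmd, s = raw$s),
            params = p, final_state = raw$final_state,
            class = c("v1r_trace", "data.frame"))
}

# Sustained-oscillation test: discard `transient`, then require every
# `subwin`-ms subwindow of the last `window` ms to span > threshold mV.
.oscillating <- function(p, x0, transient = 2000, window = 1000,
                         subwin = 250, threshold = 20, dt = 0.01) {
  tr <- simulate_autonomous(p, x0, transient + window, dt = dt)
  keep <- tr$t > transient
  V <- tr$V[keep]
  ns <- max(1L, floor(window / subwin))
  idx <- cut(seq_along(V), ns, labels = FALSE)
  spans <- tapply(V, idx, function(v) diff(range(v)))
  list(osc = all(spans > threshold), final = attr(tr, "final_state"),
       trace = tr)
}

.branch_fp <- function(p, branch = c("quiescent", "plateau")) {
  branch <- match.arg(branch)
  fp <- find_fixed_points(p)
  if (!nrow(fp)) return(NULL)
  i <- if (branch == "quiescent") which.min(fp$V) else which.max(fp$V)
  fp[i, , drop = FALSE]
}

#' Hopf bifurcations along a one-parameter sweep
#'
#' Tracks a fixed-point branch (`"quiescent"` = lowest-voltage root,
#' `"plateau"` = highest-voltage root) over the sweep and locates every
#' parameter value where the real part of the leading complex-conjugate
#' eigenvalue pair crosses zero, refined by bisection.
#'
#' @param p A `v1r_params` object.
#' @param sweep `"GNap"`, `"GKdr"` or `"I"`.
#' @param range Length-2 sweep range.
#' @param branch Which fixed-point branch to follow.
#' @param n_scan Grid points of the initial scan.
#' @param tol Bisection tolerance (parameter units).
#' @return Data frame of crossings `(kind, param, value, V, direction)` where
#'   `direction` is `"destabilizing"` (real part turns positive) or
#'   `"stabilizing"`; zero rows if no crossing lies in the range.
#' @export
hopf_scan <- function(p, sweep = c("GNap", "GKdr", "I"), range,
                      branch = c("quiescent", "plateau"),
                      n_scan = 101, tol = 1e-3) {
  sweep <- match.arg(sweep)
  branch <- match.arg(branch)
  grid <- seq(range[1], range[2], length.out = n_scan)
  f <- function(g) {
    p[[sweep]] <- g
    b <- .branch_fp(p, branch)
    if (is.null(b)) NA_real_ else b$max_re_complex
  }
  vals <- vapply(grid, f, numeric(1))
  out <- list()
  for (i in seq_len(n_scan - 1)) {
    a <- vals[i]; b <- vals[i + 1]
    if (is.na(a) || is.na(b) || a * b > 0) next
    r <- stats::uniroot(f, c(grid[i], grid[i + 1]), tol = tol)$root
    p[[sweep]] <- r
    bf <- .branch_fp(p, branch)
    out[[length(out) + 1]] <- data.frame(
      kind = "Hopf", param = sweep, value = r, V = bf$V,
      direction = if (a < b) "destabilizing" else "stabilizing")
  }
  if (!length(out))
    return(data.frame(kind = character(0), param = character(0),
                      value = numeric(0), V = numeric(0),
                      direction = character(0)))
  do.call(rbind, out)
}

#' Fold of limit cycles along a one-parameter sweep
#'
#' Locates the parameter value where the stable repetitive-firing cycle
#' appears (`side = "onset"`, smallest value with a cycle) or disappears
#' (`side = "offset"`). The cycle is followed by attractor continuation: the
#' initial condition at each step is inherited from the neighbouring
#' converged cycle, a 2 s transient is discarded, and a sustained oscillation
#' is declared when the voltage span stays above `threshold` (default 20 mV,
#' separating full spiking from subthreshold ringing near the Hopf) over the
#' last second.
#'
#' @inheritParams hopf_scan
#' @param side `"onset"` (low-parameter fold) or `"offset"`.
#' @param n_scan Coarse continuation grid points.
#' @param tol Bisection resolution (parameter units).
#' @param threshold Peak-to-trough oscillation criterion (mV).
#' @param dt Integration step (ms).
#' @return One-row data frame `(kind, param, value, side)` with the cycle
#'   state nearest the fold attached as attribute `cycle_state`; zero rows if
#'   no stable cycle exists anywhere in the range.
#' @export
limit_cycle_fold_scan <- function(p, sweep = c("GNap", "GKdr", "I"), range,
                                  side = c("onset", "offset"), n_scan = 26,
                                  tol = 1e-3, threshold = 20, dt = 0.01) {
  sweep <- match.arg(sweep)
  side <- match.arg(side)
  grid <- seq(range[1], range[2], length.out = n_scan)

  # seed: a grid point whose quiescent fixed point is unstable necessarily
  # relaxes onto the spiking (or plateau) attractor; test oscillation there
  seed_idx <- NULL; seed_state <- NULL
  order_try <- order(abs(grid - stats::median(grid)))
  for (pass in 1:2) {
    for (i in order_try) {
      p[[sweep]] <- grid[i]
      fp <- find_fixed_points(p)
      if (!nrow(fp)) next
      qi <- which.min(fp$V)
      # pass 1: only destabilized quiescent points (guaranteed off the rest
      # state); pass 2: any point, with a stronger kick
      if (pass == 1 && fp$stable[qi]) next
      x0 <- attr(fp, "states")[[qi]]
      x0["V"] <- x0["V"] + if (pass == 1) 2 else 15
      r <- .oscillating(p, x0, threshold = threshold, dt = dt)
      if (r$osc) { seed_idx <- i; seed_state <- r$final; break }
    }
    if (!is.null(seed_idx)) break
  }
  if (is.null(seed_idx))
    return(data.frame(kind = character(0), param = character(0),
                      value = numeric(0), side = character(0)))

  step <- if (side == "onset") -1L else 1L
  i <- seed_idx; x <- seed_state
  g_ok <- grid[seed_idx]; g_fail <- NULL
  while (is.null(g_fail)) {
    j <- i + step
    if (j < 1 || j > n_scan) break
    p[[sweep]] <- grid[j]
    r <- .oscillating(p, x, threshold = threshold, dt = dt)
    if (r$osc) { i <- j; x <- r$final; g_ok <- grid[j] } else g_fail <- grid[j]
  }
  if (is.null(g_fail)) {  # cycle survives to the range end
    out <- data.frame(kind = "FoldLimitCycle", param = sweep, value = g_ok,
                      side = side)
    attr(out, "cycle_state") <- x
    attr(out, "censored") <- TRUE
    return(out)
  }
  while (abs(g_fail - g_ok) > tol) {
    mid <- (g_ok + g_fail) / 2
    p[[sweep]] <- mid
    r <- .oscillating(p, x, threshold = threshold, dt = dt)
    if (r$osc) { g_ok <- mid; x <- r$final } else g_fail <- mid
  }
  out <- data.frame(kind = "FoldLimitCycle", param = sweep, value = g_ok,
                    side = side)
  attr(out, "cycle_state") <- x
  attr(out, "censored") <- FALSE
  out
}

#' Firing rate on the stable limit cycle
#'
#' Simulates from a state on (or near) the cycle, discards the transient and
#' computes the rate from mean inter-spike intervals, spikes being upward
#' crossings of the mid-range voltage.
#'
#' @inheritParams simulate_autonomous
#' @param t_total Total simulated time (ms).
#' @param transient Discarded transient (ms).
#' @return Rate in Hz (`NA` if fewer than two spikes).
#' @export
cycle_rate <- function(p, x0, t_total = 10000, transient = 2000, dt = 0.01) {
  tr <- simulate_autonomous(p, x0, t_total, dt = dt)
  keep <- tr$t > transient
  V <- tr$V[keep]; t <- tr$t[keep]
  thr <- (max(V) + min(V)) / 2
  up <- which(V[-1] > thr & V[-length(V)] <= thr)
  if (length(up) < 2) return(NA_real_)
  1000 * (length(up) - 1) / (t[up[length(up)]] - t[up[1]])
}

#' Firing rate along a one-parameter sweep
#'
#' Attractor-following continuation of the cycle with the rate computed at
#' each parameter value.
#'
#' @inheritParams limit_cycle_fold_scan
#' @param values Parameter values (swept in the given order; the cycle state
#'   is inherited from one value to the next).
#' @param x0 State on the cycle at `values[1]`.
#' @return Data frame `(value, rate_hz)`.
#' @export
firing_rate_curve <- function(p, sweep = c("GNap", "GKdr", "I"), values, x0,
                              t_total = 10000, transient = 2000, dt = 0.01) {
  sweep <- match.arg(sweep)
  x <- x0
  rows <- lapply(values, function(g) {
    p[[sweep]] <- g
    tr <- simulate_autonomous(p, x, t_total, dt = dt)
    x <<- attr(tr, "final_state")
    keep <- tr$t > transient
    V <- tr$V[keep]; t <- tr$t[keep]
    thr <- (max(V) + min(V)) / 2
    up <- which(V[-1] > thr & V[-length(V)] <= thr)
    rate <- if (length(up) >= 2)
      1000 * (length(up) - 1) / (t[up[length(up)]] - t[up[1]]) else NA_real_
    data.frame(value = g, rate_hz = rate)
  })
  do.call(rbind, rows)
}

#' Two-parameter activity map in the GNap-GKdr plane
#'
#' Classifies every grid cell through the full simulate-and-phenotype path
#' (2 s current pulse from rest) and, optionally, traces the Hopf and
#' fold-of-cycles boundary curves by repeating the one-parameter scans at a
#' set of GKdr values.
#'
#' @param p A `v1r_params` object (its `I` is ignored; use `I`).
#' @param gnap_range,gkdr_range Ranges (nS).
#' @param n_gnap,n_gkdr Grid resolution.
#' @param I Injected current of the classifying pulse (pA).
#' @param boundaries Number of GKdr levels at which boundary curves are
#'   traced (0 disables).
#' @return List with `map` (data frame `GNap`, `GKdr`, `pattern`) and
#'   `boundaries` (data frame of curve points, or `NULL`).
#' @export
two_parameter_map <- function(p, gnap_range = c(0, 2.5), gkdr_range = c(0.5, 25),
                              n_gnap = 26, n_gkdr = 26, I = 20,
                              boundaries = 0) {
  if (diff(gnap_range) <= 0 || diff(gkdr_range) <= 0)
    stop("ranges must be positive")
  gnap <- seq(gnap_range[1], gnap_range[2], length.out = n_gnap)
  gkdr <- seq(gkdr_range[1], gkdr_range[2], length.out = n_gkdr)
  map <- expand.grid(GNap = gnap, GKdr = gkdr)
  map$pattern <- vapply(seq_len(nrow(map)), function(i) {
    pi <- p; pi$GNap <- map$GNap[i]; pi$GKdr <- map$GKdr[i]
    classify_point(pi, amplitude = I, settle = 500)
  }, character(1))
  bnd <- NULL
  if (boundaries > 0) {
    lev <- seq(gkdr_range[1], gkdr_range[2], length.out = boundaries)
    rows <- list()
    for (gk in lev) {
      pb <- p; pb$GKdr <- gk; pb$I <- I
      hb <- hopf_scan(pb, "GNap", gnap_range)
      if (nrow(hb))
        rows[[length(rows) + 1]] <- data.frame(curve = paste0("HB_",
          ifelse(hb$direction == "destabilizing", "1", "2")),
          GKdr = gk, GNap = hb$value)
      for (sd in c("onset", "offset")) {
        fo <- limit_cycle_fold_scan(pb, "GNap", gnap_range, side = sd)
        if (nrow(fo))
          rows[[length(rows) + 1]] <- data.frame(
            curve = if (sd == "onset") "SN_1" else "SN_2",
            GKdr = gk, GNap = fo$value)
      }
    }
    if (length(rows)) bnd <- do.call(rbind, rows)
  }
  list(map = map, boundaries = bnd)
}

#' Injected-current window of quiescence/plateau coexistence
#'
#' The interval of injected current over which two stable fixed points (the
#' quiescent and the plateau state) coexist at the current parameter values,
#' located on an I grid and refined by bisection.
#'
#' @param p A basic-model `v1r_params`.
#' @param I_range Current range scanned (pA).
#' @param n_grid Grid points of the initial scan.
#' @param tol Bisection tolerance (pA).
#' @return `c(I_lo, I_hi)` in pA, or `c(NA, NA)` when no coexistence exists
#'   in the range.
#' @export
bistability_window <- function(p, I_range = c(-20, 20), n_grid = 81,
                               tol = 1e-2) {
  .coexist_window(p, I_range, n_grid = n_grid, tol = tol)
}

# I-window of coexistence of two stable fixed points at the current params
.coexist_window <- function(p, I_range, n_grid = 81, tol = 1e-2) {
  Ig <- seq(I_range[1], I_range[2], length.out = n_grid)
  co <- vapply(Ig, function(I) {
    p$I <- I
    sum(find_fixed_points(p)$stable) >= 2
  }, logical(1))
  if (!any(co)) return(c(NA_real_, NA_real_))
  i1 <- which(co)[1]; i2 <- rev(which(co))[1]
  refine <- function(lo, hi, want_hi) {
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      p$I <- mid
      if ((sum(find_fixed_points(p)$stable) >= 2) == want_hi) hi <- mid
      else lo <- mid
    }
    (lo + hi) / 2
  }
  lo <- if (i1 == 1) Ig[1] else refine(Ig[i1 - 1], Ig[i1], TRUE)
  hi <- if (i2 == n_grid) Ig[n_grid] else refine(Ig[i2], Ig[i2 + 1], FALSE)
  c(lo, hi)
}

#' Quiescence/plateau bistability region in the I-GNap plane
#'
#' For each GNap the injected-current interval over which a stable quiescent
#' and a stable plateau fixed point coexist (computed from the steady-state
#' I-V relation and Jacobian eigenvalues), plus the minimal GNap admitting
#' any coexistence, refined by bisection.
#'
#' @param p A basic-model `v1r_params` (no slow inactivation).
#' @param I_range Injected-current range scanned (pA).
#' @param gnap_range GNap range scanned (nS).
#' @param n_gnap GNap grid points.
#' @param tol Bisection tolerance on GNap (nS).
#' @return List with `region` (data frame `GNap`, `I_lo`, `I_hi`; `NA` where
#'   no coexistence) and `gnap_min` (smallest GNap with a nonempty window).
#' @export
bistability_region <- function(p, I_range = c(-20, 20),
                               gnap_range = c(1, 2.5), n_gnap = 31,
                               tol = 1e-3) {
  if (p$include_slow_inactivation)
    stop("bistability region is defined for the basic model")
  gnap <- seq(gnap_range[1], gnap_range[2], length.out = n_gnap)
  win <- t(vapply(gnap, function(g) {
    p$GNap <- g
    .coexist_window(p, I_range)
  }, numeric(2)))
  region <- data.frame(GNap = gnap, I_lo = win[, 1], I_hi = win[, 2])
  has <- !is.na(region$I_lo)
  gnap_min <- NA_real_
  if (any(has)) {
    i1 <- which(has)[1]
    if (i1 == 1) gnap_min <- gnap[1]
    else {
      lo <- gnap[i1 - 1]; hi <- gnap[i1]
      while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        p$GNap <- mid
        if (!is.na(.coexist_window(p, I_range)[1])) hi <- mid else lo <- mid
      }
      gnap_min <- (lo + hi) / 2
    }
  }
  list(region = region, gnap_min = gnap_min)
}
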