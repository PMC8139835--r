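#' Build a protocol description
#'
#' A protocol is an ordered list of segments, each holding a command (injected
#' current in pA for current clamp, command voltage in mV for voltage clamp)
#' that is either constant or ramps linearly over the segment.
#'
#' @param mode `"current_clamp"` or `"voltage_clamp"`.
#' @param segments Data frame or matrix with columns `dur` (ms), `from`, `to`
#'   (command at segment start/end; equal values give a step).
#' @param holding Command value imposed before the protocol (used for the
#'   settling run and the initial state).
#' @param dt Integration step (ms). Spiking simulations need `dt <= 0.05`.
#' @param record_every Store every k-th sample (thins the output).
#' @return A `v1r_protocol` object.
#' @export
v1r_protocol <- function(mode = c("current_clamp", "voltage_clamp"),
                         segments, holding = 0, dt = 0.01, record_every = 10L) {
  mode <- match.arg(mode)
  segments <- as.data.frame(segments)
  names(segments) <- c("dur", "from", "to")[seq_len(ncol(segments))]
  if (ncol(segments) == 2) segments$to <- segments$from
  if (any(segments$dur <= 0)) stop("segment durations must be > 0")
  if (dt <= 0) stop("dt must be > 0")
  structure(list(mode = mode, segments = segments, holding = holding,
                 dt = dt, record_every = as.integer(record_every)),
            class = "v1r_protocol")
}

#' Integrate the deterministic model under a protocol
#'
#' Fixed-step fourth-order Runge-Kutta integration. The initial state is the
#' gate steady state at the holding command followed by a settling simulation
#' (default 2 s) at holding, so the same code path serves every model variant
#' including slow inactivation. In voltage clamp the clamp is ideal: V follows
#' the command exactly and the per-conductance currents (outward positive) are
#' returned alongside the total.
#'
#' @param p A `v1r_params` object.
#' @param protocol A `v1r_protocol`.
#' @param settle Settling duration at holding before the protocol (ms).
#' @param x0 Optional explicit initial state (overrides settling).
#' @param leak_subtracted In voltage clamp, exclude the leak current from the
#'   reported total (emulates offline leak subtraction).
#' @return A `v1r_trace` data frame with columns `t` (ms), `V` (mV), `cmd`,
#'   `s`, and in voltage clamp the current components `I_*` and total `I`
#'   (pA); attributes `params`, `protocol`, `final_state`.
#' @export
integrate_protocol <- function(p, protocol, settle = 2000, x0 = NULL,
                               leak_subtracted = FALSE) {
  stopifnot(inherits(protocol, "v1r_protocol"))
  pv <- .param_vec(p)
  mode <- if (protocol$mode == "current_clamp") 0L else 1L
  if (is.null(x0)) {
    if (mode == 0L) {
      ph <- p; ph$I <- protocol$holding
      fp <- find_fixed_points(ph, s_frozen = if (p$include_slow_inactivation)
        NULL else 1)
      v0 <- if (nrow(fp)) min(fp$V) else p$Vr
    } else v0 <- protocol$holding
    x0 <- steady_state_at(p, v0)
    if (!p$include_slow_inactivation) x0["s"] <- 1
    if (settle > 0) {
      hseg <- matrix(c(settle, protocol$holding, protocol$holding), 1)
      st <- rcpp_integrate(pv, hseg, mode, protocol$dt, x0,
                           record_every = 1000L)
      x0 <- st$final_state
    }
  }
  seg <- as.matrix(protocol$segments[, c("dur", "from", "to")])
  raw <- rcpp_integrate(pv, seg, mode, protocol$dt, as.numeric(x0),
                        protocol$record_every)
  tr <- data.frame(t = raw$t, V = raw$V, cmd = raw$cmd, s = raw$s)
  if (mode == 1L) {
    tr$I_leak <- raw$I_leak; tr$I_Nat <- raw$I_Nat; tr$I_Nap <- raw$I_Nap
    tr$I_Kdr <- raw$I_Kdr; tr$I_A <- raw$I_A
    tr$I <- raw$I_Nat + raw$I_Nap + raw$I_Kdr + raw$I_A +
      if (leak_subtracted) 0 else raw$I_leak
  }
  structure(tr, params = p, protocol = protocol,
            final_state = raw$final_state, class = c("v1r_trace", "data.frame"))
}

#' Simulate a single depolarizing current step
#'
#' The standard stimulation: baseline at holding, a rectangular depolarizing
#' pulse, then return to holding. The pulse window is attached for the event
#' detector.
#'
#' @inheritParams integrate_protocol
#' @param amplitude Step amplitude (pA).
#' @param duration Pulse width (ms); the experiments use 2 s.
#' @param pre,post Baseline before/after the pulse (ms).
#' @param holding Holding current (pA).
#' @param dt,record_every Integration step and output thinning.
#' @return A `v1r_trace` with attribute `pulse = c(onset, offset)` in ms.
#' @export
current_step <- function(p, amplitude, duration = 2000, pre = 200, post = 500,
                         holding = 0, dt = 0.01, record_every = 10L,
                         settle = 2000, x0 = NULL) {
  pr <- v1r_protocol("current_clamp",
                     data.frame(dur = c(pre, duration, post),
                                from = c(holding, amplitude, holding)),
                     holding = holding, dt = dt, record_every = record_every)
  tr <- integrate_protocol(p, pr, settle = settle, x0 = x0)
  attr(tr, "pulse") <- c(pre, pre + duration)
  tr
}

#' Family of depolarizing current steps
#'
#' One trace per amplitude, each started from the holding steady state (the
#' experimental interpulse interval exists only to restore that state, so it
#' is not simulated).
#'
#' @inheritParams current_step
#' @param amplitudes Step amplitudes (pA), all >= 0.
#' @return List of `v1r_trace`, named by amplitude.
#' @export
current_step_family <- function(p, amplitudes, duration = 2000, ...) {
  if (any(amplitudes < 0)) stop("amplitudes must be >= 0")
  out <- lapply(amplitudes, function(a)
    current_step(p, a, duration = duration, ...))
  names(out) <- paste0(amplitudes, "pA")
  out
}

#' Rheobase by bisection on step amplitude
#'
#' Smallest step amplitude evoking at least one detected event, bracketed on
#' `range` and bisected to `tol` pA.
#'
#' @inheritParams current_step
#' @param range Amplitude bracket (pA).
#' @param tol Bisection tolerance (pA).
#' @return Rheobase estimate (pA), or `NA` if no spike anywhere in range.
#' @export
rheobase <- function(p, range = c(0, 50), tol = 0.5, duration = 2000, ...) {
  spikes <- function(a) {
    tr <- current_step(p, a, duration = duration, ...)
    nrow(detect_events(tr))
  }
  lo <- range[1]; hi <- range[2]
  if (spikes(hi) == 0) return(NA_real_)
  if (spikes(lo) > 0) return(lo)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (spikes(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Voltage-clamp step protocol
#'
#' Emulates the potassium-current protocol: a conditioning prepulse followed
#' by a family of depolarizing steps from a holding potential. A prepulse at
#' -30 mV inactivates the A-current and isolates the delayed rectifier; the
#' A-current is recovered offline by subtraction of two step families.
#'
#' @inheritParams integrate_protocol
#' @param VH Holding potential (mV).
#' @param prepulse Length-2 `c(mV, ms)` conditioning prepulse.
#' @param steps Step command potentials (mV).
#' @param step_dur Step duration (ms).
#' @param ttx Zero the sodium conductances (TTX emulation).
#' @return List of voltage-clamp `v1r_trace`, named by step potential, each
#'   with attribute `step_window = c(onset, offset)` ms.
#' @export
vclamp_steps <- function(p, VH = -60, prepulse = c(-30, 300),
                         steps = seq(-100, 40, by = 10), step_dur = 500,
                         ttx = TRUE, dt = 0.01, record_every = 10L,
                         leak_subtracted = FALSE) {
  if (ttx) { p$GNat <- 0; p$GNap <- 0 }
  out <- lapply(steps, function(vs) {
    pr <- v1r_protocol("voltage_clamp",
                       data.frame(dur = c(prepulse[2], step_dur, 100),
                                  from = c(prepulse[1], vs, VH)),
                       holding = VH, dt = dt, record_every = record_every)
    tr <- integrate_protocol(p, pr, settle = 1000,
                             leak_subtracted = leak_subtracted)
    attr(tr, "step_window") <- c(prepulse[2], prepulse[2] + step_dur)
    tr
  })
  names(out) <- paste0(steps, "mV")
  out
}

#' Slow voltage ramp isolating the persistent sodium current
#'
#' A depolarizing ramp (default 70 mV/s) slow enough that the transient
#' sodium current inactivates; the persistent current is estimated by
#' subtracting the ramp current recorded with sodium conductances zeroed
#' (TTX) from the control ramp current.
#'
#' @inheritParams integrate_protocol
#' @param slope Ramp speed (mV/s).
#' @param from,to Ramp limits (mV).
#' @return List with `control` and `ttx` voltage-clamp traces, `inap` data
#'   frame `(t, V, I)` of the subtraction estimate (pA, inward negative),
#'   `peak` (pA) and `V_peak` (mV) of the estimate.
#' @export
ramp_inap <- function(p, slope = 70, from = -100, to = 0, dt = 0.01,
                      record_every = 10L) {
  dur <- (to - from) / (slope / 1000)  # mV / (mV/ms)
  pr <- v1r_protocol("voltage_clamp",
                     data.frame(dur = dur, from = from, to = to),
                     holding = from, dt = dt, record_every = record_every)
  ctrl <- integrate_protocol(p, pr, settle = 1000)
  ptx <- p; ptx$GNat <- 0; ptx$GNap <- 0
  ttx <- integrate_protocol(ptx, pr, settle = 1000)
  inap <- data.frame(t = ctrl$t, V = ctrl$cmd, I = ctrl$I - ttx$I)
  ipk <- which.min(inap$I)  # inward peak
  list(control = ctrl, ttx = ttx, inap = inap,
       peak = inap$I[ipk], V_peak = inap$V[ipk])
}

#' Pharmacological manipulations as parameter scalings
#'
#' TTX zeroes both sodium conductances. 4-AP scales the delayed-rectifier
#' conductance by the Hill remaining fraction at the given concentration
#' (default dose-response: IC50 = 2.9 uM, nH = 1, Imin = 5% residual) and the
#' input conductance by a factor interpolated linearly in log-concentration
#' between 1 at the lowest applied concentration (0.3 uM) and `gin_factor_300`
#' at 300 uM. With `rheobase_matched = TRUE` the injected current is rescaled
#' by the same factor as Gin, mimicking the experimental re-adjustment of the
#' stimulus to the reduced rheobase.
#'
#' @param p A `v1r_params` object.
#' @param four_ap 4-AP concentration (uM), >= 0.
#' @param ttx Logical; apply TTX.
#' @param dose_response Hill model list `(Imin, IC50, nH)` for the block of
#'   the delayed rectifier.
#' @param gin_factor_300 Gin multiplier reached at 300 uM (default 0.77, a
#'   23% mean reduction).
#' @param rheobase_matched Rescale `I` proportionally to Gin.
#' @return Modified `v1r_params`.
#' @export
apply_pharmacology <- function(p, four_ap = 0, ttx = FALSE,
                               dose_response = list(Imin = 5, IC50 = 2.9, nH = 1),
                               gin_factor_300 = 0.77,
                               rheobase_matched = FALSE) {
  if (four_ap < 0) stop("4-AP concentration must be >= 0")
  if (ttx) { p$GNat <- 0; p$GNap <- 0 }
  if (four_ap > 0) {
    rem <- hill_inhibition(four_ap, dose_response) / 100
    p$GKdr <- p$GKdr * rem
    lc <- (log10(max(four_ap, 0.3)) - log10(0.3)) / (log10(300) - log10(0.3))
    fac <- 1 + (gin_factor_300 - 1) * min(max(lc, 0), 1)
    p$Gin <- p$Gin * fac
    if (rheobase_matched) p$I <- p$I * fac
  }
  validate_params(p)
  p
}

#' Write a trace to CSV with a JSON sidecar
#'
#' The CSV holds the recorded columns; the sidecar records the parameter set
#' and protocol so the run can be reproduced.
#'
#' @param trace A `v1r_trace`.
#' @param path CSV path; the sidecar is written to `paste0(path, ".json")`.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  side <- list(params = .params_plain(attr(trace, "params")),
               protocol = unclass(attr(trace, "protocol")))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
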