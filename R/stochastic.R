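#' Number of discrete channels behind a conductance
#'
#' @param G Maximal conductance (nS).
#' @param gamma Unitary channel conductance (nS); default 0.01 nS = 10 pS.
#' @return Integer channel count `round(G / gamma)`.
#' @export
channel_counts <- function(G, gamma = 0.01) {
  if (any(G < 0)) stop("G must be >= 0")
  as.integer(round(G / gamma))
}

#' Channel-noise simulation of a current step (hybrid Gillespie)
#'
#' Discrete Markov channel populations (8-state m^3 h for the transient
#' sodium current, mp^3 x s for the persistent current, 4-state n^3 for the
#' delayed rectifier) are simulated by an exact stochastic simulation
#' algorithm with per-subunit rates alpha = xinf(V)/tau, beta =
#' (1 - xinf(V))/tau frozen between voltage updates. Voltage relaxes exactly
#' (the membrane equation is linear while the open-channel counts are
#' constant) and rates are refreshed after every advance and at least every
#' `dt_max` ms. The A-current is not included in the stochastic variant.
#'
#' @inheritParams current_step
#' @param seed RNG seed; recorded in the trace attributes.
#' @param gamma Unitary conductance (nS); smaller values mean more, smaller
#'   channels and weaker noise.
#' @param dt_max Maximum interval between rate refreshes (ms).
#' @param record_dt Output sampling interval (ms).
#' @return A `v1r_trace` with columns `t`, `V`, `cmd` and `s` (open fraction
#'   of the slow gate); attributes `seed`, `gamma`, `n_channels`, `pulse`.
#' @export
gillespie_simulate <- function(p, amplitude, seed, duration = 2000, pre = 200,
                               post = 500, holding = 0, gamma = 0.01,
                               dt_max = 0.025, record_dt = 0.1) {
  if (p$include_IA) stop("channel-noise simulation does not include the A-current")
  set.seed(seed)
  ph <- p; ph$I <- holding
  fp <- find_fixed_points(ph, s_frozen = if (p$include_slow_inactivation) NULL else 1)
  v0 <- if (nrow(fp)) min(fp$V) else p$Vr
  x0 <- steady_state_at(p, v0)
  if (!p$include_slow_inactivation) x0["s"] <- 1
  seg <- matrix(c(pre, holding, holding,
                  duration, amplitude, amplitude,
                  post, holding, holding), 3, byrow = TRUE)
  raw <- rcpp_gillespie(.param_vec(p), seg, gamma, dt_max, record_dt,
                        as.numeric(x0))
  tr <- data.frame(t = raw$t, V = raw$V, cmd = raw$cmd, s = raw$s)
  structure(tr, params = p, seed = seed, gamma = gamma,
            n_channels = raw$n_channels, pulse = c(pre, pre + duration),
            class = c("v1r_trace", "data.frame"))
}

#' Plateau / quiescence duration statistics under channel noise
#'
#' Runs the slow-inactivation model with channel noise for several seeds and
#' segments each voltage trace into up (plateau) and down (quiescent) states.
#'
#' @inheritParams gillespie_simulate
#' @param seeds Integer vector of seeds, one run per seed.
#' @return List with `per_seed` (list of `burst_structure()` results) and
#'   `summary` data frame of mean and CV of up/down durations per seed.
#' @export
stochastic_burst_statistics <- function(p, amplitude, seeds, duration = 10000,
                                        pre = 200, post = 200, ...) {
  if (!p$include_slow_inactivation)
    stop("burst statistics require the slow-inactivation model")
  per_seed <- lapply(seeds, function(sd) {
    tr <- gillespie_simulate(p, amplitude, seed = sd, duration = duration,
                             pre = pre, post = post, ...)
    burst_structure(tr)
  })
  names(per_seed) <- paste0("seed", seeds)
  cv <- function(x) if (length(x) > 1) stats::sd(x) / mean(x) else NA_real_
  summ <- do.call(rbind, lapply(seq_along(seeds), function(i) {
    b <- per_seed[[i]]
    data.frame(seed = seeds[i],
               n_up = length(b$up_durations),
               mean_up = mean(b$up_durations),
               cv_up = cv(b$up_durations),
               n_down = length(b$down_durations),
               mean_down = if (length(b$down_durations)) mean(b$down_durations) else NA_real_,
               cv_down = cv(b$down_durations))
  }))
  list(per_seed = per_seed, summary = summ)
}
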