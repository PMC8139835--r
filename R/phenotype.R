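#' Detect depolarizing events in a current-step trace
#'
#' Two-stage detection. The detection level is the baseline (mean voltage
#' over the 100 ms preceding the pulse) plus the expected passive
#' depolarization of the leaky membrane (command current change / Gin, when
#' the trace carries its command and parameters) plus `detection_offset`, so
#' that only regenerative excursions - action potentials and plateau
#' potentials, not the leak-driven depolarization - are detected. Within each
#' excursion, events are the sub-excursions above the excursion's
#' half-amplitude level (baseline + (excursion peak - baseline)/2), which
#' separates individual spikes riding on a depolarized envelope. Each event
#' is then measured at half its own amplitude: 1/2Ad is the time spent above
#' baseline + (event peak - baseline)/2 between the troughs bounding the
#' event. Events are clipped to the pulse window; an event is a plateau when
#' its 1/2Ad reaches `plateau_threshold`.
#'
#' @param trace A `v1r_trace` from a current-step protocol.
#' @param pulse Length-2 `c(onset, offset)` ms; defaults to the trace's
#'   `pulse` attribute.
#' @param detection_offset Detection level above baseline (mV). The default
#'   10 mV stays clear of channel-noise fluctuations of a few mV.
#' @param plateau_threshold 1/2Ad (ms) at and above which an event is a
#'   plateau rather than an action potential.
#' @return Data frame `(onset, offset, peak, half_ad, kind)`; `kind` is
#'   `"AP"` or `"plateau"`. Zero rows for a flat trace.
#' @export
detect_events <- function(trace, pulse = attr(trace, "pulse"),
                          detection_offset = 10, plateau_threshold = 100) {
  if (is.null(pulse)) stop("no pulse window available")
  t <- trace$t; V <- trace$V
  if (pulse[1] < t[1] || pulse[2] > t[length(t)] + 1e-9)
    stop("pulse window outside trace")
  base_idx <- t >= pulse[1] - 100 & t < pulse[1]
  if (!any(base_idx)) base_idx <- t < pulse[1]
  baseline <- mean(V[base_idx])
  dt <- t[2] - t[1]

  empty <- data.frame(onset = numeric(0), offset = numeric(0),
                      peak = numeric(0), half_ad = numeric(0),
                      kind = character(0))
  # expected passive depolarization from the command step, if available
  passive_dv <- 0
  prm <- attr(trace, "params")
  if (!is.null(trace$cmd) && !is.null(prm$Gin)) {
    dI <- mean(trace$cmd[t >= pulse[1] & t <= pulse[2]]) -
      mean(trace$cmd[base_idx])
    passive_dv <- max(dI, 0) / prm$Gin
  }

  win <- t >= pulse[1] & t <= pulse[2]
  tw <- t[win]; Vw <- V[win]
  above <- Vw > baseline + passive_dv + detection_offset
  if (!any(above)) return(empty)

  runs_of <- function(x) {
    r <- rle(x)
    ends <- cumsum(r$lengths)
    starts <- c(1, utils::head(ends, -1) + 1)
    cbind(start = starts[r$values], end = ends[r$values])
  }

  ev <- list()
  regions <- runs_of(above)
  for (k in seq_len(nrow(regions))) {
    i0 <- regions[k, 1]; i1 <- regions[k, 2]
    seg <- Vw[i0:i1]
    half_region <- baseline + (max(seg) - baseline) / 2
    cores <- runs_of(seg > half_region)
    if (!nrow(cores)) next
    # event boundaries: troughs between adjacent cores, region edges outside
    bounds <- integer(nrow(cores) + 1)
    bounds[1] <- 1L
    bounds[nrow(cores) + 1] <- length(seg)
    if (nrow(cores) > 1) {
      for (j in seq_len(nrow(cores) - 1)) {
        gap <- cores[j, 2]:cores[j + 1, 1]
        bounds[j + 1] <- gap[which.min(seg[gap])]
      }
    }
    for (j in seq_len(nrow(cores))) {
      b0 <- bounds[j]; b1 <- bounds[j + 1]
      sub <- seg[b0:b1]
      peak <- max(sub)
      half <- baseline + (peak - baseline) / 2
      ev[[length(ev) + 1]] <- data.frame(
        onset = tw[i0 + b0 - 1], offset = tw[i0 + b1 - 1],
        peak = peak, half_ad = sum(sub > half) * dt)
    }
  }
  if (!length(ev)) return(empty)
  ev <- do.call(rbind, ev)
  ev <- ev[ev$half_ad > 0, , drop = FALSE]
  ev$kind <- ifelse(ev$half_ad >= plateau_threshold, "plateau", "AP")
  rownames(ev) <- NULL
  ev
}

#' Firing-pattern descriptors from an event list
#'
#' The three descriptors used throughout: mean half-amplitude event duration
#' (mean 1/2Ad, ms), its coefficient of variation (population SD / mean, in
#' percent, forced to 0 when the pulse evoked three or fewer events), and the
#' depolarizing duration ratio ddr = sum(1/2Ad) / Pw.
#'
#' @param events Event data frame from [detect_events()].
#' @param Pw Pulse width (ms), > 0.
#' @return List `(mean_half_ad, cv_half_ad, ddr, n_events, n_ap, n_plateau)`;
#'   `NULL` fields with `n_events = 0` flag a non-excitable trace.
#' @export
compute_features <- function(events, Pw) {
  if (Pw <= 0) stop("Pw must be > 0")
  n <- nrow(events)
  if (n == 0)
    return(list(mean_half_ad = NA_real_, cv_half_ad = NA_real_,
                ddr = NA_real_, n_events = 0L, n_ap = 0L, n_plateau = 0L))
  had <- events$half_ad
  m <- mean(had)
  cv <- if (n <= 3) 0 else 100 * sqrt(mean((had - m)^2)) / m
  list(mean_half_ad = m, cv_half_ad = cv,
       ddr = min(sum(had) / Pw, 1),
       n_events = n,
       n_ap = sum(events$kind == "AP"),
       n_plateau = sum(events$kind == "plateau"))
}

#' Classify the firing pattern of a pulse response
#'
#' Single spiking (SS): 1-3 action potentials and no plateau. Repetitive
#' spiking (RS): four or more action potentials, no plateau. Plateau
#' potential (PP): at least one plateau with at most one accompanying action
#' potential. Mixed events (ME): at least one plateau alternating with two or
#' more action potentials. A trace with no events is `"quiescent"`, kept
#' distinct from SS.
#'
#' @param events Event data frame from [detect_events()].
#' @return One of `"quiescent"`, `"SS"`, `"RS"`, `"ME"`, `"PP"`.
#' @export
classify_pattern <- function(events) {
  n_ap <- sum(events$kind == "AP")
  n_pl <- sum(events$kind == "plateau")
  if (n_ap + n_pl == 0) return("quiescent")
  if (n_pl == 0) return(if (n_ap <= 3) "SS" else "RS")
  if (n_ap >= 2) "ME" else "PP"
}

#' Classify a parameter point through the simulate-and-phenotype path
#'
#' Convenience wrapper: run a 2 s current step and classify the response.
#'
#' @inheritParams current_step
#' @return Pattern label from [classify_pattern()].
#' @export
classify_point <- function(p, amplitude = 20, duration = 2000, ...) {
  tr <- current_step(p, amplitude, duration = duration, ...)
  classify_pattern(detect_events(tr))
}

#' Burst structure of a slow-inactivation trace
#'
#' Segments the voltage trace into up (plateau / spiking-episode) and down
#' (quiescent) states by hysteresis thresholding of a median-smoothed
#' voltage, and labels the four phases of the slow limit cycle: (1) up state
#' with the slow gate inactivating (ds/dt < 0), (2) fast transition down,
#' (3) down state with de-inactivation (ds/dt > 0), (4) fast transition up.
#'
#' @param trace A `v1r_trace` carrying the slow gate column `s`.
#' @param pulse Analysis window; defaults to the trace's `pulse` attribute.
#' @param thr_on,thr_off Upper/lower hysteresis thresholds (mV); by default
#'   placed at 60% and 40% of the smoothed-voltage range in the window.
#' @param smooth_ms Running-median window (ms) that suppresses spikes.
#' @param min_state_ms States shorter than this are merged into their
#'   neighbours.
#' @return List with `up_durations`, `down_durations` (ms), `segments` data
#'   frame `(state, t_on, t_off, duration, ds_mean)` and `phase` labels.
#' @export
burst_structure <- function(trace, pulse = attr(trace, "pulse"),
                            thr_on = NULL, thr_off = NULL, smooth_ms = 40,
                            min_state_ms = 50) {
  if (is.null(pulse)) stop("no pulse window available")
  win <- trace$t >= pulse[1] & trace$t <= pulse[2]
  t <- trace$t[win]; V <- trace$V[win]; s <- trace$s[win]
  dt <- t[2] - t[1]
  k <- max(3, 2 * floor(smooth_ms / dt / 2) + 1)
  Vs <- stats::runmed(V, min(k, 2 * floor((length(V) - 1) / 2) + 1))
  lo <- stats::quantile(Vs, 0.05); hi <- stats::quantile(Vs, 0.95)
  if (is.null(thr_on)) thr_on <- lo + 0.6 * (hi - lo)
  if (is.null(thr_off)) thr_off <- lo + 0.4 * (hi - lo)

  up <- logical(length(Vs))
  cur <- Vs[1] > thr_on
  for (i in seq_along(Vs)) {
    if (cur && Vs[i] < thr_off) cur <- FALSE
    else if (!cur && Vs[i] > thr_on) cur <- TRUE
    up[i] <- cur
  }
  r <- rle(up)
  # merge states shorter than min_state_ms
  while (length(r$lengths) > 1 && any(r$lengths * dt < min_state_ms)) {
    j <- which.min(r$lengths)
    r$values[j] <- !r$values[j]
    r <- rle(inverse.rle(r))
  }
  ends <- cumsum(r$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  segs <- data.frame(
    state = ifelse(r$values, "up", "down"),
    t_on = t[starts], t_off = t[ends],
    duration = (ends - starts + 1) * dt,
    ds_mean = vapply(seq_along(starts), function(j) {
      ss <- s[starts[j]:ends[j]]
      if (length(ss) > 1) mean(diff(ss)) / dt else 0
    }, numeric(1)))
  segs$phase <- ifelse(segs$state == "up", 1L, 3L)
  list(up_durations = segs$duration[segs$state == "up"],
       down_durations = segs$duration[segs$state == "down"],
       segments = segs,
       thresholds = c(on = unname(thr_on), off = unname(thr_off)))
}

#' Feature table for a cohort of traces
#'
#' Runs detection, feature computation and classification over a list of
#' traces and returns the CSV-ready table consumed by the clustering stage.
#'
#' @param traces List of `v1r_trace` objects.
#' @param Pw Pulse width (ms); defaults to each trace's own pulse window.
#' @return Data frame `(cell_id, mean_half_ad_ms, cv_half_ad_pct, ddr,
#'   n_events, pattern)`.
#' @export
phenotype_traces <- function(traces, Pw = NULL) {
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    pw <- attr(tr, "pulse")
    ev <- detect_events(tr)
    f <- compute_features(ev, if (is.null(Pw)) diff(pw) else Pw)
    data.frame(cell_id = i, mean_half_ad_ms = f$mean_half_ad,
               cv_half_ad_pct = f$cv_half_ad, ddr = f$ddr,
               n_events = f$n_events, pattern = classify_pattern(ev))
  })
  do.call(rbind, rows)
}
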