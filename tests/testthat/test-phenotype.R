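mk_trace <- function(t, V, pulse, params = NULL) {
  structure(data.frame(t = t, V = V), pulse = pulse, params = params,
            class = c("v1r_trace", "data.frame"))
}

test_that("event detection handles flat traces and rectangular excursions", {
  t <- seq(0, 500, by = 0.1)
  flat <- mk_trace(t, rep(-60, length(t)), pulse = c(100, 400))
  expect_equal(nrow(detect_events(flat)), 0)
  # rectangular 20 mV excursion of 50 ms: one event, half-duration 50 ms
  V <- rep(-60, length(t))
  V[t >= 200 & t < 250] <- -40
  rect <- mk_trace(t, V, pulse = c(100, 400))
  ev <- detect_events(rect)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$half_ad, 50, tolerance = 0.01)
  expect_equal(ev$kind, "AP")
  expect_error(detect_events(mk_trace(t, V, pulse = c(100, 600))),
               "outside trace")
})

test_that("event counts match an independent peak-finder on a spiking trace", {
  tr <- current_step(par_rs(), 20)
  ev <- detect_events(tr)
  w <- tr$t >= 200 & tr$t <= 2200
  expect_equal(nrow(ev), count_peaks(tr$V[w]))
})

test_that("features implement the published descriptor conventions", {
  ev1 <- data.frame(onset = 0, offset = 20, peak = 0, half_ad = 10,
                    kind = "AP")
  f1 <- compute_features(ev1, 2000)
  expect_equal(f1$mean_half_ad, 10)
  expect_equal(f1$cv_half_ad, 0)
  expect_equal(f1$ddr, 0.005)
  # three events: CV forced to zero despite dispersion
  ev3 <- data.frame(onset = 1:3, offset = 4:6, peak = 0,
                    half_ad = c(10, 20, 30), kind = "AP")
  expect_equal(compute_features(ev3, 2000)$cv_half_ad, 0)
  ev4 <- rbind(ev3, data.frame(onset = 4, offset = 7, peak = 0,
                               half_ad = 40, kind = "AP"))
  expect_gt(compute_features(ev4, 2000)$cv_half_ad, 0)
  # a pulse-long plateau: ddr = 1
  evp <- data.frame(onset = 0, offset = 2000, peak = -20, half_ad = 2000,
                    kind = "plateau")
  expect_equal(compute_features(evp, 2000)$ddr, 1)
  expect_equal(compute_features(ev1[0, ], 2000)$n_events, 0L)
  expect_error(compute_features(ev1, 0), "Pw")
})

test_that("detected half-durations never exceed the pulse width", {
  for (pars in list(par_ss(), par_rs(), par_pp())) {
    ev <- detect_events(current_step(pars, 20))
    expect_lte(sum(ev$half_ad), 2000 + 1e-9)
    f <- compute_features(ev, 2000)
    expect_lte(f$ddr, 1)
    expect_true(all(ev$half_ad <= ev$offset - ev$onset + 0.2))
  }
})

test_that("pattern labels follow the event-composition rules", {
  ap <- function(n) data.frame(onset = as.numeric(seq_len(n)),
                               offset = as.numeric(seq_len(n)) + 1,
                               peak = rep(0, n), half_ad = rep(10, n),
                               kind = rep("AP", n))
  pl <- data.frame(onset = 0, offset = 500, peak = -20, half_ad = 400,
                   kind = "plateau")
  expect_equal(classify_pattern(ap(0)), "quiescent")
  expect_equal(classify_pattern(ap(3)), "SS")
  expect_equal(classify_pattern(ap(4)), "RS")
  expect_equal(classify_pattern(pl), "PP")
  expect_equal(classify_pattern(rbind(pl, ap(1))), "PP")
  expect_equal(classify_pattern(rbind(pl, ap(2))), "ME")
})

test_that("classification of the canonical triple survives resampling", {
  pts <- list(SS = par_ss(), RS = par_rs(), PP = par_pp())
  for (nm in names(pts)) {
    lab1 <- classify_point(pts[[nm]], 20, settle = 500)
    tr2 <- current_step(pts[[nm]], 20, dt = 0.005, record_every = 20L,
                        settle = 500)
    expect_equal(lab1, nm)
    expect_equal(classify_pattern(detect_events(tr2)), nm)
  }
})

test_that("slow inactivation produces the four-phase burst cycle", {
  p <- v1r_params("slow_inactivation", GNap = 2.5, GKdr = 5)
  tr <- current_step(p, 10, duration = 15000, pre = 200, post = 200)
  b <- burst_structure(tr)
  expect_gte(length(b$up_durations), 3)
  expect_gte(length(b$down_durations), 2)
  segs <- b$segments
  # slow gate inactivates during plateaus, de-inactivates during quiescence
  expect_true(all(segs$ds_mean[segs$state == "up"] < 0))
  interior_down <- segs$state == "down" & seq_len(nrow(segs)) > 1
  expect_true(all(segs$ds_mean[interior_down] > 0))
  # the first plateau outlasts the following ones
  ups <- b$up_durations
  expect_gt(ups[1], max(ups[-1]))
  # tau_s = 2 s gives up and down states of comparable durations here
  expect_gt(mean(ups[-1]) / mean(b$down_durations), 0.5)
  expect_lt(mean(ups[-1]) / mean(b$down_durations), 2)
})

test_that("phenotyping a trace cohort yields the feature-table schema", {
  traces <- lapply(c(0.2, 1.2), function(g) {
    pp <- v1r_params("basic", GNap = g, GKdr = 10)
    current_step(pp, 20, duration = 1000, settle = 500)
  })
  ft <- phenotype_traces(traces)
  expect_named(ft, c("cell_id", "mean_half_ad_ms", "cv_half_ad_pct", "ddr",
                     "n_events", "pattern"))
  expect_equal(ft$pattern, c("SS", "RS"))
})
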