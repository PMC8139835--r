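test_that("RK4 matches the closed-form RC response with channels blocked", {
  p <- v1r_params("basic", GNat = 0, GNap = 0, GKdr = 0)
  tr <- current_step(p, 10, duration = 100, pre = 50, post = 50, settle = 0)
  w <- tr$t >= 50 & tr$t <= 150
  exact <- -60 + 10 * (1 - exp(-(tr$t[w] - 50) / 13))
  expect_lt(max(abs(tr$V[w] - exact)), 1e-6)
  # and the decay back to rest after the pulse
  w2 <- tr$t >= 150
  v150 <- -60 + 10 * (1 - exp(-100 / 13))
  exact2 <- -60 + (v150 + 60) * exp(-(tr$t[w2] - 150) / 13)
  expect_lt(max(abs(tr$V[w2] - exact2)), 1e-6)
})

test_that("RK4 step-halving changes a spiking trace by less than 1e-3 mV", {
  p <- par_rs()
  tr1 <- current_step(p, 20, duration = 2000, record_every = 20L, dt = 0.01)
  tr2 <- current_step(p, 20, duration = 2000, record_every = 40L, dt = 0.005)
  expect_equal(nrow(tr1), nrow(tr2))
  expect_lt(max(abs(tr1$V - tr2$V)), 1e-3)
})

test_that("canonical conductance pairs give one spike, repetitive firing, plateau", {
  # single spiking: 1-3 onset spikes then sustained subthreshold depolarization
  ev_ss <- detect_events(current_step(par_ss(), 20))
  expect_gte(nrow(ev_ss), 1)
  expect_lte(nrow(ev_ss), 3)
  expect_true(all(ev_ss$kind == "AP"))
  # repetitive spiking
  ev_rs <- detect_events(current_step(par_rs(), 20))
  expect_gt(nrow(ev_rs), 10)
  expect_true(all(ev_rs$kind == "AP"))
  # plateau fills the pulse but never outlasts it
  tr_pp <- current_step(par_pp(), 20, post = 1000)
  ev_pp <- detect_events(tr_pp)
  expect_true(any(ev_pp$kind == "plateau"))
  late <- tr_pp$t > 2400  # 200 ms after pulse offset
  expect_lt(max(tr_pp$V[late]), -50)
})

test_that("a step family reproduces holding at 0 pA and firing above rheobase", {
  fam <- current_step_family(par_rs(), c(0, 10, 20), duration = 1000)
  expect_named(fam, c("0pA", "10pA", "20pA"))
  expect_lt(diff(range(fam[["0pA"]]$V)), 0.01)  # flat at rest
  expect_gt(nrow(detect_events(fam[["20pA"]])), 4)
  expect_error(current_step_family(par_rs(), c(-5, 10)), "amplitudes")
  rh <- rheobase(par_rs(), c(0, 50), tol = 1, duration = 500)
  expect_gt(rh, 5)
  expect_lt(rh, 25)
})

test_that("voltage-clamp currents superpose exactly across conductances", {
  p <- v1r_params("basic", GNap = 1, GKdr = 10, GA = 10,
                  include_IA = TRUE)
  run1 <- function(pp) vclamp_steps(pp, steps = 0, step_dur = 200,
                                    ttx = FALSE)[[1]]
  tot <- run1(p)
  pk <- p; pk$GNap <- 0; pk$GNat <- 0
  pna <- p; pna$GKdr <- 0; pna$GA <- 0
  expect_equal(tot$I_Kdr + tot$I_A, run1(pk)$I_Kdr + run1(pk)$I_A,
               tolerance = 1e-10)
  expect_equal(tot$I_Nat + tot$I_Nap, run1(pna)$I_Nat + run1(pna)$I_Nap,
               tolerance = 1e-10)
  # within one trace the K+ decomposition is exactly additive
  expect_equal(tot$I, tot$I_leak + tot$I_Nat + tot$I_Nap + tot$I_Kdr +
                 tot$I_A, tolerance = 1e-12)
  # the two-prepulse protocol isolates IA: a -30 mV prepulse inactivates hA
  # nearly completely, so subtracting the step families recovers IA (up to
  # the decaying n-gate mismatch inherited from the different prepulses)
  expect_lt(gate_steady_state(p$gates$hA, -30), 0.005)
  both <- vclamp_steps(p, prepulse = c(-100, 300), steps = 0,
                       step_dur = 200)[[1]]
  kdr_only <- vclamp_steps(p, prepulse = c(-30, 300), steps = 0,
                           step_dur = 200)[[1]]
  ia_sub <- (both$I_Kdr + both$I_A) - (kdr_only$I_Kdr + kdr_only$I_A)
  w <- both$t >= 300 & both$t <= 500
  expect_equal(max(ia_sub[w]), max(both$I_A[w]), tolerance = 0.05)
  expect_lt(max(abs(kdr_only$I_A[w])) / max(abs(both$I_A[w])), 0.01)
})

test_that("peak clamp current at +20 mV recovers the saturated Kdr conductance", {
  p <- v1r_params("basic", GNap = 1, GKdr = 10)
  tr <- vclamp_steps(p, prepulse = c(-30, 300), steps = 20, step_dur = 200,
                     leak_subtracted = TRUE)[[1]]
  w <- tr$t >= 300 & tr$t <= 500
  g_est <- max(tr$I_Kdr[w]) / (20 - p$EK)
  g_true <- p$GKdr * gate_steady_state(p$gates$n, 20)^3
  expect_equal(g_est, g_true, tolerance = 0.02)
})

test_that("the slow ramp isolates the persistent sodium current", {
  # without any sodium conductance the estimate vanishes identically
  p00 <- v1r_params("basic", GNat = 0, GNap = 0, GKdr = 10)
  r00 <- ramp_inap(p00)
  expect_true(all(abs(r00$inap$I) < 1e-9))
  # with the transient current present but GNap = 0, only the small window
  # component of INat contaminates the subtraction (well below a typical
  # persistent-current peak of tens of pA)
  p0 <- v1r_params("basic", GNap = 0, GKdr = 10)
  r0 <- ramp_inap(p0)
  expect_lt(max(abs(r0$inap$I)), 10)
  p <- v1r_params("basic", GNap = 0.8, GKdr = 10)
  r <- ramp_inap(p)
  expect_true(all(r$inap$I[r$inap$V < 55] <= 1e-9))  # inward below ENa
  expect_lt(r$peak, -10)
  # conductance recovered at the peak underestimates GNap by mp^3 * s
  g_rec <- r$peak / (r$V_peak - p$ENa)
  frac <- gate_steady_state(p$gates$mp, r$V_peak)^3
  expect_lt(g_rec, p$GNap)
  expect_equal(g_rec / p$GNap, frac, tolerance = 0.02)
})

test_that("pharmacology scales parameters as prescribed", {
  p <- v1r_params("basic", GNap = 0.2, GKdr = 10, I = 20)
  expect_equal(apply_pharmacology(p, four_ap = 0), p)
  p_ic <- apply_pharmacology(p, four_ap = 2.9,
                             dose_response = list(Imin = 0, IC50 = 2.9, nH = 1))
  expect_equal(p_ic$GKdr, 5)
  p_ttx <- apply_pharmacology(p, ttx = TRUE)
  expect_equal(p_ttx$GNat + p_ttx$GNap, 0)
  expect_error(apply_pharmacology(p, four_ap = -1), ">= 0")
  p300 <- apply_pharmacology(p, four_ap = 300, rheobase_matched = TRUE)
  expect_equal(p300$Gin, 0.77)
  expect_equal(p300$I, 20 * 0.77)
})

test_that("rising 4-AP walks a single-spiking cell through the firing sequence", {
  p <- v1r_params("basic", GNap = 0.3, GKdr = 10, I = 20)
  expect_equal(classify_point(p, p$I, settle = 500), "SS")
  labs <- vapply(c(10, 30, 100), function(conc) {
    p4 <- apply_pharmacology(p, four_ap = conc, rheobase_matched = TRUE)
    classify_point(p4, p4$I, settle = 500)
  }, character(1))
  # blocking the delayed rectifier crosses the firing-onset and
  # firing-offset boundaries in order: RS, then mixed events, then plateau
  expect_equal(labs, c("RS", "ME", "PP"))
})

test_that("membrane charging rate scales inversely with capacitance", {
  p <- v1r_params("basic", GNap = 1.2, GKdr = 10, I = 20)
  st <- steady_state_at(p, -50)
  p2 <- p; p2$Cin <- p$Cin / 2
  expect_equal(model_rhs(st, p2)[["V"]], 2 * model_rhs(st, p)[["V"]])
})

test_that("traces serialize to CSV with a JSON sidecar", {
  tr <- current_step(par_ss(), 20, duration = 100, pre = 50, post = 50,
                     settle = 100)
  f <- tempfile(fileext = ".csv")
  write_trace(tr, f)
  back <- utils::read.csv(f)
  expect_equal(back$V, tr$V)
  side <- jsonlite::read_json(paste0(f, ".json"), simplifyVector = TRUE)
  expect_equal(side$params$GNap, 0.2)
  unlink(c(f, paste0(f, ".json")))
})
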