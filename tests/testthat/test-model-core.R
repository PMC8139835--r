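test_that("gate steady states follow the Boltzmann convention", {
  n_gate <- list(V_half = -20, k = 15)
  expect_equal(gate_steady_state(n_gate, -20), 0.5)
  mp_gate <- list(V_half = -36, k = 9.5)
  expect_equal(gate_steady_state(mp_gate, -36), 0.5)
  # limits and monotonicity, activation vs inactivation
  expect_lt(gate_steady_state(n_gate, -200), 1e-5)
  expect_gt(gate_steady_state(n_gate, 200), 1 - 1e-5)
  h_gate <- list(V_half = -45, k = -5)
  V <- seq(-100, 40, by = 1)
  expect_true(all(diff(gate_steady_state(n_gate, V)) > 0))
  expect_true(all(diff(gate_steady_state(h_gate, V)) < 0))
  expect_error(gate_steady_state(list(V_half = 0, k = 0), 0), "k must be nonzero")
  expect_error(gate_spec(-20, 0, 10), "k must be nonzero")
})

test_that("sodium inactivation time constant spans 30 to 3 ms", {
  expect_equal(tau_h(-20), 16.5)
  expect_equal(tau_h(-1e6), 30)
  expect_equal(tau_h(1e6), 3)
  V <- seq(-120, 60, by = 1)
  tv <- tau_h(V)
  expect_true(all(diff(tv) < 0))
  expect_true(all(tv > 3 & tv < 30))
})

test_that("parameter construction enforces units and sign invariants", {
  p <- v1r_params("basic")
  expect_equal(p$Cin / p$Gin, 13)  # membrane time constant, ms
  expect_error(v1r_params("basic", Gin = -1), "conductances")
  expect_error(v1r_params("basic", Vr = -120), "EK < Vr < ENa")
  expect_error(v1r_params("basic", nonsense = 1), "unknown parameter")
  e14 <- v1r_params("E14_5")
  expect_equal(e14$Cin, 18)
  slow <- v1r_params("slow_inactivation")
  expect_true(slow$include_slow_inactivation)
  expect_equal(slow$gates$s$tau, 2000)
})

test_that("rhs vanishes at the leak fixed point and matches direct substitution", {
  p <- v1r_params("basic", GNat = 0, GNap = 0, GKdr = 0)
  st <- steady_state_at(p, p$Vr)
  expect_equal(unname(model_rhs(st, p)["V"]), 0)
  # V* = Vr + I/Gin
  p2 <- v1r_params("basic", GNat = 0, GNap = 0, GKdr = 0, I = 13)
  st2 <- steady_state_at(p2, -47)
  expect_equal(unname(model_rhs(st2, p2)["V"]), 0)
  # direct-substitution oracle at a depolarizing point
  p3 <- v1r_params("basic", GNap = 1.2, GKdr = 10, I = 20)
  st3 <- steady_state_at(p3, -60)
  dv <- unname(model_rhs(st3, p3)["V"])
  manual <- (p3$Gin * (p3$Vr + 60) +
             p3$GNat * st3[["m"]]^3 * st3[["h"]] * (p3$ENa + 60) +
             p3$GNap * st3[["mp"]]^3 * (p3$ENa + 60) +
             p3$GKdr * st3[["n"]]^3 * (p3$EK + 60) + 20) / p3$Cin
  expect_equal(dv, manual)
  expect_gt(dv, 0)
  expect_error(model_rhs(replace(st3, 1, NaN), p3), "non-finite")
})

test_that("steady-state current balance is consistent with the rhs", {
  p <- v1r_params("basic", GNap = 1.5, GKdr = 8, I = 10)
  for (V in c(-80, -55, -30, -10)) {
    st <- steady_state_at(p, V)
    expect_equal(steady_state_current(p, V),
                 unname(model_rhs(st, p)["V"]) * p$Cin, tolerance = 1e-12)
  }
})

test_that("gating derivatives point inward at the unit-interval boundaries", {
  p <- v1r_params("slow_inactivation", GNap = 1, GKdr = 5,
                  include_IA = TRUE, GA = 5)
  gates <- c("m", "h", "mp", "s", "n", "hA")
  for (V in c(-90, -40, 10)) {
    st0 <- steady_state_at(p, V); st0[gates] <- 0
    st1 <- steady_state_at(p, V); st1[gates] <- 1
    d0 <- model_rhs(st0, p); d1 <- model_rhs(st1, p)
    expect_true(all(d0[gates] > 0))
    expect_true(all(d1[gates] < 0))
  }
})

test_that("fixed-point counts match the known one- and three-root regimes", {
  # leak-only: unique stable fixed point at Vr
  p0 <- v1r_params("basic", GNat = 0, GNap = 0, GKdr = 0)
  fp0 <- find_fixed_points(p0)
  expect_equal(nrow(fp0), 1)
  expect_equal(fp0$V, -60, tolerance = 1e-5)
  expect_true(fp0$stable)
  # low GKdr: a unique, always stable fixed point across the GNap range
  for (g in c(0, 0.8, 1.6, 2.5)) {
    p1 <- v1r_params("basic", GNap = g, GKdr = 2.5, I = 20)
    fp1 <- find_fixed_points(p1)
    expect_equal(nrow(fp1), 1)
    expect_true(all(fp1$stable))
  }
  # bistable branch: three coexisting fixed points
  p3 <- v1r_params("basic", GNap = 1.65, GKdr = 5, I = 5)
  expect_equal(nrow(find_fixed_points(p3)), 3)
})

test_that("fixed-point stability agrees with long-horizon simulation", {
  set.seed(11)
  n_ok <- 0
  for (rep in 1:60) {
    p <- v1r_params("basic",
                    GNap = runif(1, 0, 2.5), GKdr = runif(1, 1, 15),
                    I = runif(1, 0, 30))
    fp <- find_fixed_points(p)
    i <- which.min(fp$V)
    if (abs(fp$max_re[i]) < 1e-3) next  # skip near-marginal points
    x0 <- attr(fp, "states")[[i]]
    x0["V"] <- x0["V"] + 0.5
    tr <- simulate_autonomous(p, x0, 2000)
    returned <- abs(tail(tr$V, 1) - fp$V[i]) < 0.5
    expect_equal(returned, fp$stable[i],
                 info = sprintf("GNap=%.3f GKdr=%.3f I=%.3f",
                                p$GNap, p$GKdr, p$I))
    n_ok <- n_ok + 1
  }
  expect_gte(n_ok, 50)
})

test_that("fixed-point sweep folds agree with dense-grid root counting", {
  p <- v1r_params("basic", GNap = 2, GKdr = 5)
  cv <- iv_fixed_point_curve(p, "I", c(-20, 20), n = 81)
  nr <- attr(cv, "n_roots")
  expect_true(any(nr == 3))  # S-shaped
  # dense-grid oracle on the same steady-state relation
  Ig <- seq(-20, 20, length.out = 81)
  oracle <- vapply(Ig, function(I) {
    p$I <- I
    Vg <- seq(-100, 40, length.out = 10000)
    f <- steady_state_current(p, Vg)
    sum(f[-1] * f[-length(f)] < 0)
  }, numeric(1))
  expect_equal(nr, as.integer(oracle))
  # no inward current: monotone single branch
  p2 <- v1r_params("basic", GNap = 0, GKdr = 10, GNat = 0)
  cv2 <- iv_fixed_point_curve(p2, "I", c(-20, 20), n = 41)
  expect_true(all(attr(cv2, "n_roots") == 1))
  expect_error(iv_fixed_point_curve(p, "I", c(5, 5)), "range")
})

test_that("parameter sets round-trip through JSON", {
  p <- v1r_params("slow_inactivation", GNap = 2.5, GKdr = 5, I = 10)
  f <- tempfile(fileext = ".json")
  write_params(p, f)
  q <- read_params(f)
  expect_equal(q$GNap, p$GNap)
  expect_equal(q$gates$s$tau, p$gates$s$tau)
  expect_equal(v1rex:::.param_vec(q), v1rex:::.param_vec(p))
  unlink(f)
})
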