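#' Gate specification
#'
#' Describes one Hodgkin-Huxley gating variable by its Boltzmann steady-state
#' curve and kinetics. Activation gates have positive steepness `k`,
#' inactivation gates negative `k`, so that `gate_steady_state()` is increasing
#' in voltage exactly for activation gates.
#'
#' @param V_half Mid-(in)activation voltage (mV).
#' @param k Signed steepness (mV); > 0 for activation, < 0 for inactivation.
#' @param tau Time constant (ms). Use `NA` for a voltage-dependent rule
#'   (transient sodium inactivation) and `0` for instantaneous activation
#'   (the A-current activation gate).
#' @param exponent Integer power applied to the gate in the current term.
#' @return An object of class `gate_spec`.
#' @export
gate_spec <- function(V_half, k, tau, exponent = 1L) {
  if (!is.finite(V_half) || !is.finite(k)) stop("V_half and k must be finite")
  if (k == 0) stop("invalid gate: steepness k must be nonzero")
  if (exponent < 1) stop("gate exponent must be >= 1")
  if (!is.na(tau) && tau < 0) stop("tau must be >= 0")
  structure(list(V_half = V_half, k = k, tau = tau,
                 exponent = as.integer(exponent)),
            class = "gate_spec")
}

#' Boltzmann steady-state activation/inactivation
#'
#' \eqn{x_\infty(V) = 1 / (1 + \exp(-(V - V_{1/2})/k))}. Monotone increasing in
#' `V` iff `k > 0` (activation convention).
#'
#' @param gate A `gate_spec`, or a list with `V_half` and `k`.
#' @param V Membrane voltage (mV), vectorized.
#' @return Steady-state open fraction in (0, 1).
#' @export
gate_steady_state <- function(gate, V) {
  if (is.null(gate$k) || gate$k == 0) stop("invalid gate: steepness k must be nonzero")
  1 / (1 + exp(-(V - gate$V_half) / gate$k))
}

#' Voltage-dependent inactivation time constant of the transient sodium current
#'
#' \eqn{\tau_h(V) = 16.5 - 13.5\,\tanh((V + 20)/15)} ms, decreasing
#' monotonically from 30 ms at hyperpolarized voltages to 3 ms at depolarized
#' voltages. The same rule governs the slow-inactivation gate only if its
#' constant time constant is overridden to `NA` (not the default).
#'
#' @param V Membrane voltage (mV), vectorized.
#' @param coef Coefficients `(a, b, V0, kV)` of `a - b*tanh((V + V0)/kV)`.
#' @return Time constant in ms, strictly inside (3, 30) for finite `V`.
#' @export
tau_h <- function(V, coef = c(16.5, 13.5, 20, 15)) {
  coef[1] - coef[2] * tanh((V + coef[3]) / coef[4])
}

#' Model parameter set
#'
#' Assembles the full parameter set of the single-compartment model: passive
#' properties, maximal conductances, reversal potentials and the gating
#' kinetics of the transient sodium (m, h), persistent sodium (mp, s),
#' delayed-rectifier potassium (n) and A-type potassium (mA, hA) currents.
#' Units are fixed to \{mV, ms, nS, pF, pA\} so that pF mV/ms = pA holds
#' identically.
#'
#' @param preset One of `"basic"` (E12.5 passive properties, no IA, no
#'   slow inactivation), `"slow_inactivation"` (adds the slow
#'   inactivation gate s of the persistent sodium current, tau_s = 2 s), or
#'   `"E14_5"` (basic model with Cin = 18 pF).
#' @param ... Named overrides of any top-level field (e.g. `GNap = 1.2`,
#'   `I = 20`, `tau_s = 2`).
#' @return An object of class `v1r_params`.
#' @examples
#' p <- v1r_params("basic", GNap = 1.2, GKdr = 10, I = 20)
#' @export
v1r_params <- function(preset = "basic", ...) {
  p <- list(
    Cin = 13, Gin = 1, Vr = -60, I = 0,
    ENa = 60, EK = -96,
    GNat = 20, GNap = 0, GKdr = 0, GA = 0,
    gates = list(
      m  = gate_spec(-26,  9.5, 1.5, 3L),
      h  = gate_spec(-45, -5,   NA,  1L),   # tau from tau_h()
      mp = gate_spec(-36,  9.5, 1.5, 3L),
      s  = gate_spec(-30, -5,   2000, 1L),
      n  = gate_spec(-20, 15,   10,  3L),
      mA = gate_spec(-30, 12,   0,   1L),   # instantaneous
      hA = gate_spec(-70, -7,   23,  1L)
    ),
    tau_h_coef = c(16.5, 13.5, 20, 15),
    include_IA = FALSE,
    include_slow_inactivation = FALSE
  )
  preset <- match.arg(preset,
                      c("basic", "slow_inactivation", "E14_5"))
  if (preset == "slow_inactivation") {
    p$include_slow_inactivation <- TRUE
  } else if (preset == "E14_5") {
    p$Cin <- 18
  }
  dots <- list(...)
  if (length(dots)) {
    if ("tau_s" %in% names(dots)) {
      p$gates$s$tau <- dots$tau_s
      dots$tau_s <- NULL
    }
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  p$preset <- preset
  class(p) <- "v1r_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  g <- c(p$Gin, p$GNat, p$GNap, p$GKdr, p$GA)
  if (any(g < 0)) stop("conductances must be >= 0")
  if (p$Cin <= 0 || p$Gin <= 0) stop("Cin and Gin must be > 0")
  if (!(p$EK < p$Vr && p$Vr < p$ENa)) stop("need EK < Vr < ENa")
  invisible(p)
}

#' @export
print.v1r_params <- function(x, ...) {
  cat("v1r model parameters (", x$preset, ")\n", sep = "")
  cat(sprintf("  Cin = %g pF, Gin = %g nS, Vr = %g mV, I = %g pA\n",
              x$Cin, x$Gin, x$Vr, x$I))
  cat(sprintf("  GNat = %g, GNap = %g, GKdr = %g, GA = %g nS\n",
              x$GNat, x$GNap, x$GKdr, x$GA))
  cat(sprintf("  IA: %s; slow inactivation of INap: %s (tau_s = %g ms)\n",
              x$include_IA, x$include_slow_inactivation, x$gates$s$tau))
  invisible(x)
}

# Flat numeric vector handed to the C++ engines; order is fixed and mirrored
# in src/engine.cpp.
.param_vec <- function(p) {
  g <- p$gates
  c(Cin = p$Cin, Gin = p$Gin, Vr = p$Vr, I = p$I,
    ENa = p$ENa, EK = p$EK,
    GNat = p$GNat, GNap = p$GNap, GKdr = p$GKdr,
    GA = if (p$include_IA) p$GA else 0,
    Vm = g$m$V_half,  km = g$m$k,  taum = g$m$tau,
    Vh = g$h$V_half,  kh = g$h$k,
    Vmp = g$mp$V_half, kmp = g$mp$k, taump = g$mp$tau,
    Vs = g$s$V_half,  ks = g$s$k,  taus = g$s$tau,
    Vn = g$n$V_half,  kn = g$n$k,  taun = g$n$tau,
    VmA = g$mA$V_half, kmA = g$mA$k,
    VhA = g$hA$V_half, khA = g$hA$k, tauhA = g$hA$tau,
    th1 = p$tau_h_coef[1], th2 = p$tau_h_coef[2],
    th3 = p$tau_h_coef[3], th4 = p$tau_h_coef[4],
    slow = as.numeric(p$include_slow_inactivation),
    ia = as.numeric(p$include_IA))
}

# plain-list view for JSON serialization
.params_plain <- function(p) {
  p <- unclass(p)
  p$gates <- lapply(p$gates, unclass)
  p
}

#' Write / read parameter sets as JSON
#'
#' Keys mirror the model parameter names; gate specs are stored as lists.
#'
#' @param p A `v1r_params` object.
#' @param path File path.
#' @return `read_params()` returns a `v1r_params` object.
#' @export
write_params <- function(p, path) {
  jsonlite::write_json(.params_plain(p), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- v1r_params(raw$preset)
  for (f in c("Cin", "Gin", "Vr", "I", "ENa", "EK",
              "GNat", "GNap", "GKdr", "GA",
              "include_IA", "include_slow_inactivation"))
    p[[f]] <- raw[[f]]
  for (gn in names(p$gates)) {
    tau <- raw$gates[[gn]]$tau
    if (is.null(tau)) tau <- NA  # JSON null: voltage-dependent rule
    p$gates[[gn]] <- gate_spec(raw$gates[[gn]]$V_half, raw$gates[[gn]]$k,
                               tau, raw$gates[[gn]]$exponent)
  }
  p$tau_h_coef <- as.numeric(raw$tau_h_coef)
  validate_params(p)
  p
}
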