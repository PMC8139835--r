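# Seed-deterministic generators for every pipeline input: conductance-pair
# populations with the observed GNap-GKdr zonation, firing-feature cohorts
# matching the published cluster centroids and counts, and noisy Hill
# dose-response tables.

# Cluster centroids of the five firing-pattern groups (E12.5 cohort,
# n = 163): mean 1/2Ad (ms), CV 1/2Ad (%), ddr, group size, and the standard
# deviations reconstructed from the reported SEMs (SD = SEM * sqrt(n)).
# The 1/2Ad and ddr centroids of the two mixed-event groups are not reported
# separately from each other (their difference is not significant); they are
# placed between the RS and PP centroids with a dispersion small enough to
# keep the groups resolvable.
.cohort_default <- function() {
  list(
    SS = list(n = 46, half_ad = 9.73,  cv = 0,      ddr = 0.0051,
              sd_half_ad = 0.66 * sqrt(46), sd_cv = 0,
              sd_ddr = 0.0004 * sqrt(46)),
    RS = list(n = 69, half_ad = 23.91, cv = 27.36,  ddr = 0.11,
              sd_half_ad = 1.43 * sqrt(69), sd_cv = 1.64 * sqrt(69),
              sd_ddr = 0.01 * sqrt(69)),
    PP = list(n = 35, half_ad = 833.5, cv = 0,      ddr = 0.441,
              sd_half_ad = 89.99 * sqrt(35), sd_cv = 0,
              sd_ddr = 0.044 * sqrt(35)),
    ME_short = list(n = 4, half_ad = 90, cv = 170.9, ddr = 0.16,
                    sd_half_ad = 12, sd_cv = 8.9 * sqrt(4), sd_ddr = 0.025),
    ME_long = list(n = 9, half_ad = 280, cv = 87.61, ddr = 0.30,
                   sd_half_ad = 40, sd_cv = 7.37 * sqrt(9), sd_ddr = 0.04))
}

#' Generate a synthetic firing-feature cohort
#'
#' Samples a feature table (mean 1/2Ad, CV 1/2Ad, ddr) from five groups
#' matching the published cluster centroids and sizes: single spiking (SS),
#' repetitive spiking (RS), plateau potential (PP) and the two mixed-event
#' groups (short-PP and long-PP). Mean 1/2Ad and ddr are log-normal (the
#' clustering operates in decimal-log space), CV is normal truncated at zero;
#' SS and PP rows have CV exactly 0 (three or fewer events, or a single
#' plateau). Dispersions derive from the reported SEMs via SD = SEM*sqrt(n).
#'
#' @param spec Cohort specification, a named list of groups each holding
#'   `n`, `half_ad`, `cv`, `ddr` and the matching `sd_*`; default is the
#'   published 163-cell cohort (46/69/35/4/9).
#' @param seed RNG seed; tables are bitwise reproducible given the seed.
#' @param rho Within-cluster correlation between log mean 1/2Ad and log ddr.
#' @return Data frame `(cell_id, group, mean_half_ad_ms, cv_half_ad_pct,
#'   ddr)` with `sum(n)` rows.
#' @export
generate_feature_table <- function(spec = .cohort_default(), seed = 1,
                                   rho = 0.2) {
  set.seed(seed)
  rows <- lapply(names(spec), function(g) {
    s <- spec[[g]]
    if (s$n == 0) return(NULL)
    if (s$half_ad <= 0 || s$ddr <= 0) stop("centroids must be positive")
    cv <- if (s$sd_cv == 0) rep(s$cv, s$n)
          else pmax(stats::rnorm(s$n, s$cv, s$sd_cv), 0)
    # log event duration and log duty-cycle ratio are correlated within a
    # cell (ddr is the summed duration over the pulse width), so the two
    # log-normal draws share a common component
    z1 <- stats::rnorm(s$n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(s$n)
    scale_ln <- function(z, mean, sd) {
      sdlog <- sd / (mean * log(10))
      mulog <- log10(mean) - (sdlog * log(10))^2 / (2 * log(10))
      10^(mulog + sdlog * z)
    }
    data.frame(group = g,
               mean_half_ad_ms = scale_ln(z1, s$half_ad, s$sd_half_ad),
               cv_half_ad_pct = cv,
               ddr = pmin(scale_ln(z2, s$ddr, s$sd_ddr), 1))
  })
  out <- do.call(rbind, rows)
  out <- cbind(cell_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Sample a conductance-pair population with the observed zonation
#'
#' Draws (GNap, GKdr) pairs from per-pattern boxes respecting the observed
#' zonation of the GNap-GKdr plane at E12.5: SS only below GNap = 0.6 nS;
#' above it, RS for GKdr > 3.5 nS and PP below; ME in a narrow band at the
#' RS/PP boundary. The `"E14_5"` preset shifts GNap down and GKdr up,
#' mirroring the developmental trajectory (cells sink into the SS region).
#'
#' @param n Number of cells, > 0 (0 gives an empty population).
#' @param seed RNG seed.
#' @param age `"E12_5"` or `"E14_5"`.
#' @param proportions Sampling weights of the four patterns, defaulting to
#'   the cohort proportions (SS/RS/PP/ME = 46/69/35/13 of 163).
#' @return Data frame `(GNap, GKdr, label)` in nS.
#' @export
sample_conductance_population <- function(n, seed = 1,
                                          age = c("E12_5", "E14_5"),
                                          proportions = c(SS = 46, RS = 69,
                                                          PP = 35, ME = 13)) {
  age <- match.arg(age)
  if (n == 0)
    return(data.frame(GNap = numeric(0), GKdr = numeric(0),
                      label = character(0)))
  set.seed(seed)
  lab <- sample(names(proportions), n, replace = TRUE,
                prob = proportions / sum(proportions))
  boxes <- list(  # GNap lo/hi, GKdr lo/hi (nS); interiors of the zones
    SS = c(0.05, 0.55, 3.0, 11.0),
    RS = c(0.70, 1.60, 4.5, 12.0),
    PP = c(0.80, 2.00, 1.5, 3.2),
    ME = c(1.20, 2.20, 3.3, 3.9))
  gnap <- numeric(n); gkdr <- numeric(n)
  for (i in seq_len(n)) {
    b <- boxes[[lab[i]]]
    gnap[i] <- stats::runif(1, b[1], b[2])
    gkdr[i] <- stats::runif(1, b[3], b[4])
  }
  if (age == "E14_5") {
    gnap <- gnap * 0.6   # sodium-channel density decreases
    gkdr <- gkdr * 1.8   # delayed rectifier grows with cell size
  }
  data.frame(GNap = gnap, GKdr = gkdr, label = lab)
}

#' Generate a noisy dose-response table
#'
#' Remaining-current percentages from a Hill model with additive Gaussian
#' noise, clipped to [0, 110] %.
#'
#' @param model Hill model list `(Imin, IC50, nH)`; defaults to the
#'   delayed-rectifier 4-AP block (IC50 = 2.9 uM, nH = 1, Imin = 5).
#' @param doses Concentrations (uM), all > 0 (the 100% control at zero dose
#'   is implicit in the normalization).
#' @param replicates Replicates per dose.
#' @param noise_sd Gaussian noise SD (percentage points).
#' @param seed RNG seed.
#' @return Data frame `(dose_uM, replicate, response_pct)`.
#' @export
generate_dose_response <- function(model = list(Imin = 5, IC50 = 2.9, nH = 1),
                                   doses = c(0.3, 1, 3, 10, 30, 100, 300),
                                   replicates = 3, noise_sd = 5, seed = 1) {
  if (any(doses <= 0)) stop("doses must be > 0")
  set.seed(seed)
  grid <- expand.grid(dose_uM = doses, replicate = seq_len(replicates))
  mu <- hill_inhibition(grid$dose_uM, model)
  grid$response_pct <- pmin(pmax(mu + stats::rnorm(nrow(grid), 0, noise_sd),
                                 0), 110)
  grid[order(grid$dose_uM, grid$replicate), ]
}
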