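#' Standardize a firing-feature table for clustering
#'
#' Clustering operates on (log10 mean 1/2Ad, CV 1/2Ad, log10 ddr), each
#' column centred to zero mean and scaled to unit (sample, n-1) standard
#' deviation. Mean 1/2Ad and ddr must be strictly positive for the decimal
#' logarithm to be defined.
#'
#' @param table Data frame with columns `mean_half_ad_ms`, `cv_half_ad_pct`,
#'   `ddr` (extra columns are ignored).
#' @return Numeric matrix (n x 3) with zero column means and unit column SDs.
#' @export
standardize_features <- function(table) {
  need <- c("mean_half_ad_ms", "cv_half_ad_pct", "ddr")
  if (!all(need %in% names(table)))
    stop("table must have columns ", paste(need, collapse = ", "))
  if (nrow(table) < 2) stop("need at least 2 rows to standardize")
  bad <- which(table$mean_half_ad_ms <= 0 | table$ddr <= 0)
  if (length(bad))
    stop("non-positive mean_half_ad_ms or ddr in row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  m <- cbind(log_mean_half_ad = log10(table$mean_half_ad_ms),
             cv_half_ad = table$cv_half_ad_pct,
             log_ddr = log10(table$ddr))
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) stop("zero-variance feature column; cannot z-score")
  scale(m)[, , drop = FALSE]
}

#' Complete-linkage hierarchical clustering
#'
#' Agglomerative clustering with the Euclidean metric and complete linkage
#' (intercluster distance = maximum pairwise distance); the dendrogram is cut
#' at `k` clusters. Deterministic given the row order.
#'
#' @param matrix Numeric matrix of standardized features (rows = cells).
#' @param k Number of clusters, `2 <= k <= nrow - 1`.
#' @return Integer cluster labels (length `nrow(matrix)`); the `hclust` tree
#'   is attached as attribute `tree`.
#' @export
hierarchical_cluster <- function(matrix, k) {
  n <- nrow(matrix)
  if (k < 2 || k > n - 1) stop("k must be in [2, n-1]")
  tree <- stats::hclust(stats::dist(matrix, method = "euclidean"),
                        method = "complete")
  labels <- stats::cutree(tree, k = k)
  attr(labels, "tree") <- tree
  labels
}

#' Select the number of clusters by mean silhouette width
#'
#' Computes the silhouette width of every point for each candidate `k`
#' (complete-linkage labels) and picks the `k` maximizing the mean width.
#' Singleton clusters get silhouette 0.
#'
#' @param matrix Standardized feature matrix.
#' @param k_range Candidate cluster numbers (default 2..12).
#' @return List with `best_k`, `mean_widths` (named by k) and `widths`
#'   (list of per-point silhouette vectors).
#' @export
silhouette_select_k <- function(matrix, k_range = 2:12) {
  n <- nrow(matrix)
  if (max(k_range) > n - 1) stop("max k must be <= n - 1")
  d <- stats::dist(matrix, method = "euclidean")
  tree <- stats::hclust(d, method = "complete")
  widths <- lapply(k_range, function(k) {
    lab <- stats::cutree(tree, k = k)
    sil <- cluster::silhouette(lab, d)
    w <- sil[, "sil_width"]
    w[tabulate(lab)[lab] == 1] <- 0
    w
  })
  names(widths) <- k_range
  mw <- vapply(widths, mean, numeric(1))
  list(best_k = k_range[which.max(mw)], mean_widths = mw, widths = widths)
}

#' Hill dose-inhibition curve (remaining current)
#'
#' \deqn{remaining(c) = (100 - I_{min}) / (1 + (c/IC_{50})^{n_H}) + I_{min}}
#' in percent of the control current: 100% at zero concentration, `Imin` at
#' saturating concentration, monotone decreasing.
#'
#' @param conc Concentration(s), uM, >= 0.
#' @param model List or coefficients with `Imin` (%), `IC50` (uM), `nH`.
#' @return Remaining current in percent.
#' @export
hill_inhibition <- function(conc, model) {
  if (any(conc < 0)) stop("concentration must be >= 0")
  (100 - model$Imin) / (1 + (conc / model$IC50)^model$nH) + model$Imin
}

#' Fit the Hill equation to a dose-response table
#'
#' Bounded Levenberg-Marquardt least squares of the remaining-current Hill
#' curve, with `Imin` in [0, 100), `IC50 > 0`, `nH` in (0, 10]. Initial
#' guesses: `Imin` = smallest response, `IC50` = dose whose response is
#' nearest the midpoint, `nH = 1`.
#'
#' @param doses Concentrations (uM), at least 4 points spanning the midpoint.
#' @param responses Remaining current (%) matching `doses`.
#' @return List `(Imin, IC50, nH, residual_sd, se, fit)` where `se` holds the
#'   parameter standard errors and `fit` the `nls`-class object.
#' @export
fit_hill <- function(doses, responses) {
  if (length(doses) != length(responses)) stop("length mismatch")
  if (length(doses) < 4) stop("need at least 4 dose points")
  if (max(responses) - min(responses) < 1)
    stop("no inhibition signal in responses")
  imin0 <- max(min(responses), 0)
  mid <- (100 + imin0) / 2
  ic0 <- doses[which.min(abs(responses - mid))]
  if (ic0 <= 0) ic0 <- stats::median(doses[doses > 0])
  df <- data.frame(conc = doses, resp = responses)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      resp ~ (100 - Imin) / (1 + (conc / IC50)^nH) + Imin,
      data = df,
      start = list(Imin = imin0, IC50 = ic0, nH = 1),
      lower = c(Imin = 0, IC50 = 1e-9, nH = 1e-3),
      upper = c(Imin = 99.999, IC50 = Inf, nH = 10),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("Hill fit failed (starts: Imin=", signif(imin0, 3), ", IC50=",
           signif(ic0, 3), ", nH=1): ", conditionMessage(e)))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  list(Imin = unname(cf["Imin"]), IC50 = unname(cf["IC50"]),
       nH = unname(cf["nH"]),
       residual_sd = stats::sigma(fit), se = se, fit = fit)
}
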