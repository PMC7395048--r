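#' Fit Michaelis-Menten kinetics to microsomal incubation data
#'
#' Nonlinear least-squares fit of `v = Vmax * S / (Km + S)` to metabolite
#' formation rates measured in microsomal incubations. Initial values are
#' taken from the data (`Vmax0 = max(v)`, `Km0` = substrate concentration
#' at half-maximal rate, linearly interpolated), the fit is unweighted,
#' and parameter standard deviations come from the covariance of the
#' least-squares estimate.
#'
#' @param data a data frame with columns `substrate_uM` and
#'   `rate_nmol_min_mg` (an `incubation` dataset from
#'   [read_incubation_csv()] or [gen_mm_incubation()] qualifies), or two
#'   numeric vectors via `substrate_uM` / `rate`.
#' @param substrate_uM,rate optional numeric vectors used when `data` is
#'   missing.
#' @return An object of class `mm_fit`: list with `Vmax`, `Km`, their
#'   standard deviations, `catalytic_efficiency` (uL/min/mg), residual sum
#'   of squares, convergence flag and a `reliable` flag (FALSE when `Km`
#'   exceeds 10x the largest tested concentration).
#' @examples
#' s <- c(10, 25, 50, 100, 250, 500, 1000, 1500)
#' fit <- fit_michaelis_menten(substrate_uM = s, rate = 0.82 * s / (275 + s))
#' c(fit$Vmax, fit$Km)
#' @export
fit_michaelis_menten <- function(data = NULL, substrate_uM = NULL,
                                 rate = NULL) {
  if (!is.null(data)) {
    substrate_uM <- data$substrate_uM
    rate <- data$rate_nmol_min_mg
  }
  stopifnot(length(substrate_uM) == length(rate),
            all(substrate_uM > 0), all(rate >= 0))
  if (length(unique(substrate_uM)) < 4)
    stop("Michaelis-Menten fitting requires >= 4 distinct concentrations")

  # initialization from pooled means per concentration
  agg <- stats::aggregate(rate, list(S = substrate_uM), mean)
  agg <- agg[order(agg$S), ]
  vmax0 <- max(agg$x)
  half <- vmax0 / 2
  above <- which(agg$x >= half)
  km0 <- if (length(above) && above[1] > 1) {
    i <- above[1]
    stats::approx(agg$x[c(i - 1, i)], agg$S[c(i - 1, i)], xout = half)$y
  } else {
    stats::median(agg$S)
  }
  df <- data.frame(S = substrate_uM, v = rate)
  fit <- minpack.lm::nlsLM(v ~ Vmax * S / (Km + S), data = df,
                           start = list(Vmax = vmax0, Km = km0),
                           lower = c(1e-12, 1e-12),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) c(NA_real_, NA_real_))
  converged <- fit$convInfo$isConv
  reliable <- converged && est[["Km"]] <= 10 * max(substrate_uM)
  if (!reliable)
    warning("Michaelis-Menten fit flagged unreliable (non-convergence or ",
            "Km beyond 10x the largest tested concentration)")
  structure(list(
    Vmax = est[["Vmax"]], Vmax_sd = se[[1]],
    Km = est[["Km"]], Km_sd = se[[2]],
    catalytic_efficiency = catalytic_efficiency(est[["Vmax"]], est[["Km"]]),
    rss = sum(stats::resid(fit)^2),
    converged = converged, reliable = reliable
  ), class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf(
    "Michaelis-Menten fit: Vmax = %.3g +/- %.2g nmol/min/mg, Km = %.4g +/- %.3g uM\n  catalytic efficiency %.3g uL/min/mg%s\n",
    x$Vmax, x$Vmax_sd, x$Km, x$Km_sd, x$catalytic_efficiency,
    if (x$reliable) "" else "  [UNRELIABLE]"))
  invisible(x)
}

#' Catalytic efficiency
#'
#' `Vmax / Km * 1000`, in uL/min/mg microsomal protein.
#'
#' @param Vmax maximum rate (nmol/min/mg).
#' @param Km Michaelis-Menten constant (uM).
#' @return Catalytic efficiency (uL/min/mg).
#' @export
catalytic_efficiency <- function(Vmax, Km) {
  if (any(Km <= 0)) stop("Km must be > 0")
  Vmax / Km * 1000
}

#' Scale a microsomal Vmax to the whole liver
#'
#' Converts an unscaled in vitro maximum rate (nmol/min/mg microsomal
#' protein) to a whole-body in vivo maximum rate (umol/h) using the liver
#' microsomal protein yield and liver mass (liver density 1 g/mL):
#' `Vmax_vivo = Vmax_c * 60/1000 * MPL * VLc * BW * 1000`.
#'
#' @param Vmax_c unscaled maximum rate (nmol/min/mg microsomal protein).
#' @param MPL microsomal protein yield (mg/g liver).
#' @param VLc liver volume as fraction of body weight.
#' @param BW body weight (kg).
#' @return Whole-liver Vmax (umol/h).
#' @examples
#' scale_vmax_in_vivo(0.82, 32, 0.0257, 70)   # ~2832 umol/h
#' @export
scale_vmax_in_vivo <- function(Vmax_c, MPL, VLc, BW) {
  stopifnot(Vmax_c >= 0, MPL > 0, VLc > 0, BW > 0)
  Vmax_c * 60 / 1000 * MPL * (VLc * BW * 1000)
}

#' Classify intestinal formation rates as negligible
#'
#' Formation rates observed with intestinal microsomes are compared to the
#' hepatic rates at the same substrate concentrations; when they fall below
#' a floor (default 8% of the hepatic rate) they are reported as
#' "negligible - not fitted" rather than being fitted, mirroring the
#' decision to omit intestinal metabolism from the PBK model.
#'
#' @param intestinal_rate,hepatic_rate rates at matched concentrations
#'   (nmol/min/mg).
#' @param floor_fraction fraction of the hepatic rate below which the
#'   intestinal contribution is deemed negligible.
#' @return List with `negligible` (logical) and the observed ratios.
#' @export
assess_intestinal_rates <- function(intestinal_rate, hepatic_rate,
                                    floor_fraction = 0.08) {
  stopifnot(length(intestinal_rate) == length(hepatic_rate),
            all(hepatic_rate > 0))
  ratio <- intestinal_rate / hepatic_rate
  list(negligible = all(ratio < floor_fraction), ratio = ratio,
       floor_fraction = floor_fraction)
}

#' Read a microsomal incubation CSV
#'
#' Expected columns: `substrate_uM`, `rate_nmol_min_mg`, `replicate`.
#'
#' @param path CSV file path.
#' @return A data frame of class `incubation`.
#' @export
read_incubation_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("substrate_uM", "rate_nmol_min_mg", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  class(df) <- c("incubation", "data.frame")
  df
}
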