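#' @name bmd
#' @title Benchmark dose estimation by AIC-weighted model averaging
#'
#' @description Continuous summary dose-response data (dose, group mean,
#' SD, n) are fitted by maximum likelihood under normal errors with a
#' common residual variance to a set of nested dose-response families
#' (exponential with 3 or 4 parameters, Hill, and optionally inverse
#' exponential and log-normal). Akaike weights built from delta-AIC
#' combine the fitted curves into a model-averaged curve, the benchmark
#' dose (BMD) is read off that curve at the benchmark response (BMR,
#' a relative deviation from the fitted control response), and BMDL/BMDU
#' confidence limits come from a parametric bootstrap of the group means.
NULL

bmd_families_mandatory <- c("exponential-3", "exponential-4", "hill")
bmd_families_all <- c(bmd_families_mandatory,
                      "inverse-exponential", "log-normal")

# normalize input to (dose, m, s, n)
as_bmd_data <- function(data) {
  nm <- names(data)
  pick <- function(...) {
    for (cand in c(...)) if (cand %in% nm) return(data[[cand]])
    stop("dose-response data must contain one of: ",
         paste(c(...), collapse = ", "))
  }
  out <- data.frame(dose = pick("dose", "dose_mg_day", "conc_uM"),
                    m = pick("mean", "response_mean", "response"),
                    s = pick("sd", "response_sd"),
                    n = pick("n"))
  stopifnot(all(out$dose >= 0), all(out$n >= 1), all(out$s >= 0))
  out <- out[order(out$dose), ]
  if (nrow(out) < 4) stop("at least 4 dose levels are required")
  out
}

# family mean functions; x >= 0, theta on the natural scale
bmd_mean_fun <- function(family) {
  switch(family,
    "exponential-3" = function(x, th)       # a, b, d; sign via attr
      th[["a"]] * exp(th[["sgn"]] * th[["b"]] * x^th[["d"]]),
    "exponential-4" = function(x, th)       # a, b, c, d
      th[["a"]] * (th[["c"]] - (th[["c"]] - 1) * exp(-th[["b"]] * x^th[["d"]])),
    "hill" = function(x, th)
      th[["a"]] * (1 + (th[["c"]] - 1) * x^th[["d"]] /
                     (th[["b"]]^th[["d"]] + x^th[["d"]])),
    "inverse-exponential" = function(x, th)
      th[["a"]] * (1 + (th[["c"]] - 1) *
                     ifelse(x > 0, exp(-th[["b"]] * x^(-th[["d"]])), 0)),
    "log-normal" = function(x, th)
      th[["a"]] * (1 + (th[["c"]] - 1) *
                     ifelse(x > 0, stats::pnorm(th[["d"]] *
                                                  log(x / th[["b"]])), 0)),
    stop("unknown family: ", family))
}

#' Fit one dose-response family to continuous summary data
#'
#' @param data a [concentration_response()] object or data frame with
#'   dose (`dose`/`conc_uM`/`dose_mg_day`), mean (`mean`/`response_mean`),
#'   `sd` and `n` columns.
#' @param family one of `"exponential-3"`, `"exponential-4"`, `"hill"`,
#'   `"inverse-exponential"`, `"log-normal"`.
#' @param direction `"increase"`, `"decrease"` or `"auto"` (inferred from
#'   the correlation of mean response with dose).
#' @return An object of class `bmd_model_fit` with the parameter vector,
#'   log-likelihood, AIC, convergence and no-trend flags.
#' @export
fit_family <- function(data, family = "hill",
                       direction = c("auto", "increase", "decrease")) {
  direction <- match.arg(direction)
  d <- as_bmd_data(data)
  family <- match.arg(family, bmd_families_all)
  if (direction == "auto") {
    rho <- suppressWarnings(stats::cor(d$dose, d$m))
    direction <- if (is.na(rho) || rho >= 0) "increase" else "decrease"
  }
  sgn <- if (direction == "increase") 1 else -1

  # doses normalized to [0, 1] for fitting: conditions the optimizer and
  # makes the fit exactly equivariant to dose-unit rescaling
  dose_scale <- max(d$dose)
  dn <- d
  dn$dose <- d$dose / dose_scale

  a0 <- dn$m[1]
  cmax <- dn$m[nrow(dn)] / a0
  if ((direction == "increase" && cmax <= 1) ||
      (direction == "decrease" && cmax >= 1)) cmax <- 1 + sgn * 0.1
  xmax <- max(dn$dose)
  xmid <- stats::median(dn$dose[dn$dose > 0])

  # parameters optimized on log scale; c kept on log scale too (c > 0)
  build_theta <- switch(family,
    "exponential-3" = function(p) list(a = exp(p[1]), b = exp(p[2]),
                                       d = exp(p[3]), sgn = sgn),
    "exponential-4" = function(p) list(a = exp(p[1]), b = exp(p[2]),
                                       c = exp(p[3]), d = exp(p[4])),
    "hill" = function(p) list(a = exp(p[1]), b = exp(p[2]),
                              c = exp(p[3]), d = exp(p[4])),
    "inverse-exponential" = function(p) list(a = exp(p[1]), b = exp(p[2]),
                                             c = exp(p[3]), d = exp(p[4])),
    "log-normal" = function(p) list(a = exp(p[1]), b = exp(p[2]),
                                    c = exp(p[3]), d = exp(p[4])))
  start <- switch(family,
    "exponential-3" = c(log(a0), log(abs(log(max(cmax, 1e-3))) / xmax^1),
                        log(1)),
    "exponential-4" = c(log(a0), log(1 / xmid), log(cmax), log(1)),
    "hill" = c(log(a0), log(xmid), log(cmax), log(1)),
    "inverse-exponential" = c(log(a0), log(xmid), log(cmax), log(1)),
    "log-normal" = c(log(a0), log(xmid), log(cmax), log(1)))
  start[!is.finite(start)] <- 0

  fun <- bmd_mean_fun(family)
  ssq <- function(p) {
    th <- build_theta(p)
    mu <- fun(dn$dose, th)
    if (any(!is.finite(mu))) return(1e12)
    sum(dn$n * (dn$m - mu)^2)
  }
  opt <- stats::optim(start, ssq, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  opt2 <- tryCatch(
    stats::optim(opt$par, ssq, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12)),
    error = function(e) opt)
  if (opt2$value <= opt$value) opt <- opt2

  # convert fitted parameters from the normalized dose scale back to
  # natural units (only b carries dose units)
  theta <- build_theta(opt$par)
  theta$b <- switch(family,
    "exponential-3" = ,
    "exponential-4" = theta$b / dose_scale^theta$d,
    "hill" = ,
    "log-normal" = theta$b * dose_scale,
    "inverse-exponential" = theta$b * dose_scale^theta$d)
  N <- sum(d$n)
  ss_tot <- sum((d$n - 1) * d$s^2) + opt$value
  sigma2 <- ss_tot / N
  logLik <- -N / 2 * (log(2 * pi * sigma2) + 1)
  k <- length(opt$par) + 1   # curve parameters + residual sigma
  aic <- 2 * k - 2 * logLik

  # NULL (constant) model for the no-trend flag
  m_null <- sum(d$n * d$m) / N
  ss_null <- sum((d$n - 1) * d$s^2) + sum(d$n * (d$m - m_null)^2)
  logLik_null <- -N / 2 * (log(2 * pi * ss_null / N) + 1)
  aic_null <- 2 * 2 - 2 * logLik_null

  structure(list(
    family = family, direction = direction, theta = theta,
    dose_scale = dose_scale,
    logLik = logLik, AIC = aic, AIC_null = aic_null,
    no_trend = aic_null <= aic,
    converged = is.finite(opt$value) && opt$value < 1e12,
    sigma2 = sigma2, data = d
  ), class = "bmd_model_fit")
}

#' @export
print.bmd_model_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s): AIC %.2f%s%s\n", x$family, x$direction, x$AIC,
              if (x$no_trend) " [no dose-related trend]" else "",
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Predicted mean response of a fitted dose-response model
#' @param fit a `bmd_model_fit`.
#' @param dose dose/concentration vector (>= 0).
#' @return Predicted mean response.
#' @export
predict_response <- function(fit, dose) {
  bmd_mean_fun(fit$family)(dose, fit$theta)
}

#' Fit all requested families
#' @inheritParams fit_family
#' @param families character vector of family names; the default fits the
#'   three mandatory families, `bmd_families_all` adds the inverse
#'   exponential and log-normal families.
#' @return List of `bmd_model_fit` objects (non-converged fits dropped
#'   with a warning).
#' @export
fit_families <- function(data, families = bmd_families_mandatory,
                         direction = "auto") {
  fits <- lapply(families, function(f)
    tryCatch(fit_family(data, f, direction), error = function(e) NULL))
  ok <- !vapply(fits, is.null, logical(1))
  if (!all(ok)) warning("dropped non-converged families: ",
                        paste(families[!ok], collapse = ", "))
  fits <- fits[ok]
  fits <- fits[vapply(fits, function(f) f$converged, logical(1))]
  if (!length(fits)) stop("no dose-response family converged")
  names(fits) <- vapply(fits, function(f) f$family, character(1))
  fits
}

bmd_from_curve <- function(curve_fun, BMR, direction, dose_range) {
  y0 <- curve_fun(0)
  target <- y0 * (1 + if (direction == "increase") BMR else -BMR)
  g <- function(x) {
    v <- curve_fun(x) - target
    if (!is.finite(v)) v <- 1e12   # exp overflow far beyond the data
    v
  }
  lo <- dose_range[1]; hi <- dose_range[2]
  if (g(lo) * g(hi) > 0) return(NA_real_)
  stats::uniroot(g, c(lo, hi), tol = 1e-10 * hi)$root
}

#' Model-averaged benchmark dose with bootstrap confidence limits
#'
#' Akaike weights `w_j = exp(-dAIC_j/2) / sum(exp(-dAIC/2))` combine the
#' converged fits into a model-averaged curve; the BMD is the dose at
#' which that curve deviates from its own dose-0 response by the BMR.
#' BMDL and BMDU are the 5th and 95th percentiles of BMDs recomputed on
#' parametric bootstrap datasets in which each group mean is resampled
#' from a normal distribution centred on the model-averaged fitted mean
#' with standard error `sd/sqrt(n)`.
#'
#' @param fits list of `bmd_model_fit` objects sharing one dataset (from
#'   [fit_families()]).
#' @param BMR benchmark response as a fractional change from the fitted
#'   control response (e.g. 0.10).
#' @param direction `"increase"` or `"decrease"`; defaults to the fitted
#'   direction.
#' @param n_bootstrap number of bootstrap datasets.
#' @param seed RNG seed for the bootstrap.
#' @return An object of class `bmd_estimate`: BMD, BMDL, BMDU, per-model
#'   weights and BMDs, BMR, direction, `n_bootstrap`.
#' @export
model_averaged_bmd <- function(fits, BMR, direction = NULL,
                               n_bootstrap = 200, seed = 1) {
  stopifnot(length(fits) >= 1, BMR > 0, BMR < 1)
  if (inherits(fits, "bmd_model_fit")) fits <- list(fits)
  if (is.null(direction)) direction <- fits[[1]]$direction
  d <- fits[[1]]$data
  if (all(vapply(fits, function(f) f$no_trend, logical(1))))
    stop("no dose-related trend: BMD is undefined for these data")

  aic <- vapply(fits, function(f) f$AIC, numeric(1))
  w <- exp(-(aic - min(aic)) / 2)
  w <- w / sum(w)

  dose_range <- c(min(d$dose[d$dose > 0]) / 1e3, max(d$dose) * 1e2)
  ma_curve <- function(x)
    Reduce(`+`, Map(function(f, wi) wi * predict_response(f, x), fits, w))
  bmd <- bmd_from_curve(ma_curve, BMR, direction, dose_range)
  if (is.na(bmd))
    stop("BMR of ", BMR, " is not reached within the modelled dose range")
  per_model <- vapply(fits, function(f)
    bmd_from_curve(function(x) predict_response(f, x), BMR, direction,
                   dose_range), numeric(1))

  # parametric bootstrap around the model-averaged fitted means
  mu_hat <- ma_curve(d$dose)
  se <- d$s / sqrt(d$n)
  boots <- rep(NA_real_, n_bootstrap)
  families <- vapply(fits, function(f) f$family, character(1))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  for (b in seq_len(n_bootstrap)) {
    db <- d
    db$m <- stats::rnorm(nrow(d), mu_hat, se)
    fb <- suppressWarnings(tryCatch(
      fit_families(db[, c("dose", "m", "s", "n")] |>
                     stats::setNames(c("dose", "mean", "sd", "n")),
                   families, direction),
      error = function(e) NULL))
    if (is.null(fb)) next
    aicb <- vapply(fb, function(f) f$AIC, numeric(1))
    wb <- exp(-(aicb - min(aicb)) / 2); wb <- wb / sum(wb)
    curve_b <- function(x)
      Reduce(`+`, Map(function(f, wi) wi * predict_response(f, x), fb, wb))
    boots[b] <- bmd_from_curve(curve_b, BMR, direction, dose_range)
  }
  boots <- boots[is.finite(boots)]
  if (length(boots) < n_bootstrap / 2)
    warning("fewer than half of the bootstrap datasets yielded a BMD")
  bl <- if (length(boots)) stats::quantile(boots, 0.05, names = FALSE)
        else NA_real_
  bu <- if (length(boots)) stats::quantile(boots, 0.95, names = FALSE)
        else NA_real_
  structure(list(
    BMR = BMR, direction = direction, BMD = bmd,
    BMDL = min(bl, bmd, na.rm = TRUE), BMDU = max(bu, bmd, na.rm = TRUE),
    weights = stats::setNames(w, families), per_model_bmd = per_model,
    n_bootstrap = n_bootstrap, n_bootstrap_ok = length(boots),
    seed = seed
  ), class = "bmd_estimate")
}

#' @export
print.bmd_estimate <- function(x, ...) {
  cat(sprintf(
    "Model-averaged BMD (BMR %.0f%% %s): %.4g  [BMDL %.4g, BMDU %.4g]\n",
    100 * x$BMR, x$direction, x$BMD, x$BMDL, x$BMDU))
  cat("  weights:", paste(sprintf("%s %.2f", names(x$weights), x$weights),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Benchmark concentration for a 20% FPDc change
#'
#' Convenience wrapper: fits the mandatory families to an in vitro
#' concentration-response dataset and returns the model-averaged
#' benchmark concentration for a 20% change over the control (BMC20),
#' with bootstrap confidence limits.
#'
#' @param crc a `concentration_response` object.
#' @param direction `"increase"` (FPDc prolongation) or `"decrease"`.
#' @param families model families, see [fit_families()].
#' @inheritParams model_averaged_bmd
#' @return A `bmd_estimate` (concentration units).
#' @export
bmc20 <- function(crc, direction = "auto",
                  families = bmd_families_mandatory,
                  n_bootstrap = 200, seed = 1) {
  d <- as_bmd_data(crc)
  if (all(d$dose == 0) || sum(d$dose > 0) < 3)
    stop("concentration-response data contain no usable treated ",
         "concentrations")
  fits <- fit_families(crc, families, direction)
  model_averaged_bmd(fits, BMR = 0.20, n_bootstrap = n_bootstrap,
                     seed = seed)
}

#' Four-parameter logistic fit
#'
#' Standard 4PL curve `y = lower + (upper - lower) / (1 +
#' (EC50/x)^slope)`, fitted by nonlinear least squares; used for plotting
#' and reporting of concentration-response curves.
#'
#' @param conc concentrations (> 0).
#' @param response responses.
#' @return An object of class `fit_4pl`: list with `lower`, `upper`,
#'   `EC50`, `slope`, fitted values and convergence flag.
#' @export
fit_4pl <- function(conc, response) {
  stopifnot(length(conc) == length(response), all(conc > 0))
  if (length(unique(conc)) < 4)
    stop("4PL fitting requires >= 4 distinct concentrations")
  lo0 <- min(response); hi0 <- max(response)
  if (hi0 - lo0 < 1e-12) hi0 <- lo0 + 1e-6
  increasing <- stats::cor(log(conc), response) >= 0
  df <- data.frame(x = conc, y = response)
  start <- list(lower = if (increasing) lo0 else hi0,
                upper = if (increasing) hi0 else lo0,
                lec50 = log(stats::median(conc)), slope = 1)
  fit <- minpack.lm::nlsLM(
    y ~ lower + (upper - lower) / (1 + (exp(lec50) / x)^slope),
    data = df, start = start,
    control = minpack.lm::nls.lm.control(maxiter = 300))
  cf <- stats::coef(fit)
  structure(list(lower = cf[["lower"]], upper = cf[["upper"]],
                 EC50 = exp(cf[["lec50"]]), slope = cf[["slope"]],
                 fitted = stats::fitted(fit),
                 converged = fit$convInfo$isConv), class = "fit_4pl")
}

#' @export
print.fit_4pl <- function(x, ...) {
  cat(sprintf("4PL fit: lower %.4g, upper %.4g, EC50 %.4g, slope %.3g%s\n",
              x$lower, x$upper, x$EC50, x$slope,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' @rdname predict_response
#' @export
predict_4pl <- function(fit, dose) {
  fit$lower + (fit$upper - fit$lower) / (1 + (fit$EC50 / dose)^fit$slope)
}
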