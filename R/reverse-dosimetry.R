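#' Steady-state concentration as a function of dose
#'
#' Builds a monotone map from daily oral methadone dose to the
#' steady-state Cmax of the chosen output (heart venous outflow or
#' systemic venous blood, methadone or EDDP, total concentration in uM)
#' by simulating a log-spaced dose grid and interpolating log-Cmax versus
#' log-dose with a monotone (Hyman) spline. Monotonicity of the simulated
#' grid is asserted; it underpins the uniqueness of reverse dosimetry.
#'
#' @param params a `pbk_params` object.
#' @param BW body weight (kg).
#' @param compound `"methadone"` or `"eddp"`.
#' @param output `"heart_venous"` or `"venous"`.
#' @param bracket dose range covered (mg/day).
#' @param n_grid number of grid doses (log-spaced).
#' @param n_days simulated days per grid dose.
#' @return An object of class `dose_cmax_map` with `predict(dose)` and
#'   `invert(cmax)` interpolators and the simulated grid.
#' @export
dose_cmax_map <- function(params, BW = 70, compound = "methadone",
                          output = c("heart_venous", "venous"),
                          bracket = c(1e-2, 1e4), n_grid = 19,
                          n_days = 30) {
  output <- match.arg(output)
  params <- with_body_weight(params, BW)
  doses <- 10^seq(log10(bracket[1]), log10(bracket[2]),
                  length.out = n_grid)
  cmax <- vapply(doses, function(dd) {
    sim <- pbk_simulate(params, dose_regimen(dd, n_days = n_days))
    ss <- steady_state_metrics(sim, compound)
    if (output == "heart_venous") ss$Cmax_heart_venous_uM
    else ss$Cmax_blood_uM
  }, numeric(1))
  if (any(diff(cmax) <= 0))
    stop("steady-state Cmax is not strictly increasing in dose; ",
         "reverse dosimetry would not be unique")
  fwd <- stats::splinefun(log(doses), log(cmax), method = "hyman")
  inv <- stats::splinefun(log(cmax), log(doses), method = "hyman")
  structure(list(
    doses = doses, cmax = cmax, compound = compound, output = output,
    BW = BW, n_days = n_days,
    predict = function(dose) exp(fwd(log(dose))),
    invert = function(target) {
      if (any(target < min(cmax)) || any(target > max(cmax)))
        stop("target concentration outside the mapped range")
      exp(inv(log(target)))
    }
  ), class = "dose_cmax_map")
}

#' Find the oral dose matching a target unbound concentration
#'
#' Root-searches the daily methadone dose whose steady-state unbound Cmax
#' (heart venous outflow for methadone, systemic venous blood for the
#' EDDP use case) equals a target unbound concentration. The unbound
#' concentration is `Cmax_total * fu_p / BPr`; `fu_p` and `BPr` default
#' to the compound's values in the parameter set, or come from a
#' [binding_scenario()]. Monotonicity of the dose-Cmax relation over the
#' bracket is checked before the search.
#'
#' @param params a `pbk_params` object.
#' @param compound `"methadone"` or `"eddp"`.
#' @param target_unbound_uM target unbound concentration (uM).
#' @param scenario optional [binding_scenario()] providing `fu_p`/`BPr`.
#' @param BW body weight (kg).
#' @param bracket dose search bracket (mg/day).
#' @param output output compartment; default heart venous outflow for
#'   methadone and systemic venous blood for EDDP.
#' @param tol relative tolerance on the dose.
#' @param n_days simulated days per evaluation.
#' @return Dose (mg/day); 0 for a zero target.
#' @export
dose_for_target <- function(params, compound = "methadone",
                            target_unbound_uM, scenario = NULL, BW = 70,
                            bracket = c(1e-3, 1e4), output = NULL,
                            tol = 1e-4, n_days = 30) {
  stopifnot(target_unbound_uM >= 0)
  if (target_unbound_uM == 0) return(0)
  compound <- match.arg(compound, c("methadone", "eddp"))
  if (is.null(output))
    output <- if (compound == "methadone") "heart_venous" else "venous"
  params <- with_body_weight(params, BW)
  cp <- if (compound == "methadone") params$methadone else params$eddp
  fu_p <- if (!is.null(scenario)) scenario$fu_p else cp$fu_p
  BPr <- if (!is.null(scenario)) scenario$BPr else cp$BPr
  target_total <- target_unbound_uM * BPr / fu_p

  cmax_at <- function(dose) {
    sim <- pbk_simulate(params, dose_regimen(dose, n_days = n_days))
    ss <- steady_state_metrics(sim, compound)
    if (output == "heart_venous") ss$Cmax_heart_venous_uM
    else ss$Cmax_blood_uM
  }
  clo <- cmax_at(bracket[1]); chi <- cmax_at(bracket[2])
  cmid <- cmax_at(sqrt(prod(bracket)))
  if (!(clo < cmid && cmid < chi))
    stop("dose-Cmax relation is not monotone over the bracket")
  if (target_total < clo || target_total > chi)
    stop("target of ", signif(target_unbound_uM, 4),
         " uM unbound (", signif(target_total, 4), " uM total) is outside ",
         "the achievable range for doses in [", bracket[1], ", ",
         bracket[2], "] mg/day")
  f <- function(ld) log(cmax_at(exp(ld))) - log(target_total)
  root <- stats::uniroot(f, log(bracket), tol = tol / 2)
  exp(root$root)
}

#' Translate an in vitro concentration-response curve to a predicted
#' dose-response curve
#'
#' For each in vitro concentration, the equivalent total blood
#' concentration is computed from the unbound-concentration equivalence
#' (`C_blood = C_invitro * fu_m * BPr / fu_p`) and the PBK model is
#' inverted to find the daily dose whose steady-state total Cmax in the
#' output compartment equals it. Responses are carried over unchanged
#' from the in vitro curve. Points falling outside the mapped dose range
#' are reported in `attr(, "out_of_range")`, not dropped silently.
#'
#' @param crc a `concentration_response` object (concentrations in uM).
#' @param scenario a [binding_scenario()].
#' @param params a `pbk_params` object.
#' @param BW body weight (kg).
#' @param map optional precomputed [dose_cmax_map()] (reused across
#'   scenarios); built on demand otherwise.
#' @param output output compartment for the inversion.
#' @return An object of class `dose_response_prediction`: data frame with
#'   `dose_mg_day`, `response_mean`, `response_sd`, `n` plus scenario
#'   metadata attributes.
#' @export
translate_crc <- function(crc, scenario, params, BW = 70, map = NULL,
                          output = "heart_venous") {
  stopifnot(inherits(scenario, "binding_scenario"))
  if (is.null(map))
    map <- dose_cmax_map(params, BW = BW, compound = "methadone",
                         output = output)
  conc <- crc$conc_uM
  target_total <- invitro_to_total_blood(conc, scenario)
  in_range <- target_total >= min(map$cmax) & target_total <= max(map$cmax)
  out <- data.frame(conc_uM = conc[in_range],
                    dose_mg_day = map$invert(target_total[in_range]),
                    response_mean = crc$response_mean[in_range],
                    response_sd = crc$response_sd[in_range],
                    n = crc$n[in_range])
  if (any(diff(out$dose_mg_day) <= 0))
    stop("translated doses are not strictly increasing")
  attr(out, "scenario") <- scenario
  attr(out, "BW") <- BW
  attr(out, "output") <- output
  attr(out, "out_of_range") <- conc[!in_range]
  class(out) <- c("dose_response_prediction", "data.frame")
  out
}

#' Translate a curve under all binding scenarios
#'
#' Runs [translate_crc()] for each scenario, reusing one dose-Cmax map.
#'
#' @inheritParams translate_crc
#' @param scenarios list of [binding_scenario()] objects; defaults to the
#'   four methadone plasma-binding scenarios.
#' @return Named list of `dose_response_prediction` objects.
#' @export
translate_crc_scenarios <- function(crc, params,
                                    scenarios = methadone_binding_scenarios(),
                                    BW = 70, output = "heart_venous",
                                    map = NULL) {
  if (is.null(map))
    map <- dose_cmax_map(params, BW = BW, compound = "methadone",
                         output = output)
  lapply(scenarios, function(sc)
    translate_crc(crc, sc, params, BW = BW, map = map, output = output))
}

#' QTc as a percentage of baseline
#'
#' @param qtc_ms observed QTc (ms).
#' @param baseline_ms baseline QTc (ms); the population default of 407 ms
#'   (411 ms female, 405 ms male) is used when a study baseline is
#'   missing.
#' @return Percent of baseline.
#' @export
qtc_percent <- function(qtc_ms, baseline_ms = 407) {
  stopifnot(all(baseline_ms > 0))
  100 * qtc_ms / baseline_ms
}
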