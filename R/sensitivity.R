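#' Parameters addressable by the sensitivity analysis
#'
#' Named accessors into the nested parameter set. Fractional composition
#' parameters (volumes, flows) are perturbed without re-normalizing the
#' remaining fractions, the standard one-at-a-time convention; flow-sum
#' validation is switched off for the perturbed run.
#' @keywords internal
sens_param_table <- function() {
  tab <- list(
    BW = c("physiology", "BW"), Qc = c("physiology", "Qc"),
    VLc = c("physiology", "VLc"), VFc = c("physiology", "VFc"),
    VSc = c("physiology", "VSc"), VRc = c("physiology", "VRc"),
    QLc = c("physiology", "QLc"), QFc = c("physiology", "QFc"),
    QKc = c("physiology", "QKc"), QHc = c("physiology", "QHc"),
    QSc = c("physiology", "QSc"), QRc = c("physiology", "QRc"),
    ka = c("absorption", "ka"), Fa = c("absorption", "Fa"),
    Vmaxc = c("metabolism", "Vmax_c"), Km = c("metabolism", "Km"),
    MPL = c("metabolism", "MPL"),
    RCLmet = c("clearance", "RCLmet"), RCLeddp = c("clearance", "RCLeddp"),
    kbile = c("clearance", "kbile"),
    PLmet = c("methadone", "P_liver"), PFmet = c("methadone", "P_fat"),
    PSmet = c("methadone", "P_slow"), PRmet = c("methadone", "P_rapid"),
    PLumet = c("methadone", "P_lung"), PKmet = c("methadone", "P_kidney"),
    PHmet = c("methadone", "P_heart"))
  tab
}

sens_get <- function(params, name) {
  path <- sens_param_table()[[name]]
  if (is.null(path)) stop("unknown sensitivity parameter: ", name)
  params[[path[1]]][[path[2]]]
}

sens_set <- function(params, name, value) {
  path <- sens_param_table()[[name]]
  params[[path[1]]][[path[2]]] <- value
  # body weight carries cardiac output with it (allometric Qc ~ BW^0.74)
  if (name == "BW") {
    bw0 <- sens_get(params, "BW")   # already updated
    params$physiology$Qc <- params$physiology$Qc *
      (value / attr(params, "sens_bw0"))^0.74
  }
  params
}

#' Normalized local sensitivity coefficient of a PBK output
#'
#' One-at-a-time finite-difference sensitivity
#' `SC = ((C' - C) / (P' - P)) * (P / C)` where `C` is the steady-state
#' Cmax of methadone in heart venous blood at the given regimen and `C'`
#' the same output after increasing parameter `P` by `delta` (default 1%).
#' Body-weight perturbations rescale cardiac output allometrically;
#' fractional flows/volumes are perturbed without re-normalization.
#'
#' @param params a `pbk_params` object.
#' @param param_name parameter name; see `names(sens_param_table())` for
#'   the addressable set (e.g. `"ka"`, `"Fa"`, `"BW"`, `"Vmaxc"`,
#'   `"PRmet"`).
#' @param dose_mg_per_day daily oral dose (mg).
#' @param delta fractional perturbation.
#' @param n_days simulated days (steady state).
#' @param output output definition: heart venous outflow Cmax (default)
#'   or systemic venous blood Cmax, for methadone or EDDP.
#' @param compound compound of the output.
#' @param .base_output precomputed unperturbed output (internal; lets
#'   [sensitivity_report()] reuse one baseline simulation per dose).
#' @param ... passed to [pbk_simulate()] (e.g. tighter `rtol`).
#' @return The normalized sensitivity coefficient (signed, dimensionless).
#' @export
normalized_sc <- function(params, param_name, dose_mg_per_day,
                          delta = 0.01, n_days = 30,
                          output = c("heart_venous", "venous"),
                          compound = "methadone", .base_output = NULL,
                          ...) {
  output <- match.arg(output)
  stopifnot(dose_mg_per_day > 0)
  metric <- function(p) {
    sim <- pbk_simulate(p, dose_regimen(dose_mg_per_day, n_days = n_days),
                        check_flows = FALSE, ...)
    ss <- steady_state_metrics(sim, compound)
    if (output == "heart_venous") ss$Cmax_heart_venous_uM
    else ss$Cmax_blood_uM
  }
  p0 <- sens_get(params, param_name)
  if (!is.finite(p0) || p0 <= 0)
    stop("parameter ", param_name, " must be positive for a relative ",
         "perturbation")
  C <- if (is.null(.base_output)) metric(params) else .base_output
  if (C <= 0) stop("model output is zero; SC undefined at this regimen")
  attr(params, "sens_bw0") <- params$physiology$BW
  pert <- sens_set(params, param_name, p0 * (1 + delta))
  Cp <- metric(pert)
  ((Cp - C) / (p0 * delta)) * (p0 / C)
}

#' Sensitivity report over a parameter list and dose scenarios
#'
#' Computes normalized sensitivity coefficients for each parameter at
#' each dose, sorts by magnitude at the first dose and flags parameters
#' with |SC| > 0.1 as influential.
#'
#' @inheritParams normalized_sc
#' @param param_names parameters to scan (default: the full addressable
#'   set minus EDDP-only clearances).
#' @param doses dose scenarios (mg/day).
#' @param path optional CSV path for the report.
#' @return Data frame with one row per parameter: signed SC per dose,
#'   `abs_SC` (first dose) and `influential` flag.
#' @export
sensitivity_report <- function(params,
                               param_names = NULL,
                               doses = c(20, 200), delta = 0.01,
                               n_days = 30,
                               output = "heart_venous",
                               compound = "methadone",
                               path = NULL) {
  if (is.null(param_names)) {
    param_names <- names(sens_param_table())
    if (compound == "methadone")
      param_names <- setdiff(param_names, c("RCLeddp", "kbile"))
  }
  base_metric <- function(dd) {
    sim <- pbk_simulate(params, dose_regimen(dd, n_days = n_days))
    ss <- steady_state_metrics(sim, compound)
    if (output == "heart_venous") ss$Cmax_heart_venous_uM
    else ss$Cmax_blood_uM
  }
  sc <- sapply(doses, function(dd) {
    C0 <- base_metric(dd)   # one baseline simulation per dose scenario
    vapply(param_names, function(p)
      normalized_sc(params, p, dd, delta, n_days, output, compound,
                    .base_output = C0),
      numeric(1))
  })
  sc <- matrix(sc, nrow = length(param_names),
               dimnames = list(param_names,
                               paste0("SC_", doses, "mg")))
  out <- data.frame(parameter = param_names, sc,
                    abs_SC = abs(sc[, 1]),
                    influential = abs(sc[, 1]) > 0.1,
                    row.names = NULL, check.names = FALSE)
  out <- out[order(-out$abs_SC), ]
  rownames(out) <- NULL
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
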