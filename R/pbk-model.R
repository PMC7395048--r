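#' Simulate the methadone/EDDP PBK model under repeated oral dosing
#'
#' Integrates the flow-limited nine-compartment PBK model (gut lumen,
#' liver, fat, lung, kidney, heart, slowly and rapidly perfused tissue,
#' arterial and venous blood) for methadone with a parallel submodel for
#' its primary metabolite EDDP. Oral doses enter the gut lumen as a bolus
#' of `Fa * dose` (converted to umol) at the start of every dosing
#' interval; absorbed drug flows first-order (`ka`) into the liver
#' (first-pass). Hepatic metabolism converts methadone to EDDP 1:1 molar at
#' a Michaelis-Menten rate driven by the liver venous (blood-equivalent)
#' concentration. Methadone and EDDP are cleared from venous blood by
#' renal clearance; EDDP is additionally excreted from the liver to a
#' biliary sink.
#'
#' @param params a `pbk_params` object, see [default_methadone_model()].
#' @param regimen a [dose_regimen()].
#' @param points_per_interval output grid density per dosing interval
#'   (>= 100 so that the interval Cmax is resolved).
#' @param rtol,atol solver tolerances (stiff solver, `deSolve::lsoda`).
#' @param check_flows refuse parameter sets whose flow fractions do not
#'   sum to 1 (within 1e-9) unless `FALSE`; one-at-a-time sensitivity
#'   perturbations set this to `FALSE` deliberately.
#' @return An object of class `pbk_sim`: a data frame with the time grid
#'   (`time_h`) and, per compound, compartment amounts (umol),
#'   blood/outflow concentrations (uM) and cumulative eliminated amounts,
#'   with the parameter set and regimen attached as attributes.
#' @examples
#' sim <- pbk_simulate(default_methadone_model(), dose_regimen(70, n_days = 10))
#' max(sim$m_conc_ven)   # venous blood Cmax over all days, uM
#' @export
pbk_simulate <- function(params, regimen, points_per_interval = 100,
                         rtol = 1e-8, atol = 1e-10, check_flows = TRUE) {
  stopifnot(inherits(params, "pbk_params"), inherits(regimen, "dose_regimen"))
  if (check_flows) validate_physiology(params$physiology)

  phys <- params$physiology
  met <- params$methadone
  edp <- params$eddp

  V <- list(liv = phys$VLc, fat = phys$VFc, lun = phys$VLuc,
            art = phys$VAc, ven = phys$VVc, kid = phys$VKc,
            hrt = phys$VHc, slw = phys$VSc, rpd = phys$VRc)
  V <- lapply(V, function(f) f * phys$BW)          # L (density 1 g/mL)
  Q <- list(liv = phys$QLc, fat = phys$QFc, kid = phys$QKc,
            hrt = phys$QHc, slw = phys$QSc, rpd = phys$QRc)
  Q <- lapply(Q, function(f) f * phys$Qc)          # L/h

  # whole-liver Vmax, umol/h
  Vmax_vivo <- scale_vmax_in_vivo(params$metabolism$Vmax_c,
                                  params$metabolism$MPL,
                                  phys$VLc, phys$BW)
  Km <- params$metabolism$Km
  ka <- params$absorption$ka
  cl <- params$clearance

  Pm <- c(liv = met$P_liver, fat = met$P_fat, kid = met$P_kidney,
          hrt = met$P_heart, slw = met$P_slow, rpd = met$P_rapid,
          lun = met$P_lung)
  Pe <- c(liv = edp$P_liver, fat = edp$P_fat, kid = edp$P_kidney,
          hrt = edp$P_heart, slw = edp$P_slow, rpd = edp$P_rapid,
          lun = edp$P_lung)

  state <- c(m_gut = 0, m_liv = 0, m_fat = 0, m_lun = 0, m_kid = 0,
             m_hrt = 0, m_slw = 0, m_rpd = 0, m_art = 0, m_ven = 0,
             m_met = 0, m_urn = 0,
             e_liv = 0, e_fat = 0, e_lun = 0, e_kid = 0, e_hrt = 0,
             e_slw = 0, e_rpd = 0, e_art = 0, e_ven = 0, e_urn = 0,
             e_bil = 0)

  # precomputed scalars; positional state indexing keeps the RHS cheap
  Qc <- phys$Qc
  QL <- Q$liv; QF <- Q$fat; QK <- Q$kid; QH <- Q$hrt; QS <- Q$slw
  QR <- Q$rpd
  VPm <- c(V$liv * Pm["liv"], V$fat * Pm["fat"], V$lun * Pm["lun"],
           V$kid * Pm["kid"], V$hrt * Pm["hrt"], V$slw * Pm["slw"],
           V$rpd * Pm["rpd"])
  VPe <- c(V$liv * Pe["liv"], V$fat * Pe["fat"], V$lun * Pe["lun"],
           V$kid * Pe["kid"], V$hrt * Pe["hrt"], V$slw * Pe["slw"],
           V$rpd * Pe["rpd"])
  Vart <- V$art; Vven <- V$ven

  # state order: 1 m_gut, 2 m_liv, 3 m_fat, 4 m_lun, 5 m_kid, 6 m_hrt,
  # 7 m_slw, 8 m_rpd, 9 m_art, 10 m_ven, 11 m_met, 12 m_urn,
  # 13 e_liv, 14 e_fat, 15 e_lun, 16 e_kid, 17 e_hrt, 18 e_slw, 19 e_rpd,
  # 20 e_art, 21 e_ven, 22 e_urn, 23 e_bil
  rhs <- function(t, y, parms) {
    cart <- y[9] / Vart
    cven <- y[10] / Vven
    cvl <- y[2] / VPm[1]; cvf <- y[3] / VPm[2]; cvlu <- y[4] / VPm[3]
    cvk <- y[5] / VPm[4]; cvh <- y[6] / VPm[5]; cvs <- y[7] / VPm[6]
    cvr <- y[8] / VPm[7]
    vmet <- Vmax_vivo * cvl / (Km + cvl)

    d_m_gut <- -ka * y[1]
    d_m_liv <- QL * (cart - cvl) + ka * y[1] - vmet
    d_m_fat <- QF * (cart - cvf)
    d_m_lun <- Qc * (cven - cvlu)
    d_m_kid <- QK * (cart - cvk)
    d_m_hrt <- QH * (cart - cvh)
    d_m_slw <- QS * (cart - cvs)
    d_m_rpd <- QR * (cart - cvr)
    d_m_art <- Qc * (cvlu - cart)
    d_m_ven <- QL * cvl + QF * cvf + QK * cvk + QH * cvh + QS * cvs +
      QR * cvr - Qc * cven - cl$RCLmet * cven

    eart <- y[20] / Vart
    even <- y[21] / Vven
    evl <- y[13] / VPe[1]; evf <- y[14] / VPe[2]; evlu <- y[15] / VPe[3]
    evk <- y[16] / VPe[4]; evh <- y[17] / VPe[5]; evs <- y[18] / VPe[6]
    evr <- y[19] / VPe[7]

    d_e_liv <- QL * (eart - evl) + vmet - cl$kbile * y[13]
    d_e_fat <- QF * (eart - evf)
    d_e_lun <- Qc * (even - evlu)
    d_e_kid <- QK * (eart - evk)
    d_e_hrt <- QH * (eart - evh)
    d_e_slw <- QS * (eart - evs)
    d_e_rpd <- QR * (eart - evr)
    d_e_art <- Qc * (evlu - eart)
    d_e_ven <- QL * evl + QF * evf + QK * evk + QH * evh + QS * evs +
      QR * evr - Qc * even - cl$RCLeddp * even

    list(c(d_m_gut, d_m_liv, d_m_fat, d_m_lun, d_m_kid, d_m_hrt, d_m_slw,
           d_m_rpd, d_m_art, d_m_ven, vmet, cl$RCLmet * cven,
           d_e_liv, d_e_fat, d_e_lun, d_e_kid, d_e_hrt, d_e_slw, d_e_rpd,
           d_e_art, d_e_ven, cl$RCLeddp * even, cl$kbile * y[13]))
  }

  dose_umol <- regimen$dose_mg_per_day * 1000 / met$MW
  bolus <- params$absorption$Fa * dose_umol
  t_end <- regimen$n_days * regimen$interval
  dose_times <- seq(0, t_end - regimen$interval, by = regimen$interval)
  times <- sort(unique(c(
    seq(0, t_end, length.out = regimen$n_days * points_per_interval + 1),
    dose_times)))
  events <- data.frame(var = "m_gut", time = dose_times, value = bolus,
                       method = "add")

  out <- deSolve::lsoda(state, times, rhs, parms = NULL, rtol = rtol,
                        atol = atol, events = list(data = events))
  if (attr(out, "istate")[1] < 0)
    stop("PBK ODE integration failed (solver did not converge)")
  out <- as.data.frame(out)
  neg <- min(as.matrix(out[, -1]))
  if (neg < -1e-6 * max(bolus, 1))
    stop("negative compartment amount beyond tolerance: ", neg)
  out[, -1][out[, -1] < 0] <- 0

  names(out)[1] <- "time_h"
  # derived concentrations (uM)
  out$m_conc_ven <- out$m_ven / V$ven
  out$m_conc_art <- out$m_art / V$art
  out$m_conc_heart_venous <- out$m_hrt / (V$hrt * Pm["hrt"])
  out$e_conc_ven <- out$e_ven / V$ven
  out$e_conc_art <- out$e_art / V$art
  out$e_conc_heart_venous <- out$e_hrt / (V$hrt * Pe["hrt"])
  out$m_unabsorbed <- (1 - params$absorption$Fa) * dose_umol *
    findInterval(out$time_h, dose_times)   # doses given up to and incl. t
  attr(out, "params") <- params
  attr(out, "regimen") <- regimen
  attr(out, "volumes") <- V
  attr(out, "dose_umol") <- dose_umol
  attr(out, "n_doses") <- length(dose_times)
  class(out) <- c("pbk_sim", "data.frame")
  out
}

compound_columns <- function(compound) {
  compound <- match.arg(compound, c("methadone", "eddp"))
  if (compound == "methadone") "m" else "e"
}

#' Steady-state exposure metrics over the final dosing interval
#'
#' Computes the maximum venous blood concentration (Cmax, in uM and
#' ng/mL), the trapezoidal AUC of the venous blood concentration over the
#' final dosing interval (ng.h/mL), the heart-tissue venous-outflow Cmax
#' (uM) and the unbound blood Cmax (`Cmax * fu_p / BPr`, uM).
#'
#' @param sim a `pbk_sim` result from [pbk_simulate()].
#' @param compound `"methadone"` or `"eddp"`.
#' @param fu_p plasma unbound fraction used for the unbound metric;
#'   defaults to the compound's value in the simulated parameter set.
#' @return A list of class `steady_state_metrics`.
#' @export
steady_state_metrics <- function(sim, compound = "methadone", fu_p = NULL) {
  stopifnot(inherits(sim, "pbk_sim"))
  pre <- compound_columns(compound)
  params <- attr(sim, "params")
  cp <- if (pre == "m") params$methadone else params$eddp
  if (is.null(fu_p)) fu_p <- cp$fu_p
  regimen <- attr(sim, "regimen")
  t_end <- max(sim$time_h)
  if (t_end < regimen$interval)
    stop("simulation must span at least one full dosing interval")
  idx <- sim$time_h >= t_end - regimen$interval
  tt <- sim$time_h[idx]
  cv <- sim[[paste0(pre, "_conc_ven")]][idx]
  chv <- sim[[paste0(pre, "_conc_heart_venous")]][idx]
  cmax_uM <- max(cv)
  cmax_ngml <- cmax_uM * cp$MW
  auc <- sum(diff(tt) * (head(cv, -1) + cv[-1]) / 2) * cp$MW  # ng.h/mL
  structure(list(
    compound = cp$name,
    Cmax_blood_uM = cmax_uM,
    Cmax_blood_ng_per_ml = cmax_ngml,
    AUC_interval_ng_h_per_ml = auc,
    Cmax_heart_venous_uM = max(chv),
    Cmax_unbound_blood_uM = cmax_uM * fu_p / cp$BPr,
    interval_h = regimen$interval
  ), class = "steady_state_metrics")
}

#' @export
print.steady_state_metrics <- function(x, ...) {
  cat(sprintf(
    "%s steady-state metrics (final %g h interval):\n  Cmax blood %.4g uM (%.4g ng/mL); AUC %.5g ng.h/mL\n  Cmax heart venous outflow %.4g uM; Cmax unbound blood %.4g uM\n",
    x$compound, x$interval_h, x$Cmax_blood_uM, x$Cmax_blood_ng_per_ml,
    x$AUC_interval_ng_h_per_ml, x$Cmax_heart_venous_uM,
    x$Cmax_unbound_blood_uM))
  invisible(x)
}

#' Mass-balance residual of a simulation
#'
#' For methadone: |administered - (unabsorbed + amounts in all
#' compartments + cumulative renal excretion + cumulative metabolism)| /
#' administered. For EDDP the source term is the cumulative amount of
#' methadone metabolized (1:1 molar formation) and the sinks are the EDDP
#' compartments plus renal and biliary excretion. Returns the larger of
#' the two relative residuals, evaluated at the final output time; 0 by
#' convention for a zero dose.
#'
#' @param sim a `pbk_sim` object.
#' @return Maximum relative residual (dimensionless).
#' @export
mass_balance <- function(sim) {
  stopifnot(inherits(sim, "pbk_sim"))
  last <- sim[nrow(sim), ]
  administered <- attr(sim, "dose_umol") * attr(sim, "n_doses")
  if (administered == 0) return(0)
  m_total <- last$m_unabsorbed + last$m_gut + last$m_liv + last$m_fat +
    last$m_lun + last$m_kid + last$m_hrt + last$m_slw + last$m_rpd +
    last$m_art + last$m_ven + last$m_urn + last$m_met
  res_m <- abs(administered - m_total) / administered
  formed <- last$m_met
  if (formed <= 0) return(res_m)
  e_total <- last$e_liv + last$e_fat + last$e_lun + last$e_kid +
    last$e_hrt + last$e_slw + last$e_rpd + last$e_art + last$e_ven +
    last$e_urn + last$e_bil
  max(res_m, abs(formed - e_total) / formed)
}

#' Simulate to steady state
#'
#' Convenience wrapper: simulates `n_days` when supplied; otherwise runs
#' until the venous-blood Cmax of two consecutive dosing intervals differs
#' by less than `tol` (relative), capped at 120 days.
#'
#' @inheritParams pbk_simulate
#' @param dose_mg_per_day daily oral dose (mg).
#' @param BW body weight (kg); cardiac output is rescaled allometrically.
#' @param n_days fixed duration in days, or `NULL` for automatic detection.
#' @param tol relative Cmax change between consecutive days accepted as
#'   steady state.
#' @param compound compound whose Cmax drives the steady-state check.
#' @return A `pbk_sim` object.
#' @export
simulate_steady_state <- function(params, dose_mg_per_day, BW = NULL,
                                  n_days = NULL, tol = 1e-3,
                                  compound = "methadone", ...) {
  if (!is.null(BW) && BW != params$physiology$BW)
    params <- with_body_weight(params, BW)
  if (!is.null(n_days))
    return(pbk_simulate(params, dose_regimen(dose_mg_per_day,
                                             n_days = n_days), ...))
  pre <- compound_columns(compound)
  days <- 30
  sim <- pbk_simulate(params, dose_regimen(dose_mg_per_day, n_days = days),
                      ...)
  repeat {
    cc <- sim[[paste0(pre, "_conc_ven")]]
    t_end <- max(sim$time_h)
    c1 <- max(cc[sim$time_h >= t_end - 24])
    c0 <- max(cc[sim$time_h >= t_end - 48 & sim$time_h <= t_end - 24])
    if (c1 == 0 || abs(c1 - c0) / c1 < tol || days >= 120) return(sim)
    days <- min(days * 2, 120)
    sim <- pbk_simulate(params, dose_regimen(dose_mg_per_day,
                                             n_days = days), ...)
  }
}

#' Fit EDDP clearance parameters to a steady-state blood Cmax target
#'
#' Adjusts the EDDP renal clearance (`RCLeddp`), the biliary excretion
#' rate constant (`kbile`) or both so that the simulated steady-state EDDP
#' venous-blood Cmax matches a target. Fitting both parameters to a single
#' Cmax target is under-determined, so `free_param = "both"` requires a
#' `ratio` constraint fixing `kbile / RCLeddp`.
#'
#' @param params a `pbk_params` object.
#' @param dose_mg_per_day,BW dosing scenario of the clinical observation.
#' @param target_blood_cmax_eddp target steady-state EDDP venous-blood
#'   Cmax (uM, total).
#' @param free_param `"RCLeddp"`, `"kbile"` or `"both"`.
#' @param ratio fixed `kbile / RCLeddp` ratio, required for `"both"`.
#' @param n_days simulation duration used during fitting (days).
#' @param bounds search bounds for the free parameter.
#' @return A `clearance_params` object with the fitted value(s).
#' @export
fit_eddp_clearance <- function(params, dose_mg_per_day, BW,
                               target_blood_cmax_eddp,
                               free_param = c("RCLeddp", "kbile", "both"),
                               ratio = NULL, n_days = 30,
                               bounds = c(1e-4, 1e3)) {
  free_param <- match.arg(free_param)
  stopifnot(target_blood_cmax_eddp > 0)
  if (free_param == "both" && is.null(ratio))
    stop("fitting both parameters to one Cmax target is under-determined; ",
         "supply `ratio` = kbile/RCLeddp as a second constraint")
  params <- with_body_weight(params, BW)

  cmax_at <- function(x) {
    cl <- params$clearance
    if (free_param == "RCLeddp") cl$RCLeddp <- x
    if (free_param == "kbile") cl$kbile <- x
    if (free_param == "both") { cl$RCLeddp <- x; cl$kbile <- ratio * x }
    params$clearance <- cl
    sim <- pbk_simulate(params, dose_regimen(dose_mg_per_day,
                                             n_days = n_days))
    steady_state_metrics(sim, "eddp")$Cmax_blood_uM
  }
  f <- function(lx) log(cmax_at(exp(lx))) - log(target_blood_cmax_eddp)
  flo <- f(log(bounds[1])); fhi <- f(log(bounds[2]))
  # Cmax decreases in clearance: f(lower bound) should be > 0
  if (flo * fhi > 0)
    stop("target EDDP Cmax ", target_blood_cmax_eddp,
         " uM is unreachable within clearance bounds [",
         bounds[1], ", ", bounds[2], "]")
  root <- stats::uniroot(f, log(bounds), f.lower = flo, f.upper = fhi,
                         tol = 5e-4)
  x <- exp(root$root)
  # refuse fits worse than 0.1% relative on the Cmax
  if (abs(cmax_at(x) - target_blood_cmax_eddp) /
        target_blood_cmax_eddp > 1e-3)
    stop("clearance fit did not reach the target within 0.1%")
  cl <- params$clearance
  if (free_param == "RCLeddp") cl$RCLeddp <- x
  if (free_param == "kbile") cl$kbile <- x
  if (free_param == "both") { cl$RCLeddp <- x; cl$kbile <- ratio * x }
  cl
}

#' Export a simulation to tidy long format
#'
#' @param sim a `pbk_sim` object.
#' @param path optional CSV path; when supplied the tidy table is also
#'   written there.
#' @return A data frame with columns `time_h`, `compound`, `compartment`,
#'   `amount_umol`, `conc_uM`, `conc_ng_per_ml` (concentrations only for
#'   perfused compartments).
#' @export
pbk_sim_tidy <- function(sim, path = NULL) {
  stopifnot(inherits(sim, "pbk_sim"))
  params <- attr(sim, "params")
  V <- attr(sim, "volumes")
  comp_map <- c(gut = "gut_lumen", liv = "liver", fat = "fat",
                lun = "lung", kid = "kidney", hrt = "heart",
                slw = "slowly_perfused", rpd = "rapidly_perfused",
                art = "arterial_blood", ven = "venous_blood",
                met = "cum_metabolized", urn = "cum_renal_excreted",
                bil = "cum_biliary_excreted")
  rows <- list()
  for (pre in c("m", "e")) {
    cp <- if (pre == "m") params$methadone else params$eddp
    P <- c(liv = cp$P_liver, fat = cp$P_fat, lun = cp$P_lung,
           kid = cp$P_kidney, hrt = cp$P_heart, slw = cp$P_slow,
           rpd = cp$P_rapid)
    for (cmp in names(comp_map)) {
      col <- paste0(pre, "_", cmp)
      if (!col %in% names(sim)) next
      amount <- sim[[col]]
      conc <- if (cmp %in% c("art", "ven")) amount / V[[cmp]]
              else if (cmp %in% names(P)) amount / (V[[cmp]] * P[[cmp]])
              else NA_real_
      rows[[col]] <- data.frame(
        time_h = sim$time_h, compound = cp$name,
        compartment = comp_map[[cmp]], amount_umol = amount,
        conc_uM = conc, conc_ng_per_ml = conc * cp$MW)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
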