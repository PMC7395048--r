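#' @name synthetic-data
#' @title Seeded generators for every raw input of the pipeline
#'
#' @description Each generator is deterministic given its seed, emits the
#' exact tabular schema the corresponding analysis stage consumes, and
#' attaches the generating truth as `attr(, "truth")` so downstream
#' recovery tests can compare estimates against it.
NULL

#' Generate a synthetic MEA concentration-response experiment
#'
#' Emulates a cumulative-exposure multi-well MEA experiment: per-well
#' baseline field potential duration and RR interval, a Hill-shaped
#' concentration effect on FPDc (percent increase over baseline), additive
#' between-well noise, a linear per-step drift shared with the vehicle
#' well, and waveform-irregularity flags injected from a configurable
#' concentration upward (arrhythmia-like waveforms) with beating arrest
#' at the top concentration.
#'
#' @param seed RNG seed.
#' @param conc_uM tested concentrations (uM); the default mirrors a
#'   methadone series from 0.01 to 30 uM.
#' @param n_experiments independent experiments (new cell vial each).
#' @param wells_per_experiment treated wells per experiment.
#' @param emax_pct,ec50_uM,hill truth effect curve: maximal FPDc increase
#'   (percent points), EC50 (uM) and Hill slope. The default EC50 places
#'   the analytic 20%-effect concentration at 0.6 uM.
#' @param well_sd_pct between-well SD of the response (percent points).
#' @param drift_pct_per_step vehicle/time drift in FPDc percent per
#'   exposure step (negative = rundown).
#' @param irregular_from_uM concentrations at or above this induce
#'   arrhythmia-like waveforms (excluded from FPD analysis).
#' @param arrest_at_uM concentration causing beating arrest.
#' @return A well-recording data frame (schema of [read_mea_csv()]) with
#'   `attr(, "truth")` containing the generating parameters and the
#'   analytic concentration producing any fractional effect
#'   (`conc_for_effect(frac)`).
#' @export
gen_mea_crc <- function(seed = 1,
                        conc_uM = c(0.01, 0.03, 0.1, 0.2, 0.3, 0.4, 1, 3,
                                    10, 30),
                        n_experiments = 3, wells_per_experiment = 2,
                        emax_pct = 60, ec50_uM = 0.6 * 2^(1 / 1.5),
                        hill = 1.5, well_sd_pct = 8,
                        drift_pct_per_step = -0.5,
                        irregular_from_uM = 3, arrest_at_uM = 30) {
  stopifnot(all(conc_uM > 0), !is.unsorted(conc_uM))
  effect <- function(c) emax_pct * c^hill / (ec50_uM^hill + c^hill)
  conc_for_effect <- function(frac_change) {
    # response = 100 + effect; frac_change relative to control 100
    e <- 100 * frac_change
    if (e >= emax_pct) stop("effect beyond Emax")
    ec50_uM * (e / (emax_pct - e))^(1 / hill)
  }
  with_seed(seed, {
    rows <- list()
    for (ex in seq_len(n_experiments)) {
      exp_id <- sprintf("exp%d", ex)
      # vehicle well: baseline plus one recording per exposure step
      fpd0 <- stats::rnorm(1, 0.42, 0.02)
      rr0 <- stats::rnorm(1, 1.1, 0.05)
      veh_fpdc0 <- fpd0 / rr0^(1 / 3)
      steps <- seq_along(conc_uM)
      veh_fpdc <- veh_fpdc0 * (1 + drift_pct_per_step * steps / 100)
      rows[[length(rows) + 1]] <- data.frame(
        experiment = exp_id, well = "veh",
        conc_uM = c(0, conc_uM),
        fpd_s = c(veh_fpdc0, veh_fpdc) * rr0^(1 / 3),
        rr_s = rr0, depol_uV = stats::rnorm(1, 400, 40),
        repol_uV = stats::rnorm(1, 60, 8),
        irregularity = "none", is_vehicle = TRUE)
      for (w in seq_len(wells_per_experiment)) {
        fpd0 <- stats::rnorm(1, 0.42, 0.02)
        rr0 <- stats::rnorm(1, 1.1, 0.05)
        base_fpdc <- fpd0 / rr0^(1 / 3)
        resp <- 100 + effect(conc_uM) +
          drift_pct_per_step * steps +
          stats::rnorm(length(conc_uM), 0, well_sd_pct)
        irr <- ifelse(conc_uM >= arrest_at_uM, "beating arrest",
                      ifelse(conc_uM >= irregular_from_uM,
                             "arrhythmia-like waveform", "none"))
        rows[[length(rows) + 1]] <- data.frame(
          experiment = exp_id, well = sprintf("w%d", w),
          conc_uM = c(0, conc_uM),
          fpd_s = c(base_fpdc, base_fpdc * resp / 100) * rr0^(1 / 3),
          rr_s = rr0, depol_uV = stats::rnorm(1, 400, 40),
          repol_uV = stats::rnorm(1, 60, 8),
          irregularity = c("none", irr), is_vehicle = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- list(
      emax_pct = emax_pct, ec50_uM = ec50_uM, hill = hill,
      well_sd_pct = well_sd_pct, drift_pct_per_step = drift_pct_per_step,
      conc_for_effect = conc_for_effect, seed = seed)
    out
  })
}

#' Generate synthetic microsomal Michaelis-Menten incubation data
#'
#' Metabolite formation rates over a substrate series (default the
#' 8-point design from 10 to 1500 uM, 3 replicates) with multiplicative
#' lognormal noise of a given CV.
#'
#' @param seed RNG seed.
#' @param Vmax,Km truth parameters (nmol/min/mg, uM).
#' @param substrate_uM substrate concentrations (uM).
#' @param n_replicates replicates per concentration.
#' @param cv multiplicative coefficient of variation (0 = noise-free).
#' @return An `incubation` data frame (`substrate_uM`,
#'   `rate_nmol_min_mg`, `replicate`) with truth attached.
#' @export
gen_mm_incubation <- function(seed = 1, Vmax = 0.82, Km = 275,
                              substrate_uM = c(10, 25, 50, 100, 250, 500,
                                               1000, 1500),
                              n_replicates = 3, cv = 0.05) {
  stopifnot(Vmax >= 0, Km > 0, all(substrate_uM > 0), cv >= 0)
  with_seed(seed, {
    S <- rep(substrate_uM, times = n_replicates)
    rep_id <- rep(seq_len(n_replicates), each = length(substrate_uM))
    mu <- Vmax * S / (Km + S)
    sdlog <- sqrt(log(1 + cv^2))
    v <- if (cv > 0 && Vmax > 0)
      mu * stats::rlnorm(length(S), -sdlog^2 / 2, sdlog) else mu
    out <- data.frame(substrate_uM = S, rate_nmol_min_mg = v,
                      replicate = rep_id)
    attr(out, "truth") <- list(Vmax = Vmax, Km = Km, cv = cv, seed = seed)
    class(out) <- c("incubation", "data.frame")
    out
  })
}

#' Generate synthetic equilibrium dialysis measurements
#'
#' Sample/buffer chamber concentration pairs consistent with a truth
#' unbound fraction plus multiplicative measurement noise; triplicate
#' measurements in two independent experiments by default.
#'
#' @param seed RNG seed.
#' @param fu truth fraction unbound.
#' @param sample_conc_uM nominal concentration in the sample chamber (uM).
#' @param n_replicates replicates per experiment.
#' @param n_experiments independent experiments.
#' @param cv measurement CV on each chamber concentration.
#' @param compound,matrix labels carried through to the output.
#' @return A `dialysis` data frame (`compound`, `matrix`, `replicate`,
#'   `buffer_conc`, `sample_conc`) with truth attached.
#' @export
gen_red_assay <- function(seed = 1, fu = 0.79, sample_conc_uM = 150,
                          n_replicates = 3, n_experiments = 2, cv = 0.03,
                          compound = "methadone",
                          matrix = "in vitro medium") {
  stopifnot(fu > 0, fu <= 1, sample_conc_uM > 0, cv >= 0)
  with_seed(seed, {
    n <- n_replicates * n_experiments
    sdlog <- sqrt(log(1 + cv^2))
    noise <- function(k) if (cv > 0)
      stats::rlnorm(k, -sdlog^2 / 2, sdlog) else rep(1, k)
    sample <- sample_conc_uM * noise(n)
    buffer <- fu * sample_conc_uM * noise(n)
    out <- data.frame(
      compound = compound, matrix = matrix,
      replicate = paste0("exp", rep(seq_len(n_experiments),
                                    each = n_replicates), "_r",
                         rep(seq_len(n_replicates), n_experiments)),
      buffer_conc = buffer, sample_conc = sample)
    attr(out, "truth") <- list(fu = fu, cv = cv, seed = seed)
    class(out) <- c("dialysis", "data.frame")
    out
  })
}

#' Generate a synthetic clinical plasma concentration-time dataset
#'
#' Runs the PBK model with parameters perturbed uniformly within
#' `+/- perturb` (absorption, metabolism and renal clearance of
#' methadone), converts the venous-blood curve to plasma by dividing by
#' the blood/plasma ratio, samples the last 24 h and adds lognormal
#' measurement noise. Used to exercise the model-evaluation workflow
#' (predicted/observed fold differences) without clinical data.
#'
#' @param seed RNG seed.
#' @param params a `pbk_params` object (the "true" model under test).
#' @param dose_mg_per_day,BW,n_days dosing scenario.
#' @param perturb fractional parameter perturbation amplitude (0 = none).
#' @param cv lognormal measurement CV (0 = none).
#' @param times_h sampling times within the last dosing day (h after the
#'   last dose).
#' @return Data frame `time_h` (hours after last dose),
#'   `conc_plasma_ng_ml`, with the perturbed parameter set and truth
#'   attached.
#' @export
gen_clinical_pk <- function(seed = 1, params = default_methadone_model(),
                            dose_mg_per_day = 70, BW = 70, n_days = 30,
                            perturb = 0.2, cv = 0.1,
                            times_h = seq(0, 24, by = 2)) {
  stopifnot(perturb >= 0, cv >= 0)
  with_seed(seed, {
    pert <- params
    factors <- list()
    for (nm in c("ka", "Fa")) {
      f <- stats::runif(1, 1 - perturb, 1 + perturb)
      pert$absorption[[nm]] <- min(pert$absorption[[nm]] * f,
                                   if (nm == "Fa") 1 else Inf)
      factors[[nm]] <- f
    }
    for (nm in c("Vmax_c", "Km")) {
      f <- stats::runif(1, 1 - perturb, 1 + perturb)
      pert$metabolism[[nm]] <- pert$metabolism[[nm]] * f
      factors[[nm]] <- f
    }
    f <- stats::runif(1, 1 - perturb, 1 + perturb)
    pert$clearance$RCLmet <- pert$clearance$RCLmet * f
    factors[["RCLmet"]] <- f

    pert <- with_body_weight(pert, BW)
    sim <- pbk_simulate(pert, dose_regimen(dose_mg_per_day,
                                           n_days = n_days))
    t_end <- max(sim$time_h)
    t_abs <- t_end - 24 + times_h
    conc_uM <- stats::approx(sim$time_h, sim$m_conc_ven, xout = t_abs)$y
    plasma <- conc_uM * params$methadone$MW / params$methadone$BPr
    sdlog <- sqrt(log(1 + cv^2))
    if (cv > 0)
      plasma <- plasma * stats::rlnorm(length(plasma), -sdlog^2 / 2, sdlog)
    out <- data.frame(time_h = times_h, conc_plasma_ng_ml = plasma)
    attr(out, "truth") <- list(factors = factors, perturb = perturb,
                               cv = cv, seed = seed,
                               dose_mg_per_day = dose_mg_per_day, BW = BW,
                               n_days = n_days)
    out
  })
}

#' Fold difference between model prediction and observed plasma data
#'
#' Simulates the scenario with the supplied (unperturbed) model and
#' compares predicted venous-blood Cmax and AUC over the last dosing day
#' with the observed plasma data converted to blood via the blood/plasma
#' ratio. Ratios near 1 indicate adequate predictive performance (a
#' two-fold difference is the usual acceptance band for PBK evaluation).
#'
#' @param params a `pbk_params` object.
#' @param observed data frame with `time_h` (hours after last dose) and
#'   `conc_plasma_ng_ml`.
#' @param dose_mg_per_day,BW,n_days dosing scenario.
#' @return List with `fold_cmax` and `fold_auc`
#'   (predicted/observed).
#' @export
evaluate_against_observed <- function(params, observed, dose_mg_per_day,
                                      BW = 70, n_days = 30) {
  stopifnot(all(c("time_h", "conc_plasma_ng_ml") %in% names(observed)))
  params <- with_body_weight(params, BW)
  sim <- pbk_simulate(params, dose_regimen(dose_mg_per_day,
                                           n_days = n_days))
  ss <- steady_state_metrics(sim, "methadone")
  obs_blood <- observed$conc_plasma_ng_ml * params$methadone$BPr
  obs_cmax <- max(obs_blood)
  obs_auc <- trapz(observed$time_h, obs_blood)
  list(fold_cmax = ss$Cmax_blood_ng_per_ml / obs_cmax,
       fold_auc = ss$AUC_interval_ng_h_per_ml / obs_auc,
       predicted_cmax_ng_ml = ss$Cmax_blood_ng_per_ml,
       observed_cmax_ng_ml = obs_cmax)
}
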