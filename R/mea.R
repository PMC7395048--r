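#' Fridericia-corrected field potential duration
#'
#' `FPDc = FPD / RR^(1/3)`, both inputs in seconds. The cube-root (beat
#' rate) correction is the in vitro analogue of the Fridericia QTc
#' correction on the ECG.
#'
#' @param FPD_s field potential duration (s).
#' @param RR_s RR interval, i.e. time between depolarization peaks (s).
#' @return Corrected field potential duration (s).
#' @examples
#' fpdc_fridericia(0.4, 8)   # 0.2
#' @export
fpdc_fridericia <- function(FPD_s, RR_s) {
  if (any(FPD_s <= 0) || any(RR_s <= 0))
    stop("FPD and RR interval must be positive (seconds)")
  FPD_s / RR_s^(1 / 3)
}

#' Quality-control filter for MEA well recordings
#'
#' Retains wells whose waveform shows a clearly visible depolarization
#' peak (amplitude >= 200 uV) and repolarization peak (amplitude >=
#' 20 uV); boundary values pass.
#'
#' @param wells data frame with columns `depol_uV` and `repol_uV` (one row
#'   per well recording).
#' @param depol_min,repol_min amplitude thresholds (uV).
#' @return The retained rows of `wells`.
#' @export
qc_filter <- function(wells, depol_min = 200, repol_min = 20) {
  if (NROW(wells) == 0) return(wells)
  keep <- wells$depol_uV >= depol_min & wells$repol_uV >= repol_min
  wells[keep, , drop = FALSE]
}

#' Vehicle- and time-corrected FPDc response
#'
#' Expresses a treated FPDc as a percentage of its own well's baseline and
#' subtracts the drift of the time-matched vehicle (solvent control) well:
#' `response = 100 * treated/baseline - (100 * vehicle_t/vehicle_baseline
#' - 100)`.
#'
#' @param treated_fpdc FPDc at the test concentration (s).
#' @param baseline_fpdc FPDc of the same well under the solvent baseline (s).
#' @param vehicle_fpdc_t vehicle-well FPDc at the matched time point (s).
#' @param vehicle_fpdc_baseline vehicle-well FPDc at baseline (s).
#' @return Response in percent of baseline.
#' @export
vehicle_corrected_response <- function(treated_fpdc, baseline_fpdc,
                                       vehicle_fpdc_t,
                                       vehicle_fpdc_baseline) {
  if (any(baseline_fpdc <= 0) || any(vehicle_fpdc_baseline <= 0))
    stop("baseline FPDc values must be positive")
  100 * treated_fpdc / baseline_fpdc -
    (100 * vehicle_fpdc_t / vehicle_fpdc_baseline - 100)
}

#' Build a concentration-response dataset from MEA well recordings
#'
#' Applies the full per-well analysis: amplitude QC, averaging of per-beat
#' FPD and RR before the Fridericia correction, normalization to the
#' well's own baseline recording, subtraction of the time-matched
#' vehicle-well drift, exclusion of concentrations flagged with waveform
#' irregularities (arrhythmia-like waveform, flattened second peak,
#' beating arrest), and aggregation to mean / SD / n per concentration.
#' Concentrations backed by fewer than `min_n` independent experiments
#' are excluded.
#'
#' @param wells data frame with one row per well x concentration, columns
#'   `experiment`, `well`, `conc_uM` (0 = baseline/vehicle recordings),
#'   `fpd_s`, `rr_s`, `depol_uV`, `repol_uV`, `irregularity` (`"none"` or
#'   a reason), and logical `is_vehicle` marking the vehicle-control well
#'   series. Baseline rows are the `conc_uM == 0` rows of each well.
#' @param min_n minimum number of independent experiments per retained
#'   concentration.
#' @return An object of class `concentration_response`: data frame with
#'   columns `conc_uM`, `response_mean`, `response_sd`, `n`; excluded
#'   concentrations (with reasons) in `attr(, "excluded")`.
#' @export
build_concentration_response <- function(wells, min_n = 3) {
  need <- c("experiment", "well", "conc_uM", "fpd_s", "rr_s", "depol_uV",
            "repol_uV", "irregularity", "is_vehicle")
  miss <- setdiff(need, names(wells))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  wells <- qc_filter(wells)
  if (!NROW(wells)) stop("no wells pass the amplitude QC filter")
  wells$fpdc <- fpdc_fridericia(wells$fpd_s, wells$rr_s)

  excluded <- data.frame(conc_uM = numeric(), reason = character())
  responses <- list()
  for (exp_id in unique(wells$experiment)) {
    we <- wells[wells$experiment == exp_id, ]
    veh <- we[we$is_vehicle, ]
    veh_base <- veh$fpdc[veh$conc_uM == 0]
    if (!length(veh_base))
      stop("experiment ", exp_id, " has no vehicle baseline recording")
    treated <- we[!we$is_vehicle, ]
    for (w in unique(treated$well)) {
      ww <- treated[treated$well == w, ]
      base <- ww$fpdc[ww$conc_uM == 0]
      if (!length(base)) next
      for (i in which(ww$conc_uM > 0)) {
        conc <- ww$conc_uM[i]
        if (!is.na(ww$irregularity[i]) && ww$irregularity[i] != "none") {
          excluded <- rbind(excluded, data.frame(
            conc_uM = conc, reason = ww$irregularity[i]))
          next
        }
        # vehicle drift at the matched exposure step (same concentration
        # index in the cumulative protocol)
        veh_t <- veh$fpdc[match(conc, veh$conc_uM)]
        if (is.na(veh_t)) veh_t <- veh_base[1]
        responses[[length(responses) + 1]] <- data.frame(
          experiment = exp_id, conc_uM = conc,
          response = vehicle_corrected_response(ww$fpdc[i], base[1],
                                                veh_t, veh_base[1]))
      }
    }
  }
  if (!length(responses)) stop("no analysable treated recordings")
  resp <- do.call(rbind, responses)
  agg <- do.call(rbind, lapply(split(resp, resp$conc_uM), function(d) {
    data.frame(conc_uM = d$conc_uM[1], response_mean = mean(d$response),
               response_sd = stats::sd(d$response),
               n = length(unique(d$experiment)))
  }))
  agg <- agg[order(agg$conc_uM), ]
  low_n <- agg$n < min_n
  if (any(low_n))
    excluded <- rbind(excluded, data.frame(
      conc_uM = agg$conc_uM[low_n],
      reason = sprintf("fewer than %d independent experiments", min_n)))
  agg <- agg[!low_n, , drop = FALSE]
  if (!nrow(agg))
    stop("no concentration is backed by >= ", min_n,
         " independent experiments")
  rownames(agg) <- NULL
  attr(agg, "excluded") <- unique(excluded)
  class(agg) <- c("concentration_response", "data.frame")
  agg
}

#' Assemble a concentration-response object from summary statistics
#'
#' @param conc_uM concentrations (uM).
#' @param response_mean mean response (% of baseline).
#' @param response_sd standard deviation per concentration.
#' @param n number of independent experiments per concentration.
#' @return A `concentration_response` object.
#' @export
concentration_response <- function(conc_uM, response_mean, response_sd, n) {
  response_sd <- rep_len(response_sd, length(conc_uM))
  n <- rep_len(n, length(conc_uM))
  stopifnot(length(conc_uM) == length(response_mean),
            all(is.finite(response_mean)))
  out <- data.frame(conc_uM = conc_uM, response_mean = response_mean,
                    response_sd = response_sd, n = n)
  out <- out[order(out$conc_uM), ]
  rownames(out) <- NULL
  attr(out, "excluded") <- data.frame(conc_uM = numeric(),
                                      reason = character())
  class(out) <- c("concentration_response", "data.frame")
  out
}

#' Per-concentration significance versus control
#'
#' Reporting-only annotation: Welch t-tests of each concentration's
#' per-experiment responses against the no-effect level (100%), with Holm
#' correction across concentrations. Annotation does not gate any
#' downstream analysis.
#'
#' @param responses data frame with columns `conc_uM` and `response`
#'   (per-experiment vehicle-corrected responses).
#' @param null_level no-effect response level (percent).
#' @return Data frame with `conc_uM`, `p_value`, `p_adj` and a
#'   significance code.
#' @export
response_significance <- function(responses, null_level = 100) {
  p <- vapply(split(responses, responses$conc_uM), function(d) {
    if (nrow(d) < 2) return(NA_real_)
    stats::t.test(d$response, mu = null_level)$p.value
  }, numeric(1))
  adj <- stats::p.adjust(p, method = "holm")
  code <- cut(adj, c(-Inf, 0.001, 0.01, 0.05, Inf),
              labels = c("***", "**", "*", ""))
  data.frame(conc_uM = as.numeric(names(p)), p_value = unname(p),
             p_adj = unname(adj), signif = as.character(code))
}

#' Read a MEA well-recording CSV
#'
#' Expected columns: `experiment`, `well`, `conc_uM`, `fpd_s`, `rr_s`,
#' `depol_uV`, `repol_uV`, `irregularity`, `is_vehicle`.
#'
#' @param path CSV file path.
#' @return A data frame of well recordings.
#' @export
read_mea_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("experiment", "well", "conc_uM", "fpd_s", "rr_s", "depol_uV",
            "repol_uV", "irregularity", "is_vehicle")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  df$is_vehicle <- as.logical(df$is_vehicle)
  df
}
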