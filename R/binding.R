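#' Fraction unbound from equilibrium dialysis
#'
#' The unbound fraction is the ratio of the concentration measured in the
#' buffer chamber to that in the sample chamber of a rapid equilibrium
#' dialysis (RED) insert, averaged over replicates. Concentrations may be
#' in any common unit (uM or raw peak areas) as the ratio is unitless.
#' No dialysis volume-shift correction is applied.
#'
#' Values above 1 can arise from assay noise for weakly bound compounds;
#' they are reported as-is with a QC flag rather than silently truncated.
#'
#' @param buffer_conc concentration(s) in the buffer chamber.
#' @param sample_conc concentration(s) in the sample chamber (> 0).
#' @return List with `fu` (mean buffer/sample ratio), `fu_sd` (across
#'   replicates, `NA` for a single pair), `n`, and `exceeds_one` flag.
#' @examples
#' fraction_unbound(c(0.54, 0.56), c(1, 1))$fu
#' @export
fraction_unbound <- function(buffer_conc, sample_conc) {
  stopifnot(length(buffer_conc) == length(sample_conc))
  if (any(sample_conc <= 0)) stop("sample-chamber concentration must be > 0")
  if (any(buffer_conc < 0)) stop("buffer-chamber concentration must be >= 0")
  ratios <- buffer_conc / sample_conc
  fu <- mean(ratios)
  flag <- fu > 1
  if (flag)
    warning("mean fraction unbound exceeds 1 (", signif(fu, 3),
            "); check assay equilibrium/recovery")
  list(fu = fu,
       fu_sd = if (length(ratios) > 1) stats::sd(ratios) else NA_real_,
       n = length(ratios), exceeds_one = flag)
}

#' Define a protein-binding scenario
#'
#' Bundles the unbound fraction in the in vitro exposure medium
#' (`fu_m`), the unbound fraction in plasma (`fu_p`) and the blood/plasma
#' concentration ratio (`BPr`) used by the unbound-concentration
#' equivalence that underlies reverse dosimetry.
#'
#' @param fu_m fraction unbound in the exposure medium (0-1].
#' @param fu_p fraction unbound in plasma (0-1].
#' @param BPr blood/plasma concentration ratio (> 0).
#' @param label scenario label, e.g. `"Simcyp 0.15"`.
#' @return An object of class `binding_scenario`.
#' @export
binding_scenario <- function(fu_m, fu_p, BPr, label = NULL) {
  stopifnot(fu_m > 0, fu_m <= 1, fu_p > 0, fu_p <= 1, BPr > 0)
  if (is.null(label)) label <- sprintf("fu_p %.3g", fu_p)
  structure(list(fu_m = fu_m, fu_p = fu_p, BPr = BPr, label = label),
            class = "binding_scenario")
}

#' The four methadone plasma-binding scenarios
#'
#' Methadone binding scenarios used for reverse dosimetry: fraction
#' unbound in the serum-free exposure medium 0.79 throughout, blood/plasma
#' ratio 0.70, and plasma unbound fractions 0.22 and 0.034 (literature
#' extremes), 0.15 (in silico) and 0.055 (equilibrium dialysis in pooled
#' plasma).
#'
#' @return A named list of [binding_scenario()] objects.
#' @export
methadone_binding_scenarios <- function() {
  fu_m <- 0.79; BPr <- 0.70
  list(
    `literature-high 0.22` = binding_scenario(fu_m, 0.22, BPr,
                                              "literature-high 0.22"),
    `Simcyp 0.15` = binding_scenario(fu_m, 0.15, BPr, "Simcyp 0.15"),
    `RED 0.055` = binding_scenario(fu_m, 0.055, BPr, "RED 0.055"),
    `literature-low 0.034` = binding_scenario(fu_m, 0.034, BPr,
                                              "literature-low 0.034"))
}

#' Convert an in vitro concentration to an equivalent total blood
#' concentration
#'
#' The unbound in vitro concentration (`C_invitro * fu_m`) is set equal to
#' the unbound blood concentration (`C_blood * fu_p / BPr`), giving
#' `C_blood = C_invitro * fu_m * BPr / fu_p`.
#'
#' @param C_invitro nominal (total) in vitro concentration (uM).
#' @param scenario a [binding_scenario()].
#' @return Equivalent total blood concentration (uM).
#' @export
invitro_to_total_blood <- function(C_invitro, scenario) {
  stopifnot(inherits(scenario, "binding_scenario"), all(C_invitro >= 0))
  C_invitro * scenario$fu_m * scenario$BPr / scenario$fu_p
}

#' Unbound blood concentration
#'
#' `C_total_blood * fu_p / BPr`: the fraction unbound in blood is the
#' plasma unbound fraction divided by the blood/plasma ratio.
#'
#' @param C_total_blood total blood concentration (uM).
#' @param fu_p fraction unbound in plasma.
#' @param BPr blood/plasma concentration ratio.
#' @return Unbound blood concentration (uM).
#' @export
unbound_blood <- function(C_total_blood, fu_p, BPr) {
  stopifnot(all(C_total_blood >= 0), fu_p >= 0, BPr > 0)
  C_total_blood * fu_p / BPr
}

#' Read an equilibrium dialysis CSV
#'
#' Expected columns: `compound`, `matrix`, `replicate`, `buffer_conc`,
#' `sample_conc`.
#'
#' @param path CSV file path.
#' @return A data frame of class `dialysis`.
#' @export
read_dialysis_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("compound", "matrix", "replicate", "buffer_conc", "sample_conc")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  class(df) <- c("dialysis", "data.frame")
  df
}
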