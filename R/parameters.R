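#' Physiological parameters for the PBK model
#'
#' Reference human physiology used by the flow-limited PBK model: body
#' weight, fractional tissue volumes, cardiac output and fractional tissue
#' blood flows. Defaults are the standard reference-human values for a
#' 70 kg adult.
#'
#' Cardiac output is stored together with the body weight it belongs to;
#' [with_body_weight()] rescales it allometrically (`Qc ~ BW^0.74`) when a
#' scenario uses a different body weight.
#'
#' @param BW body weight (kg).
#' @param VLc,VFc,VLuc,VAc,VVc,VKc,VHc,VSc,VRc tissue volumes as fractions
#'   of body weight: liver, fat, lung, arterial blood, venous blood,
#'   kidney, heart, slowly perfused and rapidly perfused tissue.
#' @param Qc cardiac output (L/h) at body weight `BW`.
#' @param QLc,QFc,QKc,QHc,QSc,QRc blood flows as fractions of cardiac
#'   output: liver, fat, kidney, heart, slowly and rapidly perfused tissue.
#'   Must sum to 1 (within 1e-9).
#' @return An object of class `physiology_params` (named list).
#' @export
physiology_params <- function(BW = 70,
                              VLc = 0.0257, VFc = 0.2142, VLuc = 0.0076,
                              VAc = 0.0198, VVc = 0.0593, VKc = 0.004,
                              VHc = 0.0047, VSc = 0.5318, VRc = 0.052,
                              Qc = 347.9,
                              QLc = 0.227, QFc = 0.052, QKc = 0.175,
                              QHc = 0.04, QSc = 0.188, QRc = 0.318) {
  p <- list(BW = BW, VLc = VLc, VFc = VFc, VLuc = VLuc, VAc = VAc,
            VVc = VVc, VKc = VKc, VHc = VHc, VSc = VSc, VRc = VRc,
            Qc = Qc, QLc = QLc, QFc = QFc, QKc = QKc, QHc = QHc,
            QSc = QSc, QRc = QRc)
  class(p) <- "physiology_params"
  validate_physiology(p)
  p
}

validate_physiology <- function(p, tol = 1e-9) {
  stopifnot(p$BW > 0, p$Qc > 0)
  vfrac <- unlist(p[c("VLc", "VFc", "VLuc", "VAc", "VVc", "VKc", "VHc",
                      "VSc", "VRc")])
  qfrac <- unlist(p[c("QLc", "QFc", "QKc", "QHc", "QSc", "QRc")])
  if (any(vfrac <= 0) || any(vfrac >= 1))
    stop("tissue volume fractions must lie in (0, 1)")
  if (sum(vfrac) > 1 + tol)
    stop("tissue volume fractions sum to more than 1 (", sum(vfrac), ")")
  if (any(qfrac <= 0) || any(qfrac >= 1))
    stop("blood flow fractions must lie in (0, 1)")
  if (abs(sum(qfrac) - 1) > tol)
    stop("blood flow fractions must sum to 1 (got ", sum(qfrac),
         "); pass check_flows = FALSE to pbk_simulate() to override")
  invisible(p)
}

#' Compound-specific parameters
#'
#' Physicochemical and distribution parameters for one compound: molar
#' mass, blood/plasma concentration ratio, fraction unbound in plasma and
#' tissue:blood partition coefficients. The tissue:blood partition
#' coefficients were derived from tissue:plasma coefficients divided by the
#' blood/plasma ratio; they are model inputs here, not predicted.
#'
#' @param name compound identifier.
#' @param MW molar mass (g/mol).
#' @param logP octanol-water partition coefficient (metadata only).
#' @param pKa acid dissociation constant (metadata only).
#' @param BPr blood/plasma concentration ratio (dimensionless).
#' @param fu_p fraction unbound in plasma (0-1].
#' @param P_liver,P_fat,P_slow,P_rapid,P_lung,P_kidney,P_heart tissue:blood
#'   partition coefficients (dimensionless, > 0).
#' @return An object of class `compound_params`.
#' @export
compound_params <- function(name, MW, logP = NA_real_, pKa = NA_real_,
                            BPr, fu_p,
                            P_liver, P_fat, P_slow, P_rapid,
                            P_lung, P_kidney, P_heart) {
  stopifnot(MW > 0, BPr > 0, fu_p > 0, fu_p <= 1)
  P <- c(P_liver, P_fat, P_slow, P_rapid, P_lung, P_kidney, P_heart)
  if (any(P <= 0)) stop("all partition coefficients must be > 0")
  p <- list(name = name, MW = MW, logP = logP, pKa = pKa, BPr = BPr,
            fu_p = fu_p, P_liver = P_liver, P_fat = P_fat, P_slow = P_slow,
            P_rapid = P_rapid, P_lung = P_lung, P_kidney = P_kidney,
            P_heart = P_heart)
  class(p) <- "compound_params"
  p
}

#' Oral absorption parameters
#' @param ka first-order absorption rate constant (1/h).
#' @param Fa oral fraction absorbed (0-1].
#' @return An object of class `absorption_params`.
#' @export
absorption_params <- function(ka = 0.59, Fa = 0.88) {
  stopifnot(ka > 0, Fa > 0, Fa <= 1)
  structure(list(ka = ka, Fa = Fa), class = "absorption_params")
}

#' Hepatic metabolism parameters
#'
#' Apparent Michaelis-Menten constants for the microsomal conversion of
#' methadone to EDDP, plus the microsomal protein yield used to scale the
#' in vitro maximum rate to the whole liver (see [scale_vmax_in_vivo()]).
#'
#' @param Vmax_c unscaled maximum rate (nmol/min/mg microsomal protein).
#' @param Km apparent Michaelis-Menten constant (uM).
#' @param MPL liver microsomal protein yield (mg protein/g liver).
#' @return An object of class `metabolism_params`.
#' @export
metabolism_params <- function(Vmax_c = 0.82, Km = 275, MPL = 32) {
  stopifnot(Vmax_c > 0, Km > 0, MPL > 0)
  structure(list(Vmax_c = Vmax_c, Km = Km, MPL = MPL),
            class = "metabolism_params")
}

#' Excretion parameters
#' @param RCLmet renal (blood) clearance of methadone (L/h).
#' @param RCLeddp renal (blood) clearance of EDDP (L/h).
#' @param kbile first-order biliary excretion rate constant of EDDP (1/h).
#' @return An object of class `clearance_params`.
#' @export
clearance_params <- function(RCLmet = 1.45, RCLeddp = 19.99, kbile = 1.65) {
  stopifnot(RCLmet >= 0, RCLeddp >= 0, kbile >= 0)
  structure(list(RCLmet = RCLmet, RCLeddp = RCLeddp, kbile = kbile),
            class = "clearance_params")
}

#' Repeated oral dosing regimen
#' @param dose_mg_per_day daily oral dose of methadone free base (mg).
#' @param interval dosing interval (h).
#' @param n_days number of dosing days (integer >= 1).
#' @return An object of class `dose_regimen`.
#' @export
dose_regimen <- function(dose_mg_per_day, interval = 24, n_days = 30) {
  stopifnot(dose_mg_per_day >= 0, interval > 0, n_days >= 1)
  structure(list(dose_mg_per_day = dose_mg_per_day, interval = interval,
                 n_days = as.integer(n_days)), class = "dose_regimen")
}

#' Default methadone/EDDP PBK parameterization
#'
#' Builds the complete default parameter set of the PBK model: reference
#' human physiology, compound properties for methadone and EDDP, oral
#' absorption, hepatic Michaelis-Menten metabolism (methadone -> EDDP,
#' 1:1 molar) and renal/biliary excretion.
#'
#' Compound notes: methadone free base MW 309.45 g/mol, EDDP 277.4 g/mol;
#' blood/plasma ratios 0.70 (methadone) and 0.87 (EDDP); default plasma
#' unbound fractions 0.15 (methadone, in silico derived) and 0.30 (EDDP).
#'
#' @return An object of class `pbk_params`: a list with elements
#'   `physiology`, `methadone`, `eddp`, `absorption`, `metabolism`,
#'   `clearance`.
#' @examples
#' mod <- default_methadone_model()
#' sum(unlist(mod$physiology[c("QLc","QFc","QKc","QHc","QSc","QRc")]))
#' @export
default_methadone_model <- function() {
  p <- list(
    physiology = physiology_params(),
    methadone = compound_params(
      name = "methadone", MW = 309.45, logP = 3.93, pKa = 9.20,
      BPr = 0.70, fu_p = 0.15,
      P_liver = 12.45, P_fat = 0.46, P_slow = 7.67, P_rapid = 12.45,
      P_lung = 1.77, P_kidney = 7.56, P_heart = 4.9),
    eddp = compound_params(
      name = "EDDP", MW = 277.4, logP = 4.63, pKa = 9.64,
      BPr = 0.87, fu_p = 0.30,
      P_liver = 11.51, P_fat = 0.18, P_slow = 7.06, P_rapid = 11.51,
      P_lung = 1.56, P_kidney = 6.95, P_heart = 4.48),
    absorption = absorption_params(),
    metabolism = metabolism_params(),
    clearance = clearance_params()
  )
  class(p) <- "pbk_params"
  p
}

#' Rescale a parameter set to a new body weight
#'
#' Sets body weight and rescales cardiac output allometrically,
#' `Qc' = Qc * (BW'/BW)^0.74`, keeping all fractional volumes and flows.
#'
#' @param params a `pbk_params` or `physiology_params` object.
#' @param BW new body weight (kg).
#' @return The rescaled object.
#' @export
with_body_weight <- function(params, BW) {
  stopifnot(BW > 0)
  if (inherits(params, "pbk_params")) {
    params$physiology <- with_body_weight(params$physiology, BW)
    return(params)
  }
  stopifnot(inherits(params, "physiology_params"))
  params$Qc <- params$Qc * (BW / params$BW)^0.74
  params$BW <- BW
  params
}

#' @export
print.pbk_params <- function(x, ...) {
  cat("PBK parameter set (flow-limited, methadone + EDDP submodel)\n")
  cat(sprintf("  body weight: %.1f kg; cardiac output: %.1f L/h\n",
              x$physiology$BW, x$physiology$Qc))
  cat(sprintf("  absorption: ka = %.3g /h, Fa = %.3g\n",
              x$absorption$ka, x$absorption$Fa))
  cat(sprintf("  metabolism: Vmax_c = %.3g nmol/min/mg, Km = %.4g uM, MPL = %.3g mg/g\n",
              x$metabolism$Vmax_c, x$metabolism$Km, x$metabolism$MPL))
  cat(sprintf("  clearance: RCLmet = %.3g, RCLeddp = %.3g L/h, kbile = %.3g /h\n",
              x$clearance$RCLmet, x$clearance$RCLeddp, x$clearance$kbile))
  invisible(x)
}

#' Serialize a parameter set to a plain list / file
#'
#' Parameter sets round-trip through plain named lists whose symbol names
#' mirror the model's conventional symbols (BW, VLc, ..., Qc, QLc, ...,
#' ka, Fa, Vmax_c, Km, MPL, RCLmet, RCLeddp, kbile and per-compound MW,
#' BPr, fu_p, P_*), and through JSON or YAML files.
#'
#' @param params a `pbk_params` object.
#' @return `pbk_params_to_list()`: a nested plain list.
#' @export
pbk_params_to_list <- function(params) {
  stopifnot(inherits(params, "pbk_params"))
  lapply(params, function(x) lapply(unclass(x), identity))
}

#' @rdname pbk_params_to_list
#' @param x a nested list as produced by `pbk_params_to_list()`; unknown
#'   fields are rejected.
#' @export
as_pbk_params <- function(x) {
  known <- c("physiology", "methadone", "eddp", "absorption", "metabolism",
             "clearance")
  extra <- setdiff(names(x), known)
  if (length(extra))
    stop("unknown parameter groups: ", paste(extra, collapse = ", "))
  base <- default_methadone_model()
  for (grp in names(x)) {
    extra <- setdiff(names(x[[grp]]), names(base[[grp]]))
    if (length(extra))
      stop("unknown fields in ", grp, ": ", paste(extra, collapse = ", "))
    for (f in names(x[[grp]])) base[[grp]][[f]] <- x[[grp]][[f]]
  }
  validate_physiology(base$physiology)
  base
}

#' @rdname pbk_params_to_list
#' @param path file path ending in `.json`, `.yml` or `.yaml`.
#' @export
write_pbk_params <- function(params, path) {
  lst <- pbk_params_to_list(params)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(lst, path)
  }
  invisible(path)
}

#' @rdname pbk_params_to_list
#' @export
read_pbk_params <- function(path) {
  lst <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  as_pbk_params(lst)
}
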