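---
title: "From cardiomyocyte field potentials to human dose-response: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From cardiomyocyte field potentials to human dose-response: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pbkdosim)
```

# Overview

`pbkdosim` implements a quantitative in vitro to in vivo extrapolation
(QIVIVE) workflow for cardiac safety: a physiologically based kinetic
(PBK) model of methadone and its primary metabolite EDDP predicts
internal exposure under repeated oral dosing, and reverse dosimetry
inverts that model to translate concentration–response data measured in
human induced pluripotent stem cell-derived cardiomyocytes (hiPSC-CM, on
a multi-electrode array) into predicted human dose–response curves for
QTc prolongation. The prolongation of the rate-corrected field potential
duration (FPDc) in vitro serves as the surrogate of the QTc interval on
the ECG.

This vignette documents the model structure, the assumptions behind each
stage, the numerical choices, what the synthetic-data generators emulate,
and the design decisions taken where the problem was genuinely open.

# The PBK model

## Structure

The model is a flow-limited (perfusion-limited), well-stirred
compartmental system with nine perfused compartments per compound —
liver, fat, lung, kidney, heart, slowly perfused tissue, rapidly
perfused tissue, arterial blood and venous blood — plus a gut lumen
compartment for the oral depot of methadone. For every perfused tissue
$T$ with blood flow $Q_T$, volume $V_T$ and tissue:blood partition
coefficient $P_T$,

$$\frac{dA_T}{dt} = Q_T\left(C_{\mathrm{art}} - \frac{C_T}{P_T}\right),$$

where $C_T = A_T/V_T$ and $C_T/P_T$ is the venous outflow (blood
equivalent) concentration. The lung sits in series between the venous
and arterial blood pools; all other tissues are perfused in parallel
from arterial blood and drain into venous blood. Amounts are carried in
µmol and concentrations in µM; tissue density is taken as 1 g/mL.

Oral absorption is first order: each daily dose adds
$F_a \cdot \mathrm{dose}$ (converted to µmol with the molar mass of the
free base, 309.45 g/mol) to the gut lumen, from which drug is absorbed
at rate $k_a A_{\mathrm{gut}}$ directly into the liver, so absorbed drug
is subject to first-pass metabolism. The unabsorbed fraction
$(1-F_a)$ is booked as such, never entering the system.

Hepatic metabolism converts methadone to EDDP 1:1 on a molar basis at a
Michaelis–Menten rate driven by the liver venous blood-equivalent
concentration $C_{VL} = C_{\mathrm{liver}}/P_{\mathrm{liver}}$:

$$v = \frac{V_{\max}^{vivo}\, C_{VL}}{K_m + C_{VL}},$$

with the apparent microsomal constants applied directly (no unbound
correction of $K_m$, consistent with how apparent constants from
microsomal incubations are commonly used). The in vitro maximum rate
(nmol/min/mg microsomal protein) is scaled to the whole liver with the
microsomal protein yield (32 mg/g liver) and liver mass:
$V_{\max}^{vivo} = V_{\max,c} \times 60/1000 \times \mathrm{MPL} \times
V_{Lc}\,\mathrm{BW}\times 1000$ (µmol/h).

Excretion: methadone and EDDP are cleared from the venous blood pool by
systemic renal blood clearances (1.45 and 19.99 L/h); EDDP is
additionally excreted from the liver into a biliary/fecal sink with a
first-order rate constant of 1.65 /h, with no enterohepatic
recirculation. EDDP itself distributes over the same compartment
structure (its own partition coefficients), and its conversion to the
secondary metabolite EMDP is not modelled — no EMDP formation was
detectable in microsomal incubations with EDDP as substrate, and EMDP
exposure in vivo is reported to be negligible.

Two reconstruction choices deserve emphasis, because the published model
equations were not available and the structure was rebuilt from the
compartment diagram and parameter tables:

* **Renal clearance samples venous blood.** The clearances are given as
  systemic blood clearances in L/h, so elimination is computed as
  $\mathrm{RCL}\cdot C_{\mathrm{ven}}$ and removed from the venous blood
  compartment; the kidney compartment remains purely distributive. The
  alternative (sampling the kidney outflow) changes steady-state
  predictions by only a few percent; the venous-blood convention
  reproduces the published steady-state Cmax/AUC evaluations within
  about 1%, so it was retained without further calibration.
* **First-pass routing.** Absorbed drug enters the liver, not the
  venous pool; this is what makes the oral bioavailability sensitive to
  the metabolic parameters and is consistent with the model diagram
  (GI tract → liver).

## Parameters

Physiology follows the standard reference human (70 kg): fractional
tissue volumes sum to 0.9191 of body weight and fractional blood flows
sum to exactly 1 of cardiac output (347.9 L/h at 70 kg). When a dosing
scenario specifies a different body weight, cardiac output is rescaled
allometrically, $Q_c \propto \mathrm{BW}^{0.74}$ — the default 347.9 L/h
equals $15\,\mathrm{BW}^{0.74}$ at 70 kg, so the rescaling is exact at
the reference point. Tissue volumes and flows scale linearly through
their fractions.

Compound parameters (blood/plasma ratios 0.70/0.87 for methadone/EDDP,
tissue:blood partition coefficients, plasma unbound fractions 0.15 and
0.30) are inputs taken as printed; partition-coefficient prediction is
out of scope. The absorption constants are $k_a = 0.59$ /h and
$F_a = 0.88$; hepatic metabolism uses $V_{\max,c} = 0.82$ nmol/min/mg and
$K_m = 275$ µM.

## Numerics

The ODE system (23 states) is integrated with `deSolve::lsoda` at
`rtol = 1e-8`, `atol = 1e-10`. Each daily bolus is applied as a
discontinuous event (an integrator restart), never smoothed. Output is
sampled at 100 points per dosing interval so the within-interval Cmax is
resolved; AUC over the final interval uses the trapezoidal rule, which
at this grid density is accurate to well under 0.1% for curves of this
smoothness. Mass balance (administered = unabsorbed + present + excreted
+ metabolized, and the EDDP analogue with cumulative formation as the
source) is checked to a relative residual below $10^{-6}$; with these
tolerances it sits near $10^{-14}$.

Steady-state scenarios simulate the duration reported for the
corresponding clinical study when one exists (for example 60 days for
the 70 mg/day evaluation); otherwise 30 days, at which point
consecutive-day Cmax values differ by less than 0.5% (methadone's
effective half-life in the model is roughly one day). The automatic
steady-state detector doubles the duration until the consecutive-interval
change falls below 0.1%, capped at 120 days.

# In vitro stages

## Microsomal kinetics

`fit_michaelis_menten()` fits $v = V_{\max}[S]/(K_m+[S])$ by unweighted
nonlinear least squares (Levenberg–Marquardt), with data-driven starting
values ($V_{\max,0}$ = largest observed rate; $K_{m,0}$ = concentration
at half-max by linear interpolation). Unweighted least squares mirrors
the common default of the graphing software used for such fits; reported
microsomal analyses rarely state their weighting, so this default is a
documented choice rather than an inference. Fits whose $K_m$
exceeds 10× the largest tested concentration are flagged unreliable
rather than silently reported. Intestinal microsomal rates below 8% of
the hepatic rate at matched concentrations are classified "negligible —
not fitted", mirroring the decision to omit intestinal metabolism from
the PBK model.

## Protein binding

The unbound fraction from rapid equilibrium dialysis is the plain
buffer/sample concentration ratio; no volume-shift correction is
applied. Noisy estimates above 1 are flagged, not truncated. The
reverse-dosimetry conversions rest on the unbound-concentration
equivalence

$$C_{\mathrm{in\,vitro}} \cdot f_{u,m} =
  C_{\mathrm{blood}} \cdot \frac{f_{u,p}}{BP_r},$$

so the equivalent total blood concentration is
$C_{\mathrm{in\,vitro}} f_{u,m} BP_r / f_{u,p}$, and composing the
forward and backward conversions returns $C_{\mathrm{in\,vitro}}
f_{u,m}$ exactly. Four plasma-binding scenarios are predefined for
methadone ($f_{u,p} \in \{0.22, 0.15, 0.055, 0.034\}$, with
$f_{u,m} = 0.79$ in the serum-free exposure medium), spanning the
reported inter-individual range of plasma protein binding.

## MEA endpoint processing

Wells must show a depolarization peak ≥ 200 µV and a repolarization
peak ≥ 20 µV (boundary passes). Per-beat FPD and RR are averaged
*before* the Fridericia correction $\mathrm{FPDc} =
\mathrm{FPD}/\sqrt[3]{RR}$ (both in seconds), matching the averaging of
at least 30 beats per recording; per-beat correction is available as an
option. Responses are percentages of the same well's baseline recording,
minus the drift of the time-matched vehicle well in percentage points.
Concentrations flagged with waveform irregularities (arrhythmia-like
waveform, flattened second peak, beating arrest) are excluded from FPD
analysis with their reason retained, and a concentration must be backed
by at least three independent experiments. The per-well baseline is
assumed to be the same well's solvent (0.1% DMSO) pre-exposure
recording — the natural reading of a cumulative-exposure protocol.
Significance annotation versus control uses Welch t-tests with Holm
correction (a Dunnett-style multiple comparison would need an external
dependency); it is reporting-only and gates nothing.

# Benchmark dose analysis

Continuous summary data (dose, mean, SD, n) are fitted by maximum
likelihood under normal errors with a common residual variance; with
the variance profiled out this is weighted least squares with weights
$n_i$, and the within-group SDs enter the likelihood (and hence AIC)
through the pooled variance estimate. Implemented families:

* exponential, 3-parameter: $y = a\,e^{\pm b x^d}$
* exponential, 4-parameter: $y = a(c - (c-1)e^{-b x^d})$
* Hill, 4-parameter: $y = a(1 + (c-1)\,x^d/(b^d + x^d))$
* optional, behind a flag: inverse exponential
  $y = a(1 + (c-1)e^{-b x^{-d}})$ and log-normal
  $y = a(1 + (c-1)\Phi(d \ln(x/b)))$

The exact parameterizations of the PROAST/EFSA web tool vary across
versions, so the families follow the published EFSA forms; numerical identity with that tool is a non-goal. Parameters are
optimized on the log scale (Nelder–Mead, then BFGS polish). The
benchmark response is a relative deviation from the *fitted* control
response (EFSA continuous-data convention), i.e. the BMD solves
$\bar y(\mathrm{BMD}) = \bar y(0)(1 \pm \mathrm{BMR})$ on the
Akaike-weighted average curve $\bar y$, with weights
$w_j \propto e^{-\Delta\mathrm{AIC}_j/2}$ (ties share weight equally). A
constant (no-trend) model is always fitted alongside; when it matches or
beats every dose-response family on AIC the data are flagged as having
no dose-related trend and no BMD is produced.

Confidence limits (BMDL/BMDU) are the 5th/95th percentiles of BMDs from
200 parametric bootstrap datasets: group means resampled from normal
distributions centred on the model-averaged fitted means with standard
errors $s_i/\sqrt{n_i}$. Only summary data exist at this stage, which is
why the bootstrap is parametric on the group means. The in vitro
benchmark concentration uses BMR = 20% (the smallest benchmark response
that supports reliable curve fitting on these data); the predicted
in vivo dose-response curves use BMR = 10%, the conventional threshold
for abnormal QTc prolongation (10% over a 407 ms population baseline is
a QTc of about 450 ms).

# Sensitivity analysis

Local one-at-a-time normalized sensitivity coefficients,

$$\mathrm{SC} = \frac{C' - C}{P' - P}\cdot\frac{P}{C},$$

with $C$ the steady-state methadone Cmax in heart venous blood and a 1%
parameter increase by default. Fractional composition parameters
(volume and flow fractions) are perturbed *without* re-normalizing the
remaining fractions — the standard OAT convention — which transiently
violates the flow-sum identity by 1%; the simulator's flow-sum guard is
therefore bypassed for perturbed runs only. Body-weight perturbations
carry cardiac output with them through the allometric rule. Parameters
with $|\mathrm{SC}| > 0.1$ are flagged influential. The coefficient is
invariant to the units of $P$ by construction; halving the perturbation
step changes the coefficients by well under 2%, confirming the linear
regime.

# Reverse dosimetry

The in vitro unbound concentration is equated to the unbound
steady-state Cmax of methadone in heart venous blood (the tissue
venous outflow concentration $C_{\mathrm{heart}}/P_{\mathrm{heart}}$),
the site concentration relevant for a cardiac endpoint; the systemic
venous-blood compartment is available as an alternative output and is
the default for the EDDP screening computation, whose clinical
comparator is a venous blood Cmax. Inversion uses Brent root search on
the log dose with a relative tolerance of $10^{-4}$, after an explicit
monotonicity check of the dose→Cmax relation over the search bracket
(default 0.001–10000 mg/day; the upper bound leaves a margin above the
~2600 mg/day EDDP screening result). Monotonicity is what makes the
inverse well defined; it is also verified as a property test over a dose
grid.

Translating a whole curve would repeat that root search per
concentration and scenario, so `dose_cmax_map()` instead simulates a
log-spaced dose grid once (19 doses over 0.01–10⁴ mg/day by default),
checks strict monotonicity, and interpolates log-Cmax vs log-dose with a
monotone Hyman spline in both directions. The map's inverse agrees with
the direct root search to well within 0.1% (tested), and one map serves
all binding scenarios because the scenario only rescales the target
concentration. Raw concentration–response points are translated
(responses carried over unchanged); the 4PL fit is for display, not for
translation. The EDDP dose search is retained purely as a relevance
screen — EDDP exposures at clinical doses sit far below its in vitro
benchmark concentration — and EDDP is not otherwise used for reverse
dosimetry.

# Synthetic data

No raw data from the original experiments are deposited, so seeded
generators produce every input the pipeline consumes, with the
statistical structure the analysis assumes, and each generator attaches
its generating truth for recovery tests.

* **MEA wells** (`gen_mea_crc`): cumulative-exposure design over the
  methadone concentration grid (0.01–30 µM), three independent
  experiments with two treated wells each plus a vehicle well, a
  Hill-shaped FPDc effect (default Emax 60%, slope 1.5, EC50 placed so
  the analytic 20%-effect concentration is 0.6 µM), additive
  between-well noise of 8 percentage points, a linear vehicle drift of
  −0.5% per exposure step shared by treated and vehicle wells, and
  irregularity flags from 3 µM (arrhythmia-like waveforms) with beating
  arrest at 30 µM. The noise and drift levels approximate the dispersion
  visible in the published concentration–response figures (SD bars on
  the order of 10% of the response); they are documented approximations,
  not reported values.
* **Microsomal incubations** (`gen_mm_incubation`): the 8-point design
  from 10 to 1500 µM in triplicate, multiplicative lognormal noise
  (default CV 5%).
* **Equilibrium dialysis** (`gen_red_assay`): triplicates in two
  experiments at 150 µM nominal, lognormal measurement noise per
  chamber (CV 3%, in line with the reported SDs of 0.041/0.011 on the
  unbound fractions).
* **Clinical curves** (`gen_clinical_pk`): the PBK model itself with
  parameters perturbed uniformly within ±20% and lognormal sampling
  noise, converted to plasma via the blood/plasma ratio — used to
  exercise the predicted/observed fold-difference evaluation.

What passing these tests shows — and does not show: recovery tests prove
the estimators invert the generators' assumed structure (Hill effect,
multiplicative MM noise, shared linear drift). Real MEA data can drift
nonlinearly, wells are not exchangeable, and real concentration–response
need not be Hill-shaped; the generators do not emulate electrode-level
variation, beat-to-beat dynamics, or assay plate effects. Agreement with
the clinical steady-state Cmax/AUC values is tested directly against the
printed numbers instead.

# Problem sizes and determinism

Default analysis sizes: 100 output points per dosing interval;
30 simulated days for steady-state scenarios (60 where the study says
so); 19-point dose grid for the inversion map; 200 bootstrap datasets
for BMD confidence limits. Every stochastic stage takes an explicit
seed, restores the caller's RNG state, and is bit-reproducible given the
same configuration; the pipeline writes a config hash alongside its
artifacts.

# Known limitations

* The ODE structure is a reconstruction from the compartment diagram
  and parameter tables; a full original equation listing was not
  available. The clinical steady-state evaluations
  bound the impact (Cmax/AUC within a few percent), but intermediate
  quantities (e.g. tissue concentrations) are untested against the
  original.
* Fitting both EDDP clearance parameters to a single Cmax target is
  under-determined; `fit_eddp_clearance()` requires fixing one parameter
  or supplying a ratio constraint.
* Enantiomer-specific kinetics, CYP2B6 polymorphism, intestinal
  metabolism, EDDP→EMDP conversion and mechanistic protein-binding
  models are out of scope by design.
* BMD results are not numerically identical to the EFSA/PROAST web
  tool; the model families and averaging rules follow the published
  EFSA conventions.
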