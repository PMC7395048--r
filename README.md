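# pbkdosim

PBK modelling and reverse dosimetry for cardiac safety assessment of
methadone.

`pbkdosim` is for toxicologists and pharmacologists who want to translate
in vitro cardiotoxicity data into predicted human dose–response curves
without animal data. It implements a complete quantitative in vitro to
in vivo extrapolation (QIVIVE) workflow around methadone, an opioid whose
therapeutic use is associated with QTc prolongation and torsade de
pointes:

1. **In vitro endpoints.** Field potential duration (FPD) recordings from
   human iPSC-derived cardiomyocytes on a multi-electrode array are
   rate-corrected with the Fridericia formula,
   FPDc = FPD / RR^(1/3), quality-filtered (depolarization ≥ 200 µV,
   repolarization ≥ 20 µV), normalized to each well's baseline and
   corrected for vehicle/time drift; concentrations that trigger
   arrhythmia-like waveforms or beating arrest are excluded with reasons.
2. **Microsomal kinetics.** Michaelis–Menten constants for hepatic
   conversion of methadone to its main metabolite EDDP,
   v = Vmax·[S]/(Km+[S]), are fitted from incubation data and scaled to
   the whole liver (32 mg microsomal protein/g liver).
3. **PBK model.** A nine-compartment flow-limited model of methadone with
   a parallel EDDP submodel simulates repeated oral dosing (first-order
   absorption into the liver, saturable hepatic metabolism, renal and
   biliary excretion) and reports steady-state Cmax and AUC.
4. **Reverse dosimetry.** The unbound in vitro concentration is equated
   to the unbound steady-state Cmax in heart venous blood,
   C_invitro·fu_m = C_blood·fu_p/BPr, and the model is inverted to find
   the daily dose matching each tested concentration — one predicted
   dose–response curve per plasma-binding scenario
   (fu_p ∈ {0.22, 0.15, 0.055, 0.034}).
5. **Benchmark dose analysis.** Exponential and Hill family fits,
   AIC-weighted model averaging and a 200-set parametric bootstrap yield
   BMC20 values in vitro and BMD10/BMDL10/BMDU10 values on the predicted
   dose–response curves.

Seeded generators (`gen_mea_crc()`, `gen_mm_incubation()`,
`gen_red_assay()`, `gen_clinical_pk()`) produce every input the pipeline
consumes, with known truth attached, so the full workflow runs and is
tested without any external data.

## Worked example

Simulate 70 mg/day for 60 days in a 74 kg adult and inspect the
steady-state kinetics:

```r
library(pbkdosim)

model <- default_methadone_model()
sim <- pbk_simulate(with_body_weight(model, 74),
                    dose_regimen(70, n_days = 60))
steady_state_metrics(sim, "methadone")
#> methadone steady-state metrics (final 24 h interval):
#>   Cmax blood 1.034 uM (319.9 ng/mL); AUC 4927.9 ng.h/mL
#>   Cmax heart venous outflow 1.031 uM; Cmax unbound blood 0.2215 uM
mass_balance(sim)
#> [1] 1.260734e-14
```

The predicted blood Cmax of 319.9 ng/mL and AUC of 4928 ng·h/mL sit
within a few percent of the steady-state values reported for this
dosing scenario in the clinical literature (346 ng/mL and 5097 ng·h/mL
observed in vivo), and mass is conserved to numerical precision.

Run the whole in vitro → in vivo pipeline on synthetic data:

```r
cfg <- pipeline_config(seed = 1, n_bootstrap = 200,
                       out_dir = "pipeline_out")
res <- run_pipeline(cfg)
res$bmc20
#> Model-averaged BMD (BMR 20% increase): 0.7526  [BMDL 0.4608, BMDU 1.036]
#>   weights: exponential-3 0.48, exponential-4 0.26, hill 0.26
res$bmd[["RED 0.055"]]
#> Model-averaged BMD (BMR 10% increase): 270.8  [BMDL 146.6, BMDU 367.2]
#>   weights: exponential-3 0.48, exponential-4 0.26, hill 0.26
```

The in vitro benchmark concentration (BMC20, the concentration
prolonging FPDc by 20% over control) lands near the generator's truth of
0.6 µM under this seed's well noise; the dose-level BMD10 is the predicted daily dose producing a 10%
QTc-surrogate change under the given plasma-binding scenario, with
bootstrap 90% confidence limits. `pipeline_out/` contains the
concentration–response table, one predicted dose–response CSV per
binding scenario and a JSON summary carrying the config hash.

Individual stages are plain functions: `fit_michaelis_menten()`,
`fraction_unbound()`, `build_concentration_response()`, `bmc20()`,
`normalized_sc()`, `sensitivity_report()`, `dose_for_target()`,
`translate_crc()`, `model_averaged_bmd()`. See the methods vignette
(`vignettes/methods.Rmd`) for the model equations, assumptions and
design choices.

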