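# dynamicMFR

Quantification of myocardial blood flow (MBF, mL/min/g) and myocardial flow
reserve (MFR = stress MBF / rest MBF) from frame-binned dynamic rest/stress
time–activity curves (TACs), for two modalities:

- **Dynamic ⁹⁹ᵐTc-sestamibi CZT-SPECT** — a net-retention model with
  flow-dependent extraction correction. Sestamibi is trapped in myocardium,
  so the late tissue activity, corrected for blood-pool spillover and
  partial volume and ratioed to the integrated arterial input, estimates the
  uptake rate K1:

  ```
        (1 / (PV·(t3−t2))) ∫[t2,t3] ( P(t) − Sm·Ca(t) ) dt
  R  =  ───────────────────────────────────────────────────     [1/min]
              CF · ∫[0,t1] ( Ca(t) − Sb·P(t) ) dt
  ```

  where P(t) is the myocardial TAC, Ca(t) the arterial (blood-pool) TAC,
  and the limits t1/t2/t3 are anchored at the detected bolus (defaults
  1.5 min for the input phase, 1.5–2.5 min for the tissue phase). R is
  identified with K1 and converted to flow by inverting the Renkin–Crone
  relation `K1 = MBF·(1 − A·e^(−B/MBF))` with A = 0.874, B = 0.443.

- **Dynamic ¹⁵O-water PET** — the reference modality. Water is freely
  diffusible (extraction 1), so a one-tissue-compartment model is fitted by
  bounded nonlinear least squares:
  `Ct(t) = MBF·∫ Ca(τ)·e^(−(MBF/p)(t−τ)) dτ`, measured as
  `PTF·Ct + Va·Ca` with partition coefficient p = 0.91 mL/g, perfusable
  tissue fraction PTF and arterial blood volume Va.

A synthetic cohort generator produces complete rest/stress dual-modality
studies (gamma-variate arterial input with recirculation, trapping and
washout kinetics, spillover, partial volume, count-statistics noise) with
known ground-truth MBF, MFR and per-territory fractional flow reserve
(FFR), so every stage of the pipeline is testable without any patient data.
A concordance layer classifies flows against FFR (MFR < 2 for PET,
MFR < 2.1 for CZT-SPECT, stress MBF < 2.5 mL/min/g, FFR abnormal ≤ 0.8)
and computes 2×2 diagnostic metrics, Cohen's kappa, ROC/AUC with Youden
cutoff selection, Bland–Altman limits of agreement and Pearson correlation.

The package is aimed at researchers developing or validating dynamic
cardiac SPECT/PET flow quantification.

## Worked example

Simulate one patient and quantify the SPECT arm:

```r
library(dynamicMFR)

study <- simulateStudy(simConfig(seed = 42, nPatients = 1))
pat   <- study$patients[[1]]

spectSchedule()
#> FrameSchedule: 32 frames, 345 s total
#>    21x3s, 1x9s, 1x15s, 1x21s, 1x27s, 7x30s

quantifySpect(pat$spect$rest, pat$spect$stress)
#>   region rest_mbf stress_mbf  mfr k1_rest k1_stress sm_rest sm_stress
#> 1 GLOBAL     1.01       3.21 3.19   0.440     0.767     0.3       0.3
#> 2    LAD     1.21       4.01 3.32   0.476     0.871     0.3       0.3
#> 3    LCX     1.02       2.99 2.92   0.443     0.737     0.3       0.3
#> 4    RCA     0.79       2.64 3.34   0.396     0.689     0.3       0.3
```

Columns: recovered rest and stress MBF (mL/min/g), their ratio MFR, the
retention-derived uptake rates K1 (1/min) and the spillover fractions
estimated from the blood-pool phase (the generator's true value here is
0.3). The ground truth for this patient was rest MBF 1.19/1.01/0.78 and
MFR 3.33/2.93/3.35 for LAD/LCX/RCA — noiseless recovery is within ~2%.
`quantifyPet()` runs the water arm the same way, and

```r
diagnosticMetrics(list(tp = 7, fp = 12, fn = 5, tn = 66))
#> sensitivity 58.3, specificity 84.6, accuracy 81.1, ppv 36.8, npv 93.0
```

computes the diagnostic performance of any index test vs. reference 2×2
table in percent. `runPipeline()` drives a whole study directory
(simulate → quantify both arms → concordance report) end to end.

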