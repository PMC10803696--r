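# pbrpk

Physiologically based radiopharmacokinetic (PBRPK) modeling of
radiopharmaceutical therapy in R.

Radiopharmaceutical therapy injects a receptor-targeting ligand labeled
with a therapeutic radionuclide (here a Lu-177/PSMA-like system). The
dose delivered to the tumor and to organs at risk (kidneys, salivary
glands) is a nonlinear function of the injection, because labeled
("hot") and unlabeled ("cold") ligand compete for a finite receptor
pool. `pbrpk` is for modelers and physicists who want to simulate and
analyze these kinetics: it builds an organ-resolved compartmental ODE
model (~166 state variables over 20 organs) from a declarative
**reaction graph** — compartments holding multiple interacting species —
so that new interactions (e.g. plasma-albumin binding) are added as
reactions instead of duplicating the model.

On top of the simulator sit a dosimetry layer and the three analyses the
package exists for:

* **Hot/cold competition** — sweep injected hot and cold amounts over a
  grid of virtual patients (tumor volume × receptor density) and
  quantify receptor-saturation nonlinearity by the **iso-dose twist**:
  the angle between the orthogonal-regression line of each iso-dose
  contour (on range-standardized axes) and that of the lowest-dose
  contour.
* **Injection fractionation** — split the fixed totals (10 nmol hot,
  100 nmol cold) over n boluses separated by τ minutes and report the
  **maximum relative dose change**
  `MRDC = (Dose(n*, τ*) − Dose_single) / Dose_single`.
* **Albumin-binding affinity** — sweep the albumin dissociation constant
  K<sub>D</sub><sup>alb</sup> (20 log-spaced values, 5–10⁵ nmol/L, plus
  the binding-disabled baseline) and report the **blood residence time**
  `BRT = ∫A_vein dt / (λ_phys H₀)` and the **enhancement factor**
  `EF = [D_tum(K_D)/D_OAR(K_D)] / [D_tum(∞)/D_OAR(∞)]`.

Kinetics are mass-action/transport reactions integrated with a stiff
solver (analytic Jacobian, bolus events); dosimetry is self-dose
(`D = N_decays · Δ / m`) with an analytic decay tail beyond the
simulated horizon. Models round-trip through SBML Level 3 Version 2
core. The packaged physiology table is a synthetic population baseline
(standard adult reference physiology plus published PSMA-ligand kinetics
ranges) — see the methods vignette.

## Worked example

```r
library(pbrpk)

params  <- default_parameters()
patient <- make_virtual_patient(params, tumor_volume_ml = 20,
                                receptor_density = 40)
model   <- build_pbrpk_model(patient, model_options(albumin_enabled = FALSE))
model
#> <reaction_graph>
#>   compartments: 44
#>   species:      103
#>   reactions:    237
#>   parameters:   10

result <- simulate_model(model,
                         injection_schedule(hot_total = 10, cold_total = 100))
dose_report(result, organs = c("tumor", "kidneys", "salivary_glands"))
#> # A tibble: 3 × 4
#>   organ              tia mass_kg dose_gy
#>   <chr>            <dbl>   <dbl>   <dbl>
#> 1 tumor           0.0194  0.0208   13.3
#> 2 kidneys         0.0775  0.322     3.43
#> 3 salivary_glands 0.0251  0.0884    4.04

blood_residence_time(result)
#> [1] 21.01843
```

A single 10 nmol hot / 100 nmol cold bolus delivers about 13 Gy to a
20 mL tumor with 40 nmol/L receptor density, and 3–4 Gy to the organs at
risk; the activity resides in the blood for ~21 minutes on average
(clearance is fast when no albumin binding retains the ligand). The
`tia` column is the time-integrated activity in nmol of decays; `dose_gy
= tia × 6.022e14 decays/nmol × Δ / mass`.

Studies chain the same pieces over grids and return tidy tables:

```r
study <- run_albumin_study(scale_grid(study_spec("albumin"), 3))
study$brt        # blood residence time per affinity
study$ef         # enhancement factor vs kidneys and salivary glands
autoplot(study$ef)
```

`export_sbml(model, "model.xml")` / `import_sbml("model.xml")` exchange
the model with other SBML tools; `inst/cli/pbrpk.R` wraps the same
functions as a small command line (`validate`, `simulate`,
`export-sbml`, `import-sbml`, `study ... --scale`).

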