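---
title: "PBRPK modeling: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PBRPK modeling: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbrpk)
```

# The model

`pbrpk` simulates the whole-body kinetics of a radiolabeled ("hot") and an
unlabeled ("cold") receptor-targeting ligand — the setting of
radiopharmaceutical therapy with a Lu-177-labeled PSMA ligand — as a
physiologically based compartmental ODE system, and converts the resulting
time–activity curves into absorbed doses.

Rather than duplicating the whole organ network once per tracked molecular
species ("parallel tracks"), the model is expressed as a **reaction
graph**: compartments are containers holding any number of species, and
all kinetics are reactions over those species. Adding a new interaction —
for example plasma-protein binding — adds species and reactions, not a
copy of the model. The graph is the single source of truth: the ODE
right-hand side, the SBML export, the YAML config and all audits are
derived from it.

## Structure

Every organ contributes a vascular (plasma) and an interstitial
compartment; receptor-expressing organs (tumor, kidneys, salivary glands,
liver, spleen) add an intracellular compartment and a finite receptor
pool. Two plasma pools (arterial, venous) close the circulation:

* plasma flow: artery → organ vasculature → vein → artery, at the organ's
  plasma flow $Q_i$ (L/min), applied to every plasma-borne species;
* permeability exchange of free ligand between vasculature and
  interstitium, rate $PS_i \cdot C$ (L/min times concentration), written
  as two one-way transports so every rate is non-negative;
* reversible receptor binding in the interstitium,
  $L + R \rightleftharpoons LR$ with association rate $k_{on}$
  (L/(nmol·min)) and $k_{off} = k_{on} K_D$; hot and cold ligand compete
  for the same pool;
* internalization of the bound complex at $\lambda_{int}$ (1/min), which
  moves the ligand into the cell and returns the receptor to the free
  pool, keeping the receptor moiety conserved; intracellular ligand is
  released back to the interstitium at $\lambda_{rel}$;
* renal clearance of free vascular ligand from the kidneys into an
  explicit excreta compartment at the glomerular filtration rate (L/min),
  so that ligand is never destroyed, only relocated;
* physical decay hot → cold at $\lambda_{phys}$ in **every** compartment
  and every chemical state (free, receptor-bound, internalized,
  albumin-complexed). The decayed molecule stays in place and keeps
  competing for receptors; this is what makes the total ligand count an
  exact invariant.

State variables are **amounts in nmol**; rate laws divide by compartment
volumes where concentrations are needed. With amounts, the conservation
audits (ligand, albumin, receptor moieties) are exact sums, and the
stoichiometry matrix has integer entries whose left null space encodes
the conserved moieties — both are tested directly.

## Albumin extension

With albumin enabled, albumin circulates in all plasma compartments at
the physiological plasma concentration and binds hot and cold ligand 1:1
($k_{on}^{alb}$ fixed, $K_D^{alb}$ swept via
$k_{off}^{alb} = k_{on}^{alb} K_D^{alb}$). Three structural rules follow
the biology of a ~70 kDa carrier protein:

1. complexes are not filtered by the kidney;
2. complexes cannot bind receptors;
3. complexes and free albumin cross the vascular wall **only** in the
   tumor, whose vasculature is porous, using the same permeability
   coefficient as the free ligand (an upper bound for the leak).

$K_D^{alb} = \infty$ is a sentinel meaning "binding off": the albumin
species still circulate but no binding reactions are emitted, so the
ligand kinetics are bit-for-bit those of the albumin-free model. This
makes the enhancement-factor baseline exact rather than a large-$k_{off}$
approximation.

# Parameters

The packaged table (`pbrpk_parameter_file()`) is a **synthetic**
population parameter set: organ volumes, plasma flows and
vascular/interstitial fractions follow standard adult reference
physiology, and the binding kinetics follow published ranges for
Lu-177-PSMA-style small molecules. It is a plausible baseline, not a
patient dataset. Key defaults, all overridable through the YAML document
(units are declared per field and converted on load):

| parameter | default | unit | meaning |
|---|---|---|---|
| `lambda_phys` | 7.24e-5 | 1/min | Lu-177 decay (6.647 d half-life) |
| `k_on` / `K_D` | 0.1 / 2.3 | L/(nmol·min), nmol/L | receptor binding |
| `lambda_int` | 3e-3 | 1/min | internalization |
| `lambda_rel` | 2e-4 | 1/min | intracellular release |
| `GFR` | 0.11 | L/min | renal plasma clearance |
| `albumin_conc` | 6e5 | nmol/L | plasma albumin |
| `k_on_alb` | 1e-4 | L/(nmol·min) | albumin association |
| `K_D_alb` | Inf | nmol/L | albumin affinity (off) |

Two consistency conventions matter when editing the table. First, the
mobile phase everywhere in the model is **plasma**: flows are plasma
flows, the albumin concentration is a plasma concentration, and the
vascular compartment volumes are plasma fractions of organ volume
(whole-blood vascular fraction times one minus hematocrit). Second,
receptor amounts are density (nmol per liter of tissue) times total organ
volume.

A **virtual patient** overrides the tumor volume (mL) and tumor receptor
density (nmol/L); tumor plasma flow and permeability scale proportionally
with volume. The studied ranges are 40–2100 mL and 10–890 nmol/L; values
outside warn but are allowed.

# Simulation

The graph compiles into $\dot{y} = L y + S_b r_b(y)$, where $L$ collects
every unimolecular and transport reaction into a constant matrix and
$r_b$ holds the (few dozen) bimolecular binding rates. Integration uses
`deSolve::lsoda` with the analytic Jacobian
$L + S_b \, \partial r_b/\partial y$; the rate constants span from
$k_{off}^{alb} \sim 10$/min to $\lambda_{phys} \sim 10^{-5}$/min over a
50,000-minute horizon, firmly stiff territory.

Multi-bolus injections are discontinuous additions to the venous free
hot/cold amounts at times $0, \tau, \dots, (n-1)\tau$, applied through
the integrator's event mechanism with a clean restart (the $t = 0$ bolus
is folded into the initial state). The totals are split equally across
boluses by default; the split rule is overridable per bolus since it is a
genuine modeling choice, not a physical constraint. At an event time the
reported row is the pre-bolus (left-limit) state.

Default tolerances are `rtol = 1e-8`, `atol = 1e-12` nmol, leaving two
orders of margin below the 1e-6 relative tolerance of the conservation
audits. Output values more negative than $10^3 \cdot$ `atol` abort the
run; smaller negatives are integrator noise and are clamped to zero. The
default output grid is minute-resolved over the first hour and
log-spaced out to `t_end` (about 460 points), which bounds the
trapezoidal error of the dose integrals well below the 0.1% convergence
criterion.

# Dosimetry

The activity assigned to an organ is $\lambda_{phys}$ times its total
hot-moiety amount — free, bound, internalized and albumin-complexed —
carried in nmol/min. Time-integrated activity (TIA) is the trapezoidal
integral over $[0, t_{end}]$ plus, by default, an analytic tail
$A(t_{end})/\lambda_{phys}$ that assumes pure physical decay beyond the
horizon; 50,000 min is 5.2 half-lives, so the tail is small but not
negligible. Absorbed dose uses local deposition only:
$D = N_{decays} \, \Delta / m$ with $\Delta$ the mean energy per decay
(Lu-177 beta plus conversion electrons, 2.369e-14 J) and
$m$ the organ's compartment volume times 1.04 kg/L. Because dose and TIA
differ per organ by a fixed constant, every ratio-based metric below is
independent of $\Delta$, the density, and the activity unit.

Blood residence time is the venous TIA divided by the injected activity
$\lambda_{phys} H_0$; the activity unit cancels.

# The three summary metrics

**Iso-dose twist.** Over a grid of (injected hot, injected cold)
amounts, iso-dose contours are extracted by marching squares
(`grDevices::contourLines`, linear interpolation on cell edges; the
longest polyline per level is kept). Both axes are standardized by their
sweep ranges before a line is fitted — without this the "angle" would
depend on the units and spans of the axes — and the fit is orthogonal
(total least squares, via the principal direction), because neither axis
is a response variable. Twist of a level is the absolute angle to the
lowest usable level's line, folded into [0°, 90°]. Contour levels default
to the nine interior deciles of the grid's dose range. These three
choices (standardization, orthogonal fit, decile levels) are declared
package conventions; vertical contours (90°) mean no hot/cold
competition, and twist grows only when receptors saturate.

**MRDC.** Over the $(n, \tau)$ schedule sweep with fixed totals, the
maximum relative dose change is
$(\max_i D(n_i, \tau_i) - D_{single}) / D_{single}$, ties broken toward
the smallest $n$ then the smallest $\tau$. The single bolus is part of
the searched set, so MRDC is never negative. The sweep's "injection
coefficient" axis is carried as an inert label in the study
specification: it parameterizes nothing in the kinetics and is
deliberately not interpreted.

**Enhancement factor.** For the albumin sweep,
$EF(K_D^{alb}) = \frac{D_{tum}(K_D^{alb})/D_{OAR}(K_D^{alb})}
{D_{tum}(\infty)/D_{OAR}(\infty)}$, computed against both kidneys and
salivary glands since the anchor organ is a genuine choice. $EF$ is
exactly 1 at the sentinel baseline.

# Study pipelines and problem sizes

The three studies iterate deterministic grids (no randomness anywhere, so
identical specifications give bit-identical tables): hot 5–100 nmol and
cold 25–800 nmol (10 linear samples each), tumor density 10–890 nmol/L
and volume 40–2100 mL (10 each) for the competition study; $n$ = 1–10,
$\tau \in \{10, 50, 100, 200, 300, 400, 500, 750, 1000\}$ min at fixed
10 nmol hot / 100 nmol cold for the fractionation study; 20
logarithmically spaced $K_D^{alb}$ values in 5–1e5 nmol/L plus the
$\infty$ baseline for the albumin study (the wider 5–1e6 range is
available by overriding `kd_values`). The full competition factorial is
10,000 simulations; `scale_grid()` subsamples every axis (keeping
endpoints) for desk-scale work. The shipped tests exercise 3–4 points
per axis — roughly 50–250 simulations per study — which is enough to
resolve every monotone trend and the three-region albumin pattern, while
keeping a full test run in minutes on one CPU. The albumin sweep is run
at its full 20-point grid even in tests because the intermediate region
(tumor dose still rising while the organ-at-risk dose falls) spans only a
factor of ~3 in $K_D^{alb}$ and vanishes on coarser grids.

# What the simulations do and do not show

The synthetic baseline reproduces the mechanism-level phenomenology:
receptor saturation tilting iso-dose curves, the tumor sink effect
(large tumors depressing organ-at-risk uptake and saturation),
fractionation helping most at low receptor density, albumin binding
extending blood residence and differentially favoring the tumor through
interstitial leakage. Absolute organ doses land in a clinically plausible
range (tumor ~13 Gy, kidneys ~3.4 Gy for 10 nmol hot), but they are
properties of the synthetic table, not predictions for any patient:
population-calibrated or fitted parameters, partial-volume organ
sub-structure, cross-organ dose (the model is self-dose only) and any
radiobiological cell-kill modeling are all outside scope. One observed
consequence of the synthetic parameterization worth flagging: the
kidney-anchored enhancement factor dips slightly below its baseline in
the weak-affinity band (minimum ≈ 0.73) before rising above 1 at strong
affinity, because the kidneys' comparatively large plasma pool benefits
from the longer blood residence earlier than the tumor does; the
salivary-gland-anchored EF is monotone throughout.

# Numerical and degenerate-input conventions

* Bidirectional transport is two one-way reactions; all rates are
  non-negative at non-negative states (property-tested).
* Bimolecular mass action references exactly one reaction volume; orders
  above two are rejected.
* Sources and sinks exist only as tagged injection/clearance reactions so
  conservation audits can reason about them; the renal route keeps an
  explicit excreta compartment.
* A schedule whose last bolus falls at or after `t_end` is an error, as
  are non-positive tolerances, volumes or masses.
* Iso-dose levels outside the grid's dose range are skipped with a
  warning rather than an error, so decile defaults remain usable on flat
  surfaces.
* SBML export writes amounts (`hasOnlySubstanceUnits`), explicit
  kinetic-law MathML in a canonical product form, and deterministic
  insertion order, making export → import → export byte-stable. Rules,
  constraints, function definitions and delays are rejected by name on
  import; foreign core documents without this package's annotations are
  imported with neutral metadata (kinetics preserved; organ labels and
  species kinds default conservatively).
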