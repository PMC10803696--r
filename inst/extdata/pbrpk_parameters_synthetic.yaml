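# Synthetic population physiology and Lu-177/PSMA-ligand kinetics table.
#
# SYNTHETIC stand-in: values are assembled from standard adult-human
# reference physiology (organ volumes, plasma flows, vascular/interstitial fractions) and published ranges for PSMA-ligand binding kinetics; they
# are plausible population values for a ~70 kg adult, not a copy of any
# patient dataset. Units are declared explicitly and converted on load.
meta:
  name: synthetic_adult_lu177_psma
  description: >
    Whole-body parameter set for a Lu-177-labeled PSMA-targeting
    small-molecule ligand in a reference adult, used as the default
    virtual-patient baseline.

global:
  lambda_phys: {value: 7.2416e-5, unit: 1/min}   # ln(2) / 6.647 d half-life
  k_on:        {value: 0.1,       unit: L/(nmol*min)}
  K_D:         {value: 2.3,       unit: nmol/L}
  lambda_int:  {value: 0.003,     unit: 1/min}   # receptor-mediated internalization
  lambda_rel:  {value: 2.0e-4,    unit: 1/min}   # intracellular release/degradation
  GFR:         {value: 0.11,      unit: L/min}   # glomerular filtration (plasma)
  albumin_conc: {value: 6.0e5,    unit: nmol/L}  # plasma albumin concentration
  k_on_alb:    {value: 1.0e-4,    unit: L/(nmol*min)}
  K_D_alb:     {value: .inf,      unit: nmol/L}  # infinity = albumin binding off

dosimetry:
  mean_energy_per_decay: {value: 2.369e-14, unit: J}  # Lu-177 mean beta + ce energy
  tissue_density:        {value: 1.04,      unit: kg/L}

blood:
  arterial_volume: {value: 0.9, unit: L}   # arterial plasma pool
  venous_volume:   {value: 2.0, unit: L}   # venous plasma pool

# Declared units for the organ table columns (converted on load).
organ_units:
  volume: L
  vascular_fraction: dimensionless
  interstitial_fraction: dimensionless
  plasma_flow: L/min
  receptor_density: nmol/L
  permeability: L/min

organs:
  - {name: kidneys,         volume: 0.31,  vascular_fraction: 0.088, interstitial_fraction: 0.20, plasma_flow: 0.60,  receptor_density: 15, permeability: 0.20}
  - {name: salivary_glands, volume: 0.085, vascular_fraction: 0.033, interstitial_fraction: 0.22, plasma_flow: 0.02,  receptor_density: 14, permeability: 0.008}
  - {name: liver,           volume: 1.80,  vascular_fraction: 0.115, interstitial_fraction: 0.16, plasma_flow: 0.50,  receptor_density: 2,  permeability: 0.25}
  - {name: spleen,          volume: 0.18,  vascular_fraction: 0.154, interstitial_fraction: 0.15, plasma_flow: 0.06,  receptor_density: 5,  permeability: 0.03}
  - {name: lungs,           volume: 1.00,  vascular_fraction: 0.099, interstitial_fraction: 0.19, plasma_flow: 0.10,  receptor_density: 0,  permeability: 0.03}
  - {name: red_marrow,      volume: 1.10,  vascular_fraction: 0.055, interstitial_fraction: 0.15, plasma_flow: 0.10,  receptor_density: 0,  permeability: 0.05}
  - {name: bone,            volume: 5.00,  vascular_fraction: 0.022, interstitial_fraction: 0.10, plasma_flow: 0.07,  receptor_density: 0,  permeability: 0.02}
  - {name: muscle,          volume: 29.0,  vascular_fraction: 0.017, interstitial_fraction: 0.12, plasma_flow: 0.35,  receptor_density: 0,  permeability: 0.10}
  - {name: adipose,         volume: 13.0,  vascular_fraction: 0.011, interstitial_fraction: 0.14, plasma_flow: 0.15,  receptor_density: 0,  permeability: 0.05}
  - {name: skin,            volume: 3.30,  vascular_fraction: 0.017, interstitial_fraction: 0.30, plasma_flow: 0.10,  receptor_density: 0,  permeability: 0.04}
  - {name: heart,           volume: 0.33,  vascular_fraction: 0.077, interstitial_fraction: 0.14, plasma_flow: 0.08,  receptor_density: 0,  permeability: 0.03}
  - {name: gut,             volume: 1.20,  vascular_fraction: 0.044, interstitial_fraction: 0.19, plasma_flow: 0.45,  receptor_density: 0,  permeability: 0.15}
  - {name: brain,           volume: 1.45,  vascular_fraction: 0.022, interstitial_fraction: 0.05, plasma_flow: 0.35,  receptor_density: 0,  permeability: 1.0e-6}
  - {name: pancreas,        volume: 0.14,  vascular_fraction: 0.033, interstitial_fraction: 0.18, plasma_flow: 0.03,  receptor_density: 0,  permeability: 0.01}
  - {name: thyroid,         volume: 0.02,  vascular_fraction: 0.055, interstitial_fraction: 0.15, plasma_flow: 0.04,  receptor_density: 0,  permeability: 0.01}
  - {name: prostate,        volume: 0.016, vascular_fraction: 0.022, interstitial_fraction: 0.25, plasma_flow: 0.002, receptor_density: 0,  permeability: 0.001}
  - {name: rest_of_body,    volume: 3.00,  vascular_fraction: 0.022, interstitial_fraction: 0.18, plasma_flow: 0.12,  receptor_density: 0,  permeability: 0.05}
  # Tumor defaults correspond to a 20 mL lesion at 40 nmol/L receptor
  # density; virtual patients override volume and density, with flow and
  # permeability rescaled proportionally to volume.
  - {name: tumor,           volume: 0.02,  vascular_fraction: 0.039, interstitial_fraction: 0.35, plasma_flow: 0.0012, receptor_density: 40, permeability: 0.0024}
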