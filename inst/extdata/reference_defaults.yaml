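# Default reference configuration for pterisk.
#
# Every value here is a conventional, replaceable default:
#   screening   - surface water: Class III-style surface-water quality limits
#                 (ug/L); soil: farmland screening / regional background-style
#                 values (mg/kg); crop: food contaminant-style limits (mg/kg
#                 dry weight). Crops carry no limits for Mo and V (no unified
#                 assessment criteria), so those elements are skipped in crop
#                 index calculations.
#   toxicity    - Hakanson toxicity response coefficients (dimensionless);
#                 Sb, Mo, V from the wider literature.
#   rfd         - reference doses, mg/kg/day, per exposure pathway.
#   slope       - cancer slope factors, (mg/kg/day)^-1; absent entries mean
#                 the element/pathway is not treated as carcinogenic.
#   exposure    - per-population exposure parameter distributions. The
#                 deterministic model uses each distribution's central value
#                 (point value / mean). Lognormal entries are moment-matched:
#                 meanlog = ln(mean) - sdlog^2/2.
#
# Units: r_ing_soil mg/day; r_ing_water L/day; r_inh m3/day; ef days/year;
# ed years; bw kg; sa cm2; af mg/cm2/day; abs fraction; kp cm/h; et h/day;
# pef m3/kg.

screening:
  surface_water: {Pb: 50, Cr: 50, Ni: 20, Cu: 1000, Zn: 1000, As: 50, Mo: 70, Cd: 5, Sb: 5, V: 50}
  soil: {Pb: 90, Cr: 200, Ni: 100, Cu: 100, Zn: 250, As: 30, Mo: 0.4, Cd: 0.3, Sb: 1.0, V: 130}
  crop: {Pb: 0.3, Cr: 0.5, Ni: 0.4, Cu: 10, Zn: 20, As: 0.5, Cd: 0.05, Sb: 1.0}

toxicity: {Zn: 1, Cr: 2, Cu: 5, Ni: 5, Pb: 5, As: 10, Cd: 30, Sb: 7, Mo: 5, V: 2}

rfd:
  Pb: {ingestion: 3.5e-3, dermal: 5.25e-4, inhalation: 3.52e-3}
  Cr: {ingestion: 3.0e-3, dermal: 6.0e-5, inhalation: 2.86e-5}
  Ni: {ingestion: 2.0e-2, dermal: 5.4e-3, inhalation: 2.06e-2}
  Cu: {ingestion: 4.0e-2, dermal: 1.2e-2, inhalation: 4.02e-2}
  Zn: {ingestion: 3.0e-1, dermal: 6.0e-2, inhalation: 3.0e-1}
  As: {ingestion: 3.0e-4, dermal: 1.23e-4, inhalation: 3.01e-4}
  Mo: {ingestion: 5.0e-3, dermal: 1.9e-3, inhalation: 5.0e-3}
  Cd: {ingestion: 1.0e-3, dermal: 2.5e-5, inhalation: 1.0e-3}
  Sb: {ingestion: 4.0e-4, dermal: 8.0e-6, inhalation: 4.0e-4}
  V:  {ingestion: 7.0e-3, dermal: 7.0e-5, inhalation: 7.0e-3}

slope:
  Cr: {ingestion: 0.5, inhalation: 42.0}
  Ni: {ingestion: 1.7, inhalation: 0.84}
  As: {ingestion: 1.5, dermal: 3.66, inhalation: 15.1}
  Cd: {ingestion: 6.1, inhalation: 6.3}
  Pb: {ingestion: 8.5e-3}

abs_override: {As: 0.03}

unit_factor: {surface_water: 1.0e-3, soil: 1.0e-6, crop: 1.0e-6}

exposure:
  child:
    r_ing_soil:  {kind: lognormal, meanlog: 5.186748, sdlog: 0.472381, lower: 0}   # mean 200
    r_ing_water: {kind: lognormal, meanlog: -0.399760, sdlog: 0.293560, lower: 0}  # mean 0.7
    r_inh: 7.5
    ef: {kind: uniform, min: 335, max: 365}    # central 350
    ed: 6
    bw: {kind: normal, mean: 15, sd: 2.3, lower: 0}
    sa: {kind: normal, mean: 2800, sd: 420, lower: 0}
    af: {kind: lognormal, meanlog: -1.763183, sdlog: 0.554513, lower: 0}           # mean 0.2
    abs: 0.001
    kp: 0.001
    et: 0.5
    pef: 1.36e+9
  adult:
    r_ing_soil:  {kind: lognormal, meanlog: 4.493601, sdlog: 0.472381, lower: 0}   # mean 100
    r_ing_water: {kind: lognormal, meanlog: 0.650061, sdlog: 0.293560, lower: 0}   # mean 2.0
    r_inh: 14.5
    ef: {kind: uniform, min: 335, max: 365}
    ed: 24
    bw: {kind: normal, mean: 60, sd: 9, lower: 0}
    sa: {kind: normal, mean: 5700, sd: 855, lower: 0}
    af: {kind: lognormal, meanlog: -2.813001, sdlog: 0.554513, lower: 0}           # mean 0.07
    abs: 0.001
    kp: 0.001
    et: 0.3
    pef: 1.36e+9
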