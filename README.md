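# pterisk

Source-oriented probabilistic health risk assessment of potentially toxic
elements (PTEs) in the water–soil–crop system.

`pterisk` is for environmental scientists assessing heavy-metal/metalloid
contamination around mining and agricultural areas. Given site-by-element
concentration tables for surface water (μg/L), agricultural soil and crops
(mg/kg dry weight), it answers four questions:

1. **How polluted is each sample?** Single pollution index PIᵢ = Cᵢ/Sᵢ
   against a screening/background value Sᵢ, the Nemerow comprehensive index
   NI = √((PI²max + PI²mean)/2), and the Hakanson potential ecological risk
   indices EIᵢ = PIᵢ·Tᵢr and PERI = Σ EIᵢ, each with its standard category
   scheme (safe/alert/slight/moderate/severe; low → extremely high).
2. **What does it mean for people?** A USEPA-style exposure model computes
   average daily intakes per pathway —
   ADIing = C·Ring·EF·ED/(BW·AT)·10⁻⁶,
   ADIder = C·SA·AF·ABS·EF·ED/(BW·AT)·10⁻⁶,
   ADIinh = C·Rinh·EF·ED/(PEF·BW·AT) —
   and aggregates them into the non-carcinogenic risk index
   NRI = Σ ADIᵢⱼ/RfDᵢⱼ (threshold 1) and the carcinogenic risk index
   CRI = Σ ADIᵢⱼ·SFᵢⱼ (threshold 1×10⁻⁴) for children and adults.
3. **How uncertain is that?** A Monte Carlo engine samples the exposure
   parameters from configurable distributions (10,000 iterations per site by
   default), yields risk distributions, exceedance probabilities
   P(NRI > 1) and P(CRI > 10⁻⁴), and a Spearman rank-correlation sensitivity
   analysis with signed percent contributions per parameter.
4. **Where does the risk come from?** Correlation-matrix PCA with Kaiser
   retention (eigenvalue > 1) and varimax rotation identifies pollution
   sources; squared rotated loadings give the element-to-source contribution
   matrix M (rows sum to 1), which is coupled to element-level risk shares
   NPᵢ, CPᵢ through NQₖ = Σᵢ Mᵢₖ·NPᵢ and CQₖ = Σᵢ Mᵢₖ·CPᵢ — the percent of
   the health risk attributable to each source.

A synthetic-data module generates tables with known source structure
(gamma-distributed site mixing × source signatures × lognormal noise) and
lognormal tables moment-matched to published mean/SD targets, so the entire
pipeline is testable end-to-end with no external data.

## Worked example

Simulate a 100-site soil survey from the three-source preset (geogenic,
mining, agriculture), then run the full analysis:

```r
library(pterisk)
refs <- default_reference_bundle()
gen  <- generate_mixture(preset_profiles("soil_3source"), n_sites = 100,
                         noise_cv = 20, seed = 42, medium = "soil")
soil <- gen$samples

idx <- pollution_indices(soil, refs)
category_shares(idx$ni_category, "NI")
#>   category count percent
#> 1     safe     0       0
#> 2    alert     0       0
#> 3   slight     4       4
#> 4 moderate     9       9
#> 5   severe    87      87
```

87% of the simulated sites fall in the severe Nemerow category — driven by
the mining signature's antimony, whose soil screening value (1 mg/kg) is far
below the mining source strength. The probabilistic risk for children:

```r
mc <- mc_assess(soil, refs, "child", n_iter = 10000, seed = 42)
mc$sites[[1]]
#> <mc_result> 10000 iterations
#>  NRI mean 1.03 (P95 1.95), P(NRI > 1) = 0.435
#>  CRI mean 4.79e-05 (P95 9.41e-05), P(CRI > 1e-4) = 0.038
```

At this site a child's simulated hazard index exceeds 1 in 43.5% of
iterations, while the cancer-risk threshold 10⁻⁴ is exceeded in 3.8%.
Source apportionment recovers the three generating sources:

```r
model <- pca_kaiser(standardize(soil$values))
model
#> <source_model> 3 retained component(s) (varimax), 86.4% variance
#>       PC1    PC2    PC3
#> Pb  0.918 -0.009  0.074
#> ...
profile_recovery(model, gen$truth)
#>        source component    cosine
#> 1    geogenic       PC2 0.9905205
#> 2      mining       PC1 0.9985208
#> 3 agriculture       PC3 0.9699844
```

and the source-to-risk attribution shows which source drives which risk:

```r
M <- element_source_contributions(model)
shares <- element_risk_shares(assess_risk(soil, refs, "child"))
source_risk_contributions(M, shares)
#>   source nq_percent cq_percent
#> 1    PC1   56.64069   6.265534
#> 2    PC2   17.89172  69.895150
#> 3    PC3   25.46759  23.839315
```

The mining component (PC1) contributes 57% of the non-carcinogenic risk
(antimony's low reference dose), while the geogenic component (PC2, Cr–Ni–V)
contributes 70% of the carcinogenic risk through the Cr and Ni slope
factors. Both columns sum to 100 by construction.

`run_pipeline()` chains all stages per medium and writes deterministic
CSV/JSON outputs plus a manifest.

## Configuration

Screening values, toxicity coefficients, reference doses, slope factors and
exposure-parameter distributions live in one YAML file; the shipped default
(`inst/extdata/reference_defaults.yaml`) documents the schema and is loaded
by `default_reference_bundle()`. Every value is a conventional, clearly
replaceable default — supply your own file through
`read_reference_bundle()` for regulatory work.
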