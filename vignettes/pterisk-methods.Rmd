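---
title: "Methods: source-oriented probabilistic risk assessment of PTEs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: source-oriented probabilistic risk assessment of PTEs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pterisk)
```

`pterisk` implements a complete source-oriented risk assessment for
potentially toxic elements (PTEs) across surface water, agricultural soil
and crops: pollution and ecological indices, a deterministic and a
probabilistic (Monte Carlo) USEPA-style exposure model, PCA source
apportionment, and the coupling of the two into per-source risk
contributions. This vignette documents the models, the choices that were
genuinely open, and what the synthetic tests do and do not demonstrate.

## Pollution and ecological indices

For element $i$ with measured concentration $C_i$ and screening/background
value $S_i$ (same units as the medium), the single pollution index is
$PI_i = C_i/S_i$. The Nemerow comprehensive index of a sample combines the
worst and the average element,

$$NI = \sqrt{\frac{PI_{\max}^2 + PI_{\mathrm{mean}}^2}{2}},$$

and always satisfies $PI_{\mathrm{mean}} \le NI \le PI_{\max}$ (a tested
invariant). The Hakanson indices weight pollution by toxicity:
$EI_i = PI_i \cdot T_r^i$ and $PERI = \sum_i EI_i$, with toxicity response
coefficients $T_r$ of Zn 1, Cr 2, Cu/Ni/Pb 5, As 10, Cd 30 and literature
values for Sb (7), Mo (5) and V (2).

Two conventions needed fixing because the printed category schemes overlap
at their interval endpoints:

* **Boundary assignment.** PI/NI intervals are read left-open/right-closed
  (PI = 1 is "safe", PI = 2 is "alert"); EI/PERI intervals are
  left-closed/right-open (EI = 40 is "moderate"), consistent with their
  top classes being printed with "≥" and bottom classes with "<".
* **Element sets.** Indices run over every element with a screening value
  for the medium. The shipped crop configuration deliberately omits Mo and V
  (no unified contamination criteria for crops), so they drop out of crop
  indices through data, not code.

Descriptive statistics use the sample SD ($n-1$) and the adjusted
Fisher–Pearson skewness (`e1071::skewness(type = 2)`, the spreadsheet
convention). The display CV is rounded to the nearest integer percent, half
away from zero; full precision is kept internally.

## Exposure model

Average daily intakes (mg·kg⁻¹·day⁻¹) for ingestion, dermal contact and
inhalation follow the standard forms

$$ADI_{ing} = \frac{C \cdot R_{ing} \cdot EF \cdot ED}{BW \cdot AT}\times u,\quad
ADI_{der} = \frac{C \cdot SA \cdot AF \cdot ABS \cdot EF \cdot ED}{BW \cdot AT}\times u,\quad
ADI_{inh} = \frac{C \cdot R_{inh} \cdot EF \cdot ED}{PEF \cdot BW \cdot AT},$$

with the mass-conversion factor $u = 10^{-6}$ for mg/kg media. Risk indices
are $NRI = \sum_{i,j} ADI_{i,j}/RfD_{i,j}$ (concern threshold 1) and
$CRI = \sum_{i,j} ADI_{i,j}\cdot SF_{i,j}$ (threshold $10^{-4}$), summed
over elements $i$ and pathways $j$. Elements without a slope factor
contribute only to NRI and stay *absent* (`NA`), never zero-filled, in the
carcinogenic table. The averaging time is $ED\times365$ days for NRI and a
70-year lifetime for CRI.

Default exposure parameters (all overridable in the YAML configuration;
units in the file):

| parameter | child | adult | role |
|---|---|---|---|
| soil ingestion rate $R_{ing}$ | 200 mg/d | 100 mg/d | ingestion |
| water intake | 0.7 L/d | 2 L/d | ingestion (water) |
| inhalation rate $R_{inh}$ | 7.5 m³/d | 14.5 m³/d | inhalation |
| exposure frequency $EF$ | 350 d/y | 350 d/y | all |
| exposure duration $ED$ | 6 y | 24 y | all |
| body weight $BW$ | 15 kg | 60 kg | all (inverse) |
| skin area $SA$ | 2800 cm² | 5700 cm² | dermal |
| adherence $AF$ | 0.2 | 0.07 mg/cm²·d | dermal (soil) |
| absorption $ABS$ | 0.001 (As 0.03) | same | dermal (soil) |
| emission factor $PEF$ | 1.36×10⁹ m³/kg | same | inhalation |

**Water pathways.** The water analogue of the intake equations is not
standardised in the index literature, so the package fixes it explicitly:
ingestion uses drinking-water intake with C converted μg/L → mg/L;
the dermal equation keeps its multiplicative form with the
adherence×absorption product replaced by an aqueous slot
$K_p \cdot ET \cdot CF$ (permeability 0.001 cm/h, exposure time 0.5 h/d
child / 0.3 h/d adult, $CF = 10^{-3}$ L/cm³); inhalation is disabled for
water because no airborne-particulate term is meaningful there.

**Reference values.** The shipped screening values, $T_r$ for Sb/Mo/V,
RfD/SF table and exposure distributions are conventional literature values,
chosen once and labelled replaceable. They were selected so the qualitative
structure a practitioner expects holds under the defaults: children carry
higher risk than adults at identical concentrations, ingestion > dermal >
inhalation, and Ni (ingestion SF 1.7) dominates the soil CRI. Lead is
treated through its RfD/SF like every other element (no blood-lead
modelling).

## Monte Carlo engine

Uncertainty is propagated by sampling the exposure parameters (not the
concentrations) from per-population distribution specs — point, normal,
lognormal, uniform or triangular, with optional truncation enforced by
rejection. 10,000 iterations per site is the default. Lognormal specs are
moment-matched so their mean equals the deterministic central value;
consequently, with all parameters at point masses every Monte Carlo sample
equals the deterministic result (a tested identity, exact up to
floating-point reassociation), and with one uniformly varied parameter the
Monte Carlo mean converges to the deterministic value at the parameter mean
(asserted within 3 standard errors at $n = 10{,}000$).

Because the risk total is linear in the per-pathway kernels
$k_j(t) = f_j(\text{parameters}_t)$, each site's 10,000 iterations reduce to
three vector products — the full 500-site × 10,000-iteration default study
runs in seconds on one CPU.

Design choices:

* **Seeding.** Each (site, population) run gets its own seed derived from
  the master seed by a stable string hash, so per-site results are
  independent of execution order and fully reproducible.
* **Exceedance.** Fractions use strict inequality against the thresholds
  (1 and $10^{-4}$). Basin-level probabilities pool all iterations across
  sites with equal weight; per-site probabilities are also reported, since
  either aggregation is defensible.
* **Sensitivity.** Spearman rank correlation $\rho_p$ between each
  parameter's draws and the output, reported as signed shares
  $\mathrm{sign}(\rho_p)\cdot100\,\rho_p^2/\sum_q \rho_q^2$. Constant
  parameters get 0; absolute shares sum to 100; the measure is invariant to
  monotone rescaling of the output. Standardised regression coefficients
  would be a reasonable alternative; rank correlation was chosen for
  robustness to the model's multiplicative nonlinearity. Body weight, the
  only denominator parameter, always carries a negative share.
* **Independence.** Parameters are sampled independently; no correlation
  structure is imposed.

## Source apportionment

PCA runs on the correlation matrix (columns standardised to mean 0, SD 1,
$n-1$ convention) because element scales span five orders of magnitude.
Components with eigenvalue strictly greater than 1 are retained (Kaiser);
retained loadings are varimax-rotated and sign-normalised so each
component's largest-magnitude loading is positive. Varimax is applied even
though a rotation is not strictly required, because interpretable source
loadings presuppose one; `rotation = "none"` is available. Rotation
preserves communalities and the retained subspace (tested).

The element-to-source contribution matrix normalises squared rotated
loadings per element:

$$M_{i,k} = \frac{L_{i,k}^2}{\sum_{k'} L_{i,k'}^2},$$

so each row sums to 1 and M is invariant to sign conventions and component
order. Squared-loading normalisation is an explicit, swappable
interpretation — it is the simplest construction that guarantees the
source-risk decomposition below sums to 100%. APCS-style regression would
be the natural upgrade where absolute (not relative) source contributions
are needed.

## Source-to-risk coupling

Element risk shares aggregate risk over sites and pathways *before*
normalising ($NP_i$ = element $i$'s share of the summed NRI; $CP_i$
analogous for CRI over elements with slope factors), because the coupling
equations take a single share vector. Then

$$NQ_k = \sum_i M_{i,k}\,NP_i, \qquad CQ_k = \sum_i M_{i,k}\,CP_i,$$

reported as percents; conservation ($\sum_k NQ_k = \sum_k CQ_k = 100$) is
an algebraic identity given row-normalised M and normalised shares, and is
asserted, not assumed. Shares default to the child population. They are
computed from deterministic risks: with parameters sampled independently
and distribution means equal to the central values, per-element mean
simulated risks are proportional to the deterministic ones (up to small
truncation effects), so the shares agree while the deterministic route is
exactly reproducible.

## Synthetic data: what it emulates and what it does not

`generate_mixture()` builds $C_{s,i} = (\sum_k a_{s,k}\,\sigma_{k,i})
\,\varepsilon_{s,i}$: gamma-distributed site mixing coefficients (mean 1,
shape 4 → CV 50%, right-skewed and non-negative), fixed source signatures
$\sigma$, and multiplicative lognormal noise with unit median and stated CV.
Lognormal noise was chosen over additive Gaussian because observed
concentration tables in mining basins show strong right skew and CVs above
100% on positive support. The presets encode the source structure typical
of such basins — soil: geogenic (Cr, Ni, V), mining (Pb, Zn, Mo, Cd, Sb),
agriculture (Cu, As); water: four mining/geogenic components; crops: two —
with signature magnitudes on the scale of the shipped summary-statistic
targets.

`simulate_from_moments()` targets marginal moments only, drawing each
element from a lognormal with $\mu = \ln(m^2/\sqrt{m^2+s^2})$,
$\sigma^2 = \ln(1+s^2/m^2)$ (formulas verified against numerical
quadrature). Two caveats are documented deliberately:

* For heavy-tailed targets (CV near 300%) the *sample* SD at $n = 10{,}000$
  still carries ~40% relative sampling error — a property of the estimator,
  not of the generator — so fidelity for such rows is asserted on the log
  scale, where the fit is exact.
* Per-element independence is intentional; correlation structure belongs to
  `generate_mixture()`.

**Recovery metric.** Rotated loadings are correlations, i.e. they live in a
space where every element has unit variance, so `profile_recovery()`
re-expresses each truth signature as per-element source *shares*
($\sigma_{k,i}/\sum_{k'}\sigma_{k',i}$) before cosine matching. Under the
standing fixture (soil preset, 500 sites, 20% noise) Kaiser retention finds
exactly 3 components and every source matches a distinct component with
cosine ≥ 0.99.

**What passing tests show.** Synthetic recovery demonstrates that the
pipeline's statistics are implemented correctly and that the PCA/attribution
machinery identifies well-separated sources under realistic noise. It does
not show that real basins decompose this cleanly: field data carry spatial
autocorrelation, censored values, source collinearity and medium-specific
measurement error that the generator intentionally omits.

## Numerical and interface choices

* Problem sizes: the default study uses 500 synthetic sites, 10,000 Monte
  Carlo iterations per site, and the full ten-element set — comfortably
  interactive on a single core.
* Below-detection cells substitute DL/2 (configurable to 0 or DL); the
  substitution is idempotent and never exceeds the detection limit, and
  writers emit `<DL` markers so tables round-trip exactly.
* Degenerate inputs fail loudly and early: constant columns in PCA, missing
  reference doses, zero screening values, truncation bounds excluding all
  mass, single-site descriptive statistics.
* Human-readable CSVs are written with 6 significant digits; full-precision
  values go to JSON sidecars. Re-running a pipeline with identical
  configuration reproduces outputs bit-identically.
* The orchestration surface is `run_pipeline()` plus the exported stage
  functions; the package targets interactive R use rather than a shell
  executable.

## Known limitations

* No crop dietary-intake (consumption) exposure route; risk covers water
  and soil contact pathways only.
* No PMF/UNMIX/APCS-MLR receptor models; PCA with varimax is the single
  apportionment engine.
* No uncertainty intervals on the source contributions NQ/CQ (point values
  only), and no 2-D Monte Carlo separating variability from uncertainty.
* No spatial statistics: site identifiers are opaque; mapping and
  interpolation are out of scope.
* The shipped reference values are stand-in conventions, not a regulatory
  table; real assessments must supply jurisdictionally correct values.
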