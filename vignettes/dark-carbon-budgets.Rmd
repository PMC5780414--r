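---
title: "Dark carbon budgets: models, conversions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dark carbon budgets: models, conversions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(darkcarbon)
```

`darkcarbon` implements the rate calculus of deep-water (aphotic, ≥ 200 m)
microbial carbon budgets: radiotracer incubations to volumetric rates,
ETS assays to respiration, depth integration, and the derived community
metrics. This vignette is the package's account of the science behind each
step, the parameters that matter, and the choices made where the
methodology leaves room.

## The three rate conversions

**Heterotrophic production (PHP).** Saturating [³H]-leucine (20 nmol L⁻¹,
specific activity 144.2 Ci mmol⁻¹) is incorporated into protein during a
short dark incubation (2.5 h, 1.7 mL in the micro-method geometry). Net
DPM (live replicates minus killed blanks) divide by 2.22 × 10¹² DPM Ci⁻¹
and by the specific activity to give moles of leucine, which normalise by
volume and time and scale to carbon:

$$\mathrm{PHP} = \frac{\mathrm{DPM_{net}}}
{2.22\times10^{12}\,\mathrm{DPM\,Ci^{-1}} \cdot SA}
\cdot \frac{1}{V\,t} \cdot \mathrm{CF}, \qquad
\mathrm{CF} = 1.5\ \mathrm{kg\,C\,mol^{-1}} \times \mathrm{ID}.$$

The base factor 1.5 kg C mol⁻¹ is the theoretical leucine-to-protein-carbon
ratio; the isotope dilution ID inflates it for the unlabelled ambient
leucine pool. The deep-water mean ID of 1.28 yields the working factor of
1.92 kg C mol⁻¹ leu. The base is a named constant
(`abd_constants()$leu_to_carbon_base`), defined as the working factor over
the mean ID, since only their product is ever observable in this calculus.
No saturation correction is applied: 20 nmol L⁻¹ is treated as saturating,
which kinetic series in deep Mediterranean water support.

**Isotope dilution by the kinetic method.** `estimate_isotope_dilution()`
fits the linearisation in which incubation time over the fraction of added
label incorporated is linear in added unlabelled substrate:
$t/f = (K_t + S_n + \mathrm{hot} + A)/V_{max}$. The published method has
variants; the implemented definition is fixed as
$\mathrm{ID} = (K_t+S_n+\mathrm{hot})/\mathrm{hot}$ = intercept/(slope ×
hot), exercised end-to-end through the forward simulator. A negative fitted
$K_t+S_n$ (possible under noise when the true ambient pool is near zero)
is clamped to zero with a warning, so ID ≥ 1 always — a dilution cannot
concentrate.

**Dark bicarbonate assimilation (ABD).** The 40 mL, 72 h bicarbonate
incubation adds 0.25 µCi mL⁻¹ at 56.0 mCi mmol⁻¹, i.e. 4.464 µmol L⁻¹ of
tracer against an ambient DIC pool of 2.19–2.47 mmol L⁻¹ — an isotope
dilution of 490.6–553.3. The rate is therefore computed as the *fraction*
of added activity fixed, multiplied by the full ambient pool:

$$\mathrm{ABD} = \frac{\mathrm{DPM_{net}}}{A_{added} V \cdot 2.22\times10^6}
\cdot \mathrm{DIC} \cdot 12\ \mathrm{\mu g\,\mu mol^{-1}} \cdot
\frac{10^3}{t_d} \cdot 10^3.$$

DIC is an input, never computed from pH/alkalinity (no carbonate-system
chemistry in this package). A record without DIC errors by default rather
than silently assuming the basin value; `require_dic = FALSE` opts into
the configurable default (2.3 mmol L⁻¹, mid-range for the deep
Mediterranean).

**Respiration (PR).** ETS assays measure potential respiratory activity at
the assay temperature. Conversion to in situ carbon respiration is a
three-factor chain: Arrhenius correction
$\exp\!\big(\tfrac{E_a}{R}(\tfrac{1}{T_{assay}} - \tfrac{1}{T_{insitu}})\big)$
with $E_a$ = 15.8 kcal mol⁻¹; the PR:ETS ratio 0.68 (a subtropical
mesopelagic calibration); and the Takahashi remineralization stoichiometry.
The O₂:C ratio is not stated numerically in the source methodology, so the
package defaults to the classical 122 mol C per 172 mol O₂ as a documented,
configurable constant. The assay temperature is likewise not a published
constant; `ets_measurement()` requires it explicitly per measurement rather
than assuming one (the simulator uses 18 °C as its own convention). All
raw tetrazolium chemistry (absorbance → O₂ equivalents) is upstream of the
package's contract: inputs are already O₂-rate units.

## Derived metrics and reporting conventions

PCD = PHP + PR; PGE = PHP/(PHP + PR); cell-specific rates divide a
volumetric rate by abundance (×10⁹ fg µg⁻¹ / ×10⁶ mL m⁻³, i.e. ÷ PA in
10³ cells mL⁻¹); ABD:PCD is reported in percent; generation times divide
the 10–20 fg C cell⁻¹ carbon-content range by csABD. "Not determined"
values are `NA` and propagate as `NA`, never as zeros. Report tables round
cell-specific columns to two decimals, which makes the regenerated
campaign table bit-comparable with its published counterpart.

The `scm1_cell_specific_rate()` conversion anchors field csABD values to
the cultured ammonia-oxidising archaeon *Nitrosopumilus maritimus* SCM1:
39 nmol C d⁻¹ µg⁻¹ protein at 3 × 10⁷ cells mL⁻¹ and 0.6 µg mL⁻¹ dry mass,
with protein at 40–60% of dry mass, gives 3.7–5.6 fg C cell⁻¹ d⁻¹.

## Depth integration

`integrate_profile()` applies the trapezoidal rule to the discrete profile
and extends the deepest sampled rate unchanged to the seabed. The top of
the dark column defaults to 200 m; no extrapolation is made above the
shallowest usable sample (a warning notes when integration starts deeper).
The integral is equivalently a weighted sum with per-sample weights equal
to the metres of column each sample represents, which is also how
uncertainty propagates: the delta-method sd is
$\sqrt{\sum_i (w_i\,sd_i)^2}/10^3$, assuming independent per-depth errors.
Published per-station ± values for these integrals are *not* reproducible
by this (or any standard) propagation; the fixture carries them as
as-published metadata and the package always reports its own delta-method
sd.

Samples carrying an exclusion flag are dropped from integrals and
summaries and recorded in the output. The bundled campaign flags the ST6
3,400 m sample (`DHAL-influenced`): it sits on the oxic/anoxic interface
of a deep hypersaline anoxic lake, whose anomalously high fixation is not
water-column activity. Keeping it would raise the ST6 integral from 864 to
1087 mg C m⁻² d⁻¹.

## The bundled fixture and its discrepancies

The seven-station fixture (`med_samples()`, 34 depth rows) is the
package's regression surface: integrals, cell-specific tables,
growth-efficiency extrema and dark:photic ratios are all recomputed from
it in the test suite. Three published numbers are knowingly *not*
reproducible from it and are treated as documentation, not targets: an
abstract-level ABD range of 133–370 µg C m⁻³ d⁻¹ (the station table spans
48–411); an ABD:PCD maximum of "62%" (the table's maximum is ≈ 54.8%, at
ST6 500 m); and the prose attribution of the maximum csABD to 3,500 m
(the table places it at ST6 3,000 m, which the fixture follows). The
dark:photic range 85–424% mixes denominators — its low end uses the
modelled photic production, its high end the in situ column — so
`regional_summary()` always prints the full ratio matrix rather than
replicating the asymmetric selection silently.

## The forward simulator

`make_scenario()` fixes a ground truth (depth grid, true PHP/PR/ABD/PA
profiles, temperatures, DIC, assay geometry, noise model, seed);
`simulate_campaign()` emits raw observations whose expected values are the
exact analytic inverses of the rate calculus at that truth. Design
choices:

* **Noise is lognormal with fixed CV (default 5%), mean-matched.**
  Replicate scatter in deep-water count data typically sits well above the
  Poisson floor at the DPM levels involved, indicating
  pipetting/filtration dominance; a fixed CV reflects that. Mean-matching
  (σ² half-subtracted in log space) keeps every estimator unbiased, which
  the Monte-Carlo tests verify to within 1% over 200 seeds. A `"poisson"`
  counting model is available.
* **Blanks are positive (default 100 DPM) and noisy**, so the
  blank-subtraction and zero-clamp paths are exercised; a negative net DPM
  clamps to zero with a warning (rates are physical non-negatives).
* **The `mediterranean-deep` template** draws per-depth truths uniformly
  inside the deep Mediterranean envelopes (ABD 48–411, PR 204–1761,
  PHP 3.8–125.3 µg C m⁻³ d⁻¹, PA 48–460 × 10³ cells mL⁻¹) on a
  5-depth grid to 3,600 m; `atlantic-cold` decays exponentially under a
  cold-deep temperature profile; `uniform` is the analytic edge case.
* **Coverage** in `recovery_report()` is assessed against the *nominal*
  estimator sd implied by the noise model (including the blank-subtraction
  variance term for the tracer rates), not against the n = 3 replicate sd
  estimate, whose heavy $t_2$ tails would make a ±2 sd interval cover only
  ~82% of the time. Against the nominal sd, ±2 sd intervals cover ~95%.

What the simulator does *not* emulate: depth correlation of errors,
decompression effects on retrieved samples, loss of fixed ¹⁴C to dissolved
organics or viral lysis (the particulate-only convention of the assay),
bottle effects over the 72 h incubation, and any ecological dynamics.
Passing recovery tests therefore demonstrate that the *calculus* is
self-consistent and unbiased under counting noise — not that field rates
are free of those systematic effects.

## Numerical conventions and problem sizes

Carbon molar mass is 12.0 µg µmol⁻¹ (not 12.011), matching the precision
of every derived value; all constants are configurable through
`abd_constants()` and echoed into output headers for provenance. Depths
are metres below surface, positive down, strictly ascending per station.
The test suite runs its Monte-Carlo recovery at 200 seeds on the 3-depth
uniform template (~10 s) and its property checks (envelope containment,
Riemann-oracle equivalence at 1 m steps, Arrhenius round trips) on a few
hundred generated cases each — sizes chosen to make sampling error
negligible relative to the 1% bias bound being asserted.

## Known limitations

The package deliberately excludes: carbonate-system chemistry, raw ETS
assay chemistry, partitioning of ABD into chemoautotrophic versus
anaplerotic components, hypothesis testing, spline/curvature-aware
integration, and areal extrapolation of brine-lake hotspots. Uncertainty
propagation is first-order with independence assumptions; replicate sds
with n = 2–3 are themselves noisy, so per-depth ± values should be read as
scale indicators, not confidence intervals.
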