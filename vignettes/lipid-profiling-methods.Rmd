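---
title: "Quantifying tissue lipids from 1D proton spectra: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tissue lipids from 1D proton spectra: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipospec)
```

## The measurement problem

Ceruloplasmin-deficient (CpKO) mice accumulate iron and lipid in the liver.
Two complementary proton-spectroscopy readouts characterize that phenotype:

* **Ex vivo extract NMR** (600 MHz, apolar tissue extracts in deuterated
  chloroform): narrow, well-resolved lipid resonances are integrated over
  fixed chemical-shift windows, converted to absolute millimolar
  concentrations against external standards, and normalized by tissue weight
  (dry weight for liver, fresh weight for perigonadal adipose tissue).
* **In vivo liver MRS** (7 T, single voxel): the intrahepatic lipid content
  (IHLC) is the bulk methylene (~1.3 ppm) to water (~4.7 ppm) area ratio of
  a water-unsuppressed spectrum; a triglyceride index is the summed glycerol
  backbone areas at 4.3 and 4.1 ppm divided by their 4 protons; fatty-acid
  composition indices are area ratios of the water-suppressed spectrum; and
  the full width at half maximum (FWHM) of the water line serves as an
  indirect iron-load proxy (paramagnetic iron shortens T2 and broadens the
  line).

`lipospec` implements the full quantification path, a calibrated simulator
that makes every stage testable without raw data, and the statistical layer
(normality-gated two-group tests, fold changes, gated correlations and
Pareto-scaled PCA).

## Resonance registry and proton stoichiometry

The registry (`lipid_line_catalog()`) fixes twelve assigned resonances:
olefinic –CH=CH– at 5.3 ppm, the two TG glycerol methylenes at 4.30/4.10 ppm
(2 + 2 protons), choline –N(CH3)3 at 3.48 (9 H, PC+LPC),
phosphatidylethanolamine –CH2–NH3+ at 3.40 (2 H), diallylic CH2 at 2.8,
alpha- and beta-carboxyl CH2 at 2.25 and 1.6, allylic CH2 at 2.0, the bulk
(–CH2–)n envelope at 1.3, the two terminal methyls at 0.98 (omega-3) and
0.90 ppm (3 H each), and the cholesterol C18 methyl at 0.68 ppm.

For a single acyl chain with `C` carbons and `d` methylene-interrupted double
bonds, the proton partition is forced by structure: 3 terminal-methyl
protons, `2d` olefinic, `2(d-1)` diallylic (for `d >= 1`), 4 allylic (the two
CH2 flanking the double-bond system), 2 + 2 alpha/beta-carboxyl, and the
remainder in the bulk envelope; totals always equal `2C - 1 - 2d`. These
counts are the package's analytic oracle (`expected_peak_areas()`): for any
mixture of lipid classes and acyl species, the exact window areas follow
without any lineshape.

One published-table subtlety: the extract tables list the TG glycerol signal
as "4.30–4.12 ppm", but those bounds exclude the 4.3/4.1 ppm resonance
centers named by the in vivo TG formula. We therefore integrate TG over the
union of two windows (4.05–4.15 and 4.25–4.35 ppm) and keep "4.30–4.12" only
as the display label.

## Simulator design

`simulate_extract_spectrum()` renders Lorentzian lines (liquid-state
default; half width at half maximum 0.005 ppm for extracts, 0.025 ppm for
the broad in vivo lines) on a descending ppm grid (default 32,768 points
over −0.5 to 8 ppm) and adds a chloroform reference line at 7.26 ppm plus
Gaussian noise of a stated fraction of the maximum signal.

Two simulator conventions matter:

* **Acquisition scaling.** Rendered signal is proportional to
  `RG * NS / (T * P1)`, the inverse of the external-standard normalization
  factor `m = T * P1 / (RG * NS)`, so the quantification formula
  `Conc_met = Conc_st * A_met * m / (A_st * m_st)` is exercised
  non-trivially and inverts the simulation exactly. This is a testing
  convention, not a physical model of receiver electronics.
* **Window-response calibration.** Lorentzian tails are heavy: a ±0.04 ppm
  window captures only ~92% of a 0.005 ppm-HWHM line, and the linear
  endpoint baseline removes part of the wings. Line amplitudes are therefore
  solved from the linear system `M a = t`, where `M[i, j]` is the
  baseline-corrected integral of window `i` under a unit-area line `j`
  rendered on the actual grid, and `t` are the stoichiometric target areas.
  Integration of a simulated spectrum then returns the oracle areas
  essentially exactly, including cross-window tail contamination.

`simulate_liver_mrs_pair()` builds the water-unsuppressed/suppressed pair:
a water Lorentzian at 4.7 ppm with unit window area and requested FWHM (in
Hz at 300.3 MHz), plus lipid lines scaled either so that the bulk/water area
ratio equals a requested lipid fraction (the IHLC being emulated) or, in
absolute mode, proportionally to the mixture's expected areas (so that the
TG index scales linearly with TG concentration). Water suppression
attenuates the water line 1000-fold; both members of a pair receive the same
absolute noise level (one receiver chain). Headgroup lines other than TG
glycerol are not rendered in vivo, mirroring their practical invisibility at
7 T.

`simulate_cohort()` draws per-animal measurands from normal distributions
truncated at zero (all measurands are nonnegative), patterned on the
published group means/SDs shipped as fixtures; it can render per-animal
spectra consistent with the drawn values. The truncated-normal noise model
is an assumption — per-animal raw data are not published. Water-FWHM group
parameters are likewise unpublished (figure only) and the defaults used for
rendering are synthetic, preserving only the reported direction (broader in
the knockout).

## Quantification and indices

`quantify_lipid_classes()` integrates the six quantified classes (TG,
PC+LPC, PE, omega-3 FA, total FA, total cholesterol), converts each area to
mM against one designated class standard (`Conc_st` = 10 mM for all
molecules except TG at 36.7 mM) and divides by tissue weight. The "FA"
channel at 0.90 ppm measures all non-omega-3 acyl chains — including those
esterified in TG and phospholipids — which is why liver FA concentrations
exceed three times the TG concentration in the published table. The shipped
standards registry is **synthetic** (the identity of the 21 reference
molecules is not published); its areas are generated by the package's own
acquisition model and the file is named accordingly.

The fatty-acid composition indices are configuration data
(`default_index_definitions()`), defined per chain with `A_x` the window
area at x ppm and the chain count taken from both terminal methyls
(`A_CH3 = A_0.90 + A_0.98`; omega-3 chains resonate at 0.98 ppm, so using
0.90 ppm alone would miscount chains):

| index | definition | rationale |
|---|---|---|
| ndb  | `1.5 A_5.3 / A_CH3` | 2 olefinic protons per double bond, 3 methyl protons per chain |
| SI   | `A_1.3 / A_5.3` | bulk methylene per olefinic proton |
| UFA  | `0.75 A_2.0 / A_CH3` | 4 allylic protons per unsaturated chain |
| SFA  | `1 - UFA` | complement |
| PUFA | `1.5 A_2.8 / A_CH3` | 2 diallylic protons per methylene-interrupted pair |
| MUFA | `UFA - PUFA`, floored at 0 | difference of the two |
| MCL  | `(1.5 (A_1.3+A_1.6+A_2.0+A_2.25+A_2.8) + 3 A_5.3)/A_CH3 + 2` | half a carbon per CH2 proton, one per olefinic proton (CH, not CH2), plus carboxyl and methyl carbons |

The olefinic term in MCL carries weight 3, not 1.5: olefinic carbons bear
one proton each, and the 1.5 weight would undercount them (pure oleate would
read 17 instead of 18). On pure 16:0 / 18:1 / 18:2 chains these definitions
return exactly 16 / 18 / 18 for MCL, 0 / 1 / 2 for ndb, and 0/1 values for
the saturation fractions. PUFA counts diallylic methylenes per chain, so it
equals the polyunsaturated chain fraction only when 18:2 is the dominant
PUFA (it reads 2 for a pure 18:3 chain); this matches the printed index
ranges. Indices with a zero denominator are reported as missing (`NA`),
never as zero, and are excluded pairwise by the statistics layer.

`peak_fwhm()` interpolates the half-maximum crossings linearly between
bracketing samples on the raw intensities. No baseline is subtracted there:
endpoint-baseline removal under a wide Lorentzian systematically biases the
apparent width low (about −10% for a 100 Hz water line in a 1 ppm window),
while the raw estimator recovers 20–100 Hz widths within the grid
resolution (~0.24 Hz at the default 8192-point axis).

## Statistics layer

Two-group comparisons follow the study's decision rule: both groups are
gated for normality, then an unpaired two-tailed t test (Welch by default;
a pooled-variance switch exists) or a two-tailed Mann–Whitney test. The gate
is the Lilliefors-corrected Kolmogorov–Smirnov test — with n = 5 and
parameters estimated from the data, the plain KS null is anti-conservative —
falling back to Shapiro–Wilk for n of 3–4 and failing outright for n < 3 or
constant data. Mann–Whitney uses the exact distribution when both groups
have n ≤ 8 and no ties, else the normal approximation with continuity
correction. The test actually used is always recorded. No multiple-testing
correction is applied, matching per-measurand reporting. Over 10,000 null
replicates at n = 5 the gated procedure rejects at a rate of ~0.046: the
Welch test is mildly conservative at this size and the exact Mann–Whitney
branch can only achieve a size of 0.032 below the 0.05 threshold.

Correlations use the same gate: Pearson when both variables pass, Spearman
otherwise.

PCA of lipid profiles applies total-area normalization (each sample divided
by its summed areas), then Pareto scaling (each mean-centered variable
divided by the square root of its standard deviation; centering and scaling
commute here because the scale factor is a per-column constant).
Components are sign-fixed so the largest-magnitude loading is positive;
explained-variance fractions are non-increasing by construction; columns
left constant by normalization are dropped with a warning, and a cohort of
identical samples yields all-zero scores and zero explained variance rather
than an error.

## What the tests do and do not show

The per-animal results of the source study (individual spectra, exact
p-values) are not reproducible without the deposited raw data; the test
suite substitutes properties:

* **Fold-change cells.** Only table cells that are arithmetically consistent
  with the printed (rounded) group means are asserted — e.g. adipose TG
  0.9543, liver FA 1.181, IHLC (6 months) 2.00. Other printed cells (e.g.
  adipose PC+LPC 1.4844 vs 0.0012/0.0008 = 1.5) were evidently computed from
  unrounded per-animal values and cannot be regenerated from the table.
* **Noiseless round trips are exact** by the calibration construction; they
  verify bookkeeping (window placement, acquisition factors, weight bases),
  not lineshape fitting.
* **Noisy recovery is demonstrated on single-compound samples.** At a
  spectrum-wide SNR of 50, noise integrated over a quantification window
  amounts to 20–130% of the minor-class areas of any full tissue profile
  (the bulk methylene peak dominates the maximum signal by more than
  tenfold), and the nonnegativity floor on integrals rectifies that noise
  into a positive bias no averaging removes. Recovery within 5% at SNR 50 is
  therefore shown for one-compound samples — exactly how external standards
  are acquired — using short-chain (tributyrin-style) acyl chains for the
  chain-carrying classes so the quantified resonance sits at the noise
  ceiling, with accuracy measured as the mean over repeated noise draws.
  Quantifying minor classes in a full profile at that noise level is beyond
  any window integrator; real extract acquisitions operate at far higher
  SNR.
* **PCA separation** is asserted as a Welch t test on PC1 scores (p < 0.05)
  over 200 simulated cohorts with a 3-SD group shift on one peak. Perfect
  per-sample sign separation is not attainable at a 3-SD shift (each sample
  sits 1.5 SD from the midpoint, so ~6.7% land on the wrong side and all ten
  samples classify correctly in only ~half the cohorts). The fixture gives
  the discriminating peak the dominant variance share; with 12 peaks and 10
  samples the largest noise eigenvalue is ~5x the average (random-matrix
  spreading), so a discriminating peak whose variance merely matches the
  background would not reliably own PC1 under any method.
* **Problem sizes.** Default simulations use 32,768-point extract axes and
  8,192-point MRS axes; calibration matrices are cached per grid. The
  statistical checks use 10,000 null replicates (type I), 1,000 cohorts
  (power; ~0.68 for the liver TG parameters at n = 5) and 200 cohorts (PCA).

## Known limitations

* No phase correction, apodization, zero-filling or FID-domain processing:
  inputs are assumed to be fully processed real spectra (vendor software
  territory), and only uncompressed JCAMP-DX (AFFN) or the TSV dialect are
  read.
* The Lorentzian simulator has no J-coupling, multiplet structure,
  relaxation weighting or scanner artifacts; passing tests demonstrate the
  quantification pipeline's correctness, not robustness to those effects.
* The baseline rule (straight line through the 3-point edge means of each
  window) is a deterministic stand-in for interactive manual integration;
  at very low SNR its 3-point edges are noise-sensitive (see above).
* The standards registry, the per-class representative standards, the
  0.94 ppm split between the two terminal-methyl windows and the exact index
  formulas are declared configuration, to be reconciled against laboratory
  references when available.
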