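# lipospec

Lipid quantification from 1D proton spectra: ex vivo high-resolution NMR of
tissue extracts and in vivo liver MRS, with the statistics used in two-group
mouse studies of hepatic lipid and iron accumulation.

## What it computes

Studies of ceruloplasmin-deficient (CpKO) mice read liver fat and iron with
two proton-spectroscopy assays. This package implements both quantification
paths end to end, plus a calibrated simulator so every stage is testable
without raw data:

* **Extract NMR quantification.** Lipid-class resonances (TG glycerol at
  4.30/4.10 ppm, choline at 3.48, PE at 3.40, terminal methyls at 0.98 and
  0.90, cholesterol C18 at 0.68 ppm) are integrated over fixed windows after
  referencing to chloroform at δ 7.26 and local linear baseline removal.
  Areas become absolute concentrations against external standards,

      Conc_met = Conc_st · A_met · m / (A_st · m_st),   m = T · P1 / (RG · NS),

  (10 mM standards, 36.7 mM for TG), then per-mg values on the declared
  weight basis (dry weight for liver, fresh weight for adipose tissue).
  Total lipid content is the full spectral area (reference line excluded)
  per mg.
* **In vivo MRS measurands.** Intrahepatic lipid content
  IHLC = A(‑CH₂‑)ₙ / A(water) from the unsuppressed voxel spectrum; the
  triglyceride index (A₄.₃ + A₄.₁)/4; fatty-acid composition indices (ndb,
  SI, UFA, SFA, PUFA, MUFA, MCL) as proton-stoichiometric area ratios of the
  suppressed spectrum; and the water-line FWHM (in Hz) as an iron-load
  proxy.
* **Synthetic data.** A Lorentzian line simulator whose window integrals
  reproduce the analytic proton-counting oracle exactly, an MRS pair
  simulator with tunable lipid fraction and water linewidth, and a cohort
  generator patterned on the published group means/SDs (shipped as
  fixtures).
* **Statistics.** Normality-gated tests (Lilliefors gate, then Welch t or
  Mann–Whitney), fold changes, gated Pearson/Spearman correlations, and PCA
  of total-area-normalized, Pareto-scaled lipid profiles.

## Worked example

Quantify a simulated liver extract (realistic cryoprobe noise), then read
the in vivo measurands off a simulated voxel pair:

```r
library(lipospec)

mix <- lipid_mixture(
  class_concentrations = c(TG = 6.03, PC_LPC = 0.11, PE = 0.81,
                           TC = 0.56, FA = 19.2),
  species_fractions = c(palmitate = 0.31, stearate = 0.04, oleate = 0.36,
                        linoleate = 0.18, linolenate = 0.11))
s <- simulate_extract_spectrum(mix, noise_sd = 1e-5, seed = 42)
s <- reference_to_anchor(s, 7.26)
meta <- sample_meta("mouse_01", "CpKO", 10, "liver", dry_weight = 30)
quantify_lipid_classes(s, meta, warn = FALSE)
#> <quant_result> mouse_01 (liver, dry basis)
#>  lipid_class display_shift       area    conc_mM conc_mM_per_mg basis
#>           TG     4.30-4.12  66.254537  6.0253455    0.200844849   dry
#>       PC_LPC          3.48   2.727612  0.1102469    0.003674897   dry
#>           PE           3.4   4.448678  0.8091467    0.026971558   dry
#>       omega3          0.98  35.426047  4.2956388    0.143187962   dry
#>           FA           0.9 286.965402 34.7964232    1.159880774   dry
#>           TC          0.68   4.563522  0.5533568    0.018445227   dry
#>   total lipid: 124.2 area/mg
```

The injected 6.03 mM TG comes back as 6.025 mM, i.e. 0.2008 mM per mg dry
weight; the FA channel (0.90 ppm) counts *all* non-omega-3 acyl chains
(free fatty acids plus those esterified in TG, PC and PE), which is why its
per-mg value exceeds 3x the TG value, as in real liver tables. The omega-3
channel (0.98 ppm) recovers the 11% omega-3 chain fraction.

```r
pair <- simulate_liver_mrs_pair(0.082, water_fwhm_hz = 60, seed = 7)
m <- mrs_measurands(pair$suppressed, pair$unsuppressed)
#> IHLC = 0.0825, TG index = 0.00067, water FWHM = 60.0 Hz
round(m$indices, 3)
#>    ndb     SI    UFA    SFA   PUFA   MUFA    MCL
#>  1.108  8.915  0.669  0.331  0.457  0.213 17.939
```

The injected lipid fraction 0.082 (a fatty CpKO liver) and the 60 Hz water
linewidth (iron broadening) are both recovered; the indices land in the
ranges published for mouse liver (ndb ~0.5–1.1, SI ~8–10, MCL ~15–19).

Group statistics follow the study's decision rule:

```r
set.seed(1)
compare_groups(rnorm(5, 0.2011, 0.0172), rnorm(5, 0.1579, 0.0281),
               measurand = "TG")
#> <group_comparison> TG: group1 (n=5) vs group2 (n=5)
#>   means 0.2033 / 0.1617, FC 1.257, student_t p = 0.006053 *
```

Published group means/SDs are shipped as fixtures
(`group_table_fixture("table1")`, `"table2"`, `"table3"`), and
`fold_change()` reproduces the table arithmetic, e.g. the liver FA fold
change 0.6416/0.5433 = 1.181.

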