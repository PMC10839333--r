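# Shared fixtures: analytic spectra built directly from lineshape formulas,
# independent of the package's simulator, so they can serve as oracles.

# a spectrum holding a single analytic Lorentzian of known area
lorentzian_spectrum <- function(center, hwhm, area = 1,
                                ppm_range = c(-0.5, 8), n = 16384,
                                modality = "hr_nmr", freq = NULL,
                                baseline_fun = NULL) {
  ppm <- seq(ppm_range[2], ppm_range[1], length.out = n)
  y <- (area / pi) * hwhm / ((ppm - center)^2 + hwhm^2)
  if (!is.null(baseline_fun)) y <- y + baseline_fun(ppm)
  spectrum1d(ppm, y, spectrometer_freq = freq, modality = modality)
}

gaussian_spectrum <- function(center, sigma, height = 1,
                              ppm_range = c(-0.5, 8), n = 16384) {
  ppm <- seq(ppm_range[2], ppm_range[1], length.out = n)
  spectrum1d(ppm, height * exp(-(ppm - center)^2 / (2 * sigma^2)))
}

pure_species_mixture <- function(species_name, conc = 1) {
  lipid_mixture(class_concentrations = c(FA = conc),
                species_fractions = stats::setNames(1, species_name))
}

# a random but valid mixture for property-style loops
random_mixture <- function() {
  conc <- stats::runif(5, 0.1, 10)
  names(conc) <- c("TG", "PC_LPC", "PE", "TC", "FA")
  fr <- stats::runif(5, 0.05, 1)
  names(fr) <- names(default_species())
  lipid_mixture(class_concentrations = conc, species_fractions = fr)
}

liver_meta <- function(dry_weight = 30) {
  sample_meta("test_liver", "CpKO", 10, "liver", dry_weight = dry_weight)
}

# Table-3-patterned liver mixture (per-mg values times a 30 mg dry weight)
liver_mixture <- function(wt = 30) {
  lipospec:::.mixture_with_omega3(
    c(TG = 0.2011, PC_LPC = 0.0036, PE = 0.0269, TC = 0.0186,
      FA = 0.6416) * wt,
    omega3_chain_mM = 0.0449 * wt)
}

# oracle truth for every quantified class of a mixture, in sample mM:
# headgroup classes are the class concentrations themselves; the two methyl
# channels count non-omega-3 and omega-3 chains.
class_truth_mM <- function(mix) {
  ea <- expected_peak_areas(mix)
  c(TG = mix$class_concentrations[["TG"]],
    PC_LPC = mix$class_concentrations[["PC_LPC"]],
    PE = mix$class_concentrations[["PE"]],
    omega3 = peak_area(ea, "omega3_ch3") / 3,
    FA = peak_area(ea, "fa_ch3") / 3,
    TC = mix$class_concentrations[["TC"]])
}

quant_per_mg <- function(q) {
  stats::setNames(q$concentrations$conc_mM_per_mg,
                  q$concentrations$lipid_class)
}

# single-compound mixtures used for noisy-recovery checks: short
# (tributyrin-style) acyl chains keep the quantified resonance at the noise
# ceiling, as in real external-standard acquisitions
butyrate <- function() fatty_acyl_species("butyrate", 4, 0)

single_class_mixture <- function(class, conc = 5) {
  switch(class,
    TG = lipid_mixture(c(TG = conc), c(butyrate = 1),
                       species = list(butyrate = butyrate())),
    PC_LPC = lipid_mixture(c(PC_LPC = conc), c(butyrate = 1),
                           species = list(butyrate = butyrate())),
    PE = lipid_mixture(c(PE = conc), c(butyrate = 1),
                       species = list(butyrate = butyrate())),
    TC = lipid_mixture(c(TC = conc), c(oleate = 1)),
    FA = lipid_mixture(c(FA = conc), c(butyrate = 1),
                       species = list(butyrate = butyrate())),
    omega3 = lipid_mixture(c(FA = conc), c(linolenate = 1)))
}
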