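# Line catalog, proton stoichiometry oracle, simulators and cohorts.

test_that("the resonance registry is well formed", {
  cat_df <- lipid_line_catalog()
  expect_true(all(cat_df$ppm_lo < cat_df$center &
                    cat_df$center < cat_df$ppm_hi))
  # windows pairwise disjoint (shared boundaries allowed)
  for (i in seq_len(nrow(cat_df))) {
    for (j in seq_len(nrow(cat_df))) {
      if (i == j) next
      overlap <- min(cat_df$ppm_hi[i], cat_df$ppm_hi[j]) -
        max(cat_df$ppm_lo[i], cat_df$ppm_lo[j])
      expect_lte(overlap, 0)
    }
  }
  # TG glycerol: 4 protons over the 4.30-4.12 region
  tg <- cat_df[!is.na(cat_df$lipid_class) & cat_df$lipid_class == "TG", ]
  expect_equal(sum(tg$protons), 4)
  expect_setequal(tg$center, c(4.10, 4.30))
  o3 <- cat_df[cat_df$peak_id == "omega3_ch3", ]
  expect_equal(o3$center, 0.98)
  expect_equal(o3$protons, 3)
  expect_equal(cat_df$protons[cat_df$peak_id == "choline"], 9)
})

test_that("chain proton partitions match manual counting", {
  pp <- chain_proton_partition(fatty_acyl_species("oleate", 18, 1))
  expect_equal(pp[["olefinic"]], 2)
  expect_equal(pp[["allylic"]], 4)
  expect_equal(pp[["diallylic"]], 0)
  expect_equal(pp[["bulk_ch2"]], 20)
  expect_equal(pp[["fa_ch3"]], 3)

  # palmitate CH3-(CH2)14-COOH: 12 bulk CH2 after alpha and beta
  pp16 <- chain_proton_partition(fatty_acyl_species("palmitate", 16, 0))
  expect_equal(pp16[["bulk_ch2"]], 24)
  expect_equal(pp16[["olefinic"]] + pp16[["allylic"]] + pp16[["diallylic"]],
               0)

  pp183 <- chain_proton_partition(fatty_acyl_species("linolenate", 18, 3,
                                                     omega3 = TRUE))
  expect_equal(pp183[["omega3_ch3"]], 3)
  expect_equal(pp183[["fa_ch3"]], 0)
  expect_equal(pp183[["diallylic"]], 4)

  # property: totals equal 2C - 1 - 2d for any chain
  for (C in c(12, 14, 16, 18, 20, 22)) {
    for (d in 0:4) {
      if (d > 0 && C - 3 * d - 5 < 0) next   # not enough methylenes
      sp <- fatty_acyl_species("x", C, d, omega3 = (d > 0 && C %% 2 == 0))
      pp <- chain_proton_partition(sp)
      expect_true(all(pp >= 0))
      expect_equal(sum(pp), 2 * C - 1 - 2 * d)
    }
  }
  expect_error(fatty_acyl_species("too-short", 6, 2), "impossible")
})

test_that("expected areas follow proton stoichiometry exactly", {
  u <- expected_peak_areas(pure_species_mixture("oleate"), scale = 2)
  expect_equal(peak_area(u, "olefinic"), 2 * 2)
  expect_equal(peak_area(u, "allylic"), 4 * 2)
  expect_equal(peak_area(u, "diallylic"), 0)
  expect_equal(peak_area(u, "fa_ch3"), 3 * 2)

  p <- expected_peak_areas(pure_species_mixture("palmitate"))
  expect_equal(peak_area(p, c("olefinic", "allylic", "diallylic")),
               c(0, 0, 0))
  expect_equal(peak_area(p, "bulk_ch2"), 24)

  none <- lipid_mixture(class_concentrations = c(TG = 0),
                        species_fractions = c(oleate = 1))
  expect_true(all(expected_peak_areas(none)$area == 0))

  # headgroups: TG glycerol 4 protons, choline 9, PE 2, TC 3
  hg <- expected_peak_areas(lipid_mixture(
    class_concentrations = c(TG = 1, PC_LPC = 1, PE = 1, TC = 1),
    species_fractions = c(oleate = 1)))
  expect_equal(peak_area(hg, c("tg_glycerol_41", "tg_glycerol_43")),
               c(2, 2))
  expect_equal(peak_area(hg, "choline"), 9)
  expect_equal(peak_area(hg, "pe_ch2"), 2)
  expect_equal(peak_area(hg, "tc_ch3"), 3)
})

test_that("integrating simulated spectra reproduces the analytic oracle", {
  set.seed(101)
  wins <- catalog_windows()
  for (rep in 1:10) {
    mix <- random_mixture()
    want <- expected_peak_areas(mix)
    s <- simulate_extract_spectrum(mix, noise_sd = 0)
    m <- acquisition_factor(s$acquisition)
    for (id in want$peak_id) {
      got <- integrate_window(s, wins[[id]], warn = FALSE) * m
      expect_equal(got, peak_area(want, id), tolerance = 0.01)
    }
  }
})

test_that("simulation is deterministic and scales with acquisition", {
  mix <- lipid_mixture()
  a <- simulate_extract_spectrum(mix, noise_sd = 0.02, seed = 5)
  b <- simulate_extract_spectrum(mix, noise_sd = 0.02, seed = 5)
  expect_identical(a$intensity, b$intensity)
  c2 <- simulate_extract_spectrum(mix, noise_sd = 0.02, seed = 6)
  expect_false(identical(a$intensity, c2$intensity))

  # doubling NS doubles every integrated area (signal ~ RG*NS/(T*P1))
  s1 <- simulate_extract_spectrum(mix, acq = acquisition_params(NS = 64))
  s2 <- simulate_extract_spectrum(mix, acq = acquisition_params(NS = 128))
  w <- catalog_windows("bulk_ch2")[[1]]
  expect_equal(integrate_window(s2, w), 2 * integrate_window(s1, w),
               tolerance = 1e-6)
  expect_error(simulate_extract_spectrum(mix, noise_sd = 0.1), "seed")
  expect_error(simulate_extract_spectrum(mix, axis_points = 512), "2048")
})

test_that("terminal methyl protons are conserved across omega-3 content", {
  base <- c(palmitate = 0.4, oleate = 0.4)
  totals <- sapply(c(0, 0.1, 0.2), function(f) {
    fr <- c(base / sum(base) * (1 - f))
    if (f > 0) fr <- c(fr, linolenate = f)
    ea <- expected_peak_areas(lipid_mixture(c(FA = 3), fr))
    c(o3 = peak_area(ea, "omega3_ch3"), fa = peak_area(ea, "fa_ch3"))
  })
  expect_equal(unname(colSums(totals)), rep(9, 3))       # 3 mM * 3 protons
  expect_true(all(diff(totals["o3", ]) > 0))
  expect_true(all(diff(totals["fa", ]) < 0))
})

test_that("the MRS pair realizes the requested lipid fraction and width", {
  pair0 <- simulate_liver_mrs_pair(0, water_fwhm_hz = 40, seed = 31)
  # no lipid: suppressed spectrum is residual water + noise only
  expect_lt(max(pair0$suppressed$intensity),
            0.01 * max(pair0$unsuppressed$intensity))
  expect_lt(compute_ihlc(pair0$unsuppressed), 0.002)

  pair <- simulate_liver_mrs_pair(0.082, water_fwhm_hz = 60, seed = 32)
  expect_equal(compute_ihlc(pair$unsuppressed), 0.082, tolerance = 0.05)
  expect_equal(pair$suppressed$modality, "mrs_suppressed")
  expect_equal(pair$unsuppressed$modality, "mrs_unsuppressed")

  f40 <- water_fwhm_iron_proxy(
    simulate_liver_mrs_pair(0.05, water_fwhm_hz = 40, seed = 33)$unsuppressed)
  f80 <- water_fwhm_iron_proxy(
    simulate_liver_mrs_pair(0.05, water_fwhm_hz = 80, seed = 34)$unsuppressed)
  expect_equal(f40$fwhm_hz, 40, tolerance = 2 / 40)
  expect_equal(f80$fwhm_hz, 80, tolerance = 2 / 80)
  expect_gt(f80$fwhm_hz, f40$fwhm_hz)
})

test_that("IHLC is strictly increasing in the injected lipid fraction", {
  lf <- c(0.02, 0.05, 0.1, 0.2)
  got <- sapply(lf, function(f) {
    compute_ihlc(simulate_liver_mrs_pair(f, water_fwhm_hz = 40,
                                         noise_sd = 0)$unsuppressed)
  })
  expect_true(all(diff(got) > 0))
  expect_equal(got, lf, tolerance = 0.05)
})

test_that("cohort draws honor the group structure", {
  groups <- data.frame(genotype = c("CpKO", "WT"), age_months = 10,
                       n = c(4, 4))
  meas <- data.frame(measurand = "TG",
                     genotype = c("CpKO", "WT"), age_months = 10,
                     mean = c(0.2, 0.15), sd = c(0, 0))
  spec0 <- cohort_spec(groups, meas)
  coh <- simulate_cohort(spec0, seed = 1)
  expect_equal(coh$TG, rep(c(0.2, 0.15), each = 4))    # SD 0: degenerate

  spec3 <- cohort_spec_from_table3()
  c1 <- simulate_cohort(spec3, seed = 7)
  c2 <- simulate_cohort(spec3, seed = 7)
  expect_identical(c1, c2)
  expect_equal(nrow(c1), 10)
  expect_true(all(c1$TG >= 0))
  expect_error(cohort_spec(data.frame(genotype = "WT", age_months = 6, n = 1),
                           meas), "n >= 2")
})

test_that("rendered cohort spectra are consistent with the drawn values", {
  spec2 <- cohort_spec_from_table2(age_months = 6, n = 2)
  coh <- simulate_cohort(spec2, seed = 9, render_spectra = TRUE)
  spectra <- attr(coh, "spectra")
  expect_length(spectra, nrow(coh))
  i <- 1L
  got <- compute_ihlc(spectra[[coh$animal_id[i]]]$mrs$unsuppressed)
  expect_equal(got, coh$IHLC[i], tolerance = 0.05)
  fw <- water_fwhm_iron_proxy(spectra[[coh$animal_id[i]]]$mrs$unsuppressed)
  expect_equal(fw$fwhm_hz, coh$water_fwhm_hz[i], tolerance = 0.1)
})
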