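# Absolute quantification against external standards and weight
# normalization.

test_that("the acquisition factor is T*P1/(RG*NS)", {
  expect_equal(acquisition_factor(acquisition_params(298, 128, 10, 1)),
               23.28125)
  expect_equal(acquisition_factor(acquisition_params(1, 1, 1, 1)), 1)
  m1 <- acquisition_factor(acquisition_params(NS = 64))
  m2 <- acquisition_factor(acquisition_params(NS = 128))
  expect_equal(m2, m1 / 2)
  expect_error(acquisition_params(RG = 0), "> 0")
})

test_that("standard-based concentrations follow the reference formula", {
  acq <- acquisition_params()
  std10 <- standard_record("ref", "FA", "fa_ch3", 10, 50, acq)
  expect_equal(concentration_from_standard(50, acq, std10), 10)

  std_tg <- standard_record("triolein", "TG", "tg_glycerol_43", 36.7, 100,
                            acq)
  expect_equal(concentration_from_standard(200, acq, std_tg), 73.4)

  # half the scans: same observed area means twice the concentration
  half <- acquisition_params(NS = acq$NS / 2)
  expect_equal(concentration_from_standard(50, half, std10), 20)
})

test_that("noiseless quantification recovers a full liver profile", {
  mix <- liver_mixture(wt = 30)
  s <- simulate_extract_spectrum(mix, noise_sd = 0)
  q <- quantify_lipid_classes(s, liver_meta(30), warn = FALSE)
  got <- quant_per_mg(q)
  truth <- class_truth_mM(mix) / 30
  for (cls in names(truth)) {
    expect_equal(got[[cls]], truth[[cls]], tolerance = 0.01, label = cls)
  }
  # the per-mg TG value is the published magnitude by construction
  expect_equal(got[["TG"]], 0.2011, tolerance = 0.01)
})

test_that("the acquisition factor cancels the simulator scaling", {
  mix <- lipid_mixture(class_concentrations = c(TG = 4, FA = 8))
  # sample acquired under different NS and RG than the standards
  acq <- acquisition_params(NS = 512, RG = 8)
  s <- simulate_extract_spectrum(mix, acq = acq, noise_sd = 0)
  got <- quant_per_mg(quantify_lipid_classes(s, liver_meta(1), warn = FALSE))
  truth <- class_truth_mM(mix)
  expect_equal(got[["TG"]], truth[["TG"]], tolerance = 0.01)
  expect_equal(got[["FA"]], truth[["FA"]], tolerance = 0.01)
})

test_that("estimates are linear in concentration across a decade", {
  concs <- c(0.5, 1, 2, 5)
  got <- sapply(concs, function(cc) {
    mix <- lipid_mixture(class_concentrations = c(TG = cc),
                         species_fractions = c(oleate = 1))
    s <- simulate_extract_spectrum(mix, noise_sd = 0)
    quant_per_mg(quantify_lipid_classes(s, liver_meta(1),
                                        classes = "TG", warn = FALSE))[["TG"]]
  })
  fit <- stats::lm(got ~ concs)
  expect_equal(unname(stats::coef(fit)[2]), 1, tolerance = 0.01)
})

test_that("weight normalization and basis switching are exact", {
  mix <- lipid_mixture(class_concentrations = c(TG = 4, FA = 8))
  s <- simulate_extract_spectrum(mix, noise_sd = 0)
  q1 <- quantify_lipid_classes(s, liver_meta(20), warn = FALSE)
  q2 <- quantify_lipid_classes(s, liver_meta(40), warn = FALSE)
  expect_equal(quant_per_mg(q1), 2 * quant_per_mg(q2))
  expect_equal(q1$total_lipid, 2 * q2$total_lipid)

  # same liver sample on fresh basis rescales by fresh/dry exactly
  full <- simulate_extract_spectrum(liver_mixture(), noise_sd = 0)
  meta_d <- sample_meta("x", "WT", 10, "liver", fresh_weight = 90,
                        dry_weight = 30, weight_basis = "dry")
  meta_f <- sample_meta("x", "WT", 10, "liver", fresh_weight = 90,
                        dry_weight = 30, weight_basis = "fresh")
  qd <- quantify_lipid_classes(full, meta_d, warn = FALSE)
  qf <- quantify_lipid_classes(full, meta_f, warn = FALSE)
  expect_equal(quant_per_mg(qd) / quant_per_mg(qf), rep(90 / 30, 6),
               ignore_attr = TRUE)
})

test_that("degenerate inputs are flagged, not silently quantified", {
  zero <- spectrum1d(seq(8, -0.5, length.out = 4096), numeric(4096),
                     acquisition = acquisition_params())
  expect_warning(q <- quantify_lipid_classes(zero, liver_meta(30)),
                 "zero-signal")
  expect_true(all(q$concentrations$conc_mM_per_mg == 0))
  expect_true(all(is.na(q$relative_abundance)))

  s <- simulate_extract_spectrum(lipid_mixture(), noise_sd = 0)
  expect_error(quantify_lipid_classes(s, liver_meta(30),
                                      standards = list()),
               "configuration error")
  no_acq <- s; no_acq$acquisition <- NULL
  expect_error(quantify_lipid_classes(no_acq, liver_meta(30)),
               "metadata error")
  expect_error(sample_meta("x", "WT", 10, "liver", fresh_weight = 50),
               "metadata error")      # dry basis without dry weight
})

test_that("relative abundances are normalized and scale invariant", {
  one <- peak_table(c("a", "b"), c(3, 0))
  expect_equal(relative_abundances(one), c(a = 1, b = 0))
  two <- peak_table(c("a", "b"), c(2, 2))
  expect_equal(relative_abundances(two), c(a = 0.5, b = 0.5))
  seven <- peak_table(c("a", "b", "c"), c(1, 2, 4))
  scaled <- peak_table(c("a", "b", "c"), 7 * c(1, 2, 4))
  expect_equal(relative_abundances(seven), relative_abundances(scaled))
  expect_equal(sum(relative_abundances(seven)), 1)
  expect_error(relative_abundances(peak_table("a", 0)), "undefined")
})

test_that("total lipid content is total area per mg", {
  zero <- spectrum1d(seq(8, -0.5, length.out = 2048), numeric(2048))
  expect_equal(total_lipid_content(zero, liver_meta(10)), 0)

  # single analytic line of area 3 away from the excluded reference window
  s <- lorentzian_spectrum(4, 0.005, area = 3)
  expect_equal(total_lipid_content(s, liver_meta(10)), 3 / 10,
               tolerance = 0.02)
  expect_equal(total_lipid_content(s, liver_meta(20)),
               total_lipid_content(s, liver_meta(10)) / 2)
})

test_that("the synthetic standards registry matches its shipped fixture", {
  db <- synthetic_standards_db()
  expect_equal(nrow(db), 21)
  expect_equal(length(unique(db$lipid_class)), 11)
  expect_true(all(db$conc_mM[db$lipid_class == "TG"] == 36.7))
  expect_true(all(db$conc_mM[db$lipid_class != "TG"] == 10))

  path <- system.file("extdata", "standards_synthetic.tsv",
                      package = "lipospec")
  shipped <- utils::read.delim(path, stringsAsFactors = FALSE)
  expect_equal(shipped$molecule, db$molecule)
  expect_equal(shipped$area, db$area, tolerance = 1e-9)

  recs <- read_standards(path)
  expect_s3_class(recs[["triolein"]], "standard_record")
  stds <- class_standards(db)
  expect_setequal(names(stds), lipid_class_table()$lipid_class)
})
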