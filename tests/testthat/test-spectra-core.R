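# Data model, I/O, referencing, baseline, integration and FWHM estimation.

test_that("spectrum construction enforces the axis contract", {
  s <- spectrum1d(c(1, 2, 3), c(0, 1, 0))          # ascending input
  expect_equal(s$ppm, c(3, 2, 1))                  # stored descending
  expect_equal(s$intensity, c(0, 1, 0))
  expect_error(spectrum1d(c(1, 1, 2), c(0, 0, 0)), "monotone")
  expect_error(spectrum1d(1, 1), "length")
  expect_error(spectrum1d(c(1, 2), c(0, 0, 0)), "equal length")
  expect_equal(spectrum1d(c(2, 1), c(0, 0))$spectrometer_freq, 600.13)
  expect_equal(spectrum1d(c(2, 1), c(0, 0),
                          modality = "mrs_suppressed")$spectrometer_freq,
               300.3)
})

test_that("TSV round trip is lossless and reorders ascending files", {
  s <- spectrum1d(c(3.0, 2.0, 1.0), c(0.1, 0.9, 0.2),
                  acquisition = acquisition_params(), label = "tiny")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum(s, path, "tsv")
  r <- read_spectrum(path, "tsv")
  expect_equal(r$ppm, s$ppm)
  expect_equal(r$intensity, s$intensity)
  expect_equal(r$label, "tiny")
  expect_equal(r$acquisition$NS, 128L)

  # ascending file comes back descending with intensities tracking
  writeLines(c("ppm\tintensity", "1\t10", "2\t20", "3\t30"), path)
  r2 <- read_spectrum(path, "tsv")
  expect_equal(r2$ppm, c(3, 2, 1))
  expect_equal(r2$intensity, c(30, 20, 10))
})

test_that("large spectra survive both formats to 1e-9 relative", {
  mix <- lipid_mixture()
  s <- simulate_extract_spectrum(mix, noise_sd = 0.01, seed = 21,
                                 axis_points = 10000)
  for (fmt in c("tsv", "jcamp_dx")) {
    path <- withr::local_tempfile()
    write_spectrum(s, path, fmt)
    r <- read_spectrum(path, fmt)
    expect_lt(max(abs(r$intensity - s$intensity)),
              1e-9 * max(abs(s$intensity)))
    expect_lt(max(abs(r$ppm - s$ppm)), 1e-9 * max(abs(s$ppm)))
    # window integrals agree with the in-memory original
    for (w in catalog_windows(c("bulk_ch2", "choline"))) {
      expect_equal(integrate_window(r, w, warn = FALSE),
                   integrate_window(s, w, warn = FALSE),
                   tolerance = 1e-9)
    }
    expect_equal(r$modality, s$modality)
    expect_equal(r$acquisition$RG, s$acquisition$RG)
  }
})

test_that("JCAMP reader handles XYDATA (X++(Y..Y)) AFFN blocks", {
  path <- withr::local_tempfile(fileext = ".dx")
  writeLines(c(
    "##TITLE=affn block", "##JCAMP-DX=4.24",
    "##XUNITS=PPM", "##YUNITS=ARBITRARY UNITS",
    "##.OBSERVE FREQUENCY=600.13",
    "##FIRSTX=5", "##LASTX=1", "##NPOINTS=5", "##YFACTOR=0.5",
    "##XYDATA=(X++(Y..Y))",
    "5 2 4 8", "2 4 2",
    "##END="), path)
  r <- read_spectrum(path, "jcamp_dx")
  expect_equal(r$ppm, seq(5, 1, length.out = 5))
  expect_equal(r$intensity, c(2, 4, 8, 4, 2) * 0.5)
  expect_equal(r$spectrometer_freq, 600.13)
  expect_null(r$acquisition)
})

test_that("unparseable files raise format errors naming the line", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("ppm\tintensity", "1\t0.5", "oops\tx"), path)
  expect_error(read_spectrum(path, "tsv"), "line 3")
  writeLines(c("wrong\theader", "1\t2"), path)
  expect_error(read_spectrum(path, "tsv"), "format error")
  expect_error(read_spectrum(file.path(tempdir(), "nope.tsv")), "not found")
})

test_that("referencing lands the anchor line on its nominal shift", {
  # peak already on the anchor: zero shift
  s <- lorentzian_spectrum(7.26, 0.005)
  r <- reference_to_anchor(s, 7.26)
  step <- abs(diff(s$ppm[1:2]))
  expect_lt(abs(attr(r, "shift_ppm")), step)

  # chloroform line injected at 7.31: shift must be -0.05
  s2 <- lorentzian_spectrum(7.31, 0.005)
  r2 <- reference_to_anchor(s2, 7.26)
  expect_lt(abs(attr(r2, "shift_ppm") - (-0.05)), step)
  apex <- r2$ppm[which.max(r2$intensity)]
  expect_lt(abs(apex - 7.26), step + 1e-12)

  # MRS convention: water at 4.75 referenced to 4.70
  s3 <- lorentzian_spectrum(4.75, 0.03, ppm_range = c(0, 6.5), n = 8192,
                            modality = "mrs_unsuppressed")
  r3 <- reference_to_anchor(s3, 4.70)
  expect_lt(abs(attr(r3, "shift_ppm") - (-0.05)),
            abs(diff(s3$ppm[1:2])))

  # idempotence: second application moves by less than one grid step
  r4 <- reference_to_anchor(r2, 7.26)
  expect_lt(abs(attr(r4, "shift_ppm")), step)

  # no maximum in window
  flat <- spectrum1d(seq(8, 0, length.out = 512), rep(1, 512))
  expect_error(reference_to_anchor(flat, 7.26), "referencing error")
})

test_that("baseline correction removes constants and linear ramps", {
  n <- 2048
  ppm <- seq(8, 0, length.out = n)
  win <- peak_window("w", 3, 5, 4)
  const <- spectrum1d(ppm, rep(3.7, n))
  expect_equal(max(abs(baseline_correct(const, win)$intensity)), 0)
  ramp <- spectrum1d(ppm, 2 * ppm - 1)
  expect_lt(max(abs(baseline_correct(ramp, win)$intensity)), 1e-9)
  expect_error(baseline_correct(const, peak_window("w", -2, -1)),
               "outside axis")
})

test_that("a Lorentzian on a ramp integrates like the ramp-free line", {
  g <- 0.01
  on_ramp <- lorentzian_spectrum(4, g, area = 1,
                                 baseline_fun = function(p) 0.8 * p + 2)
  free <- lorentzian_spectrum(4, g, area = 1)
  win <- peak_window("w", 4 - 50 * g, 4 + 50 * g, 4)
  a_ramp <- integrate_window(on_ramp, win, baseline = TRUE)
  a_free <- integrate_window(free, win, baseline = FALSE)
  expect_equal(a_ramp, a_free, tolerance = 0.02)
})

test_that("window integration matches the closed-form Lorentzian area", {
  # unit-height line: height 1 at apex, area pi * gamma
  g <- 0.01
  s <- lorentzian_spectrum(4, g, area = pi * g)
  expect_equal(max(s$intensity), 1, tolerance = 1e-3)
  win <- peak_window("w", 4 - 100 * g, 4 + 100 * g, 4)
  expect_equal(integrate_window(s, win, baseline = FALSE), pi * g,
               tolerance = 0.01)

  zero <- spectrum1d(seq(8, 0, length.out = 1024), numeric(1024))
  expect_equal(integrate_window(zero, win), 0)
  expect_error(integrate_window(s, peak_window("tiny", 4, 4.0005)),
               "resolution error")
})

test_that("integration is linear in the signal", {
  s1 <- lorentzian_spectrum(3, 0.01, area = 1)
  s2 <- lorentzian_spectrum(3.2, 0.02, area = 2)
  win <- peak_window("w", 2.5, 3.7, 3.1)
  combo <- s1
  combo$intensity <- 2 * s1$intensity + 5 * s2$intensity
  for (bl in c(TRUE, FALSE)) {
    expect_equal(integrate_window(combo, win, baseline = bl),
                 2 * integrate_window(s1, win, baseline = bl) +
                   5 * integrate_window(s2, win, baseline = bl),
                 tolerance = 1e-9)
  }
})

test_that("negative integrals are floored at zero with a warning", {
  n <- 1024
  s <- spectrum1d(seq(8, 0, length.out = n),
                  -exp(-(seq(8, 0, length.out = n) - 4)^2 / 0.01))
  win <- peak_window("w", 3.5, 4.5, 4)
  expect_warning(a <- integrate_window(s, win, baseline = FALSE), "floored")
  expect_equal(a, 0)
})

test_that("FWHM matches analytic lineshape widths and scales to Hz", {
  g <- 0.02
  s <- lorentzian_spectrum(4, g, area = 1)
  step <- abs(diff(s$ppm[1:2]))
  est <- peak_fwhm(s, peak_window("w", 3.5, 4.5, 4))
  expect_equal(est$fwhm_ppm, 2 * g, tolerance = step)
  expect_equal(est$fwhm_hz, est$fwhm_ppm * s$spectrometer_freq)

  sg <- gaussian_spectrum(4, 0.01)
  estg <- peak_fwhm(sg, peak_window("w", 3.5, 4.5, 4))
  expect_equal(estg$fwhm_ppm, 2 * sqrt(2 * log(2)) * 0.01,
               tolerance = abs(diff(sg$ppm[1:2])))

  # grid refinement: the one-grid-step error bound halves with density
  for (n in c(4096, 8192)) {
    sn <- lorentzian_spectrum(4, g, area = 1, n = n)
    err <- abs(peak_fwhm(sn, peak_window("w", 3.5, 4.5, 4))$fwhm_ppm - 2 * g)
    expect_lt(err, abs(diff(sn$ppm[1:2])))
  }

  expect_error(peak_fwhm(lorentzian_spectrum(4, 0.5),
                         peak_window("w", 3.9, 4.1, 4)),
               "estimation error")
})

test_that("total area adds over disjoint lines and honors exclusions", {
  zero <- spectrum1d(seq(8, 0, length.out = 1024), numeric(1024))
  expect_equal(total_area(zero, list()), 0)

  s1 <- lorentzian_spectrum(2, 0.005, area = 1)
  s2 <- lorentzian_spectrum(6, 0.005, area = 3)
  both <- s1
  both$intensity <- s1$intensity + s2$intensity
  expect_equal(total_area(both, list()),
               total_area(s1, list()) + total_area(s2, list()),
               tolerance = 1e-9)
  expect_equal(total_area(both, list()), 4, tolerance = 0.01)

  # excluding the window holding all signal leaves ~nothing
  expect_lt(total_area(s1, list(peak_window("all", 0.5, 3.5, 2))), 0.02)

  # hr_nmr default exclusion is the chloroform reference window
  excl <- default_exclusions(s1)
  expect_equal(excl[[1]]$peak_id, "ref_chcl3")
})
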