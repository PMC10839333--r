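# Spectrum simulator: Lorentzian lines at catalog shifts, amplitudes solved
# against the package's own window integration so that integrating a
# simulated spectrum returns the analytic proton-stoichiometry areas.

#' Analytic expected peak areas of a mixture
#'
#' The exact closed-form oracle behind the simulator: the area of each
#' catalog resonance is `scale * sum(concentration * protons contributed)`,
#' with the acyl-chain pool given by the class concentrations times the
#' chains each molecule carries, split over species by mole fraction. No
#' lineshape is involved.
#'
#' @param mix A [lipid_mixture()].
#' @param scale Area per proton-mM (arbitrary unit; default 1).
#' @return A [peak_table()] over all catalog peak ids.
#' @export
#' @examples
#' oleate_only <- lipid_mixture(class_concentrations = c(FA = 1),
#'                              species_fractions = c(oleate = 1))
#' expected_peak_areas(oleate_only)
expected_peak_areas <- function(mix, scale = 1) {
  stopifnot(inherits(mix, "lipid_mixture"))
  cat_df <- lipid_line_catalog()
  areas <- stats::setNames(numeric(nrow(cat_df)), cat_df$peak_id)
  conc <- mix$class_concentrations
  # headgroup / class-specific lines
  areas["tg_glycerol_41"] <- 2 * conc[["TG"]]
  areas["tg_glycerol_43"] <- 2 * conc[["TG"]]
  areas["choline"] <- 9 * conc[["PC_LPC"]]
  areas["pe_ch2"] <- 2 * conc[["PE"]]
  areas["tc_ch3"] <- 3 * conc[["TC"]]
  # pooled acyl chains
  chain_conc <- sum(conc * chains_per_molecule()[names(conc)])
  if (chain_conc > 0) {
    for (nm in names(mix$species)) {
      c_s <- chain_conc * mix$species_fractions[[nm]]
      if (c_s == 0) next
      pp <- chain_proton_partition(mix$species[[nm]])
      areas[names(pp)] <- areas[names(pp)] + c_s * pp
    }
  }
  peak_table(names(areas), unname(areas) * scale, source = "expected")
}

# internal: unit-area Lorentzian (possibly a multiplet with weights)
.render_line <- function(x, centers, hwhm, area = 1,
                         weights = rep(1, length(centers))) {
  weights <- weights / sum(weights)
  y <- 0
  for (k in seq_along(centers)) {
    y <- y + weights[k] * (area / pi) * hwhm /
      ((x - centers[k])^2 + hwhm^2)
  }
  y
}

# internal: response matrix M[i, j] = baseline-corrected window integral of
# window i when unit-area line j is rendered on the given axis. Solving
# M a = t makes the pipeline's own integration return the target areas t.
.window_response_matrix <- function(ppm, lines, windows) {
  stub <- structure(list(ppm = ppm, intensity = numeric(length(ppm)),
                         spectrometer_freq = 1, acquisition = NULL,
                         label = "", modality = "hr_nmr"),
                    class = "spectrum1d")
  m <- matrix(0, nrow = length(windows), ncol = length(lines),
              dimnames = list(names(windows), names(lines)))
  for (j in seq_along(lines)) {
    ln <- lines[[j]]
    stub$intensity <- .render_line(ppm, ln$centers, ln$hwhm)
    for (i in seq_along(windows)) {
      m[i, j] <- .trapz_window(stub, windows[[i]], baseline = TRUE)
    }
  }
  m
}

.calib_cache <- new.env(parent = emptyenv())

.solve_amplitudes <- function(ppm, lines, windows, targets, cache_key) {
  m <- if (!is.null(cache_key) && exists(cache_key, envir = .calib_cache)) {
    get(cache_key, envir = .calib_cache)
  } else {
    mm <- .window_response_matrix(ppm, lines, windows)
    if (!is.null(cache_key)) assign(cache_key, mm, envir = .calib_cache)
    mm
  }
  as.numeric(solve(m, targets))
}

#' Simulate a high-resolution extract spectrum
#'
#' Renders Lorentzian lines at the catalog shifts with amplitudes calibrated
#' so that [integrate_window()] over each catalog window recovers exactly the
#' areas of [expected_peak_areas()] scaled by the acquisition factor: the
#' rendered signal is proportional to `RG * NS / (T * P1)`, i.e. `1/m`, so
#' that external-standard quantification inverts it. A chloroform reference
#' line is placed at 7.26 ppm. Gaussian noise is added with standard
#' deviation `noise_sd * max(signal)`.
#'
#' @param mix A [lipid_mixture()].
#' @param acq [acquisition_params()] of the virtual acquisition.
#' @param noise_sd Noise standard deviation as a fraction of the maximum
#'   clean signal (0 = noiseless). An SNR of 50 corresponds to 0.02.
#' @param axis_points Number of axis points (>= 2048; default 32768).
#' @param seed Integer seed; required when `noise_sd > 0`.
#' @param hwhm Lorentzian half width at half maximum in ppm (default 0.005).
#' @param scale Area per proton-mM passed to [expected_peak_areas()].
#' @param ppm_range Axis range (low, high) in ppm.
#' @param ref_area Target area of the chloroform reference line (before
#'   acquisition scaling).
#' @param label Sample label.
#'
#' @return A [spectrum1d()] with modality `"hr_nmr"`.
#' @export
#' @examples
#' s <- simulate_extract_spectrum(lipid_mixture(), seed = 7)
#' integrate_window(s, catalog_windows("bulk_ch2")[[1]])
simulate_extract_spectrum <- function(mix,
                                      acq = acquisition_params(),
                                      noise_sd = 0,
                                      axis_points = 32768,
                                      seed = NULL,
                                      hwhm = 0.005,
                                      scale = 1,
                                      ppm_range = c(-0.5, 8.0),
                                      ref_area = 10,
                                      label = "simulated extract") {
  stopifnot(inherits(mix, "lipid_mixture"))
  if (axis_points < 2048) stop("axis_points must be >= 2048", call. = FALSE)
  if (noise_sd > 0 && is.null(seed)) {
    stop("a seed is required for noisy simulation", call. = FALSE)
  }
  ppm <- seq(ppm_range[2L], ppm_range[1L], length.out = axis_points)
  cat_df <- lipid_line_catalog()
  windows <- catalog_windows()
  windows$ref_chcl3 <- peak_window("ref_chcl3", 7.16, 7.36, 7.26)
  lines <- lapply(seq_len(nrow(cat_df)), function(i) {
    list(centers = cat_df$center[i], hwhm = hwhm)
  })
  names(lines) <- cat_df$peak_id
  lines$ref_chcl3 <- list(centers = 7.26, hwhm = hwhm)

  m_fac <- acquisition_factor(acq)
  exp_areas <- expected_peak_areas(mix, scale = scale)
  targets <- c(peak_area(exp_areas, cat_df$peak_id), ref_area) / m_fac
  key <- sprintf("hr|%d|%.6f|%.6f|%.6f", axis_points,
                 ppm_range[1L], ppm_range[2L], hwhm)
  amps <- .solve_amplitudes(ppm, lines, windows, targets, key)

  y <- numeric(axis_points)
  for (j in seq_along(lines)) {
    if (amps[j] == 0) next
    y <- y + .render_line(ppm, lines[[j]]$centers, lines[[j]]$hwhm,
                          area = amps[j])
  }
  if (noise_sd > 0) {
    set.seed(seed)
    y <- y + stats::rnorm(axis_points, 0, noise_sd * max(abs(y)))
  }
  spectrum1d(ppm = ppm, intensity = y, spectrometer_freq = 600.13,
             acquisition = acq, label = label, modality = "hr_nmr")
}

#' Simulate a water-suppressed / unsuppressed liver MRS pair
#'
#' The unsuppressed spectrum is a water Lorentzian at 4.7 ppm with the
#' requested full width at half maximum (in Hz at the MRS field) and unit
#' window area, plus acyl-chain and TG-glycerol lipid lines whose bulk
#' methylene (1.3 ppm) window area equals `lipid_fraction` times the water
#' window area. The suppressed spectrum contains the same lipid lines with
#' the water attenuated by a factor 1000. Lipid line areas follow the
#' mixture's proton stoichiometry (so composition indices are recoverable);
#' headgroup lines other than TG glycerol are not rendered, mirroring their
#' invisibility in vivo.
#'
#' @param lipid_fraction Ratio of bulk-methylene to water window areas
#'   (the intrahepatic lipid content being simulated), >= 0. When `NULL`,
#'   the lipid lines are instead scaled absolutely: each line's window area
#'   is `lipid_scale` times its [expected_peak_areas()] value, so doubling a
#'   mixture concentration doubles the corresponding areas.
#' @param mix A [lipid_mixture()] giving the relative lipid-line pattern.
#' @param water_fwhm_hz Water line full width at half maximum (Hz, > 0).
#' @param seed Integer seed for the noise.
#' @param noise_sd Noise standard deviation as a fraction of the maximum
#'   clean unsuppressed signal; the same absolute noise level is applied to
#'   both members of the pair (one receiver chain).
#' @param axis_points Number of axis points (default 8192).
#' @param lipid_hwhm Lorentzian half width of the lipid lines in ppm
#'   (default 0.025, i.e. FWHM 0.05: in vivo lines are broad).
#' @param lipid_scale Window area per proton-mM in absolute mode
#'   (`lipid_fraction = NULL`), relative to the unit water window area.
#' @param ppm_range Axis range in ppm.
#' @param spectrometer_freq MRS proton frequency in MHz (default 300.3, a
#'   7 T magnet).
#' @param label Sample label prefix.
#'
#' @return A list with elements `suppressed` and `unsuppressed`, both
#'   [spectrum1d()] objects.
#' @export
#' @examples
#' pair <- simulate_liver_mrs_pair(0.082, water_fwhm_hz = 60, seed = 3)
#' compute_ihlc(pair$unsuppressed)
simulate_liver_mrs_pair <- function(lipid_fraction,
                                    mix = lipid_mixture(),
                                    water_fwhm_hz = 40,
                                    seed = NULL,
                                    noise_sd = 5e-4,
                                    axis_points = 8192,
                                    lipid_hwhm = 0.025,
                                    ppm_range = c(0, 6.5),
                                    spectrometer_freq = 300.3,
                                    lipid_scale = 0.002,
                                    label = "simulated liver voxel") {
  stopifnot(is.null(lipid_fraction) || lipid_fraction >= 0,
            water_fwhm_hz > 0)
  if (noise_sd > 0 && is.null(seed)) {
    stop("a seed is required for noisy simulation", call. = FALSE)
  }
  ppm <- seq(ppm_range[2L], ppm_range[1L], length.out = axis_points)
  wins <- mrs_windows()
  water_hwhm <- water_fwhm_hz / (2 * spectrometer_freq)

  # water line calibrated to unit area in its own window
  stub <- structure(list(ppm = ppm, intensity = numeric(axis_points),
                         spectrometer_freq = spectrometer_freq,
                         acquisition = NULL, label = "",
                         modality = "mrs_unsuppressed"),
                    class = "spectrum1d")
  water_unit <- .render_line(ppm, 4.7, water_hwhm)
  stub$intensity <- water_unit
  water_resp <- .trapz_window(stub, wins$water, baseline = TRUE)
  y_water <- water_unit / water_resp

  # lipid lines calibrated jointly over the MRS lipid windows
  lipid_ids <- c("olefinic", "tg_glycerol_43", "tg_glycerol_41",
                 "diallylic", "alpha_carboxyl", "allylic", "beta_carboxyl",
                 "bulk_ch2", "omega3_ch3", "fa_ch3")
  y_lipid <- numeric(axis_points)
  exp_areas <- expected_peak_areas(mix)
  pat <- peak_area(exp_areas, lipid_ids)
  if (is.null(lipid_fraction)) {
    targets <- pat * lipid_scale             # absolute mode
  } else if (lipid_fraction > 0) {
    bulk <- pat[lipid_ids == "bulk_ch2"]
    if (bulk <= 0) {
      stop("mixture has no bulk methylene signal; cannot set lipid_fraction",
           call. = FALSE)
    }
    targets <- pat / bulk * lipid_fraction   # water window area is 1
  } else {
    targets <- numeric(length(pat))          # lipid_fraction == 0
  }
  if (any(targets != 0)) {
    cat_df <- lipid_line_catalog()
    lines <- lapply(lipid_ids, function(id) {
      list(centers = cat_df$center[cat_df$peak_id == id], hwhm = lipid_hwhm)
    })
    names(lines) <- lipid_ids
    key <- sprintf("mrs|%d|%.6f|%.6f|%.6f", axis_points,
                   ppm_range[1L], ppm_range[2L], lipid_hwhm)
    amps <- .solve_amplitudes(ppm, lines, wins[lipid_ids], targets, key)
    for (j in seq_along(lines)) {
      if (amps[j] == 0) next
      y_lipid <- y_lipid + .render_line(ppm, lines[[j]]$centers,
                                        lines[[j]]$hwhm, area = amps[j])
    }
  }

  clean_unsup <- y_water + y_lipid
  clean_sup <- y_water / 1000 + y_lipid
  sigma <- noise_sd * max(abs(clean_unsup))
  if (noise_sd > 0) set.seed(seed)
  noise1 <- if (noise_sd > 0) stats::rnorm(axis_points, 0, sigma) else 0
  noise2 <- if (noise_sd > 0) stats::rnorm(axis_points, 0, sigma) else 0
  acq <- acquisition_params()
  list(
    suppressed = spectrum1d(ppm, clean_sup + noise1,
                            spectrometer_freq = spectrometer_freq,
                            acquisition = acq,
                            label = paste(label, "(suppressed)"),
                            modality = "mrs_suppressed"),
    unsuppressed = spectrum1d(ppm, clean_unsup + noise2,
                              spectrometer_freq = spectrometer_freq,
                              acquisition = acq,
                              label = paste(label, "(unsuppressed)"),
                              modality = "mrs_unsuppressed")
  )
}
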