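# In vivo liver MRS measurands: intrahepatic lipid content, TG glycerol
# index, fatty-acid composition indices and the water-FWHM iron proxy.

#' Integration windows for in vivo MRS spectra
#'
#' Broader than the extract-spectrum catalog windows because in vivo lines
#' are wide (default simulated FWHM 0.05 ppm). Water is integrated over
#' 4.2-5.2 ppm and the bulk methylene over 1.15-1.45 ppm; the TG glycerol
#' windows sit at 4.05-4.15 and 4.25-4.35 ppm. All are configuration, not
#' measurements: override by passing modified windows to the compute
#' functions.
#'
#' @return A named list of [peak_window()] objects.
#' @export
mrs_windows <- function() {
  list(
    water          = peak_window("water", 4.20, 5.20, 4.70),
    olefinic       = peak_window("olefinic", 5.21, 5.45, 5.30),
    tg_glycerol_43 = peak_window("tg_glycerol_43", 4.25, 4.35, 4.30),
    tg_glycerol_41 = peak_window("tg_glycerol_41", 4.05, 4.15, 4.10),
    diallylic      = peak_window("diallylic", 2.66, 2.94, 2.80),
    alpha_carboxyl = peak_window("alpha_carboxyl", 2.14, 2.38, 2.25),
    allylic        = peak_window("allylic", 1.88, 2.12, 2.02),
    beta_carboxyl  = peak_window("beta_carboxyl", 1.46, 1.74, 1.60),
    bulk_ch2       = peak_window("bulk_ch2", 1.15, 1.45, 1.30),
    omega3_ch3     = peak_window("omega3_ch3", 0.94, 1.10, 0.98),
    fa_ch3         = peak_window("fa_ch3", 0.70, 0.94, 0.90)
  )
}

#' Intrahepatic lipid content from an unsuppressed spectrum
#'
#' The ratio of the bulk methylene `(-CH2-)n` window integral (~1.3 ppm) to
#' the water window integral (~4.7 ppm) of a water-unsuppressed voxel
#' spectrum, both baseline-corrected.
#'
#' @param unsuppressed A [spectrum1d()] with modality `"mrs_unsuppressed"`.
#' @param windows Window set; default [mrs_windows()] (`water`, `bulk_ch2`).
#' @return The dimensionless lipid/water area ratio.
#' @export
#' @examples
#' pair <- simulate_liver_mrs_pair(0.041, water_fwhm_hz = 40, seed = 11)
#' compute_ihlc(pair$unsuppressed)
compute_ihlc <- function(unsuppressed, windows = mrs_windows()) {
  stopifnot(inherits(unsuppressed, "spectrum1d"))
  if (unsuppressed$modality != "mrs_unsuppressed") {
    stop("compute_ihlc needs a water-unsuppressed MRS spectrum",
         call. = FALSE)
  }
  a_lip <- integrate_window(unsuppressed, windows$bulk_ch2, warn = FALSE)
  a_wat <- integrate_window(unsuppressed, windows$water, warn = FALSE)
  if (a_wat <= 0) {
    stop("division error: water peak area is zero (failed acquisition?)",
         call. = FALSE)
  }
  a_lip / a_wat
}

#' Triglyceride index from a water-suppressed spectrum
#'
#' `(A_4.3ppm + A_4.1ppm) / 4`, the sum of the two glycerol backbone
#' methylene areas divided by their 4 protons.
#'
#' @param suppressed A [spectrum1d()] with modality `"mrs_suppressed"`.
#' @param windows Window set; default [mrs_windows()].
#' @return The TG index in area units.
#' @export
compute_tg_index <- function(suppressed, windows = mrs_windows()) {
  stopifnot(inherits(suppressed, "spectrum1d"))
  if (suppressed$modality != "mrs_suppressed") {
    stop("compute_tg_index needs a water-suppressed MRS spectrum",
         call. = FALSE)
  }
  a43 <- integrate_window(suppressed, windows$tg_glycerol_43, warn = FALSE)
  a41 <- integrate_window(suppressed, windows$tg_glycerol_41, warn = FALSE)
  (a43 + a41) / 4
}

#' Define a fatty-acid composition index
#'
#' An index is `offset + sum(num coeff * area) / sum(den coeff * area)`, with
#' peak areas looked up by id in a [peak_table()].
#'
#' @param name Index name.
#' @param numerator Named numeric vector of peak coefficients.
#' @param denominator Named numeric vector of peak coefficients (not all
#'   zero).
#' @param offset Additive constant (default 0).
#' @param floor_zero Floor the result at 0 (used for MUFA)?
#' @return An object of class `index_definition`.
#' @export
index_definition <- function(name, numerator, denominator, offset = 0,
                             floor_zero = FALSE) {
  stopifnot(is.numeric(numerator), is.numeric(denominator),
            !is.null(names(numerator)) || length(numerator) == 0,
            !is.null(names(denominator)))
  if (all(denominator == 0)) {
    stop("denominator must not be identically zero", call. = FALSE)
  }
  if (any(!is.finite(c(numerator, denominator, offset)))) {
    stop("coefficients must be finite", call. = FALSE)
  }
  structure(list(name = name, numerator = numerator,
                 denominator = denominator, offset = offset,
                 floor_zero = isTRUE(floor_zero)),
            class = "index_definition")
}

#' Default fatty-acid composition index definitions
#'
#' Proton-stoichiometric definitions of the standard unsaturation and chain
#' indices, with `A_x` the window area at x ppm and the chain count taken
#' from the terminal methyls (3 protons per chain, 0.90 plus 0.98 ppm):
#'
#' * `ndb  = 1.5 * A_5.3 / A_CH3` — double bonds per chain (2 olefinic
#'   protons each).
#' * `SI   = A_1.3 / A_5.3` — saturation index, bulk methylene per olefinic.
#' * `UFA  = 0.75 * A_2.0 / A_CH3` — unsaturated chain fraction (4 allylic
#'   protons per unsaturated chain).
#' * `SFA  = 1 - UFA`.
#' * `PUFA = 1.5 * A_2.8 / A_CH3` — diallylic methylenes per chain.
#' * `MUFA = UFA - PUFA`, floored at 0.
#' * `MCL  = (1.5 * (A_1.3 + A_1.6 + A_2.0 + A_2.25 + A_2.8) + 3 * A_5.3) /
#'   A_CH3 + 2` — mean chain length: half a carbon per methylene proton, one
#'   per olefinic proton, plus the carboxyl and methyl carbons.
#'
#' These are configuration data, not fixed code: pass your own list of
#' [index_definition()]s to [compute_fa_indices()] to change them.
#'
#' @return Named list of [index_definition()] objects.
#' @export
default_index_definitions <- function() {
  ch3 <- c(fa_ch3 = 1, omega3_ch3 = 1)
  ch2_all <- c(bulk_ch2 = 1.5, beta_carboxyl = 1.5, allylic = 1.5,
               alpha_carboxyl = 1.5, diallylic = 1.5, olefinic = 3)
  list(
    ndb  = index_definition("ndb", c(olefinic = 1.5), ch3),
    SI   = index_definition("SI", c(bulk_ch2 = 1), c(olefinic = 1)),
    UFA  = index_definition("UFA", c(allylic = 0.75), ch3),
    SFA  = index_definition("SFA", c(allylic = -0.75), ch3, offset = 1),
    PUFA = index_definition("PUFA", c(diallylic = 1.5), ch3),
    MUFA = index_definition("MUFA", c(allylic = 0.75, diallylic = -1.5),
                            ch3, floor_zero = TRUE),
    MCL  = index_definition("MCL", ch2_all, ch3, offset = 2)
  )
}

#' Compute fatty-acid composition indices from a peak table
#'
#' Each index is evaluated as `offset + num / den` on the supplied areas. An
#' index whose denominator evaluates to zero is reported as `NA` (missing),
#' never as zero, and propagates as missing through the statistics layer.
#'
#' @param peaks A [peak_table()] containing every peak id referenced.
#' @param defs List of [index_definition()];
#'   default [default_index_definitions()].
#' @return A named numeric vector of index values (with `NA` for undefined).
#' @export
#' @examples
#' oleate <- expected_peak_areas(lipid_mixture(
#'   class_concentrations = c(FA = 1), species_fractions = c(oleate = 1)))
#' compute_fa_indices(oleate)
compute_fa_indices <- function(peaks, defs = default_index_definitions()) {
  stopifnot(inherits(peaks, "peak_table"))
  out <- stats::setNames(numeric(length(defs)),
                         vapply(defs, `[[`, "", "name"))
  for (k in seq_along(defs)) {
    d <- defs[[k]]
    num <- sum(d$numerator * peak_area(peaks, names(d$numerator)))
    den <- sum(d$denominator * peak_area(peaks, names(d$denominator)))
    v <- if (den == 0) NA_real_ else d$offset + num / den
    if (!is.na(v) && d$floor_zero) v <- max(v, 0)
    out[k] <- v
  }
  out
}

#' Integrate a suppressed MRS spectrum into a peak table
#'
#' Convenience wrapper: integrates the water-suppressed spectrum over the
#' MRS lipid windows, returning the [peak_table()] that feeds
#' [compute_fa_indices()] and [compute_tg_index()].
#'
#' @param suppressed A [spectrum1d()] with modality `"mrs_suppressed"`.
#' @param windows Window set; default [mrs_windows()] without `water`.
#' @return A [peak_table()].
#' @export
mrs_peak_table <- function(suppressed, windows = mrs_windows()) {
  stopifnot(inherits(suppressed, "spectrum1d"))
  windows <- windows[setdiff(names(windows), "water")]
  areas <- vapply(windows, function(w) {
    integrate_window(suppressed, w, warn = FALSE)
  }, 0)
  peak_table(names(windows), areas, source = suppressed$label)
}

#' Water-line FWHM as an iron-load proxy
#'
#' Paramagnetic iron shortens T2 and broadens the water resonance; the full
#' width at half maximum of the water line in an unsuppressed voxel spectrum
#' therefore indirectly reflects hepatic iron. Delegates to [peak_fwhm()] on
#' the water window; both ppm and Hz are reported.
#'
#' @param unsuppressed A [spectrum1d()] with modality `"mrs_unsuppressed"`.
#' @param window Water window; default from [mrs_windows()].
#' @return An object of class `fwhm_estimate`.
#' @export
water_fwhm_iron_proxy <- function(unsuppressed,
                                  window = mrs_windows()$water) {
  stopifnot(inherits(unsuppressed, "spectrum1d"))
  if (unsuppressed$modality != "mrs_unsuppressed") {
    stop("the iron proxy needs a water-unsuppressed MRS spectrum",
         call. = FALSE)
  }
  peak_fwhm(unsuppressed, window)
}

#' All MRS measurands of a spectrum pair
#'
#' @param suppressed,unsuppressed The MRS spectrum pair.
#' @param defs Index definitions; default [default_index_definitions()].
#' @param windows Window set; default [mrs_windows()].
#' @return A list with `ihlc`, `tg_index`, `indices` (named vector) and
#'   `water_fwhm_hz`.
#' @export
mrs_measurands <- function(suppressed, unsuppressed,
                           defs = default_index_definitions(),
                           windows = mrs_windows()) {
  peaks <- mrs_peak_table(suppressed, windows)
  list(ihlc = compute_ihlc(unsuppressed, windows),
       tg_index = compute_tg_index(suppressed, windows),
       indices = compute_fa_indices(peaks, defs),
       water_fwhm_hz = water_fwhm_iron_proxy(unsuppressed,
                                             windows$water)$fwhm_hz)
}
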