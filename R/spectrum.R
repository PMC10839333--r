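#' Acquisition parameters of a 1D spectrum
#'
#' Bundles the acquisition settings that enter the external-standard
#' normalization factor: temperature `T` (K), number of scans `NS`, 90-degree
#' pulse length `P1` (microseconds) and receiver gain `RG` (dimensionless).
#' All must be strictly positive.
#'
#' @param temperature Sample temperature in Kelvin.
#' @param NS Number of scans (transients) accumulated.
#' @param P1 90-degree pulse length in microseconds.
#' @param RG Receiver gain (dimensionless).
#'
#' @return An object of class `acquisition_params` (a named list).
#' @seealso [acquisition_factor()]
#' @export
#' @examples
#' acquisition_params(temperature = 298, NS = 128, P1 = 10, RG = 64)
acquisition_params <- function(temperature = 298, NS = 128, P1 = 10, RG = 64) {
  vals <- c(temperature = temperature, NS = NS, P1 = P1, RG = RG)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all acquisition parameters must be finite and > 0", call. = FALSE)
  }
  if (NS != round(NS)) stop("NS must be a positive integer", call. = FALSE)
  structure(list(temperature = temperature, NS = as.integer(NS),
                 P1 = P1, RG = RG),
            class = "acquisition_params")
}

#' @export
print.acquisition_params <- function(x, ...) {
  cat(sprintf("<acquisition_params> T = %g K, NS = %d, P1 = %g us, RG = %g\n",
              x$temperature, x$NS, x$P1, x$RG))
  invisible(x)
}

#' Construct a 1D spectrum
#'
#' The universal carrier for both high-resolution NMR of tissue extracts and
#' in vivo MRS voxel spectra: a chemical-shift axis in ppm, matched
#' intensities, the proton Larmor frequency, acquisition metadata and a
#' modality tag. The axis is stored descending (standard NMR display order);
#' ascending input is reversed together with its intensities.
#'
#' @param ppm Chemical-shift axis (ppm), strictly monotone, length >= 2.
#' @param intensity Signal amplitudes (arbitrary units), same length as `ppm`.
#' @param spectrometer_freq Proton Larmor frequency in MHz (> 0). Defaults to
#'   600.13 for `hr_nmr` and 300.3 for the MRS modalities.
#' @param acquisition An [acquisition_params()] object, or `NULL` if unknown
#'   (flagged missing; absolute quantification then refuses to run).
#' @param label Free-text sample identifier.
#' @param modality One of `"hr_nmr"`, `"mrs_suppressed"`, `"mrs_unsuppressed"`.
#'
#' @return An object of class `spectrum1d`.
#' @export
#' @examples
#' s <- spectrum1d(ppm = c(3, 2, 1), intensity = c(0, 1, 0))
#' s$ppm
spectrum1d <- function(ppm, intensity,
                       spectrometer_freq = NULL,
                       acquisition = NULL,
                       label = "",
                       modality = c("hr_nmr", "mrs_suppressed",
                                    "mrs_unsuppressed")) {
  modality <- match.arg(modality)
  ppm <- as.numeric(ppm)
  intensity <- as.numeric(intensity)
  if (length(ppm) < 2L) stop("axis must have length >= 2", call. = FALSE)
  if (length(ppm) != length(intensity)) {
    stop("ppm axis and intensity must have equal length", call. = FALSE)
  }
  if (any(!is.finite(ppm))) stop("ppm axis must be finite", call. = FALSE)
  d <- diff(ppm)
  if (all(d > 0)) {            # stored ascending: flip to display order
    ppm <- rev(ppm)
    intensity <- rev(intensity)
  } else if (!all(d < 0)) {
    stop("ppm axis must be strictly monotone", call. = FALSE)
  }
  if (is.null(spectrometer_freq)) {
    spectrometer_freq <- if (modality == "hr_nmr") 600.13 else 300.3
  }
  if (!is.finite(spectrometer_freq) || spectrometer_freq <= 0) {
    stop("spectrometer_freq must be > 0", call. = FALSE)
  }
  if (!is.null(acquisition) && !inherits(acquisition, "acquisition_params")) {
    stop("acquisition must be an acquisition_params object or NULL",
         call. = FALSE)
  }
  structure(list(ppm = ppm, intensity = intensity,
                 spectrometer_freq = spectrometer_freq,
                 acquisition = acquisition,
                 label = as.character(label)[1L],
                 modality = modality),
            class = "spectrum1d")
}

#' @export
print.spectrum1d <- function(x, ...) {
  cat(sprintf("<spectrum1d> %s, %d points, %.4f .. %.4f ppm @ %.2f MHz%s\n",
              x$modality, length(x$ppm), x$ppm[1L], x$ppm[length(x$ppm)],
              x$spectrometer_freq,
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  if (is.null(x$acquisition)) {
    cat("  acquisition metadata: missing\n")
  } else {
    cat("  "); print(x$acquisition)
  }
  invisible(x)
}

#' Define a named integration window
#'
#' Windows are always given as `(lo, hi)` with `lo < hi` in ppm, independent
#' of the descending storage order of the axis.
#'
#' @param peak_id Symbolic name, e.g. `"fa_ch3"`.
#' @param ppm_lo,ppm_hi Window bounds in ppm, `ppm_lo < ppm_hi`.
#' @param nominal_center Nominal resonance position; must lie inside the
#'   window. Defaults to the midpoint.
#'
#' @return An object of class `peak_window`.
#' @export
peak_window <- function(peak_id, ppm_lo, ppm_hi,
                        nominal_center = (ppm_lo + ppm_hi) / 2) {
  if (!(ppm_lo < ppm_hi)) stop("ppm_lo must be < ppm_hi", call. = FALSE)
  if (!(ppm_lo < nominal_center && nominal_center < ppm_hi)) {
    stop("nominal_center must lie strictly inside the window", call. = FALSE)
  }
  structure(list(peak_id = as.character(peak_id)[1L],
                 ppm_lo = ppm_lo, ppm_hi = ppm_hi,
                 nominal_center = nominal_center),
            class = "peak_window")
}

#' @export
print.peak_window <- function(x, ...) {
  cat(sprintf("<peak_window> %s: %.3f .. %.3f ppm (center %.3f)\n",
              x$peak_id, x$ppm_lo, x$ppm_hi, x$nominal_center))
  invisible(x)
}

#' Build a peak table
#'
#' A peak table maps unique peak identifiers to non-negative integral areas
#' (arbitrary units, after baseline correction). It is the common currency of
#' every index and quantification formula.
#'
#' @param peak_id Character vector of unique identifiers.
#' @param area Numeric vector of finite areas, same length.
#' @param source Label of the originating spectrum.
#'
#' @return A `data.frame` of class `peak_table` with columns `peak_id`, `area`.
#' @export
peak_table <- function(peak_id, area, source = "") {
  peak_id <- as.character(peak_id)
  area <- as.numeric(area)
  if (length(peak_id) != length(area)) {
    stop("peak_id and area must have equal length", call. = FALSE)
  }
  if (anyDuplicated(peak_id)) stop("peak_ids must be unique", call. = FALSE)
  if (any(!is.finite(area))) stop("areas must be finite", call. = FALSE)
  out <- data.frame(peak_id = peak_id, area = area,
                    stringsAsFactors = FALSE)
  attr(out, "source") <- as.character(source)[1L]
  class(out) <- c("peak_table", "data.frame")
  out
}

#' Look up areas in a peak table
#'
#' @param peaks A [peak_table()].
#' @param ids Character vector of peak identifiers.
#' @return Numeric vector of areas (error if any id is absent).
#' @export
peak_area <- function(peaks, ids) {
  i <- match(ids, peaks$peak_id)
  if (anyNA(i)) {
    stop("peak(s) not in table: ", paste(ids[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  peaks$area[i]
}

# internal: grid spacing (positive) of a stored-descending axis
.grid_step <- function(spec) abs(stats::median(diff(spec$ppm)))

# internal: indices of axis points inside [lo, hi]
.window_idx <- function(spec, window) {
  which(spec$ppm >= window$ppm_lo & spec$ppm <= window$ppm_hi)
}

.check_window_in_axis <- function(spec, window) {
  rng <- range(spec$ppm)
  if (window$ppm_lo < rng[1L] || window$ppm_hi > rng[2L]) {
    stop(sprintf("window %s [%.3f, %.3f] outside axis range [%.3f, %.3f]",
                 window$peak_id, window$ppm_lo, window$ppm_hi,
                 rng[1L], rng[2L]), call. = FALSE)
  }
  invisible(TRUE)
}
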