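# Low-level spectral processing: referencing, baseline, integration, FWHM.

# internal: trapezoidal integral of y over ascending x
.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

# internal: baseline-corrected intensities inside a window.
# The baseline is the straight line through the mean of the 3 outermost
# points at each window edge. Returns list(ppm_asc, y_corrected, idx).
.window_baseline <- function(spec, window, n_edge = 3L) {
  idx <- .window_idx(spec, window)
  # axis is descending; work on ascending ppm inside the window
  x <- rev(spec$ppm[idx])
  y <- rev(spec$intensity[idx])
  n <- length(x)
  k <- min(n_edge, n)
  x_lo <- mean(x[seq_len(k)]);           y_lo <- mean(y[seq_len(k)])
  x_hi <- mean(x[seq(n - k + 1L, n)]);   y_hi <- mean(y[seq(n - k + 1L, n)])
  if (x_hi == x_lo) {
    base <- rep(y_lo, n)
  } else {
    slope <- (y_hi - y_lo) / (x_hi - x_lo)
    base <- y_lo + slope * (x - x_lo)
  }
  list(x = x, y = y - base, idx = idx)
}

# internal: raw (possibly negative) window integral, baseline on/off
.trapz_window <- function(spec, window, baseline = TRUE) {
  if (baseline) {
    wb <- .window_baseline(spec, window)
    .trapz(wb$x, wb$y)
  } else {
    idx <- .window_idx(spec, window)
    .trapz(rev(spec$ppm[idx]), rev(spec$intensity[idx]))
  }
}

#' Reference a spectrum to an anchor resonance
#'
#' Rigidly shifts the chemical-shift axis so that the tallest local maximum
#' found within `anchor_ppm +/- search_halfwidth` lands exactly on
#' `anchor_ppm`. Used to pin the chloroform line to 7.26 ppm in extract
#' spectra, or the water line to its nominal position in MRS spectra. Ties
#' between equally tall maxima are broken toward the anchor.
#'
#' @param spec A [spectrum1d()].
#' @param anchor_ppm Target position of the reference resonance (ppm).
#' @param search_halfwidth Half-width of the search window (ppm).
#'
#' @return The shifted spectrum; the applied shift (ppm, added to the axis)
#'   is attached as attribute `"shift_ppm"`.
#' @export
#' @examples
#' s <- simulate_extract_spectrum(lipid_mixture(), seed = 1)
#' s$ppm <- s$ppm + 0.05            # mimic a mis-referenced acquisition
#' r <- reference_to_anchor(s, 7.26)
#' attr(r, "shift_ppm")
reference_to_anchor <- function(spec, anchor_ppm, search_halfwidth = 0.2) {
  stopifnot(inherits(spec, "spectrum1d"))
  win <- peak_window("ref_search", anchor_ppm - search_halfwidth,
                     anchor_ppm + search_halfwidth, anchor_ppm)
  idx <- .window_idx(spec, win)
  if (length(idx) < 3L) {
    stop("referencing error: search window contains fewer than 3 samples",
         call. = FALSE)
  }
  y <- spec$intensity[idx]
  interior <- seq(2L, length(idx) - 1L)
  is_max <- y[interior] >= y[interior - 1L] & y[interior] >= y[interior + 1L] &
    (y[interior] > y[interior - 1L] | y[interior] > y[interior + 1L])
  cand <- interior[is_max]
  if (!length(cand)) {
    stop("referencing error: no local maximum in search window",
         call. = FALSE)
  }
  best <- cand[y[cand] == max(y[cand])]
  if (length(best) > 1L) {               # tie: take the one nearest the anchor
    best <- best[which.min(abs(spec$ppm[idx[best]] - anchor_ppm))]
  }
  peak_ppm <- spec$ppm[idx[best]]
  shift <- anchor_ppm - peak_ppm
  out <- spec
  out$ppm <- spec$ppm + shift
  attr(out, "shift_ppm") <- shift
  out
}

#' Baseline-correct a spectrum within a window
#'
#' Subtracts the straight line through the mean intensity of the 3 outermost
#' points at each window edge; the result is restricted to the window and is
#' intended only as the integrand for [integrate_window()]. This deterministic
#' endpoint rule stands in for interactive baseline handling in commercial
#' integration tools.
#'
#' @param spec A [spectrum1d()].
#' @param window A [peak_window()], inside the axis range.
#'
#' @return A [spectrum1d()] restricted to the window with the local linear
#'   baseline removed.
#' @export
baseline_correct <- function(spec, window) {
  stopifnot(inherits(spec, "spectrum1d"), inherits(window, "peak_window"))
  .check_window_in_axis(spec, window)
  idx <- .window_idx(spec, window)
  if (length(idx) < 2L) {
    stop("range error: window contains fewer than 2 samples", call. = FALSE)
  }
  wb <- .window_baseline(spec, window)
  out <- spec
  out$ppm <- rev(wb$x)          # keep descending storage
  out$intensity <- rev(wb$y)
  out
}

#' Integrate a spectrum over a window
#'
#' Trapezoidal integral of the (optionally baseline-corrected) intensity over
#' ppm. Negative results are nonphysical for the ratio formulas downstream and
#' are floored at 0 with a warning.
#'
#' @param spec A [spectrum1d()].
#' @param window A [peak_window()] with at least 4 samples inside it.
#' @param baseline Apply the linear endpoint baseline first? Default `TRUE`.
#' @param warn Emit the flooring warning? Internal callers that integrate many
#'   noisy near-empty windows set this to `FALSE`.
#'
#' @return The integral area (arbitrary units, >= 0).
#' @export
#' @examples
#' s <- simulate_extract_spectrum(lipid_mixture(), seed = 1)
#' integrate_window(s, peak_window("bulk", 1.15, 1.45))
integrate_window <- function(spec, window, baseline = TRUE, warn = TRUE) {
  stopifnot(inherits(spec, "spectrum1d"), inherits(window, "peak_window"))
  .check_window_in_axis(spec, window)
  if (length(.window_idx(spec, window)) < 4L) {
    stop(sprintf("resolution error: < 4 samples inside window %s",
                 window$peak_id), call. = FALSE)
  }
  a <- .trapz_window(spec, window, baseline = baseline)
  if (a < 0) {
    if (warn) {
      warning(sprintf("negative integral (%.3g) in window %s floored at 0",
                      a, window$peak_id), call. = FALSE)
    }
    a <- 0
  }
  a
}

#' Estimate a peak's full width at half maximum
#'
#' Locates the apex of the dominant maximum inside the window, then finds the
#' half-maximum crossings on each side by linear interpolation between
#' bracketing samples. The raw intensities are used (no baseline removal:
#' subtracting an endpoint baseline from a wide Lorentzian biases its
#' apparent width low). The width is reported both in ppm and in Hz
#' (`fwhm_hz = fwhm_ppm * spectrometer_freq`). The water-line FWHM in
#' unsuppressed liver spectra is the iron-load proxy.
#'
#' @param spec A [spectrum1d()].
#' @param window A [peak_window()] containing a single dominant maximum.
#'
#' @return An object of class `fwhm_estimate`: list with `center_ppm`,
#'   `fwhm_ppm`, `fwhm_hz`.
#' @export
peak_fwhm <- function(spec, window) {
  stopifnot(inherits(spec, "spectrum1d"), inherits(window, "peak_window"))
  .check_window_in_axis(spec, window)
  idx <- .window_idx(spec, window)
  x <- rev(spec$ppm[idx]); y <- rev(spec$intensity[idx])
  n <- length(x)
  if (n < 5L) stop("estimation error: too few samples in window",
                   call. = FALSE)
  apex <- which.max(y)
  ymax <- y[apex]
  if (!(ymax > 0)) stop("estimation error: no positive maximum in window",
                        call. = FALSE)
  half <- ymax / 2
  cross <- function(side) {
    if (side == "left") {
      below <- which(y[seq_len(apex)] <= half)
      if (!length(below)) return(NA_real_)
      i <- max(below)                     # last point at/below half before apex
      if (i == apex) return(NA_real_)
    } else {
      below <- which(y[seq(apex, n)] <= half) + apex - 1L
      if (!length(below)) return(NA_real_)
      i <- min(below) - 1L                # point before first at/below half
      if (i < apex) return(NA_real_)
    }
    j <- i + 1L
    # linear interpolation between samples i and j bracketing the half level
    y1 <- y[i]; y2 <- y[j]
    if (y1 == y2) return((x[i] + x[j]) / 2)
    x[i] + (half - y1) * (x[j] - x[i]) / (y2 - y1)
  }
  xl <- cross("left")
  xr <- cross("right")
  if (is.na(xl) || is.na(xr)) {
    stop("estimation error: half-maximum not bracketed inside window",
         call. = FALSE)
  }
  fwhm_ppm <- xr - xl
  structure(list(center_ppm = x[apex],
                 fwhm_ppm = fwhm_ppm,
                 fwhm_hz = fwhm_ppm * spec$spectrometer_freq),
            class = "fwhm_estimate")
}

#' @export
print.fwhm_estimate <- function(x, ...) {
  cat(sprintf("<fwhm_estimate> center %.3f ppm, FWHM %.4f ppm = %.2f Hz\n",
              x$center_ppm, x$fwhm_ppm, x$fwhm_hz))
  invisible(x)
}

#' Default excluded windows for total-area integration
#'
#' For extract spectra the solvent reference line (chloroform at 7.26 ppm) is
#' excluded; MRS modalities have no default exclusion.
#'
#' @param spec A [spectrum1d()].
#' @return A list of [peak_window()] objects (possibly empty).
#' @export
default_exclusions <- function(spec) {
  if (spec$modality == "hr_nmr") {
    list(peak_window("ref_chcl3", 7.16, 7.36, 7.26))
  } else {
    list()
  }
}

#' Total spectral area outside excluded windows
#'
#' Trapezoidal integral over the full axis minus the integrals over the
#' excluded windows (no baseline correction: the quantity is the whole-profile
#' area used for total lipid content and total-area normalization).
#'
#' @param spec A [spectrum1d()].
#' @param exclusions List of [peak_window()]; defaults to
#'   [default_exclusions()] of the spectrum.
#'
#' @return The total area (floored at 0).
#' @export
total_area <- function(spec, exclusions = default_exclusions(spec)) {
  stopifnot(inherits(spec, "spectrum1d"))
  full <- .trapz(rev(spec$ppm), rev(spec$intensity))
  excl <- 0
  for (w in exclusions) {
    .check_window_in_axis(spec, w)
    excl <- excl + .trapz_window(spec, w, baseline = FALSE)
  }
  max(full - excl, 0)
}
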