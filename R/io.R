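# Spectrum and peak-table I/O: a TSV dialect and minimal JCAMP-DX.
#
# TSV dialect: two tab-separated numeric columns "ppm", "intensity"; leading
# '#'-prefixed lines carry metadata as key=value pairs.
#
# JCAMP-DX: AFFN-encoded ##XYPOINTS=(XY..XY) is written; both XYPOINTS and
# uncompressed ##XYDATA=(X++(Y..Y)) are read (DIF/DUP/SQZ vendor compression
# is not supported).

.meta_keys <- c("spectrometer_freq", "modality", "label",
                "temperature", "NS", "P1", "RG")

.spectrum_meta <- function(spec) {
  m <- list(spectrometer_freq = spec$spectrometer_freq,
            modality = spec$modality, label = spec$label)
  if (!is.null(spec$acquisition)) {
    m <- c(m, spec$acquisition[c("temperature", "NS", "P1", "RG")])
  }
  m
}

.assemble_spectrum <- function(ppm, intensity, meta, path) {
  acq <- NULL
  have <- c("temperature", "NS", "P1", "RG") %in% names(meta)
  if (all(have)) {
    acq <- acquisition_params(temperature = as.numeric(meta$temperature),
                              NS = as.numeric(meta$NS),
                              P1 = as.numeric(meta$P1),
                              RG = as.numeric(meta$RG))
  }
  spectrum1d(ppm = ppm, intensity = intensity,
             spectrometer_freq = if (!is.null(meta$spectrometer_freq))
               as.numeric(meta$spectrometer_freq) else NULL,
             acquisition = acq,
             label = if (!is.null(meta$label)) meta$label else basename(path),
             modality = if (!is.null(meta$modality)) meta$modality
             else "hr_nmr")
}

#' Read a 1D spectrum from disk
#'
#' @param path Path to the file.
#' @param format `"tsv"` (two-column dialect with `#` key=value header lines)
#'   or `"jcamp_dx"`.
#'
#' @return A [spectrum1d()] with a descending ppm axis (ascending files are
#'   reordered). Acquisition metadata is populated from the header when all
#'   four fields (temperature, NS, P1, RG) are present, otherwise left `NULL`
#'   (flagged missing on print).
#' @export
read_spectrum <- function(path, format = c("tsv", "jcamp_dx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format,
         tsv = .read_spectrum_tsv(path),
         jcamp_dx = .read_spectrum_jcamp(path))
}

#' Write a 1D spectrum to disk
#'
#' Lossless to at least 9 significant digits; output is re-readable by
#' [read_spectrum()].
#'
#' @param spec A [spectrum1d()].
#' @param path Destination path.
#' @param format `"tsv"` or `"jcamp_dx"`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path, format = c("tsv", "jcamp_dx")) {
  stopifnot(inherits(spec, "spectrum1d"))
  format <- match.arg(format)
  switch(format,
         tsv = .write_spectrum_tsv(spec, path),
         jcamp_dx = .write_spectrum_jcamp(spec, path))
  invisible(path)
}

.write_spectrum_tsv <- function(spec, path) {
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("I/O error: cannot open ", path,
                                           call. = FALSE))
  on.exit(close(con))
  meta <- .spectrum_meta(spec)
  for (k in names(meta)) {
    writeLines(sprintf("# %s=%s", k, format(meta[[k]], digits = 12)), con)
  }
  writeLines("ppm\tintensity", con)
  writeLines(sprintf("%.17g\t%.17g", spec$ppm, spec$intensity), con)
}

.read_spectrum_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^#", lines[i])) {
    kv <- sub("^#\\s*", "", lines[i])
    m <- regmatches(kv, regexec("^([^=]+)=(.*)$", kv))[[1L]]
    if (length(m) == 3L) meta[[trimws(m[2L])]] <- trimws(m[3L])
    i <- i + 1L
  }
  if (i > length(lines)) {
    stop("structural error: no data rows in ", path, call. = FALSE)
  }
  header <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
  if (!identical(tolower(trimws(header[1:2])), c("ppm", "intensity"))) {
    stop(sprintf("format error in %s, line %d: expected 'ppm\\tintensity' header, got '%s'",
                 path, i, lines[i]), call. = FALSE)
  }
  body <- lines[seq(i + 1L, length(lines))]
  body <- body[nzchar(trimws(body))]
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad)) {
    stop(sprintf("format error in %s, line %d: '%s'", path,
                 i + bad[1L], body[bad[1L]]), call. = FALSE)
  }
  ppm <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  y <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  bad <- which(is.na(ppm) | is.na(y))
  if (length(bad)) {
    stop(sprintf("format error in %s, line %d: non-numeric value '%s'",
                 path, i + bad[1L], body[bad[1L]]), call. = FALSE)
  }
  .assemble_spectrum(ppm, y, meta, path)
}

.write_spectrum_jcamp <- function(spec, path) {
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("I/O error: cannot open ", path,
                                           call. = FALSE))
  on.exit(close(con))
  n <- length(spec$ppm)
  w <- function(...) writeLines(sprintf(...), con)
  w("##TITLE=%s", spec$label)
  w("##JCAMP-DX=4.24")
  w("##DATA TYPE=NMR SPECTRUM")
  w("##XUNITS=PPM")
  w("##YUNITS=ARBITRARY UNITS")
  w("##.OBSERVE FREQUENCY=%.12g", spec$spectrometer_freq)
  w("##$MODALITY=%s", spec$modality)
  if (!is.null(spec$acquisition)) {
    w("##$TEMPERATURE=%.12g", spec$acquisition$temperature)
    w("##$NS=%d", spec$acquisition$NS)
    w("##$P1=%.12g", spec$acquisition$P1)
    w("##$RG=%.12g", spec$acquisition$RG)
  }
  w("##FIRSTX=%.17g", spec$ppm[1L])
  w("##LASTX=%.17g", spec$ppm[n])
  w("##NPOINTS=%d", n)
  w("##XYPOINTS=(XY..XY)")
  writeLines(sprintf("%.17g, %.17g", spec$ppm, spec$intensity), con)
  w("##END=")
}

.read_spectrum_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr_idx <- grep("^##", lines)
  labelled <- function(key) {
    pat <- paste0("^##", key, "=")
    hit <- grep(pat, lines, ignore.case = TRUE)
    if (!length(hit)) return(NULL)
    trimws(sub(pat, "", lines[hit[1L]], ignore.case = TRUE))
  }
  meta <- list()
  v <- labelled("\\.OBSERVE FREQUENCY")
  if (!is.null(v)) meta$spectrometer_freq <- v
  v <- labelled("\\$MODALITY");    if (!is.null(v)) meta$modality <- v
  v <- labelled("TITLE");          if (!is.null(v)) meta$label <- v
  v <- labelled("\\$TEMPERATURE"); if (!is.null(v)) meta$temperature <- v
  v <- labelled("\\$NS");          if (!is.null(v)) meta$NS <- v
  v <- labelled("\\$P1");          if (!is.null(v)) meta$P1 <- v
  v <- labelled("\\$RG");          if (!is.null(v)) meta$RG <- v

  num_or_bad <- function(tok, lineno) {
    x <- suppressWarnings(as.numeric(tok))
    if (anyNA(x)) {
      stop(sprintf("format error in %s, line %d: '%s'", path, lineno,
                   lines[lineno]), call. = FALSE)
    }
    x
  }
  data_block <- function(start_pat) {
    start <- grep(start_pat, lines, ignore.case = TRUE)
    if (!length(start)) return(NULL)
    start <- start[1L]
    stop_at <- hdr_idx[hdr_idx > start]
    end <- if (length(stop_at)) min(stop_at) - 1L else length(lines)
    if (end < start + 1L) {
      stop("structural error: empty data block in ", path, call. = FALSE)
    }
    list(rows = seq(start + 1L, end), start = start)
  }

  blk <- data_block("^##XYPOINTS=")
  if (!is.null(blk)) {
    ppm <- numeric(0); y <- numeric(0)
    for (r in blk$rows) {
      ln <- trimws(lines[r])
      if (!nzchar(ln)) next
      tok <- strsplit(ln, "[,;]\\s*|\\s+")[[1L]]
      tok <- tok[nzchar(tok)]
      if (length(tok) %% 2L != 0L) {
        stop(sprintf("format error in %s, line %d: '%s'", path, r, lines[r]),
             call. = FALSE)
      }
      vals <- num_or_bad(tok, r)
      ppm <- c(ppm, vals[seq(1L, length(vals), by = 2L)])
      y <- c(y, vals[seq(2L, length(vals), by = 2L)])
    }
    return(.assemble_spectrum(ppm, y, meta, path))
  }

  blk <- data_block("^##XYDATA=")
  if (!is.null(blk)) {
    xf <- labelled("XFACTOR"); yf <- labelled("YFACTOR")
    xf <- if (is.null(xf)) 1 else as.numeric(xf)
    yf <- if (is.null(yf)) 1 else as.numeric(yf)
    firstx <- labelled("FIRSTX"); lastx <- labelled("LASTX")
    npts <- labelled("NPOINTS")
    if (is.null(firstx) || is.null(lastx) || is.null(npts)) {
      stop("structural error: XYDATA block without FIRSTX/LASTX/NPOINTS in ",
           path, call. = FALSE)
    }
    npts <- as.integer(npts)
    ppm <- seq(as.numeric(firstx) * xf, as.numeric(lastx) * xf,
               length.out = npts)
    y <- numeric(0)
    for (r in blk$rows) {
      ln <- trimws(lines[r])
      if (!nzchar(ln)) next
      tok <- strsplit(ln, "\\s+")[[1L]]
      tok <- tok[nzchar(tok)]
      vals <- num_or_bad(tok, r)
      y <- c(y, vals[-1L])            # first token on each line is X
    }
    if (length(y) != npts) {
      stop(sprintf("structural error in %s: NPOINTS=%d but %d Y values read",
                   path, npts, length(y)), call. = FALSE)
    }
    return(.assemble_spectrum(ppm, y * yf, meta, path))
  }
  stop("structural error: no XYPOINTS or XYDATA block in ", path,
       call. = FALSE)
}

#' Write a peak table as TSV
#'
#' Columns `peak_id`, `ppm_lo`, `ppm_hi`, `area`; window bounds are taken from
#' `windows` when given (matched by `peak_id`), otherwise written as `NA`.
#'
#' @param peaks A [peak_table()].
#' @param path Destination path.
#' @param windows Optional named list of [peak_window()] objects.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, path, windows = NULL) {
  lo <- hi <- rep(NA_real_, nrow(peaks))
  if (!is.null(windows)) {
    ids <- vapply(windows, function(w) w$peak_id, "")
    m <- match(peaks$peak_id, ids)
    lo[!is.na(m)] <- vapply(windows[m[!is.na(m)]], `[[`, 0, "ppm_lo")
    hi[!is.na(m)] <- vapply(windows[m[!is.na(m)]], `[[`, 0, "ppm_hi")
  }
  out <- data.frame(peak_id = peaks$peak_id, ppm_lo = lo, ppm_hi = hi,
                    area = peaks$area)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a peak table from TSV
#'
#' @param path A TSV with at least columns `peak_id` and `area`.
#' @return A [peak_table()].
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("peak_id", "area") %in% names(df))) {
    stop("format error: peak table needs columns peak_id and area",
         call. = FALSE)
  }
  peak_table(df$peak_id, df$area, source = basename(path))
}
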