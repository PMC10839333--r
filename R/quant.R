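# External-standard absolute quantification of lipid classes from extract
# spectra, with tissue-weight normalization.

#' Acquisition normalization factor
#'
#' `m = T * P1 / (RG * NS)`: the factor that puts integral areas acquired
#' under different temperature, pulse length, receiver gain and scan count on
#' a common footing for external-standard quantification.
#'
#' @param acq An [acquisition_params()].
#' @return The dimensionless factor `m`.
#' @export
#' @examples
#' acquisition_factor(acquisition_params(298, 128, 10, 1))  # 23.28125
acquisition_factor <- function(acq) {
  stopifnot(inherits(acq, "acquisition_params"))
  acq$temperature * acq$P1 / (acq$RG * acq$NS)
}

#' Define an external standard record
#'
#' A reference compound of known concentration whose integral area over a
#' catalog peak, together with its acquisition factor, converts sample areas
#' to absolute concentrations.
#'
#' @param molecule Compound name.
#' @param lipid_class Lipid class the standard represents.
#' @param peak_id Catalog peak used for quantification.
#' @param conc_mM Standard concentration in mM (> 0).
#' @param area Reference integral area (> 0, arbitrary units).
#' @param acq [acquisition_params()] of the reference acquisition.
#' @return An object of class `standard_record`.
#' @export
standard_record <- function(molecule, lipid_class, peak_id, conc_mM, area,
                            acq = acquisition_params()) {
  stopifnot(conc_mM > 0, area > 0, inherits(acq, "acquisition_params"))
  structure(list(molecule = molecule, lipid_class = lipid_class,
                 peak_id = peak_id, conc_mM = conc_mM, area = area,
                 acq = acq),
            class = "standard_record")
}

#' Concentration of a metabolite against an external standard
#'
#' `Conc_met = Conc_st * A_met * m / (A_st * m_st)` with
#' `m = acquisition_factor(acq_met)` and `m_st` that of the standard's
#' acquisition.
#'
#' @param area_met Sample integral area (>= 0).
#' @param acq_met Sample [acquisition_params()].
#' @param std A [standard_record()].
#' @return Concentration in mM.
#' @export
#' @examples
#' std <- standard_record("triolein", "TG", "tg_glycerol_43", 36.7, 100)
#' concentration_from_standard(200, std$acq, std)  # 73.4
concentration_from_standard <- function(area_met, acq_met, std) {
  stopifnot(area_met >= 0, inherits(std, "standard_record"))
  m <- acquisition_factor(acq_met)
  m_st <- acquisition_factor(std$acq)
  std$conc_mM * area_met * m / (std$area * m_st)
}

#' Per-sample metadata for quantification
#'
#' @param animal_id Sample / animal identifier.
#' @param genotype `"CpKO"` or `"WT"`.
#' @param age_months Age in months (6 or 10 in the study design, free here).
#' @param tissue `"liver"` or `"perigonadal_AT"`.
#' @param fresh_weight Fresh tissue weight in mg (> 0 if used).
#' @param dry_weight Dry (lyophilized) weight in mg, optional.
#' @param weight_basis `"dry"` or `"fresh"`; liver defaults to dry,
#'   adipose tissue to fresh.
#' @return An object of class `sample_meta`.
#' @export
sample_meta <- function(animal_id, genotype = c("CpKO", "WT"),
                        age_months = 10,
                        tissue = c("liver", "perigonadal_AT"),
                        fresh_weight = NA_real_, dry_weight = NA_real_,
                        weight_basis = NULL) {
  genotype <- match.arg(genotype)
  tissue <- match.arg(tissue)
  if (is.null(weight_basis)) {
    weight_basis <- if (tissue == "liver") "dry" else "fresh"
  }
  weight_basis <- match.arg(weight_basis, c("dry", "fresh"))
  w <- if (weight_basis == "dry") dry_weight else fresh_weight
  if (is.na(w) || w <= 0) {
    stop(sprintf("metadata error: %s weight missing or <= 0 for basis '%s'",
                 weight_basis, weight_basis), call. = FALSE)
  }
  structure(list(animal_id = animal_id, genotype = genotype,
                 age_months = age_months, tissue = tissue,
                 fresh_weight = fresh_weight, dry_weight = dry_weight,
                 weight_basis = weight_basis),
            class = "sample_meta")
}

.basis_weight <- function(meta) {
  if (meta$weight_basis == "dry") meta$dry_weight else meta$fresh_weight
}

#' Synthetic external-standards registry
#'
#' A stand-in for an in-house reference database: 21 commercial molecules
#' across 11 lipid classes, all at 10 mM except the triglyceride standards at
#' 36.7 mM. The reference areas are generated by the package's own
#' acquisition model (`area = conc * protons / m`, area-per-proton-mM scale
#' 1) under a fixed reference acquisition, i.e. they are simulated, not
#' measured: this registry is synthetic and is labelled as such in the
#' shipped fixture `extdata/standards_synthetic.tsv`.
#'
#' @param acq Reference acquisition; default [acquisition_params()].
#' @param scale Area per proton-mM of the virtual acquisitions (default 1).
#' @return A `data.frame` with one row per molecule.
#' @export
synthetic_standards_db <- function(acq = acquisition_params(), scale = 1) {
  reg <- data.frame(
    molecule = c("triolein", "tripalmitin", "trilinolein",
                 "dipalmitoyl-PC", "dioleoyl-PC", "palmitoyl-LPC",
                 "dipalmitoyl-PE", "dioleoyl-PE",
                 "cholesterol", "cholesteryl-oleate", "cholesteryl-palmitate",
                 "palmitic-acid", "stearic-acid", "oleic-acid",
                 "linoleic-acid", "alpha-linolenic-acid",
                 "diolein", "monoolein", "sphingomyelin",
                 "phosphatidylinositol", "palmitoleic-acid"),
    lipid_class = c("TG", "TG", "TG",
                    "PC_LPC", "PC_LPC", "PC_LPC",
                    "PE", "PE",
                    "TC", "CE", "CE",
                    "FA", "FA", "FA", "FA", "omega3",
                    "DG", "MG", "SM", "PI", "FA"),
    peak_id = c("tg_glycerol_43", "tg_glycerol_43", "tg_glycerol_43",
                "choline", "choline", "choline",
                "pe_ch2", "pe_ch2",
                "tc_ch3", "tc_ch3", "tc_ch3",
                "fa_ch3", "fa_ch3", "fa_ch3", "fa_ch3", "omega3_ch3",
                "tg_glycerol_43", "tg_glycerol_43", "choline",
                "pe_ch2", "fa_ch3"),
    stringsAsFactors = FALSE)
  reg$conc_mM <- ifelse(reg$lipid_class == "TG", 36.7, 10)
  # protons behind the designated peak for one molecule of the standard;
  # classes quantified via class peaks use the class proton count
  cls <- lipid_class_table()
  protons <- cls$protons[match(reg$lipid_class, cls$lipid_class)]
  # unquantified classes fall back to the proton count of their lookup peak
  cat_df <- lipid_line_catalog()
  fallback <- cat_df$protons[match(reg$peak_id, cat_df$peak_id)]
  reg$protons <- ifelse(is.na(protons), fallback, protons)
  m_st <- acquisition_factor(acq)
  reg$area <- reg$conc_mM * reg$protons * scale / m_st
  reg$temperature <- acq$temperature
  reg$NS <- acq$NS
  reg$P1 <- acq$P1
  reg$RG <- acq$RG
  reg
}

#' Read a standards database from TSV
#'
#' @param path TSV with columns `molecule`, `lipid_class`, `peak_id`,
#'   `conc_mM`, `area`, `temperature`, `NS`, `P1`, `RG`. The packaged
#'   synthetic registry is at
#'   `system.file("extdata", "standards_synthetic.tsv", package = "lipospec")`.
#' @return A named list of [standard_record()] keyed by molecule.
#' @export
read_standards <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("molecule", "lipid_class", "peak_id", "conc_mM", "area",
            "temperature", "NS", "P1", "RG")
  if (!all(need %in% names(df))) {
    stop("format error: standards table needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    standard_record(df$molecule[i], df$lipid_class[i], df$peak_id[i],
                    df$conc_mM[i], df$area[i],
                    acquisition_params(df$temperature[i], df$NS[i],
                                       df$P1[i], df$RG[i]))
  })
  names(out) <- df$molecule
  out
}

#' Default representative standard per quantified class
#'
#' One designated standard per class (configuration: the study does not state
#' how multiple standards of a class were combined).
#'
#' @param db A standards data.frame ([synthetic_standards_db()]) or list of
#'   [standard_record()].
#' @return Named list of [standard_record()] keyed by lipid class.
#' @export
class_standards <- function(db = synthetic_standards_db()) {
  reps <- c(TG = "triolein", PC_LPC = "dipalmitoyl-PC",
            PE = "dipalmitoyl-PE", omega3 = "alpha-linolenic-acid",
            FA = "oleic-acid", TC = "cholesterol")
  if (is.data.frame(db)) {
    recs <- lapply(reps, function(mol) {
      i <- match(mol, db$molecule)
      if (is.na(i)) stop("configuration error: standard '", mol,
                         "' missing from database", call. = FALSE)
      standard_record(db$molecule[i], db$lipid_class[i], db$peak_id[i],
                      db$conc_mM[i], db$area[i],
                      acquisition_params(db$temperature[i], db$NS[i],
                                         db$P1[i], db$RG[i]))
    })
  } else {
    recs <- lapply(reps, function(mol) {
      if (is.null(db[[mol]])) stop("configuration error: standard '", mol,
                                   "' missing from database", call. = FALSE)
      db[[mol]]
    })
  }
  names(recs) <- names(reps)
  recs
}

#' Relative abundances of a peak table
#'
#' Each peak's area divided by the total area of the table; scale invariant
#' and summing to 1.
#'
#' @param peaks A [peak_table()] with at least one positive area.
#' @return Named numeric vector of fractions.
#' @export
relative_abundances <- function(peaks) {
  stopifnot(inherits(peaks, "peak_table"))
  tot <- sum(peaks$area)
  if (tot <= 0) {
    stop("undefined error: all peak areas are zero", call. = FALSE)
  }
  stats::setNames(peaks$area / tot, peaks$peak_id)
}

#' Total lipid content of an extract spectrum
#'
#' Total spectral area (solvent reference window excluded) divided by the
#' tissue weight on the declared basis: dry weight for liver, fresh weight
#' for perigonadal adipose tissue.
#'
#' @param spec A [spectrum1d()] (modality `hr_nmr`).
#' @param meta A [sample_meta()].
#' @param exclusions Excluded windows; default [default_exclusions()].
#' @return Area per mg of tissue.
#' @export
total_lipid_content <- function(spec, meta,
                                exclusions = default_exclusions(spec)) {
  stopifnot(inherits(spec, "spectrum1d"), inherits(meta, "sample_meta"))
  total_area(spec, exclusions) / .basis_weight(meta)
}

#' Quantify lipid classes in an extract spectrum
#'
#' Integrates each quantified-class window (baseline-corrected), converts
#' areas to absolute mM via [concentration_from_standard()] against the
#' designated class standard, and normalizes by tissue weight on the declared
#' basis, giving mM per mg. Also reports the relative abundance of every
#' catalog peak and the weight-normalized total area. The spectrum should be
#' referenced (chloroform at 7.26 ppm) before quantification.
#'
#' @param spec A [spectrum1d()] with modality `"hr_nmr"` and acquisition
#'   metadata present.
#' @param meta A [sample_meta()].
#' @param standards Named list of [standard_record()] per class; default
#'   [class_standards()] of the synthetic registry.
#' @param classes Classes to quantify; default all six of
#'   [lipid_class_table()].
#' @param warn Pass-through to [integrate_window()] flooring warnings.
#'
#' @return An object of class `quant_result`: list with `concentrations`
#'   (data.frame: lipid_class, display_shift, area, conc_mM, conc_mM_per_mg,
#'   basis), `relative_abundance` (named vector or `NA` if the spectrum is
#'   empty), `total_lipid` (area per mg), `meta`.
#' @export
#' @examples
#' mix <- lipid_mixture(class_concentrations = c(TG = 6, FA = 19))
#' s <- simulate_extract_spectrum(mix, seed = 5)
#' meta <- sample_meta("m1", "CpKO", 10, "liver", dry_weight = 30)
#' quantify_lipid_classes(s, meta)$concentrations
quantify_lipid_classes <- function(spec, meta,
                                   standards = class_standards(),
                                   classes = lipid_class_table()$lipid_class,
                                   warn = TRUE) {
  stopifnot(inherits(spec, "spectrum1d"), inherits(meta, "sample_meta"))
  if (is.null(spec$acquisition)) {
    stop("metadata error: spectrum has no acquisition parameters",
         call. = FALSE)
  }
  cls <- lipid_class_table()
  cls <- cls[match(classes, cls$lipid_class), ]
  if (anyNA(cls$lipid_class)) {
    stop("configuration error: unknown lipid class requested", call. = FALSE)
  }
  missing_std <- setdiff(classes, names(standards))
  if (length(missing_std)) {
    stop("configuration error: no standard for class ",
         paste(missing_std, collapse = ", "), call. = FALSE)
  }
  wins <- catalog_windows()
  w <- .basis_weight(meta)

  rows <- lapply(seq_len(nrow(cls)), function(i) {
    ids <- strsplit(cls$peak_ids[i], ",", fixed = TRUE)[[1L]]
    a <- sum(vapply(ids, function(id) {
      integrate_window(spec, wins[[id]], warn = warn)
    }, 0))
    conc <- concentration_from_standard(a, spec$acquisition,
                                        standards[[cls$lipid_class[i]]])
    data.frame(lipid_class = cls$lipid_class[i],
               display_shift = cls$display_shift[i],
               area = a, conc_mM = conc, conc_mM_per_mg = conc / w,
               basis = meta$weight_basis, stringsAsFactors = FALSE)
  })
  conc_df <- do.call(rbind, rows)

  all_areas <- vapply(wins, function(win) {
    integrate_window(spec, win, warn = FALSE)
  }, 0)
  pt <- peak_table(names(all_areas), all_areas, source = spec$label)
  rel <- if (sum(all_areas) > 0) relative_abundances(pt) else {
    if (warn) warning("zero-signal spectrum: relative abundance undefined",
                      call. = FALSE)
    NA
  }
  structure(list(concentrations = conc_df,
                 relative_abundance = rel,
                 total_lipid = total_lipid_content(spec, meta),
                 meta = meta),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("<quant_result> %s (%s, %s basis)\n", x$meta$animal_id,
              x$meta$tissue, x$meta$basis %||% x$meta$weight_basis))
  print(x$concentrations, row.names = FALSE)
  cat(sprintf("  total lipid: %.4g area/mg\n", x$total_lipid))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
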