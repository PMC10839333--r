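# Resonance registry and fatty-acyl proton stoichiometry.
#
# The registry fixes the chemical-shift windows used throughout: olefinic
# -CH=CH- (5.3), TG glycerol sn-1/sn-3 CH2 (4.10 and 4.30, 2+2 protons),
# choline -N(CH3)3 (3.48, 9H, PC+LPC), PE -CH2-NH3+ (3.40, 2H), diallylic CH2
# (2.8), alpha-carboxyl CH2 (2.25), allylic CH2 (2.0), beta-carboxyl CH2
# (1.6), bulk (-CH2-)n (1.3), omega-3 terminal CH3 (0.98, 3H), generic
# fatty-acid terminal CH3 (0.90, 3H) and the cholesterol C18 CH3 (0.68, 3H).

#' Registry of assigned lipid resonances
#'
#' Returns the fixed table of lipid-line assignments with their integration
#' windows (high-resolution extract spectra), nominal centers, the lipid class
#' each line quantifies (or `NA` for chain lines used in relative abundances
#' and composition indices) and the proton count per contributing unit. The
#' two triglyceride glycerol methylenes are listed as separate entries
#' (`tg_glycerol_41`, `tg_glycerol_43`, 2 protons each; 4 in total).
#'
#' @return A `data.frame` with columns `peak_id`, `center`, `ppm_lo`,
#'   `ppm_hi`, `lipid_class`, `protons`, `display_shift`.
#' @export
#' @examples
#' lipid_line_catalog()
lipid_line_catalog <- function() {
  df <- data.frame(
    peak_id = c("olefinic", "tg_glycerol_43", "tg_glycerol_41", "choline",
                "pe_ch2", "diallylic", "alpha_carboxyl", "allylic",
                "beta_carboxyl", "bulk_ch2", "omega3_ch3", "fa_ch3",
                "tc_ch3"),
    center  = c(5.30, 4.30, 4.10, 3.48, 3.40, 2.80, 2.25, 2.02,
                1.60, 1.30, 0.98, 0.90, 0.68),
    ppm_lo  = c(5.20, 4.25, 4.05, 3.44, 3.36, 2.70, 2.15, 1.92,
                1.50, 1.15, 0.94, 0.82, 0.60),
    ppm_hi  = c(5.40, 4.35, 4.15, 3.52, 3.44, 2.90, 2.35, 2.12,
                1.70, 1.45, 1.06, 0.94, 0.76),
    lipid_class = c(NA, "TG", "TG", "PC_LPC", "PE", NA, NA, NA, NA, NA,
                    "omega3", "FA", "TC"),
    protons = c(2L, 2L, 2L, 9L, 2L, 2L, 2L, 2L, 2L, 2L, 3L, 3L, 3L),
    display_shift = c("5.3", "4.30-4.12", "4.30-4.12", "3.48", "3.4",
                      "2.8", "2.25", "2.0", "1.6", "1.3", "0.98", "0.9",
                      "0.68"),
    stringsAsFactors = FALSE)
  df
}

#' Integration windows of the catalog
#'
#' @param ids Optional subset of peak ids.
#' @return A named list of [peak_window()] objects.
#' @export
catalog_windows <- function(ids = NULL) {
  cat_df <- lipid_line_catalog()
  if (!is.null(ids)) cat_df <- cat_df[cat_df$peak_id %in% ids, ]
  wins <- lapply(seq_len(nrow(cat_df)), function(i) {
    peak_window(cat_df$peak_id[i], cat_df$ppm_lo[i], cat_df$ppm_hi[i],
                cat_df$center[i])
  })
  names(wins) <- cat_df$peak_id
  wins
}

#' Quantified lipid classes and the peaks that measure them
#'
#' The six classes quantified absolutely: TG from the two glycerol methylenes
#' (4 protons), PC+LPC from the choline headgroup (9 protons), PE from the
#' ethanolamine CH2 (2 protons), omega-3 fatty acids and total fatty acids
#' from their terminal methyls (3 protons each, split at 0.94 ppm), and total
#' cholesterol from the C18 methyl (3 protons).
#'
#' @return A `data.frame` with columns `lipid_class`, `peak_ids`
#'   (comma-separated), `protons`, `display_shift`.
#' @export
lipid_class_table <- function() {
  data.frame(
    lipid_class = c("TG", "PC_LPC", "PE", "omega3", "FA", "TC"),
    peak_ids = c("tg_glycerol_43,tg_glycerol_41", "choline", "pe_ch2",
                 "omega3_ch3", "fa_ch3", "tc_ch3"),
    protons = c(4L, 9L, 2L, 3L, 3L, 3L),
    display_shift = c("4.30-4.12", "3.48", "3.4", "0.98", "0.9", "0.68"),
    stringsAsFactors = FALSE)
}

#' Define a fatty-acyl species
#'
#' @param name Species name, e.g. `"oleate"`.
#' @param chain_length Carbons in the acyl chain (including the carboxyl
#'   carbon and the terminal methyl).
#' @param n_double_bonds Number of C=C double bonds (>= 0).
#' @param n_diallylic_ch2 Methylene-interrupted CH2 groups between double
#'   bonds; defaults to `max(n_double_bonds - 1, 0)` (methylene-interrupted
#'   polyunsaturates).
#' @param omega3 Does the terminal methyl sit three carbons from a double
#'   bond (resonating at 0.98 instead of 0.90 ppm)?
#'
#' @return An object of class `fatty_acyl_species`.
#' @export
#' @examples
#' fatty_acyl_species("oleate", 18, 1)
fatty_acyl_species <- function(name, chain_length, n_double_bonds = 0L,
                               n_diallylic_ch2 = max(n_double_bonds - 1L, 0L),
                               omega3 = FALSE) {
  stopifnot(chain_length >= 4, n_double_bonds >= 0,
            n_diallylic_ch2 >= 0, is.logical(omega3))
  sp <- structure(list(name = name,
                       chain_length = as.integer(chain_length),
                       n_double_bonds = as.integer(n_double_bonds),
                       n_diallylic_ch2 = as.integer(n_diallylic_ch2),
                       omega3 = isTRUE(omega3)),
                  class = "fatty_acyl_species")
  pp <- chain_proton_partition(sp)     # validates: bulk CH2 must be >= 0
  if (pp[["bulk_ch2"]] < 0) {
    stop("impossible species: negative bulk methylene count", call. = FALSE)
  }
  sp
}

#' Proton partition of one acyl chain over the catalog resonances
#'
#' Counts, for a single fatty-acyl chain, the protons contributing to each
#' chain resonance: terminal methyl (3, at 0.90 or 0.98 ppm depending on
#' omega-3 status), olefinic (2 per double bond), diallylic (2 per
#' methylene-interrupted CH2), allylic (4 for any unsaturated chain: the two
#' outer CH2 flanking the double-bond system), alpha- and beta-carboxyl CH2
#' (2 each) and the remaining bulk methylenes at 1.3 ppm.
#'
#' @param species A [fatty_acyl_species()].
#' @return A named numeric vector over catalog chain peak ids.
#' @export
#' @examples
#' chain_proton_partition(fatty_acyl_species("oleate", 18, 1))
chain_proton_partition <- function(species) {
  stopifnot(inherits(species, "fatty_acyl_species"))
  C <- species$chain_length
  d <- species$n_double_bonds
  nda <- species$n_diallylic_ch2
  ch2_total <- C - 2L - 2L * d          # all CH2 carbons
  allylic_ch2 <- if (d >= 1L) 2L else 0L
  bulk_ch2 <- ch2_total - 2L - allylic_ch2 - nda   # minus alpha, beta
  out <- c(olefinic = 2 * d,
           diallylic = 2 * nda,
           allylic = 2 * allylic_ch2,
           alpha_carboxyl = 2,
           beta_carboxyl = 2,
           bulk_ch2 = 2 * bulk_ch2,
           omega3_ch3 = if (species$omega3) 3 else 0,
           fa_ch3 = if (species$omega3) 0 else 3)
  out
}

#' Default fatty-acyl species set
#'
#' Palmitate (16:0), stearate (18:0), oleate (18:1), linoleate (18:2) and
#' alpha-linolenate (18:3, omega-3): the major acyl chains of rodent liver
#' and adipose lipids.
#'
#' @return A named list of [fatty_acyl_species()].
#' @export
default_species <- function() {
  list(
    palmitate  = fatty_acyl_species("palmitate", 16, 0),
    stearate   = fatty_acyl_species("stearate", 18, 0),
    oleate     = fatty_acyl_species("oleate", 18, 1),
    linoleate  = fatty_acyl_species("linoleate", 18, 2),
    linolenate = fatty_acyl_species("linolenate", 18, 3, omega3 = TRUE)
  )
}

#' Acyl chains contributed per molecule of each lipid class
#'
#' Simulator convention for the chain pool: triglycerides carry 3 chains,
#' PC+LPC is modelled with the PC value of 2, PE 2, free fatty acids 1 and
#' cholesterol 0 (its only registered line is the C18 methyl).
#'
#' @return Named numeric vector.
#' @export
chains_per_molecule <- function() {
  c(TG = 3, PC_LPC = 2, PE = 2, FA = 1, TC = 0)
}

#' Define a lipid mixture
#'
#' A mixture couples molar lipid-class concentrations (mM) with the mole
#' fractions of the fatty-acyl species that make up the pooled acyl chains.
#'
#' @param class_concentrations Named non-negative concentrations (mM) over
#'   `c("TG", "PC_LPC", "PE", "TC", "FA")`; missing classes default to 0.
#' @param species_fractions Named non-negative mole fractions over the names
#'   of `species`; renormalized to sum to 1 (all zero is allowed only when no
#'   chain-carrying class is present).
#' @param species Named list of [fatty_acyl_species()];
#'   default [default_species()].
#'
#' @return An object of class `lipid_mixture`.
#' @export
#' @examples
#' lipid_mixture(class_concentrations = c(TG = 6, FA = 19),
#'               species_fractions = c(oleate = 0.5, palmitate = 0.5))
lipid_mixture <- function(class_concentrations = c(TG = 6, PC_LPC = 0.1,
                                                   PE = 0.8, TC = 0.5,
                                                   FA = 19),
                          species_fractions = c(palmitate = 0.30,
                                                stearate = 0.05,
                                                oleate = 0.35,
                                                linoleate = 0.20,
                                                linolenate = 0.10),
                          species = default_species()) {
  classes <- c("TG", "PC_LPC", "PE", "TC", "FA")
  conc <- stats::setNames(numeric(length(classes)), classes)
  if (length(class_concentrations)) {
    unknown <- setdiff(names(class_concentrations), classes)
    if (length(unknown)) {
      stop("unknown lipid class: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    conc[names(class_concentrations)] <- class_concentrations
  }
  if (any(conc < 0)) stop("concentrations must be >= 0", call. = FALSE)
  fr <- stats::setNames(numeric(length(species)), names(species))
  if (length(species_fractions)) {
    unknown <- setdiff(names(species_fractions), names(species))
    if (length(unknown)) {
      stop("unknown species: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    fr[names(species_fractions)] <- species_fractions
  }
  if (any(fr < 0)) stop("species fractions must be >= 0", call. = FALSE)
  tot <- sum(fr)
  chain_conc <- sum(conc * chains_per_molecule()[classes])
  if (tot > 0) {
    fr <- fr / tot
  } else if (chain_conc > 0) {
    stop("chain-carrying classes present but all species fractions are zero",
         call. = FALSE)
  }
  structure(list(class_concentrations = conc,
                 species_fractions = fr,
                 species = species),
            class = "lipid_mixture")
}

#' @export
print.lipid_mixture <- function(x, ...) {
  cat("<lipid_mixture>\n  classes (mM): ",
      paste(sprintf("%s=%.4g", names(x$class_concentrations),
                    x$class_concentrations), collapse = ", "), "\n",
      "  acyl fractions: ",
      paste(sprintf("%s=%.3g", names(x$species_fractions),
                    x$species_fractions), collapse = ", "), "\n", sep = "")
  invisible(x)
}
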