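#' Physical and procedural constants for Ncopy quantification
#'
#' Bundles the fixed constants entering the limiting-component copy
#' calculations and the defaults of the downstream pipeline. All values can
#' be overridden, but the defaults are the ones the method was calibrated
#' with and should normally be left alone.
#'
#' @param N_A Avogadro constant, molecules per mol.
#' @param bp_mass Average molar mass of a DNA base pair, g/(bp mol).
#' @param unit_factor Dimensional conversion for nM concentrations and uL
#'   volumes into mol (1e15 = 1e9 nM/M x 1e6 uL/L).
#' @param gdna_copies_per_ng Copies of a single-copy gene per ng of diploid
#'   human genomic DNA (about 3.3 pg per haploid genome, i.e. 300 per ng).
#' @param cv_warn Coefficient-of-variation threshold above which technical
#'   replicates are flagged.
#' @param genorm_cutoff Pairwise-variation cutoff V(n/n+1) below which a
#'   reference-gene set of size n is considered sufficiently stable.
#' @param alpha Default significance level for outlier and group tests.
#'
#' @return A list of class `qpcr_constants`.
#' @examples
#' qpcr_constants()$gdna_copies_per_ng
#' @export
qpcr_constants <- function(N_A = 6.022e23,
                           bp_mass = 660,
                           unit_factor = 1e15,
                           gdna_copies_per_ng = 300,
                           cv_warn = 0.3,
                           genorm_cutoff = 0.15,
                           alpha = 0.05) {
  stopifnot(N_A > 0, bp_mass > 0, unit_factor > 0, gdna_copies_per_ng > 0,
            cv_warn > 0, genorm_cutoff > 0, alpha > 0, alpha < 1)
  structure(list(N_A = N_A, bp_mass = bp_mass, unit_factor = unit_factor,
                 gdna_copies_per_ng = gdna_copies_per_ng, cv_warn = cv_warn,
                 genorm_cutoff = genorm_cutoff, alpha = alpha),
            class = "qpcr_constants")
}

#' Expected copies of a single-copy gene in human genomic DNA
#'
#' Converts a mass of human genomic DNA into the expected number of copies
#' of a single-copy gene (diploid genome, no pseudogenes): 4 ng correspond
#' to 1200 copies, 20 ng to 6000.
#'
#' @param mass_ng DNA mass in nanograms (vectorised, must be >= 0).
#' @param constants A [qpcr_constants()] list.
#' @return Expected copy number(s).
#' @examples
#' expected_copies_from_gdna(4)   # 1200
#' expected_copies_from_gdna(20)  # 6000
#' @export
expected_copies_from_gdna <- function(mass_ng, constants = qpcr_constants()) {
  stopifnot(is.numeric(mass_ng), all(mass_ng >= 0))
  mass_ng * constants$gdna_copies_per_ng
}
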