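#' Physical constants for PRE calculations
#'
#' Bundle of the physical constants entering the Solomon-Bloembergen
#' prefactor and the multiple-quantum PRE factor. Gyromagnetic ratios and
#' the Bohr magneton are CODATA 2018 values. The electron g-factor defaults
#' to 2.0, the value implicit in the numerical prefactor universally quoted
#' in the PRE literature (1.2311e16 A^6 s^-2); pass
#' `g_e = codata_electron_g()` for the full CODATA free-electron value.
#'
#' @param gamma_h 1H gyromagnetic ratio, rad s^-1 T^-1.
#' @param gamma_c 13C gyromagnetic ratio, rad s^-1 T^-1.
#' @param g_e electron g-factor (dimensionless).
#' @param beta Bohr magneton, J T^-1.
#' @param mu0_over_4pi magnetic constant over 4 pi, T^2 m^3 J^-1.
#' @param spin_s electronic spin quantum number (1/2 for a nitroxide radical).
#' @return object of class `physical_constants`.
#' @export
#' @examples
#' kappa_h(physical_constants())
physical_constants <- function(gamma_h = 2.6752218744e8,
                               gamma_c = 6.728284e7,
                               g_e = 2.0,
                               beta = 9.2740100783e-24,
                               mu0_over_4pi = 1e-7,
                               spin_s = 0.5) {
  stopifnot(gamma_h > 0, gamma_c > 0, g_e > 0, beta > 0,
            mu0_over_4pi > 0, spin_s > 0)
  structure(list(gamma_h = gamma_h, gamma_c = gamma_c, g_e = g_e,
                 beta = beta, mu0_over_4pi = mu0_over_4pi, spin_s = spin_s),
            class = "physical_constants")
}

#' CODATA 2018 free-electron g-factor (magnitude)
#' @return numeric scalar.
#' @export
codata_electron_g <- function() 2.00231930436256

#' @export
print.physical_constants <- function(x, ...) {
  cat("Physical constants (PRE):\n")
  cat(sprintf("  gamma_H  %.10e rad/s/T\n", x$gamma_h))
  cat(sprintf("  gamma_C  %.6e rad/s/T\n", x$gamma_c))
  cat(sprintf("  g_e      %.12f\n", x$g_e))
  cat(sprintf("  beta     %.10e J/T\n", x$beta))
  cat(sprintf("  mu0/4pi  %.3e T^2 m^3/J\n", x$mu0_over_4pi))
  cat(sprintf("  S        %g\n", x$spin_s))
  invisible(x)
}

# Nominal (integer, most abundant isotope) and monoisotopic masses, Da.
.isotope_table <- list(
  H = c(nominal = 1,  mono = 1.00782503207),
  C = c(nominal = 12, mono = 12.0),
  N = c(nominal = 14, mono = 14.0030740048),
  O = c(nominal = 16, mono = 15.9949146196),
  P = c(nominal = 31, mono = 30.97376163),
  S = c(nominal = 32, mono = 31.97207100),
  F = c(nominal = 19, mono = 18.99840322),
  Cl = c(nominal = 35, mono = 34.96885268),
  Br = c(nominal = 79, mono = 78.9183371),
  I = c(nominal = 127, mono = 126.904473),
  Na = c(nominal = 23, mono = 22.9897692809),
  K = c(nominal = 39, mono = 38.96370668)
)

#' Van der Waals radius table
#'
#' Default per-element van der Waals radii (Angstrom) used by the SASA
#' engine (Bondi radii, protein-relevant subset). Override entries via the
#' `radii` argument of [shrake_rupley_sasa()].
#'
#' @return named numeric vector of radii in Angstrom.
#' @export
vdw_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98, Fe = 1.80, Zn = 1.39,
    Mg = 1.73, Ca = 2.00, Na = 2.27, K = 2.75, Se = 1.90)
}

#' Reference maximum solvent accessibilities per residue type
#'
#' Theoretical Gly-X-Gly maximum accessible surface areas (Angstrom^2) used
#' as denominators for relative accessibility (Tien et al. 2013,
#' theoretical set).
#'
#' @return named numeric vector (three-letter residue codes).
#' @export
max_sasa_reference <- function() {
  c(ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
    GLN = 225.0, GLU = 223.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
    LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
    SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0)
}
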