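# Embedded X-ray reference data.
#
# Photon mass attenuation coefficients mu/rho (cm^2/g) for H, O, P and Ca on
# a 1-20 keV grid, tabulated after the NIST XCOM compilation, with the P and
# Ca K-edges represented by closely spaced below/above-edge rows so that
# log-log interpolation never bridges an edge. These four elements compose
# hydroxyapatite Ca10(PO4)6(OH)2, the absorbing matrix of enamel and dentin;
# analyte lines only ever need mu/rho of the matrix, not of the analyte.

.muRhoTable <- list(
  H = data.frame(
    E  = c(1, 1.5, 2, 3, 4, 5, 6, 8, 10, 15, 20),
    mu = c(7.217, 2.148, 1.059, 0.5612, 0.4546, 0.4193, 0.4042, 0.3914,
           0.3854, 0.3764, 0.3695)),
  O = data.frame(
    E  = c(1, 1.5, 2, 3, 4, 5, 6, 8, 10, 15, 20),
    mu = c(4576, 1545, 694.9, 217.1, 93.15, 47.90, 27.70, 11.63, 5.952,
           1.836, 0.8651)),
  P = data.frame(
    E  = c(1, 1.5, 2, 2.1454, 2.1456, 3, 4, 5, 6, 8, 10, 15, 20),
    mu = c(1913, 654.7, 305.6, 245.6, 2070, 1010, 485.0, 271.0, 165.0,
           73.40, 39.40, 12.30, 5.350)),
  Ca = data.frame(
    E  = c(1, 1.5, 2, 3, 4, 4.0385, 4.0387, 5, 6, 8, 10, 15, 20),
    mu = c(3676, 1219, 556.6, 184.9, 85.89, 83.50, 693.0, 390.0, 238.0,
           110.0, 60.00, 20.00, 9.150))
)

# K-alpha line energies (keV) for elements detectable in the Si-to-Sr range
.kAlphaKeV <- c(
  Si = 1.740, P = 2.014, S = 2.307, Cl = 2.622, Ar = 2.958, K = 3.314,
  Ca = 3.692, Ti = 4.511, Cr = 5.415, Mn = 5.899, Fe = 6.404, Ni = 7.478,
  Cu = 8.048, Zn = 8.639, Br = 11.924, Rb = 13.396, Sr = 14.165
)

# standard atomic masses, g/mol
.atomicMass <- c(H = 1.008, O = 15.999, P = 30.974, Ca = 40.078,
                 Sr = 87.62, Mg = 24.305)

# mass fractions of hydroxyapatite Ca10(PO4)6(OH)2
.hapWeights <- local({
  m <- .atomicMass
  tot <- 10 * m["Ca"] + 6 * m["P"] + 26 * m["O"] + 2 * m["H"]
  c(H = unname(2 * m["H"] / tot),
    O = unname(26 * m["O"] / tot),
    P = unname(6 * m["P"] / tot),
    Ca = unname(10 * m["Ca"] / tot))
})

#' K-alpha line energy of an element
#'
#' @param element element symbol.
#' @return line energy in keV.
#' @export
kAlphaEnergy <- function(element) {
  if (!element %in% names(.kAlphaKeV))
    stop("unknown fluorescence line for element '", element, "'")
  unname(.kAlphaKeV[[element]])
}

#' Photon mass attenuation coefficient of an element
#'
#' Log-log interpolation of the embedded mu/rho table (H, O, P, Ca; 1-20
#' keV, K-edges resolved).
#'
#' @param element one of "H", "O", "P", "Ca".
#' @param energyKeV photon energy, keV (vectorized).
#' @return mu/rho in cm^2/g.
#' @export
massAttenuation <- function(element, energyKeV) {
  tab <- .muRhoTable[[element]]
  if (is.null(tab))
    stop("no mu/rho table for element '", element, "'")
  if (any(energyKeV < min(tab$E)) || any(energyKeV > max(tab$E)))
    stop("energy outside the tabulated 1-20 keV range")
  exp(stats::approx(log(tab$E), log(tab$mu), xout = log(energyKeV))$y)
}

#' Mass attenuation coefficient of the hydroxyapatite matrix
#'
#' Mass-weighted mixture rule over Ca, P, O and H with the stoichiometric
#' weights of Ca10(PO4)6(OH)2.
#'
#' @param energyKeV photon energy, keV (vectorized).
#' @return mu/rho in cm^2/g.
#' @export
hydroxyapatiteMuRho <- function(energyKeV) {
  out <- 0
  for (el in names(.hapWeights))
    out <- out + .hapWeights[[el]] * massAttenuation(el, energyKeV)
  out
}
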