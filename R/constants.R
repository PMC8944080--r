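#' Physico-chemical constants of the Trp-to-indole conversion
#'
#' Molecular weights of l-tryptophan and indole (the molar basis of every
#' mol-percent conversion figure), the molar absorption coefficient of NADH at
#' 340 nm and average amino-acid residue masses used for theoretical protein
#' mass.
#'
#' @format A list with elements:
#' \describe{
#'   \item{mw_trp}{204.23 g/mol, l-tryptophan}
#'   \item{mw_indole}{117.15 g/mol, indole}
#'   \item{epsilon_nadh}{6.22 absorbance mM^-1 cm^-1 at 340 nm}
#'   \item{water_mass}{18.0153 Da, added once per chain}
#'   \item{residue_masses}{named vector of average residue masses (Da)}
#' }
#' @export
trp_constants <- list(
  mw_trp = 204.23,
  mw_indole = 117.15,
  epsilon_nadh = 6.22,
  water_mass = 18.0153,
  residue_masses = c(
    A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
    E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
    L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
    S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326,
    X = 110.0    # unknown residue: generic average
  )
)

AA_ALPHABET <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
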