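# Residue-level physical constants. Average masses feed the reported MW
# column; monoisotopic masses feed the m/z observability window (the
# instrument selects monoisotopic precursors).

.AA_STANDARD <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Average residue masses (Da), i.e. amino-acid mass minus one water.
.MASS_AVERAGE <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)

# Monoisotopic residue masses (Da).
.MASS_MONO <- c(
  A = 71.03711,  R = 156.10111, N = 114.04293, D = 115.02694, C = 103.00919,
  E = 129.04259, Q = 128.05858, G = 57.02146,  H = 137.05891, I = 113.08406,
  L = 113.08406, K = 128.09496, M = 131.04049, F = 147.06841, P = 97.05276,
  S = 87.03203,  T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841
)

.MASS_WATER_AVERAGE <- 18.01530
.MASS_WATER_MONO    <- 18.01056
.MASS_PROTON        <- 1.007276

# Bjellqvist-style pKa values for the Henderson-Hasselbalch charge model.
# positive: N-terminus, K, R, H; negative: C-terminus, D, E, C, Y.
.PKA_BJELLQVIST <- list(
  nterm = 7.50, cterm = 3.55,
  K = 10.00, R = 12.00, H = 5.98,
  D = 4.05,  E = 4.45,  C = 9.00, Y = 10.00
)

#' Residue mass tables
#'
#' The residue mass tables used throughout the package: average masses for
#' the reported molecular-weight column, monoisotopic masses for precursor
#' m/z calculations. Values are residue masses in daltons (amino-acid mass
#' minus one water); a peptide's neutral mass is the sum of its residue
#' masses plus one water.
#'
#' @param type `"average"` or `"monoisotopic"`.
#' @return Named numeric vector of 20 residue masses in Da.
#' @examples
#' residueMasses("average")[["G"]]  # glycine, 57.0519
#' @export
residueMasses <- function(type = c("average", "monoisotopic")) {
  type <- match.arg(type)
  if (type == "average") .MASS_AVERAGE else .MASS_MONO
}

#' pKa set for the isoelectric-point model
#'
#' Returns the named pKa configuration used by [isoelectricPoint()]. The
#' default `"bjellqvist"` set carries terminal pKa values (N-terminus 7.50,
#' C-terminus 3.55) and side-chain values for K, R, H (basic) and D, E, C, Y
#' (acidic).
#'
#' @param name Name of the set; only `"bjellqvist"` is shipped.
#' @return A list with elements `nterm`, `cterm` and one entry per
#'   ionisable side chain.
#' @export
pkaSet <- function(name = "bjellqvist") {
  if (!identical(name, "bjellqvist"))
    stop("unknown pKa set: ", name)
  .PKA_BJELLQVIST
}
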