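# Physical constants and composition tables used throughout the mass module.
# Atomic weights: IUPAC 2021 standard atomic weights (abridged to 4-5 dp).
# Monoisotopic masses: most abundant isotope, CODATA/AME2020.

#' Canonical amino-acid alphabet
#'
#' The 20 one-letter codes, alphabetical.
#' @export
AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")

# Ambiguity / non-canonical one-letter codes tolerated in input sequences.
AA_AMBIGUOUS <- c("B", "Z", "J", "U", "O", "X")

#' Mass of a proton (Da)
#' @export
PROTON_MASS <- 1.007276

.ELEMENT_MASS <- data.frame(
  element = c("H",        "C",       "N",          "O",          "P",          "S"),
  avg     = c(1.008,      12.011,    14.007,       15.999,       30.973762,    32.06),
  mono    = c(1.00782503, 12.000000, 14.00307401,  15.99491462,  30.97376200,  31.97207117),
  stringsAsFactors = FALSE
)

#' Mass of water (Da)
#'
#' Average-mass water, released on peptide-bond or phosphodiester
#' condensation.
#' @export
WATER_MASS <- 18.015

# Residue (post-condensation) elemental compositions of the 20 amino acids.
.AA_COMPOSITION <- list(
  A = c(C = 3, H = 5,  N = 1, O = 1),
  C = c(C = 3, H = 5,  N = 1, O = 1, S = 1),
  D = c(C = 4, H = 5,  N = 1, O = 3),
  E = c(C = 5, H = 7,  N = 1, O = 3),
  F = c(C = 9, H = 9,  N = 1, O = 1),
  G = c(C = 2, H = 3,  N = 1, O = 1),
  H = c(C = 6, H = 7,  N = 3, O = 1),
  I = c(C = 6, H = 11, N = 1, O = 1),
  K = c(C = 6, H = 12, N = 2, O = 1),
  L = c(C = 6, H = 11, N = 1, O = 1),
  M = c(C = 5, H = 9,  N = 1, O = 1, S = 1),
  N = c(C = 4, H = 6,  N = 2, O = 2),
  P = c(C = 5, H = 7,  N = 1, O = 1),
  Q = c(C = 5, H = 8,  N = 2, O = 2),
  R = c(C = 6, H = 12, N = 4, O = 1),
  S = c(C = 3, H = 5,  N = 1, O = 2),
  T = c(C = 4, H = 7,  N = 1, O = 2),
  V = c(C = 5, H = 9,  N = 1, O = 1),
  W = c(C = 11, H = 10, N = 2, O = 1),
  Y = c(C = 9, H = 9,  N = 1, O = 2)
)

# Approximate proteome-wide residue frequencies (Swiss-Prot composition,
# order of AA_ALPHABET); used as the default background for simulation.
.AA_BACKGROUND <- c(
  A = 0.0826, C = 0.0137, D = 0.0546, E = 0.0672, F = 0.0386,
  G = 0.0708, H = 0.0227, I = 0.0593, K = 0.0581, L = 0.0965,
  M = 0.0241, N = 0.0406, P = 0.0475, Q = 0.0393, R = 0.0553,
  S = 0.0663, T = 0.0535, V = 0.0686, W = 0.0110, Y = 0.0292
)
.AA_BACKGROUND <- .AA_BACKGROUND / sum(.AA_BACKGROUND)

#' Uniform residue background
#'
#' Probability 1/20 for each canonical residue, named by residue.
#' @return Named numeric vector of length 20 summing to 1.
#' @export
uniform_background <- function() {
  stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
}

#' Swiss-Prot-like residue background
#'
#' Average proteome residue frequencies; the default background for the
#' synthetic-genome generator.
#' @return Named numeric vector of length 20 summing to 1.
#' @export
proteome_background <- function() .AA_BACKGROUND
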