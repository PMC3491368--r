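# Monoisotopic mass bookkeeping.
#
# Everything is derived from CODATA/NIST atomic masses so that residue and
# modification deltas stay mutually consistent (mass additivity holds exactly
# in double precision). Residue compositions are the standard 20 amino-acid
# residues (i.e. amino acid minus water).

.ATOM <- c(
  H = 1.00782503207,
  D = 2.01410177785,
  C = 12.0,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100
)

PROTON_MASS <- 1.00727646688
WATER_MASS <- 2 * .ATOM[["H"]] + .ATOM[["O"]]

.formula_mass <- function(counts) {
  sum(.ATOM[names(counts)] * counts)
}

# residue elemental compositions (C, H, N, O, S)
.RESIDUE_FORMULA <- list(
  G = c(C = 2, H = 3, N = 1, O = 1),
  A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),
  P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1),
  T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1),
  I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),
  D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),
  K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),
  F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1),
  Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1)
)

RESIDUE_MASS <- vapply(.RESIDUE_FORMULA, .formula_mass, numeric(1))

# Modification deltas. Propionyl-d5 is propionyl with the five alkyl
# hydrogens replaced by deuterium.
MOD_MASS <- c(
  unmod = 0,
  me1 = .formula_mass(c(C = 1, H = 2)),
  me2 = .formula_mass(c(C = 2, H = 4)),
  me3 = .formula_mass(c(C = 3, H = 6)),
  ac = .formula_mass(c(C = 2, H = 2, O = 1)),
  `propionyl-d0` = .formula_mass(c(C = 3, H = 4, O = 1)),
  `propionyl-d5` = .formula_mass(c(C = 3, O = 1)) -
    .ATOM[["H"]] + 5 * .ATOM[["D"]]
)

#' Monoisotopic mass of an unmodified peptide backbone
#'
#' Sum of residue monoisotopic masses plus one water.
#'
#' @param sequence Peptide sequence (uppercase one-letter amino acids).
#' @return Neutral monoisotopic mass in Daltons.
#' @examples
#' peptide_mass("GG") # 132.0535
#' @export
peptide_mass <- function(sequence) {
  aa <- strsplit(sequence, "")[[1]]
  bad <- setdiff(aa, names(RESIDUE_MASS))
  if (length(bad)) {
    stop("non-amino-acid character(s): ", paste(unique(bad), collapse = ", "))
  }
  sum(RESIDUE_MASS[aa]) + WATER_MASS
}

#' m/z of a protonated ion
#'
#' @param mass Neutral monoisotopic mass (Da).
#' @param charge Positive integer charge state.
#' @return m/z = (mass + charge * proton) / charge.
#' @export
precursor_mz <- function(mass, charge) {
  if (any(charge < 1)) stop("charge must be >= 1")
  (mass + charge * PROTON_MASS) / charge
}
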