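#' Monoisotopic mass constants
#'
#' Residue (i.e. dehydrated amino-acid) monoisotopic masses in Da for the 20
#' standard amino acids, together with the physical constants used throughout
#' the mass arithmetic: the proton mass (added per charge), the mass of water
#' (added once for a linear peptide, absent from a head-to-tail cyclic one),
#' the hydrogen mass (two are lost per disulfide bond) and the
#' carbamidomethyl adduct mass (added per cysteine upon iodoacetamide
#' alkylation).
#'
#' @return A list with elements `residues` (named numeric vector of 20
#'   residue masses), `proton`, `water`, `hydrogen` and `carbamidomethyl`.
#' @examples
#' mass_constants()$residues[["G"]]  # glycine residue, 57.02146
#' @export
mass_constants <- function() {
  list(
    residues = c(
      G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
      V = 99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
      I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
      K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
      F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
    ),
    proton = 1.007276,
    water = 18.010565,
    hydrogen = 1.007825,
    carbamidomethyl = 57.021464
  )
}

# Spacing between adjacent isotope peaks of a singly-charged ion (Da).
.ISOTOPE_SPACING <- 1.00336

.AA20 <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S",
           "T","V","W","Y")

# Consensus coordinate system shared by the reference bundle, the anchoring
# stage and the synthetic generator.  Position 0 is the N-terminal cleavage
# site of the (first) cyclotide domain; prodomain positions are negative.
# All intervals are inclusive on both ends.
.consensus_layout <- function() {
  list(
    er   = c(-76L, -58L),
    ntpp = c(-57L, -20L),
    ntr  = c(-19L,  -1L),
    cd   = c(  0L,  44L),
    ctr  = c( 45L,  54L),
    # the six conserved cysteine columns of the cyclotide domain
    cys_cols = c(4L, 12L, 19L, 28L, 31L, 38L),
    # consensus column of the loop-6 Asn/Asp cyclization residue
    nd_col = 44L,
    # inter-cysteine loop column blocks (loop6b: residues preceding Cys I)
    loop_blocks = list(
      loop6b = c(0L, 3L),  loop1 = c(5L, 11L), loop2 = c(13L, 18L),
      loop3 = c(20L, 27L), loop4 = c(29L, 30L), loop5 = c(32L, 37L),
      loop6a = c(39L, 44L)
    ),
    # prodomain signature windows
    indel_window = c(-56L, -38L),
    moebius_del1 = c(-56L, -54L),
    moebius_del2 = c(-50L, -38L),
    hybrid_ins   = c(-32L, -31L),
    linear_marks = c(-49L, -48L, -39L),
    ntr_sig      = c(-9L, -8L)
  )
}

# residue pools admitted at the NTR signature positions [-9, -8]
.sig_pools <- function() {
  list(
    moebius_cyclic_9  = c("Y", "F", "H"),
    moebius_cyclic_8  = c("S", "A", "Y", "F"),
    bracelet_cyclic_9 = c("H", "N", "S", "T", "G", "K", "P", "R"),
    bracelet_cyclic_8 = c("L", "N", "S", "F", "A", "P"),
    bracelet_linear_9 = c("Q", "E", "P", "K"),
    bracelet_linear_8 = c("D", "N"),
    linear_mark_49 = c("P", "A", "L"),
    linear_mark_48 = c("N", "A"),
    linear_mark_39 = c("D", "E")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
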