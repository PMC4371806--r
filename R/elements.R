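# Elemental constants: monoisotopic masses, natural isotope abundances and
# amino-acid residue compositions over the CHNOS alphabet.
#
# Values are the standard IUPAC/NIST reference numbers used throughout
# quantitative proteomics. Only C, H, N, O and S are modeled: the twenty
# standard residues contain no other element.

# Monoisotopic masses of the lightest isotope of each element (Da).
ELEMENT_MONO_MASS <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100
)

PROTON_MASS <- 1.007276466812

# Nominal spacing between successive isotopologue sticks (Da): a compromise
# between the 13C-12C (1.003355) and 15N-14N (1.002388) mass differences,
# adequate for stick positioning at ppm-level matching tolerances.
ISOTOPOLOGUE_SPACING <- 1.00286864

# Natural isotopic abundance of each element, indexed by neutron shift
# relative to the lightest isotope (position 1 = shift 0). Sulfur has no
# 35S in nature, hence the zero at shift 3.
NATURAL_ABUNDANCE <- list(
  C = c(0.9893, 0.0107),
  H = c(0.999885, 0.000115),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205),
  S = c(0.9499, 0.0075, 0.0425, 0.0000, 0.0001)
)

NATURAL_15N <- NATURAL_ABUNDANCE$N[2]

# Residue (not free amino acid) compositions: columns C, H, N, O, S.
# A peptide's composition is the sum of its residues plus one water.
AA_RESIDUE_COMPOSITION <- matrix(
  c(
    # C   H   N  O  S
      3,  5,  1, 1, 0,  # A
      6, 12,  4, 1, 0,  # R
      4,  6,  2, 2, 0,  # N
      4,  5,  1, 3, 0,  # D
      3,  5,  1, 1, 1,  # C
      5,  7,  1, 3, 0,  # E
      5,  8,  2, 2, 0,  # Q
      2,  3,  1, 1, 0,  # G
      6,  7,  3, 1, 0,  # H
      6, 11,  1, 1, 0,  # I
      6, 11,  1, 1, 0,  # L
      6, 12,  2, 1, 0,  # K
      5,  9,  1, 1, 1,  # M
      9,  9,  1, 1, 0,  # F
      5,  7,  1, 1, 0,  # P
      3,  5,  1, 2, 0,  # S
      4,  7,  1, 2, 0,  # T
     11, 10,  2, 1, 0,  # W
      9,  9,  1, 2, 0,  # Y
      5,  9,  1, 1, 0   # V
  ),
  ncol = 5, byrow = TRUE,
  dimnames = list(
    c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
      "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
    c("C", "H", "N", "O", "S")
  )
)

WATER_COMPOSITION <- c(C = 0L, H = 2L, N = 0L, O = 1L, S = 0L)
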