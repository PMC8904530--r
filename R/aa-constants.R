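# Amino-acid constants shared by the descriptor encoders.
#
# Column-order conventions:
#   * composition-style descriptors use alphabetical single-letter order (AA_ORDER)
#   * PSSM profiles keep the PSI-BLAST column order (PSSM_COL_ORDER)

#' Standard amino-acid alphabet, alphabetical single-letter order
#' @keywords internal
AA_ORDER <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' PSI-BLAST PSSM column order
#' @keywords internal
PSSM_COL_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Synonymous-codon counts of the standard genetic code (total 61 sense codons);
# used by the dipeptide-deviation-from-expectation encoder.
CODON_COUNTS <- c(A = 4, C = 2, D = 2, E = 2, F = 2, G = 4, H = 2, I = 3,
                  K = 2, L = 6, M = 1, N = 2, P = 4, Q = 2, R = 6, S = 6,
                  T = 4, V = 4, W = 1, Y = 2)

# Thirteen physicochemical properties, each partitioning the 20 residues into
# three groups (the iFeature CTD grouping: seven hydrophobicity scales plus
# van der Waals volume, polarity, polarizability, charge, secondary structure
# and solvent accessibility). 13 properties x 3 groups = 39 composition /
# transition values and 13 x 3 x 5 = 195 distribution values.
CTD_GROUPS <- list(
  hydrophobicity_PRAM900101 = c("RKEDQN",     "GASTPHY",          "CLVIMFW"),
  hydrophobicity_ARGP820101 = c("QSTNGDE",    "RAHCKMV",          "LYPFIW"),
  hydrophobicity_ZIMJ680101 = c("QNGSWTDERA", "HMCKV",            "LPFYI"),
  hydrophobicity_PONP930101 = c("KPDESNQT",   "GRHA",             "YMFWLCVI"),
  hydrophobicity_CASG920101 = c("KDEQPSRNTG", "AHYMLV",           "FIWC"),
  hydrophobicity_ENGD860101 = c("RDKENQHYP",  "SGTAW",            "CVLIMF"),
  hydrophobicity_FASG890101 = c("KERSQD",     "NTPG",             "AYHWVMFLIC"),
  normwaalsvolume           = c("GASTPDC",    "NVEQIL",           "MHKFRYW"),
  polarity                  = c("LIFWCMVY",   "PATGS",            "HQRKNED"),
  polarizability            = c("GASDT",      "CPNVEQIL",         "KMHFRYW"),
  charge                    = c("KR",         "ANCQGHILMFPSTWYV", "DE"),
  secondarystruct           = c("EALMQKRH",   "VIYCWFT",          "GNPSD"),
  solventaccess             = c("ALFCGIVW",   "RKQEND",           "MSPTHY")
)

# The three properties of classic pseudo amino-acid composition:
# hydrophobicity (Tanford-style consensus), hydrophilicity (Hopp-Woods) and
# side-chain mass. Raw values; each is standardised over the 20 residues
# (mean 0, population sd 1) before use.
PAAC_HYDROPHOBICITY <- c(
  A =  0.62, C =  0.29, D = -0.90, E = -0.74, F =  1.19,
  G =  0.48, H = -0.40, I =  1.38, K = -1.50, L =  1.06,
  M =  0.64, N = -0.78, P =  0.12, Q = -0.85, R = -2.53,
  S = -0.18, T = -0.05, V =  1.08, W =  0.81, Y =  0.26)

PAAC_HYDROPHILICITY <- c(
  A = -0.5, C = -1.0, D =  3.0, E =  3.0, F = -2.5,
  G =  0.0, H = -0.5, I = -1.8, K =  3.0, L = -1.8,
  M = -1.3, N =  0.2, P =  0.0, Q =  0.2, R =  3.0,
  S =  0.3, T = -0.4, V = -1.5, W = -3.4, Y = -2.3)

PAAC_SIDECHAIN_MASS <- c(
  A =  15, C =  47, D =  59, E =  73, F =  91,
  G =   1, H =  82, I =  57, K =  73, L =  57,
  M =  75, N =  58, P =  42, Q =  72, R = 101,
  S =  31, T =  45, V =  43, W = 130, Y = 107)

#' Default AAindex-style property tables for the 11-dimensional AAI encoder
#'
#' Eleven broadly used residue property scales: Kyte-Doolittle hydropathy,
#' Hopp-Woods hydrophilicity, side-chain mass, residue volume (Zamyatnin),
#' Grantham polarity, amino-acid isoelectric point, average flexibility
#' (Bhaskaran-Ponnuswamy), accessible surface area (Chothia), and the
#' Chou-Fasman helix, sheet and turn propensities. Each index is min-max
#' normalised to `[0, 1]` over the 20 residues before averaging, so only the
#' relative ordering of values matters. Override by passing your own named
#' list of length-20 named vectors to [encode_aai()].
#'
#' @return Named list of 11 numeric vectors, each named by `AA_ORDER` residues.
#' @export
default_aaindex_set <- function() {
  list(
    hydropathy_KD = c(
      A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8, G = -0.4, H = -3.2,
      I =  4.5, K = -3.9, L =  3.8, M =  1.9, N = -3.5, P = -1.6, Q = -3.5,
      R = -4.5, S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3),
    hydrophilicity_HW = PAAC_HYDROPHILICITY,
    side_chain_mass = PAAC_SIDECHAIN_MASS,
    residue_volume = c(
      A =  88.6, C = 108.5, D = 111.1, E = 138.4, F = 189.9, G =  60.1,
      H = 153.2, I = 166.7, K = 168.6, L = 166.7, M = 162.9, N = 114.1,
      P = 112.7, Q = 143.8, R = 173.4, S =  89.0, T = 116.1, V = 140.0,
      W = 227.8, Y = 193.6),
    polarity_grantham = c(
      A =  8.1, C =  5.5, D = 13.0, E = 12.3, F =  5.2, G =  9.0, H = 10.4,
      I =  5.2, K = 11.3, L =  4.9, M =  5.7, N = 11.6, P =  8.0, Q = 10.5,
      R = 10.5, S =  9.2, T =  8.6, V =  5.9, W =  5.4, Y =  6.2),
    isoelectric_point = c(
      A = 6.00, C = 5.07, D = 2.77, E = 3.22, F = 5.48, G = 5.97, H = 7.59,
      I = 6.02, K = 9.74, L = 5.98, M = 5.74, N = 5.41, P = 6.30, Q = 5.65,
      R = 10.76, S = 5.68, T = 5.60, V = 5.96, W = 5.89, Y = 5.66),
    flexibility_BP = c(
      A = 0.357, C = 0.346, D = 0.511, E = 0.497, F = 0.314, G = 0.544,
      H = 0.323, I = 0.462, K = 0.466, L = 0.365, M = 0.295, N = 0.463,
      P = 0.509, Q = 0.493, R = 0.529, S = 0.507, T = 0.444, V = 0.386,
      W = 0.305, Y = 0.420),
    surface_area_chothia = c(
      A = 115, C = 135, D = 150, E = 190, F = 210, G =  75, H = 195,
      I = 175, K = 200, L = 170, M = 185, N = 160, P = 145, Q = 180,
      R = 225, S = 115, T = 140, V = 155, W = 255, Y = 230),
    helix_CF = c(
      A = 1.42, C = 0.70, D = 1.01, E = 1.51, F = 1.13, G = 0.57, H = 1.00,
      I = 1.08, K = 1.16, L = 1.21, M = 1.45, N = 0.67, P = 0.57, Q = 1.11,
      R = 0.98, S = 0.77, T = 0.83, V = 1.06, W = 1.08, Y = 0.69),
    sheet_CF = c(
      A = 0.83, C = 1.19, D = 0.54, E = 0.37, F = 1.38, G = 0.75, H = 0.87,
      I = 1.60, K = 0.74, L = 1.30, M = 1.05, N = 0.89, P = 0.55, Q = 1.10,
      R = 0.93, S = 0.75, T = 1.19, V = 1.70, W = 1.37, Y = 1.47),
    turn_CF = c(
      A = 0.66, C = 1.19, D = 1.46, E = 0.74, F = 0.60, G = 1.56, H = 0.95,
      I = 0.47, K = 1.01, L = 0.59, M = 0.60, N = 1.56, P = 1.52, Q = 0.98,
      R = 0.95, S = 1.43, T = 0.96, V = 0.50, W = 0.96, Y = 1.14)
  )
}

# Standardise a residue property table to mean 0 / population sd 1 over the
# 20 residues (the pseudo amino-acid composition convention).
paac_normalise <- function(h) {
  h <- h[AA_ORDER]
  (h - mean(h)) / sqrt(mean((h - mean(h))^2))
}
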