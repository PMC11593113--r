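# Shared alphabets and physicochemical tables used by the feature encoders.
#
# All tables are keyed by the 20 standard amino acids in the fixed order
# AA_ALPHABET; "*" is the terminal-padding symbol and never carries a value.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
PAD_SYMBOL <- "*"
AA_PAD_ALPHABET <- c(AA_ALPHABET, PAD_SYMBOL)

# Residue classes: O-phosphorylation on hydroxyl side chains, N-phosphorylation
# on nitrogen side chains.
PHOSPHO_RESIDUES <- c("S", "T", "Y", "H", "R", "K")
O_RESIDUES <- c("S", "T", "Y")
N_RESIDUES <- c("H", "R", "K")

# Fixed registry order of the ten feature channels; the integration vector
# V = (D1, ..., D10) follows this order everywhere.
FEATURE_CHANNELS <- c("APAAC", "CKSAAP", "CTDC", "DDE", "DistancePair",
                      "EAAC", "PAAC", "GPS", "TRANSFORMER", "PLM")

# Chou's pseudo-amino-acid-composition property tables (hydrophobicity,
# hydrophilicity, side-chain mass), as distributed with the original PseAAC
# server and reused by iFeature-style toolkits.
AA_HYDROPHOBICITY <- c(
  A =  0.62, C =  0.29, D = -0.90, E = -0.74, F =  1.19,
  G =  0.48, H = -0.40, I =  1.38, K = -1.50, L =  1.06,
  M =  0.64, N = -0.78, P =  0.12, Q = -0.85, R = -2.53,
  S = -0.18, T = -0.05, V =  1.08, W =  0.81, Y =  0.26)

AA_HYDROPHILICITY <- c(
  A = -0.5, C = -1.0, D =  3.0, E =  3.0, F = -2.5,
  G =  0.0, H = -0.5, I = -1.8, K =  3.0, L = -1.8,
  M = -1.3, N =  0.2, P =  0.0, Q =  0.2, R =  3.0,
  S =  0.3, T = -0.4, V = -1.5, W = -3.4, Y = -2.3)

AA_SIDECHAIN_MASS <- c(
  A =  15, C =  47, D =  59, E =  73, F =  91,
  G =   1, H =  82, I =  57, K =  73, L =  57,
  M =  75, N =  58, P =  42, Q =  72, R = 101,
  S =  31, T =  45, V =  43, W = 130, Y = 107)

# Standard-genetic-code codon multiplicities (61 sense codons) for the DDE
# descriptor's expected dipeptide means.
AA_CODON_COUNT <- c(
  A = 4, C = 2, D = 2, E = 2, F = 2,
  G = 4, H = 2, I = 3, K = 2, L = 6,
  M = 1, N = 2, P = 4, Q = 2, R = 6,
  S = 6, T = 4, V = 4, W = 1, Y = 2)

# The 13 three-class physicochemical partitions used by the CTDC descriptor
# (the partitions popularised by the composition/transition/distribution
# descriptor family; each splits the 20 amino acids into 3 disjoint groups).
CTDC_GROUPS <- list(
  hydrophobicity_PRAM900101 = c("RKEDQN",     "GASTPHY",           "CLVIMFW"),
  hydrophobicity_ARGP820101 = c("QSTNGDE",    "RAHCKMV",           "LYPFIW"),
  hydrophobicity_ZIMJ680101 = c("QNGSWTDERA", "HMCKV",             "LPFYI"),
  hydrophobicity_PONP930101 = c("KPDESNQT",   "GRHA",              "YMFWLCVI"),
  hydrophobicity_CASG920101 = c("KDEQPSRNTG", "AHYMLV",            "FIWC"),
  hydrophobicity_ENGD860101 = c("RDKENQHYP",  "SGTAW",             "CVLIMF"),
  hydrophobicity_FASG890101 = c("KERSQD",     "NTPG",              "AYHWVMFLIC"),
  normwaalsvolume           = c("GASTPDC",    "NVEQIL",            "MHKFRYW"),
  polarity                  = c("LIFWCMVY",   "PATGS",             "HQRKNED"),
  polarizability            = c("GASDT",      "CPNVEQIL",          "KMHFRYW"),
  charge                    = c("KR",         "ANCQGHILMFPSTWYV",  "DE"),
  secondarystruct           = c("EALMQKRH",   "VIYCWFT",           "GNPSD"),
  solventaccess             = c("ALFCGIVW",   "RKQEND",            "MSPTHY"))

# z-score a property table over the 20 amino acids (population sd), the
# normalisation used by the PAAC/APAAC correlation terms.
normalise_property <- function(x) {
  x <- x[AA_ALPHABET]
  (x - mean(x)) / sqrt(mean((x - mean(x))^2))
}

# Map peptide strings to an integer matrix (rows = windows) over
# AA_PAD_ALPHABET; index 21 is the padding symbol.
peptides_to_matrix <- function(peptides) {
  stopifnot(length(unique(nchar(peptides))) == 1L)
  chars <- strsplit(peptides, "", fixed = TRUE)
  m <- matrix(match(unlist(chars), AA_PAD_ALPHABET),
              nrow = length(peptides), byrow = TRUE)
  if (anyNA(m)) stop("peptide contains a symbol outside the 20 amino acids + '*'")
  m
}
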