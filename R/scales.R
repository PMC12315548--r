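# Published per-residue scales and property tables used by the descriptor
# engine. Residues are always indexed in alphabetical one-letter order.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Degenerate codes accepted at parse time; X survives normalization and is
# excluded from physicochemical averages.
AA_DEGENERATE <- c("B", "Z", "X", "U", "O")
AA_SUBSTITUTION <- c(U = "C", B = "N", Z = "Q", O = "K")

# Average isotopic residue masses (free amino acids, Da); peptide-bond water
# is subtracted per condensation when summing a chain.
AA_MASS <- c(A = 89.0932, C = 121.1582, D = 133.1027, E = 147.1293,
             F = 165.1891, G = 75.0666, H = 155.1546, I = 131.1729,
             K = 146.1876, L = 131.1729, M = 149.2113, N = 132.1179,
             P = 115.1305, Q = 146.1445, R = 174.201, S = 105.0926,
             T = 119.1192, V = 117.1463, W = 204.2252, Y = 181.1885)
WATER_MASS <- 18.0153

# Kyte & Doolittle (1982) hydropathy.
KYTE_DOOLITTLE <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4,
                    H = -3.2, I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5,
                    P = -1.6, Q = -3.5, R = -4.5, S = -0.8, T = -0.7,
                    V = 4.2, W = -0.9, Y = -1.3)

# Vihinen et al. (1994) normalized B-factor flexibility.
FLEX_VIHINEN <- c(A = 0.984, C = 0.906, D = 1.068, E = 1.094, F = 0.915,
                  G = 1.031, H = 0.95, I = 0.927, K = 1.102, L = 0.935,
                  M = 0.952, N = 1.048, P = 1.049, Q = 1.037, R = 1.008,
                  S = 1.046, T = 0.997, V = 0.931, W = 0.904, Y = 0.929)

# Campen et al. (2008) TOP-IDP disorder propensity.
TOP_IDP <- c(A = 0.06, C = 0.02, D = 0.192, E = 0.736, F = -0.697,
             G = 0.166, H = 0.303, I = -0.486, K = 0.586, L = -0.326,
             M = -0.397, N = 0.007, P = 0.987, Q = 0.318, R = 0.180,
             S = 0.341, T = 0.059, V = -0.121, W = -0.884, Y = -0.510)

# Eisenberg et al. (1984) consensus hydrophobicity, used for the helical
# hydrophobic-moment (amphipathicity) descriptor.
EISENBERG <- c(A = 0.62, C = 0.29, D = -0.90, E = -0.74, F = 1.19, G = 0.48,
               H = -0.40, I = 1.38, K = -1.50, L = 1.06, M = 0.64, N = -0.78,
               P = 0.12, Q = -0.85, R = -2.53, S = -0.18, T = -0.05,
               V = 1.08, W = 0.81, Y = 0.26)

# Radzicka & Wolfenden (1988) water-to-cyclohexane transfer free energies
# (kcal/mol); the Boman (2003) protein-binding index is minus their mean.
# Proline was not measured and is assigned 0 by the usual toolkit convention.
BOMAN_TFE <- c(A = 1.81, C = 1.28, D = -8.72, E = -6.81, F = 2.98, G = 0.94,
               H = -4.66, I = 4.92, K = -5.55, L = 4.92, M = 2.35, N = -6.64,
               P = 0, Q = -5.54, R = -14.92, S = -3.40, T = -2.57, V = 4.04,
               W = 2.33, Y = -0.14)

# Guruprasad et al. (1990) dipeptide instability weights (DIWV); rows index
# the first residue, columns the second.
DIWV <- matrix(c(
  1, 44.94, -7.49, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 1,
  1, 1, 20.26, 1, 1, 1, 33.6, 1, 1, 20.26, 33.6, 1, 20.26, -6.54, 1, 1, 33.6, -6.54, 24.68, 1,
  1, 1, 1, 1, -6.54, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, -6.54, 20.26, -14.03, 1, 1, 1,
  1, 44.94, 20.26, 33.6, 1, 1, -6.54, 20.26, 1, 1, 1, 1, 20.26, 20.26, 1, 20.26, 1, 1, -14.03, 1,
  1, 1, 13.34, 1, 1, 1, 1, 1, -14.03, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 33.601,
  -7.49, 1, 1, -6.54, 1, 13.34, 1, -7.49, -7.49, 1, 1, -7.49, 1, 1, 1, 1, -7.49, 1, 13.34, -7.49,
  1, 1, 1, 1, -9.37, -9.37, 1, 44.94, 24.68, 1, 1, 24.68, -1.88, 1, 1, 1, -6.54, 1, -1.88, 44.94,
  1, 1, 1, 44.94, 1, 1, 13.34, 1, -7.49, 20.26, 1, 1, -1.88, 1, 1, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, -7.49, 1, -7.49, 1, -7.49, 33.6, 1, -6.54, 24.64, 33.6, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, 1, 1, 1, -7.49, 1, 1, 1, 20.26, 33.6, 20.26, 1, 1, 1, 24.68, 1,
  13.34, 1, 1, 1, 1, 1, 58.28, 1, 1, 1, -1.88, 1, 44.94, -6.54, -6.54, 44.94, -1.88, 1, 1, 24.68,
  1, -1.88, 1, 1, -14.03, -14.03, 1, 44.94, 24.68, 1, 1, 1, -1.88, -6.54, 1, 1, -7.49, 1, -9.37, 1,
  20.26, -6.54, -6.54, 18.38, 20.26, 1, 1, 1, 1, 1, -6.54, 1, 20.26, 20.26, -6.54, 20.26, 1, 20.26, -1.88, 1,
  1, -6.54, 20.26, 20.26, -6.54, 1, 1, 1, 1, 1, 1, 1, 20.26, 20.26, 1, 44.94, 1, -6.54, 1, -6.54,
  1, 1, 1, 1, 1, -7.49, 20.26, 1, 1, 1, 1, 13.34, 20.26, 20.26, 58.28, 44.94, 1, 1, 58.28, -6.54,
  1, 33.6, 1, 20.26, 1, 1, 1, 1, 1, 1, 1, 1, 44.94, 20.26, 20.26, 20.26, 1, 1, 1, 1,
  1, 1, 1, 20.26, 13.34, -7.49, 1, 1, 1, 1, 1, -14.03, 1, -6.54, 1, 1, 1, 1, -14.03, 1,
  1, 1, -14.03, 1, 1, -7.49, 1, 1, -1.88, 1, 1, 1, 20.26, 1, 1, 1, -7.49, 1, 1, -6.54,
  -14.03, 1, 1, 1, 1, -9.37, 24.68, 1, 1, 13.34, 24.68, 13.34, 1, 1, 1, 1, -14.03, -7.49, 1, 1,
  24.68, 1, 24.68, -6.54, 1, -7.49, 13.34, 1, 1, 1, 44.94, 1, 13.34, 1, -15.91, 1, -7.49, 1, -9.37, 13.34
), nrow = 20, byrow = TRUE, dimnames = list(AA_ALPHABET, AA_ALPHABET))

# Bjellqvist pKa sets (as used by the standard protein-analysis toolkits) for
# the Henderson-Hasselbalch charge model behind pI and net charge at pH 7.
PKA_POSITIVE <- c(Nterm = 7.5, K = 10.0, R = 12.0, H = 5.98)
PKA_NEGATIVE <- c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
PKA_CTERMINAL <- c(D = 4.55, E = 4.75)
PKA_NTERMINAL <- c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82,
                   V = 7.44, E = 7.7)

# Residue sets for secondary-structure fractions (classic single-residue
# propensity convention: helix, sheet, turn/coil).
SS_HELIX <- c("V", "I", "Y", "F", "W", "L")
SS_SHEET <- c("E", "M", "A", "L")
SS_COIL  <- c("N", "P", "G", "S")

AROMATIC <- c("F", "Y", "W")
HYDROPHOBIC_SET <- c("A", "L", "I", "V", "F", "M", "W")

# Chou-type pseudo-amino-acid composition property scales.
PAAC_HYDROPHOBICITY <- EISENBERG
PAAC_HYDROPHILICITY <- c(A = -0.5, C = -1.0, D = 3.0, E = 3.0, F = -2.5,
                         G = 0.0, H = -0.5, I = -1.8, K = 3.0, L = -1.8,
                         M = -1.3, N = 0.2, P = 0.0, Q = 0.2, R = 3.0,
                         S = 0.3, T = -0.4, V = -1.5, W = -3.4, Y = -2.3)
PAAC_SIDECHAIN_MASS <- c(A = 15.0, C = 47.0, D = 59.0, E = 73.0, F = 91.0,
                         G = 1.0, H = 82.0, I = 57.0, K = 73.0, L = 57.0,
                         M = 75.0, N = 58.0, P = 42.0, Q = 72.0, R = 101.0,
                         S = 31.0, T = 45.0, V = 43.0, W = 130.0, Y = 107.0)

# Composition/transition/distribution class memberships (Dubchak et al. 1995
# three-class groupings over seven physicochemical properties).
CTD_GROUPS <- list(
  hydrophobicity = list(c("R", "K", "E", "D", "Q", "N"),
                        c("G", "A", "S", "T", "P", "H", "Y"),
                        c("C", "L", "V", "I", "M", "F", "W")),
  vdw_volume = list(c("G", "A", "S", "T", "P", "D"),
                    c("N", "V", "E", "Q", "I", "L"),
                    c("M", "H", "K", "F", "R", "Y", "W")),
  polarity = list(c("L", "I", "F", "W", "C", "M", "V", "Y"),
                  c("P", "A", "T", "G", "S"),
                  c("H", "Q", "R", "K", "N", "E", "D")),
  polarizability = list(c("G", "A", "S", "D", "T"),
                        c("C", "P", "N", "V", "E", "Q", "I", "L"),
                        c("K", "M", "H", "F", "R", "Y", "W")),
  charge = list(c("K", "R"),
                c("A", "N", "C", "Q", "G", "H", "I", "L", "M", "F", "P",
                  "S", "T", "W", "Y", "V"),
                c("D", "E")),
  secondary_structure = list(c("E", "A", "L", "M", "Q", "K", "R", "H"),
                             c("V", "I", "Y", "C", "W", "F", "T"),
                             c("G", "N", "P", "S", "D")),
  solvent_accessibility = list(c("A", "L", "F", "C", "G", "I", "V", "W"),
                               c("R", "K", "Q", "E", "N", "D"),
                               c("M", "S", "P", "T", "H", "Y")))

# Average amino-acid frequencies of the curated human/Swiss-Prot proteome,
# used as the background composition of the synthetic generator.
BACKGROUND_COMPOSITION <- c(A = 8.25, C = 1.38, D = 5.45, E = 6.72, F = 3.86,
                            G = 7.07, H = 2.27, I = 5.91, K = 5.80, L = 9.65,
                            M = 2.41, N = 4.06, P = 4.74, Q = 3.93, R = 5.53,
                            S = 6.65, T = 5.36, V = 6.86, W = 1.10,
                            Y = 2.92) / 100

ER_RETENTION_MOTIFS <- c("KDEL", "HDEL", "KEEL", "QEEL")
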