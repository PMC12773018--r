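# Shared constants: canonical alphabet, residue scales, pKa table.

# 20 canonical residues, fixed order used by one-hot featurizers
AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")

# Kyte-Doolittle hydropathy
KD_HYDROPATHY <- c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
                   Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
                   L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
                   S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

# average residue masses (Da); peptide MW = sum + one water
RESIDUE_MASS <- c(G =  57.0519, A =  71.0788, S =  87.0782, P =  97.1167,
                  V =  99.1326, T = 101.1051, C = 103.1388, L = 113.1594,
                  I = 113.1594, N = 114.1038, D = 115.0886, Q = 128.1307,
                  K = 128.1741, E = 129.1155, M = 131.1926, H = 137.1411,
                  F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
WATER_MASS <- 18.0153

# EMBOSS-style pKa scale (default for pI / net charge; configurable)
PKA_EMBOSS <- list(
  nterm = 8.6, cterm = 3.6,
  positive = c(K = 10.8, R = 12.5, H = 6.5),
  negative = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
)

`%||%` <- function(x, y) if (is.null(x)) y else x
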