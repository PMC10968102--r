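# Amino-acid reference tables (20 canonical residues, one-letter codes).
# Residue masses exclude water; peptide mass = sum(residues) + H2O.

.AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Kyte-Doolittle hydropathy scale
.KD_SCALE <- c(
  I =  4.5, V =  4.2, L =  3.8, F =  2.8, C =  2.5, M =  1.9, A =  1.8,
  G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6, H = -3.2,
  D = -3.5, E = -3.5, N = -3.5, Q = -3.5, K = -3.9, R = -4.5)

.AROMATIC <- c("F", "W", "Y")

# formal side-chain charge at neutral pH (His treated as neutral)
.SIDECHAIN_CHARGE <- c(R = 1L, K = 1L, H = 0L, D = -1L, E = -1L)

# side-chain nitrogen atoms (backbone contributes one N per residue)
.SIDECHAIN_N <- c(R = 3L, K = 1L, H = 2L, N = 1L, Q = 1L, W = 1L)

# monoisotopic residue masses, Da
.MASS_MONO <- c(
  G =  57.02146, A =  71.03711, S =  87.03203, P =  97.05276, V =  99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)

# average residue masses, Da
.MASS_AVG <- c(
  G =  57.0519, A =  71.0788, S =  87.0782, P =  97.1167, V =  99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)

.MASS_H2O_MONO <- 18.0105646
.MASS_H2O_AVG  <- 18.01528
.MASS_H_ATOM   <- 1.0078250319
.MASS_PROTON   <- 1.007276466
# mass shift per 14N -> 15N substitution
.MASS_D15N     <- 15.0001089 - 14.0030740
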