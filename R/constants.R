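# Physical constants and per-residue tables used across the package.
# Masses in Da; average masses follow IUPAC 2021 atomic weights, monoisotopic
# masses the most abundant isotopes.

#' Average masses of the 20 standard amino-acid residues (Da)
#'
#' Residue masses (i.e. the mass contributed inside a peptide chain, water
#' already removed). Add one water for a free linear peptide.
#' @keywords internal
AA_MASS_AVG <- c(
  G = 57.0519,  A = 71.0788,  S = 87.0782,  P = 97.1167,  V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

#' Monoisotopic masses of the 20 standard amino-acid residues (Da)
#' @keywords internal
AA_MASS_MONO <- c(
  G = 57.02146,  A = 71.03711,  S = 87.03203,  P = 97.05276,  V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

WATER_AVG  <- 18.01528
WATER_MONO <- 18.010565

# Proton mass used for charge arithmetic (m/z <-> neutral mass).
PROTON_MASS <- 1.00728

# Hydrogen masses removed per disulfide bond (2 H per bond).
HYDROGEN_AVG  <- 1.00794
HYDROGEN_MONO <- 1.0078250319

# C-terminal amidation replaces the free acid -OH by -NH2 (loss of ~1 Da).
AMIDATION_DELTA_AVG  <- 0.98476
AMIDATION_DELTA_MONO <- 0.98402

#' Kyte-Doolittle hydropathy scale
#' @keywords internal
KD_HYDROPATHY <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

# Small residues accepted at the -1/-3 positions of a signal-peptidase site.
SIGNAL_SMALL_RESIDUES <- c("A", "G", "S", "C", "T")

# Gumbel parameters for Smith-Waterman bit-free raw scores under
# BLOSUM62 / gap open 11 / gap extend 1, fitted once by the method of
# moments against 600 locally aligned shuffled-composition protein pairs
# (120 aa x 120 aa). E = K * m * n * exp(-lambda * S).
SW_EVALUE_LAMBDA <- 0.2968
SW_EVALUE_K      <- 0.0618

AA_STANDARD <- names(AA_MASS_AVG)

# IUPAC nucleotide codes accepted on input; analysis itself uses A/C/G/T and
# treats every ambiguity code like N (codons containing them are not called).
DNA_IUPAC <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V")
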