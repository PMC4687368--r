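# Physical constants and ideal backbone geometry shared across the package.
# Units throughout: Angstrom, degrees, kcal/mol, fs, amu.

#' @keywords internal
.pb <- new.env(parent = emptyenv())

# Boltzmann constant, kcal/(mol K)
KB_KCAL <- 0.0019872041
# Coulomb prefactor for charges in e and distances in Angstrom -> kcal/mol
COULOMB_K <- 332.0636
# acceleration conversion: (kcal/mol/A) / amu -> A/fs^2
ACC_CONV <- 4.184e-4

# Ideal backbone internal coordinates (standard peptide geometry).
BB_GEOM <- list(
  b_n_ca  = 1.458,  # N-CA
  b_ca_c  = 1.525,  # CA-C
  b_c_n   = 1.329,  # C-N peptide bond
  b_c_o   = 1.231,  # C=O
  b_c_oxt = 1.250,  # terminal carboxylate C-O
  b_n_h   = 1.010,  # amide N-H
  a_n_ca_c  = 111.2,
  a_ca_c_n  = 116.6,
  a_c_n_ca  = 121.9,
  a_ca_c_o  = 120.4,
  a_ca_c_oxt = 117.0,
  a_ca_n_h  = 118.2,
  omega     = 180.0
)

# Atomic masses by element (amu)
ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                  S = 32.06, P = 30.974)

# Default per-element Lennard-Jones parameters (rmin/2 in A, eps in kcal/mol).
# Plausible placeholder values for the toy force field; templates may override.
ELEMENT_LJ <- data.frame(
  element = c("H", "C", "N", "O", "S", "P"),
  rmin2   = c(1.10, 1.908, 1.824, 1.661, 2.000, 2.100),
  eps     = c(0.0157, 0.0860, 0.1700, 0.2100, 0.2500, 0.2000)
)

# Secondary-structure restraint table: ideal backbone torsions per state.
SS_TORSIONS <- list(
  H = c(phi = -60, psi = -40),
  E = c(phi = -120, psi = 120),
  C = c(phi = 180, psi = 180)   # extended conformation
)

#' Default service bounds on peptide length
#' @keywords internal
LENGTH_BOUNDS <- c(min = 7L, max = 25L)
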