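# Physical constants and static tables shared across modules.

# Boltzmann constant in kcal/(mol K); kB*T ~ 0.596 kcal/mol at 300 K.
.kB <- 0.0019872

# Standard heavy-atom chi torsion definitions (chi1..chi4), per residue type.
# Each entry is a list of atom-name quadruples in N->side-chain order.
.CHI_ATOMS <- list(
  ARG = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "NE"), c("CG", "CD", "NE", "CZ")),
  ASN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  ASP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  CYS = list(c("N", "CA", "CB", "SG")),
  GLN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  GLU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  HIS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "ND1")),
  ILE = list(c("N", "CA", "CB", "CG1"), c("CA", "CB", "CG1", "CD1")),
  LEU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  LYS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "CE"), c("CG", "CD", "CE", "NZ")),
  MET = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "SD"),
             c("CB", "CG", "SD", "CE")),
  PHE = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  PRO = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD")),
  SER = list(c("N", "CA", "CB", "OG")),
  THR = list(c("N", "CA", "CB", "OG1")),
  TRP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  TYR = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  VAL = list(c("N", "CA", "CB", "CG1"))
)

# van der Waals radii (Angstrom) used by the SASA point-sampling routine.
.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

# Ideal backbone geometry for the internal-coordinate chain builder.
.IDEAL_GEOM <- list(
  b_N_CA = 1.458, b_CA_C = 1.525, b_C_N = 1.329,
  b_C_O = 1.231, b_CA_CB = 1.521,
  a_N_CA_C = 111.2, a_CA_C_N = 116.2, a_C_N_CA = 121.7,
  a_CA_C_O = 120.8, a_N_CA_CB = 110.4,
  omega = 180
)

.deg2rad <- function(x) x * pi / 180

# wrap angles into [-pi, pi)
.wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y >= pi] <- -pi
  y
}
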