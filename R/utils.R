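# Shared lookup tables and small geometry helpers.

# 3-letter -> 1-letter codes for the 20 standard amino acids.
AA_3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

WATER_NAMES <- c("HOH", "DOD", "WAT")

# Every metallic element symbol (upper case, as PDB element columns print
# them): alkali, alkaline-earth, transition, post-transition,
# lanthanides and actinides. Na/K/Mg/Ca are metals here.
METAL_ELEMENTS <- c(
  "LI", "NA", "K", "RB", "CS", "FR",
  "BE", "MG", "CA", "SR", "BA", "RA",
  "SC", "TI", "V", "CR", "MN", "FE", "CO", "NI", "CU", "ZN",
  "Y", "ZR", "NB", "MO", "TC", "RU", "RH", "PD", "AG", "CD",
  "HF", "TA", "W", "RE", "OS", "IR", "PT", "AU", "HG",
  "AL", "GA", "IN", "SN", "TL", "PB", "BI", "PO",
  "LA", "CE", "PR", "ND", "PM", "SM", "EU", "GD", "TB", "DY",
  "HO", "ER", "TM", "YB", "LU",
  "AC", "TH", "PA", "U", "NP", "PU", "AM", "CM", "BK", "CF",
  "ES", "FM", "MD", "NO", "LR"
)

# Heavy atoms allowed in a backbone-only model. OXT is the terminal
# carboxyl oxygen, part of the main chain, not a side chain.
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "CB", "OXT")

EXCLUSION_REASONS <- c(
  NOT_IN_ASSEMBLY  = "Not in the biological assembly",
  TOO_FEW_RESIDUES = "Too few liganding residues",
  TOO_FEW_ATOMS    = "Too few liganding atoms",
  NO_SIDECHAINS    = "No side chain information"
)

#' Angle at a vertex between two points, in degrees
#'
#' Computes the angle subtended at `vertex` by `a` and `b`; used with the
#' metal as vertex when applying the minimum-angle liganding filter.
#'
#' @param vertex,a,b numeric length-3 coordinate vectors (Angstroms).
#' @return angle in degrees, in \[0, 180\].
#' @keywords internal
vertex_angle <- function(vertex, a, b) {
  u <- a - vertex
  v <- b - vertex
  cosang <- sum(u * v) / (sqrt(sum(u * u)) * sqrt(sum(v * v)))
  cosang <- max(-1, min(1, cosang))
  acos(cosang) * 180 / pi
}

# Rotation matrix for angle theta (degrees) about a unit axis (Rodrigues).
rotation_about_axis <- function(axis, theta_deg) {
  axis <- axis / sqrt(sum(axis^2))
  th <- theta_deg * pi / 180
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Deterministic key for one residue instance inside a (possibly expanded)
# model: chain id + copy index + number + insertion code + name.
residue_key <- function(atoms) {
  paste(atoms$chain, atoms$copy_index, atoms$resno, atoms$icode,
        atoms$resname, sep = "|")
}

# Source-level residue key: ignores copy_index, so symmetry copies of the
# same deposited residue share a key.
source_residue_key <- function(atoms) {
  paste(atoms$chain, atoms$resno, atoms$icode, atoms$resname, sep = "|")
}

# Source-level atom identity: (chain, residue number + insertion code,
# atom name), preserved unchanged through assembly transforms.
source_atom_key <- function(atoms) {
  paste(atoms$chain, atoms$resno, atoms$icode, atoms$name, sep = "|")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
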