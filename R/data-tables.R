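# Embedded parameter tables: amino-acid codes, van der Waals radii, reference
# maximum solvent accessibilities, a compact heavy-atom charge set, and the
# ideal-geometry side-chain topology + rotamer library used by the mutator.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
         "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
names(AA1) <- AA3

#' @noRd
aa_three <- function(one) {
  one <- toupper(one)
  hit <- AA3[match(one, AA1)]
  if (any(is.na(hit))) stop("unknown one-letter amino-acid code: ",
                            paste(one[is.na(hit)], collapse = ", "))
  hit
}

#' @noRd
aa_one <- function(three) {
  three <- toupper(three)
  hit <- unname(AA1[three])
  if (any(is.na(hit))) stop("unknown residue type: ",
                            paste(three[is.na(hit)], collapse = ", "))
  hit
}

# Heavy-atom van der Waals radii (Angstrom), used both for SASA and as
# intrinsic Born radii in the Generalized Born term.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20,
               SE = 1.90)

#' @noRd
element_of <- function(elety, elesy = NULL) {
  if (!is.null(elesy)) {
    e <- toupper(trimws(elesy))
    e[is.na(e) | e == ""] <- NA_character_
  } else {
    e <- rep(NA_character_, length(elety))
  }
  miss <- is.na(e)
  if (any(miss)) {
    # fall back to the first alphabetic character of the atom name
    e[miss] <- toupper(substr(gsub("[^A-Za-z].*$", "",
                                   sub("^[0-9]*", "", elety[miss])), 1, 1))
  }
  e
}

# Theoretical maximum (Gly-X-Gly) solvent accessibilities in Angstrom^2,
# Tien et al. 2013 values; reference denominator for relative SASA.
MAX_SASA <- c(
  ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
  GLN = 225.0, GLU = 223.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
  LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
  SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0)

# Lennard-Jones well depths (kcal/mol) and Rmin/2 (Angstrom) by element,
# in the CHARMM Emin/Rmin convention: E(r) = eps*((Rmin/r)^12 - 2*(Rmin/r)^6).
LJ_PARAMS <- data.frame(
  element = c("C", "N", "O", "S"),
  eps  = c(0.105, 0.160, 0.210, 0.250),
  rmin2 = c(1.95, 1.85, 1.70, 2.00),
  stringsAsFactors = FALSE)

# Compact heavy-atom partial charge set (united-atom style: hydrogens are not
# modelled and their charge is absorbed into the bonded heavy atom). Each
# neutral residue sums to 0; Asp/Glu to -1; Lys/Arg to +1. Atoms not listed
# for a residue carry charge 0.
backbone_charges <- c(N = -0.35, CA = 0.35, C = 0.55, O = -0.55, OXT = -0.55)

SIDECHAIN_CHARGES <- list(
  SER = c(CB = 0.30, OG = -0.30),
  THR = c(CB = 0.30, OG1 = -0.30),
  CYS = c(CB = 0.20, SG = -0.20),
  TYR = c(CZ = 0.40, OH = -0.40),
  ASN = c(CB = 0.30, CG = 0.55, OD1 = -0.55, ND2 = -0.30),
  GLN = c(CG = 0.30, CD = 0.55, OE1 = -0.55, NE2 = -0.30),
  ASP = c(CG = 0.40, OD1 = -0.70, OD2 = -0.70),
  GLU = c(CD = 0.40, OE1 = -0.70, OE2 = -0.70),
  LYS = c(CE = 0.30, NZ = 0.70),
  ARG = c(NE = -0.20, CZ = 0.50, NH1 = 0.35, NH2 = 0.35),
  HIS = c(CG = 0.00, ND1 = -0.30, CD2 = 0.15, CE1 = 0.45, NE2 = -0.30),
  TRP = c(CD1 = 0.15, NE1 = -0.30, CE2 = 0.15),
  MET = c(CG = 0.05, SD = -0.10, CE = 0.05))

#' @noRd
atom_charge <- function(resname, atomname) {
  q <- unname(backbone_charges[atomname])
  q[is.na(q)] <- 0
  for (i in seq_along(resname)) {
    sc <- SIDECHAIN_CHARGES[[resname[i]]]
    if (!is.null(sc) && atomname[i] %in% names(sc)) {
      q[i] <- q[i] + unname(sc[atomname[i]])
    }
  }
  q
}

# ---------------------------------------------------------------------------
# Side-chain topology: internal-coordinate recipe for every heavy atom beyond
# C-beta. Atom D is placed from reference atoms (a1, a2, a3) with bond length
# b (C-D), angle ang (B-C-D) and dihedral a1-a2-a3-D equal to the rotamer's
# chi[chi] + off when chi > 0, or the fixed value off when chi == 0.
# C-beta itself is placed by the ideal tetrahedral construction.

sc_row <- function(atom, a1, a2, a3, b, ang, chi, off) {
  data.frame(atom = atom, a1 = a1, a2 = a2, a3 = a3, b = b, ang = ang,
             chi = chi, off = off, stringsAsFactors = FALSE)
}

SIDECHAIN_TOPOLOGY <- list(
  GLY = NULL,
  ALA = NULL,
  SER = sc_row("OG", "N", "CA", "CB", 1.417, 110.8, 1, 0),
  CYS = sc_row("SG", "N", "CA", "CB", 1.808, 113.8, 1, 0),
  THR = rbind(sc_row("OG1", "N", "CA", "CB", 1.433, 109.5, 1, 0),
              sc_row("CG2", "N", "CA", "CB", 1.521, 110.5, 1, -122)),
  VAL = rbind(sc_row("CG1", "N", "CA", "CB", 1.527, 110.5, 1, 0),
              sc_row("CG2", "N", "CA", "CB", 1.527, 110.5, 1, 122)),
  LEU = rbind(sc_row("CG", "N", "CA", "CB", 1.530, 116.3, 1, 0),
              sc_row("CD1", "CA", "CB", "CG", 1.521, 110.7, 2, 0),
              sc_row("CD2", "CA", "CB", "CG", 1.521, 110.7, 2, 122)),
  ILE = rbind(sc_row("CG1", "N", "CA", "CB", 1.530, 110.4, 1, 0),
              sc_row("CG2", "N", "CA", "CB", 1.521, 110.5, 1, -122),
              sc_row("CD1", "CA", "CB", "CG1", 1.513, 113.8, 2, 0)),
  MET = rbind(sc_row("CG", "N", "CA", "CB", 1.520, 114.1, 1, 0),
              sc_row("SD", "CA", "CB", "CG", 1.803, 112.7, 2, 0),
              sc_row("CE", "CB", "CG", "SD", 1.791, 100.9, 3, 0)),
  ASP = rbind(sc_row("CG", "N", "CA", "CB", 1.516, 112.6, 1, 0),
              sc_row("OD1", "CA", "CB", "CG", 1.249, 118.4, 2, 0),
              sc_row("OD2", "CA", "CB", "CG", 1.249, 118.4, 2, 180)),
  ASN = rbind(sc_row("CG", "N", "CA", "CB", 1.516, 112.6, 1, 0),
              sc_row("OD1", "CA", "CB", "CG", 1.231, 120.8, 2, 0),
              sc_row("ND2", "CA", "CB", "CG", 1.328, 116.4, 2, 180)),
  GLU = rbind(sc_row("CG", "N", "CA", "CB", 1.520, 114.1, 1, 0),
              sc_row("CD", "CA", "CB", "CG", 1.516, 112.6, 2, 0),
              sc_row("OE1", "CB", "CG", "CD", 1.249, 118.4, 3, 0),
              sc_row("OE2", "CB", "CG", "CD", 1.249, 118.4, 3, 180)),
  GLN = rbind(sc_row("CG", "N", "CA", "CB", 1.520, 114.1, 1, 0),
              sc_row("CD", "CA", "CB", "CG", 1.516, 112.6, 2, 0),
              sc_row("OE1", "CB", "CG", "CD", 1.231, 120.8, 3, 0),
              sc_row("NE2", "CB", "CG", "CD", 1.328, 116.4, 3, 180)),
  LYS = rbind(sc_row("CG", "N", "CA", "CB", 1.520, 114.1, 1, 0),
              sc_row("CD", "CA", "CB", "CG", 1.520, 111.3, 2, 0),
              sc_row("CE", "CB", "CG", "CD", 1.520, 111.3, 3, 0),
              sc_row("NZ", "CG", "CD", "CE", 1.489, 111.9, 4, 0)),
  ARG = rbind(sc_row("CG", "N", "CA", "CB", 1.520, 114.1, 1, 0),
              sc_row("CD", "CA", "CB", "CG", 1.520, 111.3, 2, 0),
              sc_row("NE", "CB", "CG", "CD", 1.461, 112.0, 3, 0),
              sc_row("CZ", "CG", "CD", "NE", 1.329, 124.2, 4, 0),
              sc_row("NH1", "CD", "NE", "CZ", 1.326, 120.0, 0, 0),
              sc_row("NH2", "CD", "NE", "CZ", 1.326, 120.0, 0, 180)),
  HIS = rbind(sc_row("CG", "N", "CA", "CB", 1.497, 113.8, 1, 0),
              sc_row("ND1", "CA", "CB", "CG", 1.378, 122.7, 2, 0),
              sc_row("CD2", "CA", "CB", "CG", 1.354, 131.0, 2, 180),
              sc_row("CE1", "CB", "CG", "ND1", 1.321, 109.3, 0, 180),
              sc_row("NE2", "CB", "CG", "CD2", 1.374, 107.2, 0, 180)),
  PHE = rbind(sc_row("CG", "N", "CA", "CB", 1.502, 113.8, 1, 0),
              sc_row("CD1", "CA", "CB", "CG", 1.384, 120.7, 2, 0),
              sc_row("CD2", "CA", "CB", "CG", 1.384, 120.7, 2, 180),
              sc_row("CE1", "CB", "CG", "CD1", 1.382, 120.7, 0, 180),
              sc_row("CE2", "CB", "CG", "CD2", 1.382, 120.7, 0, 180),
              sc_row("CZ", "CG", "CD1", "CE1", 1.382, 120.0, 0, 0)),
  TYR = rbind(sc_row("CG", "N", "CA", "CB", 1.502, 113.8, 1, 0),
              sc_row("CD1", "CA", "CB", "CG", 1.384, 120.7, 2, 0),
              sc_row("CD2", "CA", "CB", "CG", 1.384, 120.7, 2, 180),
              sc_row("CE1", "CB", "CG", "CD1", 1.382, 120.7, 0, 180),
              sc_row("CE2", "CB", "CG", "CD2", 1.382, 120.7, 0, 180),
              sc_row("CZ", "CG", "CD1", "CE1", 1.382, 120.0, 0, 0),
              sc_row("OH", "CD1", "CE1", "CZ", 1.376, 119.9, 0, 180)),
  TRP = rbind(sc_row("CG", "N", "CA", "CB", 1.498, 113.6, 1, 0),
              sc_row("CD1", "CA", "CB", "CG", 1.365, 126.9, 2, 0),
              sc_row("CD2", "CA", "CB", "CG", 1.433, 126.6, 2, 180),
              sc_row("NE1", "CB", "CG", "CD1", 1.374, 110.2, 0, 180),
              sc_row("CE2", "CB", "CG", "CD2", 1.409, 107.2, 0, 180),
              sc_row("CE3", "CB", "CG", "CD2", 1.398, 133.9, 0, 0),
              sc_row("CZ2", "CG", "CD2", "CE2", 1.394, 122.4, 0, 180),
              sc_row("CZ3", "CG", "CD2", "CE3", 1.382, 118.6, 0, 180),
              sc_row("CH2", "CD2", "CE2", "CZ2", 1.368, 117.5, 0, 0)),
  PRO = rbind(sc_row("CG", "N", "CA", "CB", 1.492, 104.5, 0, -26.9),
              sc_row("CD", "CA", "CB", "CG", 1.503, 106.1, 0, 38.5)))

# Discrete rotamer library: per residue a matrix with one column per chi
# dihedral (degrees) and one row per rotamer. Residues with no variable chi
# get a single empty rotamer.
chi_grid <- function(...) as.matrix(expand.grid(..., KEEP.OUT.ATTRS = FALSE))

g3 <- c(-60, 180, 60)          # gauche-/trans/gauche+
ROTAMER_LIBRARY <- list(
  SER = chi_grid(chi1 = g3), CYS = chi_grid(chi1 = g3),
  THR = chi_grid(chi1 = g3), VAL = chi_grid(chi1 = g3),
  LEU = chi_grid(chi1 = g3, chi2 = g3),
  ILE = chi_grid(chi1 = g3, chi2 = g3),
  MET = chi_grid(chi1 = g3, chi2 = g3, chi3 = g3),
  ASP = chi_grid(chi1 = g3, chi2 = c(-90, -30, 30, 90)),
  ASN = chi_grid(chi1 = g3, chi2 = c(-90, -30, 30, 90)),
  HIS = chi_grid(chi1 = g3, chi2 = c(-90, -30, 30, 90)),
  PHE = chi_grid(chi1 = g3, chi2 = c(-90, 90)),
  TYR = chi_grid(chi1 = g3, chi2 = c(-90, 90)),
  TRP = chi_grid(chi1 = g3, chi2 = c(-90, -30, 30, 90)),
  GLU = chi_grid(chi1 = g3, chi2 = g3, chi3 = c(-30, 30)),
  GLN = chi_grid(chi1 = g3, chi2 = g3, chi3 = c(-30, 30)),
  LYS = chi_grid(chi1 = g3, chi2 = g3, chi3 = 180, chi4 = 180),
  ARG = chi_grid(chi1 = g3, chi2 = g3, chi3 = 180, chi4 = 180),
  PRO = matrix(numeric(0), nrow = 1, ncol = 0),
  GLY = matrix(numeric(0), nrow = 1, ncol = 0),
  ALA = matrix(numeric(0), nrow = 1, ncol = 0))

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")
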