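# Residue topology: canonical heavy atoms, chi-angle definitions, idealized
# side-chain internal coordinates, and the atom sets rotated by each chi.
#
# Internal-coordinate rows are (a, b, c, bond, angle, torsion): the atom is
# bonded to c, with bond angle b-c-atom and torsion a-b-c-atom. Torsions are
# either tied to a chi angle (chi k plus a fixed offset, for branches) or
# fixed (planar ring/terminal groups). Bond lengths/angles follow standard
# ideal-geometry tables; fused-ring geometry is idealized planar.

AA_THREE <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
              G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
              M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
              S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")
AA_ONE <- stats::setNames(names(AA_THREE), AA_THREE)

# Residue-type one-hot order: alphabetical by one-letter code (frozen).
AA_ORDER <- sort(names(AA_THREE))

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Convert between one- and three-letter amino-acid codes
#' @param x Character vector of codes.
#' @return Converted codes.
#' @export
aa_three <- function(x) {
  out <- AA_THREE[toupper(x)]
  if (anyNA(out)) stop("unknown amino-acid code: ", paste(x[is.na(out)], collapse = ","))
  unname(out)
}

#' @rdname aa_three
#' @export
aa_one <- function(x) {
  out <- AA_ONE[toupper(x)]
  if (anyNA(out)) stop("unknown amino-acid code: ", paste(x[is.na(out)], collapse = ","))
  unname(out)
}

zr <- function(name, a, b, c, bond, angle, chi = NA_integer_, off = 0) {
  list(name = name, a = a, b = b, c = c, bond = bond, angle = angle,
       chi = chi, off = off)
}

# Side-chain internal coordinates beyond CB. CB itself is placed uniformly
# (except GLY) from (C, N, CA) with the L-configuration branch torsion.
SIDE_CHAIN_ZMAT <- list(
  ALA = list(),
  SER = list(zr("OG", "N", "CA", "CB", 1.417, 110.8, 1L)),
  CYS = list(zr("SG", "N", "CA", "CB", 1.808, 113.8, 1L)),
  THR = list(zr("OG1", "N", "CA", "CB", 1.433, 109.5, 1L),
             zr("CG2", "N", "CA", "CB", 1.521, 110.5, 1L, -122)),
  VAL = list(zr("CG1", "N", "CA", "CB", 1.527, 110.5, 1L),
             zr("CG2", "N", "CA", "CB", 1.527, 110.5, 1L, -122)),
  ILE = list(zr("CG1", "N", "CA", "CB", 1.530, 110.4, 1L),
             zr("CG2", "N", "CA", "CB", 1.521, 110.5, 1L, -122),
             zr("CD1", "CA", "CB", "CG1", 1.513, 113.8, 2L)),
  LEU = list(zr("CG", "N", "CA", "CB", 1.530, 116.3, 1L),
             zr("CD1", "CA", "CB", "CG", 1.521, 110.7, 2L),
             zr("CD2", "CA", "CB", "CG", 1.521, 110.7, 2L, 122)),
  ASP = list(zr("CG", "N", "CA", "CB", 1.516, 112.6, 1L),
             zr("OD1", "CA", "CB", "CG", 1.249, 118.4, 2L),
             zr("OD2", "CA", "CB", "CG", 1.249, 118.4, 2L, 180)),
  ASN = list(zr("CG", "N", "CA", "CB", 1.516, 112.6, 1L),
             zr("OD1", "CA", "CB", "CG", 1.231, 120.8, 2L),
             zr("ND2", "CA", "CB", "CG", 1.328, 116.4, 2L, 180)),
  GLU = list(zr("CG", "N", "CA", "CB", 1.530, 114.1, 1L),
             zr("CD", "CA", "CB", "CG", 1.516, 112.6, 2L),
             zr("OE1", "CB", "CG", "CD", 1.249, 118.4, 3L),
             zr("OE2", "CB", "CG", "CD", 1.249, 118.4, 3L, 180)),
  GLN = list(zr("CG", "N", "CA", "CB", 1.530, 114.1, 1L),
             zr("CD", "CA", "CB", "CG", 1.516, 112.6, 2L),
             zr("OE1", "CB", "CG", "CD", 1.231, 120.8, 3L),
             zr("NE2", "CB", "CG", "CD", 1.328, 116.4, 3L, 180)),
  MET = list(zr("CG", "N", "CA", "CB", 1.530, 114.1, 1L),
             zr("SD", "CA", "CB", "CG", 1.807, 112.7, 2L),
             zr("CE", "CB", "CG", "SD", 1.789, 100.2, 3L)),
  LYS = list(zr("CG", "N", "CA", "CB", 1.530, 114.1, 1L),
             zr("CD", "CA", "CB", "CG", 1.520, 111.3, 2L),
             zr("CE", "CB", "CG", "CD", 1.520, 111.3, 3L),
             zr("NZ", "CG", "CD", "CE", 1.489, 111.9, 4L)),
  ARG = list(zr("CG", "N", "CA", "CB", 1.530, 114.1, 1L),
             zr("CD", "CA", "CB", "CG", 1.520, 111.3, 2L),
             zr("NE", "CB", "CG", "CD", 1.461, 112.0, 3L),
             zr("CZ", "CG", "CD", "NE", 1.329, 124.2, 4L),
             zr("NH1", "CD", "NE", "CZ", 1.326, 120.0, NA, 0),
             zr("NH2", "CD", "NE", "CZ", 1.326, 120.0, NA, 180)),
  HIS = list(zr("CG", "N", "CA", "CB", 1.504, 113.8, 1L),
             zr("ND1", "CA", "CB", "CG", 1.378, 122.7, 2L),
             zr("CD2", "CA", "CB", "CG", 1.354, 131.2, 2L, 180),
             zr("CE1", "CB", "CG", "ND1", 1.321, 109.3, NA, 180),
             zr("NE2", "CB", "CG", "CD2", 1.374, 107.2, NA, 180)),
  PHE = list(zr("CG", "N", "CA", "CB", 1.502, 113.8, 1L),
             zr("CD1", "CA", "CB", "CG", 1.384, 120.8, 2L),
             zr("CD2", "CA", "CB", "CG", 1.384, 120.8, 2L, 180),
             zr("CE1", "CB", "CG", "CD1", 1.384, 120.8, NA, 180),
             zr("CE2", "CB", "CG", "CD2", 1.384, 120.8, NA, 180),
             zr("CZ", "CG", "CD1", "CE1", 1.384, 120.0, NA, 0)),
  TYR = list(zr("CG", "N", "CA", "CB", 1.511, 113.9, 1L),
             zr("CD1", "CA", "CB", "CG", 1.389, 120.8, 2L),
             zr("CD2", "CA", "CB", "CG", 1.389, 120.8, 2L, 180),
             zr("CE1", "CB", "CG", "CD1", 1.382, 121.1, NA, 180),
             zr("CE2", "CB", "CG", "CD2", 1.382, 121.1, NA, 180),
             zr("CZ", "CG", "CD1", "CE1", 1.378, 119.5, NA, 0),
             zr("OH", "CD1", "CE1", "CZ", 1.376, 119.9, NA, 180)),
  TRP = list(zr("CG", "N", "CA", "CB", 1.498, 113.6, 1L),
             zr("CD1", "CA", "CB", "CG", 1.365, 126.9, 2L),
             zr("CD2", "CA", "CB", "CG", 1.433, 126.6, 2L, 180),
             zr("NE1", "CB", "CG", "CD1", 1.374, 110.2, NA, 180),
             zr("CE2", "CB", "CG", "CD2", 1.409, 107.2, NA, 180),
             zr("CE3", "CB", "CG", "CD2", 1.398, 133.9, NA, 0),
             zr("CZ2", "CG", "CD2", "CE2", 1.394, 122.4, NA, 180),
             zr("CZ3", "CG", "CD2", "CE3", 1.382, 118.6, NA, 180),
             zr("CH2", "CD2", "CE2", "CZ2", 1.368, 117.5, NA, 0)),
  PRO = list(zr("CG", "N", "CA", "CB", 1.495, 104.5, 1L),
             zr("CD", "CA", "CB", "CG", 1.507, 106.1, 2L)),
  GLY = list()
)

# chi quadruples (atom-name quartets, IUPAC definitions)
CHI_ATOMS <- list(
  ALA = list(), GLY = list(),
  SER = list(c("N", "CA", "CB", "OG")),
  CYS = list(c("N", "CA", "CB", "SG")),
  THR = list(c("N", "CA", "CB", "OG1")),
  VAL = list(c("N", "CA", "CB", "CG1")),
  ILE = list(c("N", "CA", "CB", "CG1"), c("CA", "CB", "CG1", "CD1")),
  LEU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  ASP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  ASN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  GLU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  GLN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  MET = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "SD"),
             c("CB", "CG", "SD", "CE")),
  LYS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "CE"), c("CG", "CD", "CE", "NZ")),
  ARG = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "NE"), c("CG", "CD", "NE", "CZ")),
  HIS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "ND1")),
  PHE = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  TYR = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  TRP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  PRO = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"))
)

#' Heavy-atom element from a PDB atom name
#' @param name Atom name(s), e.g. "CA", "OG1", "SD".
#' @return Element letters in C/N/O/S.
#' @export
atom_element <- function(name) {
  e <- substr(name, 1, 1)
  bad <- !e %in% c("C", "N", "O", "S")
  if (any(bad)) stop("non-CNOS heavy atom name: ", paste(name[bad], collapse = ","))
  e
}

#' Residue topology lookup
#'
#' Canonical heavy atoms, chi definitions and the atom sets moved by each chi
#' for one residue type. Moving sets are derived from the side-chain bond
#' tree: chi k rotates every atom distal to the third atom of its quadruple,
#' so deeper chis move nested subsets and backbone plus CB never move.
#'
#' @param type3 Three-letter residue code.
#' @return List with `atoms` (ordered heavy-atom names), `chi` (list of
#'   quadruples), `zmat` (side-chain internal coordinates), and
#'   `moving_sets` (list of atom-name vectors, one per chi).
#' @export
residue_topology <- function(type3) {
  type3 <- toupper(type3)
  if (!type3 %in% names(SIDE_CHAIN_ZMAT)) stop("unknown residue type: ", type3)
  zmat <- SIDE_CHAIN_ZMAT[[type3]]
  side <- if (type3 == "GLY") character(0) else c("CB", vapply(zmat, `[[`, "", "name"))
  atoms <- c(BACKBONE_ATOMS, side)
  chi <- CHI_ATOMS[[type3]]
  # bond tree: parent of CB is CA; parent of each zmat atom is its `c` ref
  parent <- c(stats::setNames("CA", "CB"),
              stats::setNames(vapply(zmat, `[[`, "", "c"),
                              vapply(zmat, `[[`, "", "name")))
  descendants <- function(root) {
    kids <- names(parent)[parent == root]
    out <- kids
    for (k in kids) out <- c(out, descendants(k))
    out
  }
  moving <- lapply(chi, function(q) descendants(q[3]))
  list(type3 = type3, atoms = atoms, chi = chi, zmat = zmat,
       moving_sets = moving)
}

#' Number of chi angles of a residue type
#' @param type3 Three-letter code.
#' @return Integer count (0 for GLY/ALA).
#' @export
n_chi <- function(type3) length(CHI_ATOMS[[toupper(type3)]])
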