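# Amino-acid constants: codes, radii, atomic solvation parameters,
# side-chain internal-coordinate topology and rotamer chi sets.

AA3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
         "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL")
AA1 <- c("A","R","N","D","C","Q","E","G","H","I",
         "L","K","M","F","P","S","T","W","Y","V")
names(AA1) <- AA3
AA3_FROM_1 <- structure(AA3, names = AA1)

WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

#' @noRd
aa_three_to_one <- function(res_name) {
  out <- AA1[res_name]
  out[is.na(out)] <- "X"
  unname(out)
}

#' @noRd
aa_one_to_three <- function(code) {
  out <- AA3_FROM_1[code]
  if (any(is.na(out))) {
    stop("unknown one-letter residue code: ",
         paste(unique(code[is.na(out)]), collapse = ", "))
  }
  unname(out)
}

# van der Waals radii (A) by element, used for clash checks and SASA
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               SE = 1.90, FE = 1.50, ZN = 1.40, MG = 1.50)

#' @noRd
element_radius <- function(element) {
  r <- VDW_RADII[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

# Atomic solvation parameters (kcal/mol/A^2), Eisenberg-McLachlan style:
# apolar carbon and sulfur favour exposure, polar N/O disfavour it,
# charged side-chain atoms strongly so.
ASP_CARBON   <-  0.016
ASP_SULFUR   <-  0.021
ASP_POLAR    <- -0.006
ASP_O_MINUS  <- -0.024
ASP_N_PLUS   <- -0.050

CHARGED_O <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
CHARGED_N <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))

#' @noRd
solvation_parameter <- function(element, res_name, atom) {
  el <- toupper(element)
  sig <- ifelse(el == "C", ASP_CARBON,
         ifelse(el == "S", ASP_SULFUR,
         ifelse(el %in% c("N", "O"), ASP_POLAR, 0)))
  for (i in seq_along(sig)) {
    rn <- res_name[i]
    if (!is.null(CHARGED_O[[rn]]) && atom[i] %in% CHARGED_O[[rn]]) sig[i] <- ASP_O_MINUS
    if (!is.null(CHARGED_N[[rn]]) && atom[i] %in% CHARGED_N[[rn]]) sig[i] <- ASP_N_PLUS
  }
  sig
}

# Side-chain topology as a Z-matrix: each atom is placed from three
# previously placed atoms (a1, a2, a3) with bond length to a3, bond
# angle a2-a3-new and dihedral a1-a2-a3-new.  Dihedrals are either a
# fixed number (degrees) or "chiK" optionally with an offset
# ("chi1-122"), so rotamers are generated by sweeping the chi values.
# CB placement (from C, N, CA) encodes L-chirality.
sc_row <- function(atom, a1, a2, a3, bond, angle, tors) {
  data.frame(atom = atom, a1 = a1, a2 = a2, a3 = a3,
             bond = bond, angle = angle, tors = tors,
             stringsAsFactors = FALSE)
}

# improper N-C-CA-CB = +122.6 deg fixes L-chirality at the alpha carbon
CB_ROW <- sc_row("CB", "N", "C", "CA", 1.530, 111.1, "122.6")

SIDECHAIN_TOPOLOGY <- list(
  GLY = NULL,
  ALA = CB_ROW,
  SER = rbind(CB_ROW, sc_row("OG",  "N", "CA", "CB", 1.417, 110.8, "chi1")),
  CYS = rbind(CB_ROW, sc_row("SG",  "N", "CA", "CB", 1.808, 113.8, "chi1")),
  THR = rbind(CB_ROW,
              sc_row("OG1", "N", "CA", "CB", 1.433, 109.6, "chi1"),
              sc_row("CG2", "N", "CA", "CB", 1.521, 110.5, "chi1-122")),
  VAL = rbind(CB_ROW,
              sc_row("CG1", "N", "CA", "CB", 1.527, 110.7, "chi1"),
              sc_row("CG2", "N", "CA", "CB", 1.527, 110.4, "chi1+122")),
  LEU = rbind(CB_ROW,
              sc_row("CG",  "N",  "CA", "CB", 1.530, 116.3, "chi1"),
              sc_row("CD1", "CA", "CB", "CG", 1.524, 110.7, "chi2"),
              sc_row("CD2", "CA", "CB", "CG", 1.525, 110.4, "chi2+122")),
  ILE = rbind(CB_ROW,
              sc_row("CG1", "N",  "CA", "CB",  1.530, 110.4, "chi1"),
              sc_row("CG2", "N",  "CA", "CB",  1.521, 110.5, "chi1-122"),
              sc_row("CD1", "CA", "CB", "CG1", 1.513, 113.8, "chi2")),
  MET = rbind(CB_ROW,
              sc_row("CG", "N",  "CA", "CB", 1.520, 114.1, "chi1"),
              sc_row("SD", "CA", "CB", "CG", 1.803, 112.7, "chi2"),
              sc_row("CE", "CB", "CG", "SD", 1.791, 100.9, "chi3")),
  PRO = rbind(CB_ROW,
              sc_row("CG", "N",  "CA", "CB", 1.495, 104.5, "25"),
              sc_row("CD", "CA", "CB", "CG", 1.507, 106.1, "-35")),
  PHE = rbind(CB_ROW,
              sc_row("CG",  "N",  "CA", "CB",  1.502, 113.8, "chi1"),
              sc_row("CD1", "CA", "CB", "CG",  1.384, 120.8, "chi2"),
              sc_row("CD2", "CA", "CB", "CG",  1.384, 120.8, "chi2+180"),
              sc_row("CE1", "CB", "CG", "CD1", 1.382, 121.0, "180"),
              sc_row("CE2", "CB", "CG", "CD2", 1.382, 121.0, "180"),
              sc_row("CZ",  "CG", "CD1", "CE1", 1.380, 120.0, "0")),
  TYR = rbind(CB_ROW,
              sc_row("CG",  "N",  "CA", "CB",  1.502, 113.8, "chi1"),
              sc_row("CD1", "CA", "CB", "CG",  1.384, 120.8, "chi2"),
              sc_row("CD2", "CA", "CB", "CG",  1.384, 120.8, "chi2+180"),
              sc_row("CE1", "CB", "CG", "CD1", 1.382, 121.0, "180"),
              sc_row("CE2", "CB", "CG", "CD2", 1.382, 121.0, "180"),
              sc_row("CZ",  "CG", "CD1", "CE1", 1.380, 120.0, "0"),
              sc_row("OH",  "CD1", "CE1", "CZ", 1.376, 119.9, "180")),
  TRP = rbind(CB_ROW,
              sc_row("CG",  "N",  "CA", "CB",  1.498, 113.6, "chi1"),
              sc_row("CD1", "CA", "CB", "CG",  1.365, 126.9, "chi2"),
              sc_row("CD2", "CA", "CB", "CG",  1.433, 126.6, "chi2+180"),
              sc_row("NE1", "CB", "CG", "CD1", 1.374, 110.2, "180"),
              sc_row("CE2", "CB", "CG", "CD2", 1.409, 107.2, "180"),
              sc_row("CE3", "CB", "CG", "CD2", 1.398, 133.9, "0"),
              sc_row("CZ2", "CG", "CD2", "CE2", 1.394, 122.4, "180"),
              sc_row("CZ3", "CG", "CD2", "CE3", 1.382, 118.7, "180"),
              sc_row("CH2", "CD2", "CE2", "CZ2", 1.368, 117.5, "0")),
  HIS = rbind(CB_ROW,
              sc_row("CG",  "N",  "CA", "CB",  1.504, 113.7, "chi1"),
              sc_row("ND1", "CA", "CB", "CG",  1.378, 122.9, "chi2"),
              sc_row("CD2", "CA", "CB", "CG",  1.356, 131.2, "chi2+180"),
              sc_row("CE1", "CB", "CG", "ND1", 1.321, 109.2, "180"),
              sc_row("NE2", "CB", "CG", "CD2", 1.374, 107.1, "180")),
  ASP = rbind(CB_ROW,
              sc_row("CG",  "N",  "CA", "CB", 1.516, 113.0, "chi1"),
              sc_row("OD1", "CA", "CB", "CG", 1.249, 118.5, "chi2"),
              sc_row("OD2", "CA", "CB", "CG", 1.249, 118.5, "chi2+180")),
  ASN = rbind(CB_ROW,
              sc_row("CG",  "N",  "CA", "CB", 1.516, 112.7, "chi1"),
              sc_row("OD1", "CA", "CB", "CG", 1.231, 120.8, "chi2"),
              sc_row("ND2", "CA", "CB", "CG", 1.328, 116.5, "chi2+180")),
  GLU = rbind(CB_ROW,
              sc_row("CG",  "N",  "CA", "CB", 1.520, 114.1, "chi1"),
              sc_row("CD",  "CA", "CB", "CG", 1.516, 112.6, "chi2"),
              sc_row("OE1", "CB", "CG", "CD", 1.249, 118.5, "chi3"),
              sc_row("OE2", "CB", "CG", "CD", 1.249, 118.5, "chi3+180")),
  GLN = rbind(CB_ROW,
              sc_row("CG",  "N",  "CA", "CB", 1.520, 114.1, "chi1"),
              sc_row("CD",  "CA", "CB", "CG", 1.516, 112.6, "chi2"),
              sc_row("OE1", "CB", "CG", "CD", 1.231, 120.8, "chi3"),
              sc_row("NE2", "CB", "CG", "CD", 1.328, 116.5, "chi3+180")),
  LYS = rbind(CB_ROW,
              sc_row("CG", "N",  "CA", "CB", 1.520, 114.1, "chi1"),
              sc_row("CD", "CA", "CB", "CG", 1.520, 111.3, "chi2"),
              sc_row("CE", "CB", "CG", "CD", 1.520, 111.3, "chi3"),
              sc_row("NZ", "CG", "CD", "CE", 1.489, 111.9, "chi4")),
  ARG = rbind(CB_ROW,
              sc_row("CG",  "N",  "CA", "CB", 1.520, 114.1, "chi1"),
              sc_row("CD",  "CA", "CB", "CG", 1.520, 111.3, "chi2"),
              sc_row("NE",  "CB", "CG", "CD", 1.461, 112.0, "chi3"),
              sc_row("CZ",  "CG", "CD", "NE", 1.329, 124.2, "chi4"),
              sc_row("NH1", "CD", "NE", "CZ", 1.326, 120.0, "0"),
              sc_row("NH2", "CD", "NE", "CZ", 1.326, 120.0, "180"))
)

# ring/closure bonds not captured by the parent (a3) relation
RING_CLOSURE_BONDS <- list(
  PHE = list(c("CZ", "CE2")),
  TYR = list(c("CZ", "CE2")),
  HIS = list(c("CE1", "NE2")),
  TRP = list(c("NE1", "CE2"), c("CZ3", "CH2")),
  PRO = list(c("CD", "N"))
)

#' @noRd
n_chi <- function(res_name) {
  topo <- SIDECHAIN_TOPOLOGY[[res_name]]
  if (is.null(topo)) return(0L)
  k <- regmatches(topo$tors, regexpr("chi[1-4]", topo$tors))
  if (length(k) == 0) return(0L)
  max(as.integer(substring(k, 4, 4)))
}

# candidate chi values for rotamer enumeration; aromatic chi2 is +/-90
CHI_STAGGERED <- c(-60, 60, 180)
CHI_AROMATIC2 <- c(90, -90)
AROMATIC_RES <- c("PHE", "TYR", "TRP", "HIS")

#' @noRd
rotamer_chi_grid <- function(res_name) {
  nc <- n_chi(res_name)
  if (nc == 0L) return(matrix(numeric(0), nrow = 1, ncol = 0))
  sets <- rep(list(CHI_STAGGERED), nc)
  if (res_name %in% AROMATIC_RES && nc >= 2) sets[[2]] <- CHI_AROMATIC2
  grid <- as.matrix(expand.grid(sets, KEEP.OUT.ATTRS = FALSE))
  dimnames(grid) <- NULL
  grid
}

#' @noRd
default_chi <- function(res_name) {
  nc <- n_chi(res_name)
  if (nc == 0L) return(numeric(0))
  chi <- rep(180, nc)
  if (res_name %in% AROMATIC_RES && nc >= 2) chi[2] <- 90
  chi[1] <- -60
  chi
}

# ideal intra-residue bond lengths used for harmonic restraints
#' @noRd
residue_bond_table <- function(res_name) {
  bonds <- data.frame(a = c("N", "CA", "C"), b = c("CA", "C", "O"),
                      d0 = c(1.458, 1.525, 1.231), stringsAsFactors = FALSE)
  topo <- SIDECHAIN_TOPOLOGY[[res_name]]
  if (!is.null(topo)) {
    bonds <- rbind(bonds, data.frame(a = topo$a3, b = topo$atom, d0 = topo$bond,
                                     stringsAsFactors = FALSE))
  }
  rc <- RING_CLOSURE_BONDS[[res_name]]
  if (!is.null(rc)) {
    for (p in rc) {
      d0 <- if (identical(sort(p), sort(c("CD", "N")))) 1.473 else 1.40
      bonds <- rbind(bonds, data.frame(a = p[1], b = p[2], d0 = d0,
                                       stringsAsFactors = FALSE))
    }
  }
  bonds
}

#' @noRd
element_from_atom_name <- function(atom) {
  lead <- sub("^[0-9']*", "", atom)
  first <- toupper(substring(lead, 1, 1))
  ifelse(substring(lead, 1, 2) %in% c("SE"), "SE", first)
}
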