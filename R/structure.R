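# The hla_structure container: chains -> residues -> non-hydrogen atoms,
# held as a flat atom table plus a chain-role map.

#' Create an hla_structure object
#'
#' The package-wide structure container: a flat table of non-hydrogen
#' atoms (file order preserved) plus a map from chain id to its role in
#' an HLA complex (`heavy_chain`, `beta2m`, `class2_alpha`,
#' `class2_beta`, `peptide`, `tcr`, `other`).
#'
#' @param atoms data.frame with columns `chain`, `res_name`, `seq_id`,
#'   `ins`, `atom`, `element`, `x`, `y`, `z`, `occ`, `b`, `altloc`
#' @param roles named character vector mapping chain id to role;
#'   unnamed chains default to "other"
#' @return object of class `hla_structure`
#' @export
hla_structure <- function(atoms, roles = NULL) {
  required <- c("chain", "res_name", "seq_id", "ins", "atom", "element",
                "x", "y", "z", "occ", "b", "altloc")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols)) {
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) && any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite atom coordinates")
  }
  atoms$seq_id <- as.integer(atoms$seq_id)
  rownames(atoms) <- NULL
  chains <- unique(atoms$chain)
  r <- setNames(rep("other", length(chains)), chains)
  if (!is.null(roles)) {
    known <- intersect(names(roles), chains)
    r[known] <- roles[known]
  }
  structure(list(atoms = atoms, roles = r), class = "hla_structure")
}

CHAIN_ROLES <- c("heavy_chain", "beta2m", "class2_alpha", "class2_beta",
                 "peptide", "tcr", "other")

#' @export
print.hla_structure <- function(x, ...) {
  cat("hla_structure:", n_atoms(x), "non-hydrogen atoms,",
      nrow(residue_table(x)), "residues,",
      length(chain_ids(x)), "chain(s)\n")
  for (ch in chain_ids(x)) {
    rt <- residue_table(x, ch)
    cat(sprintf("  chain %s [%s]: %d residues\n", ch, x$roles[[ch]], nrow(rt)))
  }
  invisible(x)
}

#' Number of atoms in a structure
#' @param s an `hla_structure`
#' @return integer atom count
#' @export
n_atoms <- function(s) nrow(s$atoms)

#' Chain identifiers of a structure, in file order
#' @param s an `hla_structure`
#' @return character vector
#' @export
chain_ids <- function(s) unique(s$atoms$chain)

#' @noRd
chains_with_role <- function(s, role) names(s$roles)[s$roles %in% role]

#' Residue table of a structure
#'
#' One row per residue in atom order, keyed by author numbering.
#' @param s an `hla_structure`
#' @param chain optional chain id filter
#' @return data.frame with columns `chain`, `seq_id`, `ins`, `res_name`
#' @export
residue_table <- function(s, chain = NULL) {
  a <- s$atoms
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  key <- paste(a$chain, a$seq_id, a$ins)
  keep <- !duplicated(key)
  out <- a[keep, c("chain", "seq_id", "ins", "res_name")]
  rownames(out) <- NULL
  out
}

#' One-letter sequence of a chain
#' @param s an `hla_structure`
#' @param chain chain id
#' @return single string (nonstandard residues become "X")
#' @export
chain_sequence <- function(s, chain) {
  rt <- residue_table(s, chain)
  paste(aa_three_to_one(rt$res_name), collapse = "")
}

#' Atom coordinates as a matrix
#' @param s an `hla_structure`
#' @return numeric n x 3 matrix
#' @export
structure_coords <- function(s) {
  as.matrix(s$atoms[, c("x", "y", "z")])
}

#' @noRd
set_structure_coords <- function(s, xyz) {
  stopifnot(nrow(xyz) == n_atoms(s))
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

#' @noRd
subset_structure <- function(s, idx) {
  out <- s
  out$atoms <- s$atoms[idx, , drop = FALSE]
  rownames(out$atoms) <- NULL
  out$roles <- s$roles[names(s$roles) %in% unique(out$atoms$chain)]
  out
}

#' @noRd
merge_structures <- function(a, b) {
  hla_structure(rbind(a$atoms, b$atoms), roles = c(a$roles, b$roles))
}

#' @noRd
atom_row <- function(chain, res_name, seq_id, atom, xyz, occ = 1, b = 0) {
  data.frame(chain = chain, res_name = res_name, seq_id = as.integer(seq_id),
             ins = "", atom = atom, element = element_from_atom_name(atom),
             x = xyz[1], y = xyz[2], z = xyz[3], occ = occ, b = b,
             altloc = "", stringsAsFactors = FALSE)
}

#' Write a structure as a PDB file
#'
#' Fixed-column PDB ATOM records with TER between chains; any `remarks`
#' are emitted as REMARK records before the coordinates, so models carry
#' their provenance (template, seed, score) in the file itself.
#'
#' @param s an `hla_structure`
#' @param path output file
#' @param remarks character vector of remark lines (without the REMARK
#'   keyword)
#' @return `path`, invisibly
#' @export
write_structure <- function(s, path, remarks = character()) {
  a <- s$atoms
  lines <- character(0)
  if (length(remarks)) {
    lines <- sprintf("REMARK 999 %s", remarks)
  }
  serial <- 0L
  for (ch in chain_ids(s)) {
    rows <- which(a$chain == ch)
    for (i in rows) {
      serial <- serial + 1L
      nm <- a$atom[i]
      namefield <- if (nchar(nm) >= 4) substr(nm, 1, 4) else sprintf(" %-3s", nm)
      rec <- if (a$res_name[i] %in% c(AA3, WATER_NAMES)) "ATOM  " else "HETATM"
      lines <- c(lines, sprintf(
        "%s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        rec, serial %% 100000L, namefield, substr(a$altloc[i], 1, 1), a$res_name[i],
        substr(ch, 1, 1), a$seq_id[i] %% 10000L, substr(a$ins[i], 1, 1),
        a$x[i], a$y[i], a$z[i], a$occ[i], a$b[i], a$element[i]))
    }
    serial <- serial + 1L
    last <- rows[length(rows)]
    lines <- c(lines, sprintf("TER   %5d      %-3s %1s%4d",
                              serial %% 100000L, a$res_name[last],
                              substr(ch, 1, 1), a$seq_id[last] %% 10000L))
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}
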