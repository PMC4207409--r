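# Reading PDB / mmCIF coordinate files into hla_structure objects.

#' Parse a macromolecular structure file
#'
#' Reads PDB or mmCIF coordinates (via bio3d) into an
#' [hla_structure()]. Hydrogens (and deuteriums), waters and
#' alternate-location indicators other than 'A'/blank are dropped at
#' parse time: every downstream metric in the package is defined over
#' non-hydrogen atoms. Heteroatom ligands are retained (their chains
#' classify as role "other").
#'
#' @param path file path
#' @param format one of "auto" (by extension), "pdb", "mmcif"
#' @return an `hla_structure` with all chain roles "other" (see
#'   [classify_chains()])
#' @export
parse_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  raw <- tryCatch(
    suppressWarnings(
      if (format == "mmcif") bio3d::read.cif(path, verbose = FALSE)
      else bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) stop("cannot parse ", path, " as ", format, ": ",
                             conditionMessage(e), call. = FALSE))
  at <- raw$atom
  if (is.null(at) || nrow(at) == 0) stop("empty structure: ", path)

  element <- toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                                   element_from_atom_name(trimws(at$elety)),
                                   at$elesy)))
  alt <- ifelse(is.na(at$alt), "", trimws(at$alt))
  ins <- ifelse(is.na(at$insert), "", trimws(at$insert))
  keep <- !(element %in% c("H", "D")) &
    !(trimws(at$resid) %in% WATER_NAMES) &
    (alt %in% c("", "A"))
  at <- at[keep, , drop = FALSE]
  element <- element[keep]; alt <- alt[keep]; ins <- ins[keep]
  if (nrow(at) == 0) stop("empty structure after filtering: ", path)

  chain <- ifelse(is.na(at$chain) | at$chain == "", "A", at$chain)
  atoms <- data.frame(
    chain = chain,
    res_name = trimws(at$resid),
    seq_id = as.integer(at$resno),
    ins = ins,
    atom = trimws(at$elety),
    element = element,
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, at$b),
    altloc = alt,
    stringsAsFactors = FALSE)
  hla_structure(atoms)
}

#' @noRd
is_protein_residue <- function(res_name) res_name %in% AA3

#' Assign HLA complex roles to the chains of a structure
#'
#' Deterministic, download-free classification by chain length:
#' 260-300 standard residues is a class I heavy chain, 95-105 is
#' beta-2-microglobulin, 8-25 is a bound peptide, 150-230 is a class II
#' groove chain (of the two, the shorter is the alpha chain), and
#' remaining protein chains longer than 150 residues are T-cell
#' receptor chains once a groove has been found. Chains of hetero
#' ligands and anything unrecognised keep role "other". The assignment
#' does not depend on chain input order.
#'
#' @param s an `hla_structure`
#' @param hla_class_hint optional 1 or 2 to force the class branch when
#'   chain lengths alone are ambiguous
#' @return the structure with `$roles` filled in
#' @export
classify_chains <- function(s, hla_class_hint = NULL) {
  if (length(chain_ids(s)) < 1) stop("structure has no chains")
  rt <- residue_table(s)
  lens <- vapply(chain_ids(s), function(ch) {
    sum(is_protein_residue(rt$res_name[rt$chain == ch]))
  }, integer(1))
  roles <- setNames(rep("other", length(lens)), names(lens))

  heavy <- names(lens)[lens >= 260 & lens <= 300]
  class2 <- names(lens)[lens >= 150 & lens <= 230]
  want1 <- if (is.null(hla_class_hint)) length(heavy) > 0 else hla_class_hint == 1
  groove_found <- FALSE
  if (want1 && length(heavy) > 0) {
    roles[heavy[which.max(lens[heavy])]] <- "heavy_chain"
    groove_found <- TRUE
  } else if (length(class2) >= 2) {
    pair <- class2[order(lens[class2], class2)][1:2]
    roles[pair[1]] <- "class2_alpha"
    roles[pair[2]] <- "class2_beta"
    groove_found <- TRUE
  }
  b2m <- names(lens)[lens >= 95 & lens <= 105 & roles == "other"]
  if (length(b2m)) roles[b2m] <- "beta2m"
  pep <- names(lens)[lens >= 8 & lens <= 25 & roles == "other"]
  if (length(pep)) roles[pep] <- "peptide"
  if (groove_found) {
    tcr <- names(lens)[lens > 150 & roles == "other"]
    if (length(tcr)) roles[tcr] <- "tcr"
  }
  if (!groove_found) {
    stop("no chain matches an HLA groove pattern; protein chain lengths: ",
         paste(sprintf("%s=%d", names(lens), lens), collapse = ", "))
  }
  s$roles[names(roles)] <- roles
  s
}

#' @noRd
structure_hla_class <- function(s) {
  if (length(chains_with_role(s, "heavy_chain"))) return(1L)
  if (length(chains_with_role(s, c("class2_alpha", "class2_beta")))) return(2L)
  NA_integer_
}
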