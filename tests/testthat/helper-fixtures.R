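# Shared fixture builders. Everything is generated in code at test
# time; nothing is downloaded or stored on disk beyond temp files.

# a small class I fixture database: n_entries miniature grooves (40
# groove residues) differing by engineered point mutations
fixture_db <- function(dir, n_entries = 3, hla_class = 1, n_residues = 40,
                       seed = 0) {
  fx <- write_fixture_set(file.path(dir, "fx"), n_entries = n_entries,
                          hla_class = hla_class, n_residues = n_residues,
                          seed = seed)
  build_db(fx$paths, fx$metadata, file.path(dir, "db"))
}

# database whose last entry is an exact duplicate of the first, for
# leave-one-out self-modeling checks
duplicate_db <- function(dir, n_residues = 40) {
  g <- make_fixture("mini_groove", n_residues = n_residues)
  g2 <- mutate_fixture(g, "A", residue_table(g, "A")$seq_id[3], "VAL")
  dir.create(file.path(dir, "src"), showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, "src", c("DA01.pdb", "DB02.pdb", "DC03.pdb"))
  write_structure(g, paths[1])
  write_structure(g2, paths[2])
  write_structure(g, paths[3])  # duplicate of the first
  md <- data.frame(pdb_id = c("DA01", "DB02", "DC03"),
                   allele_name = c("SYN*01:01", "SYN*02:01", "SYN*01:01"),
                   hla_class = 1,
                   roles = "A=heavy_chain;P=peptide",
                   stringsAsFactors = FALSE)
  build_db(paths, md, file.path(dir, "db"))
}

# groove sequence + author numbering of a record's heavy chain
groove_query <- function(record) {
  list(seq = chain_sequence(record$structure, "A"),
       seq_ids = residue_table(record$structure, "A")$seq_id)
}

fast_config <- function(...) {
  build_config(n_candidates = 1, relaxation_steps = 120, seed = 0, ...)
}

# independent NeRF implementation for brute-force torsion/rotation
# oracles (kept separate from the package's internals on purpose)
oracle_place <- function(a, b, c, bond, angle, dihedral) {
  th <- angle * pi / 180; ch <- dihedral * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-bond * cos(th), bond * sin(th) * cos(ch), -bond * sin(th) * sin(ch))
  c + d[1] * bc + d[2] * m + d[3] * n
}

# grow a backbone segment of L residues from a left anchor with ideal
# geometry and trans peptide bonds; returns the C atom of the last
# residue and predicted next N (for closure-gap oracles)
oracle_grow <- function(anchor_n, anchor_ca, anchor_c, psi0, phipsi) {
  pn <- anchor_n; pca <- anchor_ca; pc <- anchor_c
  psi_prev <- psi0
  L <- nrow(phipsi)
  for (i in seq_len(L)) {
    N <- oracle_place(pn, pca, pc, 1.329, 116.2, psi_prev)
    CA <- oracle_place(pca, pc, N, 1.458, 121.7, 180)
    C <- oracle_place(pc, N, CA, 1.525, 111.2, phipsi[i, 1])
    pn <- N; pca <- CA; pc <- C
    psi_prev <- phipsi[i, 2]
  }
  list(last_c = pc, next_n = oracle_place(pn, pca, pc, 1.329, 116.2, psi_prev))
}

# rotation matrix about z (for planar rotation-grid oracles)
rot_z <- function(deg) {
  th <- deg * pi / 180
  rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
}

# brute-force minimum RMSD over proper rotations mapping the z = 0
# plane to itself (0.5 degree steps): every in-plane rotation, plus the
# same composed with a 180-degree flip about x (det +1, turns the
# plane over). For coplanar sets these exhaust the candidate optima.
oracle_planar_rmsd <- function(mobile, reference, step = 0.5) {
  X <- sweep(mobile, 2, colMeans(mobile))
  Y <- sweep(reference, 2, colMeans(reference))
  Xflip <- X %*% diag(c(1, -1, -1))
  best <- Inf
  for (a in seq(0, 360 - step, by = step)) {
    R <- t(rot_z(a))
    r <- sqrt(mean(rowSums((X %*% R - Y)^2)))
    rf <- sqrt(mean(rowSums((Xflip %*% R - Y)^2)))
    if (r < best) best <- r
    if (rf < best) best <- rf
  }
  best
}

# one-off PDB text fixtures -------------------------------------------------

# two protein chains (5 residues each), 3 waters, hydrogens, and one
# A/B altloc side chain: exercises every parse-time filtering rule
write_filtering_pdb <- function(path) {
  fmt <- function(serial, name, alt, res, chain, sid, x, y, z, el) {
    sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, if (nchar(name) >= 4) name else sprintf(" %-3s", name),
            alt, res, chain, sid, x, y, z, 1, 0, el)
  }
  lines <- character(0); serial <- 0
  for (ch in c("A", "B")) {
    xoff <- if (ch == "A") 0 else 20
    for (i in 1:5) {
      base <- c(xoff + i * 3.8, 0, 0)
      for (at in list(c("N", "N"), c("CA", "C"), c("C", "C"), c("O", "O"))) {
        serial <- serial + 1
        d <- switch(at[1], N = c(0, 0, 0), CA = c(1.46, 0, 0),
                    C = c(2.0, 1.3, 0), O = c(2.0, 2.5, 0))
        lines <- c(lines, fmt(serial, at[1], "", "ALA", ch, i,
                              base[1] + d[1], base[2] + d[2], d[3], at[2]))
      }
      # a hydrogen that must be dropped
      serial <- serial + 1
      lines <- c(lines, fmt(serial, "H", "", "ALA", ch, i,
                            base[1], -1, 0, "H"))
      # altloc A/B pair on the CB of residue 3 in chain A
      if (ch == "A" && i == 3) {
        serial <- serial + 1
        lines <- c(lines, fmt(serial, "CB", "A", "ALA", ch, i,
                              base[1] + 1.2, -1.2, 0.6, "C"))
        serial <- serial + 1
        lines <- c(lines, fmt(serial, "CB", "B", "ALA", ch, i,
                              base[1] + 1.4, -1.4, 0.9, "C"))
      }
    }
  }
  for (w in 1:3) {
    serial <- serial + 1
    lines <- c(lines, sprintf(
      "HETATM%5d  O   HOH W%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           O",
      serial, w, 50 + w * 3, 0, 0, 1, 0))
  }
  writeLines(c(lines, "END"), path)
  path
}

# the same coordinates as an mmCIF atom_site loop
pdb_to_mmcif <- function(pdb_path, cif_path) {
  s <- parse_structure(pdb_path, format = "pdb")
  a <- s$atoms
  hdr <- c("data_fixture", "#", "loop_",
           "_atom_site.group_PDB", "_atom_site.id",
           "_atom_site.type_symbol", "_atom_site.label_atom_id",
           "_atom_site.label_alt_id", "_atom_site.label_comp_id",
           "_atom_site.label_asym_id", "_atom_site.label_entity_id",
           "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
           "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
           "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
           "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
           "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
           "_atom_site.pdbx_PDB_model_num")
  rows <- vapply(seq_len(nrow(a)), function(i) {
    sprintf("ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f %.2f %.2f %d %s %s %s 1",
            i, a$element[i], a$atom[i], a$res_name[i], a$chain[i], a$seq_id[i],
            a$x[i], a$y[i], a$z[i], a$occ[i], a$b[i], a$seq_id[i],
            a$res_name[i], a$chain[i], a$atom[i])
  }, character(1))
  writeLines(c(hdr, rows, "#"), cif_path)
  cif_path
}

# a crystal-like PDB with full header metadata (synthetic coordinates)
write_header_pdb <- function(path) {
  g <- make_fixture("mini_groove", n_residues = 40)
  tmp <- tempfile(fileext = ".pdb")
  write_structure(g, tmp)
  coords <- readLines(tmp)
  header <- c(
    "HEADER    HISTOCOMPATIBILITY ANTIGEN              21-JUL-97   1AO7",
    "TITLE     COMPLEX BETWEEN HUMAN T-CELL RECEPTOR, VIRAL PEPTIDE (TAX), AND",
    "TITLE    2 HLA-A 0201",
    "REVDAT   3   24-FEB-09 1AO7    1       VERSN",
    "EXPDTA    X-RAY DIFFRACTION",
    "REMARK   2 RESOLUTION.    2.60 ANGSTROMS.",
    "REMARK   3   FREE R VALUE                     : 0.320")
  writeLines(c(header, coords), path)
  path
}
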