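# Synthetic structure generation: ideal helices/strands, extended
# peptides and miniature groove complexes, so every pipeline stage is
# testable without downloading crystal structures. Fixtures are
# geometric scaffolds, not physically realistic proteins.

#' @noRd
ideal_chain_atoms <- function(letters, phi, psi, chain, start_id = 1L,
                              origin = c(0, 0, 0)) {
  n <- length(letters)
  phi <- rep(phi, length.out = n); psi <- rep(psi, length.out = n)
  bb <- build_backbone(phi, psi, origin = origin)
  res3 <- aa_one_to_three(letters)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sid <- start_id + i - 1L
    out <- rbind(atom_row(chain, res3[i], sid, "N", bb$n[i, ]),
                 atom_row(chain, res3[i], sid, "CA", bb$ca[i, ]),
                 atom_row(chain, res3[i], sid, "C", bb$c[i, ]),
                 atom_row(chain, res3[i], sid, "O", bb$o[i, ]))
    sc <- build_side_chain(res3[i], list(n = bb$n[i, ], ca = bb$ca[i, ], c = bb$c[i, ]))
    if (!is.null(sc)) {
      out <- rbind(out, do.call(rbind, lapply(rownames(sc), function(nm) {
        atom_row(chain, res3[i], sid, nm, sc[nm, ])
      })))
    }
    rows[[i]] <- out
  }
  do.call(rbind, rows)
}

#' @noRd
split_letters <- function(sequence, n) {
  if (is.null(sequence)) return(rep("A", n))
  l <- strsplit(validate_sequence(sequence), "")[[1]]
  if (length(l) != n) stop("sequence length ", length(l), " != n_residues ", n)
  l
}

#' Generate a synthetic structure fixture
#'
#' Kinds: `ideal_helix` (phi = -57, psi = -47), `ideal_strand`
#' (phi = -139, psi = 135), `peptide_extended` (a groove-style extended
#' chain, chain P, role peptide), and `mini_groove` — two helical walls
#' flanking a two-strand floor with an extended peptide bound above it,
#' chain roles pre-assigned (class 1: one groove chain A + peptide P;
#' class 2: alpha chain A, beta chain B, peptide P). Groove pieces are
#' numbered with single-residue gaps so each secondary-structure
#' element is a rigid, independently placed unit.
#'
#' @param kind fixture kind (see above)
#' @param n_residues residue count (mini_groove: per groove chain;
#'   defaults: helix/strand 10, peptide 9, mini_groove 270 so the
#'   groove chain classifies as a class I heavy chain)
#' @param sequence optional one-letter sequence (default poly-alanine;
#'   mini_groove peptide defaults to 9- or 15-mer poly-alanine)
#' @param perturbation_sigma per-coordinate Gaussian noise (A)
#' @param seed RNG seed for the perturbation
#' @param hla_class 1 or 2 (mini_groove only)
#' @param peptide_sequence optional peptide sequence for mini_groove
#' @return an `hla_structure` with roles assigned
#' @export
make_fixture <- function(kind = c("ideal_helix", "ideal_strand",
                                  "peptide_extended", "mini_groove"),
                         n_residues = NULL, sequence = NULL,
                         perturbation_sigma = 0, seed = 0,
                         hla_class = 1, peptide_sequence = NULL) {
  kind <- match.arg(kind)
  stopifnot(perturbation_sigma >= 0)
  s <- switch(kind,
    ideal_helix = {
      n <- if (is.null(n_residues)) 10L else n_residues
      hla_structure(ideal_chain_atoms(split_letters(sequence, n), -57, -47, "A"))
    },
    ideal_strand = {
      n <- if (is.null(n_residues)) 10L else n_residues
      hla_structure(ideal_chain_atoms(split_letters(sequence, n), -139, 135, "A"))
    },
    peptide_extended = {
      n <- if (is.null(n_residues)) 9L else n_residues
      hla_structure(ideal_chain_atoms(split_letters(sequence, n), -120, 130, "P"),
                    roles = c(P = "peptide"))
    },
    mini_groove = make_mini_groove(n_residues, sequence, hla_class,
                                   peptide_sequence))
  if (perturbation_sigma > 0) {
    set.seed(seed)
    xyz <- structure_coords(s)
    xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, perturbation_sigma),
                        ncol = 3)
    s <- set_structure_coords(s, xyz)
  }
  s
}

#' @noRd
canonical_place <- function(atoms, center) {
  # rotate the piece so its long axis runs along x, then move its
  # centroid to `center`; sign conventions are fixed so the placement
  # is deterministic
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  c0 <- colMeans(xyz)
  X <- sweep(xyz, 2, c0)
  ev <- eigen(stats::cov(X), symmetric = TRUE)
  W <- ev$vectors
  for (k in 1:3) {
    m <- which.max(abs(W[, k]))
    if (W[m, k] < 0) W[, k] <- -W[, k]
  }
  if (det(W) < 0) W[, 3] <- -W[, 3]
  atoms[, c("x", "y", "z")] <- sweep(X %*% W, 2, center, `+`)
  atoms
}

#' @noRd
separate_pieces <- function(pieces, min_dist = 3.2, max_iter = 20) {
  # push rigid pieces apart along their centre difference until no
  # inter-piece atom pair is closer than min_dist
  for (iter in seq_len(max_iter)) {
    worst <- 0
    for (i in seq_along(pieces)) {
      for (j in seq_along(pieces)) {
        if (j <= i) next
        xi <- as.matrix(pieces[[i]][, c("x", "y", "z")])
        xj <- as.matrix(pieces[[j]][, c("x", "y", "z")])
        dmin <- Inf
        for (k in seq_len(nrow(xj))) {
          dmin <- min(dmin, sqrt(min((xi[, 1] - xj[k, 1])^2 +
                                       (xi[, 2] - xj[k, 2])^2 +
                                       (xi[, 3] - xj[k, 3])^2)))
        }
        if (dmin < min_dist) {
          worst <- max(worst, min_dist - dmin)
          dir <- colMeans(xj) - colMeans(xi)
          dir <- dir / max(sqrt(sum(dir^2)), 1e-6)
          push <- (min_dist - dmin) / 2 + 0.05
          pieces[[i]][, c("x", "y", "z")] <- sweep(xi, 2, dir * push, `-`)
          pieces[[j]][, c("x", "y", "z")] <- sweep(xj, 2, dir * push, `+`)
        }
      }
    }
    if (worst == 0) break
  }
  pieces
}

#' @noRd
make_mini_groove <- function(n_residues, sequence, hla_class,
                             peptide_sequence) {
  stopifnot(hla_class %in% c(1, 2))
  piece <- function(letters, kind, chain, start, center) {
    at <- if (kind == "helix") ideal_chain_atoms(letters, -57, -47, chain, start)
          else ideal_chain_atoms(letters, -139, 135, chain, start)
    canonical_place(at, center)
  }
  groove_pieces <- function(letters, chain, centers) {
    # helix / strand / strand / helix (or helix / strand for one class
    # II chain); numbering skips one id between pieces (chain breaks)
    n <- length(letters)
    k <- length(centers)
    kinds <- if (k == 4) c("helix", "strand", "strand", "helix")
             else c("helix", "strand")
    frac <- if (k == 4) c(0.33, 0.17, 0.17, 0.33) else c(0.6, 0.4)
    sizes <- pmax(3L, round(n * frac))
    sizes[k] <- n - sum(sizes[-k])
    out <- list(); start <- 1L; used <- 0L
    for (i in seq_len(k)) {
      l <- letters[used + seq_len(sizes[i])]
      out[[i]] <- piece(l, kinds[i], chain, start, centers[[i]])
      used <- used + sizes[i]
      start <- start + sizes[i] + 1L
    }
    out
  }
  np <- if (is.null(peptide_sequence)) { if (hla_class == 1) 9L else 15L }
        else nchar(peptide_sequence)
  pep <- canonical_place(
    ideal_chain_atoms(split_letters(peptide_sequence, np), -120, 130, "P"),
    c(0, 0, 7))
  if (hla_class == 1) {
    n <- if (is.null(n_residues)) 270L else as.integer(n_residues)
    pieces <- groove_pieces(split_letters(sequence, n), "A",
                            list(c(0, -8.5, 4.5), c(0, -2.6, 0),
                                 c(0, 2.6, 0), c(0, 8.5, 4.5)))
    pieces <- separate_pieces(c(pieces, list(pep)))
    hla_structure(do.call(rbind, pieces),
                  roles = c(A = "heavy_chain", P = "peptide"))
  } else {
    n <- if (is.null(n_residues)) 181L else as.integer(n_residues)
    a <- groove_pieces(split_letters(sequence, n), "A",
                       list(c(0, -8.5, 4.5), c(0, -2.6, 0)))
    b <- groove_pieces(rep("A", n + 9L), "B",
                       list(c(0, 8.5, 4.5), c(0, 2.6, 0)))
    pieces <- separate_pieces(c(a, b, list(pep)))
    atoms <- do.call(rbind, pieces)
    atoms <- atoms[order(match(atoms$chain, c("A", "B", "P"))), ]
    hla_structure(atoms, roles = c(A = "class2_alpha", B = "class2_beta",
                                   P = "peptide"))
  }
}

#' Mutate one residue of a fixture to a new residue type
#'
#' The backbone is untouched; the side chain is replaced by the new
#' residue's default rotamer.
#'
#' @param s an `hla_structure`
#' @param chain chain id
#' @param position author seq_id of the residue
#' @param new_residue 3-letter code
#' @return the mutated `hla_structure`
#' @export
mutate_fixture <- function(s, chain, position, new_residue) {
  new_residue <- toupper(new_residue)
  if (!new_residue %in% AA3) stop("unknown residue code: ", new_residue)
  a <- s$atoms
  sel <- a$chain == chain & a$seq_id == position
  if (!any(sel)) stop("no residue ", position, " in chain ", chain)
  bb_names <- c("N", "CA", "C", "O", "OXT")
  bb <- a[sel & a$atom %in% bb_names, , drop = FALSE]
  if (!all(c("N", "CA", "C") %in% bb$atom)) {
    stop("residue ", position, " lacks backbone atoms")
  }
  get <- function(nm) as.numeric(bb[bb$atom == nm, c("x", "y", "z")][1, ])
  sc <- build_side_chain(new_residue,
                         list(n = get("N"), ca = get("CA"), c = get("C")))
  keep <- !(sel & !(a$atom %in% bb_names))
  a <- a[keep, , drop = FALSE]
  a$res_name[a$chain == chain & a$seq_id == position] <- new_residue
  if (!is.null(sc)) {
    new_rows <- do.call(rbind, lapply(rownames(sc), function(nm) {
      atom_row(chain, new_residue, position, nm, sc[nm, ])
    }))
    # insert after the residue's backbone so residue atom blocks stay contiguous
    at <- max(which(a$chain == chain & a$seq_id == position))
    a <- rbind(a[seq_len(at), , drop = FALSE], new_rows,
               if (at < nrow(a)) a[(at + 1):nrow(a), , drop = FALSE])
  }
  hla_structure(a, roles = s$roles)
}

#' Write a directory of fixture structures consumable by [build_db()]
#'
#' Emits `n_entries` miniature groove complexes (PDB files named
#' FX01.pdb, FX02.pdb, ...) differing by engineered point mutations and
#' small coordinate perturbations, plus `metadata.tsv` with the
#' pdb_id/allele mapping and explicit chain roles.
#'
#' @param dir output directory
#' @param n_entries number of fixtures (>= 2)
#' @param hla_class 1 or 2
#' @param n_residues groove-chain size (default 40: miniature)
#' @param seed RNG seed
#' @return invisible list with `paths` and `metadata`
#' @export
write_fixture_set <- function(dir, n_entries = 3, hla_class = 1,
                              n_residues = 40, seed = 0) {
  stopifnot(n_entries >= 2)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- make_fixture("mini_groove", n_residues = n_residues,
                       hla_class = hla_class)
  mut_targets <- c("THR", "SER", "VAL", "LEU", "ASN")
  paths <- character(n_entries)
  for (i in seq_len(n_entries)) {
    s <- base
    if (i > 1) {
      rt <- residue_table(s, "A")
      pos <- rt$seq_id[2 + (i - 2) %% (nrow(rt) - 2)]
      s <- mutate_fixture(s, "A", pos, mut_targets[1 + (i - 2) %% length(mut_targets)])
      set.seed(seed + i)
      xyz <- structure_coords(s)
      s <- set_structure_coords(s, xyz + matrix(stats::rnorm(length(xyz), 0, 0.05),
                                                ncol = 3))
    }
    paths[i] <- file.path(dir, sprintf("FX%02d.pdb", i))
    write_structure(s, paths[i])
  }
  metadata <- data.frame(
    pdb_id = sprintf("FX%02d", seq_len(n_entries)),
    allele_name = sprintf("SYN*%02d:01", seq_len(n_entries)),
    hla_class = hla_class,
    roles = roles_to_spec(base$roles),
    stringsAsFactors = FALSE)
  utils::write.table(metadata, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(paths = paths, metadata = metadata))
}
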