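# Tethered relaxation: steepest-descent minimisation of soft-sphere
# repulsion + harmonic bonded terms + positional tethers on every
# non-hydrogen atom. This cleans up model geometry (segment joins,
# placed rotamers) while the tethers keep the model close to the
# inherited template coordinates.

K_BOND <- 100   # kcal/mol/A^2 harmonic bond restraint
K_REP <- 25     # kcal/mol/A^2 soft-sphere repulsion
R0_APOLAR <- 2.8
R0_POLAR <- 2.6  # N/O pairs may approach to hydrogen-bond distances

#' @noRd
structure_bond_list <- function(s) {
  a <- s$atoms
  n <- nrow(a)
  rt <- residue_table(s)
  rkey <- paste(rt$chain, rt$seq_id, rt$ins)
  akey <- paste(a$chain, a$seq_id, a$ins)
  ii <- integer(0); jj <- integer(0); dd <- numeric(0)
  prev_c <- NA_integer_; prev_chain <- ""; prev_seq <- NA_integer_
  for (r in seq_len(nrow(rt))) {
    rows <- which(akey == rkey[r])
    nm <- a$atom[rows]
    bt <- residue_bond_table(rt$res_name[r])
    for (k in seq_len(nrow(bt))) {
      i <- rows[match(bt$a[k], nm)]
      j <- rows[match(bt$b[k], nm)]
      if (!is.na(i) && !is.na(j)) {
        ii <- c(ii, i); jj <- c(jj, j); dd <- c(dd, bt$d0[k])
      }
    }
    this_n <- rows[match("N", nm)]
    if (!is.na(prev_c) && !is.na(this_n) && rt$chain[r] == prev_chain &&
        rt$seq_id[r] - prev_seq == 1L) {
      ii <- c(ii, prev_c); jj <- c(jj, this_n); dd <- c(dd, BB_C_N)
    }
    prev_c <- rows[match("C", nm)]
    prev_chain <- rt$chain[r]; prev_seq <- rt$seq_id[r]
  }
  data.frame(i = ii, j = jj, d0 = dd)
}

#' @noRd
bonded_exclusions <- function(bonds, n, depth = 3) {
  # pair keys (i-1)*n + j (i < j) for atoms within `depth` bonds
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$i[k]; j <- bonds$j[k]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  keys <- numeric(0)
  for (start in seq_len(n)) {
    seen <- start
    frontier <- start
    for (d in seq_len(depth)) {
      frontier <- unique(unlist(adj[frontier]))
      frontier <- setdiff(frontier, seen)
      if (length(frontier) == 0) break
      seen <- c(seen, frontier)
      tgt <- frontier[frontier > start]
      if (length(tgt)) keys <- c(keys, (start - 1) * n + tgt)
    }
  }
  unique(keys)
}

#' @noRd
nonbonded_pairs <- function(xyz, excl_keys, polar, cutoff = 3.2) {
  n <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  idx <- which(upper.tri(d) & d < cutoff, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(data.frame(i = integer(0), j = integer(0), r0 = numeric(0)))
  }
  keys <- (idx[, 1] - 1) * n + idx[, 2]
  keep <- !(keys %in% excl_keys)
  idx <- idx[keep, , drop = FALSE]
  r0 <- ifelse(polar[idx[, 1]] & polar[idx[, 2]], R0_POLAR, R0_APOLAR)
  data.frame(i = idx[, 1], j = idx[, 2], r0 = r0)
}

#' @noRd
accumulate_grad <- function(G, ids, vals) {
  sums <- rowsum(vals, ids)
  at <- as.integer(rownames(sums))
  G[at, ] <- G[at, ] + sums
  G
}

#' @noRd
energy_gradient <- function(xyz, xyz0, bonds, nb, k_tether) {
  G <- matrix(0, nrow(xyz), 3)
  E <- 0
  if (nrow(bonds)) {
    dv <- xyz[bonds$i, , drop = FALSE] - xyz[bonds$j, , drop = FALSE]
    d <- sqrt(rowSums(dv^2))
    dev <- d - bonds$d0
    E <- E + K_BOND * sum(dev^2)
    gv <- dv * (2 * K_BOND * dev / pmax(d, 1e-8))
    G <- accumulate_grad(G, c(bonds$i, bonds$j), rbind(gv, -gv))
  }
  if (nrow(nb)) {
    dv <- xyz[nb$i, , drop = FALSE] - xyz[nb$j, , drop = FALSE]
    d <- sqrt(rowSums(dv^2))
    pen <- nb$r0 - d
    act <- pen > 0
    if (any(act)) {
      E <- E + K_REP * sum(pen[act]^2)
      gv <- dv[act, , drop = FALSE] * (-2 * K_REP * pen[act] / pmax(d[act], 1e-8))
      G <- accumulate_grad(G, c(nb$i[act], nb$j[act]), rbind(gv, -gv))
    }
  }
  dx <- xyz - xyz0
  E <- E + k_tether * sum(dx^2)
  G <- G + 2 * k_tether * dx
  list(E = E, G = G)
}

#' Relax a model by tethered steepest descent
#'
#' Minimises soft-sphere repulsion between non-bonded atoms, harmonic
#' restraints on covalent bonds, and harmonic tethers anchoring every
#' atom to its pre-relaxation position. Energy is non-increasing across
#' accepted steps (backtracking line search); more than three
#' consecutive energy increases raises a numerical error.
#'
#' @param s an `hla_structure` with a complete non-hydrogen model
#' @param config a [build_config()] (tether force constant, step limit)
#' @param mobile optional logical mask of atoms allowed to move
#' @return the relaxed `hla_structure`
#' @export
relax <- function(s, config = build_config(), mobile = NULL) {
  xyz0 <- structure_coords(s)
  n <- nrow(xyz0)
  if (is.null(mobile)) mobile <- rep(TRUE, n)
  bonds <- structure_bond_list(s)
  excl <- bonded_exclusions(bonds, n)
  polar <- s$atoms$element %in% c("N", "O")
  xyz <- xyz0
  nb <- nonbonded_pairs(xyz, excl, polar)
  eg <- energy_gradient(xyz, xyz0, bonds, nb, config$tether_force_constant)
  alpha <- 5e-4
  increases <- 0
  for (step in seq_len(config$relaxation_steps)) {
    if (step %% 25 == 0) {
      nb <- nonbonded_pairs(xyz, excl, polar)
      eg <- energy_gradient(xyz, xyz0, bonds, nb, config$tether_force_constant)
    }
    G <- eg$G
    G[!mobile, ] <- 0
    gmax <- max(abs(G))
    if (gmax < 1e-3) break
    accepted <- FALSE
    a <- alpha
    for (try in 1:30) {
      cand <- xyz - a * G
      eg2 <- energy_gradient(cand, xyz0, bonds, nb, config$tether_force_constant)
      if (eg2$E <= eg$E + 1e-12) {
        if (eg2$E > eg$E) increases <- increases + 1 else increases <- 0
        if (increases > 3) stop("relaxation diverged: energy increased on >3 successive steps")
        xyz <- cand; eg <- eg2; alpha <- min(a * 1.5, 5e-3)
        accepted <- TRUE
        break
      }
      a <- a / 2
    }
    if (!accepted) break
  }
  set_structure_coords(s, xyz)
}

#' Count steric clashes in a structure
#'
#' Non-bonded (more than three bonds apart) non-hydrogen atom pairs
#' closer than `threshold`.
#' @param s an `hla_structure`
#' @param threshold distance in Angstrom, default 1.8
#' @return integer pair count
#' @export
count_clashes <- function(s, threshold = 1.8) {
  xyz <- structure_coords(s)
  bonds <- structure_bond_list(s)
  excl <- bonded_exclusions(bonds, nrow(xyz))
  nb <- nonbonded_pairs(xyz, excl, s$atoms$element %in% c("N", "O"),
                        cutoff = threshold)
  nrow(nb)
}
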