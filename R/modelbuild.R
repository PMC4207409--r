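# Homology-model construction: segment-matching backbone inheritance
# from the template, torsion-space closure of unresolved segments,
# rotamer-based side-chain placement, tethered soft-sphere relaxation,
# and best-of-N candidate selection by hydration score.

#' Build configuration for model construction
#'
#' @param n_candidates intermediate models to build (best kept), >= 1
#' @param tether_force_constant harmonic tether on every non-hydrogen
#'   atom during relaxation, kcal/mol/A^2
#' @param relaxation_steps maximum steepest-descent iterations
#' @param segment_length fragment length used when mining closure
#'   torsions from template structures
#' @param seed integer driving every stochastic choice
#' @return object of class `build_config`
#' @export
build_config <- function(n_candidates = 10, tether_force_constant = 10,
                         relaxation_steps = 200, segment_length = 6,
                         seed = 0) {
  stopifnot(n_candidates >= 1, tether_force_constant > 0,
            relaxation_steps > 0, segment_length > 0)
  structure(list(n_candidates = as.integer(n_candidates),
                 tether_force_constant = tether_force_constant,
                 relaxation_steps = as.integer(relaxation_steps),
                 segment_length = as.integer(segment_length),
                 seed = as.integer(seed)),
            class = "build_config")
}

# ---- backbone inheritance -------------------------------------------------

#' Inherit the template backbone for aligned residues
#'
#' The segment-matching first stage: every gap-free alignment column
#' hands the template residue's backbone (N, CA, C, O) to the
#' corresponding query residue. Query positions without a template
#' residue — insertions, or template residues missing backbone atoms —
#' are collected into unresolved segments flanked by their nearest
#' resolved anchor residues (one-sided at the termini).
#'
#' @param alignment an `alignment_result` of the query against the
#'   template-site sequence
#' @param template_site single-chain `hla_structure` whose k-th residue
#'   is template position k of the alignment
#' @param chain chain id for the model under construction
#' @param query_seq_ids optional author numbering for the query
#'   residues (defaults to 1..n)
#' @return a `partial_model`: per-residue backbone list plus the
#'   unresolved segment list
#' @export
inherit_backbone <- function(alignment, template_site, chain = "A",
                             query_seq_ids = NULL) {
  rt <- residue_table(template_site)
  if (length(unique(rt$chain)) != 1) {
    stop("template site must be a single chain for backbone inheritance")
  }
  qc <- strsplit(alignment$aligned_query, "")[[1]]
  nq <- sum(qc != "-")
  if (is.null(query_seq_ids)) query_seq_ids <- seq_len(nq)
  stopifnot(length(query_seq_ids) == nq)
  mp <- alignment$matched_positions
  t_of_q <- rep(NA_integer_, nq)
  t_of_q[mp$query] <- mp$template
  qletters <- qc[qc != "-"]

  ta <- template_site$atoms
  tkey <- paste(ta$chain, ta$seq_id, ta$ins)
  rkey <- paste(rt$chain, rt$seq_id, rt$ins)

  residues <- vector("list", nq)
  resolved <- logical(nq)
  for (q in seq_len(nq)) {
    bb <- matrix(NA_real_, 4, 3, dimnames = list(c("N", "CA", "C", "O"), NULL))
    t <- t_of_q[q]
    inherited <- FALSE
    if (!is.na(t) && t <= nrow(rt)) {
      rows <- ta[tkey == rkey[t], , drop = FALSE]
      for (nm in c("N", "CA", "C", "O")) {
        hit <- which(rows$atom == nm)
        if (length(hit)) bb[nm, ] <- c(rows$x[hit[1]], rows$y[hit[1]], rows$z[hit[1]])
      }
      inherited <- all(is.finite(bb[c("N", "CA", "C"), ]))
    }
    resolved[q] <- inherited
    residues[[q]] <- list(pos = q, seq_id = query_seq_ids[q], chain = chain,
                          res_name = aa_one_to_three(qletters[q]),
                          backbone = bb, inherited = inherited,
                          template_pos = t, sidechain = NULL)
  }
  segments <- list()
  runs <- rle(resolved)
  idx_end <- cumsum(runs$lengths)
  idx_start <- idx_end - runs$lengths + 1
  for (k in seq_along(runs$values)) {
    if (!runs$values[k]) {
      left <- if (idx_start[k] > 1) idx_start[k] - 1L else NA_integer_
      right <- if (idx_end[k] < nq) idx_end[k] + 1L else NA_integer_
      segments <- c(segments, list(list(positions = idx_start[k]:idx_end[k],
                                        left = left, right = right)))
    }
  }
  structure(list(residues = residues, segments = segments, chain = chain),
            class = "partial_model")
}

#' @export
print.partial_model <- function(x, ...) {
  cat("partial_model:", length(x$residues), "residues,",
      length(x$segments), "unresolved segment(s)\n")
  invisible(x)
}

# ---- segment closure ------------------------------------------------------

CANONICAL_PHIPSI <- rbind(
  c(-57, -47), c(-139, 135), c(-78, 149), c(-60, -30),
  c(60, 45), c(-120, 120), c(-90, 0), c(-60, 120), c(80, 0))

#' @noRd
mine_library_torsions <- function(library, segment_length = 6, max_pairs = 8) {
  if (is.null(library)) return(NULL)
  if (inherits(library, "hla_structure")) library <- list(library)
  pairs <- list()
  for (s in library) {
    for (ch in chain_ids(s)) {
      bb <- chain_backbone(s, ch)
      if (is.null(bb) || nrow(bb$ca) < max(3, segment_length)) next
      tor <- backbone_torsions(bb)
      ok <- stats::complete.cases(tor)
      pairs[[length(pairs) + 1]] <- tor[ok, , drop = FALSE]
    }
  }
  if (length(pairs) == 0) return(NULL)
  tor <- do.call(rbind, pairs)
  if (nrow(tor) == 0) return(NULL)
  key <- paste(round(tor[, 1] / 20), round(tor[, 2] / 20))
  tab <- sort(table(key), decreasing = TRUE)
  keep <- names(tab)[seq_len(min(max_pairs, length(tab)))]
  out <- do.call(rbind, lapply(keep, function(k) colMeans(tor[key == k, , drop = FALSE])))
  unname(out)
}

#' @noRd
chain_backbone <- function(s, ch) {
  rt <- residue_table(s, ch)
  a <- s$atoms[s$atoms$chain == ch, , drop = FALSE]
  key <- paste(a$seq_id, a$ins)
  rk <- paste(rt$seq_id, rt$ins)
  get <- function(nm) {
    m <- matrix(NA_real_, nrow(rt), 3)
    for (i in seq_len(nrow(rt))) {
      hit <- which(key == rk[i] & a$atom == nm)
      if (length(hit)) m[i, ] <- c(a$x[hit[1]], a$y[hit[1]], a$z[hit[1]])
    }
    m
  }
  out <- list(n = get("N"), ca = get("CA"), c = get("C"), o = get("O"))
  if (all(is.na(out$ca))) return(NULL)
  out
}

#' @noRd
backbone_torsions <- function(bb) {
  n <- nrow(bb$ca)
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1 && all(is.finite(c(bb$c[i - 1, ], bb$n[i, ], bb$ca[i, ], bb$c[i, ])))) {
      phi[i] <- vec_dihedral(bb$c[i - 1, ], bb$n[i, ], bb$ca[i, ], bb$c[i, ])
    }
    if (i < n && all(is.finite(c(bb$n[i, ], bb$ca[i, ], bb$c[i, ], bb$n[i + 1, ])))) {
      psi[i] <- vec_dihedral(bb$n[i, ], bb$ca[i, ], bb$c[i, ], bb$n[i + 1, ])
    }
  }
  cbind(phi = phi, psi = psi)
}

#' @noRd
grow_segment <- function(anchor, torsions, omega_dev = NULL) {
  # anchor: list(n, ca, c) of the left anchor residue; torsions:
  # c(psi0, phi1, psi1, phi2, psi2, ...); omega_dev: optional length
  # L + 1 deviations from the trans peptide bond, used by the closure
  # search to reach conformations rigid ideal geometry cannot. Returns
  # per-residue backbone list plus the predicted N/CA of the next
  # residue after the segment.
  L <- (length(torsions) - 1) / 2
  if (is.null(omega_dev)) omega_dev <- rep(0, L + 1)
  prevN <- anchor$n; prevCA <- anchor$ca; prevC <- anchor$c
  psi_prev <- torsions[1]
  res <- vector("list", L)
  for (i in seq_len(L)) {
    phi <- torsions[2 * i]; psi <- torsions[2 * i + 1]
    N <- place_atom(prevN, prevCA, prevC, BB_C_N, ANG_CA_C_N, psi_prev)
    CA <- place_atom(prevCA, prevC, N, BB_N_CA, ANG_C_N_CA, 180 + omega_dev[i])
    C <- place_atom(prevC, N, CA, BB_CA_C, ANG_N_CA_C, phi)
    res[[i]] <- list(n = N, ca = CA, c = C)
    prevN <- N; prevCA <- CA; prevC <- C
    psi_prev <- psi
  }
  nextN <- place_atom(prevN, prevCA, prevC, BB_C_N, ANG_CA_C_N, psi_prev)
  nextCA <- place_atom(prevCA, prevC, nextN, BB_N_CA, ANG_C_N_CA,
                       180 + omega_dev[L + 1])
  list(residues = res, next_n = nextN, next_ca = nextCA)
}

#' Close unresolved backbone segments in torsion space
#'
#' Each gap is rebuilt with ideal backbone geometry: candidate
#' (phi, psi) pairs — mined from the supplied template structures,
#' falling back to canonical secondary-structure values — are
#' enumerated combinatorially, the best-closing combination is refined
#' by derivative-free minimisation of the anchor mismatch, and carbonyl
#' oxygens are rebuilt across the join. Terminal segments (a single
#' anchor) are grown with extended-chain torsions.
#'
#' @param partial a `partial_model` from [inherit_backbone()]
#' @param library optional `hla_structure` (or list of them) to mine
#'   closure torsions from
#' @param config a [build_config()]
#' @param jitter standard deviation (degrees) of torsion perturbation
#'   applied to candidate starts (used to diversify model candidates;
#'   draws from the current RNG stream)
#' @param max_gap closure failure threshold on the joining-bond length
#'   error (A)
#' @return the `partial_model` with every residue's backbone complete
#' @export
close_segments <- function(partial, library = NULL, config = build_config(),
                           jitter = 0, max_gap = 1.0) {
  if (length(partial$segments) == 0) return(partial)
  cand <- mine_library_torsions(library, config$segment_length)
  cand <- rbind(cand, CANONICAL_PHIPSI)
  res <- partial$residues
  for (seg in partial$segments) {
    L <- length(seg$positions)
    if (is.na(seg$left) && is.na(seg$right)) {
      # nothing resolved at all: build as ideal extended chain
      bb <- build_backbone(rep(-120, L), rep(130, L))
      for (k in seq_len(L)) {
        q <- seg$positions[k]
        res[[q]]$backbone[] <- rbind(bb$n[k, ], bb$ca[k, ], bb$c[k, ], bb$o[k, ])
      }
      next
    }
    if (is.na(seg$left) || is.na(seg$right)) {
      res <- grow_terminal_segment(res, seg, jitter)
      next
    }
    left <- res[[seg$left]]$backbone
    right <- res[[seg$right]]$backbone
    anchor <- list(n = left["N", ], ca = left["CA", ], c = left["C", ])
    target_n <- right["N", ]; target_ca <- right["CA", ]
    reach <- (L + 1) * 3.9
    span <- sqrt(sum((target_n - anchor$c)^2))
    if (span > reach) {
      stop(sprintf("unclosable segment at positions %d-%d: anchors %.1f A apart exceed the %.1f A reach; worst closure gap %.1f A",
                   seg$positions[1], seg$positions[L], span, reach, span - reach))
    }
    # parameters: psi0, (phi, psi) per residue, then L + 1 omega
    # deviations (penalised so the peptide bonds stay near trans)
    n_tor <- 1 + 2 * L
    objective <- function(par) {
      g <- grow_segment(anchor, par[seq_len(n_tor)], par[-seq_len(n_tor)])
      sum((g$next_n - target_n)^2) + sum((g$next_ca - target_ca)^2) +
        3e-4 * sum(par[-seq_len(n_tor)]^2)
    }
    # combinatorial scan over candidate (phi, psi) rows
    ncand <- nrow(cand)
    n_combo <- ncand^L
    combos <- if (n_combo <= 4096) {
      as.matrix(expand.grid(rep(list(seq_len(ncand)), L)))
    } else {
      matrix(sample.int(ncand, 4096 * L, replace = TRUE), ncol = L)
    }
    starts <- matrix(NA_real_, nrow(combos), n_tor + L + 1)
    vals <- numeric(nrow(combos))
    for (r in seq_len(nrow(combos))) {
      rows <- cand[combos[r, ], , drop = FALSE]
      starts[r, ] <- c(rows[1, 2], as.vector(t(rows)), rep(0, L + 1))
      vals[r] <- objective(starts[r, ])
    }
    # multi-start refinement: polish the most promising grid points
    top <- order(vals)[seq_len(min(6, nrow(starts)))]
    best <- NULL; best_val <- Inf
    for (r in top) {
      s0 <- starts[r, ]
      if (jitter > 0) s0 <- s0 + stats::rnorm(length(s0), 0, jitter)
      opt <- stats::optim(s0, objective, method = "Nelder-Mead",
                          control = list(maxit = 300 * length(s0), reltol = 1e-10))
      opt <- stats::optim(opt$par, objective, method = "Nelder-Mead",
                          control = list(maxit = 300 * length(s0), reltol = 1e-12))
      if (opt$value < best_val) { best_val <- opt$value; best <- opt$par }
    }
    g <- grow_segment(anchor, best[seq_len(n_tor)], best[-seq_len(n_tor)])
    gap <- abs(sqrt(sum((g$residues[[L]]$c - target_n)^2)) - BB_C_N)
    if (gap > max_gap) {
      stop(sprintf("unclosable segment at positions %d-%d: worst closure gap %.2f A",
                   seg$positions[1], seg$positions[L], gap))
    }
    for (k in seq_len(L)) {
      q <- seg$positions[k]
      nextN <- if (k < L) g$residues[[k + 1]]$n else target_n
      O <- place_atom(nextN, g$residues[[k]]$ca, g$residues[[k]]$c,
                      BB_C_O, ANG_CA_C_O, 180)
      res[[q]]$backbone[] <- rbind(g$residues[[k]]$n, g$residues[[k]]$ca,
                                   g$residues[[k]]$c, O)
    }
    # left anchor's O must face the rebuilt continuation
    res[[seg$left]]$backbone["O", ] <- place_atom(
      g$residues[[1]]$n, anchor$ca, anchor$c, BB_C_O, ANG_CA_C_O, 180)
  }
  partial$residues <- res
  partial$segments <- list()
  partial
}

#' @noRd
grow_terminal_segment <- function(res, seg, jitter = 0) {
  L <- length(seg$positions)
  phi <- rep(-120, L); psi <- rep(130, L)
  if (jitter > 0) {
    phi <- phi + stats::rnorm(L, 0, jitter)
    psi <- psi + stats::rnorm(L, 0, jitter)
  }
  if (!is.na(seg$left)) {
    left <- res[[seg$left]]$backbone
    anchor <- list(n = left["N", ], ca = left["CA", ], c = left["C", ])
    g <- grow_segment(anchor, c(130, as.vector(rbind(phi, psi))))
    for (k in seq_len(L)) {
      q <- seg$positions[k]
      nextN <- if (k < L) g$residues[[k + 1]]$n else g$next_n
      O <- place_atom(nextN, g$residues[[k]]$ca, g$residues[[k]]$c,
                      BB_C_O, ANG_CA_C_O, 180)
      res[[q]]$backbone[] <- rbind(g$residues[[k]]$n, g$residues[[k]]$ca,
                                   g$residues[[k]]$c, O)
    }
  } else {
    # N-terminal overhang: grow backwards from the right anchor by
    # building the reversed chain with mirrored torsions
    right <- res[[seg$right]]$backbone
    anchor <- list(n = right["C", ], ca = right["CA", ], c = right["N", ])
    g <- grow_segment(anchor, c(-phi[L], as.vector(rbind(-psi, -phi))))
    for (k in seq_len(L)) {
      q <- seg$positions[L - k + 1]
      bb <- rbind(g$residues[[k]]$c, g$residues[[k]]$ca, g$residues[[k]]$n)
      nextN <- if (q < length(res)) res[[q + 1]]$backbone["N", ] else g$next_n
      O <- place_atom(nextN, bb[2, ], bb[3, ], BB_C_O, ANG_CA_C_O, 180)
      res[[q]]$backbone[] <- rbind(bb, O)
    }
  }
  res
}

# ---- side-chain placement -------------------------------------------------

#' Place side chains on a complete backbone
#'
#' Residues whose backbone was inherited from an identically aligned
#' template residue copy the template side-chain coordinates verbatim;
#' every other residue is built from its rotamer library, keeping the
#' conformer with the lowest soft steric-clash score against the
#' growing model (ties broken by library order; the best rotamer is
#' accepted even if clashed, and flagged).
#'
#' @param partial a `partial_model` with complete backbone
#' @param template_site the template structure side chains are copied
#'   from
#' @param context optional `hla_structure` whose atoms also count as
#'   clash partners (e.g. the groove when threading a peptide)
#' @param jitter chi-angle perturbation (degrees, RNG-driven) applied
#'   to placed rotamers
#' @return the `partial_model` with `sidechain` coordinate matrices
#' @export
place_side_chains <- function(partial, template_site = NULL, context = NULL,
                              jitter = 0) {
  res <- partial$residues
  trt <- if (!is.null(template_site)) residue_table(template_site) else NULL
  ta <- if (!is.null(template_site)) template_site$atoms else NULL

  # clash context: all backbone atoms + placed side chains, grown as we go
  ctx <- do.call(rbind, lapply(res, function(r) r$backbone))
  ctx_res <- rep(seq_along(res), each = 4)
  if (!is.null(context)) {
    ctx <- rbind(ctx, structure_coords(context))
    ctx_res <- c(ctx_res, rep(0L, n_atoms(context)))
  }
  for (q in seq_along(res)) {
    r <- res[[q]]
    if (!all(is.finite(r$backbone[c("N", "CA", "C"), ]))) {
      stop("residue ", r$seq_id, " has an incomplete backbone")
    }
    topo <- SIDECHAIN_TOPOLOGY[[r$res_name]]
    if (is.null(topo)) { res[[q]]$sidechain <- NULL; next }
    copied <- FALSE
    if (r$inherited && !is.null(trt) && !is.na(r$template_pos)) {
      t <- r$template_pos
      if (t <= nrow(trt) && trt$res_name[t] == r$res_name) {
        key <- paste(ta$chain, ta$seq_id, ta$ins)
        tk <- paste(trt$chain[t], trt$seq_id[t], trt$ins[t])
        rows <- ta[key == tk & !(ta$atom %in% c("N", "CA", "C", "O", "OXT")), , drop = FALSE]
        if (all(topo$atom %in% rows$atom)) {
          sc <- as.matrix(rows[match(topo$atom, rows$atom), c("x", "y", "z")])
          rownames(sc) <- topo$atom
          res[[q]]$sidechain <- sc
          copied <- TRUE
        }
      }
    }
    if (!copied) {
      bb <- list(n = r$backbone["N", ], ca = r$backbone["CA", ],
                 c = r$backbone["C", ])
      grid <- rotamer_chi_grid(r$res_name)
      others <- ctx[ctx_res != q, , drop = FALSE]
      best_sc <- NULL; best_val <- Inf; best_chi <- numeric(0)
      for (g in seq_len(nrow(grid))) {
        sc <- build_side_chain(r$res_name, bb, chi = grid[g, ])
        val <- clash_score(sc, others)
        if (val < best_val - 1e-9) { best_val <- val; best_sc <- sc; best_chi <- grid[g, ] }
      }
      if (jitter > 0 && length(best_chi)) {
        best_sc <- build_side_chain(r$res_name, bb,
                                    chi = best_chi + stats::rnorm(length(best_chi), 0, jitter))
      }
      res[[q]]$sidechain <- best_sc
      res[[q]]$clashed <- best_val > 0
    }
    if (!is.null(res[[q]]$sidechain)) {
      ctx <- rbind(ctx, res[[q]]$sidechain)
      ctx_res <- c(ctx_res, rep(q, nrow(res[[q]]$sidechain)))
    }
  }
  partial$residues <- res
  partial
}

#' @noRd
clash_score <- function(sc, others, r0 = 2.9) {
  if (is.null(sc) || nrow(others) == 0) return(0)
  tot <- 0
  for (i in seq_len(nrow(sc))) {
    d2 <- (others[, 1] - sc[i, 1])^2 + (others[, 2] - sc[i, 2])^2 +
      (others[, 3] - sc[i, 3])^2
    close <- d2 < r0^2
    if (any(close)) tot <- tot + sum((r0 - sqrt(d2[close]))^2)
  }
  tot
}

#' Assemble a partial model into an hla_structure
#' @param partial a completed `partial_model`
#' @param role chain role recorded for the model chain
#' @return an `hla_structure`
#' @export
assemble_model <- function(partial, role = "heavy_chain") {
  rows <- lapply(partial$residues, function(r) {
    bb <- r$backbone
    out <- do.call(rbind, lapply(rownames(bb), function(nm) {
      atom_row(r$chain, r$res_name, r$seq_id, nm, bb[nm, ])
    }))
    if (!is.null(r$sidechain)) {
      out <- rbind(out, do.call(rbind, lapply(rownames(r$sidechain), function(nm) {
        atom_row(r$chain, r$res_name, r$seq_id, nm, r$sidechain[nm, ])
      })))
    }
    out
  })
  hla_structure(do.call(rbind, rows), roles = setNames(role, partial$chain))
}
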