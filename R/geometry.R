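# Internal-coordinate geometry: atom placement from bond/angle/dihedral,
# backbone construction from (phi, psi, omega) torsions, side-chain
# construction from chi angles.

DEG <- pi / 180

# ideal backbone geometry (A, degrees)
BB_N_CA  <- 1.458
BB_CA_C  <- 1.525
BB_C_N   <- 1.329
BB_C_O   <- 1.231
ANG_N_CA_C <- 111.2
ANG_CA_C_N <- 116.2
ANG_C_N_CA <- 121.7
ANG_CA_C_O <- 120.8

#' Place an atom from three reference atoms and internal coordinates
#'
#' Returns the position of a new atom D such that |C-D| = `bond`,
#' angle(B, C, D) = `angle` and dihedral(A, B, C, D) = `dihedral`
#' (degrees). This is the standard natural-extension (NeRF) construction
#' used to grow polymers in torsion space.
#' @param a,b,c numeric length-3 reference coordinates
#' @param bond bond length in Angstrom
#' @param angle bond angle in degrees
#' @param dihedral torsion angle in degrees
#' @return numeric length-3 coordinate
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, dihedral) {
  theta <- angle * DEG
  chi <- dihedral * DEG
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  nn <- sqrt(sum(n^2))
  if (nn < 1e-10) {
    # collinear reference frame: pick any perpendicular
    n <- if (abs(bc[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    n <- n - sum(n * bc) * bc
    nn <- sqrt(sum(n^2))
  }
  n <- n / nn
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(theta),
          bond * sin(theta) * cos(chi),
          -bond * sin(theta) * sin(chi))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' @noRd
vec_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(max(-1, min(1, cosang))) / DEG
}

#' @noRd
vec_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) / DEG
}

#' Build an ideal polypeptide backbone from torsion angles
#'
#' Grows N, CA, C, O for `n` residues with standard bond lengths and
#' angles, trans peptide bonds unless `omega` says otherwise. `phi[1]`
#' is unused (no preceding carbonyl); `psi[n]` only orients the final
#' carbonyl oxygen.
#'
#' @param phi,psi numeric vectors of length n (degrees)
#' @param omega peptide-bond torsions, recycled, default 180
#' @param origin coordinates of the first N atom
#' @return list with per-residue matrices `n`, `ca`, `c`, `o` (n x 3)
#' @keywords internal
build_backbone <- function(phi, psi, omega = 180, origin = c(0, 0, 0)) {
  n_res <- length(phi)
  stopifnot(length(psi) == n_res)
  omega <- rep(omega, length.out = n_res)
  N <- CA <- C <- O <- matrix(NA_real_, n_res, 3)
  N[1, ] <- origin
  CA[1, ] <- origin + c(BB_N_CA, 0, 0)
  th <- ANG_N_CA_C * DEG
  C[1, ] <- CA[1, ] + BB_CA_C * c(-cos(th), sin(th), 0)
  if (n_res > 1) {
    for (i in seq_len(n_res - 1)) {
      N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ], BB_C_N, ANG_CA_C_N, psi[i])
      CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ], BB_N_CA, ANG_C_N_CA, omega[i])
      C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], BB_CA_C, ANG_N_CA_C, phi[i + 1])
      O[i, ] <- place_atom(N[i + 1, ], CA[i, ], C[i, ], BB_C_O, ANG_CA_C_O, 180)
    }
  }
  O[n_res, ] <- place_atom(N[n_res, ], CA[n_res, ], C[n_res, ], BB_C_O, ANG_CA_C_O,
                           psi[n_res] - 180)
  list(n = N, ca = CA, c = C, o = O)
}

#' Construct side-chain atoms for one residue from chi angles
#'
#' @param res_name 3-letter residue code
#' @param bb named list with `n`, `ca`, `c` backbone coordinates
#' @param chi numeric chi angles (degrees); recycled from defaults when
#'   shorter than the residue needs
#' @return matrix of side-chain coordinates with atom-name rownames
#'   (includes CB), or NULL for glycine
#' @keywords internal
build_side_chain <- function(res_name, bb, chi = default_chi(res_name)) {
  topo <- SIDECHAIN_TOPOLOGY[[res_name]]
  if (is.null(topo)) return(NULL)
  nc <- n_chi(res_name)
  if (length(chi) < nc) chi <- c(chi, default_chi(res_name))[seq_len(nc)]
  pos <- list(N = bb$n, CA = bb$ca, C = bb$c)
  out <- matrix(NA_real_, nrow(topo), 3)
  rownames(out) <- topo$atom
  for (i in seq_len(nrow(topo))) {
    tors <- topo$tors[i]
    if (grepl("^chi", tors)) {
      k <- as.integer(substring(tors, 4, 4))
      off <- sub("^chi[1-4]", "", tors)
      tval <- chi[k] + if (nzchar(off)) as.numeric(off) else 0
    } else {
      tval <- as.numeric(tors)
    }
    p <- place_atom(pos[[topo$a1[i]]], pos[[topo$a2[i]]], pos[[topo$a3[i]]],
                    topo$bond[i], topo$angle[i], tval)
    pos[[topo$atom[i]]] <- p
    out[i, ] <- p
  }
  out
}

#' @noRd
rigid_transform <- function(xyz, rotation = diag(3), translation = c(0, 0, 0)) {
  sweep(xyz %*% t(rotation), 2, -translation)
}
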