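# Solvent-accessible surface area by deterministic sphere sampling, and
# the atomic-solvation hydration score used to pick the best model
# candidate.

#' @noRd
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area per atom
#'
#' Shrake-Rupley-style sampling: each atom's solvent-extended sphere
#' (van der Waals radius + probe) is covered with a deterministic
#' Fibonacci lattice of test points; a point is accessible when it lies
#' outside every neighbouring atom's extended sphere. For an isolated
#' atom all points are exposed, so the area is exactly
#' 4 * pi * (r + probe)^2.
#'
#' @param xyz n x 3 coordinate matrix (Angstrom)
#' @param radii per-atom van der Waals radii
#' @param probe probe radius, default 1.4 (water)
#' @param n_points sample points per atom, default 960
#' @return numeric vector of per-atom areas (Angstrom^2)
#' @export
sasa_atoms <- function(xyz, radii, probe = 1.4, n_points = 960) {
  n <- nrow(xyz)
  stopifnot(length(radii) == n)
  rext <- radii + probe
  pts <- fibonacci_sphere(n_points)
  out <- numeric(n)
  if (n > 1) {
    d2 <- as.matrix(stats::dist(xyz))^2
  }
  for (i in seq_len(n)) {
    if (n > 1) {
      nb <- which(d2[i, ] < (rext[i] + rext)^2 & seq_len(n) != i)
    } else nb <- integer(0)
    if (length(nb) == 0) {
      out[i] <- 4 * pi * rext[i]^2
      next
    }
    p <- sweep(pts * rext[i], 2, xyz[i, ], `+`)
    free <- rep(TRUE, n_points)
    for (j in nb) {
      dx <- p[, 1] - xyz[j, 1]; dy <- p[, 2] - xyz[j, 2]; dz <- p[, 3] - xyz[j, 3]
      free <- free & (dx * dx + dy * dy + dz * dz > rext[j]^2)
      if (!any(free)) break
    }
    out[i] <- 4 * pi * rext[i]^2 * sum(free) / n_points
  }
  out
}

#' Hydration score of a structure
#'
#' Sum over atoms of (atomic solvation parameter x solvent-accessible
#' area), Eisenberg-McLachlan style: exposed apolar surface raises the
#' score, exposed polar/charged surface lowers it. Used to select the
#' best model among candidates (lower = better hydrated); the absolute
#' values carry no force-field meaning.
#'
#' @param s an `hla_structure`
#' @param probe probe radius (A)
#' @param n_points sample points per atom
#' @return scalar score (kcal/mol-like units)
#' @export
hydration_score <- function(s, probe = 1.4, n_points = 960) {
  a <- s$atoms
  areas <- sasa_atoms(structure_coords(s), element_radius(a$element),
                      probe = probe, n_points = n_points)
  sum(solvation_parameter(a$element, a$res_name, a$atom) * areas)
}
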