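# Kabsch superposition, RMSD pairing, leave-one-out harness and the
# bound-peptide conservation statistic.

test_that("superposition recovers identity and rigid motions", {
  set.seed(3)
  X <- matrix(stats::rnorm(30), 10, 3)
  s0 <- kabsch_superpose(X, X)
  expect_equal(s0$rmsd, 0, tolerance = 1e-12)
  expect_equal(s0$rotation, diag(3), tolerance = 1e-9)

  Y <- X %*% t(rot_z(90))
  Y <- sweep(Y, 2, c(5, 0, 0), `+`)
  s1 <- kabsch_superpose(X, Y)
  expect_equal(s1$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(s1$rotation), 1, tolerance = 1e-6)
  moved <- sweep(X %*% t(s1$rotation), 2, s1$translation, `+`)
  expect_equal(moved, Y, tolerance = 1e-9)
})

test_that("kabsch rmsd matches a brute-force rotation grid on toy sets", {
  # coplanar sets: the optimal proper rotation is in-plane, so an
  # exhaustive in-plane grid at 0.5 degree steps is a true oracle
  base <- cbind(c(0, 3, 3, 0), c(0, 0, 3, 3), 0)
  displaced <- base
  displaced[2, 1] <- displaced[2, 1] + 1  # one point off by 1 A
  k <- kabsch_superpose(base, displaced)$rmsd
  o <- oracle_planar_rmsd(base, displaced)
  expect_lt(abs(k - o), 1e-3)
  expect_lte(k, o + 1e-9)  # never worse than the grid

  set.seed(8)
  for (rep in 1:3) {
    A <- cbind(matrix(stats::rnorm(12, sd = 2), 6, 2), 0)[1:6, ]
    B <- cbind(matrix(stats::rnorm(12, sd = 2), 6, 2), 0)[1:6, ]
    expect_lt(abs(kabsch_superpose(A, B)$rmsd - oracle_planar_rmsd(A, B)),
              1e-3)
  }
})

test_that("rmsd is symmetric and invariant under rigid motion", {
  set.seed(4)
  for (rep in 1:5) {
    A <- matrix(stats::rnorm(24), 8, 3)
    B <- A + matrix(stats::rnorm(24, sd = 0.3), 8, 3)
    r1 <- kabsch_superpose(A, B)$rmsd
    r2 <- kabsch_superpose(B, A)$rmsd
    expect_lt(abs(r1 - r2), 1e-9)
    Bmoved <- sweep(B %*% t(rot_z(37)), 2, c(3, -2, 7), `+`)
    expect_lt(abs(kabsch_superpose(A, Bmoved)$rmsd - r1), 1e-9)
  }
})

test_that("degenerate superposition inputs are rejected", {
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)),
               "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("atom pairing matches by role, number and name", {
  g <- make_fixture("mini_groove", n_residues = 30)
  pa <- paired_atoms(g, g, scope = "binding_site")
  expect_equal(nrow(pa$unmatched_model), 0)
  expect_equal(pa$coverage, 1)
  expect_identical(pa$model_xyz, pa$crystal_xyz)

  # crystal missing one side chain: pairing proceeds, atoms reported
  cr <- g
  rt <- residue_table(cr, "A")
  victim <- rt$seq_id[2]
  dropped <- cr$atoms$chain == "A" & cr$atoms$seq_id == victim &
    !(cr$atoms$atom %in% c("N", "CA", "C", "O"))
  cr$atoms <- cr$atoms[!dropped, ]
  pa2 <- paired_atoms(g, cr, scope = "binding_site")
  expect_equal(nrow(pa2$unmatched_model), sum(dropped))
  expect_lt(nrow(pa2$model_xyz), nrow(pa$model_xyz))

  # binding-site scope clips a long chain at residue 180
  long <- make_fixture("ideal_helix", n_residues = 200)
  long$roles["A"] <- "heavy_chain"
  pa3 <- paired_atoms(long, long, scope = "binding_site",
                      site = binding_site_definition(1))
  expect_equal(nrow(pa3$model_xyz), sum(long$atoms$seq_id <= 180))
})

test_that("leave-one-out models an exact duplicate to near-zero rmsd", {
  td <- withr::local_tempdir()
  db <- duplicate_db(td)
  rep <- run_loocv(db, 1, config = fast_config(), all_domains = FALSE)
  expect_equal(nrow(rep), 3)
  expect_true(all(rep$target != rep$template))
  dup_rows <- rep[rep$target %in% c("DA01", "DC03"), ]
  expect_equal(dup_rows$template, c("DC03", "DA01"))
  expect_true(all(dup_rows$binding_site_rmsd <= 0.2))
  expect_true(all(dup_rows$identity == 100))
  expect_error(run_loocv(db[1], 1), "at least 2")
})

test_that("binding-site-first modeling beats all-domain modeling on fixtures", {
  td <- withr::local_tempdir()
  db <- fixture_db(td)
  rep <- run_loocv(db, 1, config = fast_config(), all_domains = TRUE)
  # the fixture grooves sit entirely inside the binding-site ranges, so
  # the two columns measure the same atoms and must agree closely
  expect_true(all(abs(rep$binding_site_rmsd - rep$all_domain_rmsd) < 0.15))
  expect_true(stats::median(rep$binding_site_rmsd) <=
                stats::median(rep$all_domain_rmsd) + 0.05)
})

# build a conservation record set directly from coordinate matrices
conservation_records <- function(cores) {
  lapply(seq_along(cores), function(i) {
    atoms <- do.call(rbind, lapply(1:8, function(p) {
      rows <- ((p - 1) * 4 + 1):(p * 4)
      nm <- c("N", "CA", "C", "O")
      do.call(rbind, lapply(1:4, function(k) {
        hlamod:::atom_row("P", "ALA", p, nm[k], cores[[i]][rows[k], ])
      }))
    }))
    s <- hla_structure(atoms, roles = c(P = "peptide"))
    hlamod:::new_hla_record(sprintf("PP%02d", i), "SYN*77:01", s, 2L)
  })
}

test_that("identical peptides give zero conservation medians", {
  core <- matrix(stats::rnorm(96, sd = 3), 32, 3)
  recs <- conservation_records(list(core, core, core))
  rep <- peptide_conservation(recs, core_window = 1:8)
  expect_equal(rep$n_peptides, 3)
  expect_length(rep$medians, 8)
  expect_equal(unname(rep$medians), rep(0, 8), tolerance = 1e-9)
})

test_that("an engineered 0.4 A perturbation appears exactly in the median", {
  # construct a core whose total centroid and position-4 centroid are
  # both at the origin: a +v shift of position 4 compensated by -v/7
  # elsewhere leaves the Kabsch cross-covariance unchanged, so the
  # superposition is exactly the identity and the per-position rmsd is
  # analytic: |v| at position 4, |v|/7 elsewhere
  set.seed(9)
  core <- matrix(stats::rnorm(96, sd = 3), 32, 3)
  rows4 <- 13:16
  core[rows4, ] <- sweep(core[rows4, ], 2, colMeans(core[rows4, ]))
  core[-rows4, ] <- sweep(core[-rows4, ], 2, colMeans(core[-rows4, ]))
  v <- c(0.4, 0, 0)
  perturbed <- core
  perturbed[rows4, ] <- sweep(perturbed[rows4, ], 2, v, `+`)
  perturbed[-rows4, ] <- sweep(perturbed[-rows4, ], 2, v / 7, `-`)
  # reference + 4 copies, 3 of them perturbed: even count of non-
  # reference peptides, median = mean of the two middle values = 0.4
  recs <- conservation_records(list(core, perturbed, perturbed, core,
                                    perturbed))
  rep <- peptide_conservation(recs, core_window = 1:8)
  expect_equal(rep$n_peptides, 5)
  expect_equal(unname(rep$medians[4]), 0.4, tolerance = 1e-6)
  expect_equal(unname(rep$medians[-4]), rep(0.4 / 7, 7), tolerance = 1e-6)
})

test_that("conservation reports 8 positions for any peptide length", {
  td <- withr::local_tempdir()
  g15 <- make_fixture("mini_groove", n_residues = 24, hla_class = 2)
  g12 <- make_fixture("mini_groove", n_residues = 24, hla_class = 2,
                      peptide_sequence = strrep("A", 12),
                      perturbation_sigma = 0.1, seed = 4)
  paths <- file.path(td, c("PA01.pdb", "PB02.pdb"))
  write_structure(g15, paths[1]); write_structure(g12, paths[2])
  md <- data.frame(pdb_id = c("PA01", "PB02"),
                   allele_name = "SYN*50:01", hla_class = 2,
                   roles = "A=class2_alpha;B=class2_beta;P=peptide")
  db <- build_db(paths, md, file.path(td, "db"))
  rep <- peptide_conservation(db)
  expect_length(rep$medians, 8)
  expect_equal(rep$n_peptides, 2)
  expect_error(peptide_conservation(db[1]), "at least 2")
})
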