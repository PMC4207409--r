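# Segment-matching construction: backbone inheritance, closure,
# side-chain placement, relaxation and candidate selection.

test_that("identical sequences inherit the template backbone exactly", {
  tmpl <- make_fixture("ideal_helix", n_residues = 12)
  tseq <- chain_sequence(tmpl, "A")
  pm <- inherit_backbone(global_align(tseq, tseq), tmpl)
  expect_length(pm$segments, 0)
  bb <- do.call(rbind, lapply(pm$residues, `[[`, "backbone"))
  ref <- tmpl$atoms[tmpl$atoms$atom %in% c("N", "CA", "C", "O"), ]
  expect_equal(max(abs(bb - as.matrix(ref[, c("x", "y", "z")]))), 0)
})

test_that("insertions and terminal overhangs become anchored segments", {
  tseq <- "ACDEFGHIKLMN"
  tmpl <- make_fixture("ideal_helix", n_residues = 12, sequence = tseq)
  # 2-residue insertion mid-helix: one segment, two anchors
  pm <- inherit_backbone(global_align("ACDEFGWWHIKLMN", tseq), tmpl)
  expect_length(pm$segments, 1)
  expect_length(pm$segments[[1]]$positions, 2)
  expect_false(is.na(pm$segments[[1]]$left))
  expect_false(is.na(pm$segments[[1]]$right))
  # N-terminal query overhang: one single-anchor terminal segment
  pm2 <- inherit_backbone(global_align("WWACDEFGHIKLMN", tseq), tmpl)
  expect_length(pm2$segments, 1)
  expect_true(is.na(pm2$segments[[1]]$left))
  expect_false(is.na(pm2$segments[[1]]$right))
})

test_that("template residues with missing backbone join segments", {
  tmpl <- make_fixture("ideal_helix", n_residues = 10)
  tmpl$atoms <- tmpl$atoms[!(tmpl$atoms$seq_id %in% 5:6 &
                               tmpl$atoms$atom %in% c("N", "CA", "C", "O")), ]
  pm <- inherit_backbone(global_align(strrep("A", 10), strrep("A", 10)), tmpl)
  expect_length(pm$segments, 1)
  expect_equal(pm$segments[[1]]$positions, 5:6)
})

test_that("closing no segments returns the input unchanged", {
  tmpl <- make_fixture("ideal_helix", n_residues = 8)
  tseq <- chain_sequence(tmpl, "A")
  pm <- inherit_backbone(global_align(tseq, tseq), tmpl)
  expect_identical(close_segments(pm), pm)
})

test_that("a 2-residue helix gap closes at least as well as a grid oracle", {
  full <- make_fixture("ideal_helix", n_residues = 10)
  tmpl <- full
  tmpl$atoms <- tmpl$atoms[!(tmpl$atoms$seq_id %in% 5:6 &
                               tmpl$atoms$atom %in% c("N", "CA", "C", "O")), ]
  pm <- inherit_backbone(global_align(strrep("A", 10), strrep("A", 10)), tmpl)
  set.seed(0)
  closed <- close_segments(pm, library = full)
  bb <- lapply(closed$residues, `[[`, "backbone")
  gap <- abs(sqrt(sum((bb[[6]]["C", ] - bb[[7]]["N", ])^2)) - 1.329)

  # independent oracle: exhaustive grid over closure torsions with its
  # own chain-growth code (30 degree steps over psi0 and both (phi,
  # psi) pairs)
  anchor <- bb[[4]]
  target_n <- bb[[7]]["N", ]
  grid <- seq(-180, 150, by = 30)
  best_oracle <- Inf
  for (psi0 in grid) for (p1 in grid) for (s1 in grid) {
    partial <- oracle_grow(anchor["N", ], anchor["CA", ], anchor["C", ],
                           psi0, rbind(c(p1, s1)))
    # prune: second residue must be able to reach the target from here
    if (sqrt(sum((partial$last_c - target_n)^2)) > 2 * 3.9) next
    for (p2 in grid) for (s2 in grid) {
      g <- oracle_grow(anchor["N", ], anchor["CA", ], anchor["C", ],
                       psi0, rbind(c(p1, s1), c(p2, s2)))
      v <- abs(sqrt(sum((g$last_c - target_n)^2)) - 1.329)
      if (v < best_oracle) best_oracle <- v
    }
  }
  expect_lt(gap, 0.5)
  expect_lte(gap, best_oracle + 1e-3)
})

test_that("impossible closures raise an informative error", {
  tmpl <- make_fixture("ideal_helix", n_residues = 10)
  tmpl$atoms[tmpl$atoms$seq_id > 5, "x"] <-
    tmpl$atoms[tmpl$atoms$seq_id > 5, "x"] + 50
  tmpl$atoms <- tmpl$atoms[!(tmpl$atoms$seq_id == 5 &
                               tmpl$atoms$atom %in% c("N", "CA", "C", "O")), ]
  pm <- inherit_backbone(global_align(strrep("A", 10), strrep("A", 10)), tmpl)
  expect_error(close_segments(pm), "unclosable segment.*A")
})

test_that("identical residues copy template side chains verbatim", {
  seq20 <- "ACDEFGHIKLMNPQRSTVWY"
  tmpl <- make_fixture("ideal_helix", n_residues = 20, sequence = seq20)
  pm <- inherit_backbone(global_align(seq20, seq20), tmpl)
  m <- assemble_model(place_side_chains(pm, template_site = tmpl))
  expect_equal(n_atoms(m), n_atoms(tmpl))
  pa <- paired_atoms(
    hla_structure(m$atoms, roles = c(A = "heavy_chain")),
    hla_structure(tmpl$atoms, roles = c(A = "heavy_chain")),
    scope = "all_domains")
  expect_equal(max(abs(pa$model_xyz - pa$crystal_xyz)), 0)
})

test_that("a substitution rebuilds only its own side chain", {
  tseq <- "AAAAAAAAAA"
  qseq <- "AAAATAAAAA"  # Ala -> Thr at position 5
  tmpl <- make_fixture("ideal_helix", n_residues = 10, sequence = tseq)
  pm <- inherit_backbone(global_align(qseq, tseq), tmpl)
  m <- assemble_model(place_side_chains(pm, template_site = tmpl))
  thr <- m$atoms[m$atoms$seq_id == 5, ]
  expect_setequal(thr$atom, c("N", "CA", "C", "O", "CB", "OG1", "CG2"))
  others <- m$atoms[m$atoms$seq_id != 5, ]
  ref <- tmpl$atoms[tmpl$atoms$seq_id != 5, ]
  expect_equal(max(abs(as.matrix(others[, c("x", "y", "z")]) -
                         as.matrix(ref[, c("x", "y", "z")]))), 0)
})

test_that("the placed rotamer beats every alternative on clash score", {
  # substitute a LEU into a helix core and enumerate all its rotamers
  tseq <- "AAAAAAAAAA"
  tmpl <- make_fixture("ideal_helix", n_residues = 10, sequence = tseq)
  pm <- inherit_backbone(global_align("AAAALAAAAA", tseq), tmpl)
  m <- place_side_chains(pm, template_site = tmpl)
  placed <- m$residues[[5]]$sidechain

  others <- make_fixture("ideal_helix", n_residues = 10,
                         sequence = tseq)$atoms
  others <- others[others$seq_id != 5, c("x", "y", "z")]
  clash <- function(sc) {
    tot <- 0
    for (i in seq_len(nrow(sc))) {
      d <- sqrt((others$x - sc[i, 1])^2 + (others$y - sc[i, 2])^2 +
                  (others$z - sc[i, 3])^2)
      tot <- tot + sum(pmax(0, 2.9 - d)^2)
    }
    tot
  }
  bb <- m$residues[[5]]$backbone
  bbl <- list(n = bb["N", ], ca = bb["CA", ], c = bb["C", ])
  grid <- hlamod:::rotamer_chi_grid("LEU")
  all_scores <- apply(grid, 1, function(chi)
    clash(hlamod:::build_side_chain("LEU", bbl, chi)))
  expect_equal(clash(placed), min(all_scores), tolerance = 1e-8)
})

test_that("relaxation honours its contracts", {
  # clash-free ideal fixture barely moves
  h <- make_fixture("ideal_helix", n_residues = 12)
  hr <- relax(h, build_config(relaxation_steps = 200))
  expect_lt(max(sqrt(rowSums((structure_coords(hr) - structure_coords(h))^2))),
            0.2)
  # a 1 A overlap between two strands is pushed beyond 1.8 A
  s1 <- make_fixture("ideal_strand", n_residues = 4)
  s2 <- s1$atoms; s2$chain <- "B"
  s2[, c("x", "y", "z")] <- s2[, c("x", "y", "z")] +
    rep(c(0, 1.0, 0), each = nrow(s2))
  both <- hla_structure(rbind(s1$atoms, s2))
  br <- relax(both, build_config(relaxation_steps = 400))
  xyz <- structure_coords(br)
  n1 <- n_atoms(s1)
  cross <- as.matrix(stats::dist(xyz))[seq_len(n1), -seq_len(n1)]
  expect_gte(min(cross), 1.8)
  # an overwhelming tether freezes the structure
  frozen <- relax(both, build_config(tether_force_constant = 1e6,
                                     relaxation_steps = 100))
  expect_lt(max(abs(structure_coords(frozen) - structure_coords(both))), 1e-3)
})

test_that("relaxed models keep near-ideal bonds and no clashes", {
  tseq <- "ACDEFGHIKLMN"
  tmpl <- make_fixture("ideal_helix", n_residues = 12, sequence = tseq)
  pm <- inherit_backbone(global_align("ACDEFGWWHIKLMN", tseq), tmpl)
  set.seed(0)
  pm <- close_segments(pm, library = tmpl)
  m <- relax(assemble_model(place_side_chains(pm, template_site = tmpl)),
             build_config(relaxation_steps = 200))
  xyz <- structure_coords(m)
  bl <- hlamod:::structure_bond_list(m)
  d <- sqrt(rowSums((xyz[bl$i, ] - xyz[bl$j, ])^2))
  expect_lt(max(abs(d - bl$d0) / bl$d0), 0.25)
  expect_equal(count_clashes(m), 0)
})

test_that("self-modeling reproduces the template and seeds are stable", {
  td <- withr::local_tempdir()
  db <- fixture_db(td)
  q <- groove_query(db[[1]])
  cfg3 <- build_config(n_candidates = 3, relaxation_steps = 120, seed = 11)
  m3 <- model_allele(q$seq, db, 1, config = cfg3, query_seq_ids = q$seq_ids)
  r <- model_rmsd(m3$best$structure, db[[1]]$structure,
                  scope = "binding_site")
  expect_lte(r$rmsd, 0.2)
  expect_equal(r$coverage, 1)
  # reported best score is the minimum over candidates
  scores <- vapply(m3$candidates, `[[`, 0, "hydration_score")
  expect_equal(m3$best$hydration_score, min(scores))
  # candidate 0 is identical whether 1 or 3 candidates are requested
  cfg1 <- build_config(n_candidates = 1, relaxation_steps = 120, seed = 11)
  m1 <- model_allele(q$seq, db, 1, config = cfg1, query_seq_ids = q$seq_ids)
  expect_identical(structure_coords(m1$candidates[[1]]$structure),
                   structure_coords(m3$candidates[[1]]$structure))
})

test_that("model construction is byte-identical for a fixed seed", {
  td <- withr::local_tempdir()
  db <- fixture_db(td)
  q <- groove_query(db[[2]])
  cfg <- build_config(n_candidates = 2, relaxation_steps = 100, seed = 5)
  m1 <- model_allele(q$seq, db, 1, config = cfg, exclude = "FX02",
                     query_seq_ids = q$seq_ids)
  m2 <- model_allele(q$seq, db, 1, config = cfg, exclude = "FX02",
                     query_seq_ids = q$seq_ids)
  expect_identical(structure_coords(m1$best$structure),
                   structure_coords(m2$best$structure))
  expect_identical(m1$best$hydration_score, m2$best$hydration_score)
  p1 <- withr::local_tempfile(fileext = ".pdb")
  p2 <- withr::local_tempfile(fileext = ".pdb")
  write_model(m1, p1); write_model(m2, p2)
  expect_identical(readLines(p1), readLines(p2))
})
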