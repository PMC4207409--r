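# Peptide registration enumeration, threading and complex scoring.

class2_complex_db <- function(td, n_residues = 30) {
  g <- make_fixture("mini_groove", n_residues = n_residues, hla_class = 2)
  p <- file.path(td, "TX01.pdb")
  write_structure(g, p)
  md <- data.frame(pdb_id = "TX01", allele_name = "SYN*51:01", hla_class = 2,
                   roles = "A=class2_alpha;B=class2_beta;P=peptide")
  build_db(p, md, file.path(td, "db"))
}

test_that("registration counts obey |T| - |Q| + 1, against brute force", {
  for (nt in 1:15) {
    for (nq in 1:nt) {
      regs <- enumerate_registrations(strrep("A", nq), strrep("G", nt))
      # brute force: count every contiguous placement by sliding a window
      brute <- 0L
      for (start in 1:nt) if (start + nq - 1 <= nt) brute <- brute + 1L
      expect_length(regs, brute)
      expect_length(regs, nt - nq + 1)
      expect_equal(vapply(regs, `[[`, 0L, "offset"), 0:(nt - nq))
      for (r in regs) {
        expect_equal(nrow(r$aligned_pairs), nq)
        expect_equal(r$aligned_pairs$template,
                     r$aligned_pairs$query + r$offset)
      }
    }
  }
  expect_error(enumerate_registrations(strrep("A", 10), strrep("A", 9)),
               "between 1 and the template length")
})

test_that("the immunodominant nonapeptide has seven registrations", {
  regs <- enumerate_registrations("KVTVAFNQF", "RKFHYLPFLPSTGGS")
  expect_length(regs, 7)
  # anchors of the native frame sit inside the query span
  expect_equal(regs[[1]]$anchor_map[["P1"]], 3)
  expect_equal(regs[[1]]$anchor_map[["P4"]], 6)
  expect_equal(regs[[1]]$anchor_map[["P6"]], 8)
  one <- enumerate_registrations("AAAA", "AAAA")
  expect_length(one, 1)
  expect_equal(one[[1]]$offset, 0)
})

test_that("self-threading reproduces the template peptide", {
  td <- withr::local_tempdir()
  db <- class2_complex_db(td)
  rec <- db[[1]]
  tpep <- chain_sequence(rec$structure, "P")
  reg <- enumerate_registrations(tpep, tpep)[[1]]
  cm <- thread_peptide(reg, rec, tpep, config = fast_config())
  ref <- hlamod:::record_peptide_chain(rec)
  sup <- kabsch_superpose(structure_coords(cm$peptide),
                          structure_coords(ref))
  expect_lte(sup$rmsd, 0.2)
})

test_that("threaded poly-Ala carries exactly the alanine atom set", {
  td <- withr::local_tempdir()
  db <- class2_complex_db(td)
  tpep <- chain_sequence(db[[1]]$structure, "P")
  reg <- enumerate_registrations(strrep("A", 9), tpep)[[2]]
  cm <- thread_peptide(reg, db[[1]], strrep("A", 9), config = fast_config())
  rt <- residue_table(cm$peptide)
  expect_equal(nrow(rt), 9)
  for (sid in rt$seq_id) {
    expect_setequal(cm$peptide$atoms$atom[cm$peptide$atoms$seq_id == sid],
                    c("N", "CA", "C", "O", "CB"))
  }
})

test_that("shifting the registration shifts the inherited CA trace", {
  td <- withr::local_tempdir()
  db <- class2_complex_db(td)
  rec <- db[[1]]
  tpep <- chain_sequence(rec$structure, "P")
  regs <- enumerate_registrations(strrep("A", 9), tpep)
  # huge tether: relaxation leaves the threaded backbone in place
  cfg <- build_config(n_candidates = 1, tether_force_constant = 1e6,
                      relaxation_steps = 50)
  cm1 <- thread_peptide(regs[[2]], rec, strrep("A", 9), config = cfg)
  ref <- hlamod:::record_peptide_chain(rec)
  tca <- as.matrix(ref$atoms[ref$atoms$atom == "CA", c("x", "y", "z")])
  mca <- as.matrix(cm1$peptide$atoms[cm1$peptide$atoms$atom == "CA",
                                     c("x", "y", "z")])
  expect_equal(unname(mca), unname(tca[2:10, ]), tolerance = 1e-3)
})

test_that("threading errors name positions lacking template backbone", {
  td <- withr::local_tempdir()
  db <- class2_complex_db(td)
  rec <- db[[1]]
  s <- rec$structure
  rtp <- residue_table(s, "P")
  drop_sid <- rtp$seq_id[4]
  s$atoms <- s$atoms[!(s$atoms$chain == "P" & s$atoms$seq_id == drop_sid &
                         s$atoms$atom %in% c("N", "CA", "C", "O")), ]
  rec$structure <- s
  tpep <- chain_sequence(s, "P")
  reg <- enumerate_registrations(strrep("A", 9), tpep)[[1]]
  expect_error(thread_peptide(reg, rec, strrep("A", 9)),
               "missing backbone atoms at aligned position")
})

test_that("the interface score is zero afar, negative seated, monotone in burial", {
  td <- withr::local_tempdir()
  db <- class2_complex_db(td)
  rec <- db[[1]]
  tpep <- chain_sequence(rec$structure, "P")
  reg <- enumerate_registrations(tpep, tpep)[[1]]
  cm <- thread_peptide(reg, rec, tpep, config = fast_config())
  seated <- score_complex(cm)
  expect_lt(seated, 0)

  far <- cm
  far$peptide <- hlamod:::set_structure_coords(
    cm$peptide, sweep(structure_coords(cm$peptide), 2, c(500, 0, 0), `+`))
  expect_lt(abs(score_complex(far)), 0.1)

  # pull the peptide halfway out of the groove: buried area (by the
  # package's own SASA routine) drops, and the score follows
  buried <- function(m) {
    gx <- structure_coords(m$groove); px <- structure_coords(m$peptide)
    rg <- hlamod:::element_radius(m$groove$atoms$element)
    rp <- hlamod:::element_radius(m$peptide$atoms$element)
    sep <- sum(sasa_atoms(gx, rg)) + sum(sasa_atoms(px, rp))
    sep - sum(sasa_atoms(rbind(gx, px), c(rg, rp)))
  }
  lifted <- cm
  lifted$peptide <- hlamod:::set_structure_coords(
    cm$peptide, sweep(structure_coords(cm$peptide), 2, c(0, 0, 6), `+`))
  expect_gt(buried(cm), buried(lifted))
  expect_lt(seated, score_complex(lifted))
})

test_that("complex modeling ranks registrations reproducibly", {
  td <- withr::local_tempdir()
  db <- class2_complex_db(td)
  qa <- chain_sequence(db[[1]]$structure, "A")
  qb <- chain_sequence(db[[1]]$structure, "B")
  cfg <- fast_config()
  res <- model_complex(c(qa, qb), "KVTVAFNQF", db, 2, config = cfg)
  expect_equal(nrow(res$table), 7)
  expect_equal(res$table$rank, 1:7)
  expect_true(!is.unsorted(res$table$score))
  res2 <- model_complex(c(qa, qb), "KVTVAFNQF", db, 2, config = cfg)
  expect_identical(res$table, res2$table)

  # a peptide identical to the template's own reproduces its placement
  tpep <- chain_sequence(db[[1]]$structure, "P")
  self <- model_complex(c(qa, qb), tpep, db, 2, config = cfg)
  expect_equal(nrow(self$table), 1)
  expect_equal(self$table$offset[1], 0)
  ref <- hlamod:::record_peptide_chain(db[[1]]$structure)
  sup <- kabsch_superpose(structure_coords(self$models[[1]]$peptide),
                          structure_coords(ref))
  expect_lte(sup$rmsd, 0.3)
})

test_that("a database without bound peptides cannot seed a complex", {
  td <- withr::local_tempdir()
  g <- make_fixture("mini_groove", n_residues = 30, hla_class = 2)
  nopep <- hlamod:::subset_structure(g, g$atoms$chain != "P")
  p <- file.path(td, "NP01.pdb")
  write_structure(nopep, p)
  md <- data.frame(pdb_id = "NP01", allele_name = "SYN*52:01", hla_class = 2,
                   roles = "A=class2_alpha;B=class2_beta")
  db <- build_db(p, md, file.path(td, "db"))
  expect_error(model_complex(c("AAAA", "AAAA"), "AAA", db, 2),
               "no peptide-bearing template")
})
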