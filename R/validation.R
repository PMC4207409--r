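# Superposition and RMSD machinery, the leave-one-out cross-validation
# harness, and the bound-peptide backbone conservation analysis.

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimising the RMSD of
#' `mobile` onto `reference`; reflections are corrected so
#' det(rotation) = +1. Apply as `mobile %*% t(rotation) + translation`
#' (rowwise).
#'
#' @param mobile,reference n x 3 coordinate matrices, n >= 3,
#'   non-collinear
#' @return a `superposition_result`: `rotation` (3x3), `translation`
#'   (length 3), `rmsd` (A), `n_atoms`
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference)) stop("coordinate sets differ in length")
  n <- nrow(mobile)
  if (n < 3) stop("superposition needs at least 3 atoms")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  X <- sweep(mobile, 2, cm); Y <- sweep(reference, 2, cr)
  if (qr(X)$rank < 2 || qr(Y)$rank < 2) stop("degenerate (collinear) geometry")
  H <- t(X) %*% Y
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  rotated <- X %*% t(R)
  rmsd <- sqrt(sum((rotated - Y)^2) / n)
  translation <- cr - as.vector(R %*% cm)
  structure(list(rotation = R, translation = translation,
                 rmsd = rmsd, n_atoms = n),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("superposition over %d atoms: rmsd %.3f A\n", x$n_atoms, x$rmsd))
  invisible(x)
}

#' @noRd
apply_superposition <- function(xyz, sup) {
  sweep(xyz %*% t(sup$rotation), 2, -sup$translation)
}

#' Match atoms between a model and a crystal structure
#'
#' Pairs non-hydrogen atoms by (chain role, author seq_id, atom name),
#' over the binding-site residues or over all residues of the
#' groove-role chains. Unmatched atoms on either side are reported so
#' coverage can be tracked.
#'
#' @param model,crystal classified `hla_structure`s sharing residue
#'   numbering
#' @param site a [binding_site_definition()] (used when
#'   `scope = "binding_site"`)
#' @param scope "binding_site" or "all_domains"
#' @return list with matrices `model_xyz`, `crystal_xyz`, data.frames
#'   `unmatched_model`, `unmatched_crystal`, and `coverage` (matched
#'   fraction of crystal atoms in scope)
#' @export
paired_atoms <- function(model, crystal, site = NULL,
                         scope = c("binding_site", "all_domains")) {
  scope <- match.arg(scope)
  roles <- c("heavy_chain", "class2_alpha", "class2_beta")
  pick <- function(s) {
    a <- s$atoms
    role <- unname(s$roles[a$chain])
    keep <- role %in% roles
    if (scope == "binding_site") {
      if (is.null(site)) {
        cls <- structure_hla_class(s)
        if (is.na(cls)) stop("cannot infer HLA class for binding-site pairing")
        site <<- binding_site_definition(cls)
      }
      ok <- rep(FALSE, nrow(a))
      for (i in seq_len(nrow(site$ranges))) {
        ok <- ok | (role == site$ranges$role[i] &
                      a$seq_id >= site$ranges$start[i] &
                      a$seq_id <= site$ranges$end[i])
      }
      keep <- keep & ok
    }
    cbind(a[keep, , drop = FALSE], role = role[keep])
  }
  am <- pick(model); ac <- pick(crystal)
  km <- paste(am$role, am$seq_id, am$ins, am$atom)
  kc <- paste(ac$role, ac$seq_id, ac$ins, ac$atom)
  shared <- intersect(km, kc)
  if (length(shared) == 0) stop("no atoms could be paired")
  im <- match(shared, km); ic <- match(shared, kc)
  list(model_xyz = as.matrix(am[im, c("x", "y", "z")]),
       crystal_xyz = as.matrix(ac[ic, c("x", "y", "z")]),
       unmatched_model = am[!(km %in% shared), c("chain", "seq_id", "atom")],
       unmatched_crystal = ac[!(kc %in% shared), c("chain", "seq_id", "atom")],
       coverage = length(shared) / nrow(ac))
}

#' RMSD between a model and a crystal after optimal superposition
#'
#' The superposition is fitted on the same atom set the RMSD is
#' reported over (binding-site fit for binding-site RMSD, all-domain
#' fit for all-domain RMSD).
#' @inheritParams paired_atoms
#' @return list with `rmsd`, `n_atoms`, `coverage`
#' @export
model_rmsd <- function(model, crystal, site = NULL,
                       scope = c("binding_site", "all_domains")) {
  scope <- match.arg(scope)
  pr <- paired_atoms(model, crystal, site = site, scope = scope)
  sup <- kabsch_superpose(pr$model_xyz, pr$crystal_xyz)
  list(rmsd = sup$rmsd, n_atoms = sup$n_atoms, coverage = pr$coverage)
}

#' Leave-one-out cross-validation over a structure database
#'
#' For every record of the class: remove it from the template pool,
#' select the most homologous remaining template, build the model of
#' its groove sequence, and measure the non-hydrogen-atom RMSD against
#' its own crystal structure — over the binding site (model built
#' binding-site-first) and over all groove-chain domains (model built
#' from the whole chains).
#'
#' @param db list of `hla_record`
#' @param hla_class 1 or 2
#' @param config a [build_config()]
#' @param site optional [binding_site_definition()]
#' @param all_domains also compute the all-domain column (default TRUE)
#' @return a `loocv_report` data.frame with one row per target
#' @export
run_loocv <- function(db, hla_class, config = build_config(), site = NULL,
                      all_domains = TRUE) {
  targets <- Filter(function(r) r$hla_class == hla_class, db)
  if (length(targets) < 2) stop("leave-one-out needs at least 2 records of class ",
                                hla_class)
  if (is.null(site)) site <- binding_site_definition(hla_class)
  rows <- lapply(targets, function(tg) {
    gs <- record_groove_sequences(tg)
    query <- vapply(gs, `[[`, "", "seq")
    sids <- lapply(gs, `[[`, "seq_ids")
    names(sids) <- names(gs)
    if (hla_class == 1) { query <- query[["heavy_chain"]]; }
    m <- model_allele(query, db, hla_class, config = config,
                      exclude = tg$pdb_id, site = site,
                      query_seq_ids = if (hla_class == 1) sids[["heavy_chain"]] else sids)
    bs <- model_rmsd(m$best$structure, tg$structure, site = site,
                     scope = "binding_site")
    ad <- if (all_domains) {
      ma <- model_allele(query, db, hla_class, config = config,
                         exclude = tg$pdb_id, scope = "all", site = site,
                         query_seq_ids = if (hla_class == 1) sids[["heavy_chain"]] else sids)
      model_rmsd(ma$best$structure, tg$structure, scope = "all_domains")
    } else list(rmsd = NA_real_, coverage = NA_real_)
    data.frame(target = tg$pdb_id, template = m$template_pdb_id,
               identity = m$identity, binding_site_rmsd = bs$rmsd,
               all_domain_rmsd = ad$rmsd, coverage = bs$coverage,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(out$target == out$template)) stop("leave-one-out exclusion violated")
  class(out) <- c("loocv_report", class(out))
  out
}

#' @export
print.loocv_report <- function(x, ...) {
  cat("leave-one-out cross-validation over", nrow(x), "targets\n")
  print.data.frame(x, digits = 3, row.names = FALSE)
  cat(sprintf("median binding-site rmsd: %.3f A\n",
              stats::median(x$binding_site_rmsd)))
  invisible(x)
}

#' @noRd
peptide_core_mainchain <- function(record, core_window) {
  s <- record$structure
  ch <- chains_with_role(s, "peptide")
  if (length(ch) == 0) return(NULL)
  rt <- residue_table(s, ch[1])
  pos <- core_window
  if (max(pos) > nrow(rt)) return(NULL)
  a <- s$atoms[s$atoms$chain == ch[1], , drop = FALSE]
  rk <- paste(rt$seq_id, rt$ins)[pos]
  out <- matrix(NA_real_, length(pos) * 4, 3)
  k <- 0
  for (p in seq_along(pos)) {
    rows <- a[paste(a$seq_id, a$ins) == rk[p], , drop = FALSE]
    for (nm in c("N", "CA", "C", "O")) {
      k <- k + 1
      hit <- which(rows$atom == nm)
      if (length(hit)) out[k, ] <- c(rows$x[hit[1]], rows$y[hit[1]], rows$z[hit[1]])
    }
  }
  if (any(!is.finite(out))) return(NULL)
  out
}

#' Conservation of the bound-peptide backbone core
#'
#' Superimposes the main-chain atoms (N, CA, C, O) of the conserved
#' 8-residue core of every bound peptide onto the first peptide (by
#' pdb_id order) and reports the per-position median RMSD across
#' peptides — the statistic summarising how strongly class II peptides
#' share one extended backbone conformation in the groove.
#'
#' @param db list of `hla_record` (peptide-bearing entries are used)
#' @param hla_class restrict to this class (default 2)
#' @param core_window 8 consecutive peptide residue indices (1-based
#'   along the peptide chain); default 2:9, spanning the P1, P4 and P6
#'   anchor positions with one flanking residue
#' @return a `conservation_report`: `medians` (length 8), `n_peptides`,
#'   `per_peptide` matrix
#' @export
peptide_conservation <- function(db, hla_class = 2, core_window = 2:9) {
  if (length(core_window) != 8) stop("the conserved core spans 8 residues")
  recs <- Filter(function(r) r$hla_class == hla_class &&
                   length(chains_with_role(r$structure, "peptide")) > 0, db)
  recs <- recs[order(vapply(recs, `[[`, "", "pdb_id"))]
  cores <- lapply(recs, peptide_core_mainchain, core_window = core_window)
  keep <- !vapply(cores, is.null, TRUE)
  cores <- cores[keep]; recs <- recs[keep]
  if (length(cores) < 2) stop("need at least 2 peptides with complete core main chains")
  ref <- cores[[1]]
  per_pos <- matrix(NA_real_, length(cores) - 1, 8)
  rownames(per_pos) <- vapply(recs[-1], `[[`, "", "pdb_id")
  for (i in seq_along(cores)[-1]) {
    sup <- kabsch_superpose(cores[[i]], ref)
    moved <- apply_superposition(cores[[i]], sup)
    for (p in 1:8) {
      rows <- ((p - 1) * 4 + 1):(p * 4)
      per_pos[i - 1, p] <- sqrt(mean(rowSums((moved[rows, ] - ref[rows, ])^2)))
    }
  }
  medians <- apply(per_pos, 2, stats::median)
  structure(list(medians = medians, n_peptides = length(cores),
                 per_peptide = per_pos, core_window = core_window),
            class = "conservation_report")
}

#' @export
print.conservation_report <- function(x, ...) {
  cat(sprintf("peptide-core conservation over %d peptides (core positions %s)\n",
              x$n_peptides, paste(range(x$core_window), collapse = "-")))
  cat("per-position median rmsd (A):",
      paste(sprintf("%.2f", x$medians), collapse = " "), "\n")
  invisible(x)
}
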