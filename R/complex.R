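# HLA-peptide complex construction: slide the query peptide along the
# conserved template peptide backbone, thread each registration, relax,
# score, and rank.

#' Enumerate gapless registrations of a peptide against a template peptide
#'
#' The bound-peptide backbone is conserved, so a query peptide is
#' threaded by sliding it along the template peptide: each registration
#' is one offset, with |template| - |query| + 1 registrations in total.
#'
#' @param query_peptide,template_peptide single-letter sequences,
#'   1 <= |query| <= |template|
#' @param core_start template-peptide index where the conserved
#'   8-residue core begins (default 2); the P1, P4 and P6 anchors sit
#'   at core_start + 1, + 4 and + 6
#' @return list of `peptide_registration` (offset, aligned pairs,
#'   anchor map, core positions; score NA until the complex is scored)
#' @export
enumerate_registrations <- function(query_peptide, template_peptide,
                                    core_start = 2) {
  query_peptide <- validate_sequence(query_peptide, "query peptide")
  template_peptide <- validate_sequence(template_peptide, "template peptide")
  nq <- nchar(query_peptide); nt <- nchar(template_peptide)
  if (nq < 1 || nq > nt) {
    stop("query peptide (", nq, ") must be between 1 and the template length (",
         nt, ")")
  }
  core_positions <- core_start:(core_start + 7)
  anchors_t <- c(P1 = core_start + 1, P4 = core_start + 4, P6 = core_start + 6)
  lapply(0:(nt - nq), function(off) {
    anchor_map <- anchors_t - off
    anchor_map <- anchor_map[anchor_map >= 1 & anchor_map <= nq]
    structure(list(
      offset = off,
      aligned_pairs = data.frame(query = seq_len(nq),
                                 template = seq_len(nq) + off),
      anchor_map = anchor_map,
      core_positions = core_positions,
      score = NA_real_), class = "peptide_registration")
  })
}

#' @export
print.peptide_registration <- function(x, ...) {
  cat(sprintf("registration offset %d (%d aligned residues)%s\n",
              x$offset, nrow(x$aligned_pairs),
              if (is.na(x$score)) "" else sprintf(", score %.3f", x$score)))
  invisible(x)
}

#' @noRd
record_peptide_chain <- function(x) {
  s <- if (inherits(x, "hla_record")) x$structure else x
  ch <- chains_with_role(s, "peptide")
  if (length(ch) == 0) stop("no peptide chain in the template structure")
  subset_structure(s, s$atoms$chain == ch[1])
}

#' Thread a query peptide onto the template peptide backbone
#'
#' The query peptide inherits the template peptide's main-chain
#' coordinates at the registration's aligned positions; side chains are
#' copied where the residue is unchanged and otherwise placed by the
#' rotamer procedure against the groove; finally the complex is relaxed
#' under tethers (jointly, or with the groove held fixed).
#'
#' @param registration a `peptide_registration`
#' @param template_complex an `hla_record` (or classified structure)
#'   with a bound peptide
#' @param query_peptide single-letter peptide sequence
#' @param groove optional groove `hla_structure` (default: the template
#'   complex without its peptide/tcr/other chains)
#' @param config a [build_config()]
#' @param relax_mode "joint" (default) or "peptide_only"
#' @return a `complex_model` (groove, peptide, registration, score NA)
#' @export
thread_peptide <- function(registration, template_complex, query_peptide,
                           groove = NULL, config = build_config(),
                           relax_mode = c("joint", "peptide_only")) {
  relax_mode <- match.arg(relax_mode)
  query_peptide <- validate_sequence(query_peptide, "query peptide")
  pep <- record_peptide_chain(template_complex)
  tseq <- chain_sequence(pep, chain_ids(pep)[1])
  nq <- nchar(query_peptide); nt <- nchar(tseq)
  off <- registration$offset
  if (off + nq > nt) stop("registration offset ", off, " overruns the template peptide")
  if (is.null(groove)) {
    s <- if (inherits(template_complex, "hla_record")) template_complex$structure
         else template_complex
    keep_roles <- c("heavy_chain", "beta2m", "class2_alpha", "class2_beta")
    ch <- chains_with_role(s, keep_roles)
    groove <- subset_structure(s, s$atoms$chain %in% ch)
  }
  aligned_query <- paste0(strrep("-", off), query_peptide,
                          strrep("-", nt - nq - off))
  aln <- structure(list(
    aligned_query = aligned_query, aligned_template = tseq, score = NA_real_,
    identity = NA_real_,
    matched_positions = registration$aligned_pairs),
    class = "alignment_result")
  partial <- inherit_backbone(aln, pep, chain = "P")
  if (length(partial$segments)) {
    bad <- unlist(lapply(partial$segments, `[[`, "positions"))
    stop("template peptide missing backbone atoms at aligned position(s): ",
         paste(bad + off, collapse = ", "))
  }
  partial <- place_side_chains(partial, template_site = pep, context = groove)
  pep_model <- assemble_model(partial, role = "peptide")
  full <- merge_structures(groove, pep_model)
  mobile <- if (relax_mode == "joint") NULL else full$atoms$chain == "P"
  full <- relax(full, config, mobile = mobile)
  is_pep <- full$atoms$chain == "P"
  structure(list(groove = subset_structure(full, !is_pep),
                 peptide = subset_structure(full, is_pep),
                 registration = registration, score = NA_real_),
            class = "complex_model")
}

#' @export
print.complex_model <- function(x, ...) {
  cat(sprintf("complex_model: offset %d, %d peptide residues%s\n",
              x$registration$offset, nrow(residue_table(x$peptide)),
              if (is.na(x$score)) "" else sprintf(", score %.3f", x$score)))
  invisible(x)
}

#' Interface score of an HLA-peptide complex
#'
#' Buried-surface interface score: hydration score of the complex minus
#' the scores of the separated groove and peptide, plus a weighted
#' groove-peptide contact term. Partners that do not touch score 0;
#' burying apolar surface drives the score negative, so lower is
#' better. Only the arg-min over registrations is meaningful — the
#' values are not binding free energies.
#'
#' @param model a `complex_model`
#' @param w_contact weight per groove-peptide atom pair within 4 A
#' @param n_points SASA sample points per atom
#' @return scalar score (the model's `$score` is not modified)
#' @export
score_complex <- function(model, w_contact = 0.02, n_points = 960) {
  full <- merge_structures(model$groove, model$peptide)
  s_complex <- hydration_score(full, n_points = n_points)
  s_groove <- hydration_score(model$groove, n_points = n_points)
  s_pep <- hydration_score(model$peptide, n_points = n_points)
  gx <- structure_coords(model$groove)
  px <- structure_coords(model$peptide)
  contacts <- 0L
  for (i in seq_len(nrow(px))) {
    d2 <- (gx[, 1] - px[i, 1])^2 + (gx[, 2] - px[i, 2])^2 + (gx[, 3] - px[i, 3])^2
    contacts <- contacts + sum(d2 < 16)
  }
  (s_complex - s_groove - s_pep) - w_contact * contacts
}

#' Model an HLA-peptide complex over all registrations
#'
#' Builds the groove homology model from the most homologous
#' peptide-bearing template, threads the query peptide at every
#' registration along the template peptide, relaxes and scores each
#' complex, and returns them ranked by score (ascending); rank 1 is the
#' predicted binding mode.
#'
#' @param hla_query groove sequence(s) as in [build_model()]
#' @param peptide_query single-letter peptide sequence
#' @param db list of `hla_record`
#' @param hla_class 1 or 2
#' @param config a [build_config()]
#' @param exclude pdb_ids excluded from the template pool
#' @param template_pdb_id optional explicit template
#' @param relax_mode "joint" or "peptide_only"
#' @param core_start conserved-core start along the template peptide
#' @return an `hla_complex_set`: ranked `$models`, a `$table` of
#'   (offset, score, anchors), the groove `$model`
#' @export
model_complex <- function(hla_query, peptide_query, db, hla_class,
                          config = build_config(), exclude = character(),
                          template_pdb_id = NULL,
                          relax_mode = c("joint", "peptide_only"),
                          core_start = 2) {
  relax_mode <- match.arg(relax_mode)
  pool <- Filter(function(r) length(chains_with_role(r$structure, "peptide")) > 0,
                 db)
  if (length(pool) == 0) stop("no peptide-bearing template in the database")
  groove_model <- model_allele(hla_query, pool, hla_class, config = config,
                               exclude = exclude,
                               template_pdb_id = template_pdb_id)
  record <- Filter(function(r) r$pdb_id == groove_model$template_pdb_id, pool)[[1]]
  pep <- record_peptide_chain(record)
  tseq <- chain_sequence(pep, chain_ids(pep)[1])
  regs <- enumerate_registrations(peptide_query, tseq, core_start = core_start)
  models <- lapply(regs, function(reg) {
    cm <- thread_peptide(reg, record, peptide_query,
                         groove = groove_model$best$structure,
                         config = config, relax_mode = relax_mode)
    cm$score <- score_complex(cm)
    cm$registration$score <- cm$score
    cm
  })
  scores <- vapply(models, `[[`, numeric(1), "score")
  offs <- vapply(models, function(m) m$registration$offset, numeric(1))
  ord <- order(scores, offs)
  models <- models[ord]
  tab <- data.frame(
    rank = seq_along(models),
    offset = offs[ord],
    score = scores[ord],
    anchors = vapply(models, function(m) {
      am <- m$registration$anchor_map
      paste(sprintf("%s=%d", names(am), am), collapse = ",")
    }, character(1)), stringsAsFactors = FALSE)
  structure(list(models = models, table = tab, groove_model = groove_model,
                 template_pdb_id = record$pdb_id,
                 template_peptide = tseq, peptide_query = peptide_query),
            class = "hla_complex_set")
}

#' @export
print.hla_complex_set <- function(x, ...) {
  cat(sprintf("hla_complex_set: %d registration(s) of %s on template %s (%s)\n",
              nrow(x$table), x$peptide_query, x$template_pdb_id,
              x$template_peptide))
  print.data.frame(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}
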