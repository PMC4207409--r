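# Top-level homology-model construction: run the segment-matching
# stages per groove chain, generate multiple candidates under distinct
# seeds, relax each, and keep the one with the lowest hydration score.

MODEL_CHAIN_IDS <- c(heavy_chain = "A", class2_alpha = "A", class2_beta = "B")

#' @noRd
trim_terminal_segments <- function(partial) {
  term <- Filter(function(seg) is.na(seg$left) || is.na(seg$right), partial$segments)
  drop <- unlist(lapply(term, `[[`, "positions"))
  if (length(drop)) {
    partial$residues <- partial$residues[-drop]
    # re-derive segments over the retained residues
    resolved <- vapply(partial$residues, `[[`, TRUE, "inherited")
    segments <- list()
    runs <- rle(resolved)
    e <- cumsum(runs$lengths); s0 <- e - runs$lengths + 1
    for (k in seq_along(runs$values)) {
      if (!runs$values[k]) {
        left <- if (s0[k] > 1) s0[k] - 1L else NA_integer_
        right <- if (e[k] < length(resolved)) e[k] + 1L else NA_integer_
        segments <- c(segments, list(list(positions = s0[k]:e[k],
                                          left = left, right = right)))
      }
    }
    partial$segments <- segments
  }
  partial
}

#' @noRd
template_site_chain <- function(record, role, scope, site) {
  s <- record$structure
  ch <- chains_with_role(s, role)
  if (length(ch) == 0) stop("template lacks a chain with role ", role)
  full <- subset_structure(s, s$atoms$chain == ch[1])
  if (scope == "all") return(full)
  keep <- full$atoms$seq_id %in% binding_site_seq_ids(site, role)
  if (!any(keep)) stop("template binding-site selection is empty for role ", role)
  subset_structure(full, keep)
}

#' Build a homology model of the query binding site
#'
#' Runs the full construction for `n_candidates` intermediate models:
#' template backbone inheritance, torsion-space closure of unresolved
#' segments, side-chain copy/rotamer placement, and tethered
#' relaxation. Candidate 0 is built without perturbation; later
#' candidates perturb closure torsions and rotamer chi angles under
#' per-candidate seeds derived from `config$seed`, so a fixed seed
#' reproduces every coordinate exactly. The candidate with the lowest
#' hydration score is reported as the model.
#'
#' @param query groove-chain sequence(s): a single string (class 1) or
#'   a length-2 alpha/beta vector (class 2)
#' @param template a `template_match` from [select_template()]
#' @param config a [build_config()]
#' @param scope "binding_site" (model the groove only, the default) or
#'   "all" (model the whole groove chain(s))
#' @param site optional [binding_site_definition()]
#' @param query_seq_ids optional author numbering for query residues:
#'   vector (class 1) or list per role (class 2)
#' @return an `hla_model`: `$best` candidate, all `$candidates`, the
#'   template identity and alignment, and the configuration
#' @export
build_model <- function(query, template, config = build_config(),
                        scope = c("binding_site", "all"), site = NULL,
                        query_seq_ids = NULL) {
  scope <- match.arg(scope)
  record <- template$record
  hla_class <- record$hla_class
  if (is.null(site)) site <- binding_site_definition(hla_class)
  qs <- as_query_list(query, hla_class)
  roles <- names(qs)
  tsites <- lapply(roles, function(role) template_site_chain(record, role, scope, site))
  names(tsites) <- roles
  alns <- lapply(roles, function(role) {
    tseq <- chain_sequence(tsites[[role]], chain_ids(tsites[[role]])[1])
    global_align(qs[[role]], tseq)
  })
  names(alns) <- roles

  candidates <- vector("list", config$n_candidates)
  for (idx in seq_len(config$n_candidates) - 1L) {
    set.seed(config$seed + idx)
    jitter <- if (idx == 0L) 0 else 8
    parts <- lapply(roles, function(role) {
      sid <- if (is.null(query_seq_ids)) NULL
             else if (is.list(query_seq_ids)) query_seq_ids[[role]]
             else query_seq_ids
      partial <- inherit_backbone(alns[[role]], tsites[[role]],
                                  chain = MODEL_CHAIN_IDS[[role]],
                                  query_seq_ids = sid)
      if (scope == "binding_site") partial <- trim_terminal_segments(partial)
      partial <- close_segments(partial, library = tsites, config = config,
                                jitter = jitter)
      partial <- place_side_chains(partial, template_site = tsites[[role]],
                                   jitter = jitter / 2)
      assemble_model(partial, role = role)
    })
    m <- Reduce(merge_structures, parts)
    m <- relax(m, config)
    candidates[[idx + 1L]] <- list(
      structure = m, hydration_score = hydration_score(m),
      candidate_index = idx, seed = config$seed + idx)
  }
  scores <- vapply(candidates, `[[`, numeric(1), "hydration_score")
  best <- which.min(scores)
  structure(list(
    best = candidates[[best]], candidates = candidates,
    template_pdb_id = record$pdb_id, template_allele = record$allele_name,
    identity = template$identity, alignments = alns, config = config,
    scope = scope, hla_class = hla_class), class = "hla_model")
}

#' @export
print.hla_model <- function(x, ...) {
  cat(sprintf("hla_model (class %d, %s): template %s (%s), identity %.1f%%\n",
              x$hla_class, x$scope, x$template_pdb_id, x$template_allele,
              x$identity))
  cat(sprintf("  %d candidate(s); best index %d, hydration score %.2f\n",
              length(x$candidates), x$best$candidate_index,
              x$best$hydration_score))
  invisible(x)
}

#' Model a query allele against a database
#'
#' Convenience wrapper: select the most homologous template (optionally
#' excluding entries, as the leave-one-out protocol does) and build the
#' model from it.
#'
#' @inheritParams build_model
#' @param db list of `hla_record`
#' @param hla_class 1 or 2
#' @param exclude pdb_ids removed from the template pool
#' @param template_pdb_id optional explicit template override
#' @param mode identity mode passed to [select_template()]
#' @return an `hla_model`
#' @export
model_allele <- function(query, db, hla_class, config = build_config(),
                         exclude = character(), template_pdb_id = NULL,
                         scope = c("binding_site", "all"), site = NULL,
                         query_seq_ids = NULL, mode = "binding_site") {
  scope <- match.arg(scope)
  matches <- select_template(query, db, hla_class, exclude = exclude,
                             mode = mode, site = site)
  if (!is.null(template_pdb_id)) {
    hit <- Filter(function(m) m$record$pdb_id == toupper(template_pdb_id), matches)
    if (length(hit) == 0) stop("requested template ", template_pdb_id,
                               " is not an eligible database entry")
    matches <- hit
  }
  build_model(query, matches[[1]], config = config, scope = scope,
              site = site, query_seq_ids = query_seq_ids)
}

#' Write a model to a PDB file with a provenance header
#'
#' @param model an `hla_model`
#' @param path output PDB path
#' @return `path`, invisibly
#' @export
write_model <- function(model, path) {
  remarks <- c(
    sprintf("hlamod %s", as.character(utils::packageVersion("hlamod"))),
    sprintf("TEMPLATE %s (%s)  IDENTITY %.1f%%", model$template_pdb_id,
            model$template_allele, model$identity),
    sprintf("SEED %d  CANDIDATE %d  HYDRATION SCORE %.3f",
            model$best$seed, model$best$candidate_index,
            model$best$hydration_score))
  write_structure(model$best$structure, path, remarks = remarks)
}
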