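# Pairwise global alignment, sequence identity and template selection.

#' @noRd
validate_sequence <- function(seq, what = "sequence") {
  chars <- strsplit(toupper(seq), "")[[1]]
  bad <- which(!chars %in% c(names(AA3_FROM_1), "X"))
  if (length(bad)) {
    stop("illegal character '", chars[bad[1]], "' at position ", bad[1],
         " of ", what)
  }
  paste(chars, collapse = "")
}

#' @noRd
blosum62_x0 <- function() {
  mat <- get_blosum62()
  mat["X", ] <- 0L
  mat[, "X"] <- 0L
  mat
}

# cache: loading the matrix via data() each call is wasteful
.align_env <- new.env(parent = emptyenv())
get_blosum62 <- function() {
  if (is.null(.align_env$B62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .align_env$B62 <- e$BLOSUM62
  }
  .align_env$B62
}

#' Optimal global alignment of two protein sequences
#'
#' Needleman-Wunsch global alignment under BLOSUM62 with affine gap
#' penalties (Biostrings backend). 'X' is tolerated and scored 0
#' against everything. The traceback is canonicalised so the result is
#' symmetric: `global_align(a, b)` and `global_align(b, a)` report the
#' same score, identity and matched columns.
#'
#' @param query,template protein sequences (single strings)
#' @param gap_open,gap_extend affine gap penalties (positive costs)
#' @return an `alignment_result`: gapped strings, score, percent
#'   `identity` (identical columns / columns where neither side is a
#'   gap), and `matched_positions` (1-based query/template index pairs
#'   for every gap-free column)
#' @export
global_align <- function(query, template, gap_open = 10, gap_extend = 1) {
  if (!nzchar(query) || !nzchar(template)) stop("empty sequence")
  query <- validate_sequence(query, "query")
  template <- validate_sequence(template, "template")
  swapped <- query > template  # canonical order => symmetric traceback
  p <- if (swapped) template else query
  s <- if (swapped) query else template
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(p), Biostrings::AAString(s),
    substitutionMatrix = blosum62_x0(), type = "global",
    gapOpening = gap_open, gapExtension = gap_extend)
  gq <- as.character(Biostrings::alignedPattern(aln))
  gt <- as.character(Biostrings::alignedSubject(aln))
  if (swapped) { tmp <- gq; gq <- gt; gt <- tmp }
  qc <- strsplit(gq, "")[[1]]
  tc <- strsplit(gt, "")[[1]]
  both <- qc != "-" & tc != "-"
  qpos <- cumsum(qc != "-")
  tpos <- cumsum(tc != "-")
  res <- list(
    aligned_query = gq, aligned_template = gt,
    score = as.numeric(Biostrings::score(aln)),
    identity = 100 * sum(qc[both] == tc[both]) / max(1L, sum(both)),
    matched_positions = data.frame(query = qpos[both], template = tpos[both]))
  class(res) <- "alignment_result"
  res
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("alignment: score %.1f, identity %.1f%% over %d columns\n",
              x$score, x$identity, nrow(x$matched_positions)))
  invisible(x)
}

#' @noRd
identity_over_columns <- function(aln, keep_template_pos) {
  qc <- strsplit(aln$aligned_query, "")[[1]]
  tc <- strsplit(aln$aligned_template, "")[[1]]
  both <- qc != "-" & tc != "-"
  sel <- both & cumsum(tc != "-") %in% keep_template_pos
  if (!any(sel)) return(c(ident = NA_real_, n = 0))
  c(ident = 100 * sum(qc[sel] == tc[sel]) / sum(sel), n = sum(sel))
}

#' @noRd
groove_roles <- function(hla_class) {
  if (hla_class == 1) "heavy_chain" else c("class2_alpha", "class2_beta")
}

#' @noRd
record_groove_sequences <- function(record, defn = NULL) {
  roles <- groove_roles(record$hla_class)
  out <- list()
  for (role in roles) {
    ch <- chains_with_role(record$structure, role)
    if (length(ch) == 0) next
    rt <- residue_table(record$structure, ch[1])
    out[[role]] <- list(chain = ch[1],
                        seq = paste(aa_three_to_one(rt$res_name), collapse = ""),
                        seq_ids = rt$seq_id)
  }
  out
}

#' @noRd
as_query_list <- function(query, hla_class) {
  roles <- groove_roles(hla_class)
  if (length(roles) == 1) {
    stopifnot(is.character(query), length(query) == 1)
    return(setNames(list(query), roles))
  }
  if (length(query) != 2) {
    stop("class II queries need two sequences (alpha and beta chains)")
  }
  if (is.null(names(query))) names(query) <- roles
  as.list(query[roles])
}

#' Rank database templates by sequence homology to a query
#'
#' Aligns the query against the groove chain(s) of every eligible
#' record and ranks by percent identity, computed (by default) over the
#' binding-site residues only — the structurally conserved part of the
#' molecule that the modeling strategy is built around. Ties are broken
#' by better (smaller) resolution, then more recent deposition date,
#' then pdb_id. Records named in `exclude` are skipped, which is how
#' the leave-one-out protocol removes the identical structure.
#'
#' @param query heavy-chain sequence (class 1) or length-2 vector of
#'   alpha/beta sequences (class 2)
#' @param db list of `hla_record`
#' @param hla_class 1 or 2
#' @param exclude character vector of pdb_ids to skip
#' @param mode "binding_site" (default) or "whole_chain" identity
#' @param site optional [binding_site_definition()]
#' @return list of `template_match` (record, alignments, identity,
#'   rank), best first
#' @export
select_template <- function(query, db, hla_class, exclude = character(),
                            mode = c("binding_site", "whole_chain"),
                            site = NULL) {
  mode <- match.arg(mode)
  if (is.null(site)) site <- binding_site_definition(hla_class)
  qs <- as_query_list(query, hla_class)
  eligible <- Filter(function(r) r$hla_class == hla_class &&
                       !(r$pdb_id %in% toupper(exclude)), db)
  if (length(eligible) == 0) {
    stop("no eligible class ", hla_class, " template in the database")
  }
  matches <- lapply(eligible, function(rec) {
    gs <- record_groove_sequences(rec)
    alns <- list(); ident_num <- 0; ident_den <- 0
    for (role in names(qs)) {
      if (is.null(gs[[role]])) return(NULL)
      aln <- global_align(qs[[role]], gs[[role]]$seq)
      if (mode == "binding_site") {
        keep <- which(gs[[role]]$seq_ids %in% binding_site_seq_ids(site, role))
      } else {
        keep <- seq_along(gs[[role]]$seq_ids)
      }
      st <- identity_over_columns(aln, keep)
      ident_num <- ident_num + st[["ident"]] * st[["n"]] / 100
      ident_den <- ident_den + st[["n"]]
      alns[[role]] <- aln
    }
    structure(list(record = rec, alignments = alns,
                   identity = 100 * ident_num / max(1, ident_den),
                   rank = NA_integer_), class = "template_match")
  })
  matches <- Filter(Negate(is.null), matches)
  if (length(matches) == 0) stop("no eligible template with groove chains")
  res <- vapply(matches, function(m) {
    r <- m$record$resolution
    if (is.na(r)) Inf else r
  }, numeric(1))
  dep <- vapply(matches, function(m) {
    d <- m$record$deposition_date
    if (is.na(d)) "0000-00-00" else d
  }, character(1))
  ids <- vapply(matches, function(m) m$record$pdb_id, character(1))
  idents <- vapply(matches, function(m) m$identity, numeric(1))
  ord <- order(-idents, res, -xtfrm(dep), ids)
  matches <- matches[ord]
  for (i in seq_along(matches)) matches[[i]]$rank <- i
  matches
}

#' @export
print.template_match <- function(x, ...) {
  cat(sprintf("template_match rank %d: %s (%s), identity %.1f%%\n",
              x$rank, x$record$pdb_id, x$record$allele_name, x$identity))
  invisible(x)
}

#' Differing binding-site residues between two database entries
#'
#' Aligns the binding-site sequences of two records role by role and
#' reports every aligned (gap-free) column where the one-letter codes
#' differ.
#'
#' @param a,b `hla_record`s of the same class
#' @param site optional [binding_site_definition()]
#' @return data.frame with columns `role`, `seq_id_a`, `seq_id_b`,
#'   `res_a`, `res_b` (3-letter codes)
#' @export
binding_site_differences <- function(a, b, site = NULL) {
  if (a$hla_class != b$hla_class) stop("records are of different HLA classes")
  if (is.null(site)) site <- binding_site_definition(a$hla_class)
  out <- list()
  for (role in groove_roles(a$hla_class)) {
    bs_ids <- binding_site_seq_ids(site, role)
    ga <- record_groove_sequences(a)[[role]]
    gb <- record_groove_sequences(b)[[role]]
    if (is.null(ga) || is.null(gb)) next
    ka <- ga$seq_ids %in% bs_ids
    kb <- gb$seq_ids %in% bs_ids
    sa <- paste(strsplit(ga$seq, "")[[1]][ka], collapse = "")
    sb <- paste(strsplit(gb$seq, "")[[1]][kb], collapse = "")
    aln <- global_align(sa, sb)
    mp <- aln$matched_positions
    ca <- strsplit(sa, "")[[1]][mp$query]
    cb <- strsplit(sb, "")[[1]][mp$template]
    diff <- which(ca != cb)
    if (length(diff)) {
      out[[role]] <- data.frame(
        role = role,
        seq_id_a = ga$seq_ids[ka][mp$query[diff]],
        seq_id_b = gb$seq_ids[kb][mp$template[diff]],
        res_a = aa_one_to_three(ca[diff]),
        res_b = aa_one_to_three(cb[diff]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(role = character(), seq_id_a = integer(),
                      seq_id_b = integer(), res_a = character(),
                      res_b = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Read the first sequence from a FASTA file
#' @param path FASTA file
#' @return named character vector of sequences (one element per entry)
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) stop("no FASTA header in ", path)
  starts <- hdr + 1
  ends <- c(hdr[-1] - 1, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    paste(gsub("[^A-Za-z]", "", lines[starts[i]:ends[i]]), collapse = "")
  }, character(1))
  names(seqs) <- sub("^>\\s*", "", sub("\\s.*$", "", lines[hdr]))
  toupper(seqs)
}
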