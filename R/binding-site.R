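# The antigenic peptide-binding site: domain-range definitions and
# extraction.

#' Define the peptide-binding site of an HLA class
#'
#' The groove is formed by the alpha-1 + alpha-2 domains of the class I
#' heavy chain, or the alpha-1 domain of the class II alpha chain plus
#' the beta-1 domain of the beta chain. Defaults follow the canonical
#' domain boundaries in author numbering (class I heavy chain 1-180;
#' class II alpha 1-84 and beta 1-90), and are fully configurable.
#'
#' @param hla_class 1 or 2
#' @param ranges data.frame with columns `role`, `start`, `end`
#'   (inclusive, author numbering); NULL for the class default
#' @return object of class `binding_site_definition`
#' @export
binding_site_definition <- function(hla_class, ranges = NULL) {
  stopifnot(hla_class %in% c(1, 2))
  if (is.null(ranges)) {
    ranges <- if (hla_class == 1) {
      data.frame(role = "heavy_chain", start = 1L, end = 180L,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(role = c("class2_alpha", "class2_beta"),
                 start = c(1L, 1L), end = c(84L, 90L),
                 stringsAsFactors = FALSE)
    }
  }
  stopifnot(all(c("role", "start", "end") %in% names(ranges)))
  for (r in unique(ranges$role)) {
    rr <- ranges[ranges$role == r, , drop = FALSE]
    if (nrow(rr) > 1) {
      rr <- rr[order(rr$start), ]
      if (any(rr$start[-1] <= rr$end[-nrow(rr)])) {
        stop("overlapping binding-site ranges for role ", r)
      }
    }
  }
  structure(list(hla_class = as.integer(hla_class), ranges = ranges),
            class = "binding_site_definition")
}

#' Extract the peptide-binding site from a structure
#'
#' Keeps only residues whose author seq_id falls in the defined ranges
#' of chains carrying the matching roles; atom order is preserved, so
#' repeated extraction is idempotent.
#'
#' @param x an `hla_record` or a classified `hla_structure`
#' @param defn a [binding_site_definition()]; default = class default
#' @return an `hla_structure` containing only binding-site atoms
#' @export
extract_binding_site <- function(x, defn = NULL) {
  s <- if (inherits(x, "hla_record")) x$structure else x
  cls <- if (inherits(x, "hla_record")) x$hla_class else structure_hla_class(s)
  if (is.null(defn)) defn <- binding_site_definition(cls)
  if (!is.na(cls) && cls != defn$hla_class) {
    stop("structure is HLA class ", cls, " but binding-site definition is class ",
         defn$hla_class)
  }
  keep <- rep(FALSE, n_atoms(s))
  for (i in seq_len(nrow(defn$ranges))) {
    role <- defn$ranges$role[i]
    ch <- chains_with_role(s, role)
    keep <- keep | (s$atoms$chain %in% ch &
                      s$atoms$seq_id >= defn$ranges$start[i] &
                      s$atoms$seq_id <= defn$ranges$end[i])
  }
  if (!any(keep)) stop("binding-site selection is empty")
  subset_structure(s, keep)
}

#' @noRd
binding_site_seq_ids <- function(defn, role) {
  rr <- defn$ranges[defn$ranges$role == role, , drop = FALSE]
  if (nrow(rr) == 0) return(integer(0))
  unlist(lapply(seq_len(nrow(rr)), function(i) rr$start[i]:rr$end[i]))
}
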