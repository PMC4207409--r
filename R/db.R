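# Local HLA structure database: one record per crystal structure,
# persisted as a TSV metadata index plus per-entry PDB coordinate files
# so the database stays inspectable with standard tools.

DB_INDEX_COLUMNS <- c("pdb_id", "allele_name", "complex_composition",
                      "hla_class", "header", "deposition_date",
                      "modification_date", "experiment_type", "resolution",
                      "free_r", "mean_b", "other_components", "roles", "file")

#' @noRd
new_hla_record <- function(pdb_id, allele_name, structure, hla_class,
                           header = "", deposition_date = NA_character_,
                           modification_date = NA_character_,
                           experiment_type = NA_character_,
                           resolution = NA_real_, free_r = NA_real_,
                           mean_b = NA_real_, other_components = character()) {
  pdb_id <- toupper(pdb_id)
  if (!grepl("^[0-9A-Z]{4}$", pdb_id)) stop("invalid pdb_id: ", pdb_id)
  if (!hla_class %in% c(1L, 2L)) stop("hla_class must be 1 or 2")
  if (!is.na(resolution) && resolution <= 0) stop("resolution must be > 0")
  roles <- structure$roles
  comp <- c(
    if (any(roles %in% c("heavy_chain", "class2_alpha", "class2_beta"))) "HLA",
    if (any(roles == "peptide")) "peptide",
    if (any(roles == "tcr")) "TCR")
  structure(list(
    pdb_id = pdb_id, allele_name = allele_name, structure = structure,
    hla_class = as.integer(hla_class),
    complex_composition = paste(comp, collapse = "/"),
    header = header, deposition_date = deposition_date,
    modification_date = modification_date, experiment_type = experiment_type,
    resolution = resolution, free_r = free_r, mean_b = mean_b,
    other_components = other_components), class = "hla_record")
}

#' @export
print.hla_record <- function(x, ...) {
  cat(sprintf("hla_record %s  allele %s  class %d  [%s]\n",
              x$pdb_id, x$allele_name, x$hla_class, x$complex_composition))
  cat(sprintf("  %s  resolution %s A\n",
              ifelse(is.na(x$experiment_type), "?", x$experiment_type),
              ifelse(is.na(x$resolution), "?", format(x$resolution))))
  invisible(x)
}

MONTHS3 <- c(JAN = 1, FEB = 2, MAR = 3, APR = 4, MAY = 5, JUN = 6,
             JUL = 7, AUG = 8, SEP = 9, OCT = 10, NOV = 11, DEC = 12)

#' @noRd
parse_pdb_date <- function(txt) {
  # "21-JUL-97" -> "1997-07-21"
  m <- regmatches(txt, regexec("([0-9]{2})-([A-Z]{3})-([0-9]{2,4})", toupper(txt)))[[1]]
  if (length(m) != 4) return(NA_character_)
  yr <- as.integer(m[4])
  if (yr < 100) yr <- ifelse(yr >= 50, 1900 + yr, 2000 + yr)
  mo <- MONTHS3[[m[3]]]
  sprintf("%04d-%02d-%02d", yr, mo, as.integer(m[2]))
}

#' @noRd
read_pdb_header_info <- function(path) {
  out <- list(header = "", deposition_date = NA_character_,
              modification_date = NA_character_,
              experiment_type = NA_character_,
              resolution = NA_real_, free_r = NA_real_)
  lines <- tryCatch(readLines(path, warn = FALSE), error = function(e) character())
  hd <- grep("^HEADER", lines, value = TRUE)
  if (length(hd)) {
    out$header <- trimws(substr(hd[1], 11, 50))
    out$deposition_date <- parse_pdb_date(substr(hd[1], 51, 59))
  }
  ti <- grep("^TITLE", lines, value = TRUE)
  if (length(ti)) out$header <- paste(trimws(substr(ti, 11, 80)), collapse = " ")
  rv <- grep("^REVDAT", lines, value = TRUE)
  if (length(rv)) out$modification_date <- parse_pdb_date(substr(rv[1], 14, 22))
  ex <- grep("^EXPDTA", lines, value = TRUE)
  if (length(ex)) {
    et <- trimws(substr(ex[1], 11, 79))
    out$experiment_type <- if (grepl("X-RAY", et)) "X-ray" else et
  }
  rs <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(rs)) {
    v <- suppressWarnings(as.numeric(regmatches(rs[1],
        regexpr("[0-9]+\\.[0-9]+", rs[1]))))
    if (length(v) && !is.na(v)) out$resolution <- v
  }
  fr <- grep("FREE R VALUE *(\\(NO CUTOFF\\))? *:", lines, value = TRUE)
  fr <- fr[grepl("^REMARK   3", fr) & !grepl("TEST SET|ERROR", fr)]
  if (length(fr)) {
    v <- suppressWarnings(as.numeric(sub(".*: *", "", fr[1])))
    if (length(v) && !is.na(v)) out$free_r <- v
  }
  out
}

#' @noRd
parse_roles_spec <- function(txt) {
  if (is.na(txt) || !nzchar(txt)) return(NULL)
  parts <- strsplit(txt, "[;,]")[[1]]
  kv <- strsplit(trimws(parts), "=")
  setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
}

#' @noRd
roles_to_spec <- function(roles) paste(sprintf("%s=%s", names(roles), roles), collapse = ";")

#' Build the local HLA structure database
#'
#' Parses every input file, classifies chains, attaches allele metadata
#' and persists the result as `dir/index.tsv` (tab-separated, fixed
#' column order) plus `dir/entries/<pdb_id>.pdb`, so a database can be
#' reloaded with [load_db()] or inspected with any PDB viewer.
#'
#' @param paths character vector of PDB/mmCIF files; the PDB id of each
#'   entry is its file name (without extension), uppercased
#' @param metadata data.frame mapping `pdb_id` to `allele_name`;
#'   optional columns `hla_class` (forces the class branch) and `roles`
#'   (explicit `chain=role;...` assignments that bypass length-based
#'   classification, e.g. for miniature synthetic entries)
#' @param dir output directory (created)
#' @return list of `hla_record`, invisibly also written to `dir`
#' @export
build_db <- function(paths, metadata, dir) {
  ids <- toupper(tools::file_path_sans_ext(basename(paths)))
  if (anyDuplicated(ids)) {
    stop("duplicate pdb_id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  metadata$pdb_id <- toupper(metadata$pdb_id)
  records <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    s <- parse_structure(paths[i])
    mrow <- metadata[metadata$pdb_id == ids[i], , drop = FALSE]
    allele <- if (nrow(mrow)) mrow$allele_name[1] else {
      warning("pdb_id ", ids[i], " missing from metadata; allele set to \"unknown\"")
      "unknown"
    }
    hint <- if (nrow(mrow) && "hla_class" %in% names(mrow)) mrow$hla_class[1] else NULL
    roles <- if (nrow(mrow) && "roles" %in% names(mrow)) parse_roles_spec(mrow$roles[1]) else NULL
    if (!is.null(roles)) {
      s$roles[names(roles)] <- roles
    } else {
      s <- classify_chains(s, hla_class_hint = hint)
    }
    cls <- if (!is.null(hint) && !is.na(hint)) as.integer(hint) else structure_hla_class(s)
    info <- if (tolower(tools::file_ext(paths[i])) %in% c("cif", "mmcif")) {
      list(header = "", deposition_date = NA_character_,
           modification_date = NA_character_, experiment_type = NA_character_,
           resolution = NA_real_, free_r = NA_real_)
    } else read_pdb_header_info(paths[i])
    hets <- setdiff(unique(s$atoms$res_name[!is_protein_residue(s$atoms$res_name)]),
                    WATER_NAMES)
    records[[i]] <- new_hla_record(
      pdb_id = ids[i], allele_name = allele, structure = s, hla_class = cls,
      header = info$header, deposition_date = info$deposition_date,
      modification_date = info$modification_date,
      experiment_type = info$experiment_type, resolution = info$resolution,
      free_r = info$free_r, mean_b = round(mean(s$atoms$b), 2),
      other_components = hets)
  }
  save_db(records, dir)
  invisible(records)
}

#' @noRd
save_db <- function(records, dir) {
  dir.create(file.path(dir, "entries"), recursive = TRUE, showWarnings = FALSE)
  idx <- do.call(rbind, lapply(records, function(r) {
    f <- file.path("entries", paste0(r$pdb_id, ".pdb"))
    data.frame(pdb_id = r$pdb_id, allele_name = r$allele_name,
               complex_composition = r$complex_composition,
               hla_class = r$hla_class, header = r$header,
               deposition_date = r$deposition_date,
               modification_date = r$modification_date,
               experiment_type = r$experiment_type,
               resolution = r$resolution, free_r = r$free_r, mean_b = r$mean_b,
               other_components = paste(r$other_components, collapse = ";"),
               roles = roles_to_spec(r$structure$roles), file = f,
               stringsAsFactors = FALSE)
  }))
  idx <- idx[, DB_INDEX_COLUMNS]
  utils::write.table(idx, file.path(dir, "index.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  for (r in records) {
    write_structure(r$structure, file.path(dir, "entries", paste0(r$pdb_id, ".pdb")))
  }
  invisible(dir)
}

#' Load a structure database written by [build_db()]
#' @param dir database directory containing `index.tsv`
#' @return list of `hla_record`
#' @export
load_db <- function(dir) {
  idx_path <- file.path(dir, "index.tsv")
  if (!file.exists(idx_path)) stop("no database index at ", idx_path)
  idx <- utils::read.table(idx_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "",
                           na.strings = "", colClasses = "character")
  lapply(seq_len(nrow(idx)), function(i) {
    s <- parse_structure(file.path(dir, idx$file[i]), format = "pdb")
    roles <- parse_roles_spec(idx$roles[i])
    if (!is.null(roles)) s$roles[names(roles)] <- roles
    oc <- idx$other_components[i]
    new_hla_record(
      pdb_id = idx$pdb_id[i], allele_name = idx$allele_name[i], structure = s,
      hla_class = as.integer(idx$hla_class[i]), header = ifelse(is.na(idx$header[i]), "", idx$header[i]),
      deposition_date = idx$deposition_date[i],
      modification_date = idx$modification_date[i],
      experiment_type = idx$experiment_type[i],
      resolution = as.numeric(idx$resolution[i]),
      free_r = as.numeric(idx$free_r[i]), mean_b = as.numeric(idx$mean_b[i]),
      other_components = if (is.na(oc) || !nzchar(oc)) character() else strsplit(oc, ";")[[1]])
  })
}
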