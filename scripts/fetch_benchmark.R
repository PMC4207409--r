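#!/usr/bin/env Rscript
# Benchmark harness against real crystal structures. This is the only
# network-touching script: it downloads the named PDB entries, builds a
# database, and recomputes the benchmark quantities (template
# identities, binding-site differences, model-vs-crystal RMSDs, and the
# bound-peptide conservation statistic) with the installed package.
#
#   Rscript scripts/fetch_benchmark.R --dir benchmark [--seed 1]
#
# Results are printed and written to <dir>/benchmark.json.

suppressPackageStartupMessages(library(hlamod))

args <- commandArgs(trailingOnly = TRUE)
flag <- function(name, default = NULL) {
  i <- which(args == paste0("--", name))
  if (length(i) && i < length(args)) args[i + 1] else default
}
dir <- flag("dir", "benchmark")
seed <- as.integer(flag("seed", "1"))
dir.create(dir, recursive = TRUE, showWarnings = FALSE)

# allele mapping for the benchmark entries (user-supplied input; the
# package never queries IMGT/HLA)
metadata <- data.frame(
  pdb_id = c("1AO7", "1QQD", "1M60", "1LP9", "2UWE", "4GBX", "3C5J"),
  allele_name = c("A*02:01", "C*04:01", "B*44:02", "A*02:01",
                  "A*02:01-mutant", "DRA/DRB1*01:01", "DRA/DRB3*03:01"),
  hla_class = c(1, 1, 1, 1, 1, 2, 2),
  stringsAsFactors = FALSE)

status <- hla_cli(c("fetch-benchmark", "--out", file.path(dir, "pdb")))
if (status != 0) stop("download failed; this script needs network access")

paths <- file.path(dir, "pdb", paste0(metadata$pdb_id, ".pdb"))
db <- build_db(paths, metadata, file.path(dir, "db"))
names(db) <- vapply(db, `[[`, "", "pdb_id")

results <- list()
note <- function(name, value) {
  results[[name]] <<- value
  message(sprintf("%-36s %s", name, format(value, digits = 4)))
}

site_seq <- function(rec) {
  bs <- extract_binding_site(rec)
  chain_sequence(bs, chain_ids(bs)[1])
}

# pairwise groove identities for the two worked class I examples
note("identity_1QQD_vs_1M60",
     global_align(site_seq(db[["1QQD"]]), site_seq(db[["1M60"]]))$identity)
note("identity_1LP9_vs_2UWE",
     global_align(site_seq(db[["1LP9"]]), site_seq(db[["2UWE"]]))$identity)

d <- binding_site_differences(db[["2UWE"]], db[["1LP9"]])
note("n_binding_site_diffs_2UWE_1LP9", nrow(d))
if (nrow(d)) note("diff_residues", paste(d$res_a, d$res_b, sep = "/"))

cfg <- build_config(n_candidates = 3, seed = seed)
model_vs_crystal <- function(target_id, template_id) {
  tg <- db[[target_id]]
  gs <- chain_sequence(tg$structure, chains_with_role(tg$structure, "heavy_chain")[1])
  sid <- residue_table(tg$structure,
                       chains_with_role(tg$structure, "heavy_chain")[1])$seq_id
  m <- model_allele(gs, db, 1, config = cfg, template_pdb_id = template_id,
                    exclude = target_id, query_seq_ids = sid)
  model_rmsd(m$best$structure, tg$structure, scope = "binding_site")$rmsd
}
note("rmsd_model_1LP9_from_2UWE", model_vs_crystal("1LP9", "2UWE"))
note("rmsd_model_1QQD_from_1M60", model_vs_crystal("1QQD", "1M60"))

# leave-one-out over whatever class I entries are present
loocv <- run_loocv(db, 1, config = cfg, all_domains = TRUE)
note("loocv_class1_median_binding_site", stats::median(loocv$binding_site_rmsd))
note("loocv_class1_median_all_domain", stats::median(loocv$all_domain_rmsd))
utils::write.table(loocv, file.path(dir, "loocv_class1.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

# bound-peptide core conservation over the class II entries
cons <- tryCatch(peptide_conservation(db), error = function(e) NULL)
if (!is.null(cons)) {
  note("peptide_core_median_rmsd_max", max(cons$medians))
  note("peptide_core_n", cons$n_peptides)
}

if (requireNamespace("jsonlite", quietly = TRUE)) {
  jsonlite::write_json(results, file.path(dir, "benchmark.json"),
                       auto_unbox = TRUE, digits = NA)
}
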