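#!/usr/bin/env Rscript
# One-command replication of the landscape-scale categorization against the
# deposited study dataset (figshare DOI 10.23645/epacomptox.26524327; the
# substance list is also published on the EPA CompTox Chemicals Dashboard as
# list "PFAS8a7v3"). Download the deposited landscape table, then run:
#
#   Rscript scripts/replicate_landscape.R \
#     --input <landscape.csv> [--degradants <degradants.csv>] \
#     [--id-column DTXSID] [--smiles-column SMILES] [--outdir results/landscape]
#
# The landscape CSV needs an identifier column and a SMILES column; the
# optional degradants CSV needs parent_id and degradant_smiles columns. The
# run takes hours at the full ~15,000-substance scale; outputs are the
# terminal assignments, threshold report, selections and a summary of the
# headline counts (objective threshold, categories subcategorized per
# generation, terminal category count, representative picks).

suppressMessages(library(pfascat))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
input <- get_arg("--input")
if (is.null(input)) stop("--input <landscape.csv> is required")
outdir <- get_arg("--outdir", "results/landscape")
id_col <- get_arg("--id-column", "DTXSID")
smiles_col <- get_arg("--smiles-column", "SMILES")
degradants <- get_arg("--degradants")

dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

registry <- read_substances(input, id_column = id_col,
                            smiles_column = smiles_col)
is_pfas <- matches_pfas_definition(registry$qsar_ready_smiles)
registry <- registry[!is.na(is_pfas) & is_pfas, ]
if (!is.null(degradants)) {
  preds <- readr::read_csv(degradants, show_col_types = FALSE)
  registry <- merge_degradants(registry, preds)
}
write_registry(registry, file.path(outdir, "registry.csv"))

pipe <- run_categorization_pipeline(registry)

readr::write_csv(pipe$assignments, file.path(outdir, "assignments.csv"))
readr::write_csv(pipe$selections, file.path(outdir, "selections.csv"))
readr::write_csv(pipe$coverage_summary, file.path(outdir, "coverage_summary.csv"))
readr::write_csv(pipe$threshold_report$within_medians,
                 file.path(outdir, "within_medians.csv"))

asn <- pipe$assignments
sizes <- table(asn$terminal_label)
maxmin_cats <- unique(pipe$selections$terminal_label[
  pipe$selections$role != "centroid"])
summary <- list(
  n_substances = nrow(asn),
  objective_threshold = pipe$threshold_report$tau,
  n_secondary_categories = length(unique(asn$secondary_category)),
  n_secondary_split = length(unique(asn$secondary_category[asn$tertiary != "nan"])),
  n_tertiary_split = length(unique(paste(asn$secondary_category, asn$tertiary)[
    asn$quaternary != "nan"])),
  n_terminal_categories = length(sizes),
  n_categories_with_maxmin = length(maxmin_cats),
  n_selected_substances = nrow(pipe$selections),
  n_for_80pct_total = sum(pipe$coverage_summary$n_picks[
    pipe$coverage_summary$target == 0.8], na.rm = TRUE)
)
jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                     auto_unbox = TRUE, digits = NA)
cat("replication summary written to", file.path(outdir, "summary.json"), "\n")
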