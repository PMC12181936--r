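# Substance registry: ingestion, standardization, PFAS-definition filtering and
# degradation-product merging.

#' Read a substance table into a registry
#'
#' Reads a delimited file of chemical substances (one row per substance) and
#' returns a registry tibble. Structures are standardized to "QSAR-ready" form
#' (salts stripped, stereochemistry removed, common protonation states
#' neutralized) and given hashed structure keys (InChIKeys). Rows whose SMILES
#' cannot be parsed are retained with `qsar_ready_smiles` and `structure_key`
#' set to `NA` and a warning is raised, so downstream stages can treat them as
#' unclassifiable rather than silently losing them.
#'
#' @param path Path to a CSV or TSV file.
#' @param id_column,smiles_column Names of the identifier and SMILES columns.
#' @param name_column,casrn_column Optional names of name/CASRN columns.
#' @return A registry tibble with columns `substance_id`, `smiles`,
#'   `qsar_ready_smiles`, `structure_key`, `name`, `casrn`, `origin`
#'   (`"source"` for all ingested rows) and `parent_id` (`NA`).
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' write.csv(data.frame(id = c("S1", "S2"), smiles = c("CCO", "CC(F)(F)F")),
#'           path, row.names = FALSE)
#' read_substances(path, id_column = "id", smiles_column = "smiles")
read_substances <- function(path, id_column = "substance_id",
                            smiles_column = "smiles",
                            name_column = NULL, casrn_column = NULL) {
  if (!file.exists(path)) {
    stop("substance file does not exist: ", path, call. = FALSE)
  }
  delim <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (nrow(raw) == 0) return(empty_registry())
  as_registry(raw, id_column = id_column, smiles_column = smiles_column,
              name_column = name_column, casrn_column = casrn_column)
}

#' Build a registry from an in-memory data frame
#'
#' @param data Data frame with one row per substance.
#' @inheritParams read_substances
#' @return A registry tibble (see [read_substances()]).
#' @export
as_registry <- function(data, id_column = "substance_id",
                        smiles_column = "smiles",
                        name_column = NULL, casrn_column = NULL) {
  needed <- c(id_column, smiles_column)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  ids <- as.character(data[[id_column]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicate substance_id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  smiles <- as.character(data[[smiles_column]])
  qsar <- standardize_structure(smiles)
  keys <- chem_inchikey(qsar)
  n_bad <- sum(is.na(qsar))
  if (n_bad > 0) {
    warning(n_bad, " structure(s) could not be parsed; retained without ",
            "structure keys", call. = FALSE)
  }
  tibble::tibble(
    substance_id = ids,
    smiles = smiles,
    qsar_ready_smiles = qsar,
    structure_key = keys,
    name = if (!is.null(name_column)) as.character(data[[name_column]]) else NA_character_,
    casrn = if (!is.null(casrn_column)) as.character(data[[casrn_column]]) else NA_character_,
    origin = "source",
    parent_id = NA_character_
  )
}

empty_registry <- function() {
  tibble::tibble(
    substance_id = character(), smiles = character(),
    qsar_ready_smiles = character(), structure_key = character(),
    name = character(), casrn = character(),
    origin = character(), parent_id = character()
  )
}

#' Standardize a structure to QSAR-ready form
#'
#' Produces a standardized ("QSAR-ready") SMILES: the largest organic component
#' is retained (salt/counterion stripping), stereochemistry descriptors are
#' removed, common protonation states are neutralized (for example
#' carboxylates back to the neutral acid), and the result is written as a
#' canonical SMILES. Standardization is idempotent.
#'
#' Component size is ranked by carbon count, then molecular weight; components
#' without carbon are only kept when no component contains carbon.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of standardized canonical SMILES; `NA` where the
#'   input could not be parsed.
#' @export
#' @examples
#' standardize_structure("C(F)(F)(F)[C@@H](O)C")   # stereo removed
#' standardize_structure("OC(=O)C(F)(F)F.[Na+]")   # salt stripped
standardize_structure <- function(smiles) {
  purrr::map_chr(smiles, standardize_structure_one)
}

standardize_structure_one <- function(s) {
  if (is.na(s) || !nzchar(s)) return(NA_character_)
  if (is.na(chem_canonical(s))) return(NA_character_)
  # Remove stereo descriptors textually: tetrahedral marks and cis/trans bonds.
  s <- gsub("@", "", s, fixed = TRUE)
  s <- gsub("[/\\\\]", "", s)
  comps <- strsplit(s, ".", fixed = TRUE)[[1]]
  comps <- comps[nzchar(comps)]
  if (length(comps) == 0) return(NA_character_)
  if (length(comps) > 1) {
    form <- chem_formula(comps)
    nc <- formula_carbon_count(form)
    mw <- chem_mw(comps)
    keep <- which(!is.na(form))
    if (length(keep) == 0) return(NA_character_)
    organic <- keep[nc[keep] > 0]
    pool <- if (length(organic) > 0) organic else keep
    best <- pool[order(-nc[pool], -mw[pool], pool)][1]
    s <- comps[best]
  }
  s <- neutralize_charges(s)
  chem_canonical(s)
}

# Neutralize common protonation states at the SMILES-text level. Deliberately
# conservative: quaternary nitrogens and metal ions are left untouched (metals
# are removed earlier as non-organic components).
neutralize_charges <- function(s) {
  subs <- c(
    "[O-]" = "O", "[OH-]" = "O", "[S-]" = "S", "[SH-]" = "S",
    "[N-]" = "N", "[NH-]" = "N",
    "[NH4+]" = "N", "[NH3+]" = "N", "[NH2+]" = "N", "[NH+]" = "N",
    "[OH2+]" = "O", "[OH+]" = "O", "[SH+]" = "S"
  )
  out <- s
  for (from in names(subs)) {
    out <- gsub(from, subs[[from]], out, fixed = TRUE)
  }
  # Fall back to the un-neutralized form if the edit broke the SMILES.
  if (is.na(chem_canonical(out))) s else out
}

#' Structural PFAS definition patterns
#'
#' The three definitional substructures, encoded as SMARTS with explicit
#' saturation constraints:
#' 1. `R-(CF2)-CF(R')R''` with both carbons saturated;
#' 2. `R-CF2-O-CF2-R'` with `R`, `R'` one of fluorine, oxygen or a saturated
#'    carbon;
#' 3. `CF3-C(CF3)(R')(R'')` with `R'`, `R''` fluorine or a saturated carbon.
#'
#' Shipping the patterns as data means an alternative definition (for example
#' the broader single `-CF3`/`-CF2-` rule) can be swapped in via the
#' `patterns` argument of [matches_pfas_definition()].
#'
#' @return A tibble with columns `pattern_id` and `smarts`.
#' @export
pfas_definition_patterns <- function() {
  tibble::tibble(
    pattern_id = c("cf2_cf_saturated", "cf2_ether_bridge", "gem_bis_cf3"),
    smarts = c(
      "[CX4](F)(F)[CX4]F",
      "[F,OX2,CX4][CX4](F)(F)O[CX4](F)(F)[F,OX2,CX4]",
      "[CX4]([CX4](F)(F)F)([CX4](F)(F)F)([F,CX4])[F,CX4]"
    )
  )
}

#' Test structures against the structural PFAS definition
#'
#' A structure is a PFAS if it contains at least one of the three definitional
#' substructures (see [pfas_definition_patterns()]).
#'
#' @param smiles Character vector of (preferably QSAR-ready) SMILES.
#' @param patterns Pattern table as returned by [pfas_definition_patterns()].
#' @return Logical vector: `TRUE`/`FALSE` per structure, `NA` (with a warning)
#'   where the structure cannot be parsed -- deliberately distinct from
#'   `FALSE`.
#' @export
#' @examples
#' matches_pfas_definition(c("CC(F)(F)F", "FC(F)(F)OC(F)(F)F"))
matches_pfas_definition <- function(smiles, patterns = pfas_definition_patterns()) {
  hits <- matrix(FALSE, nrow = length(smiles), ncol = nrow(patterns))
  parseable <- chem_is_parseable(smiles)
  for (j in seq_len(nrow(patterns))) {
    m <- chem_smarts_match(smiles, patterns$smarts[j])
    hits[, j] <- !is.na(m) & m
  }
  out <- rowSums(hits) > 0
  out[!parseable] <- NA
  if (any(!parseable)) {
    warning(sum(!parseable), " structure(s) could not be parsed; PFAS status NA",
            call. = FALSE)
  }
  out
}

#' Merge predicted degradation products into a registry
#'
#' Degradant predictions (parent identifier plus degradant SMILES, as exported
#' by a biodegradation simulator) are standardized, grouped to unique
#' structures by hashed structure key, filtered to structures meeting the
#' PFAS definition, cross-matched against the existing registry to drop
#' structures already in the landscape, and appended with
#' `origin = "degradant"` and identifiers of the form
#' `<parent_id>_m_<rank>` (rank = 1-based order of listing under the parent).
#'
#' @param registry A registry tibble (see [read_substances()]).
#' @param predictions Tibble with columns `parent_id`, `degradant_smiles` and
#'   optionally `rank` (defaults to listing order within parent).
#' @param patterns PFAS definition patterns passed to
#'   [matches_pfas_definition()].
#' @return The augmented registry, with a `merge_report` attribute: a list with
#'   counts `predicted`, `unique`, `non_pfas_removed`, `duplicate_removed` and
#'   `added`.
#' @export
merge_degradants <- function(registry, predictions,
                             patterns = pfas_definition_patterns()) {
  stopifnot(all(c("parent_id", "degradant_smiles") %in% names(predictions)))
  unknown <- setdiff(unique(predictions$parent_id), registry$substance_id)
  if (length(unknown) > 0) {
    stop("unknown parent_id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  preds <- tibble::as_tibble(predictions)
  if (!"rank" %in% names(preds)) {
    preds <- preds |>
      dplyr::group_by(.data$parent_id) |>
      dplyr::mutate(rank = dplyr::row_number()) |>
      dplyr::ungroup()
  }
  if (anyDuplicated(preds[c("parent_id", "rank")]) > 0) {
    stop("duplicate (parent_id, rank) in degradant predictions", call. = FALSE)
  }
  preds <- preds |>
    dplyr::mutate(
      qsar_ready_smiles = standardize_structure(.data$degradant_smiles),
      structure_key = chem_inchikey(.data$qsar_ready_smiles),
      degradant_id = paste0(.data$parent_id, "_m_", .data$rank)
    )
  n_predicted <- nrow(preds)

  # One representative per unique structure key (first listed wins); structures
  # that failed to parse cannot be deduplicated or PFAS-checked and are dropped.
  uniq <- preds |>
    dplyr::filter(!is.na(.data$structure_key)) |>
    dplyr::distinct(.data$structure_key, .keep_all = TRUE)
  n_unique <- nrow(uniq)

  is_pfas <- matches_pfas_definition(uniq$qsar_ready_smiles, patterns = patterns)
  uniq <- uniq[!is.na(is_pfas) & is_pfas, , drop = FALSE]
  n_non_pfas <- n_unique - nrow(uniq)

  dup_existing <- uniq$structure_key %in% registry$structure_key
  n_dup <- sum(dup_existing)
  survivors <- uniq[!dup_existing, , drop = FALSE]

  added <- tibble::tibble(
    substance_id = survivors$degradant_id,
    smiles = survivors$degradant_smiles,
    qsar_ready_smiles = survivors$qsar_ready_smiles,
    structure_key = survivors$structure_key,
    name = NA_character_,
    casrn = NA_character_,
    origin = "degradant",
    parent_id = survivors$parent_id
  )
  out <- dplyr::bind_rows(registry, added)
  attr(out, "merge_report") <- list(
    predicted = n_predicted,
    unique = n_unique,
    non_pfas_removed = n_non_pfas,
    duplicate_removed = n_dup,
    added = nrow(added)
  )
  out
}

#' Write a registry and its merge report
#'
#' @param registry Registry tibble (optionally carrying a `merge_report`
#'   attribute from [merge_degradants()]).
#' @param path Output CSV path; the merge report, when present, is written
#'   next to it as JSON.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  readr::write_csv(registry, path)
  report <- attr(registry, "merge_report")
  if (!is.null(report)) {
    jsonlite::write_json(report, sub("\\.csv$", "_merge_report.json", path),
                         auto_unbox = TRUE)
  }
  invisible(path)
}
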