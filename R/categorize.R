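# Primary/secondary categorization: structural class rules, the hybrid
# membership rule and perfluorinated chain-length binning.

#' Maximum contiguous perfluorinated chain length
#'
#' Length of the longest simple path of carbons each bearing at least two
#' fluorines and no hydrogens. A terminal `CF3` counts as one unit of the run,
#' so perfluorooctanoic acid scores 7 (seven fluorinated carbons; the eighth
#' backbone carbon is the carboxyl) and perfluorooctane sulfonic acid scores 8.
#' Computed as in the source methodology: substructure patterns of increasing
#' run length are matched until the first failure.
#'
#' @param smiles Character vector of (QSAR-ready) SMILES.
#' @param max_length Chain lengths are scanned up to this value; longer runs
#'   are still computed exactly but raise a warning.
#' @param strict_cf2 If `TRUE`, require exactly two fluorines per chain carbon
#'   (so terminal `CF3` carbons do not count). Default `FALSE`, matching the
#'   worked examples above.
#' @return Integer vector of chain lengths (`0` when no qualifying carbon,
#'   `NA` with a warning where the structure cannot be parsed).
#' @export
#' @examples
#' max_chain_length("OC(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F")
max_chain_length <- function(smiles, max_length = 30, strict_cf2 = FALSE) {
  # Recursive-SMARTS atom terms keep the match enumeration linear in chain
  # length (explicit (F)(F) branches would enumerate every fluorine
  # permutation along the run).
  unit <- if (strict_cf2) {
    "[CX4;H0;$(C(F)F);!$(C(F)(F)F)]"
  } else {
    "[CX4;H0;$(C(F)F)]"
  }
  mols <- chem_parse(smiles)
  out <- purrr::map_int(mols, function(m) {
    if (is.null(m)) return(NA_integer_)
    len <- 0L
    k <- 1L
    hard_cap <- max(max_length * 4L, 120L)
    while (k <= hard_cap) {
      pat <- paste(rep(unit, k), collapse = "")
      hit <- tryCatch(
        as.numeric(ChemmineOB::smartsSearch_OB(list(m), pat, uniqueMatches = TRUE)[[1]]) > 0,
        error = function(e) FALSE
      )
      if (!hit) break
      len <- k
      k <- k + 1L
    }
    len
  })
  if (any(is.na(out))) {
    warning(sum(is.na(out)), " structure(s) could not be parsed; chain length NA",
            call. = FALSE)
  }
  if (any(!is.na(out) & out > max_length)) {
    warning("chain length exceeds the configured maximum (", max_length,
            ") for ", sum(!is.na(out) & out > max_length),
            " structure(s); computed exactly", call. = FALSE)
  }
  out
}

#' Ordered structural rules for primary class assignment
#'
#' An editable, ordered rule table approximating the published class
#' vocabulary: each rule carries a first (broad) class and a second (finer)
#' class, any-of SMARTS patterns, optional none-may-match SMARTS, and an
#' optional element whitelist. Rules are evaluated most-specific-first; the
#' first matching rule wins. The internals of the published classification
#' tool are not public, so this table is the package's own reconstruction and
#' can be replaced wholesale via the `rules` argument of
#' [assign_primary_classes()].
#'
#' @return A tibble with columns `rule`, `first_class`, `second_class`,
#'   `smarts_any` (list of character), `smarts_none` (list of character) and
#'   `elements_only` (comma-separated whitelist or `NA`).
#' @export
primary_class_rules <- function() {
  tibble::tibble(
    rule = c("pfaa", "pasf", "fluorotelomer_n2", "polyfca_derivative",
             "polyfluoroalkyl_acid", "si_pfas", "perfluoroalkane",
             "hfc", "aromatic_pfas", "other"),
    first_class = c("PFAAs", "PFAA precursors", "PFAA precursors",
                    "Polyfluoroalkyl acids", "Polyfluoroalkyl acids",
                    "Other PFAS", "Other PFAS", "PFAA precursors",
                    "Other PFAS", "Other PFAS"),
    second_class = c("PFAAs", "PASF-based substances",
                     "n:2 fluorotelomer-based substances",
                     "PolyFCA derivatives", "Polyfluoroalkyl acids",
                     "Si PFASs", "Polyfluoroalkanes", "HFCs",
                     "Aromatic PFASs", "others"),
    smarts_any = list(
      # acid head (carboxylic, sulfonic or phosphonic) on a perfluorinated
      # carbon; the element/no-CH constraints below make it a perfluoro acid
      c("[CX4](F)(F)[CX3](=O)[OX2H1,OX1-]",
        "[CX4](F)(F)[SX4](=O)(=O)[OX2H1,OX1-]",
        "[CX4](F)(F)[PX4](=O)([OX2H1,OX1-])"),
      c("FS(=O)(=O)[CX4](F)F", "[NX3]S(=O)(=O)[CX4](F)F"),
      "[CX4](F)(F)[CH2][CH2]",
      c("[CX4](F)(F)[CX3](=O)[OX2H0]", "[CX4](F)(F)[CX3](=O)[NX3]"),
      c("[CX3](=O)[OX2H1,OX1-]", "[SX4](=O)(=O)[OX2H1,OX1-]"),
      "[Si]",
      "[CX4](F)F",
      "[CX4](F)F",
      "a",
      character(0)
    ),
    smarts_none = list(
      "[#6;!H0]",          # no hydrogen-bearing carbon: fully fluorinated
      character(0),
      character(0),
      character(0),
      character(0),
      character(0),
      c("[#6;!H0]", "a"),  # perfluoroalkanes: fully fluorinated, non-aromatic
      c("a", "[R]"),       # hydrofluorocarbons: acyclic C/H/F only
      character(0),
      character(0)
    ),
    elements_only = c(NA, NA, NA, NA, NA, NA, "C,F", "C,H,F", NA, NA)
  )
}

# Elements present in a molecular formula string, e.g. "C2H3F3" -> C,H,F.
formula_elements <- function(formula) {
  purrr::map(formula, function(f) {
    if (is.na(f)) return(character(0))
    unique(stringr::str_extract_all(f, "[A-Z][a-z]?")[[1]])
  })
}

#' Assign first and second structural classes
#'
#' Applies the ordered rule table in [primary_class_rules()] to each
#' QSAR-ready structure. Structures failing the PFAS definition are classed
#' `"Not PFAS"`; unparseable structures are `"unclassified"`. Structures with
#' a fluorinated ring carbon have `", cyclic"` appended to the first class
#' (and to the second class when it duplicates the first).
#'
#' @param data Tibble with a SMILES column (a registry works directly).
#' @param smiles_col Name of the SMILES column.
#' @param rules Rule table, by default [primary_class_rules()].
#' @param patterns PFAS definition patterns.
#' @return `data` with `first_class` and `second_class` columns added.
#' @export
assign_primary_classes <- function(data, smiles_col = "qsar_ready_smiles",
                                   rules = primary_class_rules(),
                                   patterns = pfas_definition_patterns()) {
  smiles <- data[[smiles_col]]
  n <- length(smiles)
  first <- rep("unclassified", n)
  second <- rep("unclassified", n)
  parseable <- chem_is_parseable(smiles)
  is_pfas <- suppressWarnings(matches_pfas_definition(smiles, patterns = patterns))
  elements <- formula_elements(chem_formula(smiles))
  cyclic <- !is.na(smiles) & chem_smarts_match(smiles, "[#6;R]F") %in% TRUE

  # Cache SMARTS hits over all distinct patterns in the rule table.
  all_pats <- unique(unlist(c(rules$smarts_any, rules$smarts_none)))
  hits <- matrix(FALSE, nrow = n, ncol = length(all_pats),
                 dimnames = list(NULL, all_pats))
  for (p in all_pats) hits[, p] <- chem_smarts_match(smiles, p) %in% TRUE

  assigned <- rep(FALSE, n)
  candidates <- which(parseable & !is.na(is_pfas) & is_pfas)
  for (r in seq_len(nrow(rules))) {
    any_pats <- rules$smarts_any[[r]]
    none_pats <- rules$smarts_none[[r]]
    elem <- rules$elements_only[r]
    idx <- candidates[!assigned[candidates]]
    if (length(idx) == 0) break
    ok <- rep(TRUE, length(idx))
    if (length(any_pats) > 0) {
      ok <- rowSums(hits[idx, any_pats, drop = FALSE]) > 0
    }
    if (length(none_pats) > 0) {
      ok <- ok & rowSums(hits[idx, none_pats, drop = FALSE]) == 0
    }
    if (!is.na(elem)) {
      allowed <- strsplit(elem, ",")[[1]]
      ok <- ok & purrr::map_lgl(elements[idx], ~ length(setdiff(.x, allowed)) == 0)
    }
    sel <- idx[ok]
    first[sel] <- rules$first_class[r]
    second[sel] <- rules$second_class[r]
    assigned[sel] <- TRUE
  }
  not_pfas <- parseable & !is.na(is_pfas) & !is_pfas
  first[not_pfas] <- "Not PFAS"
  second[not_pfas] <- "Not PFAS"

  add_cyclic <- cyclic & assigned
  same <- first == second
  second[add_cyclic & same] <- paste0(second[add_cyclic & same], ", cyclic")
  first[add_cyclic] <- paste0(first[add_cyclic], ", cyclic")

  data$first_class <- first
  data$second_class <- second
  data
}

#' Resolve primary categories with the hybrid membership rule
#'
#' When a first class holds more than `max_first_class` substances its members
#' take their second-class labels instead, keeping no primary category
#' unmanageably large. Second-class labels ending up with fewer than
#' `min_second_class` members fall back to the catch-all `"others"` bucket
#' (`"others, cyclic"` for cyclic first classes). `"Not PFAS"` and structures
#' without a usable QSAR-ready SMILES become `"unclassified"`.
#'
#' @param data Tibble with `first_class` and `second_class` columns (from
#'   [assign_primary_classes()]).
#' @param max_first_class Membership above which a first class is replaced by
#'   its second classes (default 300).
#' @param min_second_class Minimum membership for a promoted second class
#'   before it collapses to `"others"` (default 10).
#' @return `data` with a `primary_category` column added.
#' @export
apply_hybrid_rule <- function(data, max_first_class = 300,
                              min_second_class = 10) {
  stopifnot(all(c("first_class", "second_class") %in% names(data)))
  counts <- table(data$first_class)
  use_second <- data$first_class %in% names(counts)[counts > max_first_class]
  primary <- ifelse(use_second, data$second_class, data$first_class)

  promoted <- unique(data$second_class[use_second])
  p_counts <- table(primary)
  low <- intersect(promoted, names(p_counts)[p_counts < min_second_class])
  is_low <- primary %in% low
  primary[is_low] <- ifelse(grepl(", cyclic$", data$first_class[is_low]),
                            "others, cyclic", "others")

  primary[data$first_class %in% c("Not PFAS", "Not PFAS, cyclic")] <- "unclassified"
  primary[is.na(data$first_class)] <- "unclassified"
  if ("qsar_ready_smiles" %in% names(data)) {
    primary[is.na(data$qsar_ready_smiles)] <- "unclassified"
  }
  data$primary_category <- primary
  data
}

#' Secondary categories from chain length
#'
#' Bins each substance by its maximum contiguous perfluorinated chain length
#' at the stated threshold (default 7): `"gte7"` for lengths at or above it,
#' `"lt7"` below. The secondary category label is the primary category plus
#' the bin, e.g. `"Aromatic PFASs, gte7"`.
#'
#' @param data Tibble with `primary_category` and `chain_length` columns.
#' @param threshold Chain-length threshold (default 7).
#' @return `data` with `chain_bin` and `secondary_category` columns added.
#' @export
assign_secondary <- function(data, threshold = 7) {
  stopifnot(all(c("primary_category", "chain_length") %in% names(data)))
  bin_names <- paste0(c("gte", "lt"), threshold)
  data$chain_bin <- ifelse(!is.na(data$chain_length) & data$chain_length >= threshold,
                           bin_names[1], bin_names[2])
  data$secondary_category <- paste0(data$primary_category, ", ", data$chain_bin)
  data
}

#' Full categorization of a registry
#'
#' Convenience wrapper running class assignment, the hybrid rule, chain-length
#' computation and secondary binning in one step.
#'
#' @param registry Registry tibble.
#' @param chain_threshold Chain-length bin threshold.
#' @param max_first_class,min_second_class Hybrid-rule thresholds, see
#'   [apply_hybrid_rule()].
#' @param rules,patterns Rule and pattern tables.
#' @return Assignment tibble with identifier, class, chain and category
#'   columns.
#' @export
categorize_substances <- function(registry, chain_threshold = 7,
                                  max_first_class = 300, min_second_class = 10,
                                  rules = primary_class_rules(),
                                  patterns = pfas_definition_patterns()) {
  out <- assign_primary_classes(registry, rules = rules, patterns = patterns)
  out <- apply_hybrid_rule(out, max_first_class = max_first_class,
                           min_second_class = min_second_class)
  out$chain_length <- suppressWarnings(max_chain_length(out$qsar_ready_smiles))
  out$chain_length[is.na(out$chain_length)] <- 0L
  out <- assign_secondary(out, threshold = chain_threshold)
  dplyr::select(out, "substance_id", "qsar_ready_smiles", "first_class",
                "second_class", "primary_category", "chain_length",
                "chain_bin", "secondary_category")
}
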