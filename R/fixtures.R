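# Deterministic synthetic chemical landscapes with known ground truth, so
# every pipeline stage is testable without external downloads. SMILES are
# built from homologous-series templates; the truth table records the
# intended chain length, family and PFAS-definition status of every
# substance.

cf2 <- function(n) strrep("C(F)(F)", n)

# Template set: each family has variants, each a function of the
# perfluorinated run length n returning the SMILES and the intended maximum
# contiguous chain length. Runs of n >= 2 are used so every non-decoy member
# meets the structural PFAS definition.
fixture_families <- function() {
  list(
    pfca = list(  # perfluorocarboxylic acids -> PFAAs
      linear = function(n) list(smiles = paste0("OC(=O)", cf2(n), "F"), chain = n),
      diacid = function(n) list(smiles = paste0("OC(=O)", cf2(n), "C(=O)O"), chain = n)
    ),
    pfsa = list(  # perfluorosulfonic acids -> PFAAs
      linear = function(n) list(smiles = paste0("OS(=O)(=O)", cf2(n), "F"), chain = n),
      disulfo = function(n) list(smiles = paste0("OS(=O)(=O)", cf2(n), "S(=O)(=O)O"), chain = n)
    ),
    ftoh = list(  # n:2 fluorotelomer alcohols/esters -> PFAA precursors
      alcohol = function(n) list(smiles = paste0("OCC", cf2(n), "F"), chain = n),
      acetate = function(n) list(smiles = paste0("CC(=O)OCC", cf2(n), "F"), chain = n)
    ),
    pasf = list(  # perfluoroalkane sulfonyl fluorides/amides -> PFAA precursors
      fluoride = function(n) list(smiles = paste0("FS(=O)(=O)", cf2(n), "F"), chain = n),
      amide = function(n) list(smiles = paste0("CNS(=O)(=O)", cf2(n), "F"), chain = n)
    ),
    aromatic = list(  # ring-bearing perfluoroalkyl chains -> Aromatic PFASs
      phenyl = function(n) list(smiles = paste0("c1ccccc1", cf2(n), "F"), chain = n),
      chlorophenyl = function(n) list(smiles = paste0("Clc1ccccc1", cf2(n), "F"), chain = n)
    ),
    ether = list(  # perfluoroalkyl ethers -> catch-all others
      methyl = function(n) list(smiles = paste0("F", cf2(n), "OC(F)(F)F"), chain = n),
      ethyl = function(n) list(smiles = paste0("F", cf2(n), "OC(F)(F)C(F)(F)F"),
                               chain = max(n, 2)),
      propyl = function(n) list(smiles = paste0("F", cf2(n), "OC(F)(F)C(F)(F)C(F)(F)F"),
                                chain = max(n, 3))
    ),
    hpfca = list(  # omega-H polyfluoro acids -> Polyfluoroalkyl acids
      omega_h = function(n) list(smiles = paste0("OC(=O)", cf2(n - 1), "C(F)F"),
                                 chain = n - 1),
      telomer_acid = function(n) list(smiles = paste0("OC(=O)C", cf2(n), "F"), chain = n)
    )
  )
}

fixture_decoys <- function() {
  # Fluorinated and non-fluorinated structures that all fail the structural
  # PFAS definition (1,1,1-trifluoroethane has no CF2-CF pair).
  c("CCO", "CCCCCC", "c1ccccc1", "CC(F)(F)F", "CCOC(C)C", "ClCCCl",
    "OCCN", "CC(=O)OC", "c1ccncc1", "OC(=O)C")
}

#' Generate a synthetic PFAS landscape with known ground truth
#'
#' Builds homologous series of perfluorinated chemicals from structural
#' templates spanning seven families (perfluorocarboxylic and -sulfonic
#' acids, fluorotelomers, sulfonyl fluorides, aromatic, ether and omega-H
#' series) plus non-PFAS decoys, so every primary category branch and both
#' chain-length bins are populated. Output is fully determined by the
#' arguments (and `seed`, reserved for generators that sample).
#'
#' @param families Subset of the template family names (default all).
#' @param chain_range Perfluorinated run lengths per series (default 2:11,
#'   spanning both sides of the chain-length threshold of 7).
#' @param n_variants Variants (homologous series) used per family.
#' @param n_decoys Number of non-PFAS decoy structures appended.
#' @param seed Integer seed (kept for interface symmetry; the landscape
#'   itself is deterministic).
#' @return List with `registry` (a standardized registry tibble) and `truth`
#'   (`substance_id`, `family`, `variant`, `true_chain_length`, `is_pfas`).
#' @export
generate_landscape <- function(families = names(fixture_families()),
                               chain_range = 2:11, n_variants = 2,
                               n_decoys = 6, seed = 1) {
  all_fams <- fixture_families()
  if (length(families) == 0) stop("at least one family required", call. = FALSE)
  stopifnot(all(families %in% names(all_fams)), all(chain_range >= 2))
  rows <- list()
  for (fam in families) {
    variants <- head(all_fams[[fam]], n_variants)
    for (v in names(variants)) {
      for (n in chain_range) {
        mol <- variants[[v]](n)
        rows[[length(rows) + 1]] <- tibble::tibble(
          substance_id = sprintf("SYN-%s-%s-%02d", toupper(fam), v, n),
          smiles = mol$smiles, family = fam, variant = v,
          true_chain_length = mol$chain, is_pfas = TRUE
        )
      }
    }
  }
  decoys <- head(fixture_decoys(), n_decoys)
  if (length(decoys) > 0) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      substance_id = sprintf("SYN-DECOY-%02d", seq_along(decoys)),
      smiles = decoys, family = "decoy", variant = "decoy",
      true_chain_length = c(0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L)[seq_along(decoys)],
      is_pfas = FALSE
    )
  }
  truth <- dplyr::bind_rows(rows)
  registry <- as_registry(truth[c("substance_id", "smiles")])
  list(registry = registry, truth = truth)
}

#' Generate degradant predictions for a synthetic landscape
#'
#' Emulates a biodegradation simulator's export: each fluorotelomer parent is
#' predicted to degrade to (1) the matching perfluorocarboxylic acid - a
#' structure usually already in the landscape, exercising the
#' duplicate-removal path and shared across the two fluorotelomer variants
#' of the same run length, exercising structure-key grouping; (2) the
#' matching perfluoroaldehyde, a novel PFAS structure; and (3) ethanol,
#' which fails the PFAS definition.
#'
#' @param truth Truth table from [generate_landscape()].
#' @return Tibble with `parent_id`, `degradant_smiles`, `rank`.
#' @export
generate_degradant_predictions <- function(truth) {
  parents <- truth[truth$family == "ftoh", ]
  purrr::pmap_dfr(parents[c("substance_id", "true_chain_length")],
                  function(substance_id, true_chain_length) {
    n <- true_chain_length
    tibble::tibble(
      parent_id = substance_id,
      degradant_smiles = c(paste0("OC(=O)", cf2(n), "F"),
                           paste0("O=C", cf2(n), "F"),
                           "CCO"),
      rank = 1:3
    )
  })
}

#' Generate a synthetic physicochemical property table
#'
#' Property values follow simple monotone trends in chain length (heavier
#' homologues melt and boil higher, dissolve less, evaporate less) with
#' lognormal noise; a small fraction of substances is left entirely without
#' properties to exercise the `"not determined"` path.
#'
#' @param truth Truth table from [generate_landscape()].
#' @param missing_rate Fraction of substances with all properties missing.
#' @param seed Integer seed.
#' @return Tibble with `substance_id`, `melting_point`, `boiling_point`
#'   (deg C), `water_solubility` (mg/L), `vapour_pressure` (mmHg),
#'   `henrys_law` (atm m3/mol).
#' @export
generate_property_table <- function(truth, missing_rate = 0.05, seed = 1) {
  set.seed(seed)
  n <- nrow(truth)
  chain <- truth$true_chain_length
  out <- tibble::tibble(
    substance_id = truth$substance_id,
    melting_point = -60 + 18 * chain + stats::rnorm(n, 0, 8),
    boiling_point = 20 + 22 * chain + stats::rnorm(n, 0, 10),
    water_solubility = 10^(3 - 0.6 * chain + stats::rnorm(n, 0, 0.4)),
    vapour_pressure = 10^(2.2 - 0.45 * chain + stats::rnorm(n, 0, 0.4)),
    henrys_law = 10^(-4 + 0.35 * chain + stats::rnorm(n, 0, 0.4))
  )
  missing <- stats::runif(n) < missing_rate
  out[missing, -1] <- NA_real_
  out
}

#' Generate synthetic toxicity records with a planted chain-length effect
#'
#' Each selected substance gets a true human-equivalent benchmark-dose
#' median; substances at or above the chain threshold have medians
#' `gte_shift` times lower (long-chain members planted as more potent).
#' Per-record BMDh values are drawn lognormally around the substance median
#' and then inflated back through the harmonization factors (effect-level,
#' duration, species, conceptual models) so the pipeline recovers the
#' planted values. Record counts below the sd-substitution threshold are
#' included by design.
#'
#' @param truth Truth table from [generate_landscape()] (decoys are skipped).
#' @param median_pod True BMDh median for short-chain substances
#'   (mg/kg-bw/day, default 10).
#' @param gte_shift Fold-reduction of the median for chain lengths at or
#'   above `chain_threshold` (default 10).
#' @param chain_threshold Chain-length threshold (default 7).
#' @param gsd Geometric standard deviation of record noise (default 1.5;
#'   use 1 for noise-free records).
#' @param records_range Range of record counts per substance (default 2:8,
#'   spanning the fewer-than-5 substitution rule).
#' @param effect_class Effect class stream to generate.
#' @param species_factors,conceptual_models Factor tables inverted when
#'   constructing reported values (defaults match
#'   [harmonize_tox_records()]).
#' @param seed Integer seed.
#' @return Tibble of raw records (`substance_id`, `route`, `study_type`,
#'   `effect_type`, `value`, `units`, `species`, `effect_class`) with a
#'   `truth` attribute giving each substance's true BMDh median.
#' @export
generate_tox_records <- function(truth, median_pod = 10, gte_shift = 10,
                                 chain_threshold = 7, gsd = 1.5,
                                 records_range = 2:8,
                                 effect_class = "noncancer",
                                 species_factors = default_species_factors(),
                                 conceptual_models = default_conceptual_models(),
                                 seed = 1) {
  set.seed(seed)
  subs <- truth[truth$family != "decoy", ]
  long_chain <- subs$true_chain_length >= chain_threshold
  true_median <- ifelse(long_chain, median_pod / gte_shift, median_pod)
  cm <- conceptual_models[conceptual_models$effect_class == effect_class, ]
  m_mean <- (cm$m1 + cm$m2) / 2
  duration <- study_duration_classes()
  records <- purrr::map_dfr(seq_len(nrow(subs)), function(i) {
    k <- sample(records_range, 1)
    bmdh <- exp(stats::rnorm(k, log(true_median[i]), log(gsd)))
    study_type <- sample(duration$study_type, k, replace = TRUE)
    effect_type <- sample(c("NOAEL", "NOEL", "LOAEL", "LOEL"), k, replace = TRUE)
    species <- sample(species_factors$species, k, replace = TRUE)
    dur_f <- dplyr::case_when(
      duration$duration_class[match(study_type, duration$study_type)] == "subchronic" ~ 2,
      duration$duration_class[match(study_type, duration$study_type)] == "subacute" ~ 5,
      TRUE ~ 1
    )
    loael_f <- ifelse(effect_type %in% pod_loael_types(), 3, 1)
    sp_f <- species_factors$factor[match(species, species_factors$species)]
    tibble::tibble(
      substance_id = subs$substance_id[i], route = "oral",
      study_type = study_type, effect_type = effect_type,
      value = bmdh / m_mean * loael_f * dur_f * sp_f,
      units = "mg/kg-bw/day", species = species,
      effect_class = effect_class
    )
  })
  attr(records, "truth") <- tibble::tibble(
    substance_id = subs$substance_id, true_median_bmdh = true_median
  )
  records
}

#' Generate a synthetic flag table with a planted feature association
#'
#' Flags are sampled so that carriers of the designated binary feature have
#' the target odds ratio of being flag-positive, in expectation, relative to
#' non-carriers at baseline rate `p0`: carriers are positive with
#' probability `OR * p0 / (1 - p0 + OR * p0)`. Positive substances are
#' graded 1 or 2 (so either binarization convention detects them); a
#' fraction of values is missing and a fraction of substances fails QC.
#'
#' @param substance_id Character vector of substance ids.
#' @param feature 0/1 vector: the planted structural feature per substance.
#' @param odds_ratio Target odds ratio (must be positive and finite).
#' @param p0 Baseline flag-positive probability for non-carriers.
#' @param flag_name Name of the flag column.
#' @param missing_rate,qc_fail_rate Rates of missing flag values and QC
#'   failures.
#' @param seed Integer seed.
#' @return Tibble with `substance_id`, `qc_pass` and one graded flag column.
#' @export
generate_flag_table <- function(substance_id, feature, odds_ratio = 10,
                                p0 = 0.2, flag_name = "flag",
                                missing_rate = 0, qc_fail_rate = 0,
                                seed = 1) {
  stopifnot(length(substance_id) == length(feature))
  if (!is.finite(odds_ratio) || odds_ratio <= 0) {
    stop("odds_ratio must be positive and finite", call. = FALSE)
  }
  set.seed(seed)
  n <- length(substance_id)
  p1 <- odds_ratio * p0 / (1 - p0 + odds_ratio * p0)
  prob <- ifelse(feature == 1, p1, p0)
  positive <- stats::runif(n) < prob
  value <- ifelse(positive, sample(c(1L, 2L), n, replace = TRUE), 0L)
  value[stats::runif(n) < missing_rate] <- NA_integer_
  out <- tibble::tibble(
    substance_id = substance_id,
    qc_pass = stats::runif(n) >= qc_fail_rate
  )
  out[[flag_name]] <- value
  out
}

#' Generate random noise features for enrichment testing
#'
#' @param substance_id Character vector of substance ids.
#' @param n_features Number of noise features.
#' @param prevalence Bit prevalence.
#' @param seed Integer seed.
#' @return 0/1 matrix with substance ids as row names.
#' @export
generate_noise_features <- function(substance_id, n_features = 15,
                                    prevalence = 0.3, seed = 1) {
  set.seed(seed)
  m <- matrix(
    as.integer(stats::runif(length(substance_id) * n_features) < prevalence),
    nrow = length(substance_id),
    dimnames = list(substance_id, paste0("noise_", seq_len(n_features)))
  )
  m
}

#' Generate synthetic inventory and monitoring lists
#'
#' @param substance_id Character vector of substance ids.
#' @param inventory_rate Fraction of substances on the inventory; half of
#'   those are marked active.
#' @param list_rate Fraction of substances on each monitoring list.
#' @param n_lists Number of monitoring lists.
#' @param seed Integer seed.
#' @return List with `inventory` (tibble `substance_id`, `status`) and
#'   `monitoring` (named list of tibbles with `substance_id`).
#' @export
generate_membership_lists <- function(substance_id, inventory_rate = 0.4,
                                      list_rate = 0.2, n_lists = 3, seed = 1) {
  set.seed(seed)
  n <- length(substance_id)
  on_inv <- sample(substance_id, round(n * inventory_rate))
  active <- sample(on_inv, round(length(on_inv) / 2))
  inventory <- tibble::tibble(
    substance_id = on_inv,
    status = ifelse(on_inv %in% active, "active", "inactive")
  )
  monitoring <- setNames(
    lapply(seq_len(n_lists), function(i) {
      tibble::tibble(substance_id = sample(substance_id, round(n * list_rate)))
    }),
    paste0("monitoring_list_", seq_len(n_lists))
  )
  list(inventory = inventory, monitoring = monitoring)
}

#' Write a complete fixture bundle to a directory
#'
#' Emits the synthetic registry, degradant predictions, properties, toxicity
#' records, flags and membership lists as CSV files plus a JSON manifest.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed forwarded to every generator.
#' @param ... Passed to [generate_landscape()].
#' @return The directory path, invisibly.
#' @export
generate_fixture_bundle <- function(dir, seed = 1, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  land <- generate_landscape(seed = seed, ...)
  readr::write_csv(land$registry, file.path(dir, "registry.csv"))
  readr::write_csv(land$truth, file.path(dir, "truth.csv"))
  readr::write_csv(generate_degradant_predictions(land$truth),
                   file.path(dir, "degradants.csv"))
  readr::write_csv(generate_property_table(land$truth, seed = seed),
                   file.path(dir, "properties.csv"))
  tox <- generate_tox_records(land$truth, seed = seed)
  readr::write_csv(tox, file.path(dir, "tox_records.csv"))
  feature <- as.integer(land$truth$family %in% c("pfsa", "pasf"))
  flags <- generate_flag_table(land$truth$substance_id, feature, seed = seed)
  readr::write_csv(flags, file.path(dir, "flags.csv"))
  lists <- generate_membership_lists(land$truth$substance_id, seed = seed)
  readr::write_csv(lists$inventory, file.path(dir, "inventory.csv"))
  for (nm in names(lists$monitoring)) {
    readr::write_csv(lists$monitoring[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  manifest <- list(
    seed = seed,
    files = c("registry.csv", "truth.csv", "degradants.csv", "properties.csv",
              "tox_records.csv", "flags.csv", "inventory.csv",
              names(lists$monitoring) |> paste0(".csv")),
    n_substances = nrow(land$registry)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
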