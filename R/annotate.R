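# Exposure and physicochemical annotation, inventory/monitoring tagging and
# the candidate-triage workflow.

#' Physical state at 25 degrees C
#'
#' Gases have boiling points below 25 C; solids have melting points at or
#' above 25 C; liquids have melting points below 25 C and boiling points at
#' or above 25 C. Insufficient data gives `"unknown"`.
#'
#' @param melting_point,boiling_point Numeric vectors in degrees C (`NA`
#'   permitted).
#' @param reference_temp Reference temperature (default 25).
#' @return Character vector in `{"gas", "liquid", "solid", "unknown"}`.
#' @export
physical_state <- function(melting_point, boiling_point, reference_temp = 25) {
  dplyr::case_when(
    !is.na(boiling_point) & boiling_point < reference_temp ~ "gas",
    !is.na(melting_point) & melting_point >= reference_temp ~ "solid",
    !is.na(melting_point) & melting_point < reference_temp &
      !is.na(boiling_point) & boiling_point >= reference_temp ~ "liquid",
    TRUE ~ "unknown"
  )
}

#' Physicochemical designations A-D
#'
#' Substances are designated by physical state, solubility (water solubility
#' at or above `ws_cutoff`, default 0.5 mg/L), volatility (vapour pressure at
#' or above `vp_cutoff`, default 75 mmHg) and high volatility (Henry's law
#' constant at or above `hlc_cutoff`, default 0.1 atm m3/mol, applied to
#' gases):
#' * A - insoluble solids;
#' * B - soluble solids and soluble non-volatile liquids;
#' * C - soluble volatile liquids, insoluble liquids and soluble gases;
#' * D - insoluble gases and highly volatile gases.
#'
#' Substances that cannot be placed (missing properties on every rule path)
#' are `"not determined"`. A soluble gas that is also highly volatile is
#' assigned D (the high-volatility rule takes precedence).
#'
#' @param data Tibble with columns `melting_point`, `boiling_point` (C),
#'   `water_solubility` (mg/L), `vapour_pressure` (mmHg) and `henrys_law`
#'   (atm m3/mol); missing values permitted.
#' @param ws_cutoff,vp_cutoff,hlc_cutoff Rule thresholds (comparisons use
#'   `>=` on the soluble/volatile side).
#' @return `data` with `physical_state` and `designation` columns added.
#' @export
assign_designation <- function(data, ws_cutoff = 0.5, vp_cutoff = 75,
                               hlc_cutoff = 0.1) {
  state <- physical_state(data$melting_point, data$boiling_point)
  soluble <- data$water_solubility >= ws_cutoff
  volatile <- data$vapour_pressure >= vp_cutoff
  high_vol <- data$henrys_law >= hlc_cutoff
  desig <- dplyr::case_when(
    state == "solid" & soluble %in% FALSE ~ "A",
    state == "solid" & soluble %in% TRUE ~ "B",
    state == "liquid" & soluble %in% TRUE & volatile %in% FALSE ~ "B",
    state == "liquid" & soluble %in% TRUE & volatile %in% TRUE ~ "C",
    state == "liquid" & soluble %in% FALSE ~ "C",
    state == "gas" & high_vol %in% TRUE ~ "D",
    state == "gas" & soluble %in% FALSE ~ "D",
    state == "gas" & soluble %in% TRUE ~ "C",
    TRUE ~ "not determined"
  )
  data$physical_state <- state
  data$designation <- desig
  data
}

#' Production-volume bins
#'
#' Maps numeric pounds (or an already-binned source range string) to one of
#' the ten reporting ranges. Boundary values go to the bin whose lower bound
#' they equal.
#'
#' @param value Numeric pounds, or character range strings (returned
#'   unchanged when they match a bin label).
#' @return Character vector of bin labels; `NA` with a warning where
#'   unparseable.
#' @export
bin_production_volume <- function(value) {
  bins <- production_volume_bins()
  if (is.character(value)) {
    out <- ifelse(value %in% bins$label, value, NA_character_)
    suppressWarnings(num <- as.numeric(gsub("[,lbs ]", "", value)))
    needs_num <- is.na(out) & !is.na(num)
    out[needs_num] <- bin_production_volume(num[needs_num])
    if (any(is.na(out) & !is.na(value))) {
      warning("unparseable production volume value(s) set to NA", call. = FALSE)
    }
    return(out)
  }
  numeric_bins <- bins[!is.na(bins$lower), ]
  idx <- findInterval(value, numeric_bins$lower)
  out <- numeric_bins$label[idx]
  out[is.na(value)] <- NA_character_
  out
}

#' The ten production-volume reporting ranges
#'
#' @return Tibble with `label` and numeric `lower` bound (pounds). The source
#'   ranges overlap in places; numeric values are assigned to the narrowest
#'   bin containing them.
#' @export
production_volume_bins <- function() {
  tibble::tibble(
    label = c("<25,000 lbs", "25,000-<100,000 lbs", "100,000-<500,000 lbs",
              "500,000-<1,000,000 lbs", "<1,000,000 lbs",
              "1,000,000-<10,000,000 lbs", "1,000,000-<20,000,000 lbs",
              "20,000,000-<100,000,000 lbs", "50,000,000-<100,000,000 lbs",
              "100,000,000-<1,000,000,000 lbs"),
    lower = c(0, 25e3, 100e3, 500e3, NA, 1e6, NA, 20e6, 50e6, 100e6)
  )
}

#' Tag registry members with list memberships
#'
#' @param registry Registry tibble.
#' @param lists Named list of tibbles/data frames, each with a `substance_id`
#'   column and optionally `structure_key`; names become list tags.
#' @return Tibble with `substance_id`, one logical column per list, and
#'   `n_lists`. Identifiers are matched on `substance_id` first, then on
#'   `structure_key`. List entries matching no registry member are logged
#'   with a message, not an error.
#' @export
tag_lists <- function(registry, lists) {
  stopifnot(!is.null(names(lists)), all(nzchar(names(lists))))
  out <- tibble::tibble(substance_id = registry$substance_id)
  for (nm in names(lists)) {
    lst <- lists[[nm]]
    hit <- registry$substance_id %in% lst$substance_id
    if ("structure_key" %in% names(lst)) {
      hit <- hit | (!is.na(registry$structure_key) &
                      registry$structure_key %in% lst$structure_key)
    }
    matched <- sum(lst$substance_id %in% registry$substance_id)
    if (matched < nrow(lst)) {
      message(nrow(lst) - matched, " identifier(s) on list '", nm,
              "' not matched by substance_id")
    }
    out[[nm]] <- hit
  }
  out$n_lists <- rowSums(as.matrix(out[names(lists)]))
  out
}

# Effect-level types that qualify a record as repeated-dose evidence for the
# data-poor gate.
repeated_dose_effect_types <- function() {
  c("NOAEL", "LOAEL", "LOEL", "NOEL", "NEL", "LEL")
}

#' Data-poor terminal categories
#'
#' A terminal category is data-poor when no member has a repeated-dose
#' toxicity record by the oral or inhalation route with a qualifying reported
#' effect-level type (NOAEL, LOAEL, LOEL, NOEL, NEL or LEL).
#'
#' @param assignments Tibble with `substance_id` and `terminal_label`.
#' @param tox_records Tibble with `substance_id`, `route` and `effect_type`.
#' @return Character vector of data-poor terminal labels.
#' @export
data_poor_categories <- function(assignments, tox_records) {
  qualifying <- tox_records |>
    dplyr::filter(.data$route %in% c("oral", "inhalation"),
                  .data$effect_type %in% repeated_dose_effect_types())
  with_data <- assignments |>
    dplyr::filter(.data$substance_id %in% qualifying$substance_id) |>
    dplyr::pull(.data$terminal_label) |>
    unique()
  setdiff(unique(assignments$terminal_label), with_data)
}

#' Triage terminal categories and nominate data-collection candidates
#'
#' Implements the candidate-prioritization workflow: a category is triaged
#' when it is data-poor, contains at least one inventory member and contains
#' at least one member on a monitoring list. For triaged categories,
#' candidates are nominated in order of preference:
#' 1. centroid/MaxMin picks that are on the inventory;
#' 2. otherwise the inventory member closest to the centroid (by Jaccard
#'    distance, ties to lowest index);
#' 3. otherwise the centroid and MaxMin picks recomputed on the category
#'    restricted to its inventory members.
#'
#' @param assignments Tibble with `substance_id` and `terminal_label`.
#' @param selections Selections tibble from [select_representatives()].
#' @param bits Fingerprint matrix.
#' @param tox_records Toxicity records (see [data_poor_categories()]).
#' @param inventory_ids Substance ids on the inventory (e.g. the active
#'   inventory).
#' @param monitored_ids Substance ids appearing on at least one monitoring
#'   list (e.g. `tags$substance_id[tags$n_lists > 0]` from [tag_lists()]).
#' @param k MaxMin picks for the constrained re-selection fallback.
#' @return Tibble with one row per terminal category: gate outcomes
#'   (`data_poor`, `on_inventory`, `on_monitoring_lists`, `triaged`) and a
#'   list-column `candidates` of tibbles (`substance_id`, `rationale`).
#' @export
triage_categories <- function(assignments, selections, bits, tox_records,
                              inventory_ids, monitored_ids, k = 3) {
  labels <- sort(unique(assignments$terminal_label))
  poor <- data_poor_categories(assignments, tox_records)
  members_of <- split(assignments$substance_id, assignments$terminal_label)
  purrr::map_dfr(labels, function(lab) {
    members <- members_of[[lab]]
    inv <- intersect(members, inventory_ids)
    gates <- tibble::tibble(
      terminal_label = lab,
      data_poor = lab %in% poor,
      on_inventory = length(inv) > 0,
      on_monitoring_lists = length(intersect(members, monitored_ids)) > 0
    )
    gates$triaged <- gates$data_poor & gates$on_inventory & gates$on_monitoring_lists
    if (!gates$triaged) {
      failing <- c("data_poor", "on_inventory", "on_monitoring_lists")[
        !unlist(gates[c("data_poor", "on_inventory", "on_monitoring_lists")])]
      gates$candidates <- list(tibble::tibble(
        substance_id = character(0),
        rationale = character(0)
      ))
      gates$gate_rationale <- paste("not triaged: failed gate(s):",
                               paste(failing, collapse = ", "))
      return(gates)
    }
    picks <- selections$substance_id[selections$terminal_label == lab]
    cands <- NULL
    pick_inv <- intersect(picks, inventory_ids)
    if (length(pick_inv) > 0) {
      cands <- tibble::tibble(
        substance_id = pick_inv,
        rationale = "representative pick on inventory"
      )
    } else if (length(inv) > 0) {
      fp_ids <- intersect(members, rownames(bits))
      centroid <- picks[1]
      inv_fp <- intersect(inv, fp_ids)
      if (length(inv_fp) > 0 && centroid %in% fp_ids) {
        d <- jaccard_distance_matrix(bits[fp_ids, , drop = FALSE])
        dist_to_centroid <- d[inv_fp, centroid]
        nearest <- inv_fp[which.min(dist_to_centroid)]
        cands <- tibble::tibble(
          substance_id = nearest,
          rationale = "nearest inventory member to centroid"
        )
        # Fallback 3 adds the inventory-constrained selection when it differs.
        constrained <- select_representatives(
          assignments[assignments$terminal_label == lab, ], bits,
          k = k, constrain_to = inv
        )$selections
        extra <- setdiff(constrained$substance_id, cands$substance_id)
        if (length(extra) > 0) {
          cands <- dplyr::bind_rows(cands, tibble::tibble(
            substance_id = extra,
            rationale = "inventory-constrained centroid/MaxMin pick"
          ))
        }
      }
    }
    if (is.null(cands)) {
      cands <- tibble::tibble(substance_id = character(0), rationale = character(0))
      gates$gate_rationale <- "triaged but no inventory member with usable structure"
    } else {
      gates$gate_rationale <- "triaged"
    }
    gates$candidates <- list(cands)
    gates
  })
}

#' Data-availability matrix for terminal categories
#'
#' Presence/absence (0/1) of toxicity records by study type and of list
#' memberships, aggregated to terminal categories. Oral and inhalation routes
#' both count here (the heatmap view is broader than the POD workflow).
#'
#' @param assignments Tibble with `substance_id`, `terminal_label`.
#' @param tox_records Tibble with `substance_id`, `route`, `study_type`.
#' @param tags Tibble from [tag_lists()].
#' @return Tibble: one row per terminal category, one 0/1 column per study
#'   type and per list.
#' @export
data_availability_matrix <- function(assignments, tox_records, tags) {
  tox <- tox_records |>
    dplyr::filter(.data$route %in% c("oral", "inhalation")) |>
    dplyr::inner_join(assignments[c("substance_id", "terminal_label")],
                      by = "substance_id") |>
    dplyr::distinct(.data$terminal_label, .data$study_type) |>
    dplyr::mutate(present = 1L) |>
    tidyr::pivot_wider(names_from = "study_type", values_from = "present",
                       values_fill = 0L)
  list_cols <- setdiff(names(tags), c("substance_id", "n_lists"))
  lists <- tags |>
    dplyr::inner_join(assignments[c("substance_id", "terminal_label")],
                      by = "substance_id") |>
    dplyr::group_by(.data$terminal_label) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(list_cols),
                                   ~ as.integer(any(.x))), .groups = "drop")
  tibble::tibble(terminal_label = sort(unique(assignments$terminal_label))) |>
    dplyr::left_join(tox, by = "terminal_label") |>
    dplyr::left_join(lists, by = "terminal_label") |>
    dplyr::mutate(dplyr::across(-"terminal_label", ~ tidyr::replace_na(.x, 0L)))
}
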