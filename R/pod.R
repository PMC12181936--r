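# Harmonization of in vivo effect levels to chronic human-equivalent
# benchmark doses (BMDh) and per-substance/per-category POD summaries.

pod_effect_types <- function() {
  c("NOEL", "NOAEL", "NEL", "NOAEC", "LOAEL", "LOEL", "LOAEC", "LEL")
}

pod_loael_types <- function() c("LOAEL", "LOEL", "LOAEC", "LEL")

pod_study_types <- function() {
  c("short-term", "subchronic", "chronic", "developmental", "reproduction",
    "reproduction developmental", "28-day")
}

pod_units <- function() c("mg/kg-bw/day", "mg/kg")

pod_species <- function() {
  c("rat", "mouse", "rabbit", "dog", "hamster", "guinea pig")
}

#' Duration class per study type
#'
#' Short-term and 28-day studies are treated as subacute; subchronic as
#' subchronic; chronic, developmental and reproduction designs carry no
#' duration extrapolation.
#'
#' @return Tibble with `study_type` and `duration_class`.
#' @export
study_duration_classes <- function() {
  tibble::tibble(
    study_type = pod_study_types(),
    duration_class = c("subacute", "subchronic", "chronic", "chronic",
                       "chronic", "chronic", "subacute")
  )
}

#' Filter raw toxicity records for POD harmonization
#'
#' Retains oral-route records with a qualifying effect-level type (NOEL,
#' NOAEL, NEL, NOAEC, LOAEL, LOEL, LOAEC, LEL), a listed study type, dose
#' units of mg/kg-bw/day or mg/kg, a standardizable species and a positive
#' dose value. Species names are lower-cased and trimmed before matching.
#'
#' @param records Tibble with columns `substance_id`, `route`, `study_type`,
#'   `effect_type`, `value`, `units`, `species` and optionally
#'   `effect_class` (`"noncancer"`/`"repro_dev"`, defaulted to
#'   `"noncancer"`).
#' @return The filtered tibble.
#' @export
filter_tox_records <- function(records) {
  out <- tibble::as_tibble(records)
  if (!"effect_class" %in% names(out)) out$effect_class <- "noncancer"
  out |>
    dplyr::mutate(species = tolower(trimws(.data$species))) |>
    dplyr::filter(
      .data$route == "oral",
      .data$effect_type %in% pod_effect_types(),
      .data$study_type %in% pod_study_types(),
      .data$units %in% pod_units(),
      .data$species %in% pod_species(),
      !is.na(.data$value), .data$value > 0
    )
}

#' Default species body-weight conversion factors
#'
#' Allometric body-weight scaling: the animal dose is divided by
#' `(bw_human / bw_animal)^exponent` to obtain the human-equivalent dose. The
#' body weights and quarter-power exponent are the package's reconstruction
#' of the cited harmonization framework (the source does not print them);
#' pass an explicit table to [harmonize_tox_records()] to override.
#'
#' @param bw_human Human body weight in kg (default 70).
#' @param exponent Allometric exponent (default 0.25).
#' @return Tibble with `species` and `factor`.
#' @export
default_species_factors <- function(bw_human = 70, exponent = 0.25) {
  bw <- c(rat = 0.25, mouse = 0.03, rabbit = 2, dog = 10, hamster = 0.1,
          `guinea pig` = 0.5)
  tibble::tibble(species = names(bw),
                 factor = (bw_human / unname(bw))^exponent)
}

#' Default conceptual-model multipliers
#'
#' Each effect class maps to two conceptual-model multipliers; the BMDh is
#' the mean of the two multiplied human-equivalent values. The default
#' multipliers are a documented reconstruction (the source assigns models per
#' critical effect without printing values) and should be overridden when a
#' calibrated table is available.
#'
#' @return Tibble with `effect_class`, `m1`, `m2`.
#' @export
default_conceptual_models <- function() {
  tibble::tibble(
    effect_class = c("noncancer", "repro_dev"),
    m1 = c(0.5, 0.5),
    m2 = c(1.0, 1.0)
  )
}

#' Harmonize filtered records to human-equivalent benchmark doses
#'
#' Applies, in order, with every factor logged in audit columns:
#' 1. effect-level extrapolation - LOAEL-type records divided by 3;
#' 2. duration extrapolation - subchronic divided by 2, subacute divided
#'    by 5, chronic-class designs unadjusted;
#' 3. species-to-human conversion - division by the species body-weight
#'    factor;
#' 4. benchmark-dose conversion - mean of the two conceptual-model
#'    multipliers applied to the human-equivalent value.
#'
#' Records with an unknown study type, species or effect class are skipped
#' with a message. Multiplying the audit factors together reconstructs the
#' input/output ratio exactly:
#' `bmdh = value / (loael_factor * duration_factor * species_factor) * mean(m1, m2)`.
#'
#' @param records Filtered records from [filter_tox_records()].
#' @param species_factors Tibble (`species`, `factor`), default
#'   [default_species_factors()].
#' @param conceptual_models Tibble (`effect_class`, `m1`, `m2`), default
#'   [default_conceptual_models()].
#' @param loael_factor,subchronic_factor,subacute_factor Extrapolation
#'   divisors (defaults 3, 2, 5).
#' @return The records with `loael_factor`, `duration_factor`,
#'   `species_factor`, `m1`, `m2`, `chronic_noael_equiv`, `human_equiv` and
#'   `bmdh` columns added.
#' @export
harmonize_tox_records <- function(records,
                                  species_factors = default_species_factors(),
                                  conceptual_models = default_conceptual_models(),
                                  loael_factor = 3,
                                  subchronic_factor = 2,
                                  subacute_factor = 5) {
  out <- tibble::as_tibble(records)
  known_study <- out$study_type %in% study_duration_classes()$study_type
  known_species <- out$species %in% species_factors$species
  known_class <- out$effect_class %in% conceptual_models$effect_class
  skip <- !(known_study & known_species & known_class)
  if (any(skip)) {
    message(sum(skip), " record(s) skipped (unknown study type, species or ",
            "effect class)")
    out <- out[!skip, , drop = FALSE]
  }
  duration <- study_duration_classes()
  out <- out |>
    dplyr::left_join(duration, by = "study_type") |>
    dplyr::left_join(dplyr::rename(species_factors, species_factor = "factor"),
                     by = "species") |>
    dplyr::left_join(conceptual_models, by = "effect_class") |>
    dplyr::mutate(
      loael_factor = ifelse(.data$effect_type %in% pod_loael_types(),
                            loael_factor, 1),
      duration_factor = dplyr::case_when(
        .data$duration_class == "subchronic" ~ subchronic_factor,
        .data$duration_class == "subacute" ~ subacute_factor,
        TRUE ~ 1
      ),
      chronic_noael_equiv = .data$value / .data$loael_factor / .data$duration_factor,
      human_equiv = .data$chronic_noael_equiv / .data$species_factor,
      bmdh = (.data$m1 * .data$human_equiv + .data$m2 * .data$human_equiv) / 2
    )
  out
}

#' Lognormal 25th-percentile POD
#'
#' Fits a lognormal by moment matching to a mean and standard deviation
#' (`sigma^2 = log(1 + sd^2/mean^2)`, `mu = log(mean) - sigma^2/2`) and
#' returns its 25th percentile `exp(mu + z_0.25 * sigma)`. With `sd = 0` the
#' distribution is degenerate and the mean is returned.
#'
#' @param mean,sd Moments of the BMDh records (same units).
#' @param prob Percentile (default 0.25).
#' @return The percentile value.
#' @export
lognormal_percentile <- function(mean, sd, prob = 0.25) {
  stopifnot(all(mean > 0, na.rm = TRUE))
  sigma2 <- log(1 + (sd / mean)^2)
  mu <- log(mean) - sigma2 / 2
  out <- exp(mu + stats::qnorm(prob) * sqrt(sigma2))
  out[sd == 0] <- mean[sd == 0]
  out
}

#' Per-substance 25th-percentile PODs
#'
#' Summarizes harmonized BMDh records per substance (within each effect
#' class) by the 25th percentile of a moment-matched lognormal. For
#' substances with fewer than `min_records` records the standard deviation
#' is replaced by the median sd over all substances (within the effect
#' class); substances with a single record use that substitute sd too (their
#' own sd is undefined).
#'
#' @param bmdh_records Tibble from [harmonize_tox_records()].
#' @param min_records Records needed before a substance's own sd is trusted
#'   (default 5).
#' @param prob Percentile (default 0.25).
#' @return Tibble with `substance_id`, `effect_class`, `n_records`,
#'   `mean_bmdh`, `sd_bmdh`, `sd_used`, `pod` and `log10_pod`.
#' @export
substance_pod <- function(bmdh_records, min_records = 5, prob = 0.25) {
  stats_tbl <- bmdh_records |>
    dplyr::group_by(.data$substance_id, .data$effect_class) |>
    dplyr::summarise(
      n_records = dplyr::n(),
      mean_bmdh = mean(.data$bmdh),
      sd_bmdh = ifelse(dplyr::n() > 1, sd(.data$bmdh), NA_real_),
      .groups = "drop"
    ) |>
    dplyr::group_by(.data$effect_class) |>
    dplyr::mutate(
      median_sd = median(.data$sd_bmdh, na.rm = TRUE),
      sd_used = ifelse(.data$n_records < min_records | is.na(.data$sd_bmdh),
                       .data$median_sd, .data$sd_bmdh),
      sd_used = ifelse(is.na(.data$sd_used), 0, .data$sd_used)
    ) |>
    dplyr::ungroup()
  stats_tbl |>
    dplyr::mutate(
      pod = lognormal_percentile(.data$mean_bmdh, .data$sd_used, prob = prob),
      log10_pod = log10(.data$pod)
    ) |>
    dplyr::select(-"median_sd")
}

#' Per-category POD distribution summaries
#'
#' Summarizes log10 POD distributions per terminal category and effect
#' class: quartiles, IQR, range and 1.5 x IQR whiskers (box-and-whisker
#' statistics), with median chain length attached when available.
#'
#' @param pods Tibble from [substance_pod()].
#' @param assignments Tibble with `substance_id`, `terminal_label` and
#'   optionally `chain_length`.
#' @return Tibble with one row per (terminal category, effect class).
#' @export
category_pod_summary <- function(pods, assignments) {
  joined <- dplyr::inner_join(pods, assignments, by = "substance_id")
  joined |>
    dplyr::group_by(.data$terminal_label, .data$effect_class) |>
    dplyr::summarise(
      n_substances = dplyr::n(),
      log10_pod_median = median(.data$log10_pod),
      log10_pod_q1 = unname(quantile(.data$log10_pod, 0.25, type = 7)),
      log10_pod_q3 = unname(quantile(.data$log10_pod, 0.75, type = 7)),
      log10_pod_min = min(.data$log10_pod),
      log10_pod_max = max(.data$log10_pod),
      chain_length_median = if ("chain_length" %in% names(joined))
        median(.data$chain_length) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      log10_pod_iqr = .data$log10_pod_q3 - .data$log10_pod_q1,
      whisker_low = pmax(.data$log10_pod_min,
                         .data$log10_pod_q1 - 1.5 * .data$log10_pod_iqr),
      whisker_high = pmin(.data$log10_pod_max,
                          .data$log10_pod_q3 + 1.5 * .data$log10_pod_iqr)
    )
}
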