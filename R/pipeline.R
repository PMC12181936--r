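# End-to-end orchestration: registry -> categories -> threshold -> terminal
# categories -> representative selections, and the candidate-triage run.

#' Default pipeline configuration
#'
#' All thresholds of the categorization workflow in one place: chain-length
#' bin threshold 7; objective-threshold percentile 15; at most 2
#' subcategorization generations; 3 MaxMin picks for categories larger
#' than 5; hybrid-rule limits 300/10; dendrogram cut fraction 0.7.
#'
#' @param ... Named overrides of any default.
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(...) {
  config <- list(
    chain_threshold = 7,
    percentile = 15,
    max_generations = 2,
    maxmin_k = 3,
    min_size_for_maxmin = 5,
    max_first_class = 300,
    min_second_class = 10,
    cut_height_frac = 0.7,
    coverage_targets = c(0.5, 0.8),
    n_bits = 1024,
    split_ties = FALSE
  )
  overrides <- list(...)
  stopifnot(all(names(overrides) %in% names(config)))
  utils::modifyList(config, overrides)
}

#' Run the full categorization pipeline
#'
#' Executes, in order: primary class assignment with the hybrid membership
#' rule; chain-length computation and secondary binning; fingerprinting;
#' within/between-category median distances and the objective threshold;
#' iterative Ward subcategorization to terminal categories; and centroid +
#' MaxMin representative selection with coverage curves.
#'
#' @param registry Registry tibble (see [read_substances()]), or the list
#'   returned by [generate_landscape()].
#' @param config Configuration from [pipeline_config()].
#' @param tau Optional fixed objective threshold; computed from the data
#'   when `NULL`.
#' @return List with `assignments` (per-substance categories incl.
#'   `terminal_label`), `fingerprints`, `threshold_report` (within/between
#'   medians and tau), `selections`, `coverage`, `coverage_summary` and the
#'   resolved `config`.
#' @export
run_categorization_pipeline <- function(registry, config = pipeline_config(),
                                        tau = NULL) {
  if (is.list(registry) && !is.data.frame(registry) && "registry" %in% names(registry)) {
    registry <- registry$registry
  }
  assignments <- categorize_substances(
    registry,
    chain_threshold = config$chain_threshold,
    max_first_class = config$max_first_class,
    min_second_class = config$min_second_class
  )
  bits <- suppressWarnings(morgan_fingerprints(registry, n_bits = config$n_bits))
  within <- within_category_medians(bits, assignments)
  between <- between_category_medians(bits, assignments)
  if (is.null(tau)) {
    tau <- objective_threshold(between, percentile = config$percentile)
  }
  assignments <- derive_terminal_categories(
    assignments, bits, tau,
    max_generations = config$max_generations,
    split_ties = config$split_ties,
    cut_height_frac = config$cut_height_frac
  )
  sel <- select_representatives(
    assignments, bits,
    k = config$maxmin_k,
    min_size_for_maxmin = config$min_size_for_maxmin,
    coverage_targets = config$coverage_targets
  )
  list(
    assignments = assignments,
    fingerprints = bits,
    threshold_report = list(within_medians = within,
                            between_medians = between,
                            percentile = config$percentile,
                            tau = tau),
    selections = sel$selections,
    coverage = sel$coverage,
    coverage_summary = sel$summary,
    config = config
  )
}

#' Run the candidate-triage workflow on pipeline outputs
#'
#' @param pipeline Result of [run_categorization_pipeline()].
#' @param tox_records Raw toxicity records (`substance_id`, `route`,
#'   `effect_type`, ...).
#' @param inventory Tibble with `substance_id` and `status`
#'   (`"active"`/`"inactive"`), or a character vector of inventory ids.
#' @param monitoring Named list of monitoring-list tibbles (each with
#'   `substance_id`).
#' @param active_only Constrain the inventory gate to active members.
#' @return Triage tibble from [triage_categories()].
#' @export
run_triage <- function(pipeline, tox_records, inventory, monitoring,
                       active_only = FALSE) {
  missing_inputs <- c(
    if (is.null(tox_records)) "tox_records",
    if (is.null(inventory)) "inventory",
    if (is.null(monitoring)) "monitoring"
  )
  if (length(missing_inputs) > 0) {
    stop("missing triage input(s): ", paste(missing_inputs, collapse = ", "),
         call. = FALSE)
  }
  if (is.data.frame(inventory)) {
    inventory_ids <- if (active_only) {
      inventory$substance_id[inventory$status == "active"]
    } else {
      inventory$substance_id
    }
  } else {
    inventory_ids <- inventory
  }
  monitored_ids <- unique(unlist(lapply(monitoring, `[[`, "substance_id")))
  triage_categories(
    pipeline$assignments, pipeline$selections, pipeline$fingerprints,
    tox_records, inventory_ids, monitored_ids
  )
}
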