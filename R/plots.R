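# ggplot2 views of the main result types.

#' Plot diversity-coverage curves
#'
#' Coverage fraction as a function of the number of diverse picks, one line
#' per terminal category.
#'
#' @param coverage Coverage tibble from [select_representatives()] (or the
#'   `coverage` element of a pipeline run).
#' @param categories Optional subset of terminal labels to show.
#' @return A ggplot object.
#' @export
plot_coverage_curves <- function(coverage, categories = NULL) {
  if (!is.null(categories)) {
    coverage <- coverage[coverage$terminal_label %in% categories, ]
  }
  ggplot2::ggplot(coverage,
                  ggplot2::aes(x = .data$k, y = .data$coverage_fraction,
                               colour = .data$terminal_label)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "diverse picks", y = "structural diversity captured",
                  colour = "terminal category") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::theme_minimal()
}

#' Plot pairwise-distance ECDFs per category
#'
#' @param bits Fingerprint matrix.
#' @param assignments Assignment tibble.
#' @param category_col Category column to facet by.
#' @return A ggplot object.
#' @export
plot_distance_ecdf <- function(bits, assignments,
                               category_col = "secondary_category") {
  groups <- split(assignments$substance_id, assignments[[category_col]])
  groups <- groups[lengths(groups) >= 2]
  df <- purrr::imap_dfr(groups, function(ids, cat) {
    ids <- intersect(ids, rownames(bits))
    if (length(ids) < 2) return(NULL)
    d <- jaccard_distance_matrix(bits[ids, , drop = FALSE])
    dplyr::mutate(distance_ecdf(upper_tri_values(d)), category = cat)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$cdf,
                                   colour = .data$category)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Jaccard distance", y = "ECDF", colour = "category") +
    ggplot2::theme_minimal()
}

#' Box-and-whisker plot of category POD distributions
#'
#' @param pods Per-substance PODs from [substance_pod()].
#' @param assignments Assignment tibble with `terminal_label` (and
#'   optionally `chain_length` for the strip overlay colour).
#' @return A ggplot object (log10 POD by terminal category, one panel per
#'   effect class).
#' @export
plot_category_pods <- function(pods, assignments) {
  df <- dplyr::inner_join(pods, assignments, by = "substance_id")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$terminal_label,
                                        y = .data$log10_pod)) +
    ggplot2::geom_boxplot(outlier.shape = NA)
  p <- if ("chain_length" %in% names(df)) {
    p + ggplot2::geom_jitter(ggplot2::aes(colour = .data$chain_length),
                             width = 0.15, height = 0)
  } else {
    p + ggplot2::geom_jitter(width = 0.15, height = 0)
  }
  p +
    ggplot2::facet_wrap(~effect_class, scales = "free_x") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "log10 POD (mg/kg-bw/day)",
                  colour = "chain length") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pfas_category_model <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$class, .data$recall),
                                   y = .data$recall)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "held-out recall") +
    ggplot2::theme_minimal()
}
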