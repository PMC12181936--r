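# Structural-feature enrichment against qualitative assay-derived (NAM)
# flags: QC filtering, binarization, one-sided Fisher enrichment, landscape
# prediction and performance scoring.

#' Drop substances failing analytical quality control
#'
#' @param flags Tibble with a logical/0-1 `qc_pass` column; one row per
#'   substance.
#' @return The rows passing QC; all-fail input yields an empty tibble with a
#'   warning.
#' @export
filter_by_qc <- function(flags) {
  stopifnot("qc_pass" %in% names(flags))
  out <- flags[as.logical(flags$qc_pass) %in% TRUE, , drop = FALSE]
  if (nrow(out) == 0) warning("no substances passed QC", call. = FALSE)
  tibble::as_tibble(out)
}

#' Binarize graded flags
#'
#' Flag values are graded 0 (low concern), 1 (medium confidence), 2 (high
#' confidence). The positive set is configurable: medium-plus-high (default)
#' or high-only. Missing values stay missing and are excluded from
#' contingency tables downstream.
#'
#' @param values Numeric/integer vector of flag values in `{0, 1, 2, NA}`.
#' @param positive Values counted as positive (default `c(1, 2)`).
#' @return Integer 0/1 vector with `NA` preserved.
#' @export
binarize_flags <- function(values, positive = c(1, 2)) {
  out <- ifelse(values %in% positive, 1L, 0L)
  out[is.na(values)] <- NA_integer_
  out
}

#' Binarize toxicokinetic half-life bins
#'
#' Half-life bins run 1 (fastest, half-life of 12 h or less) to 4 (slowest,
#' 2 months or more); only bin 4 is scored positive.
#'
#' @param bins Integer vector with values in 1..4.
#' @return Integer 0/1 vector (`NA` preserved).
#' @export
binarize_tk_bins <- function(bins) {
  ok <- is.na(bins) | (bins %in% 1:4)
  if (!all(ok)) stop("TK bins must be in 1..4", call. = FALSE)
  out <- as.integer(bins == 4)
  out[is.na(bins)] <- NA_integer_
  out
}

#' Feature enrichment by one-sided Fisher's exact test
#'
#' For each binary structural feature, a 2x2 contingency table against the
#' binary flag is formed (`a` = feature present and flag positive, the true
#' positives; `b` = present/negative; `c` = absent/positive; `d` =
#' absent/negative). The odds ratio is `ad/bc`, with a Haldane-Anscombe 0.5
#' added to every cell when any cell is zero (set
#' `zero_cell_correction = FALSE` for the raw, possibly infinite, ratio).
#' The p-value is the one-sided Fisher exact probability in the enrichment
#' direction. A feature is enriched when the odds ratio is at least
#' `or_min` (3), the p-value is below `p_max` (0.05) and the true positives
#' are at least `tp_min` (3). A constant feature or flag gives p = 1 and is
#' never enriched. Substances with a missing flag are excluded.
#'
#' @param features 0/1 matrix (substances x features, column names =
#'   feature names) or a tibble with a `substance_id` column and feature
#'   columns.
#' @param flag Binary vector aligned with the feature rows (`NA` allowed).
#' @param flag_name Label recorded in the output.
#' @param or_min,p_max,tp_min Enrichment criteria.
#' @param zero_cell_correction Apply the 0.5 correction (default `TRUE`).
#' @return Tibble with `feature`, `flag`, `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `p_value`, `enriched`.
#' @export
enrich_features <- function(features, flag, flag_name = "flag",
                            or_min = 3, p_max = 0.05, tp_min = 3,
                            zero_cell_correction = TRUE) {
  if (is.data.frame(features)) {
    features <- as.matrix(features[setdiff(names(features), "substance_id")])
  }
  stopifnot(nrow(features) == length(flag))
  keep <- !is.na(flag)
  features <- features[keep, , drop = FALSE]
  y <- as.integer(flag[keep]) == 1L
  purrr::map_dfr(colnames(features), function(feat) {
    x <- features[, feat] == 1
    a <- sum(x & y); b <- sum(x & !y); c_ <- sum(!x & y); d <- sum(!x & !y)
    constant <- (a + b == 0) || (c_ + d == 0) || (a + c_ == 0) || (b + d == 0)
    if (constant) {
      p <- 1
    } else {
      p <- fisher.test(matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE),
                       alternative = "greater")$p.value
    }
    if (zero_cell_correction && any(c(a, b, c_, d) == 0)) {
      or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
    } else {
      or <- (a * d) / (b * c_)
    }
    tibble::tibble(
      feature = feat, flag = flag_name,
      a = a, b = b, c = c_, d = d,
      odds_ratio = or, p_value = p,
      enriched = !constant & or >= or_min & p < p_max & a >= tp_min
    )
  })
}

#' Predict flags across a landscape from enriched features
#'
#' A substance is predicted positive for a flag when it carries at least one
#' feature enriched for that flag. A flag with no enriched features yields an
#' all-negative prediction column with a message.
#'
#' @param features 0/1 matrix (substances x features).
#' @param enrichment Tibble from [enrich_features()] (possibly several flags
#'   row-bound together).
#' @return Tibble with `substance_id` (row names of `features`, or row
#'   index) and one 0/1 column per flag.
#' @export
predict_flags <- function(features, enrichment) {
  if (is.data.frame(features)) {
    ids <- features$substance_id
    features <- as.matrix(features[setdiff(names(features), "substance_id")])
  } else {
    ids <- rownames(features) %||% as.character(seq_len(nrow(features)))
  }
  out <- tibble::tibble(substance_id = ids)
  for (fl in unique(enrichment$flag)) {
    feats <- enrichment$feature[enrichment$flag == fl & enrichment$enriched]
    feats <- intersect(feats, colnames(features))
    if (length(feats) == 0) {
      message("flag '", fl, "' has no enriched features; predictions all negative")
      out[[fl]] <- 0L
    } else {
      out[[fl]] <- as.integer(rowSums(features[, feats, drop = FALSE]) > 0)
    }
  }
  out
}

#' Sensitivity, specificity and AUC for binary predictions
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP); for hard 0/1
#' predictions the ROC AUC reduces to balanced accuracy,
#' `(sensitivity + specificity) / 2`. With single-class actuals the AUC (and
#' the undefined rate) are `NA`.
#'
#' @param actual,predicted Binary vectors (`NA` pairs dropped).
#' @return One-row tibble with `n`, `sensitivity`, `specificity`, `roc_auc`.
#' @export
prediction_metrics <- function(actual, predicted) {
  keep <- !is.na(actual) & !is.na(predicted)
  a <- as.integer(actual[keep]); p <- as.integer(predicted[keep])
  tp <- sum(a == 1 & p == 1); fn <- sum(a == 1 & p == 0)
  tn <- sum(a == 0 & p == 0); fp <- sum(a == 0 & p == 1)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  auc <- if (!is.na(sens) && !is.na(spec)) (sens + spec) / 2 else NA_real_
  tibble::tibble(n = sum(keep), sensitivity = sens, specificity = spec,
                 roc_auc = auc)
}
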