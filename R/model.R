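# Operationalizing terminal categories as a supervised classifier so new
# substances can be assigned without re-running the landscape categorization.

#' Aggregate small terminal categories
#'
#' Terminal categories with fewer than `min_size` members are merged into a
#' single `"miscellaneous"` class so the classifier has trainable classes.
#'
#' @param labels Character vector of terminal labels.
#' @param min_size Minimum class membership (default 10).
#' @return Character vector with small classes replaced by
#'   `"miscellaneous"`; warns when every class was merged.
#' @export
aggregate_small_categories <- function(labels, min_size = 10) {
  counts <- table(labels)
  small <- names(counts)[counts < min_size]
  out <- ifelse(labels %in% small, "miscellaneous", labels)
  if (all(out == "miscellaneous")) {
    warning("all categories fell below min_size; single miscellaneous class",
            call. = FALSE)
  }
  out
}

#' Build the classifier feature matrix
#'
#' Combines fingerprint bits, chain length and the ordinal-encoded primary
#' category. The encoder (category level map, per-column means and standard
#' deviations for standardization) is fitted on the supplied data when
#' `encoder` is `NULL` and must be reused, not refitted, for test or new
#' data; unseen primary categories map to a reserved code 0 with a warning,
#' and constant columns standardize to zero.
#'
#' @param bits Fingerprint matrix (rows named by substance id).
#' @param assignments Tibble with `substance_id`, `primary_category`,
#'   `chain_length`.
#' @param encoder `NULL` to fit, or an encoder from a previous call.
#' @param standardize Standardize features to zero mean/unit variance
#'   (default `TRUE`, matching the source pipeline; set `FALSE` to pass raw
#'   bits).
#' @return List with `features` (numeric matrix, rows aligned to
#'   `assignments` rows present in `bits`), `substance_id` and `encoder`.
#' @export
build_category_features <- function(bits, assignments, encoder = NULL,
                                    standardize = TRUE) {
  asn <- assignments[assignments$substance_id %in% rownames(bits), ]
  x_bits <- bits[asn$substance_id, , drop = FALSE]
  colnames(x_bits) <- paste0("fp_", seq_len(ncol(x_bits)))
  fit <- is.null(encoder)
  if (fit) {
    encoder <- list(levels = sort(unique(asn$primary_category)),
                    standardize = standardize)
  }
  code <- match(asn$primary_category, encoder$levels)
  if (anyNA(code)) {
    warning(sum(is.na(code)), " substance(s) with unseen primary category ",
            "mapped to reserved code 0", call. = FALSE)
    code[is.na(code)] <- 0L
  }
  x <- cbind(primary_code = code, chain_length = asn$chain_length, x_bits)
  if (encoder$standardize) {
    num_cols <- setdiff(colnames(x), "primary_code")
    if (fit) {
      encoder$center <- colMeans(x[, num_cols, drop = FALSE])
      s <- apply(x[, num_cols, drop = FALSE], 2, sd)
      encoder$scale <- ifelse(is.na(s) | s == 0, 1, s)
    }
    x[, num_cols] <- sweep(sweep(x[, num_cols, drop = FALSE], 2,
                                 encoder$center), 2, encoder$scale, "/")
  }
  list(features = x, substance_id = asn$substance_id, encoder = encoder)
}

balanced_accuracy <- function(actual, predicted) {
  classes <- unique(actual)
  mean(vapply(classes, function(cl) {
    mean(predicted[actual == cl] == cl)
  }, numeric(1)))
}

# Stratified fold ids (1..k) per observation, deterministic given the RNG
# state.
stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    folds[idx] <- rep_len(sample(k), length(idx))
  }
  folds
}

#' Train and evaluate the terminal-category classifier
#'
#' Random-forest classifier over fingerprints, chain length and the encoded
#' primary category. The data is split 80/20 with stratification on the
#' label; a majority-class baseline is scored; a small random hyperparameter
#' search (over the number of trees) is run under stratified k-fold
#' cross-validation on the training split; the best configuration is scored
#' on the held-out test split and finally refit on all data. Balanced
#' accuracy (macro-averaged recall) is the metric throughout. The whole
#' procedure is deterministic given `seed`.
#'
#' @param bits Fingerprint matrix.
#' @param assignments Tibble with `substance_id`, `primary_category`,
#'   `chain_length` and `terminal_label` columns.
#' @param min_size Small-category aggregation threshold, see
#'   [aggregate_small_categories()].
#' @param seed Integer seed controlling the split, search and forests.
#' @param test_prop Held-out fraction (default 0.2).
#' @param cv_folds Cross-validation folds (default 5).
#' @param trees_grid Candidate numbers of trees (default 100-400).
#' @param n_candidates Random-search draws from the grid (default 4).
#' @param standardize Standardize features (see
#'   [build_category_features()]).
#' @return A `pfas_category_model` object: the fitted forest, the encoder,
#'   the label map and a report (CV mean/sd, test and baseline balanced
#'   accuracy, per-class recall, hyperparameters, seed). Inspect with
#'   [tidy()]/[glance()], apply with [predict()].
#' @export
fit_category_model <- function(bits, assignments, min_size = 10, seed = 1,
                               test_prop = 0.2, cv_folds = 5,
                               trees_grid = c(100, 200, 300, 400),
                               n_candidates = 4, standardize = TRUE) {
  stopifnot("terminal_label" %in% names(assignments))
  asn <- assignments[assignments$substance_id %in% rownames(bits), ]
  labels <- aggregate_small_categories(asn$terminal_label, min_size = min_size)
  counts <- table(labels)
  if (any(counts < 2)) {
    stop("class(es) with a single member: ",
         paste(names(counts)[counts < 2], collapse = ", "),
         "; lower min_size or aggregate further before training",
         call. = FALSE)
  }
  if (length(counts) < 2) {
    stop("need at least 2 classes after aggregation", call. = FALSE)
  }
  set.seed(seed)
  built <- build_category_features(bits, asn, standardize = standardize)
  x <- built$features
  y <- factor(labels)

  # Stratified 80/20 split.
  test_idx <- unlist(lapply(split(seq_along(y), y), function(idx) {
    n_test <- max(1, round(length(idx) * test_prop))
    sample(idx, n_test)
  }), use.names = FALSE)
  train_idx <- setdiff(seq_along(y), test_idx)

  fit_rf <- function(idx, num_trees, rf_seed) {
    ranger::ranger(
      x = x[idx, , drop = FALSE], y = droplevels(y[idx]),
      num.trees = num_trees, min.node.size = 2,
      mtry = floor(sqrt(ncol(x))), num.threads = 1, seed = rf_seed
    )
  }
  baseline_class <- names(which.max(table(y[train_idx])))

  candidates <- sample(trees_grid, min(n_candidates, length(trees_grid)))
  folds <- stratified_folds(as.character(y[train_idx]), cv_folds)
  cv_scores <- purrr::map(candidates, function(nt) {
    vapply(seq_len(cv_folds), function(f) {
      tr <- train_idx[folds != f]
      va <- train_idx[folds == f]
      rf <- fit_rf(tr, nt, rf_seed = seed + f)
      pred <- predict(rf, x[va, , drop = FALSE], num.threads = 1)$predictions
      balanced_accuracy(as.character(y[va]), as.character(pred))
    }, numeric(1))
  })
  cv_means <- vapply(cv_scores, mean, numeric(1))
  best <- which.max(cv_means)
  best_trees <- candidates[best]

  rf_final <- fit_rf(train_idx, best_trees, rf_seed = seed)
  test_pred <- as.character(
    predict(rf_final, x[test_idx, , drop = FALSE], num.threads = 1)$predictions)
  test_actual <- as.character(y[test_idx])
  per_class <- tibble::tibble(
    class = sort(unique(test_actual)),
    n_test = as.integer(table(test_actual)[sort(unique(test_actual))]),
    recall = vapply(sort(unique(test_actual)), function(cl) {
      mean(test_pred[test_actual == cl] == cl)
    }, numeric(1))
  )
  report <- list(
    n_classes = nlevels(y),
    n_train = length(train_idx), n_test = length(test_idx),
    cv_balanced_accuracy_mean = cv_means[best],
    cv_balanced_accuracy_sd = sd(cv_scores[[best]]),
    test_balanced_accuracy = balanced_accuracy(test_actual, test_pred),
    baseline_balanced_accuracy = balanced_accuracy(
      test_actual, rep(baseline_class, length(test_actual))),
    per_class_recall = per_class,
    hyperparameters = list(num_trees = best_trees, min_node_size = 2,
                           mtry = floor(sqrt(ncol(x))),
                           candidates = candidates),
    seed = seed
  )
  model_all <- fit_rf(seq_along(y), best_trees, rf_seed = seed)
  structure(
    list(forest = model_all, encoder = built$encoder,
         classes = levels(y), min_size = min_size, report = report),
    class = "pfas_category_model"
  )
}

#' Predict terminal categories for new substances
#'
#' @param object A `pfas_category_model`.
#' @param bits Fingerprint matrix for the new substances.
#' @param assignments Tibble with `substance_id`, `primary_category` and
#'   `chain_length` for the new substances.
#' @param ... Unused.
#' @return Tibble with `substance_id` and `terminal_label`.
#' @export
predict.pfas_category_model <- function(object, bits, assignments, ...) {
  built <- build_category_features(bits, assignments, encoder = object$encoder)
  pred <- predict(object$forest, built$features, num.threads = 1)$predictions
  tibble::tibble(substance_id = built$substance_id,
                 terminal_label = as.character(pred))
}

#' @export
print.pfas_category_model <- function(x, ...) {
  r <- x$report
  cat("Terminal-category random forest:", r$n_classes, "classes\n")
  cat(sprintf("  CV balanced accuracy:   %.3f (sd %.3f)\n",
              r$cv_balanced_accuracy_mean, r$cv_balanced_accuracy_sd))
  cat(sprintf("  Test balanced accuracy: %.3f (baseline %.3f)\n",
              r$test_balanced_accuracy, r$baseline_balanced_accuracy))
  invisible(x)
}

#' Per-class recall of a fitted category model
#'
#' @param x A `pfas_category_model`.
#' @param ... Unused.
#' @return Tibble with `class`, `n_test`, `recall`.
#' @export
tidy.pfas_category_model <- function(x, ...) {
  x$report$per_class_recall
}

#' One-row summary of a fitted category model
#'
#' @param x A `pfas_category_model`.
#' @param ... Unused.
#' @return One-row tibble with class counts, CV/test/baseline balanced
#'   accuracy, chosen tree count and seed.
#' @export
glance.pfas_category_model <- function(x, ...) {
  r <- x$report
  tibble::tibble(
    n_classes = r$n_classes, n_train = r$n_train, n_test = r$n_test,
    cv_balanced_accuracy = r$cv_balanced_accuracy_mean,
    cv_balanced_accuracy_sd = r$cv_balanced_accuracy_sd,
    test_balanced_accuracy = r$test_balanced_accuracy,
    baseline_balanced_accuracy = r$baseline_balanced_accuracy,
    num_trees = r$hyperparameters$num_trees,
    seed = r$seed
  )
}
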