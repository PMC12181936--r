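# Fingerprints, Jaccard distances, the objective distance threshold and
# iterative subcategorization to terminal categories.

#' Circular (Morgan-style) fingerprints
#'
#' Radius-3 extended-connectivity fingerprints folded to `n_bits` bits
#' (default 1024), one row per substance. Identical structures always yield
#' identical rows, and rows are invariant to SMILES atom ordering.
#'
#' @param data Tibble with identifier and SMILES columns (a registry or an
#'   assignment table works directly).
#' @param id_col,smiles_col Column names.
#' @param n_bits Folded fingerprint length.
#' @return A 0/1 integer matrix with substance identifiers as row names.
#'   Unparseable structures are omitted with a warning.
#' @export
morgan_fingerprints <- function(data, id_col = "substance_id",
                                smiles_col = "qsar_ready_smiles",
                                n_bits = 1024) {
  smiles <- data[[smiles_col]]
  ids <- as.character(data[[id_col]])
  raw <- chem_ecfp6(smiles)
  parsed <- attr(raw, "parsed")
  if (any(!parsed)) {
    warning(sum(!parsed), " structure(s) could not be parsed; fingerprint rows omitted",
            call. = FALSE)
  }
  if (nrow(raw) == 0) {
    return(matrix(integer(0), nrow = 0, ncol = n_bits,
                  dimnames = list(character(0), NULL)))
  }
  stopifnot(ncol(raw) %% n_bits == 0)
  folds <- ncol(raw) / n_bits
  bits <- matrix(0L, nrow = nrow(raw), ncol = n_bits)
  for (f in seq_len(folds)) {
    bits <- bits | raw[, ((f - 1) * n_bits + 1):(f * n_bits), drop = FALSE]
  }
  bits <- matrix(as.integer(bits), nrow = nrow(raw), ncol = n_bits)
  rownames(bits) <- ids[parsed]
  bits
}

#' Jaccard distance matrix from binary fingerprints
#'
#' `d[i, j] = 1 - |bits_i AND bits_j| / |bits_i OR bits_j|`; two all-zero
#' rows are at distance 0 by convention.
#'
#' @param bits 0/1 matrix, rows = substances (as from
#'   [morgan_fingerprints()]).
#' @return Symmetric distance matrix in `[0, 1]` with the same row names.
#' @export
jaccard_distance_matrix <- function(bits) {
  bits <- matrix(as.numeric(bits != 0), nrow = nrow(bits),
                 dimnames = dimnames(bits))
  inter <- tcrossprod(bits)
  sizes <- rowSums(bits)
  union <- outer(sizes, sizes, "+") - inter
  d <- 1 - inter / union
  d[union == 0] <- 0
  diag(d) <- 0
  rownames(d) <- colnames(d) <- rownames(bits)
  d
}

upper_tri_values <- function(d) d[upper.tri(d)]

#' Median within-category pairwise distances
#'
#' @param bits Fingerprint matrix covering (at least) all assigned substances.
#' @param assignments Tibble with `substance_id` and a category column.
#' @param category_col Name of the category column (default
#'   `"secondary_category"`).
#' @return Tibble with `category`, `n` and `median_distance`. Singleton
#'   categories are excluded with a message, as are substances without a
#'   fingerprint row.
#' @export
within_category_medians <- function(bits, assignments,
                                    category_col = "secondary_category") {
  assignments <- assignments[assignments$substance_id %in% rownames(bits), ]
  split_ids <- split(assignments$substance_id, assignments[[category_col]])
  singles <- names(split_ids)[lengths(split_ids) < 2]
  if (length(singles) > 0) {
    message("excluding singleton categor", if (length(singles) == 1) "y: " else "ies: ",
            paste(singles, collapse = "; "))
  }
  split_ids <- split_ids[lengths(split_ids) >= 2]
  purrr::imap_dfr(split_ids, function(ids, cat) {
    d <- jaccard_distance_matrix(bits[ids, , drop = FALSE])
    tibble::tibble(category = cat, n = length(ids),
                   median_distance = median(upper_tri_values(d)))
  })
}

#' Enumerate between-category pairs
#'
#' All unordered pairs of secondary categories whose primary roots differ;
#' pairs sharing a primary root (for example the two chain bins of one
#' primary) are excluded.
#'
#' @param categories Character vector of secondary category labels, or a
#'   tibble with `secondary_category` and `primary_category` columns.
#' @param primaries Primary roots aligned with `categories` (ignored when
#'   `categories` is a tibble). When missing, the root is taken as the label
#'   with its final `", <bin>"` component removed.
#' @return Tibble with `category_a`, `category_b`.
#' @export
between_category_pairs <- function(categories, primaries = NULL) {
  if (is.data.frame(categories)) {
    tab <- dplyr::distinct(categories, .data$secondary_category, .data$primary_category)
    cats <- tab$secondary_category
    primaries <- tab$primary_category
  } else {
    cats <- unique(categories)
    if (is.null(primaries)) {
      primaries <- sub(",\\s*[^,]+$", "", cats)
    } else {
      primaries <- primaries[match(cats, categories)]
    }
  }
  if (length(cats) < 2) {
    return(tibble::tibble(category_a = character(), category_b = character()))
  }
  idx <- utils::combn(seq_along(cats), 2)
  keep <- primaries[idx[1, ]] != primaries[idx[2, ]]
  tibble::tibble(category_a = cats[idx[1, keep]],
                 category_b = cats[idx[2, keep]])
}

#' Median between-category pairwise distances
#'
#' For every pair from [between_category_pairs()], the median of the
#' cross-category pairwise distances (distances within either member category
#' are not included).
#'
#' @param bits Fingerprint matrix.
#' @param assignments Tibble with `substance_id`, `secondary_category` and
#'   `primary_category`.
#' @return Tibble with `category_a`, `category_b` and `median_distance`.
#' @export
between_category_medians <- function(bits, assignments) {
  assignments <- assignments[assignments$substance_id %in% rownames(bits), ]
  pairs <- between_category_pairs(assignments)
  split_ids <- split(assignments$substance_id, assignments$secondary_category)
  purrr::pmap_dfr(pairs, function(category_a, category_b) {
    ids_a <- split_ids[[category_a]]
    ids_b <- split_ids[[category_b]]
    d <- jaccard_distance_matrix(bits[c(ids_a, ids_b), , drop = FALSE])
    cross <- d[seq_along(ids_a), length(ids_a) + seq_along(ids_b), drop = FALSE]
    tibble::tibble(category_a = category_a, category_b = category_b,
                   median_distance = median(cross))
  })
}

#' Objective distance threshold
#'
#' A stated percentile (default the 15th) of the distribution of
#' between-category median distances, using the linear-interpolation quantile
#' convention (R type 7).
#'
#' @param between_medians Numeric vector of between-category medians, or the
#'   tibble from [between_category_medians()].
#' @param percentile Percentile in (0, 100), default 15.
#' @return The threshold, a scalar in `[0, 1]`.
#' @export
objective_threshold <- function(between_medians, percentile = 15) {
  if (is.data.frame(between_medians)) {
    between_medians <- between_medians$median_distance
  }
  if (length(between_medians) == 0) {
    stop("no between-category medians supplied", call. = FALSE)
  }
  unname(quantile(between_medians, probs = percentile / 100, type = 7))
}

#' Empirical cumulative distribution function sample points
#'
#' `F(x) =` (number of values `<= x`) `/ n`, evaluated at each distinct value.
#'
#' @param values Non-empty numeric vector.
#' @return Tibble with `value` (sorted distinct values) and `cdf`.
#' @export
distance_ecdf <- function(values) {
  stopifnot(length(values) > 0)
  f <- stats::ecdf(values)
  v <- sort(unique(values))
  tibble::tibble(value = v, cdf = f(v))
}

#' Ward subcategorization of a distance matrix
#'
#' Agglomerative hierarchical clustering with Ward's criterion on the
#' precomputed distance matrix, cut at `cut_height_frac` times the maximum
#' merge height (the conventional dendrogram colouring threshold) to obtain
#' the first-generation clusters. Cluster labels are 1-based in order of
#' first appearance.
#'
#' @param d Symmetric distance matrix (row names = substance ids).
#' @param cut_height_frac Fraction of the maximum merge height at which to
#'   cut (default 0.7).
#' @return Integer vector of cluster labels named by substance id.
#' @export
ward_subcategorize <- function(d, cut_height_frac = 0.7) {
  n <- nrow(d)
  if (is.null(n) || n < 2) stop("need at least 2 members to cluster", call. = FALSE)
  hc <- hclust(as.dist(d), method = "ward.D2")
  h_max <- max(hc$height)
  labels <- if (h_max <= 0) {
    rep(1L, n)
  } else {
    cutree(hc, h = cut_height_frac * h_max)
  }
  # Renumber in order of first appearance for determinism.
  labels <- match(labels, unique(labels))
  names(labels) <- rownames(d)
  labels
}

#' Derive terminal categories by iterative subcategorization
#'
#' Any category whose within-category median pairwise distance strictly
#' exceeds the threshold (use `split_ties = TRUE` for "meets or exceeds") and
#' that has at least two members is Ward-split; children are named by
#' appending `", <k>"`. At most `max_generations` rounds are performed below
#' the secondary level. The terminal label is the deepest assigned name,
#' padded with `"nan"` markers for unsplit levels, e.g.
#' `"Aromatic PFASs, gte7, nan, nan"` (never split) or
#' `"Aromatic PFASs, lt7, 4, 1"` (split twice).
#'
#' @param assignments Tibble with `substance_id` and `secondary_category`
#'   columns (e.g. from [categorize_substances()]).
#' @param bits Fingerprint matrix covering the assigned substances.
#' @param tau Objective distance threshold from [objective_threshold()].
#' @param max_generations Maximum subcategorization rounds (default 2).
#' @param split_ties Split categories whose median equals `tau` (default
#'   `FALSE`: strict exceedance).
#' @param cut_height_frac Passed to [ward_subcategorize()].
#' @return `assignments` with `tertiary`, `quaternary` (character, `"nan"`
#'   when unsplit) and `terminal_label` columns added.
#' @export
derive_terminal_categories <- function(assignments, bits, tau,
                                       max_generations = 2,
                                       split_ties = FALSE,
                                       cut_height_frac = 0.7) {
  out <- tibble::as_tibble(assignments)
  out$tertiary <- "nan"
  out$quaternary <- "nan"
  exceeds <- function(m) if (split_ties) m >= tau else m > tau

  level_cols <- c("tertiary", "quaternary")
  group_label <- function(i, gen) {
    parts <- out$secondary_category[i]
    if (gen >= 2) parts <- paste(parts, out$tertiary[i], sep = ", ")
    parts
  }
  for (gen in seq_len(max_generations)) {
    labels <- vapply(seq_len(nrow(out)), function(i) group_label(i, gen), "")
    # Groups created in the previous generation (or the secondary categories
    # in generation 1); groups already marked "nan" at this level stay put.
    eligible <- if (gen == 1) rep(TRUE, nrow(out)) else out[[level_cols[gen - 1]]] != "nan"
    for (lab in unique(labels[eligible])) {
      rows <- which(labels == lab & eligible)
      ids <- out$substance_id[rows]
      ids <- ids[ids %in% rownames(bits)]
      if (length(ids) < 2) next
      d <- jaccard_distance_matrix(bits[ids, , drop = FALSE])
      med <- median(upper_tri_values(d))
      if (!exceeds(med)) next
      cl <- ward_subcategorize(d, cut_height_frac = cut_height_frac)
      out[[level_cols[gen]]][rows[match(ids, out$substance_id[rows])]] <-
        as.character(cl)
    }
  }
  out$terminal_label <- paste(out$secondary_category, out$tertiary,
                              out$quaternary, sep = ", ")
  out
}
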