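# Representative substance selection: category centroids (medoids), greedy
# MaxMin diversity picking and diversity-coverage curves.

#' Category centroid (medoid)
#'
#' The member minimizing the sum of distances to all other members; ties go
#' to the lowest index. A singleton's centroid is its only member.
#'
#' @param d Symmetric distance matrix with substance ids as row names.
#' @return The centroid substance id (or index when `d` has no row names).
#' @export
category_centroid <- function(d) {
  stopifnot(nrow(d) >= 1)
  sums <- rowSums(d)
  i <- which.min(sums)  # which.min returns the first (lowest-index) minimum
  if (!is.null(rownames(d))) rownames(d)[i] else i
}

#' Greedy MaxMin diversity picking
#'
#' Starting from a seed (normally the centroid), repeatedly adds the
#' candidate whose minimum distance to the already-picked set is largest.
#' Ties are broken toward the lowest candidate index for determinism.
#'
#' @param d Symmetric distance matrix with substance ids as row names.
#' @param seed_id Substance id of the initial pick.
#' @param k Number of additional substances to pick beyond the seed. When `k`
#'   exceeds the number of remaining candidates the picks are truncated with
#'   a message.
#' @return Character vector of the `k` picked ids, in pick order (the seed is
#'   not included).
#' @export
maxmin_pick <- function(d, seed_id, k) {
  ids <- rownames(d)
  stopifnot(seed_id %in% ids)
  candidates <- setdiff(ids, seed_id)
  if (k > length(candidates)) {
    message("k = ", k, " exceeds remaining candidates (", length(candidates),
            "); picks truncated")
    k <- length(candidates)
  }
  picked <- seed_id
  picks <- character(0)
  for (step in seq_len(k)) {
    min_d <- apply(d[candidates, picked, drop = FALSE], 1, min)
    best <- candidates[which.max(min_d)]
    picks <- c(picks, best)
    picked <- c(picked, best)
    candidates <- setdiff(candidates, best)
  }
  picks
}

#' Diversity-coverage curve for an ordered selection
#'
#' For a full diversity ordering of a category (centroid first, then MaxMin
#' picks to exhaustion), `m(k)` is the mean over members of the minimum
#' distance to the first `k` picks, and the coverage fraction is the
#' normalized cumulative sum `c(k) = sum(m[1:k]) / sum(m)`. `m` is
#' nonincreasing, `c` nondecreasing with `c(n) = 1`. A singleton category is
#' defined as fully covered by its single member.
#'
#' @param d Symmetric distance matrix.
#' @param ordering Character vector covering all row names of `d`, in pick
#'   order.
#' @param include_picked Average `m(k)` over all members (default) or only
#'   the not-yet-picked members.
#' @return Tibble with `k`, `pick_id`, `mean_min_distance` and
#'   `coverage_fraction`.
#' @export
coverage_curve <- function(d, ordering, include_picked = TRUE) {
  ids <- rownames(d)
  stopifnot(setequal(ordering, ids))
  n <- length(ids)
  if (n == 1) {
    return(tibble::tibble(k = 1L, pick_id = ordering,
                          mean_min_distance = 0, coverage_fraction = 1))
  }
  m <- numeric(n)
  for (k in seq_len(n)) {
    picked <- ordering[seq_len(k)]
    min_d <- apply(d[, picked, drop = FALSE], 1, min)
    members <- if (include_picked) ids else setdiff(ids, picked)
    m[k] <- if (length(members) == 0) 0 else mean(min_d[members])
  }
  total <- sum(m)
  cov <- if (total > 0) cumsum(m) / total else rep(1, n)
  tibble::tibble(k = seq_len(n), pick_id = ordering,
                 mean_min_distance = m, coverage_fraction = cov)
}

#' Picks needed to reach target coverage fractions
#'
#' @param curve Tibble from [coverage_curve()].
#' @param targets Coverage fractions (default 0.5 and 0.8; the 80% level is
#'   illustrative, not prescriptive).
#' @return Tibble with `target` and `n_picks` (minimal `k` with coverage at
#'   or above the target).
#' @export
picks_for_coverage <- function(curve, targets = c(0.5, 0.8)) {
  purrr::map_dfr(targets, function(f) {
    k <- curve$k[curve$coverage_fraction >= f]
    tibble::tibble(target = f, n_picks = if (length(k)) min(k) else NA_integer_)
  })
}

#' Select representative substances for every terminal category
#'
#' For each terminal category: the centroid is identified; for categories
#' with more than `min_size_for_maxmin` members (default 5), `k` further
#' substances are picked by MaxMin; and the diversity-coverage curve over the
#' full pick ordering is computed.
#'
#' @param assignments Tibble with `substance_id` and a `terminal_label`
#'   column (from [derive_terminal_categories()]).
#' @param bits Fingerprint matrix.
#' @param k Additional MaxMin picks beyond the centroid (default 3).
#' @param min_size_for_maxmin MaxMin is applied only to categories with more
#'   members than this (default 5).
#' @param coverage_targets Coverage fractions summarized per category.
#' @param constrain_to Optional character vector of substance ids; selection
#'   is recomputed on the category restricted to these ids (the
#'   constrained-landscape workflow). Categories with no constrained members
#'   are dropped.
#' @return List with tibbles `selections` (`terminal_label`, `role`,
#'   `substance_id`), `coverage` (per-category curves) and `summary`
#'   (`terminal_label`, `n`, `n_picks` per coverage target).
#' @export
select_representatives <- function(assignments, bits, k = 3,
                                   min_size_for_maxmin = 5,
                                   coverage_targets = c(0.5, 0.8),
                                   constrain_to = NULL) {
  stopifnot("terminal_label" %in% names(assignments))
  asn <- assignments[assignments$substance_id %in% rownames(bits), ]
  if (!is.null(constrain_to)) {
    asn <- asn[asn$substance_id %in% constrain_to, ]
  }
  groups <- split(asn$substance_id, asn$terminal_label)
  selections <- list(); coverages <- list(); summaries <- list()
  for (lab in names(groups)) {
    ids <- groups[[lab]]
    d <- jaccard_distance_matrix(bits[ids, , drop = FALSE])
    centroid <- category_centroid(d)
    ordering <- centroid
    if (length(ids) > 1) {
      ordering <- c(centroid, maxmin_pick(d, centroid, k = length(ids) - 1))
    }
    n_maxmin <- if (length(ids) > min_size_for_maxmin) min(k, length(ids) - 1) else 0
    sel_ids <- ordering[seq_len(1 + n_maxmin)]
    selections[[lab]] <- tibble::tibble(
      terminal_label = lab,
      role = c("centroid", if (n_maxmin > 0) paste0("maxmin_", seq_len(n_maxmin))),
      substance_id = sel_ids
    )
    curve <- coverage_curve(d, ordering)
    coverages[[lab]] <- dplyr::mutate(curve, terminal_label = lab,
                                      .before = 1)
    summaries[[lab]] <- picks_for_coverage(curve, coverage_targets) |>
      dplyr::mutate(terminal_label = lab, n = length(ids), .before = 1)
  }
  list(
    selections = dplyr::bind_rows(selections),
    coverage = dplyr::bind_rows(coverages),
    summary = dplyr::bind_rows(summaries)
  )
}
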