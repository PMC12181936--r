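test_that("fingerprints are deterministic and order-invariant", {
  df <- tibble::tibble(
    substance_id = c("a", "b", "c", "d"),
    qsar_ready_smiles = c(
      smiles_pfoa, smiles_pfoa,
      "FC(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(O)=O",  # rewrite
      smiles_pfos
    )
  )
  bits <- morgan_fingerprints(df)
  expect_equal(dim(bits), c(4L, 1024L))
  expect_true(all(bits %in% c(0L, 1L)))
  expect_equal(bits["a", ], bits["b", ])   # identical input
  expect_equal(bits["a", ], bits["c", ])   # atom-order rewrite
  expect_gt(sum(bits["a", ] != bits["d", ]), 0)  # PFOA vs PFOS differ
})

test_that("unparseable structures are omitted from the fingerprint matrix", {
  df <- tibble::tibble(substance_id = c("ok", "bad"),
                       qsar_ready_smiles = c("CCO", NA))
  expect_warning(bits <- morgan_fingerprints(df), "omitted")
  expect_equal(rownames(bits), "ok")
})

test_that("Jaccard distances match their hand-computed cases", {
  bits <- bits_from_sets(list(c(1, 2, 3), c(2, 3, 4), c(1, 2, 3), c(9, 10)))
  d <- jaccard_distance_matrix(bits)
  expect_equal(d["s1", "s2"], 0.5)   # |intersect| 2, |union| 4
  expect_equal(d["s1", "s3"], 0)     # identical rows
  expect_equal(d["s1", "s4"], 1)     # disjoint sets
  expect_equal(diag(d), setNames(rep(0, 4), rownames(bits)))
  expect_equal(d, t(d))
  # both-empty convention
  empty <- jaccard_distance_matrix(bits_from_sets(list(integer(0), integer(0))))
  expect_equal(empty["s1", "s2"], 0)
})

test_that("Jaccard distances agree with a set-arithmetic oracle", {
  set.seed(42)
  for (trial in seq_len(1000)) {
    x <- as.integer(runif(16) < 0.4)
    y <- as.integer(runif(16) < 0.4)
    d <- jaccard_distance_matrix(rbind(x, y))[1, 2]
    inter <- length(intersect(which(x == 1), which(y == 1)))
    uni <- length(union(which(x == 1), which(y == 1)))
    oracle <- if (uni == 0) 0 else 1 - inter / uni
    expect_equal(d, oracle)
  }
})

test_that("within-category medians summarize upper-triangle distances", {
  # s1/s2/s3 in category X: pairwise distances 0.5, 0, 0.5 -> median 0.5;
  # s4/s5 in category Y at distance 1 -> median 1; Z is a singleton.
  bits <- bits_from_sets(list(c(1, 2, 3), c(2, 3, 4), c(1, 2, 3),
                              c(5), c(6), c(7)))
  asn <- tibble::tibble(
    substance_id = paste0("s", 1:6),
    secondary_category = c("X", "X", "X", "Y", "Y", "Z")
  )
  expect_message(med <- within_category_medians(bits, asn), "singleton")
  expect_equal(med$median_distance[med$category == "X"], 0.5)
  expect_equal(med$median_distance[med$category == "Y"], 1)
  expect_false("Z" %in% med$category)
})

test_that("between-category pairs exclude shared primary roots", {
  asn <- tibble::tibble(
    secondary_category = c("A, lt7", "A, gte7", "B, lt7"),
    primary_category = c("A", "A", "B")
  )
  pairs <- between_category_pairs(asn)
  got <- sort(paste(pairs$category_a, pairs$category_b, sep = " | "))
  expect_equal(got, sort(c("A, lt7 | B, lt7", "A, gte7 | B, lt7")))
  # all categories sharing one root -> empty
  one_root <- between_category_pairs(tibble::tibble(
    secondary_category = c("A, lt7", "A, gte7"),
    primary_category = c("A", "A")
  ))
  expect_equal(nrow(one_root), 0)
})

test_that("between-category medians use only cross-category distances", {
  bits <- bits_from_sets(list(c(1), c(1), c(2), c(2)))
  asn <- tibble::tibble(
    substance_id = paste0("s", 1:4),
    secondary_category = c("A, lt7", "A, lt7", "B, lt7", "B, lt7"),
    primary_category = c("A", "A", "B", "B")
  )
  med <- between_category_medians(bits, asn)
  # within-category distances are all 0; every cross distance is 1
  expect_equal(med$median_distance, 1)
})

test_that("the objective threshold is the linear-interpolated percentile", {
  expect_equal(objective_threshold(rep(0.9, 5)), 0.9)
  expect_equal(objective_threshold(c(0.70, 0.80, 0.90, 1.00), percentile = 15),
               0.745)
  expect_error(objective_threshold(numeric(0)), "no between-category")
})

test_that("ECDF sample points count values at or below x", {
  e <- distance_ecdf(c(1, 2, 3))
  expect_equal(e$cdf[e$value == 2], 2 / 3)
  expect_equal(distance_ecdf(5)$cdf, 1)
  r <- distance_ecdf(runif(50))
  expect_true(all(diff(r$cdf) >= 0))
  expect_equal(max(r$cdf), 1)
})

test_that("Ward subcategorization separates well-separated pairs", {
  d <- dist_matrix(c(0.1, 0.95, 0.95, 0.95, 0.95, 0.1))  # {s1,s2} vs {s3,s4}
  cl <- ward_subcategorize(d)
  expect_equal(length(unique(cl)), 2)
  expect_equal(cl[["s1"]], cl[["s2"]])
  expect_equal(cl[["s3"]], cl[["s4"]])
  expect_true(cl[["s1"]] != cl[["s3"]])
  expect_error(ward_subcategorize(d[1, 1, drop = FALSE]), "at least 2")
})

test_that("Ward labels are a deterministic 1-based partition", {
  set.seed(7)
  for (trial in 1:20) {
    d <- random_dist_matrix(sample(3:12, 1))
    cl1 <- ward_subcategorize(d)
    cl2 <- ward_subcategorize(d)
    expect_identical(cl1, cl2)
    expect_equal(sort(unique(unname(cl1))), seq_len(max(cl1)))
    expect_equal(names(cl1), rownames(d))
  }
})

test_that("terminal categories follow the naming and stopping rules", {
  land <- test_landscape()
  pipe <- test_pipeline()
  asn <- pipe$assignments
  # partition: every substance appears in exactly one terminal category
  expect_equal(sort(asn$substance_id), sort(land$registry$substance_id))
  expect_false(any(is.na(asn$terminal_label)))
  # label structure: secondary root is recoverable from the terminal label
  expect_true(all(startsWith(asn$terminal_label,
                             paste0(asn$secondary_category, ", "))))
  expect_true(all(grepl(", (nan|[0-9]+), (nan|[0-9]+)$", asn$terminal_label)))
  # depth never exceeds two generations: labels have exactly 2 extra fields
  extra <- sub("^.*(lt7|gte7), ", "", asn$terminal_label)
  expect_true(all(lengths(strsplit(extra, ", ")) == 2))
  # quaternary implies tertiary
  expect_false(any(asn$tertiary == "nan" & asn$quaternary != "nan"))
})

test_that("categories at or below the threshold keep their secondary name", {
  land <- test_landscape()
  pipe <- test_pipeline()
  out <- derive_terminal_categories(pipe$assignments, pipe$fingerprints,
                                    tau = 1)  # nothing exceeds 1
  expect_equal(out$terminal_label,
               paste0(out$secondary_category, ", nan, nan"))
})

test_that("splitting reduces the within-category median on separated fixtures", {
  # two structural blocks far apart within one category
  bits <- bits_from_sets(c(
    lapply(1:6, function(i) c(1, 2, 3, 3 + i)),
    lapply(1:6, function(i) c(40, 41, 42, 42 + i))
  ), n_bits = 64)
  asn <- tibble::tibble(substance_id = rownames(bits),
                        secondary_category = "X, lt7")
  parent_median <- within_category_medians(bits, asn)$median_distance
  out <- derive_terminal_categories(asn, bits, tau = parent_median - 0.01,
                                    max_generations = 1)
  child_medians <- within_category_medians(bits, out,
                                           category_col = "terminal_label")
  expect_gt(length(unique(out$terminal_label)), 1)
  expect_true(all(child_medians$median_distance <= parent_median))
})
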