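test_that("QC filtering drops failing substances", {
  flags <- tibble::tibble(substance_id = paste0("s", 1:10),
                          qc_pass = c(rep(TRUE, 7), rep(FALSE, 3)),
                          f = 1)
  expect_equal(nrow(filter_by_qc(flags)), 7)
  expect_equal(nrow(filter_by_qc(flags[1:7, ])), 7)  # all pass: identity
  expect_warning(out <- filter_by_qc(flags[8:10, ]), "no substances")
  expect_equal(nrow(out), 0)
})

test_that("flag and TK-bin binarization follow their conventions", {
  expect_equal(binarize_flags(c(0, 1, 2, NA)), c(0L, 1L, 1L, NA))
  expect_equal(binarize_flags(c(0, 1, 2), positive = 2), c(0L, 0L, 1L))
  expect_equal(binarize_tk_bins(c(4, 3, 1, NA)), c(1L, 0L, 0L, NA))
  expect_error(binarize_tk_bins(5), "1..4")
})

test_that("enrichment applies the OR, p-value and true-positive criteria", {
  feat <- function(a, b, c_, d) {
    x <- c(rep(1, a + b), rep(0, c_ + d))
    y <- c(rep(1, a), rep(0, b), rep(1, c_), rep(0, d))
    enrich_features(matrix(x, ncol = 1, dimnames = list(NULL, "f")), y)
  }
  strong <- feat(5, 0, 2, 93)
  expect_true(strong$enriched)
  expect_gt(strong$odds_ratio, 3)       # Haldane-corrected, zero cell
  expect_lt(strong$p_value, 0.05)
  # a = 2 fails the true-positive rule regardless of OR and p
  tp_fail <- feat(2, 0, 1, 97)
  expect_false(tp_fail$enriched)
  expect_equal(tp_fail$a, 2)
  # strong p but OR below 3 fails
  weak_or <- feat(30, 20, 20, 30)
  expect_lt(weak_or$p_value, 0.05)
  expect_lt(weak_or$odds_ratio, 3)
  expect_false(weak_or$enriched)
})

test_that("constant features or flags give p = 1 and no enrichment", {
  x <- matrix(c(1, 1, 1, 1, 0, 0, 0, 0), ncol = 2,
              dimnames = list(NULL, c("always", "never")))
  y <- c(1, 0, 1, 0)
  out <- enrich_features(x, y)
  expect_equal(out$p_value, c(1, 1))
  expect_false(any(out$enriched))
  const_flag <- enrich_features(matrix(c(1, 0, 1, 0), ncol = 1,
                                       dimnames = list(NULL, "f")),
                                c(1, 1, 1, 1))
  expect_equal(const_flag$p_value, 1)
})

test_that("missing flags are excluded from the contingency table", {
  x <- matrix(c(1, 1, 0, 0, 1), ncol = 1, dimnames = list(NULL, "f"))
  y <- c(1, NA, 0, 0, 1)
  out <- enrich_features(x, y)
  expect_equal(out$a + out$b + out$c + out$d, 4)
})

test_that("one-sided p-values match the hypergeometric tail oracle", {
  # all small tables, plus random larger tables up to n = 50
  tables <- expand.grid(a = 0:5, b = 0:5, c_ = 0:5, d = 0:5)
  tables <- tables[rowSums(tables) > 0, ]
  set.seed(31)
  extra <- t(replicate(300, {
    n <- sample(4:50, 1)
    as.vector(stats::rmultinom(1, n, prob = runif(4, 0.05, 1)))
  }))
  tables <- rbind(as.matrix(tables), extra)
  for (i in seq_len(nrow(tables))) {
    a <- tables[i, 1]; b <- tables[i, 2]; c_ <- tables[i, 3]; d <- tables[i, 4]
    x <- c(rep(1, a + b), rep(0, c_ + d))
    y <- c(rep(1, a), rep(0, b), rep(1, c_), rep(0, d))
    constant <- (a + b == 0) || (c_ + d == 0) || (a + c_ == 0) || (b + d == 0)
    if (constant) next
    got <- enrich_features(matrix(x, ncol = 1, dimnames = list(NULL, "f")),
                           y)$p_value
    expect_equal(got, fisher_oracle_p(a, b, c_, d), tolerance = 1e-12)
  }
})

test_that("landscape prediction requires one enriched feature", {
  enr <- tibble::tibble(feature = c("f1", "f2"), flag = "fl",
                        enriched = c(TRUE, FALSE))
  x <- matrix(c(1, 0, 0,
                1, 1, 0), ncol = 2,
              dimnames = list(c("a", "b", "c"), c("f1", "f2")))
  pred <- predict_flags(x, enr)
  expect_equal(pred$fl, c(1L, 0L, 0L))
  none <- tibble::tibble(feature = "f1", flag = "empty", enriched = FALSE)
  expect_message(pred2 <- predict_flags(x, none), "no enriched")
  expect_equal(pred2$empty, c(0L, 0L, 0L))
})

test_that("performance metrics match confusion-matrix arithmetic", {
  perfect <- prediction_metrics(c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_equal(unlist(perfect[c("sensitivity", "specificity", "roc_auc")]),
               c(sensitivity = 1, specificity = 1, roc_auc = 1))
  all_neg <- prediction_metrics(c(1, 1, 0, 0), c(0, 0, 0, 0))
  expect_equal(unlist(all_neg[c("sensitivity", "specificity", "roc_auc")]),
               c(sensitivity = 0, specificity = 1, roc_auc = 0.5))
  # TP=7, FN=3, TN=8, FP=2
  actual <- c(rep(1, 10), rep(0, 10))
  predicted <- c(rep(1, 7), rep(0, 3), rep(0, 8), rep(1, 2))
  m <- prediction_metrics(actual, predicted)
  expect_equal(unlist(m[c("sensitivity", "specificity", "roc_auc")]),
               c(sensitivity = 0.7, specificity = 0.8, roc_auc = 0.75))
  # single-class actuals: AUC undefined
  expect_true(is.na(prediction_metrics(c(1, 1), c(1, 0))$roc_auc))
})

test_that("a planted feature-flag association is detected", {
  set.seed(37)
  ids <- paste0("s", 1:150)
  feature <- as.integer(runif(150) < 0.3)
  flags <- generate_flag_table(ids, feature, odds_ratio = 10, seed = 41)
  x <- cbind(planted = feature, generate_noise_features(ids, 10, seed = 43))
  out <- enrich_features(x, binarize_flags(flags$flag))
  expect_true(out$enriched[out$feature == "planted"])
})

test_that("shuffled flags stay near the nominal false-enrichment rate", {
  set.seed(47)
  ids <- paste0("s", 1:150)
  feature <- as.integer(runif(150) < 0.3)
  flags <- generate_flag_table(ids, feature, odds_ratio = 10, seed = 53)
  y <- binarize_flags(flags$flag)
  x <- cbind(planted = feature, generate_noise_features(ids, 10, seed = 59))
  hits <- replicate(500, {
    mean(enrich_features(x, sample(y))$p_value < 0.05)
  })
  expect_lte(mean(hits), 0.08)
})
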