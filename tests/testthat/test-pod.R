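make_record <- function(value, effect_type = "NOAEL", study_type = "chronic",
                        species = "rat", route = "oral",
                        units = "mg/kg-bw/day", substance_id = "s1",
                        effect_class = "noncancer") {
  tibble::tibble(substance_id = substance_id, route = route,
                 study_type = study_type, effect_type = effect_type,
                 value = value, units = units, species = species,
                 effect_class = effect_class)
}

test_that("record filtering enforces route, effect, study, unit and species", {
  records <- dplyr::bind_rows(
    make_record(10),                                 # retained
    make_record(10, route = "dermal"),               # route
    make_record(10, effect_type = "LD50"),           # effect type
    make_record(10, study_type = "acute"),           # study type
    make_record(10, units = "ppm"),                  # units
    make_record(10, species = "monkey"),             # species
    make_record(-1)                                  # non-positive dose
  )
  out <- filter_tox_records(records)
  expect_equal(nrow(out), 1)
  expect_equal(out$value, 10)
})

test_that("effect-level and duration extrapolation use the stated factors", {
  records <- dplyr::bind_rows(
    make_record(30, effect_type = "LOAEL", study_type = "subchronic"),
    make_record(10, effect_type = "NOAEL", study_type = "chronic"),
    make_record(50, effect_type = "LOAEL", study_type = "28-day")
  )
  identity_factors <- tibble::tibble(species = "rat", factor = 1)
  identity_models <- tibble::tibble(effect_class = "noncancer", m1 = 1, m2 = 1)
  out <- harmonize_tox_records(records, species_factors = identity_factors,
                               conceptual_models = identity_models)
  expect_equal(out$chronic_noael_equiv, c(30 / 3 / 2, 10, 50 / 3 / 5))
  expect_equal(out$bmdh, out$chronic_noael_equiv)  # identity config
})

test_that("species conversion divides by the configured factor", {
  factors <- tibble::tibble(species = c("rat", "mouse"), factor = c(4, 7))
  models <- tibble::tibble(effect_class = "noncancer", m1 = 1, m2 = 1)
  records <- dplyr::bind_rows(make_record(8, species = "rat"),
                              make_record(8, species = "mouse"))
  out <- harmonize_tox_records(records, species_factors = factors,
                               conceptual_models = models)
  expect_equal(out$human_equiv, c(2, 8 / 7))  # ordered inversely to factors
})

test_that("BMDh is the mean of the two conceptual-model multiples", {
  records <- make_record(10)
  factors <- tibble::tibble(species = "rat", factor = 1)
  for (ms in list(c(1, 1), c(0.5, 1.5), c(0.3, 0.9))) {
    models <- tibble::tibble(effect_class = "noncancer", m1 = ms[1], m2 = ms[2])
    out <- harmonize_tox_records(records, species_factors = factors,
                                 conceptual_models = models)
    expect_equal(out$bmdh, 10 * mean(ms))
  }
})

test_that("unknown study types or species are skipped with a note", {
  records <- dplyr::bind_rows(make_record(10),
                              make_record(10, species = "monkey"))
  expect_message(
    out <- harmonize_tox_records(records),
    "skipped"
  )
  expect_equal(nrow(out), 1)
})

test_that("the factor audit reconstructs input/output ratios exactly", {
  land <- test_landscape()
  records <- generate_tox_records(land$truth, seed = 5)
  out <- harmonize_tox_records(filter_tox_records(records))
  reconstructed <- out$value / (out$loael_factor * out$duration_factor *
                                  out$species_factor) *
    (out$m1 + out$m2) / 2
  expect_equal(reconstructed, out$bmdh)
})

test_that("the lognormal 25th percentile matches its closed form", {
  # mean 10, sd 5: sigma^2 = log(1.25), mu = log(10) - sigma^2/2
  sigma <- sqrt(log(1.25))
  expected <- exp(log(10) - log(1.25) / 2 + stats::qnorm(0.25) * sigma)
  expect_equal(lognormal_percentile(10, 5), expected)
  expect_equal(round(expected, 2), 6.50)
  expect_equal(lognormal_percentile(10, 0), 10)  # degenerate case
  # below the mean whenever sd > 0
  for (s in c(0.1, 1, 5, 20)) expect_lt(lognormal_percentile(10, s), 10)
})

test_that("substances with few records use the global median sd", {
  records <- dplyr::bind_rows(
    # 5 records, own sd
    make_record(c(8, 9, 10, 11, 12), substance_id = "many"),
    # 2 records: below the threshold, substituted sd
    make_record(c(10, 30), substance_id = "few")
  )
  out <- harmonize_tox_records(records,
                               species_factors = tibble::tibble(species = "rat", factor = 1),
                               conceptual_models = tibble::tibble(effect_class = "noncancer",
                                                                  m1 = 1, m2 = 1))
  pods <- substance_pod(out, min_records = 5)
  median_sd <- median(c(sd(c(8, 9, 10, 11, 12)), sd(c(10, 30))))
  few <- pods[pods$substance_id == "few", ]
  expect_equal(few$sd_used, median_sd)
  expect_equal(few$pod, lognormal_percentile(few$mean_bmdh, median_sd))
  many <- pods[pods$substance_id == "many", ]
  expect_equal(many$sd_used, sd(c(8, 9, 10, 11, 12)))
})

test_that("the pipeline recovers planted lognormal 25th percentiles", {
  # parameter recovery: many records per substance, known truth
  set.seed(23)
  n_sub <- 200; n_rec <- 50
  true_median <- 10; true_gsd <- 2
  sigma <- log(true_gsd)
  records <- purrr::map_dfr(seq_len(n_sub), function(i) {
    make_record(exp(rnorm(n_rec, log(true_median), sigma)),
                substance_id = paste0("s", i))
  })
  out <- harmonize_tox_records(
    records,
    species_factors = tibble::tibble(species = "rat", factor = 1),
    conceptual_models = tibble::tibble(effect_class = "noncancer", m1 = 1, m2 = 1)
  )
  pods <- substance_pod(out)
  true_p25 <- exp(log(true_median) + stats::qnorm(0.25) * sigma)
  # moment-matched lognormal percentile is consistent: small relative bias
  expect_lt(abs(mean(pods$pod) - true_p25) / true_p25, 0.1)
})

test_that("category summaries preserve ordering and degenerate cases", {
  pods <- tibble::tibble(
    substance_id = c("a", "b", "c"),
    effect_class = "noncancer",
    n_records = 5, mean_bmdh = 1, sd_bmdh = 0, sd_used = 0,
    pod = c(100, 1, 2), log10_pod = log10(c(100, 1, 2))
  )
  asn <- tibble::tibble(substance_id = c("a", "b", "c"),
                        terminal_label = c("HI", "LO", "LO"),
                        chain_length = c(4, 8, 9))
  s <- category_pod_summary(pods, asn)
  expect_equal(s$log10_pod_iqr[s$terminal_label == "HI"], 0)  # singleton
  expect_gt(s$log10_pod_median[s$terminal_label == "HI"],
            s$log10_pod_median[s$terminal_label == "LO"])
})
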