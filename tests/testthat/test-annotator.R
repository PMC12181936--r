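test_that("physical state follows the 25-degree rules", {
  expect_equal(physical_state(NA, -10), "gas")
  expect_equal(physical_state(120, NA), "solid")
  expect_equal(physical_state(10, 150), "liquid")
  expect_equal(physical_state(NA, NA), "unknown")
})

test_that("designations A-D cover their rule paths", {
  props <- tibble::tibble(
    melting_point   = c(100, 100, 10,  10,  10, NA,  NA, NA),
    boiling_point   = c(300, 300, 150, 150, 150, -5, -5, NA),
    water_solubility = c(0.001, 100, 100, 100, 0.0001, 0.0001, 100, NA),
    vapour_pressure = c(NA, NA, 1, 200, 1, NA, 1, NA),
    henrys_law      = c(NA, NA, NA, NA, NA, 0.5, 0.001, NA)
  )
  out <- assign_designation(props)
  expect_equal(out$designation,
               c("A", "B", "B", "C", "C", "D", "C", "not determined"))
})

test_that("boundary values sit on the soluble/volatile side", {
  out <- assign_designation(tibble::tibble(
    melting_point = c(100, 10), boiling_point = c(300, 150),
    water_solubility = c(0.5, 0.5), vapour_pressure = c(NA, 75),
    henrys_law = c(NA, NA)
  ))
  expect_equal(out$designation, c("B", "C"))
})

test_that("designations partition fully-annotated substances", {
  land <- test_landscape()
  props <- generate_property_table(land$truth, missing_rate = 0, seed = 3)
  out <- assign_designation(props)
  expect_true(all(out$designation %in% c("A", "B", "C", "D")))
  # highly volatile soluble gases take D over C
  hv <- assign_designation(tibble::tibble(
    melting_point = NA, boiling_point = -10, water_solubility = 100,
    vapour_pressure = NA, henrys_law = 0.5
  ))
  expect_equal(hv$designation, "D")
})

test_that("production volumes map to the stated ranges", {
  expect_equal(bin_production_volume(30000), "25,000-<100,000 lbs")
  expect_equal(bin_production_volume(25000), "25,000-<100,000 lbs")  # boundary
  expect_equal(bin_production_volume(10), "<25,000 lbs")
  expect_equal(bin_production_volume(5e8), "100,000,000-<1,000,000,000 lbs")
  # pass-through of source range strings, including the overlapping ones
  expect_equal(bin_production_volume("<1,000,000 lbs"), "<1,000,000 lbs")
  expect_warning(out <- bin_production_volume("confidential"))
  expect_true(is.na(out))
})

test_that("list tagging matches ids and counts memberships", {
  reg <- suppressWarnings(as_registry(data.frame(
    substance_id = c("A", "B", "C"),
    smiles = c("CCO", "CCC", "CCCC")
  )))
  lists <- list(
    l1 = tibble::tibble(substance_id = c("A", "B", "ZZZ")),
    l2 = tibble::tibble(substance_id = "A")
  )
  expect_message(tags <- tag_lists(reg, lists), "not matched")
  expect_equal(tags$n_lists, c(2, 1, 0))
  # structure-key fallback: same structure under a different id
  lists_key <- list(k = tibble::tibble(substance_id = "OTHER",
                                       structure_key = reg$structure_key[1]))
  tags_key <- suppressMessages(tag_lists(reg, lists_key))
  expect_equal(tags_key$k, c(TRUE, FALSE, FALSE))
})

test_that("data-poor categories lack qualifying repeated-dose records", {
  asn <- tibble::tibble(substance_id = c("a", "b", "c", "d"),
                        terminal_label = c("X", "X", "Y", "Z"))
  tox <- tibble::tibble(
    substance_id = c("a", "c"),
    route = c("oral", "dermal"),
    effect_type = c("NOAEL", "LOAEL")
  )
  poor <- data_poor_categories(asn, tox)
  expect_setequal(poor, c("Y", "Z"))  # Y has only a dermal record
})

test_that("triage gates and candidate fallbacks behave as specified", {
  # category X: data-poor, on inventory + monitoring; centroid not on
  # inventory, but another member is -> fallback candidates
  bits <- bits_from_sets(list(c(1, 2, 3), c(1, 2, 4), c(1, 2, 3, 4), c(9, 10)),
                         ids = c("x1", "x2", "x3", "y1"))
  asn <- tibble::tibble(substance_id = c("x1", "x2", "x3", "y1"),
                        terminal_label = c("X", "X", "X", "Y"))
  d <- jaccard_distance_matrix(bits[1:3, ])
  centroid <- category_centroid(d)
  sel <- select_representatives(asn, bits, k = 0)$selections
  tox <- tibble::tibble(substance_id = "y1", route = "oral",
                        effect_type = "NOAEL")
  non_centroid <- setdiff(c("x1", "x2", "x3"), centroid)
  res <- triage_categories(asn, sel, bits, tox,
                           inventory_ids = non_centroid[1],
                           monitored_ids = "x1")
  x_row <- res[res$terminal_label == "X", ]
  expect_true(x_row$triaged)
  cands <- x_row$candidates[[1]]
  expect_true(non_centroid[1] %in% cands$substance_id)
  expect_match(cands$rationale[1], "nearest inventory member")
  # Y fails the inventory/monitoring gates
  y_row <- res[res$terminal_label == "Y", ]
  expect_false(y_row$triaged)
  expect_match(y_row$gate_rationale, "failed gate")
  # centroid directly on inventory -> nominated directly
  res2 <- triage_categories(asn, sel, bits, tox,
                            inventory_ids = centroid, monitored_ids = "x1")
  cands2 <- res2$candidates[res2$terminal_label == "X"][[1]]
  expect_equal(cands2$substance_id, centroid)
  expect_match(cands2$rationale, "representative pick on inventory")
})

test_that("triage is monotone in toxicity evidence", {
  bits <- bits_from_sets(list(c(1), c(2)), ids = c("x1", "x2"))
  asn <- tibble::tibble(substance_id = c("x1", "x2"),
                        terminal_label = c("X", "X"))
  sel <- select_representatives(asn, bits, k = 0)$selections
  no_tox <- tibble::tibble(substance_id = character(0), route = character(0),
                           effect_type = character(0))
  with_tox <- tibble::tibble(substance_id = "x1", route = "oral",
                             effect_type = "NOAEL")
  before <- triage_categories(asn, sel, bits, no_tox, "x1", "x1")
  after <- triage_categories(asn, sel, bits, with_tox, "x1", "x1")
  expect_true(before$triaged)
  expect_false(after$triaged)  # adding evidence can only remove a category
})

test_that("the data-availability matrix is 0/1 by category", {
  asn <- tibble::tibble(substance_id = c("a", "b"), terminal_label = c("X", "Y"))
  tox <- tibble::tibble(substance_id = "a", route = "inhalation",
                        study_type = "chronic")
  tags <- tibble::tibble(substance_id = c("a", "b"), l1 = c(TRUE, FALSE),
                         n_lists = c(1, 0))
  m <- data_availability_matrix(asn, tox, tags)
  expect_equal(m$chronic[m$terminal_label == "X"], 1L)
  expect_equal(m$chronic[m$terminal_label == "Y"], 0L)
  expect_equal(m$l1, c(1L, 0L))
})
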