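test_that("feature_map normalizes codes and counts features", {
  map <- toy_map()
  expect_equal(length(map$feature_ids), 2L)
  expect_equal(nrow(map$features), 3L)
  expect_true(all(!grepl(".", map$features$code, fixed = TRUE)))
})

test_that("strict mode rejects a code shared across features", {
  tab <- data.frame(
    feature_id = c("a", "b"), feature_name = c("A", "B"),
    icd_version = c(10, 10), code = c("I50.9", "I509"))
  expect_error(feature_map("d", tab, strict = TRUE), "shared across")
  expect_message(m <- feature_map("d", tab, strict = FALSE), "shared")
  expect_equal(length(m$feature_ids), 2L)
})

test_that("JSON and CSV encodings load to identical maps", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("feature_id,feature_name,icd_version,code",
               "a,Alpha,10,I50.0", "a,Alpha,10,I50.1", "a,Alpha,9,428.0",
               "b,Beta,10,G56.0", "b,Beta,10,G56.1", "b,Beta,9,354.0"),
             csv)
  suppressMessages(m_csv <- load_feature_map(csv, disease_name = "d"))
  expect_equal(length(m_csv$feature_ids), 2L)
  expect_equal(nrow(m_csv$features), 6L)

  js <- withr::local_tempfile(fileext = ".json")
  write_feature_map(m_csv, js)
  suppressMessages(m_js <- load_feature_map(js))
  expect_equal(m_js$features, m_csv$features)
  expect_equal(m_js$feature_ids, m_csv$feature_ids)
})

test_that("expand_hierarchy follows the same-version prefix rule", {
  cat10 <- code_catalog(data.frame(
    icd_version = 10, code = c("I50", "I500", "I501", "I509", "I10")))
  got <- expand_hierarchy(data.frame(icd_version = 10, code = "I50"),
                          cat10)
  expect_setequal(got$code, c("I50", "I500", "I501", "I509"))
  got2 <- expand_hierarchy(data.frame(icd_version = 10, code = "I10"),
                           cat10)
  expect_equal(got2$code, "I10")
  expect_warning(
    got3 <- expand_hierarchy(data.frame(icd_version = 10, code = "Z99"),
                             cat10),
    "no catalog match")
  expect_equal(nrow(got3), 0L)
  # version is part of the identity: same string, other version, no match
  expect_warning(
    got4 <- expand_hierarchy(data.frame(icd_version = 9, code = "I50"),
                             cat10),
    "no catalog match")
  expect_equal(nrow(got4), 0L)
  expect_error(code_catalog(data.frame(icd_version = integer(0),
                                       code = character(0))), "empty")
})

test_that("expand_hierarchy is monotone in the catalog", {
  seeds <- data.frame(icd_version = 10, code = c("I50", "G56"))
  base_codes <- c("I50", "I509", "G560", "E11")
  extra_codes <- c("I5021", "G5601", "Z99")
  small <- code_catalog(data.frame(icd_version = 10, code = base_codes))
  big <- code_catalog(data.frame(icd_version = 10,
                                 code = c(base_codes, extra_codes)))
  got_small <- expand_hierarchy(seeds, small)
  got_big <- expand_hierarchy(seeds, big)
  expect_true(all(got_small$code %in% got_big$code))
})

test_that("exclude_disease_codes removes expanded codes and drops empty features", {
  tab <- data.frame(
    feature_id = c("a", "a", "b"),
    feature_name = c("A", "A", "B"),
    icd_version = c(10, 10, 10),
    code = c("Q874", "M350", "G560"))
  map <- feature_map("marfanlike", tab)
  cat10 <- code_catalog(data.frame(
    icd_version = 10, code = c("Q874", "Q8740", "M350", "G560")))
  seeds <- data.frame(icd_version = 10, code = "Q874")

  out <- exclude_disease_codes(map, seeds, cat10)
  expect_equal(out$features$code[out$features$feature_id == "a"], "M350")
  expect_equal(length(out$feature_ids), 2L)
  # input untouched
  expect_equal(nrow(map$features), 3L)

  # disjoint exclusion set: identity
  same <- exclude_disease_codes(
    map, data.frame(icd_version = 10, code = "M350")[0, ], cat10)
  expect_equal(same$features, map$features)

  # a feature whose every code is excluded is dropped with a warning
  expect_warning(
    fewer <- exclude_disease_codes(
      map, data.frame(icd_version = 10, code = "G560"), cat10),
    "dropped")
  expect_equal(fewer$feature_ids, c("a"))
})

test_that("presence_matrix implements the at-least-one-code rule", {
  map <- toy_map()
  dx <- toy_events(list("p1", "I509", 10, "2020-01-01"),
                   list("p1", "I509", 10, "2021-01-01"),
                   list("p1", "G560", 10, "2020-05-01"),
                   list("p3", "E119", 10, "2020-05-01"))
  pm <- presence_matrix(dx, map, c("p1", "p2", "p3"))
  expect_equal(pm["p1", ], c(hf = 1L, cts = 1L))
  expect_equal(pm["p2", ], c(hf = 0L, cts = 0L))  # no diagnoses at all
  expect_equal(pm["p3", ], c(hf = 0L, cts = 0L))  # unmapped code only
})

test_that("presence_matrix matches exhaustive set-membership on hand-built data", {
  map <- toy_map()
  dx <- toy_events(list("p1", "4280", 9, "1999-03-01"),
                   list("p2", "G560", 10, "2010-01-01"),
                   list("p2", "I509", 10, "2011-01-01"),
                   list("p3", "G560", 10, "2012-01-01"))
  patients <- c("p1", "p2", "p3")
  pm <- presence_matrix(dx, map, patients)
  # oracle: per-patient, per-feature membership check over raw events
  for (p in patients) {
    for (fid in map$feature_ids) {
      codes <- map$features[map$features$feature_id == fid, ]
      has <- any(dx$patient_id == p &
                   paste(dx$icd_version, dx$icd_code) %in%
                     paste(codes$icd_version, codes$code))
      expect_identical(pm[p, fid], as.integer(has))
    }
  }
})

test_that("presence_matrix is invariant to event duplication and order", {
  map <- toy_map()
  dx <- toy_events(list("p1", "I509", 10, "2020-01-01"),
                   list("p2", "G560", 10, "2010-01-01"))
  patients <- c("p1", "p2")
  base <- presence_matrix(dx, map, patients)
  dup <- rbind(dx, dx, dx)
  shuffled <- dup[rev(seq_len(nrow(dup))), ]
  expect_identical(presence_matrix(dup, map, patients), base)
  expect_identical(presence_matrix(shuffled, map, patients), base)
})

test_that("excluding codes from the map equals zeroing them from the event stream", {
  map <- toy_map()
  cat_all <- code_catalog(map$features[, c("icd_version", "code")])
  seeds <- data.frame(icd_version = 10, code = "I509")
  dx <- toy_events(list("p1", "I509", 10, "2020-01-01"),
                   list("p1", "4280", 9, "2020-02-01"),
                   list("p2", "G560", 10, "2010-01-01"))
  patients <- c("p1", "p2")
  pruned_map <- exclude_disease_codes(map, seeds, cat_all)
  via_map <- presence_matrix(dx, pruned_map, patients)
  # oracle route: drop the excluded codes from the events, keep full map,
  # then compare the surviving feature columns
  excl <- expand_hierarchy(seeds, cat_all)
  drop <- paste(dx$icd_version, dx$icd_code) %in%
    paste(excl$icd_version, excl$code)
  via_events <- presence_matrix(dx[!drop, ], map, patients)
  expect_identical(via_map, via_events[, colnames(via_map), drop = FALSE])
})
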