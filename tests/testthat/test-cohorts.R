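toy_genotypes <- function() {
  data.frame(patient_id = c("p1", "p2", "p3", "p4", "p5"),
             status = c("carrier", "noncarrier_confirmed", "unknown",
                        "unknown", "carrier"),
             stringsAsFactors = FALSE)
}

test_that("assign_roles maps genotype status to cohort roles", {
  asn <- assign_roles(toy_genotypes())
  expect_equal(asn$role,
               c("case", "control", "training", "training", "case"))
  # roles partition the patient set
  expect_equal(sort(asn$patient_id), sort(toy_genotypes()$patient_id))
  expect_equal(nrow(asn), 5L)

  all_unknown <- data.frame(patient_id = c("a", "b"),
                            status = c("unknown", "unknown"))
  expect_true(all(assign_roles(all_unknown)$role == "training"))

  empty <- data.frame(patient_id = character(0), status = character(0))
  expect_equal(nrow(assign_roles(empty)), 0L)
})

test_that("age_at_last_diagnosis uses calendar-year arithmetic", {
  demo <- data.frame(patient_id = c("p1", "p2", "p3"),
                     birth_year = c(1950L, 2000L, 1960L),
                     sex = "F", race_ethnicity = "WHITE")
  dx <- toy_events(list("p1", "I509", 10, "2018-01-01"),
                   list("p1", "I509", 10, "2020-03-01"),
                   list("p2", "G560", 10, "2020-07-15"))
  ages <- age_at_last_diagnosis(dx, demo)
  expect_equal(ages$age[ages$patient_id == "p1"], 70L)
  expect_equal(ages$age[ages$patient_id == "p2"], 20L)
  expect_true(is.na(ages$age[ages$patient_id == "p3"]))
})

strata_fixture <- function() {
  demo <- data.frame(
    patient_id = sprintf("p%d", 1:5),
    birth_year = c(1940L, 1945L, 1990L, 1950L, 1935L),
    sex = "F",
    race_ethnicity = c("BLACK OR AFRICAN AMERICAN", "WHITE",
                       "BLACK OR AFRICAN AMERICAN",
                       "BLACK OR AFRICAN AMERICAN", "WHITE"),
    stringsAsFactors = FALSE)
  dx <- toy_events(list("p1", "I509", 10, "2020-01-01"),
                   list("p2", "I509", 10, "2020-01-01"),
                   list("p3", "G560", 10, "2020-01-01"),
                   list("p4", "G560", 10, "2020-01-01"))
  # p5 has no diagnoses at all
  asn <- assign_roles(data.frame(
    patient_id = demo$patient_id,
    status = c("carrier", "noncarrier_confirmed", "unknown",
               "noncarrier_confirmed", "carrier")))
  pm <- presence_matrix(dx, toy_map(), demo$patient_id)
  list(demo = demo, dx = dx, asn = asn, pm = pm)
}

test_that("apply_strata enumerates the filtered subset by hand", {
  fx <- strata_fixture()
  # ages at last dx: p1=80, p2=75, p3=30, p4=70, p5=NA
  got <- apply_strata(fx$asn, fx$demo, fx$pm, fx$dx,
                      stratification_spec(min_age_at_last_dx = 60))
  expect_setequal(as.character(got), c("p1", "p2", "p4"))
  expect_equal(attr(got, "attrition")[["min_age_at_last_dx"]], 2L)

  # empty spec is the identity
  all_in <- apply_strata(fx$asn, fx$demo, fx$pm, fx$dx,
                         stratification_spec())
  expect_setequal(as.character(all_in), fx$demo$patient_id)

  # race filter with an unmatched label: empty with a warning
  expect_warning(
    none <- apply_strata(fx$asn, fx$demo, fx$pm, fx$dx,
                         stratification_spec(
                           race_ethnicity_values = "NO SUCH LABEL")),
    "matched no patients")
  expect_length(none, 0L)

  # feature-history filter uses the presence column
  hf <- apply_strata(fx$asn, fx$demo, fx$pm, fx$dx,
                     stratification_spec(require_feature_history = "hf"))
  expect_setequal(as.character(hf), c("p1", "p2"))
  expect_error(
    apply_strata(fx$asn, fx$demo, fx$pm, fx$dx,
                 stratification_spec(require_feature_history = "nope")),
    "not found in presence")
})

test_that("strata compose as set intersection and are idempotent", {
  fx <- strata_fixture()
  age_spec <- stratification_spec(min_age_at_last_dx = 60)
  race_spec <- stratification_spec(
    race_ethnicity_values = "BLACK OR AFRICAN AMERICAN")
  both_spec <- stratification_spec(
    min_age_at_last_dx = 60,
    race_ethnicity_values = "BLACK OR AFRICAN AMERICAN")
  age_only <- as.character(apply_strata(fx$asn, fx$demo, fx$pm, fx$dx,
                                        age_spec))
  race_only <- as.character(apply_strata(fx$asn, fx$demo, fx$pm, fx$dx,
                                         race_spec))
  both <- as.character(apply_strata(fx$asn, fx$demo, fx$pm, fx$dx,
                                    both_spec))
  expect_setequal(both, intersect(age_only, race_only))
  # idempotence: re-filtering the survivors changes nothing
  sub_asn <- fx$asn[fx$asn$patient_id %in% both, ]
  again <- as.character(apply_strata(sub_asn, fx$demo, fx$pm, fx$dx,
                                     both_spec))
  expect_setequal(again, both)
})

test_that("subsample_training is deterministic, exact, and role-preserving", {
  pool <- data.frame(patient_id = sprintf("t%03d", 1:1000),
                     status = "unknown", stringsAsFactors = FALSE)
  extra <- data.frame(patient_id = c("c1", "k1"),
                      status = c("carrier", "noncarrier_confirmed"))
  asn <- assign_roles(rbind(pool, extra))

  a <- subsample_training(asn, 100, seed = 5)
  b <- subsample_training(asn, 100, seed = 5)
  expect_identical(a, b)
  expect_equal(sum(a$role == "training"), 100L)
  expect_equal(a$role[a$patient_id == "c1"], "case")
  expect_equal(a$role[a$patient_id == "k1"], "control")

  c2 <- subsample_training(asn, 100, seed = 6)
  expect_false(identical(sort(c2$patient_id[c2$role == "training"]),
                         sort(a$patient_id[a$role == "training"])))

  full <- subsample_training(asn, 1000, seed = 5)
  expect_identical(full, asn)
  expect_error(subsample_training(asn, 1001, seed = 5), "exceeds")
})
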