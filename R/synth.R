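#' Specify a synthetic EHR cohort generator
#'
#' The generator emulates the statistical structure a genotype-first PheRS
#' study assumes, without claiming clinical realism: a rare carrier
#' genotype; per-feature baseline presence probabilities in the general
#' population; carrier effects expressed as odds ratios that switch on only
#' above a penetrance onset age (incomplete, age-dependent penetrance, the
#' hallmark of late-onset variants such as TTR V142I); and raw ICD-coded
#' encounters drawn from each feature's code group, so the full ingestion
#' and scoring path is exercised.
#'
#' @param n_patients cohort size (>= 1).
#' @param carrier_prevalence probability a patient carries the variant.
#' @param confirmed_noncarrier_fraction among non-carriers, the fraction
#'   with sequencing-confirmed absence (`noncarrier_confirmed`; the rest
#'   are `unknown` and become the training pool).
#' @param age_mean,age_sd age distribution in years (normal, truncated to
#'   \[18, 100\] by resampling).
#' @param penetrance_onset_age age (years) at which carrier odds ratios
#'   activate; below it carriers look like non-carriers.
#' @param onset_ramp_years 0 (default) for a hard threshold at onset;
#'   a positive value s replaces the step with a logistic ramp
#'   `plogis((age - onset)/s)` scaling the log odds ratio.
#' @param baseline_prob per-feature baseline presence probability, aligned
#'   with the feature map's feature order.
#' @param carrier_odds_ratio per-feature carrier odds ratio (> 0), applied
#'   on the odds scale when the age gate is open.
#' @param events_lambda Poisson rate: each present feature emits
#'   `1 + Poisson(events_lambda)` diagnosis events.
#' @param reference_year fixed calendar year the simulated "now" maps to;
#'   `birth_year = reference_year - age`, so ages round-trip through
#'   [age_at_last_diagnosis()].
#' @param race_levels,race_probs categorical race/ethnicity labels and
#'   sampling probabilities — present purely so stratification code paths
#'   run; no demographic realism is claimed.
#' @param sex_probs probabilities for `c("Female", "Male")`.
#' @param seed integer RNG seed; generation is fully deterministic given it.
#' @return validated list of class `synth_config`.
#' @export
synth_config <- function(n_patients,
                         carrier_prevalence = 0.013,
                         confirmed_noncarrier_fraction = 0.5,
                         age_mean = 65, age_sd = 17,
                         penetrance_onset_age = 60,
                         onset_ramp_years = 0,
                         baseline_prob,
                         carrier_odds_ratio,
                         events_lambda = 2,
                         reference_year = 2024,
                         race_levels = c("BLACK OR AFRICAN AMERICAN",
                                         "HISPANIC OR LATINO", "WHITE",
                                         "OTHERS"),
                         race_probs = c(0.25, 0.18, 0.28, 0.29),
                         sex_probs = c(0.6, 0.4),
                         seed = 1L) {
  stopifnot(n_patients >= 1,
            carrier_prevalence >= 0, carrier_prevalence < 1,
            confirmed_noncarrier_fraction >= 0,
            confirmed_noncarrier_fraction <= 1,
            age_sd > 0, onset_ramp_years >= 0,
            events_lambda >= 0,
            length(baseline_prob) == length(carrier_odds_ratio),
            all(baseline_prob > 0), all(baseline_prob < 1),
            all(carrier_odds_ratio > 0),
            length(race_levels) == length(race_probs))
  structure(
    list(n_patients = as.integer(n_patients),
         carrier_prevalence = carrier_prevalence,
         confirmed_noncarrier_fraction = confirmed_noncarrier_fraction,
         age_mean = age_mean, age_sd = age_sd,
         penetrance_onset_age = penetrance_onset_age,
         onset_ramp_years = onset_ramp_years,
         baseline_prob = baseline_prob,
         carrier_odds_ratio = carrier_odds_ratio,
         events_lambda = events_lambda,
         reference_year = as.integer(reference_year),
         race_levels = race_levels,
         race_probs = race_probs / sum(race_probs),
         sex_probs = sex_probs / sum(sex_probs),
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

# age gate in [0, 1]: how much of the carrier log-odds-ratio applies
age_gate <- function(age, onset, ramp) {
  if (ramp == 0) as.numeric(age >= onset)
  else stats::plogis((age - onset) / ramp)
}

#' Generate a synthetic EHR cohort
#'
#' For each patient: carrier status ~ Bernoulli(prevalence); age ~ normal
#' truncated to \[18, 100\]; each feature present with probability given by
#' baseline odds times the carrier odds ratio when the age gate is open;
#' each present feature emits `1 + Poisson(lambda)` diagnosis events with
#' codes uniform over the feature's code group and dates uniform over the
#' patient's adult years. Non-carriers are labelled
#' `noncarrier_confirmed` with the configured fraction, else `unknown`.
#'
#' The returned `truth` matrix records the latent per-patient feature
#' indicators used for emission. It exists for oracle tests only (emission
#' consistency: [presence_matrix()] on the emitted diagnoses reproduces it
#' exactly) and must never be consumed by scoring or evaluation.
#'
#' @param config a [synth_config()] whose per-feature parameter vectors
#'   align with `map`'s feature order.
#' @param map a [feature_map].
#' @return list of class `synth_cohort`: `diagnoses`, `demographics`,
#'   `genotypes` (the three ingestion tables), `truth` (0/1 matrix,
#'   patients x features), `config`.
#' @export
generate_cohort <- function(config, map) {
  P <- length(map$feature_ids)
  if (length(config$baseline_prob) != P) {
    stop(sprintf(
      "config has %d per-feature parameters but map has %d features",
      length(config$baseline_prob), P), call. = FALSE)
  }
  with_seed(config$seed, {
    n <- config$n_patients
    ids <- sprintf("P%06d", seq_len(n))
    carrier <- stats::runif(n) < config$carrier_prevalence

    # truncated-normal ages by resampling
    age <- stats::rnorm(n, config$age_mean, config$age_sd)
    bad <- which(age < 18 | age > 100)
    while (length(bad) > 0L) {
      age[bad] <- stats::rnorm(length(bad), config$age_mean, config$age_sd)
      bad <- bad[age[bad] < 18 | age[bad] > 100]
    }
    age <- as.integer(floor(age))

    gate <- age_gate(age, config$penetrance_onset_age,
                     config$onset_ramp_years) * carrier
    base_logodds <- stats::qlogis(config$baseline_prob)
    # n x P matrix of presence probabilities
    logodds <- outer(gate, log(config$carrier_odds_ratio)) +
      matrix(base_logodds, n, P, byrow = TRUE)
    truth <- matrix(
      as.integer(stats::runif(n * P) < stats::plogis(logodds)),
      n, P, dimnames = list(ids, map$feature_ids))

    # diagnosis emission: one block of events per present (patient, feature)
    pres <- which(truth == 1L, arr.ind = TRUE)
    if (nrow(pres) > 0L) {
      n_events <- 1L + stats::rpois(nrow(pres), config$events_lambda)
      pat_i <- rep(pres[, 1L], n_events)
      feat_i <- rep(pres[, 2L], n_events)
      n_ev <- length(pat_i)
      # uniform code draw within each event's feature
      feat_of_code <- match(map$features$feature_id, map$feature_ids)
      ord <- order(feat_of_code)
      codes_sorted <- map$features[ord, , drop = FALSE]
      sizes <- tabulate(feat_of_code, nbins = P)
      offsets <- cumsum(c(0L, sizes))[seq_len(P)]
      pick <- offsets[feat_i] +
        floor(stats::runif(n_ev) * sizes[feat_i]) + 1L
      # uniform event year over the patient's adult span
      span <- pmax(age[pat_i] - 18L, 0L)
      yr <- config$reference_year - age[pat_i] + 18L +
        as.integer(floor(stats::runif(n_ev) * (span + 1L)))
      doy <- as.integer(floor(stats::runif(n_ev) * 365)) # day of year, 0-364
      diagnoses <- data.frame(
        patient_id = ids[pat_i],
        icd_code = codes_sorted$code[pick],
        icd_version = codes_sorted$icd_version[pick],
        event_date = as.Date(sprintf("%d-01-01", yr)) + doy,
        stringsAsFactors = FALSE
      )
      diagnoses <- diagnoses[order(diagnoses$patient_id,
                                   diagnoses$event_date), , drop = FALSE]
      rownames(diagnoses) <- NULL
    } else {
      diagnoses <- data.frame(patient_id = character(0),
                              icd_code = character(0),
                              icd_version = integer(0),
                              event_date = as.Date(character(0)))
    }

    demographics <- data.frame(
      patient_id = ids,
      birth_year = config$reference_year - age,
      sex = sample(c("Female", "Male"), n, replace = TRUE,
                   prob = config$sex_probs),
      race_ethnicity = sample(config$race_levels, n, replace = TRUE,
                              prob = config$race_probs),
      stringsAsFactors = FALSE
    )
    status <- ifelse(
      carrier, "carrier",
      ifelse(stats::runif(n) < config$confirmed_noncarrier_fraction,
             "noncarrier_confirmed", "unknown"))
    genotypes <- data.frame(patient_id = ids, status = status,
                            stringsAsFactors = FALSE)
    structure(
      list(diagnoses = diagnoses, demographics = demographics,
           genotypes = genotypes, truth = truth, config = config),
      class = "synth_cohort"
    )
  })
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf(
    "<synth_cohort> %d patients, %d diagnosis events, %d carriers\n",
    nrow(x$demographics), nrow(x$diagnoses),
    sum(x$genotypes$status == "carrier")))
  invisible(x)
}

#' Write a synthetic cohort to the ingestion CSV dialects
#'
#' Emits `diagnoses.csv`, `demographics.csv`, `genotypes.csv` (exactly the
#' files [read_diagnoses()] and friends consume) plus `truth.csv`, the
#' latent feature indicators in long format for oracle use only.
#'
#' @param cohort a `synth_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_diagnoses(cohort$diagnoses, file.path(dir, "diagnoses.csv"))
  write_demographics(cohort$demographics,
                     file.path(dir, "demographics.csv"))
  write_genotypes(cohort$genotypes, file.path(dir, "genotypes.csv"))
  truth_long <- data.frame(
    patient_id = rep(rownames(cohort$truth), ncol(cohort$truth)),
    feature_id = rep(colnames(cohort$truth), each = nrow(cohort$truth)),
    present = as.integer(cohort$truth)
  )
  utils::write.csv(truth_long, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' ATTRv-like simulation preset
#'
#' A self-consistent configuration and feature map whose magnitudes echo a
#' variant-transthyretin-amyloidosis case-finding study: carrier prevalence
#' 0.013, penetrance onset at age 60, and 21 phenotype features spanning
#' 292 version-qualified codes, one flagged as the heart-failure-like
#' feature (`feature_id` `"f01"`, common baseline, used to exercise
#' feature-history stratification and score exclusion). All codes are
#' fabricated strings (`SF<feature><index>`) with no ICD semantics claimed;
#' the map is a synthetic stand-in, not a curated clinical artifact.
#'
#' Common, nonspecific features (heart-failure-like, arrhythmia-like) get
#' high baselines and moderate odds ratios; rarer, disease-specific
#' features get low baselines and larger odds ratios — the regime in which
#' log-inverse-frequency weighting is expected to help.
#'
#' @param n_patients cohort size for the returned config (default 35000).
#' @param seed RNG seed stored in the config (default 1).
#' @return list with elements `config` (a [synth_config()]) and `map`
#'   (a [feature_map] with 21 features / 292 codes).
#' @export
attrv_like_preset <- function(n_patients = 35000, seed = 1L) {
  n_feat <- 21L
  feature_names <- c(
    "heart failure (HF-like)", "atrial fibrillation-like",
    "other arrhythmia-like", "carpal tunnel-like",
    "polyneuropathy-like", "cardiomyopathy-like",
    "conduction disorder-like", "edema-like",
    "orthostatic hypotension-like", "cardiomegaly-like",
    "pleural effusion-like", "renal insufficiency-like",
    "gastroparesis-like", "diarrhea/constipation-like",
    "spinal stenosis-like", "biceps tendon rupture-like",
    "restrictive physiology-like", "low-voltage ECG-like",
    "amyloid organ deposit-like", "autonomic dysfunction-like",
    "vitreous opacity-like")
  feature_ids <- sprintf("f%02d", seq_len(n_feat))
  # 19 features x 14 codes + 2 x 13 = 292 codes
  codes_per_feature <- c(rep(14L, 19L), rep(13L, 2L))
  rows <- lapply(seq_len(n_feat), function(i) {
    j <- seq_len(codes_per_feature[i])
    data.frame(feature_id = feature_ids[i],
               feature_name = feature_names[i],
               icd_version = ifelse(j %% 2L == 0L, 9L, 10L),
               code = sprintf("SF%02dX%02d", i, j),
               stringsAsFactors = FALSE)
  })
  map <- feature_map("ATTRv-like (synthetic)", do.call(rbind, rows),
                     strict = TRUE)
  baseline <- c(0.20, 0.12, 0.08, 0.06, 0.05, 0.05, 0.04, 0.04, 0.03,
                0.03, 0.025, 0.025, 0.02, 0.02, 0.02, 0.015, 0.015,
                0.012, 0.01, 0.01, 0.01)
  odds_ratio <- c(4, 3, 3, 5, 5, 4, 3, 3, 6, 4, 4, 3, 5, 4, 3, 6, 5, 4,
                  8, 6, 5)
  config <- synth_config(
    n_patients = n_patients,
    carrier_prevalence = 0.013,
    confirmed_noncarrier_fraction = 0.5,
    age_mean = 65, age_sd = 17,
    penetrance_onset_age = 60,
    baseline_prob = baseline,
    carrier_odds_ratio = odds_ratio,
    events_lambda = 2,
    seed = seed
  )
  list(config = config, map = map)
}
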