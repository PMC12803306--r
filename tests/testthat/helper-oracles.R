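# Independent oracles: deliberately brute-force, enumeration-based
# implementations used only to check the fast paths in the package.

# AUC by exhaustive pair counting (ties count one half).
brute_auc <- function(case_scores, control_scores) {
  wins <- 0
  for (a in case_scores) {
    for (b in control_scores) {
      wins <- wins + (a > b) + 0.5 * (a == b)
    }
  }
  wins / (length(case_scores) * length(control_scores))
}

# Exact two-sided Wilcoxon rank-sum p-value by enumerating every
# assignment of group labels to the pooled, untied sample. Mirrors the
# doubled-smaller-tail definition of the exact test.
perm_wilcoxon_p <- function(case_scores, control_scores) {
  pooled <- c(case_scores, control_scores)
  stopifnot(anyDuplicated(pooled) == 0L)
  m <- length(case_scores)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  subsets <- utils::combn(length(pooled), m)
  u_all <- apply(subsets, 2L, function(idx) {
    sum(r[idx]) - m * (m + 1) / 2
  })
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Precision-at-k averaged over every way of filling the boundary-tie
# slots (enumerates subsets of the tie group; independent of the
# closed-form expectation in the package).
enum_tie_precision <- function(scores, labels, k) {
  kth <- sort(scores, decreasing = TRUE)[k]
  above <- which(scores > kth)
  tied <- which(scores == kth)
  m <- k - length(above)
  if (m == 0L) return(sum(labels[above]) / k)
  fills <- utils::combn(length(tied), m)
  mean(apply(fills, 2L, function(idx) {
    (sum(labels[above]) + sum(labels[tied[idx]])) / k
  }))
}

# Tiny two-feature map used across module tests.
toy_map <- function(strict = TRUE) {
  feature_map("toydisease", data.frame(
    feature_id = c("hf", "hf", "cts"),
    feature_name = c("heart failure", "heart failure", "carpal tunnel"),
    icd_version = c(10, 9, 10),
    code = c("I50.9", "428.0", "G56.0")
  ), strict = strict)
}

toy_events <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(patient_id = r[[1]], icd_code = r[[2]],
               icd_version = as.integer(r[[3]]),
               event_date = as.Date(r[[4]]), stringsAsFactors = FALSE)
  }))
  df$icd_code <- normalize_icd(df$icd_code)
  df
}

# Small zero-effect generator configuration for calibration-style tests:
# enough carriers and confirmed non-carriers per replicate to run the
# rank tests, all odds ratios 1.
null_effect_config <- function(n, seed) {
  synth_config(
    n_patients = n, carrier_prevalence = 0.25,
    confirmed_noncarrier_fraction = 0.7,
    age_mean = 65, age_sd = 17, penetrance_onset_age = 60,
    baseline_prob = c(0.3, 0.2, 0.15, 0.1, 0.1, 0.05),
    carrier_odds_ratio = rep(1, 6), events_lambda = 1, seed = seed)
}

null_effect_map <- function() {
  feature_map("nulldisease", data.frame(
    feature_id = sprintf("n%02d", rep(1:6, each = 2)),
    feature_name = sprintf("null feature %d", rep(1:6, each = 2)),
    icd_version = rep(c(9, 10), 6),
    code = sprintf("NU%02dX%d", rep(1:6, each = 2), rep(1:2, 6))
  ))
}

# Fit-score-evaluate a generated cohort; returns scores, labels, and the
# pieces tests poke at.
run_pipeline <- function(cohort, map, pseudocount = 0.5,
                         excluded = character(0)) {
  pm <- presence_matrix(cohort$diagnoses, map,
                        cohort$demographics$patient_id)
  asn <- assign_roles(cohort$genotypes)
  training <- asn$patient_id[asn$role == "training"]
  w <- fit_weights(pm, training, pseudocount = pseudocount)
  test_ids <- asn$patient_id[asn$role %in% c("case", "control")]
  sc <- score_cohort(pm[test_ids, , drop = FALSE], w,
                     excluded_features = excluded)
  labels <- as.integer(asn$role[match(test_ids, asn$patient_id)] == "case")
  list(presence = pm, assignment = asn, weights = w,
       scores = sc$score, score_set = sc, labels = labels,
       test_ids = test_ids)
}
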