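#' Assign case/control/training roles from genotype status
#'
#' The genotype-first cohort design: confirmed variant carriers are cases,
#' sequencing-confirmed non-carriers are controls, and everyone whose
#' status is unknown forms the "training" cohort used solely to estimate
#' feature frequencies — disjoint from the scored case/control set, so
#' weight fitting cannot leak the target label.
#'
#' @param genotypes data.frame as from [read_genotypes()].
#' @return `cohort_assignment`: data.frame with columns `patient_id`,
#'   `role` (`"case"`, `"control"`, `"training"`, or `"excluded"`).
#' @export
assign_roles <- function(genotypes) {
  role <- c(carrier = "case", noncarrier_confirmed = "control",
            unknown = "training")[genotypes$status]
  if (anyNA(role)) {
    stop("invalid genotype status: ",
         paste(unique(genotypes$status[is.na(role)]), collapse = ", "),
         call. = FALSE)
  }
  structure(
    data.frame(patient_id = genotypes$patient_id, role = unname(role),
               stringsAsFactors = FALSE),
    class = c("cohort_assignment", "data.frame")
  )
}

role_ids <- function(assignment, roles) {
  assignment$patient_id[assignment$role %in% roles]
}

#' Age at the last recorded diagnosis
#'
#' Computed in calendar years: year of the latest diagnosis date minus
#' birth year (only the year of birth is ingested, so finer arithmetic
#' would be spurious precision). Patients without any diagnosis get `NA`
#' and fail every age-based stratum rather than erroring — genotyped
#' individuals with no ICD data are a normal occurrence in biobanks.
#'
#' @param diagnoses data.frame as from [read_diagnoses()].
#' @param demographics data.frame as from [read_demographics()].
#' @return data.frame `patient_id`, `age` (integer years, `NA` if no
#'   diagnoses), one row per demographics patient.
#' @export
age_at_last_diagnosis <- function(diagnoses, demographics) {
  last_year <- tapply(as.integer(format(diagnoses$event_date, "%Y")),
                      diagnoses$patient_id, max)
  age <- unname(last_year[demographics$patient_id]) - demographics$birth_year
  data.frame(patient_id = demographics$patient_id, age = as.integer(age),
             stringsAsFactors = FALSE)
}

#' Build a stratification specification
#'
#' Deployment context for the score: restrict to patients old enough for
#' the disease's penetrance window, to the ancestry group carrying the
#' variant, and/or to patients with a history of a sentinel feature (e.g.
#' heart failure) — while removing that feature from the score itself to
#' avoid circularity.
#'
#' @param min_age_at_last_dx optional minimum [age_at_last_diagnosis()] in
#'   years; patients without diagnoses fail this filter.
#' @param race_ethnicity_values optional character vector of verbatim EHR
#'   race/ethnicity labels to keep (exact, case-sensitive match).
#' @param require_feature_history optional feature id; keep only patients
#'   whose presence-matrix entry for it is 1.
#' @param exclude_feature_from_score optional feature id to drop from
#'   scoring (consumed by [score_cohort()] callers, not by
#'   [apply_strata()]).
#' @return list of class `stratification_spec`.
#' @export
stratification_spec <- function(min_age_at_last_dx = NULL,
                                race_ethnicity_values = NULL,
                                require_feature_history = NULL,
                                exclude_feature_from_score = NULL) {
  structure(
    list(min_age_at_last_dx = min_age_at_last_dx,
         race_ethnicity_values = race_ethnicity_values,
         require_feature_history = require_feature_history,
         exclude_feature_from_score = exclude_feature_from_score),
    class = "stratification_spec"
  )
}

#' Apply stratification filters to a patient set
#'
#' Returns the intersection of all active filters over the assignment's
#' patient universe. Filters are independent set restrictions, so the
#' result does not depend on their order and applying the same spec twice
#' is a no-op. Per-filter attrition counts (patients failing each filter,
#' counted against the full universe) are attached for logging.
#'
#' @param assignment a `cohort_assignment` (defines the patient universe).
#' @param demographics data.frame as from [read_demographics()].
#' @param presence 0/1 matrix from [presence_matrix()]; required when
#'   `require_feature_history` is set.
#' @param diagnoses data.frame as from [read_diagnoses()]; required when
#'   `min_age_at_last_dx` is set.
#' @param spec a [stratification_spec()].
#' @return character vector of surviving patient ids, with attribute
#'   `attrition` (named integer vector of per-filter exclusion counts).
#' @export
apply_strata <- function(assignment, demographics, presence = NULL,
                         diagnoses = NULL, spec = stratification_spec()) {
  universe <- assignment$patient_id
  keep <- rep(TRUE, length(universe))
  attrition <- integer(0)
  if (!is.null(spec$min_age_at_last_dx)) {
    if (is.null(diagnoses)) {
      stop("age stratification needs the diagnosis table", call. = FALSE)
    }
    ages <- age_at_last_diagnosis(diagnoses, demographics)
    age <- ages$age[match(universe, ages$patient_id)]
    pass <- !is.na(age) & age >= spec$min_age_at_last_dx
    attrition["min_age_at_last_dx"] <- sum(!pass)
    keep <- keep & pass
  }
  if (!is.null(spec$race_ethnicity_values)) {
    race <- demographics$race_ethnicity[match(universe,
                                              demographics$patient_id)]
    pass <- !is.na(race) & race %in% spec$race_ethnicity_values
    attrition["race_ethnicity"] <- sum(!pass)
    if (!any(pass)) {
      warning("race/ethnicity filter matched no patients (labels: ",
              paste(spec$race_ethnicity_values, collapse = ", "), ")",
              call. = FALSE)
    }
    keep <- keep & pass
  }
  if (!is.null(spec$require_feature_history)) {
    feat <- spec$require_feature_history
    if (is.null(presence) || !feat %in% colnames(presence)) {
      stop("feature '", feat, "' not found in presence matrix",
           call. = FALSE)
    }
    col <- presence[match(universe, rownames(presence)), feat]
    pass <- !is.na(col) & col == 1L
    attrition["require_feature_history"] <- sum(!pass)
    keep <- keep & pass
  }
  structure(universe[keep], attrition = attrition)
}

#' Subsample the training cohort to a target size
#'
#' Used to study how many reference patients weight estimation actually
#' needs: draws a uniformly random subset of the current training patients
#' of exactly `target_size`, reassigning the rest to `"excluded"`. Case and
#' control roles are untouched. Deterministic given `seed`.
#'
#' @param assignment a `cohort_assignment`.
#' @param target_size number of training patients to keep.
#' @param seed integer RNG seed.
#' @return a new `cohort_assignment`.
#' @export
subsample_training <- function(assignment, target_size, seed) {
  pool <- role_ids(assignment, "training")
  target_size <- as.integer(target_size)
  if (target_size > length(pool)) {
    stop(sprintf("target_size %d exceeds training pool of %d",
                 target_size, length(pool)), call. = FALSE)
  }
  if (target_size == length(pool)) return(assignment)
  kept <- with_seed(seed, sample(pool, target_size))
  out <- assignment
  drop <- out$role == "training" & !out$patient_id %in% kept
  out$role[drop] <- "excluded"
  out
}
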