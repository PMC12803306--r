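#' Fit per-feature PheRS weights on a training cohort
#'
#' Weights follow the log-inverse-frequency scheme: the rarer a phenotype
#' feature is in a reference population, the more informative its presence.
#' For feature p with raw presence count c over the n training patients,
#' the frequency is continuity-corrected with a symmetric pseudocount a,
#' \deqn{f_p = (c + a) / (n + 2a),}
#' and the weight is \deqn{w_p = \log(1 / f_p).}
#' With the default pseudocount a = 0.5 a feature absent from the whole
#' training cohort keeps a finite (large) weight instead of being dropped —
#' rare curated features are exactly the informative ones. With `pseudocount
#' = 0` a zero-count feature has no defined weight and fitting errors.
#'
#' The training cohort must be disjoint from the cases and controls that
#' will be scored (see [assign_roles()]); fitting on scored patients leaks
#' the target.
#'
#' @param presence 0/1 matrix from [presence_matrix()], rows named by
#'   patient id.
#' @param training_ids patient ids to fit on; must be a nonempty subset of
#'   the matrix rows.
#' @param pseudocount symmetric continuity correction a >= 0 (default 0.5).
#' @param log_base base of the logarithm (default `exp(1)`). The base
#'   rescales every score by the same constant, so rankings, AUC and
#'   precision-at-k are unaffected by this choice.
#' @return a `weight_table`: data.frame with columns `feature_id`,
#'   `frequency`, `weight`, plus attributes `n_train`, `pseudocount`,
#'   `log_base`, `provenance = "fitted"`.
#' @export
fit_weights <- function(presence, training_ids, pseudocount = 0.5,
                        log_base = exp(1)) {
  if (length(training_ids) == 0L) {
    stop("training set is empty", call. = FALSE)
  }
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  missing <- setdiff(training_ids, rownames(presence))
  if (length(missing) > 0L) {
    stop("training ids absent from presence matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  sub <- presence[as.character(training_ids), , drop = FALSE]
  n <- nrow(sub)
  counts <- colSums(sub)
  if (pseudocount == 0 && any(counts == 0)) {
    stop("feature(s) with zero training count and pseudocount 0: ",
         paste(colnames(sub)[counts == 0], collapse = ", "),
         "; use a positive pseudocount", call. = FALSE)
  }
  f <- (counts + pseudocount) / (n + 2 * pseudocount)
  w <- log(1 / f, base = log_base)
  structure(
    data.frame(feature_id = colnames(presence), frequency = unname(f),
               weight = unname(w), stringsAsFactors = FALSE),
    n_train = n, pseudocount = pseudocount, log_base = log_base,
    provenance = "fitted",
    class = c("weight_table", "data.frame")
  )
}

#' Load a precomputed weight table
#'
#' Weights fitted in another health system (cross-system generalizability
#' runs) are supplied as a CSV with header `feature_id,weight` and an
#' optional `frequency` column. Without frequencies the table supports the
#' standard/precomputed score arithmetic only; the negative-weights variant
#' needs each feature's training frequency and errors without it.
#'
#' @param path CSV path.
#' @return a `weight_table` with `provenance = "precomputed"`.
#' @export
load_precomputed_weights <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  check_columns(df, c("feature_id", "weight"), "weight", path)
  dup <- which(duplicated(df$feature_id))
  if (length(dup) > 0L) report_rows(dup, "duplicate feature_id")
  w <- suppressWarnings(as.numeric(df$weight))
  bad <- which(is.na(w))
  if (length(bad) > 0L) report_rows(bad, "non-numeric weight")
  f <- rep(NA_real_, nrow(df))
  if ("frequency" %in% names(df)) {
    f <- suppressWarnings(as.numeric(df$frequency))
    badf <- which(is.na(f) & trimws(df$frequency) != "")
    if (length(badf) > 0L) report_rows(badf, "non-numeric frequency")
  }
  structure(
    data.frame(feature_id = df$feature_id, frequency = f, weight = w,
               stringsAsFactors = FALSE),
    n_train = if ("n_train" %in% names(df))
      suppressWarnings(as.integer(df$n_train[1L])) else NA_integer_,
    pseudocount = NA_real_, log_base = exp(1), provenance = "precomputed",
    class = c("weight_table", "data.frame")
  )
}

#' Write a weight table as CSV
#' @param weights a `weight_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(weights, path) {
  out <- data.frame(feature_id = weights$feature_id,
                    weight = weights$weight,
                    frequency = weights$frequency,
                    n_train = attr(weights, "n_train") %||% NA_integer_)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Score a cohort under a PheRS variant
#'
#' Three variants share one weight table:
#' \describe{
#'   \item{standard}{score = sum of `weight` over present, non-excluded
#'     features; a patient with no present features scores exactly 0.}
#'   \item{negative_weights}{presence contributes `weight` as in the
#'     standard variant, and absence of a feature contributes
#'     `log(1 - frequency)` (a non-positive penalty: missing a common
#'     disease feature is stronger evidence against the disease than
#'     missing a rare one). Requires frequencies with `f < 1`.}
#'   \item{precomputed}{identical arithmetic to standard; the name records
#'     that the weights came from [load_precomputed_weights()] rather than
#'     [fit_weights()] on this cohort.}
#' }
#' Excluded features contribute nothing under any variant — used e.g. to
#' drop the heart-failure feature when deploying inside a heart-failure
#' stratum, so the score is not circular.
#'
#' @param presence 0/1 matrix from [presence_matrix()].
#' @param weights a `weight_table` covering every non-excluded column of
#'   `presence`.
#' @param variant one of `"standard"`, `"negative_weights"`,
#'   `"precomputed"`.
#' @param excluded_features feature ids to leave out of the score.
#' @return a `score_set`: data.frame with columns `patient_id`, `score`,
#'   and attributes `variant`, `excluded_features`, `presence` (the scored
#'   submatrix).
#' @export
score_cohort <- function(presence, weights,
                         variant = c("standard", "negative_weights",
                                     "precomputed"),
                         excluded_features = character(0)) {
  variant <- match.arg(variant)
  feats <- colnames(presence)
  unknown <- setdiff(excluded_features, feats)
  if (length(unknown) > 0L) {
    stop("excluded feature(s) not in presence matrix: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  keep <- setdiff(feats, excluded_features)
  if (length(keep) == 0L) stop("no features left to score", call. = FALSE)
  miss <- setdiff(keep, weights$feature_id)
  if (length(miss) > 0L) {
    stop("feature(s) missing from weight table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  idx <- match(keep, weights$feature_id)
  w <- weights$weight[idx]
  P <- presence[, keep, drop = FALSE]
  if (variant == "negative_weights") {
    f <- weights$frequency[idx]
    if (anyNA(f)) {
      stop("negative_weights variant requires per-feature frequencies; ",
           "this weight table has none for: ",
           paste(keep[is.na(f)], collapse = ", "), call. = FALSE)
    }
    if (any(f >= 1)) {
      stop("negative_weights variant requires frequency < 1; offending ",
           "feature(s): ", paste(keep[f >= 1], collapse = ", "),
           call. = FALSE)
    }
    base <- attr(weights, "log_base") %||% exp(1)
    absent_term <- log(1 - f, base = base)
    scores <- as.numeric(P %*% w + (1 - P) %*% absent_term)
  } else {
    scores <- as.numeric(P %*% w)
  }
  structure(
    data.frame(patient_id = rownames(presence), score = scores,
               stringsAsFactors = FALSE),
    variant = variant, excluded_features = excluded_features,
    presence = P,
    class = c("score_set", "data.frame")
  )
}

#' Write scores as CSV
#' @param scores a `score_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  out <- data.frame(patient_id = scores$patient_id, score = scores$score,
                    variant = attr(scores, "variant") %||% "standard")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
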