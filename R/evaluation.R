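#' Wilcoxon rank-sum test on case vs control scores
#'
#' Two-sided test that case and control score distributions differ — the
#' conventional headline statistic in the phenotype-risk-score literature.
#' Note that on heavily imbalanced cohorts a significant p-value can
#' coexist with almost completely overlapping distributions, which is why
#' [evaluate()] also reports AUC and precision-at-k.
#'
#' `mode = "auto"` uses the exact null distribution when the pooled sample
#' has at most 12 observations and no ties, and the tie-corrected normal
#' approximation with continuity correction otherwise. `"exact"` and
#' `"normal"` force the choice (`"exact"` with tied data is an error, as
#' the exact distribution assumes continuity).
#'
#' @param case_scores,control_scores nonempty numeric vectors.
#' @param mode `"auto"` (default), `"exact"`, or `"normal"`.
#' @return two-sided p-value in (0, 1].
#' @export
wilcoxon_rank_sum <- function(case_scores, control_scores,
                              mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (length(case_scores) == 0L || length(control_scores) == 0L) {
    stop("both score groups must be nonempty", call. = FALSE)
  }
  pooled <- c(case_scores, control_scores)
  ties <- anyDuplicated(pooled) > 0L
  exact <- switch(mode,
                  auto = length(pooled) <= 12L && !ties,
                  exact = TRUE,
                  normal = FALSE)
  if (mode == "exact" && ties) {
    stop("exact mode is unavailable with tied scores; use mode = 'normal'",
         call. = FALSE)
  }
  # degenerate pooled sample (all values equal): no separation, p = 1
  if (length(unique(pooled)) == 1L) return(1.0)
  res <- suppressWarnings(
    stats::wilcox.test(case_scores, control_scores, alternative = "two.sided",
                       exact = exact, correct = TRUE)
  )
  unname(res$p.value)
}

#' Mann-Whitney AUC of case vs control scores
#'
#' The probability that a uniformly random case outscores a uniformly
#' random control, ties counted one-half:
#' \deqn{AUC = [\#(case > control) + 0.5\,\#(case = control)]
#'   / (n_{case} n_{control}),}
#' computed via the rank-sum identity, which equals brute-force pair
#' counting exactly.
#'
#' @param case_scores,control_scores nonempty numeric vectors.
#' @return AUC in \[0, 1\].
#' @export
auc_mann_whitney <- function(case_scores, control_scores) {
  m <- length(case_scores)
  n <- length(control_scores)
  if (m == 0L || n == 0L) {
    stop("both score groups must be nonempty", call. = FALSE)
  }
  r <- rank(c(case_scores, control_scores))
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  u / (m * n)
}

#' Precision among the top-k scoring individuals
#'
#' Models the yield of sending the k highest-scoring patients for genetic
#' testing: the fraction of those k who are true cases. Ties at the k-th
#' score are resolved deterministically. Let A be the individuals strictly
#' above the k-th order statistic, T the tie group at that score, and
#' m = k - |A| the slots filled from T:
#' \describe{
#'   \item{expected}{the mean over all ways of drawing m of |T|:
#'     precision = (cases(A) + m * cases(T)/|T|) / k. Reproducible with no
#'     random tie-break; the default.}
#'   \item{pessimistic}{fills the m slots with controls from T first.}
#'   \item{optimistic}{fills them with cases first.}
#' }
#' At k = n every policy returns the overall case prevalence.
#'
#' @param scores numeric vector.
#' @param labels 0/1 vector aligned with `scores` (1 = case).
#' @param k number of top slots, 1 <= k <= length(scores).
#' @param tie_policy `"expected"` (default), `"pessimistic"`, or
#'   `"optimistic"`.
#' @return precision in \[0, 1\].
#' @export
precision_at_k <- function(scores, labels, k,
                           tie_policy = c("expected", "pessimistic",
                                          "optimistic")) {
  tie_policy <- match.arg(tie_policy)
  n <- length(scores)
  if (length(labels) != n) {
    stop("scores and labels have different lengths", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1))) {
    stop("labels must be 0/1", call. = FALSE)
  }
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > n) {
    stop(sprintf("k must be in [1, %d]", n), call. = FALSE)
  }
  kth <- sort(scores, decreasing = TRUE)[k]
  above <- scores > kth
  tied <- scores == kth
  m <- k - sum(above)
  cases_above <- sum(labels[above])
  cases_tied <- sum(labels[tied])
  n_tied <- sum(tied)
  from_ties <- switch(
    tie_policy,
    expected = m * cases_tied / n_tied,
    pessimistic = max(0L, m - (n_tied - cases_tied)),
    optimistic = min(m, cases_tied)
  )
  (cases_above + from_ties) / k
}

#' Default k grid for precision-at-k curves
#'
#' Dense where small cohorts of prioritized patients are actionable and
#' sparse beyond: 10 to 100 in steps of 10, 200 to 1000 in steps of 100,
#' then three points per decade (spacing 10^(1/3), i.e.
#' `round(10^(3 + j/3))`) until the cohort size n, which always terminates
#' the grid.
#'
#' @param n cohort size, at least 10.
#' @return strictly increasing integer vector ending in `n`.
#' @export
default_k_grid <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 10L) stop("n must be at least 10", call. = FALSE)
  ks <- c(seq(10L, 100L, by = 10L), seq(200L, 1000L, by = 100L))
  j <- 1L
  repeat {
    v <- as.integer(round(10^(3 + j / 3)))
    if (v >= n) break
    ks <- c(ks, v)
    j <- j + 1L
  }
  sort(unique(c(ks[ks <= n], n)))
}

#' Expected precision of random prioritization
#'
#' A strategy that flags patients at random achieves, in expectation, the
#' cohort's case prevalence at every k; this is the baseline every curve in
#' [evaluate()] is drawn against, and the exact precision at k = n.
#'
#' @param labels nonempty 0/1 vector.
#' @return case fraction in \[0, 1\].
#' @export
random_baseline_precision <- function(labels) {
  if (length(labels) == 0L) stop("labels must be nonempty", call. = FALSE)
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  mean(labels)
}

#' Full discrimination and prioritization report
#'
#' Assembles the Wilcoxon rank-sum p-value, Mann-Whitney AUC, and the
#' precision-at-k curve over a k grid, next to the random-prioritization
#' baseline. Deterministic given its inputs (no random tie-breaking).
#'
#' @param scores numeric vector of PheRS values.
#' @param labels 0/1 vector aligned with `scores` (1 = case).
#' @param k_grid increasing k values within `[1, length(scores)]`; default
#'   [default_k_grid()] of the cohort size.
#' @param tie_policy passed to [precision_at_k()].
#' @param mode passed to [wilcoxon_rank_sum()].
#' @return object of class `phers_eval`: list with `p_value`, `auc`,
#'   `precision_curve` (data.frame `k`, `precision`, `baseline`),
#'   `baseline_prevalence`, `n_cases`, `n_controls`.
#' @export
evaluate <- function(scores, labels, k_grid = NULL,
                     tie_policy = "expected", mode = "auto") {
  n <- length(scores)
  if (length(labels) != n) {
    stop("scores and labels have different lengths", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  if (is.null(k_grid)) k_grid <- default_k_grid(n)
  k_grid <- as.integer(k_grid)
  if (any(is.na(k_grid)) || any(k_grid < 1L) || any(k_grid > n) ||
      is.unsorted(k_grid, strictly = TRUE)) {
    stop("k_grid must be strictly increasing within [1, n]", call. = FALSE)
  }
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  if (length(cases) == 0L || length(controls) == 0L) {
    stop("evaluation needs at least one case and one control",
         call. = FALSE)
  }
  prev <- random_baseline_precision(labels)
  curve <- data.frame(
    k = k_grid,
    precision = vapply(k_grid, function(k) {
      precision_at_k(scores, labels, k, tie_policy)
    }, numeric(1)),
    baseline = prev
  )
  structure(
    list(p_value = wilcoxon_rank_sum(cases, controls, mode = mode),
         auc = auc_mann_whitney(cases, controls),
         precision_curve = curve,
         baseline_prevalence = prev,
         n_cases = length(cases),
         n_controls = length(controls)),
    class = "phers_eval"
  )
}

#' @export
print.phers_eval <- function(x, ...) {
  cat(sprintf(
    "<phers_eval> %d cases vs %d controls\n  Wilcoxon p = %.3g | AUC = %.3f | prevalence = %.4g\n",
    x$n_cases, x$n_controls, x$p_value, x$auc, x$baseline_prevalence))
  show_k <- x$precision_curve[x$precision_curve$k %in%
                                c(100L, 200L, max(x$precision_curve$k)), ]
  for (i in seq_len(nrow(show_k))) {
    cat(sprintf("  precision@%-6d = %.4f\n", show_k$k[i],
                show_k$precision[i]))
  }
  invisible(x)
}

#' Serialize an evaluation report
#'
#' Writes the report as JSON and, optionally, the precision curve as CSV
#' (`k,precision,baseline`).
#'
#' @param report a `phers_eval`.
#' @param json_path output JSON path.
#' @param csv_path optional output CSV path for the curve.
#' @return `json_path`, invisibly.
#' @export
write_eval_report <- function(report, json_path, csv_path = NULL) {
  jsonlite::write_json(
    list(p_value = report$p_value, auc = report$auc,
         baseline_prevalence = report$baseline_prevalence,
         n_cases = report$n_cases, n_controls = report$n_controls,
         precision_curve = report$precision_curve),
    json_path, auto_unbox = TRUE, dataframe = "columns", digits = NA)
  if (!is.null(csv_path)) {
    utils::write.csv(report$precision_curve, csv_path, row.names = FALSE)
  }
  invisible(json_path)
}
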