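#' Diagnostic validity of total scores against the criterion reference
#'
#' ROC analysis of informant totals against the family caseness label:
#' candidate cutpoints, the equal-sensitivity/specificity optimal cutoff,
#' Mann-Whitney AUC with a Hanley-McNeil normal-approximation CI, exact
#' binomial CIs for sensitivity and specificity, and cross-reporter
#' correlations. The classification rule is distressed iff
#' `total >= threshold`.
#'
#' @name diagnostic_validity
NULL

check_labels <- function(labels) {
  labels <- as.logical(labels)
  if (anyNA(labels)) stop("labels must be case/non-case", call. = FALSE)
  if (length(unique(labels)) < 2) {
    stop("degenerate labels: need both cases and non-cases",
         call. = FALSE)
  }
  labels
}

#' Empirical ROC curve
#'
#' Candidate thresholds are the midpoints between consecutive distinct
#' observed scores, plus one sentinel below the minimum and one above the
#' maximum, so every achievable confusion matrix appears exactly once.
#'
#' @param scores Numeric informant totals.
#' @param labels Logical (or coercible) caseness of each informant's
#'   family: `TRUE` = case.
#' @return Tibble of `threshold`, `sensitivity`, `specificity`, ordered by
#'   increasing threshold.
#' @export
roc_curve <- function(scores, labels) {
  labels <- check_labels(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  s <- sort(unique(scores))
  thr <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
           s[length(s)] + 1)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  se <- vapply(thr, function(t) sum(scores[labels] >= t) / n1, numeric(1))
  sp <- vapply(thr, function(t) sum(scores[!labels] < t) / n0, numeric(1))
  tibble::tibble(threshold = thr, sensitivity = se, specificity = sp)
}

#' Optimal cutpoint from an ROC curve
#'
#' The default method picks the threshold at which sensitivity and
#' specificity are closest (minimum |Se - Sp|), breaking ties by the
#' larger Se + Sp and then by the smaller threshold — the
#' equal-sensitivity/specificity criterion used to set the published
#' cutoffs. `method = "youden"` maximises Se + Sp - 1 instead (same tie
#' breaks on |Se - Sp| then smaller threshold).
#'
#' @param roc Output of [roc_curve()].
#' @param method `"equal_se_sp"` (default) or `"youden"`.
#' @return List with `threshold`, `sensitivity`, `specificity`.
#' @export
optimal_cutpoint <- function(roc, method = c("equal_se_sp", "youden")) {
  method <- match.arg(method)
  stopifnot(nrow(roc) > 0)
  d <- abs(roc$sensitivity - roc$specificity)
  y <- roc$sensitivity + roc$specificity
  ord <- if (method == "equal_se_sp") {
    order(d, -y, roc$threshold)
  } else {
    order(-y, d, roc$threshold)
  }
  best <- roc[ord[1], ]
  list(threshold = best$threshold, sensitivity = best$sensitivity,
       specificity = best$specificity)
}

#' Mann-Whitney AUC
#'
#' The probability that a randomly chosen case scores above a randomly
#' chosen non-case, ties counted one half — identical to the area under
#' the empirical ROC curve.
#'
#' @inheritParams roc_curve
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- check_labels(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Hanley-McNeil confidence interval for an AUC
#'
#' Normal approximation `auc +/- z * SE` with the Hanley-McNeil standard
#' error. The interval is deliberately not truncated to \[0, 1\]: with
#' small samples and a high AUC the upper bound can exceed 1, as in the
#' published tables.
#'
#' @param auc AUC estimate in \[0, 1\].
#' @param n_case,n_noncase Class sizes (>= 1).
#' @param level Confidence level (default 0.95).
#' @return Numeric `c(lower, upper)`.
#' @export
auc_ci <- function(auc, n_case, n_noncase, level = 0.95) {
  stopifnot(auc >= 0, auc <= 1)
  if (n_case < 1 || n_noncase < 1) {
    stop("degenerate labels: need cases and non-cases", call. = FALSE)
  }
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_case - 1) * (q1 - auc^2) +
              (n_noncase - 1) * (q2 - auc^2)) / (n_case * n_noncase))
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(lower = auc - z * se, upper = auc + z * se)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' @param successes,trials Counts with `0 <= successes <= trials`,
#'   `trials >= 1`.
#' @param level Confidence level (default 0.95).
#' @return Numeric `c(lower, upper)`; the lower bound is 0 at
#'   `successes = 0` and the upper bound 1 at `successes = trials`.
#' @export
binomial_ci <- function(successes, trials, level = 0.95) {
  if (trials < 1) stop("trials must be >= 1", call. = FALSE)
  stopifnot(successes >= 0, successes <= trials)
  a <- (1 - level) / 2
  lower <- if (successes == 0) 0 else
    stats::qbeta(a, successes, trials - successes + 1)
  upper <- if (successes == trials) 1 else
    stats::qbeta(1 - a, successes + 1, trials - successes)
  c(lower = lower, upper = upper)
}

#' Full diagnostic report at a cutoff
#'
#' Confusion counts under `total >= cutoff` => distressed, accuracy,
#' sensitivity and specificity with exact binomial CIs, and the AUC with
#' its Hanley-McNeil CI.
#'
#' @inheritParams roc_curve
#' @param cutoff Classification threshold.
#' @param alpha Optional internal-consistency alpha to carry in the report.
#' @param reporter_group Optional group tag for the report.
#' @param level Confidence level for all intervals.
#' @return A one-row tibble mirroring the published diagnostic table:
#'   cutoff, alpha, confusion counts, accuracy, AUC and Se/Sp with CIs.
#' @export
evaluate <- function(scores, labels, cutoff, alpha = NA_real_,
                     reporter_group = NA_character_, level = 0.95) {
  labels <- check_labels(labels)
  stopifnot(is.finite(cutoff))
  pred <- scores >= cutoff
  tp <- sum(pred & labels)
  fn <- sum(!pred & labels)
  tn <- sum(!pred & !labels)
  fp <- sum(pred & !labels)
  se <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  a <- auc(scores, labels)
  aci <- auc_ci(a, sum(labels), sum(!labels), level)
  seci <- binomial_ci(tp, tp + fn, level)
  spci <- binomial_ci(tn, tn + fp, level)
  tibble::tibble(
    reporter_group = reporter_group,
    cutoff = cutoff, alpha = alpha,
    true_positives = tp, false_negatives = fn,
    true_negatives = tn, false_positives = fp,
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    auc = a, auc_lower = aci[["lower"]], auc_upper = aci[["upper"]],
    sensitivity = se, se_lower = seci[["lower"]], se_upper = seci[["upper"]],
    specificity = sp, sp_lower = spci[["lower"]], sp_upper = spci[["upper"]]
  )
}

#' Correlation between child and adult totals
#'
#' Pearson correlation of child and adult total scores paired by family,
#' optionally restricted to one adult role (to mirror the published
#' child-man and child-woman correlations).
#'
#' @param scores Score table from [score_cohort()] (needs `family_id`,
#'   `reporter_group`, `total`, and `role` when filtering).
#' @param adult_role Optional: `"adult-female"` or `"adult-male"` to pair
#'   the child with that adult only; default pairs with the mean adult
#'   total per family.
#' @param roster Roster table (`informant_id`, `role`) required when
#'   `adult_role` is given and `scores` lacks a `role` column.
#' @return Pearson correlation over families with both reporters present.
#' @export
reporter_correlation <- function(scores, adult_role = NULL, roster = NULL) {
  sc <- tibble::as_tibble(scores)
  if (!is.null(adult_role) && !"role" %in% names(sc)) {
    if (is.null(roster)) {
      stop("need a roster with roles to filter by adult role",
           call. = FALSE)
    }
    sc <- dplyr::left_join(sc, roster[, c("informant_id", "role")],
                           by = "informant_id")
  }
  child <- sc[sc$reporter_group == "child" & sc$valid, ]
  adult <- sc[sc$reporter_group == "adult" & sc$valid, ]
  if (!is.null(adult_role)) adult <- adult[adult$role == adult_role, ]
  adult <- dplyr::summarise(dplyr::group_by(adult, .data$family_id),
                            adult_total = mean(.data$total),
                            .groups = "drop")
  child <- dplyr::summarise(dplyr::group_by(child, .data$family_id),
                            child_total = mean(.data$total),
                            .groups = "drop")
  pairs <- dplyr::inner_join(child, adult, by = "family_id")
  if (nrow(pairs) < 3) {
    stop("insufficient pairs: need >= 3 families with both reporters",
         call. = FALSE)
  }
  stats::cor(pairs$child_total, pairs$adult_total)
}
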