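#!/usr/bin/env Rscript
# Stage 6 — diagnostic validity against the criterion reference.
#
# For each reporter group: the ROC of informant totals against the
# family caseness label, the cutoff that equalizes sensitivity and
# specificity, the Mann-Whitney AUC with a Hanley-McNeil interval,
# exact binomial intervals for Se/Sp, standardized alpha, and the
# child-adult score correlations.

suppressPackageStartupMessages({library(ftsvalid); library(dplyr)})

scores <- utils::read.csv("results/scores.csv")
labels <- utils::read.csv("results/caseness.csv")
responses <- utils::read.csv("results/cohort/responses.csv")
roster <- utils::read.csv("results/cohort/roster.csv")
selection <- utils::read.csv("results/selection.csv")

items <- battery_items()
items$in_final_scale <- items$item_id %in%
  selection$item_id[selection$selected]
scale_items <- items[items$in_final_scale, ]
item_rows <- split(scale_items, scale_items$item_id)

retained <- labels[labels$label != "dropped", c("family_id", "label")]
sc <- inner_join(scores[scores$valid, ], retained, by = "family_id")

alpha_for <- function(group) {
  sel <- if (group == "child") responses$role == "child" else
    responses$role != "child"
  d <- responses[sel & responses$item_id %in% scale_items$item_id, ]
  d$value <- NA_real_
  for (id in unique(d$item_id)) {
    rows <- d$item_id == id
    code <- code_response(d$response[rows], item_rows[[id]])
    d$value[rows] <- transform_item(code, item_rows[[id]])
  }
  wide <- tidyr::pivot_wider(d[, c("informant_id", "item_id", "value")],
                             names_from = "item_id",
                             values_from = "value")
  mat <- as.matrix(wide[, -1])
  keep <- apply(mat, 2, stats::var, na.rm = TRUE) > 0
  standardized_alpha(mat[, keep, drop = FALSE])
}

validity <- bind_rows(lapply(c("adult", "child"), function(g) {
  d <- sc[sc$reporter_group == g, ]
  roc <- roc_curve(d$total, d$label == "case")
  cut <- optimal_cutpoint(roc)
  evaluate(d$total, d$label == "case", cut$threshold,
           alpha = alpha_for(g), reporter_group = g)
}))
utils::write.csv(validity, "results/validity.csv", row.names = FALSE)

cnt <- caseness_counts(labels)
report <- format_validity_report(validity, cnt)
writeLines(report, "results/validity_report.txt")
writeLines(report)

r_man <- tryCatch(
  reporter_correlation(scores, "adult-male", roster),
  error = function(e) NA_real_)
r_woman <- tryCatch(
  reporter_correlation(scores, "adult-female", roster),
  error = function(e) NA_real_)
cat(sprintf(
  "\nChild-adult score correlations: r(child, man) = %.2f, r(child, woman) = %.2f\n",
  r_man, r_woman))
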