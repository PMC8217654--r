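#!/usr/bin/env Rscript
# Stage 5 — score the index test.
#
# Codes every informant's responses on the selected items, rescales each
# item to 0-1 and sums to the 0-30 total (prorating when at least 90% of
# items are answered). Higher totals mean more family distress.

suppressPackageStartupMessages(library(ftsvalid))

responses <- utils::read.csv("results/cohort/responses.csv")
selection <- utils::read.csv("results/selection.csv")

items <- battery_items()
items$in_final_scale <- items$item_id %in%
  selection$item_id[selection$selected]

scores <- score_cohort(responses, items)
utils::write.csv(scores, "results/scores.csv", row.names = FALSE)

for (g in c("adult", "child")) {
  s <- scores$total[scores$reporter_group == g & scores$valid]
  cat(sprintf("%s scores: n = %d, mean %.1f, range %.1f-%.1f\n",
              g, length(s), mean(s), min(s), max(s)))
}
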