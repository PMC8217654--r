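#!/usr/bin/env Rscript
# Stage 3 — gradient screening of the 66-item battery.
#
# For every item and reporter group, computes the endorsement proportion
# among case and non-case informants (6-10 on the ladder, 2-3 on the
# coded communication scale) and their difference, the gradient score.
# Items from dropped families are excluded.

suppressPackageStartupMessages(library(ftsvalid))

responses <- utils::read.csv("results/cohort/responses.csv")
labels <- utils::read.csv("results/caseness.csv")

gradients <- gradient_table(responses, labels, battery_items())
utils::write.csv(gradients, "results/gradients.csv", row.names = FALSE)

top <- gradients[order(-gradients$gradient), ]
cat(sprintf("Computed %d item x reporter-group gradients.\n",
            nrow(gradients)))
cat("Strongest discriminators:\n")
for (i in 1:5) {
  cat(sprintf("  %s (%s): %.1f%% (case %.1f%% vs non-case %.1f%%)\n",
              top$item_id[i], top$reporter_group[i],
              100 * top$gradient[i], 100 * top$p_case[i],
              100 * top$p_noncase[i]))
}
cat(sprintf("Items with negative gradients in both groups: %d\n",
            sum(tapply(gradients$gradient, gradients$item_id,
                       function(g) all(g < 0)))))
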