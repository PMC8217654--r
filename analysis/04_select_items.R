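#!/usr/bin/env Rscript
# Stage 4 — cross-validated importance and item selection.
#
# Trains a CART tree, bagged trees and a random forest to predict family
# caseness from the coded battery (adults and children separately) under
# 5x10 stratified cross-validation grouped by family, averages each
# model's built-in variable importance over the training fits, and
# combines top-20 importance membership with gradient evidence to select
# the 30-item index test.

suppressPackageStartupMessages({library(ftsvalid); library(dplyr)})

seed <- 42
responses <- utils::read.csv("results/cohort/responses.csv")
labels <- utils::read.csv("results/caseness.csv")
gradients <- utils::read.csv("results/gradients.csv")
items <- battery_items()

retained <- labels[labels$label != "dropped", ]
resp <- responses[responses$family_id %in% retained$family_id, ]

code_wide <- function(group) {
  sel <- if (group == "child") resp$role == "child" else
    resp$role != "child"
  d <- resp[sel, ]
  item_rows <- split(items, items$item_id)
  d$code <- NA_real_
  for (id in unique(d$item_id)) {
    rows <- d$item_id == id
    d$code[rows] <- code_response(d$response[rows], item_rows[[id]])
  }
  tidyr::pivot_wider(d[, c("informant_id", "family_id", "item_id", "code")],
                     names_from = "item_id", values_from = "code")
}

imp <- bind_rows(lapply(c("adult", "child"), function(g) {
  wide <- code_wide(g)
  xy <- left_join(wide, retained[, c("family_id", "label")],
                  by = "family_id")
  fit_importance_models(
    xy[, setdiff(names(xy), c("informant_id", "family_id", "label"))],
    xy$label == "case", xy$family_id, reporter_group = g,
    seed = seed + match(g, c("adult", "child"))
  )
}))
agg <- aggregate_importance(imp, k = 20)
utils::write.csv(agg, "results/importance.csv", row.names = FALSE)

selection <- select_items(gradients, agg, target_size = 30)
utils::write.csv(selection, "results/selection.csv", row.names = FALSE)

cat(sprintf("Selected %d of %d items.\n", sum(selection$selected),
            nrow(selection)))
planted_pos <- grepl("^FTS", selection$item_id)
cat(sprintf(
  "Planted discriminating items recovered: %d/30 (null/negative items selected: %d)\n",
  sum(selection$selected & planted_pos),
  sum(selection$selected & !planted_pos)))
writeLines(c(
  "Selected:",
  paste(" ", selection$item_id[selection$selected], collapse = ""),
  "Not selected:",
  paste(" ", selection$item_id[!selection$selected], collapse = "")
), "results/selection_report.txt")
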