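#!/usr/bin/env Rscript
# Stage 1 — simulate a study-shaped cohort.
#
# Draws a synthetic multi-informant cohort with the shape of the
# validation study: 30 families, 1-2 adult informants plus one child
# each, three imperfect criterion sources tied to a latent distress
# state, and a 66-item battery with planted discriminating, null and
# negatively discriminating items.

suppressPackageStartupMessages(library(ftsvalid))

seed <- 42
out_dir <- "results/cohort"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cohort <- generate_cohort(generator_config(seed = seed))

utils::write.csv(cohort$roster, file.path(out_dir, "roster.csv"),
                 row.names = FALSE)
utils::write.csv(cohort$families, file.path(out_dir, "families.csv"),
                 row.names = FALSE)
utils::write.csv(cohort$members, file.path(out_dir, "members.csv"),
                 row.names = FALSE)
utils::write.csv(cohort$responses, file.path(out_dir, "responses.csv"),
                 row.names = FALSE)
utils::write.csv(cohort$truth, file.path(out_dir, "ground_truth.csv"),
                 row.names = FALSE)
utils::write.csv(cohort$item_params, file.path(out_dir, "item_params.csv"),
                 row.names = FALSE)

n_adults <- sum(cohort$roster$role != "child")
cat(sprintf(
  "Simulated %d families (%d adults, %d children), %d latently distressed.\n",
  nrow(cohort$families), n_adults,
  sum(cohort$roster$role == "child"), sum(cohort$truth$distressed)))
cat(sprintf("Responses: %d informant x item records -> %s\n",
            nrow(cohort$responses), out_dir))
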