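#!/usr/bin/env Rscript
# Stage 4 — select the proposed models and summarize.
#
# Following the survey's reasoning, model choice is driven by validation
# APS (not training APS), and the final proposal is restricted to the
# 10-input models: per output variable, the reduced model with the best
# validation APS.

suppressPackageStartupMessages(library(tomauth))
catalog <- read.csv("results/aps.csv", stringsAsFactors = FALSE)

reduced <- catalog[catalog$type %in% c("ANN_3", "ANN_4"), ]
selected <- select_models(reduced)

rows <- do.call(rbind, selected)
write.csv(rows, "results/selected_models.csv", row.names = FALSE)

lines <- c("Proposed 10-input authentication models:")
for (v in names(selected)) {
  r <- selected[[v]]
  lines <- c(lines, sprintf(
    "  %-8s %-6s %-8s %6d cycles  APS: training %.1f / validation %.1f / average %.1f",
    v, r$type, r$topology, r$cycles,
    round_half_up(r$aps_training, 1), round_half_up(r$aps_validation, 1),
    round_half_up(r$aps_average, 1)))
}
pc <- read.csv("results/per_class.csv", stringsAsFactors = FALSE)
for (v in names(selected)) {
  sub <- pc[pc$model_id == selected[[v]]$model_id & pc$output == v, ]
  lines <- c(lines, sprintf("  per-class success (%s): %s", v,
    paste(sprintf("%s %.1f%%", sub$class, round_half_up(sub$success_pct, 1)),
          collapse = ", ")))
}
writeLines(lines)
writeLines(lines, "results/summary.txt")
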