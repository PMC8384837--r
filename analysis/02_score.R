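#!/usr/bin/env Rscript
# Score every variant: log2 enrichment per base, specificity, QC flags.

suppressPackageStartupMessages(library(pufcode))
if (!file.exists("results/counts_input.tsv"))
  stop("run analysis/01_simulate.R first")

inp <- read_count_table("results/counts_input.tsv")
sel <- read_count_table("results/counts_selected.tsv")
scores <- interaction_scores(inp, sel)
write.table(scores, "results/scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("scored %d variants (%d dropped: absent from input)\n",
            nrow(scores), nrow(attr(scores, "dropped"))))
cat(sprintf("nonsense false-positive rate: %.4f\n", nonsense_fpr(scores)))

hits <- select_hits(scores)          # interaction > 5, specificity > 4
write.table(hits, "results/hits.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("hits per repeat (interaction score > 5, specificity > 4):\n")
print(table(factor(hits$repeat_id, levels = 1:8)))
cat("preferred bases among hits:\n")
print(table(hits$preferred_base))
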