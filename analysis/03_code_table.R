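#!/usr/bin/env Rscript
# Cluster the hits, summarize recognition patterns as logos, and derive
# the repeat-by-base recognition-code table.

suppressPackageStartupMessages(library(pufcode))
if (!file.exists("results/hits.tsv"))
  stop("run analysis/02_score.R first")

hits <- read.delim("results/hits.tsv", stringsAsFactors = FALSE)
class(hits) <- c("puf_hits", "data.frame")

clustered <- cluster_hits(hits)
cat(sprintf("clustered %d hits into %d base-pure clusters\n",
            nrow(clustered), length(unique(clustered$cluster))))

logo_rows <- list()
for (cl in unique(clustered$cluster)) {
  members <- clustered[clustered$cluster == cl, ]
  members <- subgroup_by_property(members)   # splits clusters > 10
  for (sg in unique(members$subgroup)) {
    grp <- members[members$subgroup == sg, ]
    lg <- build_logo(grp)
    logo_rows[[length(logo_rows) + 1]] <- data.frame(
      cluster = cl, subgroup = sg, n = lg$n,
      base = grp$preferred_base[1],
      position = names(lg$information),
      information = unname(lg$information))
  }
}
logos <- do.call(rbind, logo_rows)
write.table(logos, "results/logos.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("wrote %d logo summaries (information in bits)\n",
            length(logo_rows)))

code <- derive_code_table(hits)
write_code_table(code, "results/code_table.tsv")
cat(sprintf("code table: %d of 32 (repeat, base) cells filled\n",
            sum(code$trm != "---")))
print(stats::xtabs(~ repeat_id + base, code[code$trm != "---", ]))
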