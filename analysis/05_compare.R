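#!/usr/bin/env Rscript
# Two-library comparison: shared/specific clean tags, target-gene Venn,
# overlapped/independent network partition, graph exports and hub
# miRNAs.

suppressPackageStartupMessages(library(paredeg))
dir.create("results/network", showWarnings = FALSE, recursive = TRUE)

tags_cl <- read.delim("results/preprocess/tags_cl.tsv")
tags_dl <- read.delim("results/preprocess/tags_dl.tsv")
cmp <- compare_tag_sets(tags_cl, tags_dl)
message(sprintf(
  "clean tags: %d common unique (%d reads), %d CL-specific, %d DL-specific",
  cmp$common_unique, cmp$common_total, cmp$specific_a_unique,
  cmp$specific_b_unique))

rec_cl <- read.delim("results/targets/records_cl.tsv", check.names = FALSE)
rec_dl <- read.delim("results/targets/records_dl.tsv", check.names = FALSE)
pairs_cl <- data.frame(mirna = rec_cl$miRNA, target = rec_cl$Target)
pairs_dl <- data.frame(mirna = rec_dl$miRNA, target = rec_dl$Target)

v <- venn_targets(pairs_cl$target, pairs_dl$target)
message(sprintf(
  "targets: %d CL-only, %d shared, %d DL-only (%.2f%% of the union DL-only)",
  v$a_only, v$shared, v$b_only, v$pct_b_only))

sp <- split_networks(pairs_cl, pairs_dl)
message(sprintf(
  "pairs: independent networks hold %d/%d CL (%.2f%%) and %d/%d DL (%.2f%%)",
  sp$independent_a, sp$n_a, sp$pct_independent_a,
  sp$independent_b, sp$n_b, sp$pct_independent_b))

export_network(pairs_cl, "results/network/cl")
export_network(pairs_dl, "results/network/dl")
export_network(sp$overlapped_a_records, "results/network/overlapped")
hubs <- hub_mirnas(rbind(pairs_cl, pairs_dl), n = 5)
write.table(hubs, "results/network/hub_mirnas.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

summary_df <- data.frame(
  statistic = c("common_unique_tags", "cl_specific_tags", "dl_specific_tags",
                "targets_cl_only", "targets_shared", "targets_dl_only",
                "pct_dl_only", "independent_cl", "pct_independent_cl",
                "independent_dl", "pct_independent_dl"),
  value = c(cmp$common_unique, cmp$specific_a_unique, cmp$specific_b_unique,
            v$a_only, v$shared, v$b_only, v$pct_b_only,
            sp$independent_a, sp$pct_independent_a,
            sp$independent_b, sp$pct_independent_b))
write.table(summary_df, "results/network/comparison_summary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message("network exports written to results/network/")
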