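#!/usr/bin/env Rscript
# Summaries of the packaged mulberry drought-study pair tables (72
# significant miRNA-mRNA pairs in CL, 63 in DL) and the published
# arithmetic they anchor: library accounting, category tallies, family
# tallies, Venn and network-partition percentages.

suppressPackageStartupMessages(library(paredeg))
dir.create("results/reference", showWarnings = FALSE, recursive = TRUE)

print(library_accounting(raw_tags = 17193823L, filtered_n = 129L,
                         filtered_low_quality = 5043L))
print(library_accounting(raw_tags = 20200629L, filtered_n = 167L,
                         filtered_low_quality = 7996L))

for (lib in c("CL", "DL")) {
  fx <- load_fixture(lib)
  by_cat <- summarize_fixture(fx, "category")
  by_fam <- summarize_fixture(fx, "mirna_family")
  write.table(by_cat, sprintf("results/reference/%s_by_category.tsv", lib),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(by_fam, sprintf("results/reference/%s_by_family.tsv", lib),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("%s: %d pairs; categories %s", lib, nrow(fx),
                  paste(sprintf("%s:%d", by_cat$group, by_cat$n),
                        collapse = " ")))
}

# example T-plot data in the layout of the published figures: the
# mno-miR166f site on XM_010099828.1 at position 560 (DL, 126 tags)
tp <- render_tplot(c(`10` = 1L, `560` = 126L), 560, mode = "tsv",
                   file = "results/reference/tplot_example.tsv")
print(tp)
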