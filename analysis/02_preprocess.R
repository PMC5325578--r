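#!/usr/bin/env Rscript
# Adapter clipping, quality/N filtering, tag collapsing and TP100M
# normalisation for both libraries; writes the library accounting table
# and the collapsed tag lists.

suppressPackageStartupMessages(library(paredeg))
dir.create("results/preprocess", showWarnings = FALSE, recursive = TRUE)

adapter <- "TGGAATTCTCGGGTGCCAAGG"
acc_rows <- list()
for (lib in c("cl", "dl")) {
  pre <- preprocess_reads(sprintf("results/sim/%s.fastq", lib), adapter)
  acc <- pre$accounting
  acc_rows[[lib]] <- data.frame(
    library = toupper(lib), raw_tags = acc$raw_tags,
    filtered_N = acc$filtered_N,
    filtered_low_quality = acc$filtered_low_quality,
    clean_tags = acc$clean_tags,
    clean_pct = round(100 * acc$clean_fraction, 2),
    polyN = acc$polyN_count, unique_tags = acc$unique_tag_count)
  write.table(pre$tags, sprintf("results/preprocess/tags_%s.tsv", lib),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("%s: %d raw -> %d clean (%.2f%%), %d unique tags",
                  toupper(lib), acc$raw_tags, acc$clean_tags,
                  100 * acc$clean_fraction, acc$unique_tag_count))
}
accounting <- do.call(rbind, acc_rows)
write.table(accounting, "results/preprocess/accounting.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message("accounting written to results/preprocess/accounting.tsv")
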