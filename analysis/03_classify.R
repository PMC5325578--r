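#!/usr/bin/env Rscript
# Priority-rule classification of the clean tags (tier-1 ncRNA classes,
# polyN, transcript sense/antisense, other) and the per-class summary
# tables for both libraries.

suppressPackageStartupMessages(library(paredeg))
dir.create("results/classify", showWarnings = FALSE, recursive = TRUE)

transcripts <- read_fasta("results/sim/transcripts.fa")
tier1 <- lapply(setNames(nm = c("rRNA", "tRNA", "snRNA", "snoRNA")),
                function(cls) read_fasta(
                  sprintf("results/sim/ncrna_%s.fa", cls)))

for (lib in c("cl", "dl")) {
  tags <- read.delim(sprintf("results/preprocess/tags_%s.tsv", lib))
  cls <- classify_tags(tags, tier1, list(), transcripts)
  summ <- classification_summary(cls)
  write.table(cls, sprintf("results/classify/tags_%s.tsv", lib),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(summ, sprintf("results/classify/summary_%s.tsv", lib),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(toupper(lib), " class counts (total reads): ",
          paste(sprintf("%s=%d", summ$label, summ$total), collapse = ", "))
}

# strand accounting against the transcript set as pseudo-chromosomes
tags_cl <- read.delim("results/preprocess/tags_cl.tsv")
strand <- genome_strand_report(tags_cl, transcripts)
write.table(strand, "results/classify/strand_report_cl.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message("sense/antisense strand report written for CL (",
        sum(strand$sense_total), " sense vs ",
        sum(strand$antisense_total), " antisense tag occurrences)")
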