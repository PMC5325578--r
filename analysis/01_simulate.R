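#!/usr/bin/env Rscript
# Build the synthetic study: one reference set (transcriptome, miRNAs,
# ncRNA contaminant references, CDS annotation) with planted cleavage
# sites, then two degradome libraries that share part of their target
# repertoire - a contrast library (CL) and a "drought" library (DL) -
# so the downstream two-library comparison has real structure.

suppressPackageStartupMessages(library(paredeg))
dir.create("results/sim", showWarnings = FALSE, recursive = TRUE)

cfg <- synthetic_config(n_transcripts = 20L, n_mirnas = 6L,
                        sites_per_mirna = 2L,
                        transcript_length_range = c(300L, 600L),
                        noise_rate = 0.02,
                        contaminant_fractions = c(rRNA = 0.06, tRNA = 0.01,
                                                  snRNA = 0.01, snoRNA = 0.01,
                                                  polyN = 0.02, n_read = 0.01,
                                                  low_quality = 0.02),
                        seed = 20160615L)
refs <- generate_references(cfg)
sim <- simulate_degradome(cfg, refs)
write_references(refs, "results/sim")

# CL sees the first 8 planted events, DL the last 8 (4 shared);
# background and contaminant reads go to both libraries.
truth <- sim$truth
site_id <- with(truth, paste(mirna, transcript, site, sep = "_"))
keep_cl <- site_id[1:8]
keep_dl <- site_id[5:12]
sig <- grepl("^sig_", sim$reads$id)
read_site <- sub("^sig_(.*)_\\d+$", "\\1", sim$reads$id)
for (lib in c("cl", "dl")) {
  keep <- if (lib == "cl") keep_cl else keep_dl
  reads <- sim$reads[!sig | read_site %in% keep, ]
  write_fastq(reads, sprintf("results/sim/%s.fastq", lib))
  tr <- truth[site_id %in% keep, ]
  write.table(tr, sprintf("results/sim/truth_%s.tsv", lib),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("%s: %d reads, %d planted cleavage events",
                  toupper(lib), nrow(reads), nrow(tr)))
}
message("references and libraries written to results/sim/")
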