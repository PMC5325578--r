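zero_noise_cfg <- function(...) {
  synthetic_config(n_transcripts = 6L, n_mirnas = 2L, sites_per_mirna = 1L,
                   transcript_length_range = c(250L, 350L),
                   noise_rate = 0, seed = 101L, ...)
}

test_that("planted windows are exact reverse complements when unedited", {
  cfg <- zero_noise_cfg()
  refs <- generate_references(cfg)
  ts <- refs$truth_sites
  expect_equal(nrow(ts), 2L)
  expect_equal(ts$expected_score, c(0, 0))
  for (i in seq_len(nrow(ts))) {
    win <- substr(refs$transcripts[[ts$transcript[i]]], ts$start[i],
                  ts$start[i] + cfg$mirna_length - 1)
    expect_equal(win, revcomp(refs$mirnas[[ts$mirna[i]]]))
    expect_equal(ts$site[i], ts$start[i] + cfg$mirna_length - 10L)
  }
  # CDS sidecar covers every planted site at cds_fraction = 1
  cds <- refs$cds
  for (i in seq_len(nrow(ts))) {
    row <- cds[cds$transcript == ts$transcript[i], ]
    expect_true(ts$site[i] >= row$cds_start && ts$site[i] <= row$cds_end)
  }
})

test_that("duplex edits yield the oracle-computed penalty", {
  # one G:U at miRNA position 15: 0.5 outside the core
  cfg_gu <- zero_noise_cfg(duplex_edits = list(list(position = 15L,
                                                    edit = "GU")))
  expect_equal(unique(generate_references(cfg_gu)$truth_sites$expected_score),
               oracle_score(append(rep("WC", 20), "GU", after = 14)))
  expect_equal(unique(generate_references(cfg_gu)$truth_sites$expected_score),
               0.5)
  # one mismatch at position 5: doubled inside the core
  cfg_mm <- zero_noise_cfg(duplex_edits = list(list(position = 5L,
                                                    edit = "mismatch")))
  expect_equal(unique(generate_references(cfg_mm)$truth_sites$expected_score),
               2)
  # edits at the cleavage site are rejected outright
  expect_error(zero_noise_cfg(duplex_edits = list(list(position = 10L,
                                                       edit = "mismatch"))),
               "not 10 or 11")
})

test_that("zero-noise simulation emits exactly the planted reads", {
  cfg <- synthetic_config(n_transcripts = 2L, n_mirnas = 1L,
                          sites_per_mirna = 1L,
                          transcript_length_range = c(250L, 300L),
                          signal_depth_range = c(5L, 5L),
                          noise_rate = 0, seed = 7L)
  refs <- generate_references(cfg)
  sim <- simulate_degradome(cfg, refs)
  expect_equal(nrow(sim$reads), 5L)
  expect_equal(sim$truth$planted_count, 5L)
  expect_equal(sim$truth$expected_category, 0L)
  # every read starts at the cleavage site and carries the adapter
  tx <- refs$transcripts[[sim$truth$transcript]]
  site <- sim$truth$site
  for (s in sim$reads$seq) {
    expect_true(startsWith(s, substr(tx, site, site + 19)))
    insert_len <- nchar(s) - nchar(cfg$adapter)
    expect_true(insert_len %in% 20:21)
    expect_equal(substr(s, insert_len + 1, nchar(s)), cfg$adapter)
  }
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- synthetic_config(n_transcripts = 4L, n_mirnas = 2L,
                          sites_per_mirna = 1L, noise_rate = 0.02,
                          contaminant_fractions = c(rRNA = 0.05,
                                                    polyN = 0.03),
                          seed = 33L)
  r1 <- generate_references(cfg); r2 <- generate_references(cfg)
  expect_identical(r1, r2)
  s1 <- simulate_degradome(cfg, r1); s2 <- simulate_degradome(cfg, r2)
  expect_identical(s1, s2)
  f1 <- file.path(withr::local_tempdir(), "a.fastq")
  f2 <- file.path(withr::local_tempdir(), "b.fastq")
  write_fastq(s1$reads, f1); write_fastq(s2$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("contaminant classes are emitted as configured", {
  cfg <- synthetic_config(n_transcripts = 4L, n_mirnas = 2L,
                          sites_per_mirna = 1L, noise_rate = 0,
                          contaminant_fractions = c(rRNA = 0.10,
                                                    polyN = 0.05,
                                                    n_read = 0.05,
                                                    low_quality = 0.05),
                          seed = 11L)
  refs <- generate_references(cfg)
  sim <- simulate_degradome(cfg, refs)
  ids <- sim$reads$id
  polyn <- sim$reads$seq[grepl("^polyn_", ids)]
  expect_true(length(polyn) > 0)
  insert <- substr(polyn, 1, nchar(polyn) - nchar(cfg$adapter))
  expect_true(all(detect_polyn(insert)))
  nreads <- sim$reads$seq[grepl("^nread_", ids)]
  n_count <- nchar(nreads) - nchar(gsub("N", "", nreads, fixed = TRUE))
  expect_true(all(n_count == 1L))
  lowq <- sim$reads$qual[grepl("^lowq_", ids)]
  low_bases <- nchar(lowq) - nchar(gsub("#", "", lowq, fixed = TRUE))
  expect_true(all(low_bases == 3L))
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(contaminant_fractions = c(rRNA = 0.6,
                                                          tRNA = 0.5)),
               "sum to < 1")
  expect_error(synthetic_config(signal_depth_range = c(0L, 5L)))
  expect_error(synthetic_config(adapter = "ACGT"))
  # a transcript too short to host a site names the transcript
  tiny <- synthetic_config(n_transcripts = 1L, n_mirnas = 1L,
                           sites_per_mirna = 1L,
                           transcript_length_range = c(30L, 30L))
  expect_error(generate_references(tiny), "TX001")
})

test_that("references round-trip through FASTA/TSV on disk", {
  cfg <- zero_noise_cfg()
  refs <- generate_references(cfg)
  dir <- withr::local_tempdir()
  write_references(refs, dir)
  expect_equal(read_fasta(file.path(dir, "transcripts.fa")),
               refs$transcripts)
  expect_equal(read_fasta(file.path(dir, "mirnas.fa")), refs$mirnas)
  cds <- read.delim(file.path(dir, "cds.tsv"))
  expect_equal(cds$cds_end, refs$cds$cds_end)
})
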