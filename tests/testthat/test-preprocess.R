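test_that("adapter clipping truncates at the first 8-nt adapter seed", {
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  tag <- "ACGTACGTACGTACGTACGT"
  expect_equal(clip_adapter(paste0(tag, adapter), adapter), tag)
  expect_equal(clip_adapter(tag, adapter), tag)
  # adapter seed occurring twice: cut at first occurrence
  seed <- substr(adapter, 1, 8)
  double <- paste0("AAAA", seed, "CCCC", seed, "GG")
  expect_equal(clip_adapter(double, adapter), "AAAA")
  expect_error(clip_adapter(tag, "ACGT"), "at least 8")
})

test_that("polyN detection is strictly greater than 70 percent", {
  expect_true(detect_polyn(paste0(strrep("A", 15), "CGTCG")))    # 75%
  expect_false(detect_polyn(paste0(strrep("A", 14), "CGTCGT")))  # exactly 70%
  expect_true(detect_polyn(strrep("A", 21)))
  expect_true(detect_polyn(strrep("N", 20)))
  expect_error(detect_polyn(""))
})

test_that("read filtering separates N, low-quality and clean tags", {
  good <- function(n) strrep("I", n)
  reads <- data.frame(
    seq = c(strrep("ACGTA", 4),                  # clean, 20 nt
            paste0(strrep("ACGTA", 4), "C"),     # clean, 21 nt
            sub("A", "N", strrep("ACGTA", 4)),   # N read
            strrep("ACGTA", 4),                  # low quality
            strrep("ACGTA", 3),                  # 15 nt -> low quality bin
            strrep("ACGTA", 5)),                 # 25 nt -> low quality bin
    qual = c(good(20), good(21), good(20),
             paste0("###", good(17)), good(15), good(25)),
    stringsAsFactors = FALSE)
  out <- filter_reads(reads)
  acc <- out$accounting
  expect_equal(acc$raw_tags, 6L)
  expect_equal(acc$filtered_N, 1L)
  expect_equal(acc$filtered_low_quality, 3L)
  expect_equal(acc$clean_tags, 2L)
  expect_equal(nrow(out$tags), 2L)
  # conservation identity
  expect_equal(acc$filtered_N + acc$filtered_low_quality + acc$clean_tags,
               acc$raw_tags)
})

test_that("ten reads with one N and two low-quality give seven clean", {
  reads <- data.frame(
    seq = c(rep(strrep("AC", 10), 9), sub("A", "N", strrep("AC", 10))),
    qual = c(rep(strrep("I", 20), 7), rep(paste0("!!!", strrep("I", 17)), 2),
             strrep("I", 20)),
    stringsAsFactors = FALSE)
  acc <- filter_reads(reads)$accounting
  expect_equal(acc$filtered_N, 1L)
  expect_equal(acc$filtered_low_quality, 2L)
  expect_equal(acc$clean_tags, 7L)
})

test_that("accounting conservation holds on random read sets", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(5:60, 1)
    len <- sample(15:25, n, replace = TRUE)
    seqs <- vapply(len, rand_dna, character(1))
    # sprinkle N and low-quality reads
    hasn <- runif(n) < 0.2
    seqs[hasn] <- vapply(seqs[hasn], function(s) {
      p <- sample.int(nchar(s), 1); substr(s, p, p) <- "N"; s
    }, character(1))
    qual <- vapply(len, function(l) {
      q <- rep("I", l)
      if (runif(1) < 0.3) q[sample.int(l, min(3, l))] <- "#"
      paste(q, collapse = "")
    }, character(1))
    acc <- filter_reads(data.frame(seq = seqs, qual = qual))$accounting
    expect_equal(acc$filtered_N + acc$filtered_low_quality + acc$clean_tags,
                 acc$raw_tags)
  }
})

test_that("tag collapsing preserves count multisets", {
  expect_equal(collapse_tags(c("AA", "AA", "CC")),
               data.frame(seq = c("AA", "CC"), raw_count = c(2L, 1L)))
  expect_equal(nrow(collapse_tags(character(0))), 0L)
  five <- replicate(5, rand_dna(20))
  expect_equal(collapse_tags(five)$raw_count, rep(1L, 5))
  # collapse . expand is the identity on count multisets
  set.seed(11)
  seqs <- sample(replicate(6, rand_dna(20)), 40, replace = TRUE)
  tab <- collapse_tags(seqs)
  expanded <- rep(tab$seq, tab$raw_count)
  expect_equal(sort(expanded), sort(seqs))
  expect_equal(sum(tab$raw_count), length(seqs))
})

test_that("TP100M normalisation and its sum identity", {
  expect_equal(tp100m(10, 1e8), 10)
  expect_equal(tp100m(1, 1e8), 1)
  expect_equal(tp100m(3, 2e7), 15)
  expect_error(tp100m(1, 0), "clean_total")
  set.seed(3)
  seqs <- sample(replicate(8, rand_dna(20)), 100, replace = TRUE)
  tab <- collapse_tags(seqs)
  expect_equal(sum(tp100m(tab$raw_count, length(seqs))), 1e8)
})

test_that("preprocess_reads trims, filters and normalises in one pass", {
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  tag1 <- rand_dna(20); tag2 <- rand_dna(21)
  reads <- data.frame(
    seq = paste0(c(tag1, tag1, tag2), adapter),
    qual = strrep("I", nchar(paste0(c(tag1, tag1, tag2), adapter))),
    stringsAsFactors = FALSE)
  out <- preprocess_reads(reads, adapter)
  expect_equal(out$accounting$clean_tags, 3L)
  expect_equal(sort(out$tags$seq), sort(c(tag1, tag2)))
  expect_equal(sum(out$tags$raw_count), 3L)
  expect_equal(sum(out$tags$tp100m), 1e8)
})
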