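test_that("the five-category ladder matches its printed rules", {
  expect_equal(categorize(c(`100` = 5, `200` = 2), 100), 0L)
  expect_equal(categorize(c(`100` = 5, `200` = 5, `300` = 1), 100), 1L)
  expect_equal(categorize(c(`100` = 3, `200` = 5, `300` = 1, `400` = 1), 100), 2L)
  expect_equal(categorize(c(`100` = 1, `200` = 7), 100), 4L)
  expect_equal(categorize(c(`100` = 2, `200` = 7, `300` = 2, `400` = 2), 100), 3L)
  expect_error(categorize(c(`100` = 5), 200), "no degradome evidence")
})

test_that("categorize matches a brute-force re-implementation on random profiles", {
  set.seed(17)
  for (i in 1:1000) {
    prof <- rand_profile()
    site <- as.integer(sample(names(prof), 1))
    expect_identical(categorize(prof, site), oracle_categorize(prof, site))
  }
})

test_that("raising the count at a site never worsens its category", {
  set.seed(19)
  for (i in 1:200) {
    prof <- rand_profile()
    site <- as.integer(sample(names(prof), 1))
    if (prof[[as.character(site)]] < 2) next
    before <- categorize(prof, site)
    prof2 <- prof
    prof2[[as.character(site)]] <- prof2[[as.character(site)]] + sample(1:5, 1)
    expect_lte(categorize(prof2, site), before)
  }
})

test_that("profiles sum tag counts by 5' position", {
  hits <- data.frame(seq = c("a", "b", "c"), raw_count = c(3L, 2L, 4L),
                     transcript = c("T1", "T1", "T2"),
                     pos = c(100L, 100L, 7L))
  profs <- build_profiles(hits, clean_total = 1000L)
  expect_equal(profs[["T1"]], c(`100` = 5L))
  expect_equal(profs[["T2"]], c(`7` = 4L))
  expect_equal(attr(profs, "clean_total"), 1000L)
})

test_that("call_targets keeps supported sites and annotates location", {
  cands <- data.frame(
    mirna = c("m1", "m1", "m2"), transcript = c("T1", "T1", "T1"),
    start = c(91L, 191L, 5L), end = c(111L, 211L, 25L),
    site = c(102L, 202L, 16L), score = c(0, 1.5, 2),
    gap_pos = 0L, bulge_pos = 0L, pairing = strrep(":", 21),
    stringsAsFactors = FALSE)
  profs <- build_profiles(
    data.frame(seq = "x", raw_count = 5L, transcript = "T1", pos = 102L),
    clean_total = 1e8)
  cds <- data.frame(transcript = "T1", cds_start = 50L, cds_end = 400L)
  rec <- call_targets(cands, profs, cds)
  expect_equal(nrow(rec), 1L)           # unsupported candidates dropped
  expect_equal(attr(rec, "n_unsupported"), 2L)
  expect_equal(rec$c_site, 102L)
  expect_equal(rec$location, "CDS")
  expect_equal(rec$category, 0L)
  expect_equal(rec$tp100m, 5)
  # site upstream of the CDS interval is 5UTR
  cds2 <- data.frame(transcript = "T1", cds_start = 150L, cds_end = 400L)
  expect_equal(call_targets(cands, profs, cds2)$location, "5UTR")
})

test_that("the best-scoring duplex is kept per (miRNA, target, site)", {
  cands <- data.frame(
    mirna = "m1", transcript = "T1",
    start = c(91L, 90L), end = c(111L, 111L), site = c(102L, 102L),
    score = c(3, 1.5), gap_pos = c(0L, 2L), bulge_pos = 0L,
    pairing = "x", stringsAsFactors = FALSE)
  profs <- build_profiles(
    data.frame(seq = "x", raw_count = 2L, transcript = "T1", pos = 102L),
    clean_total = 100L)
  rec <- call_targets(cands, profs)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$score, 1.5)
})

test_that("empirical p-values follow the add-one estimator at both extremes", {
  set.seed(23)
  tx <- c(T1 = rand_dna(150))
  profs <- build_profiles(
    data.frame(seq = "x", raw_count = 3L, transcript = "T1", pos = 60L),
    clean_total = 100L)
  # a miRNA that cannot match anywhere: k = 0, p = 1 / (R + 1)
  mir <- rand_dna(21)
  p0 <- empirical_pvalue(0, 0, mir, tx, profs, shuffles = 24L, seed = 5L)
  expect_equal(p0, 1 / 25)
  # a homopolymer miRNA shuffles to itself; plant its perfect site with
  # tag support so every shuffle reproduces the call: k = R, p = 1
  mir_a <- strrep("A", 21)
  tx2 <- c(T1 = paste0(rand_dna(40), strrep("T", 21), rand_dna(40)))
  site <- 41L + 21L - 10L
  profs2 <- build_profiles(
    data.frame(seq = "x", raw_count = 3L, transcript = "T1", pos = site),
    clean_total = 100L)
  p1 <- empirical_pvalue(0, 0, mir_a, tx2, profs2, shuffles = 9L, seed = 5L)
  expect_equal(p1, 1)
})

test_that("add_pvalues reuses one null per miRNA and respects thresholds", {
  set.seed(29)
  mir <- c(m1 = rand_dna(21))
  tx <- c(T1 = paste0(rand_dna(60), revcomp(mir[[1]]), rand_dna(60)))
  site <- 61L + 21L - 10L
  hits <- data.frame(seq = "x", raw_count = 5L, transcript = "T1",
                     pos = site)
  profs <- build_profiles(hits, clean_total = 1000L)
  cands <- find_candidates_set(mir, tx)
  rec <- call_targets(cands, profs)
  out <- add_pvalues(rec, mir, tx, profs, shuffles = 20L, seed = 7L)
  expect_true(all(out$p_value > 0 & out$p_value <= 1))
  expect_equal(out$p_value[out$c_site == site], 1 / 21)
  # determinism under the seed
  out2 <- add_pvalues(rec, mir, tx, profs, shuffles = 20L, seed = 7L)
  expect_equal(out, out2)
})
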