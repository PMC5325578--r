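test_that("Venn summary performs set algebra with half-up percentages", {
  v <- venn_targets(c("a", "b", "c"), c("b", "c", "d", "e"))
  expect_equal(v$a_only, 1L); expect_equal(v$shared, 2L)
  expect_equal(v$b_only, 2L); expect_equal(v$union, 5L)
  expect_equal(v$pct_b_only, 40)
  same <- venn_targets(letters[1:4], letters[1:4])
  expect_equal(same$shared, 4L)
  expect_equal(same$pct_shared, 100)
  disj <- venn_targets(c("a", "b"), c("c"))
  expect_equal(disj$shared, 0L)
})

test_that("network partition computes per-library overlap on records", {
  pairs_a <- data.frame(mirna = c("m1", "m2", "m3"),
                        target = c("t1", "t2", "t3"))
  pairs_b <- data.frame(mirna = c("m1", "m4"), target = c("t1", "t4"))
  sp <- split_networks(pairs_a, pairs_b)
  expect_equal(sp$overlapped_a, 1L)
  expect_equal(sp$independent_a, 2L)
  expect_equal(sp$independent_b, 1L)
  # identical libraries: empty independents
  sp2 <- split_networks(pairs_a, pairs_a)
  expect_equal(sp2$independent_a, 0L)
  expect_equal(sp2$pct_independent_a, 0)
  # duplicate records make per-library overlap asymmetric
  dup_a <- rbind(pairs_a, pairs_a[1, ])
  sp3 <- split_networks(dup_a, pairs_b)
  expect_equal(sp3$overlapped_a, 2L)
  expect_equal(sp3$overlapped_b, 1L)
})

test_that("partition conservation holds on random pair sets", {
  set.seed(53)
  for (i in 1:20) {
    mk <- function(n) data.frame(
      mirna = sample(paste0("m", 1:6), n, replace = TRUE),
      target = sample(paste0("t", 1:8), n, replace = TRUE))
    a <- mk(sample(5:30, 1)); b <- mk(sample(5:30, 1))
    sp <- split_networks(a, b)
    expect_equal(sp$overlapped_a + sp$independent_a, nrow(a))
    expect_equal(sp$overlapped_b + sp$independent_b, nrow(b))
    v <- venn_targets(a$target, b$target)
    expect_equal(v$a_only + v$shared + v$b_only, v$union)
    expect_true(all(c(v$pct_a_only, v$pct_shared, v$pct_b_only) >= 0))
    expect_true(all(c(v$pct_a_only, v$pct_shared, v$pct_b_only) <= 100))
  }
})

test_that("network export writes deduplicated bipartite edges and nodes", {
  dir <- withr::local_tempdir()
  pairs <- data.frame(mirna = c("m1", "m1", "m1"),
                      target = c("t1", "t2", "t1"))
  out <- export_network(pairs, file.path(dir, "net"))
  expect_equal(nrow(out$edges), 2L)
  expect_equal(nrow(out$nodes), 3L)
  expect_equal(sort(out$nodes$type), c("gene", "gene", "miRNA"))
  sif <- readLines(file.path(dir, "net.sif"))
  expect_equal(length(sif), 2L)
  # degree sum equals twice the edge count
  deg <- table(c(out$edges$mirna, out$edges$target))
  expect_equal(sum(deg), 2L * nrow(out$edges))
  # empty input: header-only files
  out0 <- export_network(pairs[0, ], file.path(dir, "empty"))
  expect_equal(nrow(out0$edges), 0L)
  expect_true(file.exists(file.path(dir, "empty_edges.tsv")))
})

test_that("hub report matches independent degree counting", {
  set.seed(59)
  pairs <- data.frame(
    mirna = sample(paste0("m", 1:5), 40, replace = TRUE),
    target = sample(paste0("t", 1:12), 40, replace = TRUE))
  hubs <- hub_mirnas(pairs, n = 5)
  g <- igraph::graph_from_data_frame(unique(pairs))
  deg <- igraph::degree(g, v = unique(pairs$mirna))
  for (i in seq_len(nrow(hubs)))
    expect_equal(hubs$n_targets[i], unname(deg[hubs$mirna[i]]))
  expect_true(all(diff(hubs$n_targets) <= 0))
})

test_that("tag-set comparison splits common and specific mass", {
  a <- data.frame(seq = c("AA", "CC", "GG"), raw_count = c(3L, 1L, 2L))
  b <- data.frame(seq = c("AA", "TT"), raw_count = c(4L, 9L))
  cmp <- compare_tag_sets(a, b)
  expect_equal(cmp$common_unique, 1L)
  expect_equal(cmp$common_total, 7L)      # 3 in A + 4 in B
  expect_equal(cmp$specific_a_unique, 2L)
  expect_equal(cmp$specific_a_total, 3L)
  expect_equal(cmp$specific_b_total, 9L)
  ident <- compare_tag_sets(a, a)
  expect_equal(ident$specific_a_unique, 0L)
  expect_equal(ident$specific_b_total, 0L)
  disj <- compare_tag_sets(a, data.frame(seq = "TT", raw_count = 1L))
  expect_equal(disj$common_unique, 0L)
  expect_equal(disj$common_total, 0L)
})
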