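# Independent brute-force oracles used to check the implementation.
# Written as direct transliterations of the scoring/category rules,
# with no shared code with the package internals they verify.

oracle_pair <- function(m, t) {
  wc <- c(A = "T", C = "G", G = "C", T = "A")
  if (!m %in% names(wc) || !t %in% names(wc)) return("mismatch")
  if (wc[[m]] == t) return("WC")
  if ((m == "G" && t == "T") || (m == "T" && t == "G")) return("GU")
  "mismatch"
}

# Penalty-table scorer over a duplex path (entries WC/GU/mismatch/gap/
# bulge, walked along the miRNA 5'->3'; bulge entries consume no miRNA
# position). Mismatch 1, G:U 0.5, gap/bulge 1; doubled at miRNA
# positions 2-13 (a bulge when both flanks are in 2-13).
oracle_score <- function(path) {
  pos <- 0L
  total <- 0
  for (st in path) {
    if (st != "bulge") pos <- pos + 1L
    pen <- switch(st, WC = 0, GU = 0.5, mismatch = 1, gap = 1, bulge = 1)
    core <- if (st == "bulge") (pos >= 2 && pos + 1 <= 13)
            else (pos >= 2 && pos <= 13)
    total <- total + pen * (if (core) 2 else 1)
  }
  total
}

# Exhaustive enumeration of candidate duplexes of one miRNA on one
# transcript: every ungapped window, every single target gap, every
# single bulged target base; score <= max_score and Watson-Crick pairs
# at miRNA positions 10 and 11.
oracle_enumerate <- function(mirna, transcript, max_score = 7) {
  mb <- strsplit(chartr("Uu", "Tt", toupper(mirna)), "")[[1]]
  tb <- strsplit(toupper(transcript), "")[[1]]
  L <- length(mb); n <- length(tb)
  res <- list()
  keep <- function(start, end, site, score, gap, bulge) {
    res[[length(res) + 1L]] <<- data.frame(
      start = start, end = end, site = site, score = score,
      gap_pos = gap, bulge_pos = bulge)
  }

  for (s in seq_len(max(0, n - L + 1))) {            # ungapped
    states <- vapply(1:L, function(i) oracle_pair(mb[i], tb[s + L - i]),
                     character(1))
    if (states[10] != "WC" || states[11] != "WC") next
    sc <- oracle_score(states)
    if (sc <= max_score + 1e-9)
      keep(s, s + L - 1, s + L - 10, sc, 0L, 0L)
  }

  for (g in setdiff(1:L, c(10L, 11L))) {             # one target gap
    for (s in seq_len(max(0, n - (L - 1) + 1))) {
      states <- character(L)
      states[g] <- "gap"
      for (i in setdiff(1:L, g)) {
        off <- if (i < g) i else i - 1L
        states[i] <- oracle_pair(mb[i], tb[s + L - 1 - off])
      }
      if (states[10] != "WC" || states[11] != "WC") next
      sc <- oracle_score(states)
      if (sc <= max_score + 1e-9) {
        off10 <- if (10 < g) 10L else 9L
        keep(s, s + L - 2, s + L - 1 - off10, sc, g, 0L)
      }
    }
  }

  for (b in setdiff(1:(L - 1), 10L)) {               # one bulged target base
    for (s in seq_len(max(0, n - (L + 1) + 1))) {
      states <- vapply(1:L, function(i) {
        off <- if (i <= b) i else i + 1L
        oracle_pair(mb[i], tb[s + L - off + 1])
      }, character(1))
      if (states[10] != "WC" || states[11] != "WC") next
      path <- append(states, "bulge", after = b)
      sc <- oracle_score(path)
      if (sc <= max_score + 1e-9) {
        off10 <- if (10 <= b) 10L else 11L
        keep(s, s + L, s + L - off10 + 1, sc, 0L, b)
      }
    }
  }
  if (!length(res))
    return(data.frame(start = integer(0), end = integer(0),
                      site = integer(0), score = numeric(0),
                      gap_pos = integer(0), bulge_pos = integer(0)))
  out <- do.call(rbind, res)
  out[order(out$start, out$end, out$gap_pos, out$bulge_pos), , drop = FALSE]
}

# Direct transliteration of the printed five-category ladder.
oracle_categorize <- function(counts, site) {
  cnt <- counts[[as.character(site)]]
  mx <- max(counts)
  med <- stats::median(counts)
  if (cnt == 1) 4L
  else if (cnt == mx && sum(counts == mx) == 1) 0L
  else if (cnt == mx) 1L
  else if (cnt > med) 2L
  else 3L
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

# A random occupied profile (names = positions, values >= 1).
rand_profile <- function(max_pos = 50, max_count = 9) {
  k <- sample(1:8, 1)
  pos <- sort(sample.int(max_pos, k))
  stats::setNames(sample.int(max_count, k, replace = TRUE),
                  as.character(pos))
}
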