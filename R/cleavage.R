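#' Cleavage-site calling: degradome profiles, peak categories, p-values
#'
#' A degradome profile is the per-position sum of raw tag counts whose
#' 5' ends fall at each transcript position. Each candidate duplex site
#' supported by at least one tag is called and assigned one of five
#' peak-shape categories computed over the transcript's occupied
#' positions (positions with no tags are excluded; in particular the
#' median is taken over occupied positions only):
#'
#' * category 0: count >= 2, equal to the transcript maximum, and the
#'   maximum is attained at exactly one position;
#' * category 1: count >= 2, equal to the maximum, more than one
#'   position attains the maximum;
#' * category 2: count >= 2, below the maximum but above the median;
#' * category 3: count >= 2, at or below the median;
#' * category 4: exactly 1 raw tag at the position.
#'
#' Significance is assessed by an explicit permutation null: the miRNA
#' is shuffled preserving mononucleotide composition, the full search
#' and calling is re-run against the transcript set, and the add-one
#' estimator p = (1 + k) / (1 + R) counts the shuffles k that produce a
#' call at least as good (score <= observed and category <= observed)
#' anywhere in the transcript set.
#'
#' @name cleavage_caller
NULL

#' Build per-transcript degradome profiles
#'
#' @param hits data frame from [map_tags_to_transcripts()].
#' @param clean_total clean-tag total of the library (for TP100M).
#' @return named list of profiles (named integer vectors, names =
#'   1-based positions) with attribute `clean_total`.
#' @export
build_profiles <- function(hits, clean_total) {
  profs <- lapply(split(hits, hits$transcript), function(h) {
    cnt <- tapply(h$raw_count, h$pos, sum)
    v <- as.integer(cnt)
    names(v) <- names(cnt)
    v[order(as.integer(names(v)))]
  })
  attr(profs, "clean_total") <- clean_total
  profs
}

#' Assign the degradome peak category of a supported site
#'
#' @param counts named integer vector: raw tag counts at occupied
#'   positions (names are 1-based positions, values >= 1).
#' @param site 1-based transcript position; must be occupied.
#' @return integer category in 0..4.
#' @export
categorize <- function(counts, site) {
  key <- as.character(site)
  if (!length(counts) || !key %in% names(counts))
    stop("no degradome evidence at position ", site)
  cnt <- counts[[key]]
  if (cnt == 1L) return(4L)
  mx <- max(counts)
  if (cnt == mx)
    return(if (sum(counts == mx) == 1L) 0L else 1L)
  if (cnt > stats::median(counts)) 2L else 3L
}

# Location of a site relative to a CDS annotation table
# (columns transcript, cds_start, cds_end).
locate_site <- function(cds, transcript, site) {
  if (is.null(cds)) return(NA_character_)
  row <- cds[cds$transcript == transcript, , drop = FALSE]
  if (!nrow(row)) return(NA_character_)
  if (site < row$cds_start[1]) "5UTR"
  else if (site > row$cds_end[1]) "3UTR"
  else "CDS"
}

#' Call cleavage targets from candidates and degradome profiles
#'
#' Candidates without any tag at their predicted site are dropped (the
#' number dropped is attached as attribute `n_unsupported`); each
#' surviving site keeps its best-scoring duplex per (miRNA, transcript,
#' site).
#'
#' @param candidates data frame from [find_candidates_set()].
#' @param profiles profiles from [build_profiles()].
#' @param cds optional CDS annotation (`transcript`, `cds_start`,
#'   `cds_end`) for the Location column.
#' @return data frame of target records: `mirna`, `target`, `c_site`,
#'   `location`, `score`, `category`, `raw_count`, `tp100m`, `pairing`,
#'   `p_value` (NA until [add_pvalues()]).
#' @export
call_targets <- function(candidates, profiles, cds = NULL) {
  clean_total <- attr(profiles, "clean_total")
  empty <- data.frame(mirna = character(0), target = character(0),
                      c_site = integer(0), location = character(0),
                      score = numeric(0), category = integer(0),
                      raw_count = integer(0), tp100m = numeric(0),
                      pairing = character(0), p_value = numeric(0))
  if (!nrow(candidates)) {
    attr(empty, "n_unsupported") <- 0L
    return(empty)
  }
  prof <- profiles[candidates$transcript]
  cnt <- mapply(function(p, s) {
    if (is.null(p)) NA_integer_ else {
      v <- p[as.character(s)]
      if (is.na(v)) NA_integer_ else as.integer(v)
    }
  }, prof, candidates$site)
  supported <- !is.na(cnt)
  n_unsupported <- sum(!supported)
  cand <- candidates[supported, , drop = FALSE]
  cnt <- cnt[supported]
  if (!nrow(cand)) {
    attr(empty, "n_unsupported") <- n_unsupported
    return(empty)
  }
  cat_ <- mapply(function(tx, s) categorize(profiles[[tx]], s),
                 cand$transcript, cand$site)
  loc <- mapply(function(tx, s) locate_site(cds, tx, s),
                cand$transcript, cand$site)
  rec <- data.frame(mirna = cand$mirna, target = cand$transcript,
                    c_site = cand$site, location = unname(loc),
                    score = cand$score, category = as.integer(cat_),
                    raw_count = cnt,
                    tp100m = tp100m(cnt, clean_total),
                    pairing = cand$pairing,
                    p_value = NA_real_,
                    stringsAsFactors = FALSE)
  # best duplex per (miRNA, target, site)
  key <- paste(rec$mirna, rec$target, rec$c_site)
  rec <- rec[order(key, rec$score), , drop = FALSE]
  rec <- rec[!duplicated(paste(rec$mirna, rec$target, rec$c_site)), ,
             drop = FALSE]
  rec <- rec[order(rec$mirna, rec$target, rec$c_site), , drop = FALSE]
  rownames(rec) <- NULL
  attr(rec, "n_unsupported") <- n_unsupported
  rec
}

# Composition-preserving shuffle of a sequence.
shuffle_seq <- function(seq) {
  paste(sample(strsplit(seq, "")[[1]]), collapse = "")
}

# (score, category) pairs of all calls for one miRNA sequence against
# the transcript set.
.calls_for_mirna <- function(mirna_seq, transcripts, profiles, max_score) {
  cands <- find_candidates_set(c(m = unname(mirna_seq)), transcripts,
                               max_score = max_score)
  rec <- call_targets(cands, profiles)
  rec[, c("score", "category")]
}

#' Empirical p-value of a called target by miRNA shuffling
#'
#' @param score,category the observed record's duplex score and peak
#'   category.
#' @param mirna the miRNA sequence.
#' @param transcripts named transcript set searched under the null.
#' @param profiles degradome profiles from [build_profiles()].
#' @param shuffles number of composition-preserving shuffles R (>= 1).
#' @param seed RNG seed.
#' @param max_score score ceiling used in the search.
#' @return p-value in (0, 1]: `(1 + k) / (1 + R)` where k is the number
#'   of shuffles yielding a call with score <= `score` and category <=
#'   `category` anywhere in the transcript set.
#' @export
empirical_pvalue <- function(score, category, mirna, transcripts, profiles,
                             shuffles = 100L, seed = 1L, max_score = 7) {
  stopifnot(shuffles >= 1)
  with_seed(seed, {
    k <- 0L
    for (r in seq_len(shuffles)) {
      calls <- .calls_for_mirna(shuffle_seq(mirna), transcripts, profiles,
                                max_score)
      if (nrow(calls) &&
          any(calls$score <= score + 1e-9 & calls$category <= category))
        k <- k + 1L
    }
    (1 + k) / (1 + shuffles)
  })
}

#' Attach empirical p-values to a record table
#'
#' One shuffle set is drawn per distinct miRNA and reused for all of its
#' records (the null calls depend on the miRNA only; each record then
#' counts the shuffles at least as good as itself).
#'
#' @param records data frame from [call_targets()].
#' @param mirnas named character vector of miRNA sequences.
#' @inheritParams empirical_pvalue
#' @return `records` with `p_value` filled in.
#' @export
add_pvalues <- function(records, mirnas, transcripts, profiles,
                        shuffles = 100L, seed = 1L, max_score = 7) {
  if (!nrow(records)) return(records)
  stopifnot(shuffles >= 1)
  with_seed(seed, {
    for (m in unique(records$mirna)) {
      null_calls <- vector("list", shuffles)
      for (r in seq_len(shuffles))
        null_calls[[r]] <- .calls_for_mirna(shuffle_seq(mirnas[[m]]),
                                            transcripts, profiles, max_score)
      idx <- which(records$mirna == m)
      for (i in idx) {
        k <- sum(vapply(null_calls, function(cl) {
          nrow(cl) > 0 &&
            any(cl$score <= records$score[i] + 1e-9 &
                cl$category <= records$category[i])
        }, logical(1)))
        records$p_value[i] <- (1 + k) / (1 + shuffles)
      }
    }
    records
  })
}
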