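#' Plant miRNA:target duplex scoring
#'
#' Candidate target sites are scored with the Allen-style penalty scheme
#' standard for plant miRNA/target pairings: each mismatch costs 1, each
#' G:U wobble 0.5 and each single-nucleotide gap or bulge 1, with every
#' penalty doubled inside the core region spanning miRNA positions 2-13.
#' The duplex is antiparallel: miRNA position 1 (its 5' end) pairs the
#' 3'-most base of the target window. Slicing occurs between the target
#' nucleotides paired with miRNA positions 10 and 11, so candidates are
#' required to have canonical Watson-Crick pairs at both positions (no
#' G:U, no gap) and the reported cleavage site is the target position
#' paired with miRNA position 10. Candidates must score at most 7.
#'
#' @name target_scoring
NULL

.CORE_FROM <- 2L
.CORE_TO <- 13L

#' Score a duplex from its per-position pair states
#'
#' `pair_states` describes the duplex path walked along the miRNA 5'->3':
#' each entry is one of `"WC"`, `"GU"`, `"mismatch"`, `"gap"` (miRNA
#' position unpaired, i.e. a deleted target base) or `"bulge"` (an extra
#' target base that consumes no miRNA position). Non-bulge entries
#' occupy consecutive miRNA positions 1..L. A penalty is doubled when
#' its miRNA position is in 2-13; a bulge is doubled when both flanking
#' miRNA positions are in the core.
#'
#' @param pair_states character vector of duplex path states.
#' @return numeric penalty score.
#' @export
score_duplex <- function(pair_states) {
  valid <- c("WC", "GU", "mismatch", "gap", "bulge")
  if (!all(pair_states %in% valid))
    stop("unknown pair state(s): ",
         paste(setdiff(pair_states, valid), collapse = ", "))
  base <- c(WC = 0, GU = 0.5, mismatch = 1, gap = 1, bulge = 1)
  pos <- cumsum(pair_states != "bulge")   # miRNA position of each entry
  pen <- unname(base[pair_states])
  core <- ifelse(pair_states == "bulge",
                 pos >= .CORE_FROM & pos + 1L <= .CORE_TO,
                 pos >= .CORE_FROM & pos <= .CORE_TO)
  sum(pen * ifelse(core, 2, 1))
}

# Encode a DNA string as integers 0=A,1=C,2=G,3=T (-1 otherwise).
encode_dna <- function(seq) {
  v <- match(strsplit(dna_u2t(seq), "")[[1]], c("A", "C", "G", "T"))
  v[is.na(v)] <- 0L
  as.integer(v) - 1L
}

#' Enumerate candidate target sites of one miRNA on one transcript
#'
#' Exhaustively scans every target window of length L (and L-1 / L+1 for
#' the single-gap and single-bulge variants, at most one per duplex),
#' keeping alignments that score at most `max_score` and have canonical
#' Watson-Crick pairs at miRNA positions 10 and 11.
#'
#' @param mirna miRNA sequence, 5'->3' (U allowed), at least 11 nt.
#' @param transcript transcript sequence (sense strand).
#' @param max_score maximum penalty score (default 7).
#' @param reduce keep only the best-scoring alignment per cleavage site
#'   (ties broken in favour of ungapped alignments).
#' @return data frame `start`, `end` (target window), `site` (target
#'   position paired with miRNA nt 10), `score`, `gap_pos`, `bulge_pos`
#'   (0 = none), `pairing` (per-path symbols: `:` Watson-Crick, `.` G:U,
#'   space mismatch, `-` gap, `^` bulged target base).
#' @export
find_candidates <- function(mirna, transcript, max_score = 7, reduce = TRUE) {
  if (nchar(mirna) < 11)
    stop("miRNA shorter than 11 nt: cleavage-site rule undefined")
  hits <- scan_duplex_cpp(encode_dna(mirna), encode_dna(transcript),
                          as.numeric(max_score))
  if (nrow(hits) && reduce) {
    ungapped <- hits$gap_pos == 0 & hits$bulge_pos == 0
    hits <- hits[order(hits$site, hits$score, !ungapped, hits$start), ,
                 drop = FALSE]
    hits <- hits[!duplicated(hits$site), , drop = FALSE]
    rownames(hits) <- NULL
  }
  hits
}

#' Enumerate candidates for a set of miRNAs against a transcript set
#'
#' @param mirnas named character vector of miRNA sequences.
#' @param transcripts named character vector of transcript sequences.
#' @inheritParams find_candidates
#' @return data frame with `mirna`, `transcript` prepended to the
#'   [find_candidates()] columns.
#' @export
find_candidates_set <- function(mirnas, transcripts, max_score = 7,
                                reduce = TRUE) {
  out <- list()
  for (m in names(mirnas)) {
    for (tx in names(transcripts)) {
      h <- find_candidates(mirnas[[m]], transcripts[[tx]], max_score, reduce)
      if (nrow(h)) {
        h <- cbind(mirna = m, transcript = tx, h, stringsAsFactors = FALSE)
        out[[length(out) + 1L]] <- h
      }
    }
  }
  if (!length(out))
    return(data.frame(mirna = character(0), transcript = character(0),
                      start = integer(0), end = integer(0), site = integer(0),
                      score = numeric(0), gap_pos = integer(0),
                      bulge_pos = integer(0), pairing = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
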