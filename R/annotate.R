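#' Priority-rule tag classification and exact tag mapping
#'
#' Clean tags are assigned exactly one class by a tiered priority rule:
#' Rfam-like ncRNA references first (rRNA, tRNA, snRNA, snoRNA), then
#' GenBank-like references (rRNA, tRNA), then the polyN rule, then exact
#' sense/antisense matches to the transcriptome, else "other". Matching
#' is exact substring search - degradome tags are only 20-21 nt, so
#' perfect matching is both the convention and the correct granularity.
#' ncRNA matching checks both strands; transcript target mapping is
#' sense-only because degradome tags are 5' fragments of the mRNA itself.
#'
#' @name annotate_filter
NULL

# Concatenated two-strand haystack for one reference class.
.haystack <- function(refs, both_strands = TRUE) {
  refs <- dna_u2t(unname(refs))
  if (both_strands) refs <- c(refs, revcomp(refs))
  paste(refs, collapse = "\n")
}

#' Classify clean tags by the tiered priority rule
#'
#' @param tags data frame with `seq` and optionally `polyn` columns
#'   (from [preprocess_reads()] / [collapse_tags()]).
#' @param tier1 named list of Rfam-like reference sets (character
#'   vectors), searched in the order given, conventionally
#'   `list(rRNA=, tRNA=, snRNA=, snoRNA=)`.
#' @param tier2 named list of GenBank-like reference sets (rRNA, tRNA).
#' @param transcripts named character vector of transcript sequences.
#' @return the `tags` data frame with a `label` column added; labels are
#'   tier-1/2 class names, `polyN`, `cDNA_sense`, `cDNA_antisense` or
#'   `other`, exactly one per tag.
#' @export
classify_tags <- function(tags, tier1 = list(), tier2 = list(), transcripts) {
  seqs <- dna_u2t(tags$seq)
  n <- length(seqs)
  label <- rep(NA_character_, n)

  for (tier in list(tier1, tier2)) {
    for (cls in names(tier)) {
      if (!length(tier[[cls]])) next
      todo <- which(is.na(label))
      if (!length(todo)) break
      hay <- .haystack(tier[[cls]])
      hit <- vapply(seqs[todo], grepl, logical(1), x = hay,
                    fixed = TRUE, USE.NAMES = FALSE)
      label[todo[hit]] <- cls
    }
  }

  todo <- which(is.na(label))
  if (length(todo)) {
    pn <- if (!is.null(tags$polyn)) tags$polyn[todo] else detect_polyn(seqs[todo])
    label[todo[pn]] <- "polyN"
  }

  todo <- which(is.na(label))
  if (length(todo) && length(transcripts)) {
    hay_s <- .haystack(transcripts, both_strands = FALSE)
    hit_s <- vapply(seqs[todo], grepl, logical(1), x = hay_s,
                    fixed = TRUE, USE.NAMES = FALSE)
    label[todo[hit_s]] <- "cDNA_sense"
    todo <- which(is.na(label))
    if (length(todo)) {
      hit_a <- vapply(revcomp(seqs[todo]), grepl, logical(1), x = hay_s,
                      fixed = TRUE, USE.NAMES = FALSE)
      label[todo[hit_a]] <- "cDNA_antisense"
    }
  }
  label[is.na(label)] <- "other"
  tags$label <- label
  tags
}

#' Per-class totals and unique-tag counts
#'
#' @param tags data frame from [classify_tags()] with `raw_count`.
#' @return data frame `label`, `total`, `unique`.
#' @export
classification_summary <- function(tags) {
  if (!nrow(tags))
    return(data.frame(label = character(0), total = integer(0),
                      unique = integer(0)))
  agg_t <- tapply(tags$raw_count, tags$label, sum)
  agg_u <- tapply(tags$raw_count, tags$label, length)
  data.frame(label = names(agg_t), total = as.integer(agg_t),
             unique = as.integer(agg_u), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Map tags to transcripts (exact, sense strand, all occurrences)
#'
#' @param tags data frame with `seq` and `raw_count`.
#' @param transcripts named character vector.
#' @return data frame `seq`, `raw_count`, `transcript`, `pos` (1-based
#'   position of the tag's 5'-most nucleotide); multi-mapping tags yield
#'   one row per occurrence.
#' @export
map_tags_to_transcripts <- function(tags, transcripts) {
  empty <- data.frame(seq = character(0), raw_count = integer(0),
                      transcript = character(0), pos = integer(0))
  if (!nrow(tags) || !length(transcripts)) return(empty)
  txs <- dna_u2t(transcripts)
  seqs <- dna_u2t(tags$seq)
  out <- vector("list", length(txs))
  for (j in seq_along(txs)) {
    rows <- vector("list", nrow(tags))
    for (i in seq_len(nrow(tags))) {
      m <- gregexpr(seqs[i], txs[[j]], fixed = TRUE)[[1]]
      if (m[1] > 0)
        rows[[i]] <- data.frame(seq = tags$seq[i],
                                raw_count = tags$raw_count[i],
                                transcript = names(txs)[j],
                                pos = as.integer(m),
                                stringsAsFactors = FALSE)
    }
    out[[j]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) empty else `rownames<-`(res, NULL)
}

#' Per-chromosome sense/antisense tag counts
#'
#' @param tags data frame with `seq`, `raw_count`.
#' @param genome named character vector of chromosome sequences, or
#'   `NULL` (report skipped with a warning).
#' @return data frame `chrom`, `sense_total`, `sense_unique`,
#'   `antisense_total`, `antisense_unique`, or `NULL`.
#' @export
genome_strand_report <- function(tags, genome) {
  if (is.null(genome) || !length(genome)) {
    warning("no genome provided; strand report skipped")
    return(NULL)
  }
  seqs <- dna_u2t(tags$seq)
  rc <- revcomp(seqs)
  out <- lapply(names(genome), function(chr) {
    hay <- dna_u2t(genome[[chr]])
    s <- vapply(seqs, grepl, logical(1), x = hay, fixed = TRUE,
                USE.NAMES = FALSE)
    a <- vapply(rc, grepl, logical(1), x = hay, fixed = TRUE,
                USE.NAMES = FALSE)
    data.frame(chrom = chr,
               sense_total = sum(tags$raw_count[s]),
               sense_unique = sum(s),
               antisense_total = sum(tags$raw_count[a]),
               antisense_unique = sum(a),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
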