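#' Adapter clipping, read filtering, tag collapsing and library accounting
#'
#' Degradome tags are short (20-21 nt) 5' fragments of sliced mRNAs; the
#' sequencer reads through the insert into the 3' adapter, so the first
#' step truncates each read at the adapter and the second keeps only
#' high-quality 20-21 nt tags. Identical tags are then collapsed into
#' unique sequences with raw counts and normalised to tags per 100
#' million (TP100M) of the library's clean total.
#'
#' @name preprocess
NULL

#' Clip a 3' adapter from read sequences
#'
#' Truncates each sequence at the first exact occurrence of the adapter's
#' first 8 nt; sequences without the adapter are returned unchanged.
#'
#' @param seqs character vector of read sequences.
#' @param adapter 3' adapter sequence (at least 8 nt).
#' @return character vector of trimmed sequences.
#' @export
clip_adapter <- function(seqs, adapter) {
  if (nchar(adapter) < 8) stop("adapter must be at least 8 nt long")
  seed <- substr(toupper(adapter), 1, 8)
  pos <- regexpr(seed, toupper(seqs), fixed = TRUE)
  hit <- pos > 0
  seqs[hit] <- substr(seqs[hit], 1L, pos[hit] - 1L)
  seqs
}

#' Flag polyN tags
#'
#' A degraded (polyN) tag is one in which a single base accounts for more
#' than 70 percent of the sequence (strictly greater; exactly 70 percent
#' is not polyN).
#'
#' @param seqs character vector of nonempty sequences.
#' @return logical vector.
#' @export
detect_polyn <- function(seqs) {
  if (any(!nzchar(seqs))) stop("detect_polyn: empty sequence")
  up <- toupper(seqs)
  n <- nchar(up)
  frac <- rep(0, length(up))
  for (b in c("A", "C", "G", "T", "N")) {
    cnt <- n - nchar(gsub(b, "", up, fixed = TRUE))
    frac <- pmax(frac, cnt / n)
  }
  frac > 0.70
}

#' Summarise library accounting from filter counts
#'
#' The identity `clean_tags = raw_tags - filtered_N - filtered_low_quality`
#' holds by construction: adapter trimming shortens reads but removes
#' none, and trimmed reads outside 20-21 nt are counted as low quality.
#'
#' @param raw_tags,filtered_n,filtered_low_quality integer counts.
#' @param polyn_count clean reads flagged polyN (kept in the clean total
#'   under their own class).
#' @param unique_tag_count unique clean tag sequences, if known.
#' @return object of class `paredeg_accounting` (a list).
#' @export
library_accounting <- function(raw_tags, filtered_n, filtered_low_quality,
                               polyn_count = NA_integer_,
                               unique_tag_count = NA_integer_) {
  clean <- raw_tags - filtered_n - filtered_low_quality
  structure(list(
    raw_tags = raw_tags,
    filtered_N = filtered_n,
    filtered_low_quality = filtered_low_quality,
    clean_tags = clean,
    clean_fraction = if (raw_tags > 0) clean / raw_tags else NA_real_,
    polyN_count = polyn_count,
    unique_tag_count = unique_tag_count
  ), class = "paredeg_accounting")
}

#' @export
print.paredeg_accounting <- function(x, ...) {
  cat("Degradome library accounting\n")
  cat(sprintf("  raw tags            %12d\n", x$raw_tags))
  cat(sprintf("  filtered (N)        %12d\n", x$filtered_N))
  cat(sprintf("  filtered (low qual) %12d\n", x$filtered_low_quality))
  cat(sprintf("  clean tags          %12d (%.2f%%)\n",
              x$clean_tags, 100 * x$clean_fraction))
  if (!is.na(x$polyN_count))
    cat(sprintf("  polyN (kept)        %12d\n", x$polyN_count))
  if (!is.na(x$unique_tag_count))
    cat(sprintf("  unique clean tags   %12d\n", x$unique_tag_count))
  invisible(x)
}

#' Filter adapter-trimmed reads into clean 20-21 nt tags
#'
#' Reads containing N are removed first; a read is low quality when at
#' least 3 of its bases have Phred score below 20 (skipped for FASTA
#' input without qualities) or when its trimmed length falls outside
#' `[length_min, length_max]`. polyN tags survive filtering but are
#' flagged so downstream classification can set them aside.
#'
#' @param reads data frame with `seq` and optionally `qual` (Phred+33)
#'   columns, already adapter-trimmed (qualities must be trimmed to the
#'   same lengths).
#' @param length_min,length_max clean tag length bounds (20 and 21 nt).
#' @param min_phred,max_low_bases a read with more than `max_low_bases`
#'   bases under `min_phred` is low quality.
#' @return list with `tags` (data frame `seq`, `polyn` for surviving
#'   reads) and `accounting` ([library_accounting()]).
#' @export
filter_reads <- function(reads, length_min = 20L, length_max = 21L,
                         min_phred = 20L, max_low_bases = 2L) {
  n <- nrow(reads)
  if (n == 0) {
    return(list(tags = data.frame(seq = character(0), polyn = logical(0)),
                accounting = library_accounting(0L, 0L, 0L, 0L, 0L)))
  }
  seq <- toupper(reads$seq)
  has_n <- grepl("N", seq, fixed = TRUE)

  low <- rep(FALSE, n)
  if (!is.null(reads$qual)) {
    has_q <- !is.na(reads$qual)
    nlow <- integer(n)
    nlow[has_q] <- vapply(reads$qual[has_q],
                          function(q) sum(phred_scores(q) < min_phred),
                          integer(1), USE.NAMES = FALSE)
    low <- nlow > max_low_bases
  }
  len <- nchar(seq)
  bad_len <- len < length_min | len > length_max
  low_quality <- !has_n & (low | bad_len)
  clean <- !has_n & !low_quality

  seq_clean <- seq[clean]
  polyn <- if (length(seq_clean)) detect_polyn(seq_clean) else logical(0)
  acc <- library_accounting(n, sum(has_n), sum(low_quality),
                            polyn_count = sum(polyn),
                            unique_tag_count = length(unique(seq_clean)))
  list(tags = data.frame(seq = seq_clean, polyn = polyn,
                         stringsAsFactors = FALSE),
       accounting = acc)
}

#' Collapse clean reads into unique tags with raw counts
#'
#' @param seqs character vector of clean tag sequences.
#' @return data frame `seq`, `raw_count`, ordered by decreasing count
#'   then sequence; `sum(raw_count)` equals `length(seqs)`.
#' @export
collapse_tags <- function(seqs) {
  if (length(seqs) == 0)
    return(data.frame(seq = character(0), raw_count = integer(0)))
  tab <- table(seqs)
  out <- data.frame(seq = names(tab), raw_count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$raw_count, out$seq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tags per 100 million (TP100M)
#'
#' @param raw_count raw tag count(s).
#' @param clean_total clean-tag total of the library (>= 1).
#' @return `raw_count / clean_total * 1e8`.
#' @export
tp100m <- function(raw_count, clean_total) {
  if (length(clean_total) != 1 || is.na(clean_total) || clean_total < 1)
    stop("clean_total must be a single count >= 1")
  raw_count / clean_total * 1e8
}

#' Preprocess raw degradome reads end to end
#'
#' Convenience wrapper: adapter clipping, filtering, collapsing.
#'
#' @param reads data frame from [read_reads()] (or a FASTQ/FASTA path).
#' @param adapter 3' adapter sequence.
#' @inheritParams filter_reads
#' @return list with `tags` (collapsed, with `seq`, `raw_count`, `polyn`,
#'   `tp100m`) and `accounting`.
#' @export
preprocess_reads <- function(reads, adapter, length_min = 20L, length_max = 21L,
                             min_phred = 20L, max_low_bases = 2L) {
  if (is.character(reads) && length(reads) == 1) reads <- read_reads(reads)
  trimmed <- clip_adapter(reads$seq, adapter)
  if (!is.null(reads$qual)) {
    keep <- !is.na(reads$qual)
    reads$qual[keep] <- substr(reads$qual[keep], 1L, nchar(trimmed[keep]))
  }
  reads$seq <- trimmed
  flt <- filter_reads(reads, length_min, length_max, min_phred, max_low_bases)
  tags <- collapse_tags(flt$tags$seq)
  if (nrow(tags)) {
    pn <- tapply(flt$tags$polyn, flt$tags$seq, any)
    tags$polyn <- as.logical(pn[tags$seq])
    tags$tp100m <- tp100m(tags$raw_count, flt$accounting$clean_tags)
  } else {
    tags$polyn <- logical(0)
    tags$tp100m <- numeric(0)
  }
  list(tags = tags, accounting = flt$accounting)
}
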