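#' Sequence utilities and FASTA/FASTQ input/output
#'
#' Thin wrappers around Biostrings for the formats the pipeline consumes.
#' All internal comparisons are done on the DNA alphabet: transcriptomes
#' arrive as DNA FASTA while mature miRNAs are usually written as RNA, so
#' every sequence is passed through [dna_u2t()] before matching.
#'
#' @name seq_io
NULL

#' Map U to T and uppercase
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector over the DNA alphabet.
#' @export
dna_u2t <- function(x) chartr("Uu", "Tt", toupper(x))

#' Reverse complement of DNA sequences
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(dna_u2t(x))))
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file path.
#' @return named character vector (names are the first word of each header).
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fasta")
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write a named character vector as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path, format = "fasta", width = 80L)
  invisible(path)
}

#' Read sequencing reads from FASTQ or FASTA
#'
#' @param path input file; format is inferred from the first character
#'   (`@` for FASTQ, `>` for FASTA).
#' @return data frame with columns `id`, `seq` and `qual` (Phred+33 string,
#'   `NA` for FASTA input).
#' @export
read_reads <- function(path) {
  first <- substr(readLines(path, n = 1L), 1, 1)
  if (identical(first, "@")) {
    # the reader warns that it drops its own metadata columns; harmless
    ss <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
    data.frame(id = sub("\\s.*$", "", names(ss)),
               seq = as.character(ss),
               qual = as.character(Biostrings::quality(ss)),
               stringsAsFactors = FALSE, row.names = NULL)
  } else if (identical(first, ">")) {
    seqs <- read_fasta(path)
    data.frame(id = names(seqs), seq = unname(seqs), qual = NA_character_,
               stringsAsFactors = FALSE)
  } else {
    stop("cannot infer read format of '", path, "' (expected FASTQ or FASTA)")
  }
}

#' Write reads as Phred+33 FASTQ
#'
#' @param reads data frame with `id`, `seq`, `qual` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- reads$qual
  qual[is.na(qual)] <- vapply(nchar(reads$seq[is.na(qual)]),
                              function(n) strrep("I", n), character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", qual), con)
  invisible(path)
}

# Phred scores of a quality string (offset 33).
phred_scores <- function(qual) utf8ToInt(qual) - 33L
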