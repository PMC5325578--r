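#' Run the full degradome target-identification pipeline
#'
#' Chains the whole analysis: adapter clipping and read filtering,
#' tag collapsing and TP100M normalisation, priority-rule classification
#' (tier-1 ncRNA, tier-2 ncRNA, polyN, transcriptome), exact sense
#' mapping of the remaining tags, profile building, duplex candidate
#' search, cleavage-site calling with peak categories, and (optionally)
#' shuffle-based empirical p-values with a significance cut.
#'
#' @param reads data frame from [read_reads()] or a FASTQ/FASTA path.
#' @param transcripts named character vector (or FASTA path).
#' @param mirnas named character vector (or FASTA path).
#' @param adapter 3' adapter sequence.
#' @param ncrna_tier1,ncrna_tier2 named lists of ncRNA reference sets
#'   for the two classification tiers.
#' @param cds optional CDS annotation table (`transcript`, `cds_start`,
#'   `cds_end`).
#' @param max_score duplex score ceiling (default 7).
#' @param shuffles shuffles per miRNA for empirical p-values; 0 skips
#'   the p-value step.
#' @param seed RNG seed for the shuffles.
#' @param pval_max keep records with `p_value <= pval_max` (ignored when
#'   `shuffles = 0`).
#' @return list with `accounting`, `tags` (classified collapsed tags),
#'   `classification` (per-class summary), `hits`, `profiles`, and
#'   `records` (the called targets).
#' @export
run_degradome_pipeline <- function(reads, transcripts, mirnas, adapter,
                                   ncrna_tier1 = list(),
                                   ncrna_tier2 = list(),
                                   cds = NULL, max_score = 7,
                                   shuffles = 0L, seed = 1L,
                                   pval_max = 0.05) {
  if (is.character(transcripts) && length(transcripts) == 1 &&
      file.exists(transcripts)) transcripts <- read_fasta(transcripts)
  if (is.character(mirnas) && length(mirnas) == 1 && file.exists(mirnas))
    mirnas <- read_fasta(mirnas)

  pre <- preprocess_reads(reads, adapter)
  tags <- classify_tags(pre$tags, ncrna_tier1, ncrna_tier2, transcripts)

  mappable <- tags[tags$label == "cDNA_sense", , drop = FALSE]
  hits <- map_tags_to_transcripts(mappable, transcripts)
  profiles <- build_profiles(hits, pre$accounting$clean_tags)

  cands <- find_candidates_set(mirnas, transcripts, max_score = max_score)
  records <- call_targets(cands, profiles, cds = cds)
  if (shuffles > 0 && nrow(records)) {
    records <- add_pvalues(records, mirnas, transcripts, profiles,
                           shuffles = shuffles, seed = seed,
                           max_score = max_score)
    records <- records[records$p_value <= pval_max, , drop = FALSE]
    rownames(records) <- NULL
  }
  list(accounting = pre$accounting, tags = tags,
       classification = classification_summary(tags),
       hits = hits, profiles = profiles, records = records)
}
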