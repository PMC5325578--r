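#' Two-library comparison and miRNA-mRNA network decomposition
#'
#' The two degradome libraries (e.g. a control library CL and a drought
#' library DL) are compared at three levels: shared/specific clean tags,
#' a Venn summary of target genes, and a partition of each library's
#' miRNA-mRNA pairs into the overlapped network (pairs whose (miRNA,
#' target) key also occurs in the other library) and that library's
#' independent network. Overlap is computed per library against its own
#' records, so the two overlapped counts need not be equal when a
#' library holds several records with the same pair key.
#'
#' @name network
NULL

#' Venn summary of two target-gene sets
#'
#' @param targets_a,targets_b character vectors of target identifiers
#'   (duplicates ignored).
#' @return list with `a_only`, `shared`, `b_only`, `union` counts and
#'   `pct_a_only`, `pct_shared`, `pct_b_only` (percent of the union,
#'   2 decimals, half-up).
#' @export
venn_targets <- function(targets_a, targets_b) {
  a <- unique(targets_a); b <- unique(targets_b)
  shared <- length(intersect(a, b))
  a_only <- length(a) - shared
  b_only <- length(b) - shared
  uni <- a_only + shared + b_only
  pct <- function(x) if (uni > 0) round_half_up(100 * x / uni, 2) else NA_real_
  list(a_only = a_only, shared = shared, b_only = b_only, union = uni,
       pct_a_only = pct(a_only), pct_shared = pct(shared),
       pct_b_only = pct(b_only))
}

.pair_key <- function(pairs) paste(pairs$mirna, pairs$target, sep = "\r")

#' Partition two libraries' pair records into overlapped and independent
#'
#' @param pairs_a,pairs_b data frames with `mirna` and `target` columns,
#'   one row per record.
#' @return list with per-library record counts, `overlapped_a`,
#'   `overlapped_b`, `independent_a`, `independent_b`,
#'   `pct_independent_a`, `pct_independent_b` (percent of that library's
#'   records, 2 decimals, half-up) and the record subsets
#'   `overlapped_a_records` etc.
#' @export
split_networks <- function(pairs_a, pairs_b) {
  ka <- .pair_key(pairs_a); kb <- .pair_key(pairs_b)
  in_b <- ka %in% kb
  in_a <- kb %in% ka
  pct <- function(x, n) if (n > 0) round_half_up(100 * x / n, 2) else NA_real_
  list(n_a = nrow(pairs_a), n_b = nrow(pairs_b),
       overlapped_a = sum(in_b), overlapped_b = sum(in_a),
       independent_a = sum(!in_b), independent_b = sum(!in_a),
       pct_independent_a = pct(sum(!in_b), nrow(pairs_a)),
       pct_independent_b = pct(sum(!in_a), nrow(pairs_b)),
       overlapped_a_records = pairs_a[in_b, , drop = FALSE],
       overlapped_b_records = pairs_b[in_a, , drop = FALSE],
       independent_a_records = pairs_a[!in_b, , drop = FALSE],
       independent_b_records = pairs_b[!in_a, , drop = FALSE])
}

#' Export a bipartite miRNA-target network
#'
#' Writes a deduplicated edge list as TSV and SIF plus a node table with
#' node types, loadable by common graph GUIs.
#'
#' @param pairs data frame with `mirna`, `target` columns.
#' @param prefix output path prefix; writes `<prefix>_edges.tsv`,
#'   `<prefix>.sif`, `<prefix>_nodes.tsv`.
#' @return invisible list with `edges` and `nodes` data frames.
#' @export
export_network <- function(pairs, prefix) {
  edges <- unique(pairs[, c("mirna", "target"), drop = FALSE])
  rownames(edges) <- NULL
  nodes <- data.frame(
    node = c(unique(edges$mirna), unique(edges$target)),
    type = c(rep("miRNA", length(unique(edges$mirna))),
             rep("gene", length(unique(edges$target)))),
    stringsAsFactors = FALSE)
  write.table(edges, paste0(prefix, "_edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  sif <- if (nrow(edges))
    paste(edges$mirna, "cleaves", edges$target) else character(0)
  writeLines(sif, paste0(prefix, ".sif"))
  write.table(nodes, paste0(prefix, "_nodes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(edges = edges, nodes = nodes))
}

#' Top miRNAs by number of distinct targets
#'
#' @param pairs data frame with `mirna`, `target`.
#' @param n number of hubs to report.
#' @return data frame `mirna`, `n_targets`, decreasing.
#' @export
hub_mirnas <- function(pairs, n = 10L) {
  edges <- unique(pairs[, c("mirna", "target"), drop = FALSE])
  if (!nrow(edges))
    return(data.frame(mirna = character(0), n_targets = integer(0)))
  cnt <- sort(table(edges$mirna), decreasing = TRUE)
  utils::head(data.frame(mirna = names(cnt), n_targets = as.integer(cnt),
                         stringsAsFactors = FALSE), n)
}

#' Shared and library-specific clean tags of two libraries
#'
#' @param tags_a,tags_b collapsed tag tables (`seq`, `raw_count`).
#' @return list with `common_unique`, `common_total` (raw counts summed
#'   over both libraries), `specific_a_unique`, `specific_a_total`,
#'   `specific_b_unique`, `specific_b_total`.
#' @export
compare_tag_sets <- function(tags_a, tags_b) {
  common <- intersect(tags_a$seq, tags_b$seq)
  ina <- tags_a$seq %in% common
  inb <- tags_b$seq %in% common
  list(common_unique = length(common),
       common_total = sum(tags_a$raw_count[ina]) + sum(tags_b$raw_count[inb]),
       specific_a_unique = sum(!ina),
       specific_a_total = sum(tags_a$raw_count[!ina]),
       specific_b_unique = sum(!inb),
       specific_b_total = sum(tags_b$raw_count[!inb]))
}
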