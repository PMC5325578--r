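#' Synthetic degradome libraries with planted, ground-truthed cleavage
#'
#' The simulator emulates a plant degradome (PARE) library: transcripts
#' carry target windows that are reverse complements of the miRNAs with
#' configurable edits (mismatch, G:U wobble, single bulge), and each
#' planted site emits 20-21 nt reads whose 5' ends sit exactly at the
#' cleavage position opposite miRNA nucleotide 10, suffixed with the 3'
#' adapter. Background decay tags, ncRNA contaminants, polyN reads,
#' N-containing reads and low-quality reads are added at configurable
#' rates, and every planted event is returned as a truth record whose
#' expected duplex score is computed by the scoring oracle, never
#' hand-entered.
#'
#' @name synthetic_data
NULL

#' Build and validate a simulation configuration
#'
#' @param n_transcripts number of transcripts.
#' @param transcript_length_range min/max transcript length (nt).
#' @param cds_fraction fraction of each transcript annotated as CDS
#'   (centred; 1 = the whole transcript).
#' @param n_mirnas number of miRNAs.
#' @param mirna_length miRNA length in nt (default 21).
#' @param sites_per_mirna planted target sites per miRNA.
#' @param duplex_edits list of `list(position =, edit =)` entries, with
#'   `edit` one of `"mismatch"`, `"GU"`, `"bulge"`; applied to every
#'   planted window. Positions 10/11 (and a bulge at 10) are rejected
#'   because candidates require canonical pairing at the cleavage site.
#' @param signal_depth_range min/max raw read count per planted site.
#' @param noise_rate expected background tags per transcript nt.
#' @param contaminant_fractions named fractions (of all reads) for
#'   `rRNA`, `tRNA`, `snRNA`, `snoRNA`, `polyN`, `n_read`,
#'   `low_quality`; must sum to < 1.
#' @param adapter 3' adapter sequence (>= 8 nt).
#' @param seed RNG seed; a fixed seed gives byte-identical output.
#' @return validated list of class `paredeg_config`.
#' @export
synthetic_config <- function(n_transcripts = 20L,
                             transcript_length_range = c(300L, 600L),
                             cds_fraction = 1,
                             n_mirnas = 5L,
                             mirna_length = 21L,
                             sites_per_mirna = 2L,
                             duplex_edits = list(),
                             signal_depth_range = c(5L, 30L),
                             noise_rate = 0.02,
                             contaminant_fractions = c(
                               rRNA = 0, tRNA = 0, snRNA = 0, snoRNA = 0,
                               polyN = 0, n_read = 0, low_quality = 0),
                             adapter = "TGGAATTCTCGGGTGCCAAGG",
                             seed = 1L) {
  stopifnot(n_transcripts >= 1, n_mirnas >= 1, sites_per_mirna >= 1,
            length(transcript_length_range) == 2,
            transcript_length_range[1] <= transcript_length_range[2],
            mirna_length >= 14, cds_fraction >= 0, cds_fraction <= 1,
            length(signal_depth_range) == 2,
            signal_depth_range[1] >= 1,
            signal_depth_range[1] <= signal_depth_range[2],
            noise_rate >= 0, nchar(adapter) >= 8)
  known <- c("rRNA", "tRNA", "snRNA", "snoRNA", "polyN", "n_read",
             "low_quality")
  cf <- setNames(rep(0, length(known)), known)
  cf[names(contaminant_fractions)] <- contaminant_fractions
  if (any(cf < 0) || any(cf > 1) || sum(cf) >= 1)
    stop("contaminant fractions must lie in [0,1] and sum to < 1")
  for (e in duplex_edits) {
    stopifnot(is.list(e), all(c("position", "edit") %in% names(e)),
              e$edit %in% c("mismatch", "GU", "bulge"))
    if (e$edit == "bulge") {
      if (e$position < 1 || e$position > mirna_length - 1 || e$position == 10)
        stop("bulge position must be in 1..L-1 and not 10")
    } else if (e$position %in% c(10, 11) ||
               e$position < 1 || e$position > mirna_length) {
      stop("edit position must be in 1..L and not 10 or 11")
    }
  }
  structure(list(n_transcripts = as.integer(n_transcripts),
                 transcript_length_range = as.integer(transcript_length_range),
                 cds_fraction = cds_fraction,
                 n_mirnas = as.integer(n_mirnas),
                 mirna_length = as.integer(mirna_length),
                 sites_per_mirna = as.integer(sites_per_mirna),
                 duplex_edits = duplex_edits,
                 signal_depth_range = as.integer(signal_depth_range),
                 noise_rate = noise_rate,
                 contaminant_fractions = cf,
                 adapter = toupper(adapter),
                 seed = as.integer(seed)),
            class = "paredeg_config")
}

.BASES <- c("A", "C", "G", "T")

.rand_dna <- function(n) paste(sample(.BASES, n, replace = TRUE),
                               collapse = "")

# WC and wobble partners of a miRNA base on the target strand.
.wc_partner <- c(A = "T", C = "G", G = "C", T = "A")
.gu_partner <- c(G = "T", T = "G")

# Target window for one miRNA with the configured edits; returns the
# window sequence, the duplex path (for the scoring oracle) and the
# offset of the cleavage site from the window start.
.build_window <- function(mirna, edits) {
  L <- nchar(mirna)
  mb <- strsplit(mirna, "")[[1]]
  w <- strsplit(revcomp(mirna), "")[[1]]          # window 5'->3'
  states <- rep("WC", L)                           # per miRNA position
  bulge_after <- NA_integer_
  for (e in edits) {
    p <- e$position
    if (e$edit == "mismatch") {
      choices <- setdiff(.BASES, c(.wc_partner[[mb[p]]],
                                   .gu_partner[mb[p]]))
      choices <- choices[!is.na(choices)]
      w[L - p + 1] <- sample(choices, 1)
      states[p] <- "mismatch"
    } else if (e$edit == "GU") {
      if (!mb[p] %in% names(.gu_partner))
        stop("G:U edit at miRNA position ", p,
             " impossible: base is ", mb[p])
      w[L - p + 1] <- .gu_partner[[mb[p]]]
      states[p] <- "GU"
    } else {                                       # bulge after position p
      bulge_after <- p
    }
  }
  path <- states
  window <- paste(w, collapse = "")
  if (!is.na(bulge_after)) {
    b <- bulge_after
    window <- paste0(substr(window, 1, L - b), sample(.BASES, 1),
                     substr(window, L - b + 1, L))
    path <- append(states, "bulge", after = b)
  }
  lw <- nchar(window)
  idx3p <- if (!is.na(bulge_after) && bulge_after < 10) 11L else 10L
  list(window = window, path = path, site_offset = lw - idx3p,
       score = score_duplex(path))
}

#' Generate synthetic references with planted target windows
#'
#' @param config a [synthetic_config()].
#' @return list with `transcripts` and `mirnas` (named character
#'   vectors), `cds` (data frame `transcript`, `cds_start`, `cds_end`),
#'   `ncrna` (named list of reference sets for rRNA/tRNA/snRNA/snoRNA)
#'   and `truth_sites` (data frame `mirna`, `transcript`, `start`,
#'   `site`, `expected_score`).
#' @export
generate_references <- function(config) {
  stopifnot(inherits(config, "paredeg_config"))
  with_seed(config$seed, {
    L <- config$mirna_length
    adapter_seed <- substr(config$adapter, 1, 8)

    # miRNAs; G:U edit positions are forced to a wobble-capable base
    gu_pos <- vapply(Filter(function(e) e$edit == "GU", config$duplex_edits),
                     function(e) e$position, integer(1))
    mirnas <- character(config$n_mirnas)
    for (i in seq_len(config$n_mirnas)) {
      b <- sample(.BASES, L, replace = TRUE)
      if (length(gu_pos)) b[gu_pos] <- sample(c("G", "T"), length(gu_pos),
                                              replace = TRUE)
      mirnas[i] <- paste(b, collapse = "")
    }
    names(mirnas) <- sprintf("syn-miR%02d", seq_len(config$n_mirnas))

    # site -> transcript assignment, round robin
    n_sites <- config$n_mirnas * config$sites_per_mirna
    site_mirna <- rep(names(mirnas), each = config$sites_per_mirna)
    site_tx <- ((seq_len(n_sites) - 1L) %% config$n_transcripts) + 1L

    lens <- sample(seq(config$transcript_length_range[1],
                       config$transcript_length_range[2]),
                   config$n_transcripts, replace = TRUE)
    tx_names <- sprintf("TX%03d", seq_len(config$n_transcripts))

    transcripts <- character(config$n_transcripts)
    truth <- vector("list", n_sites)

    for (j in seq_len(config$n_transcripts)) {
      mine <- which(site_tx == j)
      placed <- FALSE
      for (attempt in 1:25) {
        tx <- .rand_dna(lens[j])
        occupied <- matrix(integer(0), ncol = 2)
        rows <- vector("list", length(mine))
        ok <- TRUE
        for (k in seq_along(mine)) {
          s <- mine[k]
          wi <- .build_window(mirnas[[site_mirna[s]]], config$duplex_edits)
          lw <- nchar(wi$window)
          max_start <- lens[j] - 20L - wi$site_offset
          if (max_start < 1)
            stop("transcript ", tx_names[j],
                 " too short to host a planted site (length ", lens[j], ")")
          start <- NA_integer_
          for (try in 1:200) {
            cand <- sample.int(max_start, 1)
            if (!nrow(occupied) ||
                all(cand > occupied[, 2] + 2 | cand + lw - 1 < occupied[, 1] - 2)) {
              start <- cand
              break
            }
          }
          if (is.na(start))
            stop("transcript ", tx_names[j],
                 " too short to host all planted sites (length ", lens[j], ")")
          substr(tx, start, start + lw - 1) <- wi$window
          occupied <- rbind(occupied, c(start, start + lw - 1))
          rows[[k]] <- data.frame(mirna = site_mirna[s],
                                  transcript = tx_names[j],
                                  start = start,
                                  site = start + wi$site_offset,
                                  expected_score = wi$score,
                                  stringsAsFactors = FALSE)
        }
        if (ok && !grepl(adapter_seed, tx, fixed = TRUE)) {
          transcripts[j] <- tx
          for (k in seq_along(mine)) truth[[mine[k]]] <- rows[[k]]
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not build transcript ", tx_names[j],
             " free of the adapter seed")
    }
    names(transcripts) <- tx_names

    cds <- data.frame(transcript = tx_names,
                      cds_start = NA_integer_, cds_end = NA_integer_)
    for (j in seq_len(config$n_transcripts)) {
      clen <- max(1L, round(config$cds_fraction * lens[j]))
      cds$cds_start[j] <- floor((lens[j] - clen) / 2) + 1L
      cds$cds_end[j] <- cds$cds_start[j] + clen - 1L
    }

    ncrna <- lapply(setNames(nm = c("rRNA", "tRNA", "snRNA", "snoRNA")),
                    function(cls) {
                      refs <- character(3)
                      for (i in 1:3) {
                        repeat {
                          r <- .rand_dna(120)
                          if (!grepl(adapter_seed, r, fixed = TRUE)) break
                        }
                        refs[i] <- r
                      }
                      names(refs) <- paste0(cls, "_", 1:3)
                      refs
                    })

    truth_sites <- do.call(rbind, truth)
    rownames(truth_sites) <- NULL
    list(transcripts = transcripts, mirnas = mirnas, cds = cds,
         ncrna = ncrna, truth_sites = truth_sites)
  })
}

#' Write generated references to a directory
#'
#' @param refs list from [generate_references()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_references <- function(refs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(refs$transcripts, file.path(dir, "transcripts.fa"))
  write_fasta(refs$mirnas, file.path(dir, "mirnas.fa"))
  write.table(refs$cds, file.path(dir, "cds.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (cls in names(refs$ncrna))
    write_fasta(refs$ncrna[[cls]], file.path(dir, paste0("ncrna_", cls, ".fa")))
  write.table(refs$truth_sites, file.path(dir, "truth_sites.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

# All exact occurrences of each insert across the transcripts,
# accumulated into per-transcript 5'-end count profiles.
.expected_profiles <- function(inserts, transcripts) {
  profs <- lapply(transcripts, function(tx) integer(0))
  tab <- table(inserts)
  for (seq in names(tab)) {
    for (tx in names(transcripts)) {
      m <- gregexpr(seq, transcripts[[tx]], fixed = TRUE)[[1]]
      if (m[1] > 0) {
        for (p in as.integer(m)) {
          key <- as.character(p)
          profs[[tx]][key] <- sum(profs[[tx]][key], tab[[seq]], na.rm = TRUE)
        }
      }
    }
  }
  lapply(profs, function(v) v[order(as.integer(names(v)))])
}

#' Simulate a raw degradome read library
#'
#' Signal reads start exactly at each planted cleavage site and extend
#' 20 or 21 nt 3'-ward (seeded coin flip per read); background reads are
#' uniform 20-21 nt transcript substrings whose placements are re-rolled
#' so they never land on a planted site, never tie or exceed the
#' smallest planted count on their transcript, and never multi-map.
#' All reads carry the 3' adapter. Truth categories are derived from the
#' exact expected tag profile (signal plus background, all occurrences).
#'
#' @param config the [synthetic_config()] used for the references.
#' @param refs list from [generate_references()] (same seed lineage).
#' @return list with `reads` (data frame `id`, `seq`, `qual`) and
#'   `truth` (data frame `mirna`, `transcript`, `site`, `planted_count`,
#'   `expected_score`, `expected_category`).
#' @export
simulate_degradome <- function(config, refs) {
  stopifnot(inherits(config, "paredeg_config"))
  with_seed(config$seed + 1L, {
    txs <- refs$transcripts
    truth <- refs$truth_sites
    adapter <- config$adapter
    qual_for <- function(seq) strrep("I", nchar(seq))

    # planted counts, distinct within a transcript so the peak ranking
    # (and hence the expected category) is unambiguous
    depth <- seq(config$signal_depth_range[1], config$signal_depth_range[2])
    counts <- integer(nrow(truth))
    for (j in split(seq_len(nrow(truth)), truth$transcript)) {
      for (try in 1:100) {
        cnt <- if (length(depth) == 1L) rep(depth, length(j))
               else sample(depth, length(j),
                           replace = length(depth) < length(j))
        if (!anyDuplicated(cnt) || length(depth) < length(j)) break
      }
      counts[j] <- cnt
    }
    truth$planted_count <- counts

    reads <- list()
    inserts <- character(0)

    emit <- function(id, insert, qual = NULL) {
      seq <- paste0(insert, adapter)
      q <- if (is.null(qual)) qual_for(seq)
           else paste0(qual, strrep("I", nchar(adapter)))
      reads[[length(reads) + 1L]] <<- data.frame(
        id = id, seq = seq, qual = q, stringsAsFactors = FALSE)
    }

    # signal reads
    for (i in seq_len(nrow(truth))) {
      tx <- txs[[truth$transcript[i]]]
      site <- truth$site[i]
      for (r in seq_len(truth$planted_count[i])) {
        len <- if (runif(1) < 0.5) 20L else 21L
        if (site + len - 1L > nchar(tx)) len <- 20L
        insert <- substr(tx, site, site + len - 1L)
        inserts <- c(inserts, insert)
        emit(sprintf("sig_%s_%s_%d_%d", truth$mirna[i],
                     truth$transcript[i], site, r), insert)
      }
    }

    # background decay tags
    tx_min_planted <- tapply(truth$planted_count, truth$transcript, min)
    bg_i <- 0L
    for (txn in names(txs)) {
      len_tx <- nchar(txs[[txn]])
      n_bg <- rpois(1, config$noise_rate * len_tx)
      if (n_bg == 0) next
      cap <- if (txn %in% names(tx_min_planted))
        tx_min_planted[[txn]] - 1L else Inf
      banned <- truth$site[truth$transcript == txn]
      placed <- integer(0)
      for (b in seq_len(n_bg)) {
        for (try in 1:50) {
          pos <- sample.int(len_tx - 21L, 1)
          if (pos %in% banned) next
          if (sum(placed == pos) + 1L > cap) next
          len <- if (runif(1) < 0.5) 20L else 21L
          insert <- substr(txs[[txn]], pos, pos + len - 1L)
          # skip placements that would multi-map (e.g. inside a window
          # shared by several planted copies of the same miRNA)
          n_occ <- sum(vapply(txs, function(t) {
            m <- gregexpr(insert, t, fixed = TRUE)[[1]]
            sum(m > 0)
          }, numeric(1)))
          if (n_occ != 1) next
          placed <- c(placed, pos)
          bg_i <- bg_i + 1L
          inserts <- c(inserts, insert)
          emit(sprintf("bg_%s_%d_%d", txn, pos, bg_i), insert)
          break
        }
      }
    }

    # contaminants, as fractions of the final library
    core_n <- length(reads)
    cf <- config$contaminant_fractions
    total <- ceiling(core_n / (1 - sum(cf)))
    n_cls <- setNames(as.integer(round(cf * total)), names(cf))

    for (cls in c("rRNA", "tRNA", "snRNA", "snoRNA")) {
      for (i in seq_len(n_cls[[cls]])) {
        ref <- refs$ncrna[[cls]][[sample.int(length(refs$ncrna[[cls]]), 1)]]
        len <- if (runif(1) < 0.5) 20L else 21L
        pos <- sample.int(nchar(ref) - len + 1L, 1)
        emit(sprintf("nc_%s_%d", cls, i), substr(ref, pos, pos + len - 1L))
      }
    }
    for (i in seq_len(n_cls[["polyN"]])) {
      b <- sample(.BASES, 1)
      chars <- sample(c(rep(b, 16), sample(setdiff(.BASES, b), 5,
                                           replace = TRUE)))
      emit(sprintf("polyn_%d", i), paste(chars, collapse = ""))
    }
    for (i in seq_len(n_cls[["n_read"]])) {
      txn <- sample(names(txs), 1)
      len <- if (runif(1) < 0.5) 20L else 21L
      pos <- sample.int(nchar(txs[[txn]]) - len + 1L, 1)
      insert <- substr(txs[[txn]], pos, pos + len - 1L)
      np <- sample.int(len, 1)
      substr(insert, np, np) <- "N"
      emit(sprintf("nread_%d", i), insert)
    }
    for (i in seq_len(n_cls[["low_quality"]])) {
      txn <- sample(names(txs), 1)
      len <- if (runif(1) < 0.5) 20L else 21L
      pos <- sample.int(nchar(txs[[txn]]) - len + 1L, 1)
      insert <- substr(txs[[txn]], pos, pos + len - 1L)
      q <- rep("I", len)
      q[sample.int(len, 3)] <- "#"    # Phred 2
      emit(sprintf("lowq_%d", i), insert, paste(q, collapse = ""))
    }

    profs <- .expected_profiles(inserts, txs)
    truth$expected_category <- vapply(seq_len(nrow(truth)), function(i)
      categorize(profs[[truth$transcript[i]]], truth$site[i]), integer(1))

    reads <- do.call(rbind, reads)
    rownames(reads) <- NULL
    list(reads = reads,
         truth = truth[, c("mirna", "transcript", "site", "planted_count",
                           "expected_score", "expected_category")])
  })
}
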