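#' Read-binning configuration
#'
#' @param min_aln_len_aa minimum translated alignment length in amino
#'   acids (inclusive).
#' @param identity_threshold named numeric vector of minimum percent
#'   identities per reference species (inclusive); the `default` entry
#'   applies to species without their own entry.
#' @param repeat_filter apply the repeat pre-filter before alignment.
#' @param repeat_k exact k-mer length used for repeat masking.
#' @param min_free_len minimum repeat-free run (bp) a read must retain.
#' @return list of class `binning_config`.
#' @export
binning_config <- function(min_aln_len_aa = 30L,
                           identity_threshold = c(default = 70),
                           repeat_filter = TRUE, repeat_k = 20L,
                           min_free_len = 100L) {
  if (any(identity_threshold <= 0 | identity_threshold > 100)) {
    stop("identity thresholds must be in (0, 100]")
  }
  structure(list(min_aln_len_aa = as.integer(min_aln_len_aa),
                 identity_threshold = identity_threshold,
                 repeat_filter = isTRUE(repeat_filter),
                 repeat_k = as.integer(repeat_k),
                 min_free_len = as.integer(min_free_len)),
            class = "binning_config")
}

#' Mask repetitive reads against a repeat library
#'
#' Read positions covered by an exact k-mer match to the repeat library
#' (either strand) are masked.  A read survives if it retains a maximal
#' unmasked run of at least `min_free_len` bp; survivors are trimmed to
#' their longest unmasked run.  The operation is idempotent.
#'
#' @param reads [seq_records()] of reads.
#' @param repeat_library [seq_records()] of repeat elements.
#' @param k exact-match k-mer length (>= 12).
#' @param min_free_len minimum repeat-free run length (bp).
#' @return surviving [seq_records()], trimmed; attribute `n_removed`
#'   gives the number of reads dropped.
#' @export
mask_repeats <- function(reads, repeat_library, k = 20L,
                         min_free_len = 100L) {
  if (k < 12L) stop("k must be >= 12")
  if (nrow(reads) == 0L) return(reads)
  if (nrow(repeat_library) == 0L) {
    warning("empty repeat library: repeat filter is a pass-through")
    attr(reads, "n_removed") <- 0L
    return(reads)
  }
  lib <- unique(unlist(lapply(c(repeat_library$seq,
                                revcomp(repeat_library$seq)),
                              .seq_kmers, k = k), use.names = FALSE))
  read_kmers <- lapply(reads$seq, .seq_kmers, k = k)
  flat_hit <- unlist(read_kmers, use.names = FALSE) %in% lib
  counts <- lengths(read_kmers)
  idx_end <- cumsum(counts)
  idx_start <- idx_end - counts + 1L

  ids <- character(0); seqs <- character(0); quals <- character(0)
  n_removed <- 0L
  for (i in seq_len(nrow(reads))) {
    n <- nchar(reads$seq[[i]])
    masked <- rep(FALSE, n)
    if (counts[[i]] > 0L) {
      hits <- which(flat_hit[idx_start[[i]]:idx_end[[i]]])
      for (h in hits) masked[h:(h + k - 1L)] <- TRUE
    }
    runs <- rle(!masked)
    free <- which(runs$values)
    if (!length(free)) { n_removed <- n_removed + 1L; next }
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    best <- free[[which.max(runs$lengths[free])]]
    if (runs$lengths[[best]] < min_free_len) {
      n_removed <- n_removed + 1L
      next
    }
    ids <- c(ids, reads$id[[i]])
    seqs <- c(seqs, substr(reads$seq[[i]], starts[[best]], ends[[best]]))
    quals <- c(quals, if (is.na(reads$qual[[i]])) NA_character_
               else substr(reads$qual[[i]], starts[[best]], ends[[best]]))
  }
  out <- seq_records(ids, seqs, quals)
  attr(out, "n_removed") <- n_removed
  out
}

# Align translated frame segments of reads against a set of proteins.
# seg_dt comes from .six_frame_segments(); pairs is a data.table
# (qid = segment row, sid = protein index).  Returns a hit table with
# read-level nucleotide query coordinates.
.translated_hits <- function(seg_dt, read_ids, read_lens, proteins,
                             protein_ids, pairs, gap = 8) {
  if (!nrow(pairs)) return(empty_hits())
  aln <- align_pairs(seg_dt$aa_seq, proteins, pairs$qid, pairs$sid,
                     type = "aa", mode = "local", gap = gap)
  seg <- seg_dt[pairs$qid]
  # vectorised frame-aa -> forward-strand nt coordinate mapping
  off <- abs(seg$frame) - 1L
  fs <- off + 3L * (seg$aa_off + aln$q_start)
  fe <- off + 3L * (seg$aa_off + aln$q_end)
  rl <- read_lens[seg$read]
  neg <- seg$frame < 0L
  qcoords <- cbind(ifelse(neg, rl - fe, fs), ifelse(neg, rl - fs, fe))
  data.frame(query_id = read_ids[seg$read],
             subject_id = protein_ids[pairs$sid],
             pct_identity = aln$pct_identity,
             aln_len = aln$aln_len,
             mismatches = aln$mismatches,
             gap_opens = aln$gap_opens,
             q_start = as.integer(qcoords[, 1L]),
             q_end = as.integer(qcoords[, 2L]),
             s_start = aln$s_start, s_end = aln$s_end,
             frame = seg$frame, score = aln$score,
             stringsAsFactors = FALSE)
}

#' Translated alignment of a nucleotide read against a protein
#'
#' All six reading frames are translated, broken into segments at stop
#' codons, and each segment is locally aligned against the protein with
#' BLOSUM62.  Query coordinates are reported in nucleotides on the
#' forward strand of the read (0-based half-open); subject coordinates
#' in amino acids on the protein.
#'
#' @param read nucleotide sequence (length >= 3).
#' @param protein amino-acid sequence.
#' @param min_score drop hits below this raw score.
#' @param min_seg_aa skip translated segments shorter than this.
#' @return hit data.frame (see [empty_hits()]).
#' @export
translated_align <- function(read, protein, min_score = 15,
                             min_seg_aa = 8L) {
  if (nchar(read) < 3L) stop("read shorter than one codon")
  segs <- .six_frame_segments(read, min_aa = min_seg_aa)
  if (!nrow(segs)) return(empty_hits())
  pairs <- data.table::data.table(qid = seq_len(nrow(segs)), sid = 1L)
  hits <- .translated_hits(segs, "query", nchar(read), protein,
                           "subject", pairs)
  hits <- hits[hits$score >= min_score, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Filter translated hits by length and identity
#'
#' Keeps hits with alignment length of at least `min_aln_len_aa` amino
#' acids and percent identity of at least the threshold configured for
#' the subject's reference species (both inclusive).
#'
#' @param hits hit data.frame.
#' @param cfg [binning_config()].
#' @param subject_species single species name applying to all hits, or a
#'   named character vector mapping subject ids to species.
#' @return filtered hit data.frame.
#' @export
filter_hits <- function(hits, cfg = binning_config(),
                        subject_species = "default") {
  if (!nrow(hits)) return(hits)
  species <- if (length(subject_species) == 1L &&
                 is.null(names(subject_species))) {
    rep(subject_species, nrow(hits))
  } else {
    sp <- subject_species[hits$subject_id]
    if (any(is.na(sp))) {
      stop("no species mapping for subject: ",
           hits$subject_id[is.na(sp)][[1L]])
    }
    sp
  }
  thr <- cfg$identity_threshold[species]
  fallback <- is.na(thr)
  if (any(fallback)) {
    if (!"default" %in% names(cfg$identity_threshold)) {
      stop("unknown species key: ", unique(species[fallback])[[1L]])
    }
    thr[fallback] <- cfg$identity_threshold[["default"]]
  }
  keep <- hits$aln_len >= cfg$min_aln_len_aa &
    hits$pct_identity >= unname(thr) - 1e-9
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' First-best-hit assignment of reads to OGRs
#'
#' Each read is assigned to the OGR of its single best surviving hit:
#' highest score, ties broken by longer alignment, then lexicographic
#' OGR id.  Reads without hits stay unassigned.
#'
#' @param hits filtered hit data.frame (query = read, subject = OGR).
#' @return list of class `read_bins`: `assignments` (data.frame read_id,
#'   ogr_id) and `bins` (named list ogr_id -> read ids).
#' @export
assign_fbh <- function(hits) {
  if (!nrow(hits)) {
    return(structure(list(assignments = data.frame(
      read_id = character(0), ogr_id = character(0),
      stringsAsFactors = FALSE), bins = list()), class = "read_bins"))
  }
  dt <- data.table::as.data.table(hits)
  data.table::setorderv(dt, c("query_id", "score", "aln_len", "subject_id"),
                        c(1L, -1L, -1L, 1L))
  best <- dt[!duplicated(dt$query_id)]
  assignments <- data.frame(read_id = best$query_id,
                            ogr_id = best$subject_id,
                            stringsAsFactors = FALSE)
  bins <- split(assignments$read_id, assignments$ogr_id)
  structure(list(assignments = assignments, bins = bins),
            class = "read_bins")
}

#' Allocate reads to orthologous group representatives
#'
#' The full binning pipeline: optional repeat pre-filtering, six-frame
#' translated alignment against the OGR proteins (k-mer seeded to limit
#' the candidate set), length/identity filtering, and first-best-hit
#' assignment.
#'
#' @param reads [seq_records()] of reads.
#' @param ogrs [seq_records()] of OGR proteins.
#' @param cfg [binning_config()].
#' @param repeat_library [seq_records()] repeat library; `NULL` disables
#'   the repeat filter regardless of `cfg$repeat_filter`.
#' @param subject_species species mapping passed to [filter_hits()].
#' @param seed_k,seed_top amino-acid seed length and per-segment
#'   candidate cap for the seeded search.
#' @return list of class `read_bins` (see [assign_fbh()]); attribute
#'   `hits` carries the filtered hit table, `reads_kept` the surviving
#'   read set after repeat filtering.
#' @export
bin_reads <- function(reads, ogrs, cfg = binning_config(),
                      repeat_library = NULL, subject_species = "default",
                      seed_k = 5L, seed_top = 4L) {
  kept <- reads
  if (cfg$repeat_filter && !is.null(repeat_library) &&
      nrow(repeat_library) > 0L) {
    kept <- mask_repeats(reads, repeat_library, k = cfg$repeat_k,
                         min_free_len = cfg$min_free_len)
  }
  if (nrow(kept) == 0L) {
    res <- assign_fbh(empty_hits())
    attr(res, "hits") <- empty_hits()
    attr(res, "reads_kept") <- kept
    return(res)
  }
  segs <- .six_frame_segments(kept$seq,
                              min_aa = max(8L, cfg$min_aln_len_aa %/% 2L))
  pairs <- .kmer_candidates(segs$aa_seq, ogrs$seq, k = seed_k,
                            min_share = 2L, top_n = seed_top)
  hits <- .translated_hits(segs, kept$id, nchar(kept$seq), ogrs$seq,
                           ogrs$id, pairs)
  hits <- filter_hits(hits, cfg, subject_species)
  res <- assign_fbh(hits)
  attr(res, "hits") <- hits
  attr(res, "reads_kept") <- kept
  res
}
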