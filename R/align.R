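#' @useDynLib polygenespace, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

.pg_cache <- new.env(parent = emptyenv())

# BLOSUM62 with its native 25-letter alphabet; cached after first load.
.aa_matrix <- function() {
  if (is.null(.pg_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pg_cache$blosum62 <- e$BLOSUM62
  }
  .pg_cache$blosum62
}

.aa_alphabet <- function() rownames(.aa_matrix())
.nt_alphabet <- function() c("A", "C", "G", "T", "N")

# Nucleotide scoring: +1 match, -2 mismatch; N is neutral (0) against
# everything so masked or ambiguous bases neither reward nor punish.
.nt_matrix <- function(match = 1, mismatch = -2) {
  ab <- .nt_alphabet()
  m <- matrix(mismatch, 5, 5, dimnames = list(ab, ab))
  diag(m) <- match
  m["N", ] <- 0
  m[, "N"] <- 0
  m
}

.encode_one <- function(seq, map, fallback) {
  v <- map[utf8ToInt(seq)]
  v[is.na(v)] <- fallback
  v
}

.char_map <- function(alphabet) {
  map <- rep(NA_integer_, 256L)
  map[vapply(alphabet, function(ch) utf8ToInt(ch), integer(1))] <-
    seq_along(alphabet) - 1L
  map
}

.encode_seqs <- function(seqs, type = c("nt", "aa")) {
  type <- match.arg(type)
  if (type == "nt") {
    map <- .char_map(.nt_alphabet())
    fallback <- 4L # N
  } else {
    ab <- .aa_alphabet()
    map <- .char_map(ab)
    fallback <- match("X", ab) - 1L
  }
  lapply(seqs, .encode_one, map = map, fallback = fallback)
}

.mode_code <- function(mode) {
  switch(mode, local = 0L, global = 1L, overlap = 2L,
         stop("unknown alignment mode: ", mode))
}

#' Pairwise sequence alignment
#'
#' Aligns pairs of sequences with a linear gap penalty.  Amino-acid
#' alignments use BLOSUM62; nucleotide alignments use +1/-2 scoring with
#' `N` neutral.  Percent identity is matches divided by aligned columns
#' (gap columns count against identity), times 100.
#'
#' @param qseqs,sseqs character vectors of query and subject sequences.
#' @param qi,si integer indices pairing `qseqs[qi[k]]` with `sseqs[si[k]]`;
#'   default aligns them positionally.
#' @param type `"nt"` or `"aa"`.
#' @param mode `"local"` (Smith-Waterman), `"global"` (Needleman-Wunsch)
#'   or `"overlap"` (ends-free, for read suffix-prefix overlaps).
#' @param gap linear gap penalty (positive).
#' @return data.frame with score, matches, mismatches, gap_opens, aln_len,
#'   pct_identity and 0-based half-open coordinates `q_start`, `q_end`,
#'   `s_start`, `s_end`.
#' @export
align_pairs <- function(qseqs, sseqs, qi = seq_along(qseqs),
                        si = seq_along(sseqs), type = c("nt", "aa"),
                        mode = c("local", "global", "overlap"),
                        gap = if (match.arg(type) == "aa") 8 else 3) {
  type <- match.arg(type)
  mode <- match.arg(mode)
  S <- if (type == "aa") .aa_matrix() else .nt_matrix()
  qe <- .encode_seqs(qseqs, type)
  se <- .encode_seqs(sseqs, type)
  out <- .cpp_align_pairs(qe, se, as.integer(qi), as.integer(si),
                          S, gap, .mode_code(mode))
  out$pct_identity <- ifelse(out$aln_len > 0,
                             100 * out$matches / out$aln_len, 0)
  out
}

#' @rdname align_pairs
#' @param qseq,sseq single sequences.
#' @export
align_pair <- function(qseq, sseq, type = c("nt", "aa"),
                       mode = c("local", "global", "overlap"),
                       gap = if (match.arg(type) == "aa") 8 else 3) {
  align_pairs(qseq, sseq, 1L, 1L, type = type, mode = mode, gap = gap)
}

# All k-mers of one sequence (character); sequences shorter than k give
# character(0).
.seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

# Shared-k-mer candidate pairing between many queries and many subjects.
# Returns a data.table (qid, sid, shared) keeping for each query the
# `top_n` subjects sharing at least `min_share` k-mers.
.kmer_candidates <- function(queries, subjects, k, min_share = 2L,
                             top_n = 5L) {
  skm <- lapply(subjects, function(s) unique(.seq_kmers(s, k)))
  qkm <- lapply(queries, function(s) unique(.seq_kmers(s, k)))
  sub_dt <- data.table::data.table(
    kmer = unlist(skm, use.names = FALSE),
    sid = rep(seq_along(skm), lengths(skm)))
  qry_dt <- data.table::data.table(
    kmer = unlist(qkm, use.names = FALSE),
    qid = rep(seq_along(qkm), lengths(qkm)))
  if (!nrow(sub_dt) || !nrow(qry_dt)) {
    return(data.table::data.table(qid = integer(0), sid = integer(0),
                                  shared = integer(0)))
  }
  data.table::setkey(sub_dt, kmer)
  hits <- sub_dt[qry_dt, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  cnt <- hits[, list(shared = .N), by = c("qid", "sid")]
  cnt <- cnt[cnt$shared >= min_share]
  data.table::setorderv(cnt, c("qid", "shared", "sid"), c(1L, -1L, 1L))
  keep <- cnt[, list(row = .I[seq_len(min(.N, top_n))]), by = "qid"]$row
  cnt[keep]
}

#' Reverse complement
#' @param seq nucleotide string(s).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  vapply(chartr("ACGTNacgtn", "TGCANtgcan", seq), function(s) {
    intToUtf8(rev(utf8ToInt(s)))
  }, character(1), USE.NAMES = FALSE)
}

.gc_vec <- function() {
  if (is.null(.pg_cache$gc_vec)) {
    .pg_cache$gc_vec <- Biostrings::GENETIC_CODE
  }
  .pg_cache$gc_vec
}

# Standard-code translation of one string; partial codons dropped,
# codons with ambiguous bases become X, stops are "*".
.translate_str <- function(s) {
  n <- nchar(s)
  n <- n - n %% 3L
  if (n < 3L) return("")
  cod <- substring(s, seq.int(1L, n - 2L, 3L), seq.int(3L, n, 3L))
  aa <- .gc_vec()[cod]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# Translate one frame (1:3) of many sequences.
.translate_frame <- function(seqs, frame) {
  vapply(seqs, function(s) {
    .translate_str(substr(s, frame, nchar(s)))
  }, character(1), USE.NAMES = FALSE)
}

# Six-frame translation of reads split at stop codons.  Returns a
# data.table with one row per open segment: read (index), frame (+-1..3),
# aa_off (0-based offset of the segment within its frame translation) and
# aa_seq.  Segments shorter than min_aa are dropped.
.six_frame_segments <- function(seqs, min_aa = 10L) {
  seqs_r <- revcomp(seqs)
  out <- vector("list", 6L)
  slot <- 1L
  for (fr in 1:3) {
    for (strand in c(1L, -1L)) {
      aa <- .translate_frame(if (strand > 0) seqs else seqs_r, fr)
      segs <- strsplit(aa, "*", fixed = TRUE)
      rows <- lapply(seq_along(segs), function(i) {
        ss <- segs[[i]]
        if (!length(ss)) return(NULL)
        offs <- cumsum(c(0L, nchar(ss) + 1L))[seq_along(ss)]
        keep <- nchar(ss) >= min_aa
        if (!any(keep)) return(NULL)
        data.table::data.table(read = i, frame = strand * fr,
                               aa_off = offs[keep], aa_seq = ss[keep])
      })
      out[[slot]] <- data.table::rbindlist(rows)
      slot <- slot + 1L
    }
  }
  data.table::rbindlist(out)
}

# Map amino-acid coordinates on a frame translation back to 0-based
# half-open nucleotide coordinates on the forward strand of the read.
.aa_to_nt <- function(frame, read_len, aa_start, aa_end) {
  off <- abs(frame) - 1L
  nt_start_fr <- off + 3L * aa_start
  nt_end_fr <- off + 3L * aa_end
  if (frame > 0) {
    c(nt_start_fr, nt_end_fr)
  } else {
    c(read_len - nt_end_fr, read_len - nt_start_fr)
  }
}
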