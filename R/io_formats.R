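#' Sequence record container
#'
#' Sequence sets are plain data.frames with columns `id`, `seq` and
#' optionally `qual` (Sanger Phred+33 quality string, `NA` when absent).
#' This keeps reads, contigs, proteins and repeat elements in one
#' lightweight currency across the package.
#'
#' @param id character vector of unique identifiers.
#' @param seq character vector of sequences (upper-cased).
#' @param qual optional character vector of Phred+33 quality strings.
#' @return data.frame of class `pg_seqs`.
#' @export
seq_records <- function(id, seq, qual = NULL) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq)) stop("id and seq lengths differ")
  if (any(!nzchar(id))) stop("empty sequence id")
  dup <- id[duplicated(id)]
  if (length(dup)) stop("duplicate sequence id: ", dup[[1L]])
  if (is.null(qual)) {
    qual <- rep(NA_character_, length(id))
  } else {
    qual <- as.character(qual)
    bad <- !is.na(qual) & nchar(qual) != nchar(seq)
    if (any(bad)) stop("quality length mismatch for id: ", id[bad][[1L]])
  }
  out <- data.frame(id = id, seq = seq, qual = qual,
                    stringsAsFactors = FALSE)
  class(out) <- c("pg_seqs", "data.frame")
  out
}

#' Read/write FASTA and FASTQ
#'
#' Thin wrappers around Biostrings I/O returning [seq_records()] frames.
#' Ids are the first whitespace-delimited token of each header and must
#' be unique; sequences are upper-cased.
#'
#' @param path file path.
#' @return [seq_records()] data.frame.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    warning("empty FASTA file: ", path)
    return(seq_records(character(0), character(0)))
  }
  ids <- sub("\\s.*$", "", names(set))
  seq_records(ids, as.character(set))
}

#' @rdname read_fasta
#' @param records [seq_records()] data.frame.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @rdname read_fasta
#' @export
read_fastq <- function(path) {
  # suppress Biostrings' informational metadata-column note
  set <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  if (length(set) == 0L) {
    warning("empty FASTQ file: ", path)
    return(seq_records(character(0), character(0)))
  }
  ids <- sub("\\s.*$", "", names(set))
  seq_records(ids, as.character(set),
              as.character(Biostrings::quality(set)))
}

#' @rdname read_fasta
#' @export
write_fastq <- function(records, path) {
  qual <- records$qual
  if (any(is.na(qual))) {
    qual[is.na(qual)] <- vapply(nchar(records$seq)[is.na(qual)],
                                function(n) strrep("I", n), character(1))
  }
  set <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(records$seq),
    Biostrings::PhredQuality(qual))
  names(set) <- records$id
  Biostrings::writeQualityScaledXStringSet(set, path)
  invisible(path)
}

#' Read a genetic marker map
#'
#' Tab-delimited, four columns with a header row: marker id, chromosome,
#' centiMorgan position, marker sequence.  Rows are returned sorted by
#' (chromosome, cM) with a stable order for markers at equal positions.
#'
#' @param path file path.
#' @return data.frame (marker_id, chromosome, cm_position, seq).
#' @export
read_marker_map <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  if (ncol(raw) != 4L) stop("marker map must have 4 tab-separated columns")
  names(raw) <- c("marker_id", "chromosome", "cm_position", "seq")
  cm <- suppressWarnings(as.numeric(raw$cm_position))
  bad <- which(is.na(cm) | !is.finite(cm))
  if (length(bad)) {
    stop("non-numeric cM position at line ", bad[[1L]] + 1L,
         " of ", path)
  }
  raw$cm_position <- cm
  raw$seq <- toupper(raw$seq)
  ord <- order(raw$chromosome, raw$cm_position, seq_len(nrow(raw)))
  out <- raw[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.hit_cols <- c("query_id", "subject_id", "pct_identity", "aln_len",
               "mismatches", "gap_opens", "q_start", "q_end",
               "s_start", "s_end", "frame", "score")

#' Empty alignment hit table
#' @return zero-row hit data.frame with the canonical 12 columns.
#' @export
empty_hits <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             pct_identity = numeric(0), aln_len = integer(0),
             mismatches = integer(0), gap_opens = integer(0),
             q_start = integer(0), q_end = integer(0),
             s_start = integer(0), s_end = integer(0),
             frame = integer(0), score = numeric(0),
             stringsAsFactors = FALSE)
}

#' Convert between internal and on-disk coordinates
#'
#' Internally every interval is 0-based half-open; serialized tables use
#' 1-based inclusive coordinates.  The two converters are inverse
#' bijections.
#'
#' @param start,end interval bounds.
#' @return list with `start` and `end` in the other convention.
#' @export
coords_to_1based <- function(start, end) list(start = start + 1L, end = end)

#' @rdname coords_to_1based
#' @export
coords_to_0based <- function(start, end) list(start = start - 1L, end = end)

#' Read/write the 12-column alignment hit table
#'
#' A tab-delimited dialect mirroring the classic tabular alignment
#' format: query, subject, percent identity (2 decimals), alignment
#' length (aa for translated hits), mismatches, gap opens, query
#' start/end, subject start/end (all 1-based inclusive on disk), frame
#' and score.  `read_hit_table(write_hit_table(x)) == x` for tables whose
#' identities carry at most 2 decimals.
#'
#' @param hits hit data.frame (see [empty_hits()] for columns).
#' @param path file path.
#' @export
write_hit_table <- function(hits, path) {
  if (nrow(hits) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  q <- coords_to_1based(hits$q_start, hits$q_end)
  s <- coords_to_1based(hits$s_start, hits$s_end)
  lines <- sprintf("%s\t%s\t%.2f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%g",
                   hits$query_id, hits$subject_id, hits$pct_identity,
                   as.integer(hits$aln_len), as.integer(hits$mismatches),
                   as.integer(hits$gap_opens), q$start, q$end,
                   s$start, s$end, as.integer(hits$frame), hits$score)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_hit_table
#' @export
read_hit_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_hits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    stop("malformed hit table line ", which(nf != 12L)[[1L]],
         ": expected 12 columns, got ", nf[nf != 12L][[1L]])
  }
  m <- do.call(rbind, fields)
  q <- coords_to_0based(as.integer(m[, 7L]), as.integer(m[, 8L]))
  s <- coords_to_0based(as.integer(m[, 9L]), as.integer(m[, 10L]))
  data.frame(query_id = m[, 1L], subject_id = m[, 2L],
             pct_identity = as.numeric(m[, 3L]),
             aln_len = as.integer(m[, 4L]),
             mismatches = as.integer(m[, 5L]),
             gap_opens = as.integer(m[, 6L]),
             q_start = q$start, q_end = q$end,
             s_start = s$start, s_end = s$end,
             frame = as.integer(m[, 11L]),
             score = as.numeric(m[, 12L]),
             stringsAsFactors = FALSE)
}
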