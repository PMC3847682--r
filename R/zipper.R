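# Translated first-best-hit table of nucleotide queries against an
# ordered reference protein set.
.translated_fbh <- function(queries, proteins, identity_min = 70,
                            min_len_aa = 30L, seed_k = 5L,
                            seed_top = 4L) {
  if (nrow(queries) == 0L || nrow(proteins) == 0L) {
    return(data.frame(query_id = character(0), gene_id = character(0),
                      score = numeric(0), pct_identity = numeric(0),
                      aln_len = integer(0), stringsAsFactors = FALSE))
  }
  segs <- .six_frame_segments(queries$seq, min_aa = max(8L, min_len_aa %/% 2L))
  pairs <- .kmer_candidates(segs$aa_seq, proteins$seq, k = seed_k,
                            min_share = 2L, top_n = seed_top)
  hits <- .translated_hits(segs, queries$id, nchar(queries$seq),
                           proteins$seq, proteins$id, pairs)
  cfg <- binning_config(min_aln_len_aa = min_len_aa,
                        identity_threshold = c(default = identity_min),
                        repeat_filter = FALSE)
  hits <- filter_hits(hits, cfg)
  if (!nrow(hits)) {
    return(data.frame(query_id = character(0), gene_id = character(0),
                      score = numeric(0), pct_identity = numeric(0),
                      aln_len = integer(0), stringsAsFactors = FALSE))
  }
  fbh <- assign_fbh(hits)$assignments
  m <- match(paste(fbh$read_id, fbh$ogr_id),
             paste(hits$query_id, hits$subject_id))
  data.frame(query_id = fbh$read_id, gene_id = fbh$ogr_id,
             score = hits$score[m], pct_identity = hits$pct_identity[m],
             aln_len = hits$aln_len[m], stringsAsFactors = FALSE)
}

#' Detect syntenic conserved blocks against an ordered reference
#'
#' Query sequences are matched to the reference gene set by translated
#' first-best hits (minimum identity and 30 aa alignment length); a
#' sliding window of `window` consecutive reference genes qualifies
#' when at least `min_density` of its genes are hit, and overlapping
#' qualifying windows are merged into maximal blocks.
#'
#' @param query_seqs [seq_records()] query sequences (repeat-filtered).
#' @param reference [seq_records()] of reference gene proteins whose row
#'   order is their genomic order.
#' @param gene_order optional character vector giving the genomic order
#'   of the reference gene ids; must be a permutation of them.
#' @param identity_min minimum percent identity for a hit.
#' @param min_len_aa minimum alignment length (aa).
#' @param window sliding-window size in genes.
#' @param min_density minimum hit genes per window.
#' @return data.frame of blocks: block_id, start_idx, end_idx (1-based
#'   gene indices on the reference order), n_genes_hit, support (total
#'   FBHs in the block); attributes `fbh` (the hit table) and
#'   `gene_order`.
#' @export
detect_synteny <- function(query_seqs, reference, gene_order = NULL,
                           identity_min = 70, min_len_aa = 30L,
                           window = 5L, min_density = 3L) {
  if (is.null(gene_order)) {
    gene_order <- reference$id
  } else if (!setequal(gene_order, reference$id) ||
             length(gene_order) != nrow(reference)) {
    stop("gene_order must be a permutation of the reference gene ids")
  }
  fbh <- .translated_fbh(query_seqs, reference, identity_min, min_len_aa)
  idx <- match(fbh$gene_id, gene_order)
  hit_genes <- sort(unique(idx))
  n <- length(gene_order)
  qual <- logical(n) # windows marked by start index
  if (length(hit_genes) && n >= window) {
    ishit <- logical(n)
    ishit[hit_genes] <- TRUE
    cs <- cumsum(ishit)
    starts <- seq_len(n - window + 1L)
    dens <- cs[starts + window - 1L] - c(0, cs)[starts]
    qual[starts[dens >= min_density]] <- TRUE
  }
  blocks <- list()
  r <- rle(qual[seq_len(max(1L, n - window + 1L))])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  bi <- 0L
  for (i in seq_along(r$values)) {
    if (!r$values[[i]]) next
    bi <- bi + 1L
    lo <- starts[[i]]
    hi <- min(ends[[i]] + window - 1L, n)
    span <- lo:hi
    blocks[[bi]] <- data.frame(
      block_id = sprintf("block%02d", bi), start_idx = lo, end_idx = hi,
      n_genes_hit = sum(span %in% hit_genes),
      support = sum(idx %in% span), stringsAsFactors = FALSE)
  }
  out <- if (length(blocks)) do.call(rbind, blocks) else data.frame(
    block_id = character(0), start_idx = integer(0), end_idx = integer(0),
    n_genes_hit = integer(0), support = integer(0),
    stringsAsFactors = FALSE)
  attr(out, "fbh") <- fbh
  attr(out, "gene_order") <- gene_order
  out
}

#' Anchor genetic markers to reference genes by bidirectional best hits
#'
#' A marker anchors a reference gene when the gene is the marker's best
#' translated hit AND the marker is that gene's best hit (reciprocity);
#' non-reciprocal or hitless markers stay unanchored.
#'
#' @param markers marker map data.frame ([read_marker_map()]).
#' @param reference [seq_records()] of reference gene proteins.
#' @param identity_min,min_len_aa hit filters as in [detect_synteny()].
#' @return data.frame (marker_id, gene_id) of anchored pairs.
#' @export
anchor_markers <- function(markers, reference, identity_min = 70,
                           min_len_aa = 30L) {
  qrec <- seq_records(markers$marker_id, markers$seq)
  segs <- .six_frame_segments(qrec$seq, min_aa = max(8L, min_len_aa %/% 2L))
  pairs <- .kmer_candidates(segs$aa_seq, reference$seq, k = 5L,
                            min_share = 2L, top_n = 6L)
  hits <- .translated_hits(segs, qrec$id, nchar(qrec$seq),
                           reference$seq, reference$id, pairs)
  cfg <- binning_config(min_aln_len_aa = min_len_aa,
                        identity_threshold = c(default = identity_min),
                        repeat_filter = FALSE)
  hits <- filter_hits(hits, cfg)
  if (!nrow(hits)) {
    return(data.frame(marker_id = character(0), gene_id = character(0),
                      stringsAsFactors = FALSE))
  }
  dt <- data.table::as.data.table(hits)
  data.table::setorderv(dt, c("query_id", "score", "aln_len", "subject_id"),
                        c(1L, -1L, -1L, 1L))
  m_best <- dt[!duplicated(dt$query_id), c("query_id", "subject_id")]
  data.table::setorderv(dt, c("subject_id", "score", "aln_len", "query_id"),
                        c(1L, -1L, -1L, 1L))
  g_best <- dt[!duplicated(dt$subject_id), c("subject_id", "query_id")]
  bbh <- merge(m_best, g_best, by = "subject_id")
  bbh <- bbh[bbh$query_id.x == bbh$query_id.y]
  out <- data.frame(marker_id = bbh$query_id.x, gene_id = bbh$subject_id,
                    stringsAsFactors = FALSE)
  out[order(out$marker_id), , drop = FALSE]
}

#' Build the virtual gene-order map
#'
#' Markers in genetic order form the backbone.  Between each pair of
#' consecutive anchored markers, the genes lying between their anchor
#' genes on the highest-ranked reference carrying both anchors are
#' inserted in reference order (reversed, with an inversion flag, when
#' the anchors are inverted relative to the genetic map); lower-ranked
#' references only fill intervals the higher ranks cannot.  NGS
#' sequences attach to the row of their first-best-hit gene.
#'
#' @param marker_map marker data.frame sorted by cM
#'   ([read_marker_map()]).
#' @param anchors named list (by reference) of (marker_id, gene_id)
#'   data.frames from [anchor_markers()].
#' @param reference_orders named list (by reference) of gene ids in
#'   genomic order.
#' @param synteny_genes optional named list (by reference) restricting
#'   insertable genes to those inside detected synteny blocks; `NULL`
#'   allows all.
#' @param ngs_anchors named character vector: NGS sequence id ->
#'   first-best-hit gene id.
#' @param rank character vector of reference names, highest rank first;
#'   defaults to `names(reference_orders)`.
#' @return data.frame of class `zipper_map`: position_index, marker_id,
#'   cm, one gene column per reference, `anchored_ngs`
#'   (comma-separated), `inverted`; attribute `unplaced` lists
#'   references' genes and NGS ids that found no row.
#' @export
build_zipper <- function(marker_map, anchors, reference_orders,
                         synteny_genes = NULL, ngs_anchors = character(0),
                         rank = names(reference_orders)) {
  mm <- marker_map[order(marker_map$cm_position,
                         seq_len(nrow(marker_map))), , drop = FALSE]
  refs <- rank
  anchor_of <- lapply(refs, function(rf) {
    a <- anchors[[rf]]
    if (is.null(a) || !nrow(a)) return(character(0))
    stats::setNames(a$gene_id, a$marker_id)
  })
  names(anchor_of) <- refs
  allowed <- lapply(refs, function(rf) {
    if (is.null(synteny_genes) || is.null(synteny_genes[[rf]])) {
      reference_orders[[rf]]
    } else synteny_genes[[rf]]
  })
  names(allowed) <- refs
  used <- lapply(refs, function(rf) character(0))
  names(used) <- refs

  rows <- list()
  add_row <- function(marker_id, cm, genes, inverted) {
    row <- list(marker_id = marker_id, cm = cm, inverted = inverted)
    for (rf in refs) row[[rf]] <- genes[[rf]] %||% NA_character_
    rows[[length(rows) + 1L]] <<- row
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a

  for (i in seq_len(nrow(mm))) {
    mid <- mm$marker_id[[i]]
    genes <- list()
    for (rf in refs) {
      g <- anchor_of[[rf]][mid]
      if (!is.na(g) && !g %in% used[[rf]]) {
        genes[[rf]] <- unname(g)
        used[[rf]] <- c(used[[rf]], unname(g))
      }
    }
    add_row(mid, mm$cm_position[[i]], genes, FALSE)
    if (i == nrow(mm)) break
    nxt <- mm$marker_id[[i + 1L]]
    # highest-ranked reference anchoring both flanking markers
    for (rf in refs) {
      g1 <- anchor_of[[rf]][mid]
      g2 <- anchor_of[[rf]][nxt]
      if (is.na(g1) || is.na(g2)) next
      ord <- reference_orders[[rf]]
      i1 <- match(unname(g1), ord)
      i2 <- match(unname(g2), ord)
      if (is.na(i1) || is.na(i2) || abs(i2 - i1) <= 1L) break
      inverted <- i1 > i2
      between <- if (inverted) ord[(i1 - 1L):(i2 + 1L)] else
        ord[(i1 + 1L):(i2 - 1L)]
      between <- between[between %in% allowed[[rf]] &
                           !between %in% used[[rf]]]
      for (g in between) {
        used[[rf]] <- c(used[[rf]], g)
        gl <- list(); gl[[rf]] <- g
        add_row(NA_character_, NA_real_, gl, inverted)
      }
      break
    }
  }

  out <- data.frame(position_index = seq_along(rows),
                    marker_id = vapply(rows, function(r)
                      r$marker_id, character(1)),
                    cm = vapply(rows, function(r) r$cm, numeric(1)),
                    stringsAsFactors = FALSE)
  for (rf in refs) {
    out[[rf]] <- vapply(rows, function(r) r[[rf]], character(1))
  }
  out$inverted <- vapply(rows, function(r) r$inverted, logical(1))

  # attach NGS sequences to the row of their FBH gene, once each
  out$anchored_ngs <- ""
  unplaced_ngs <- character(0)
  if (length(ngs_anchors)) {
    gene_cols <- as.matrix(out[, refs, drop = FALSE])
    for (nid in names(ngs_anchors)) {
      hit <- which(gene_cols == ngs_anchors[[nid]], arr.ind = TRUE)
      if (nrow(hit)) {
        r <- hit[1L, 1L]
        out$anchored_ngs[[r]] <- if (nzchar(out$anchored_ngs[[r]])) {
          paste(out$anchored_ngs[[r]], nid, sep = ",")
        } else nid
      } else {
        unplaced_ngs <- c(unplaced_ngs, nid)
      }
    }
  }
  unplaced_genes <- lapply(refs, function(rf) {
    setdiff(allowed[[rf]], used[[rf]])
  })
  names(unplaced_genes) <- refs
  attr(out, "unplaced") <- list(genes = unplaced_genes,
                                ngs = unplaced_ngs)
  class(out) <- c("zipper_map", "data.frame")
  out
}

#' Run the full zipper workflow for one chromosome
#'
#' Repeat-filters the NGS sequences, detects synteny blocks against each
#' ranked reference, anchors the markers by bidirectional best hits,
#' anchors NGS sequences by first best hits and assembles the virtual
#' gene-order map.
#'
#' @param marker_map [read_marker_map()] data.frame.
#' @param references named list of [seq_records()] protein sets in
#'   genomic order; list order = rank (closest reference first).
#' @param ngs [seq_records()] NGS survey sequences.
#' @param repeat_library optional [seq_records()] repeat library.
#' @param identity_top,identity_rest percent-identity thresholds for the
#'   top-ranked and the remaining references.
#' @param min_len_aa minimum alignment length (aa).
#' @param window,min_density synteny sliding-window parameters.
#' @return `zipper_map` data.frame (see [build_zipper()]).
#' @export
genome_zipper <- function(marker_map, references, ngs,
                          repeat_library = NULL, identity_top = 75,
                          identity_rest = 70, min_len_aa = 30L,
                          window = 5L, min_density = 3L) {
  if (!is.null(repeat_library) && nrow(repeat_library) > 0L) {
    ngs <- mask_repeats(ngs, repeat_library)
  }
  refs <- names(references)
  thresholds <- stats::setNames(
    c(identity_top, rep(identity_rest, length(refs) - 1L)), refs)
  blocks <- list(); anchors <- list(); synteny_genes <- list()
  fbh_all <- list()
  for (rf in refs) {
    bl <- detect_synteny(ngs, references[[rf]],
                         identity_min = thresholds[[rf]],
                         min_len_aa = min_len_aa, window = window,
                         min_density = min_density)
    blocks[[rf]] <- bl
    ord <- attr(bl, "gene_order")
    keep <- unlist(lapply(seq_len(nrow(bl)), function(i) {
      ord[bl$start_idx[[i]]:bl$end_idx[[i]]]
    }), use.names = FALSE)
    synteny_genes[[rf]] <- unique(keep)
    anchors[[rf]] <- anchor_markers(marker_map, references[[rf]],
                                    identity_min = thresholds[[rf]],
                                    min_len_aa = min_len_aa)
    fbh_all[[rf]] <- attr(bl, "fbh")
  }
  # NGS first-best hit across references, in rank order
  ngs_anchor <- character(0)
  for (rf in refs) {
    fbh <- fbh_all[[rf]]
    fbh <- fbh[!fbh$query_id %in% names(ngs_anchor), , drop = FALSE]
    if (nrow(fbh)) {
      ngs_anchor <- c(ngs_anchor,
                      stats::setNames(fbh$gene_id, fbh$query_id))
    }
  }
  out <- build_zipper(marker_map, anchors,
                      lapply(references, function(r) r$id),
                      synteny_genes, ngs_anchor, rank = refs)
  attr(out, "blocks") <- blocks
  out
}
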