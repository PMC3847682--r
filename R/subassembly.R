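#' Assembly configuration
#'
#' @param mi minimum overlap identity in percent; overlaps below this
#'   are rejected.  97, 99 and 100 are the calibration settings used
#'   throughout.
#' @param min_overlap_bp minimum overlap alignment length.
#' @param min_contig_bp contigs shorter than this are dropped from the
#'   sub-assembly output (their reads still count as assembled).
#' @param min_read_bp reads shorter than this are excluded (ultra-short).
#' @param band diagonal band half-width for overlap alignment.
#' @param seed_k nucleotide k-mer length used to propose overlap
#'   candidates and diagonals.
#' @param depth_factor a read whose median k-mer depth exceeds the bin
#'   median by this factor is excluded as over-represented (repeat).
#' @param outlier_margin reads aligning to their layout consensus at
#'   identity below `mi - outlier_margin` are excluded as outliers.
#' @param candidate_slack overlap edges down to `mi - candidate_slack`
#'   raw identity are considered as merge candidates; every merge is
#'   still gated at `mi` on the consensus level, where sequencing
#'   errors have been voted out (see [assemble_bin()]).
#' @return list of class `assembly_config`.
#' @export
assembly_config <- function(mi = 99, min_overlap_bp = 40L,
                            min_contig_bp = 100L, min_read_bp = 50L,
                            band = 8L, seed_k = 16L, depth_factor = 10,
                            outlier_margin = 5, candidate_slack = 3) {
  if (mi <= 0 || mi > 100) stop("mi must be in (0, 100]")
  structure(list(mi = mi, min_overlap_bp = as.integer(min_overlap_bp),
                 min_contig_bp = as.integer(min_contig_bp),
                 min_read_bp = as.integer(min_read_bp),
                 band = as.integer(band), seed_k = as.integer(seed_k),
                 depth_factor = depth_factor,
                 outlier_margin = outlier_margin,
                 candidate_slack = candidate_slack),
            class = "assembly_config")
}

# Canonical k-mer occurrence table for a set of reads: (kmer, read, pos,
# flag) where flag is TRUE when the canonical k-mer equals the forward
# k-mer of the read.  pos is the 0-based forward-strand position.
.canon_kmer_table <- function(seqs, k) {
  rcs <- revcomp(seqs)
  km <- lapply(seqs, .seq_kmers, k = k)
  # reverse-complement k-mer at forward position p is the mirrored
  # k-mer of the reverse-complemented read
  kmr <- lapply(rcs, function(s) rev(.seq_kmers(s, k)))
  lens <- lengths(km)
  flat_f <- unlist(km, use.names = FALSE)
  if (!length(flat_f)) {
    return(data.table::data.table(kmer = character(0), read = integer(0),
                                  pos = integer(0), fwd = logical(0)))
  }
  flat_r <- unlist(kmr, use.names = FALSE)
  fwd <- flat_f <= flat_r
  data.table::data.table(
    kmer = ifelse(fwd, flat_f, flat_r),
    read = rep(seq_along(km), lens),
    pos = unlist(lapply(lens, function(n) seq_len(n) - 1L),
                 use.names = FALSE),
    fwd = fwd)
}

#' Detect read overlaps within a bin
#'
#' Candidate pairs and diagonals are proposed by shared (canonical)
#' k-mers; each candidate is verified by banded ends-free alignment on
#' either strand.  An edge is kept when the overlap alignment spans at
#' least `min_overlap_bp` columns with identity (matches over aligned
#' columns, including indel columns) of at least `mi` percent.
#'
#' @param reads [seq_records()] of the bin's reads (ultra-short reads
#'   should already be removed; [assemble_bin()] does this).
#' @param cfg [assembly_config()].
#' @return data.frame of edges: a, b (read indices, a < b), orient (+1
#'   same strand, -1 opposite), offset (start of laid b in a's forward
#'   coordinates), ov_len, pct_identity, matches.
#' @export
find_overlaps <- function(reads, cfg = assembly_config()) {
  empty <- data.frame(a = integer(0), b = integer(0), orient = integer(0),
                      offset = integer(0), ov_len = integer(0),
                      pct_identity = numeric(0), matches = integer(0))
  n <- nrow(reads)
  if (n < 2L) return(empty)
  kt <- .canon_kmer_table(reads$seq, cfg$seed_k)
  if (!nrow(kt)) return(empty)
  j <- kt[kt, on = "kmer", allow.cartesian = TRUE]
  j <- j[j$read < j$i.read]
  if (!nrow(j)) return(empty)
  lens <- nchar(reads$seq)
  k <- cfg$seed_k
  same <- j$fwd == j$i.fwd
  # diagonal of laid b within a's forward coordinates
  diag_val <- ifelse(same, j$pos - j$i.pos,
                     j$pos - (lens[j$i.read] - k - j$i.pos))
  cand <- data.table::data.table(a = j$read, b = j$i.read,
                                 orient = ifelse(same, 1L, -1L),
                                 diag = diag_val)
  cand <- cand[, list(votes = .N), by = c("a", "b", "orient", "diag")]
  data.table::setorderv(cand, c("a", "b", "orient", "votes", "diag"),
                        c(1L, 1L, 1L, -1L, 1L))
  cand <- cand[!duplicated(cand[, c("a", "b", "orient")])]

  enc <- .encode_seqs(reads$seq, "nt")
  enc_rc <- .encode_seqs(revcomp(reads$seq), "nt")
  nc <- nrow(cand)
  offset <- integer(nc); ov_len <- integer(nc)
  ident <- numeric(nc); matches <- integer(nc)
  keep <- logical(nc)
  for (r in seq_len(nc)) {
    b <- cand$b[[r]]
    bseq <- if (cand$orient[[r]] > 0) enc[[b]] else enc_rc[[b]]
    aln <- .cpp_overlap_banded(enc[[cand$a[[r]]]], bseq, cand$diag[[r]],
                               cfg$band, 1, -2, 3)
    if (is.na(aln$score[[1L]]) || aln$aln_len < cfg$min_overlap_bp) next
    idt <- 100 * aln$matches / aln$aln_len
    if (idt < cfg$mi - 1e-9) next
    keep[[r]] <- TRUE
    offset[[r]] <- aln$a_start - aln$b_start
    ov_len[[r]] <- aln$aln_len
    ident[[r]] <- idt
    matches[[r]] <- aln$matches
  }
  if (!any(keep)) return(empty)
  data.frame(a = cand$a[keep], b = cand$b[keep],
             orient = cand$orient[keep], offset = offset[keep],
             ov_len = ov_len[keep], pct_identity = ident[keep],
             matches = matches[keep])
}

# per-bin cache of split bases (as indices into ACGT), their reverse
# complements, and per-base consensus weights from the quality strings
.seq_cache <- function(reads) {
  n <- nrow(reads)
  bi <- vector("list", n); bi_rc <- vector("list", n)
  w <- vector("list", n); w_rc <- vector("list", n)
  rcs <- revcomp(reads$seq)
  for (i in seq_len(n)) {
    bi[[i]] <- match(strsplit(reads$seq[[i]], "", fixed = TRUE)[[1L]],
                     c("A", "C", "G", "T"))
    bi_rc[[i]] <- match(strsplit(rcs[[i]], "", fixed = TRUE)[[1L]],
                        c("A", "C", "G", "T"))
    q <- reads$qual[[i]]
    wi <- if (is.na(q)) rep(1, nchar(reads$seq[[i]])) else {
      ph <- utf8ToInt(q) - 33L
      1 - 10^(-ph / 10)
    }
    w[[i]] <- wi
    w_rc[[i]] <- rev(wi)
  }
  list(bi = bi, bi_rc = bi_rc, w = w, w_rc = w_rc)
}

# identity between two consensus fragments (character vectors) over
# their overlap, ignoring uncovered (N) columns
.span_identity <- function(cons_a, start_a, cons_b, start_b) {
  lo <- max(start_a, start_b)
  hi <- min(start_a + length(cons_a), start_b + length(cons_b))
  if (hi <= lo) return(list(len = 0L, identity = 100))
  ca <- cons_a[(lo - start_a + 1L):(hi - start_a)]
  cb <- cons_b[(lo - start_b + 1L):(hi - start_b)]
  use <- ca != "N" & cb != "N"
  if (!any(use)) return(list(len = 0L, identity = 100))
  list(len = sum(use), identity = 100 * sum(ca[use] == cb[use]) / sum(use))
}

# Greedy best-overlap-first layout merging.  Components carry their
# layout and a cached consensus; an edge is applied only if the two
# component consensi agree at >= mi percent identity over the full
# overlap the edge implies, so a single short clean overlap cannot glue
# two layouts that disagree elsewhere (the homeolog-collapse guard).
.merge_layouts <- function(kept, edges, cfg, cache = NULL) {
  if (is.null(cache)) cache <- .seq_cache(kept)
  nk <- nrow(kept)
  comp_of <- seq_len(nk)
  comps <- lapply(seq_len(nk), function(i) {
    list(layout = data.frame(read = i, pos = 0L, ori = 1L),
         cons = strsplit(kept$seq[[i]], "", fixed = TRUE)[[1L]])
  })
  lens <- nchar(kept$seq)
  comp_map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  # edges are retried across passes until a fixpoint: a merge rejected
  # while both sides were raw reads can succeed later, once a layout's
  # consensus has voted the sequencing errors out
  repeat {
  changed <- FALSE
  for (r in seq_len(nrow(edges))) {
    a <- edges$a[[r]]; b <- edges$b[[r]]
    ca <- comp_of[[a]]; cb <- comp_of[[b]]
    if (ca == cb) next
    A <- comps[[ca]]; B <- comps[[cb]]
    ra <- A$layout[A$layout$read == a, , drop = FALSE]
    rb <- B$layout[B$layout$read == b, , drop = FALSE]
    # affine maps stored-read coords -> component frame: x -> s*x + t
    sa <- ra$ori[[1L]]
    ta <- if (sa > 0) ra$pos[[1L]] else ra$pos[[1L]] + lens[[a]] - 1L
    sb <- rb$ori[[1L]]
    tb <- if (sb > 0) rb$pos[[1L]] else rb$pos[[1L]] + lens[[b]] - 1L
    # edge maps b-stored coords into a-stored coords
    if (edges$orient[[r]] > 0) {
      se <- 1L; te <- edges$offset[[r]]
    } else {
      se <- -1L; te <- edges$offset[[r]] + lens[[b]] - 1L
    }
    s_bA <- sa * se; t_bA <- sa * te + ta
    # frame B -> frame A (sb is +-1 so its own inverse)
    sF <- s_bA * sb; tF <- t_bA - s_bA * sb * tb
    # B consensus placed in A's frame
    lb <- length(B$cons)
    if (sF > 0) {
      consB <- B$cons; startB <- tF
    } else {
      consB <- rev(unname(comp_map[B$cons])); startB <- tF - lb + 1L
    }
    chk <- .span_identity(A$cons, 0L, consB, startB)
    if (chk$len >= 1L && chk$identity < cfg$mi - 1e-9) next
    # transform B's layout rows and merge
    layB <- B$layout
    s_r <- layB$ori
    t_r <- ifelse(s_r > 0, layB$pos, layB$pos + lens[layB$read] - 1L)
    s_n <- sF * s_r
    t_n <- sF * t_r + tF
    layB$ori <- s_n
    layB$pos <- ifelse(s_n > 0, t_n, t_n - (lens[layB$read] - 1L))
    lay <- rbind(A$layout, layB)
    shift <- min(lay$pos)
    lay$pos <- as.integer(lay$pos - shift)
    comps[[ca]] <- list(layout = lay,
                        cons = .consensus_from_layout(kept, lay, cache))
    comp_of[comp_of == cb] <- ca
    changed <- TRUE
  }
  if (!changed) break
  }
  comps[sort(unique(comp_of))]
}

# Reads left unmerged after layout construction are re-aligned against
# the multi-read layout consensi; a read matching a consensus at
# >= mi - outlier_margin identity joins that layout as a member (the
# complement of the outlier-exclusion rule).  Absorption never merges
# two layouts and never creates a new contig, it only moves reads from
# the singleton pool into existing contigs.
.absorb_singletons <- function(kept, comps, cfg, cache = NULL) {
  if (is.null(cache)) cache <- .seq_cache(kept)
  multi <- which(vapply(comps, function(cc) nrow(cc$layout) >= 2L,
                        logical(1)))
  single <- setdiff(seq_along(comps), multi)
  if (!length(multi) || !length(single)) return(comps)
  cons_seqs <- vapply(comps[multi], function(cc) {
    paste(cc$cons, collapse = "")
  }, character(1))
  sing_reads <- vapply(single, function(ci) {
    kept$seq[[comps[[ci]]$layout$read[[1L]]]]
  }, character(1))
  pool <- seq_records(c(sprintf("C%06d", seq_along(multi)),
                        sprintf("S%06d", seq_along(single))),
                      c(cons_seqs, sing_reads))
  acfg <- cfg
  acfg$mi <- max(0, cfg$mi - cfg$outlier_margin)
  ed <- find_overlaps(pool, acfg)
  nc <- length(multi)
  ed <- ed[ed$a <= nc & ed$b > nc, , drop = FALSE]
  if (!nrow(ed)) return(comps)
  ord <- order(ed$b, -ed$pct_identity, -ed$ov_len, ed$a)
  ed <- ed[ord, , drop = FALSE]
  ed <- ed[!duplicated(ed$b), , drop = FALSE]
  touched <- integer(0)
  drop <- integer(0)
  for (r in seq_len(nrow(ed))) {
    ci <- multi[[ed$a[[r]]]]
    si <- single[[ed$b[[r]] - nc]]
    read_i <- comps[[si]]$layout$read[[1L]]
    comps[[ci]]$layout <- rbind(
      comps[[ci]]$layout,
      data.frame(read = read_i, pos = ed$offset[[r]],
                 ori = ed$orient[[r]]))
    touched <- c(touched, ci)
    drop <- c(drop, si)
  }
  for (ci in unique(touched)) {
    lay <- comps[[ci]]$layout
    lay$pos <- as.integer(lay$pos - min(lay$pos))
    comps[[ci]]$layout <- lay
    comps[[ci]]$cons <- .consensus_from_layout(kept, lay, cache)
  }
  comps[setdiff(seq_along(comps), drop)]
}

.median_kmer_depth <- function(seqs, k) {
  kt <- .canon_kmer_table(seqs, k)
  if (!nrow(kt)) return(rep(0, length(seqs)))
  cnt <- kt[, list(depth = .N), by = "kmer"]
  kt <- kt[cnt, on = "kmer"]
  med <- kt[, list(m = as.numeric(stats::median(depth))), by = "read"]
  out <- rep(0, length(seqs))
  out[med$read] <- med$m
  out
}

# Consensus over a layout as a character vector (uncovered columns N).
# `cache` comes from .seq_cache(reads).
.consensus_from_layout <- function(reads, layout, cache = NULL) {
  if (is.null(cache)) cache <- .seq_cache(reads)
  width <- max(layout$pos + nchar(reads$seq)[layout$read])
  votes <- matrix(0, nrow = 4L, ncol = width)
  for (r in seq_len(nrow(layout))) {
    i <- layout$read[[r]]
    fwd <- layout$ori[[r]] > 0
    base <- if (fwd) cache$bi[[i]] else cache$bi_rc[[i]]
    w <- if (fwd) cache$w[[i]] else cache$w_rc[[i]]
    cols <- layout$pos[[r]] + seq_along(base)
    ok <- !is.na(base)
    idx <- cbind(base[ok], cols[ok])
    votes[idx] <- votes[idx] + w[ok]
  }
  covered <- colSums(votes) > 0
  cons <- c("A", "C", "G", "T")[max.col(t(votes), ties.method = "first")]
  cons[!covered] <- "N"
  cons
}

# gapless identity of a laid read against the consensus (char vector)
.read_vs_consensus <- function(cache, i, ori, pos, consensus) {
  a <- if (ori > 0) cache$bi[[i]] else cache$bi_rc[[i]]
  a <- c("A", "C", "G", "T")[a]
  b <- consensus[(pos + 1L):min(pos + length(a), length(consensus))]
  n <- min(length(a), length(b))
  if (n == 0L) return(0)
  100 * sum(a[seq_len(n)] == b[seq_len(n)]) / n
}

#' Assemble one read bin
#'
#' Greedy best-overlap-first layout construction: overlap edges are
#' applied from longest (then highest-identity, then lexicographically
#' smallest read pair) downward, merging read layouts with consistent
#' affine placements; the consensus is a per-column (quality-weighted)
#' majority vote.  Reads aligning to their layout consensus below
#' `mi - outlier_margin` percent are excluded as outliers and the
#' consensus recomputed.  Contigs shorter than `min_contig_bp` are
#' dropped from the output but their reads still count as assembled;
#' unmerged reads are emitted as singletons.
#'
#' @param reads [seq_records()] of the bin's reads.
#' @param cfg [assembly_config()].
#' @param bin_id label used to derive sub-assembly ids.
#' @return list with `subassemblies` (data.frame id, seq, kind
#'   contig/singleton, bin, and `members` list-column of read ids) and
#'   `stats` (data.frame n_assembled, n_singleton, n_excluded,
#'   n_contigs).
#' @export
assemble_bin <- function(reads, cfg = assembly_config(), bin_id = "bin") {
  n_total <- nrow(reads)
  stats0 <- function(na, ns, ne, nc) {
    data.frame(bin = bin_id, n_assembled = na, n_singleton = ns,
               n_excluded = ne, n_contigs = nc, stringsAsFactors = FALSE)
  }
  if (n_total == 0L) {
    return(list(subassemblies = data.frame(
      id = character(0), seq = character(0), kind = character(0),
      bin = character(0), stringsAsFactors = FALSE),
      stats = stats0(0L, 0L, 0L, 0L)))
  }
  ultra <- nchar(reads$seq) < cfg$min_read_bp
  kept <- reads[!ultra, , drop = FALSE]
  n_excluded <- sum(ultra)
  over <- rep(FALSE, nrow(kept))
  if (nrow(kept) >= 4L) {
    depth <- .median_kmer_depth(kept$seq, cfg$seed_k)
    bin_med <- stats::median(depth)
    if (bin_med >= 1) over <- depth > cfg$depth_factor * bin_med
  }
  n_excluded <- n_excluded + sum(over)
  kept <- kept[!over, , drop = FALSE]
  rownames(kept) <- NULL

  # candidate overlaps slightly below mi are admitted: the merge gate in
  # .merge_layouts compares layout consensi (error-corrected) at mi, so
  # a read whose raw overlap dips below mi through sequencing error can
  # still join a layout it truly belongs to
  cand_cfg <- cfg
  cand_cfg$mi <- max(0, cfg$mi - cfg$candidate_slack)
  edges <- find_overlaps(kept, cand_cfg)
  cache <- .seq_cache(kept)
  # deterministic edge order: longest overlap, then identity, then ids
  if (nrow(edges)) {
    ord <- order(-edges$ov_len, -edges$pct_identity,
                 kept$id[edges$a], kept$id[edges$b])
    edges <- edges[ord, , drop = FALSE]
  }
  nk <- nrow(kept)
  comps <- .merge_layouts(kept, edges, cfg, cache)
  comps <- .absorb_singletons(kept, comps, cfg, cache)

  subs <- list(); n_assembled <- 0L; n_singleton <- 0L; n_contigs <- 0L
  ctg_i <- 0L
  singles <- integer(0)
  for (cmp in comps) {
    if (nrow(cmp$layout) == 1L) { singles <- c(singles, cmp$layout$read); next }
    lay <- cmp$layout
    # orient the layout so its lexicographically first read is forward
    first <- lay$read[order(kept$id[lay$read])][[1L]]
    if (lay$ori[lay$read == first] < 0) {
      ends <- lay$pos + nchar(kept$seq)[lay$read]
      m <- max(ends)
      lay$pos <- m - ends
      lay$ori <- -lay$ori
    }
    lay$pos <- as.integer(lay$pos - min(lay$pos))
    cons <- .consensus_from_layout(kept, lay, cache)
    ident <- vapply(seq_len(nrow(lay)), function(r) {
      .read_vs_consensus(cache, lay$read[[r]], lay$ori[[r]],
                         lay$pos[[r]], cons)
    }, numeric(1))
    bad <- ident < cfg$mi - cfg$outlier_margin - 1e-9
    if (any(bad)) {
      n_excluded <- n_excluded + sum(bad)
      lay <- lay[!bad, , drop = FALSE]
      if (nrow(lay) == 0L) next
      if (nrow(lay) == 1L) { singles <- c(singles, lay$read); next }
      lay$pos <- as.integer(lay$pos - min(lay$pos))
      cons <- .consensus_from_layout(kept, lay, cache)
    }
    n_assembled <- n_assembled + nrow(lay)
    if (length(cons) >= cfg$min_contig_bp) {
      ctg_i <- ctg_i + 1L
      n_contigs <- n_contigs + 1L
      subs[[length(subs) + 1L]] <- data.frame(
        id = sprintf("%s_ctg%03d", bin_id, ctg_i),
        seq = paste(cons, collapse = ""),
        kind = "contig", bin = bin_id, stringsAsFactors = FALSE,
        members = I(list(sort(kept$id[lay$read]))))
    }
  }
  for (i in singles) {
    n_singleton <- n_singleton + 1L
    subs[[length(subs) + 1L]] <- data.frame(
      id = sprintf("%s_sgl_%s", bin_id, kept$id[[i]]),
      seq = kept$seq[[i]], kind = "singleton", bin = bin_id,
      stringsAsFactors = FALSE, members = I(list(kept$id[[i]])))
  }
  subassemblies <- if (length(subs)) do.call(rbind, subs) else data.frame(
    id = character(0), seq = character(0), kind = character(0),
    bin = character(0), stringsAsFactors = FALSE)
  rownames(subassemblies) <- NULL
  list(subassemblies = subassemblies,
       stats = stats0(n_assembled, n_singleton, n_excluded, n_contigs))
}

#' Sweep the minimum overlap identity parameter
#'
#' Re-assembles every bin at each `mi` value and tabulates the assembly
#' statistics, the comparison that exposes the collapse/overestimate
#' trade-off of the overlap identity threshold.
#'
#' @param bins named list of [seq_records()] (one per bin).
#' @param mi_values percent identity values to sweep.
#' @param cfg base [assembly_config()]; its `mi` is overridden.
#' @return data.frame with one row per (mi, bin) plus per-mi totals in
#'   attribute `totals` (mi, n_assembled, n_singleton, n_excluded,
#'   frac_assembled).
#' @export
assembly_sweep <- function(bins, mi_values = c(97, 99, 100),
                           cfg = assembly_config()) {
  rows <- list()
  for (mi in mi_values) {
    cfg$mi <- mi
    for (bn in names(bins)) {
      st <- assemble_bin(bins[[bn]], cfg, bin_id = bn)$stats
      st$mi <- mi
      rows[[length(rows) + 1L]] <- st
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(bin = character(0), n_assembled = integer(0),
               n_singleton = integer(0), n_excluded = integer(0),
               n_contigs = integer(0), mi = numeric(0))
  if (nrow(out)) {
    agg <- stats::aggregate(
      out[, c("n_assembled", "n_singleton", "n_excluded")],
      by = list(mi = out$mi), FUN = sum)
    tot <- agg$n_assembled + agg$n_singleton + agg$n_excluded
    agg$frac_assembled <- ifelse(tot > 0, agg$n_assembled / tot, 0)
    attr(out, "totals") <- agg
  }
  out
}
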