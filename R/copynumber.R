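#' Spliced re-alignment of a sub-assembly to its template protein
#'
#' Translates the sub-assembly in all six frames (segments broken at
#' stop codons), collects high-scoring segment pairs (HSPs) against the
#' template by iterated local alignment (masking previously aligned
#' query stretches), filters them with the same length/identity rules
#' used for read binning, and chains the co-linear subset of maximal
#' summed score.  Unaligned gaps between chained HSPs accommodate
#' introns and UTRs; chained HSPs may overlap by at most
#' `chain_overlap_aa` on the template.
#'
#' @param subassembly nucleotide sequence of the sub-assembly.
#' @param protein template protein sequence.
#' @param cfg [binning_config()] supplying the per-HSP filters.
#' @param subject_species species key for the identity threshold.
#' @param max_hsps iterated-alignment cap per translated segment.
#' @param min_hsp_score stop iterating below this raw score.
#' @param chain_overlap_aa tolerated template overlap between chained
#'   HSPs (aa).
#' @return hit data.frame of the chained HSPs (possibly 0 rows);
#'   query coordinates in nt on the sub-assembly's forward strand,
#'   subject coordinates in aa on the template.
#' @export
spliced_realign <- function(subassembly, protein, cfg = binning_config(),
                            subject_species = "default", max_hsps = 8L,
                            min_hsp_score = 25, chain_overlap_aa = 5L) {
  segs <- .six_frame_segments(subassembly,
                              min_aa = max(8L, cfg$min_aln_len_aa %/% 2L))
  if (!nrow(segs)) return(empty_hits())
  prot_enc <- .encode_seqs(protein, "aa")
  S <- .aa_matrix()
  x_code <- match("X", .aa_alphabet()) - 1L
  acc <- list(pct = numeric(0), len = integer(0), mm = integer(0),
              go = integer(0), qs = integer(0), qe = integer(0),
              ss = integer(0), se = integer(0), fr = integer(0),
              sc = numeric(0))
  for (si in seq_len(nrow(segs))) {
    enc <- .encode_seqs(segs$aa_seq[[si]], "aa")[[1L]]
    for (it in seq_len(max_hsps)) {
      aln <- .cpp_align_pairs(list(enc), prot_enc, 1L, 1L, S, 8, 0L)
      if (aln$score[[1L]] < min_hsp_score || aln$aln_len[[1L]] == 0L) break
      qa <- segs$aa_off[[si]] + aln$q_start[[1L]]
      qb <- segs$aa_off[[si]] + aln$q_end[[1L]]
      qnt <- .aa_to_nt(segs$frame[[si]], nchar(subassembly), qa, qb)
      acc$pct <- c(acc$pct, 100 * aln$matches[[1L]] / aln$aln_len[[1L]])
      acc$len <- c(acc$len, aln$aln_len[[1L]])
      acc$mm <- c(acc$mm, aln$mismatches[[1L]])
      acc$go <- c(acc$go, aln$gap_opens[[1L]])
      acc$qs <- c(acc$qs, as.integer(qnt[[1L]]))
      acc$qe <- c(acc$qe, as.integer(qnt[[2L]]))
      acc$ss <- c(acc$ss, aln$s_start[[1L]])
      acc$se <- c(acc$se, aln$s_end[[1L]])
      acc$fr <- c(acc$fr, segs$frame[[si]])
      acc$sc <- c(acc$sc, aln$score[[1L]])
      enc[(aln$q_start[[1L]] + 1L):aln$q_end[[1L]]] <- x_code
    }
  }
  if (!length(acc$sc)) return(empty_hits())
  hits <- data.frame(
    query_id = "subassembly", subject_id = "template",
    pct_identity = acc$pct, aln_len = acc$len, mismatches = acc$mm,
    gap_opens = acc$go, q_start = acc$qs, q_end = acc$qe,
    s_start = acc$ss, s_end = acc$se, frame = acc$fr, score = acc$sc,
    stringsAsFactors = FALSE)
  hits <- filter_hits(hits, cfg, subject_species)
  if (!nrow(hits)) return(hits)
  chain_hsps(hits, chain_overlap_aa = chain_overlap_aa)
}

#' Maximal-score co-linear HSP chain
#'
#' Dynamic programme over HSPs sorted by template start: a chain must be
#' strand-consistent, increasing on the template (overlaps up to
#' `chain_overlap_aa` tolerated) and co-linear on the query.  The chain
#' with maximal summed HSP score is returned.
#'
#' @param hits HSP hit data.frame for one (sub-assembly, template) pair.
#' @param chain_overlap_aa tolerated template overlap (aa).
#' @param query_overlap_nt tolerated query overlap (nt).
#' @return subset of `hits` forming the best chain, in template order.
#' @export
chain_hsps <- function(hits, chain_overlap_aa = 5L,
                       query_overlap_nt = 15L) {
  if (nrow(hits) <= 1L) return(hits)
  best_chain <- NULL
  best_score <- -Inf
  for (strand in c(1, -1)) {
    sub <- hits[sign(hits$frame) == strand, , drop = FALSE]
    if (!nrow(sub)) next
    sub <- sub[order(sub$s_start, sub$s_end), , drop = FALSE]
    n <- nrow(sub)
    dp <- sub$score
    prev <- rep(0L, n)
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1L)) {
        ok_t <- sub$s_end[[j]] <= sub$s_start[[i]] + chain_overlap_aa
        ok_q <- if (strand > 0) {
          sub$q_end[[j]] <= sub$q_start[[i]] + query_overlap_nt
        } else {
          sub$q_start[[j]] >= sub$q_end[[i]] - query_overlap_nt
        }
        if (ok_t && ok_q && dp[[j]] + sub$score[[i]] > dp[[i]]) {
          dp[[i]] <- dp[[j]] + sub$score[[i]]
          prev[[i]] <- j
        }
      }
    }
    end <- which.max(dp)
    if (dp[[end]] > best_score) {
      best_score <- dp[[end]]
      idx <- integer(0)
      while (end != 0L) { idx <- c(end, idx); end <- prev[[end]] }
      best_chain <- sub[idx, , drop = FALSE]
    }
  }
  rownames(best_chain) <- NULL
  best_chain
}

#' Position-specific hit-count profile
#'
#' Counts, for each amino-acid position of the template, the number of
#' distinct sub-assemblies whose chained alignment covers it.  A
#' sub-assembly contributes at most 1 per position regardless of how
#' many HSPs it has there.
#'
#' @param chains named list (by sub-assembly id) of chained hit
#'   data.frames from [spliced_realign()].
#' @param template_len template protein length (aa).
#' @param ogr_id template identifier.
#' @return list of class `hit_count_profile`: `ogr_id`, `counts`
#'   (integer vector of length `template_len`), `contributing`
#'   (character vector of sub-assembly ids with >= 1 chained HSP).
#' @export
build_profile <- function(chains, template_len, ogr_id = "ogr") {
  counts <- integer(template_len)
  contributing <- character(0)
  for (sid in names(chains)) {
    ch <- chains[[sid]]
    if (is.null(ch) || !nrow(ch)) next
    if (any(ch$s_end > template_len)) {
      stop("chain coordinate beyond template for sub-assembly ", sid)
    }
    covered <- rep(FALSE, template_len)
    for (r in seq_len(nrow(ch))) {
      covered[(ch$s_start[[r]] + 1L):ch$s_end[[r]]] <- TRUE
    }
    counts[covered] <- counts[covered] + 1L
    contributing <- c(contributing, sid)
  }
  structure(list(ogr_id = ogr_id, counts = counts,
                 contributing = contributing),
            class = "hit_count_profile")
}

#' Cumulative coverage distribution of a hit-count profile
#'
#' Over template positions tagged by at least one sub-assembly, the
#' fraction covered by `h` or more sub-assemblies, for `h` from 1 to the
#' profile maximum.  The distribution starts at 1 and is non-increasing.
#'
#' @param profile [build_profile()] result.
#' @return named numeric vector (names = hit count h); empty for an
#'   uncovered profile.
#' @export
cumulative_distribution <- function(profile) {
  covered <- profile$counts[profile$counts > 0L]
  if (!length(covered)) return(stats::setNames(numeric(0), character(0)))
  hmax <- max(covered)
  vapply(stats::setNames(seq_len(hmax), seq_len(hmax)),
         function(h) mean(covered >= h), numeric(1))
}

#' Estimate gene copy number from a hit-count profile
#'
#' The copy number is the largest hit count `h` such that at least a
#' fraction `C` of the covered template positions carry `h` or more
#' distinct sub-assemblies; 0 for an uncovered profile.
#'
#' @param profile [build_profile()] result.
#' @param C minimum covered-template fraction, in (0, 1].
#' @return list of class `copy_number_call`: `ogr_id`, `copy_number`,
#'   `C`, `covered_positions`, `max_hit_count`.
#' @export
estimate_copy_number <- function(profile, C = 0.9) {
  if (C <= 0 || C > 1) stop("C must be in (0, 1]")
  cdist <- cumulative_distribution(profile)
  covered <- sum(profile$counts > 0L)
  cn <- if (!length(cdist)) 0L else max(which(cdist >= C - 1e-12))
  structure(list(ogr_id = profile$ogr_id, copy_number = as.integer(cn),
                 C = C, covered_positions = covered,
                 max_hit_count = if (length(cdist)) length(cdist) else 0L),
            class = "copy_number_call")
}

#' Copy-number estimation across assembled bins
#'
#' Re-aligns every sub-assembly of every bin to its OGR template,
#' builds the hit-count profiles and calls copy numbers.
#'
#' @param subassemblies data.frame as returned by [assemble_bin()]
#'   (rows from several bins may be concatenated); column `bin` names
#'   the OGR.
#' @param ogrs [seq_records()] of OGR proteins.
#' @param C covered-template fraction for [estimate_copy_number()].
#' @param cfg [binning_config()] HSP filters.
#' @param subject_species species key for identity thresholds.
#' @return data.frame (ogr_id, copy_number, covered_fraction,
#'   max_hit_count, n_subassemblies); attribute `profiles` holds the
#'   per-OGR [build_profile()] objects.
#' @export
estimate_copy_numbers <- function(subassemblies, ogrs, C = 0.9,
                                  cfg = binning_config(),
                                  subject_species = "default") {
  prot <- stats::setNames(ogrs$seq, ogrs$id)
  bins <- split(seq_len(nrow(subassemblies)), subassemblies$bin)
  rows <- list()
  profiles <- list()
  for (bn in names(bins)) {
    if (!bn %in% names(prot)) next
    tlen <- nchar(prot[[bn]])
    idx <- bins[[bn]]
    chains <- lapply(idx, function(i) {
      spliced_realign(subassemblies$seq[[i]], prot[[bn]], cfg,
                      subject_species)
    })
    names(chains) <- subassemblies$id[idx]
    prof <- build_profile(chains, tlen, ogr_id = bn)
    call <- estimate_copy_number(prof, C)
    profiles[[bn]] <- prof
    rows[[length(rows) + 1L]] <- data.frame(
      ogr_id = bn, copy_number = call$copy_number,
      covered_fraction = call$covered_positions / tlen,
      max_hit_count = call$max_hit_count,
      n_subassemblies = length(prof$contributing),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    ogr_id = character(0), copy_number = integer(0),
    covered_fraction = numeric(0), max_hit_count = integer(0),
    n_subassemblies = integer(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "profiles") <- profiles
  out
}
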