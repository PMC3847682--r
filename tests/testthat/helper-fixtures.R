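# Shared fixture builders.  These deliberately avoid the package's own
# mutation/translation helpers where they serve as oracles.

NT <- c("A", "C", "G", "T")

rand_nt <- function(n) paste(sample(NT, n, replace = TRUE), collapse = "")

# substitute the base at `pos` (1-based) deterministically (A->C->G->T->A)
sub_base <- function(seq, pos) {
  rot <- c(A = "C", C = "G", G = "T", T = "A")
  for (p in pos) substr(seq, p, p) <- rot[[substr(seq, p, p)]]
  seq
}

# evenly spaced substitutions: one every `every` bases, starting at
# `offset`; gives an exactly controlled divergence
even_mutate <- function(seq, every = 100L, offset = 50L) {
  sub_base(seq, seq(offset, nchar(seq), by = every))
}

rc <- function(seq) {
  vapply(chartr("ACGT", "TGCA", seq), function(s) {
    intToUtf8(rev(utf8ToInt(s)))
  }, character(1), USE.NAMES = FALSE)
}

# tiling reads over a template: fixed length/stride, forward strand
tile_reads <- function(template, len = 200L, stride = 40L,
                       prefix = "r") {
  starts <- seq(0L, nchar(template) - len, by = stride)
  seq_records(sprintf("%s%03d", prefix, seq_along(starts)),
              vapply(starts, function(s) substr(template, s + 1L, s + len),
                     character(1)))
}

random_protein <- function(len) {
  aas <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], "")
  paste(c("M", sample(aas, len - 1L, replace = TRUE)), collapse = "")
}

# simple deterministic back-translation (first codon of each amino acid
# in the standard code) -- intentionally different from the package's
# sampled back-translation
codon1 <- local({
  gc <- Biostrings::GENETIC_CODE
  vapply(split(names(gc), unname(gc)), `[[`, character(1), 1L)
})

back_translate1 <- function(protein) {
  paste(codon1[strsplit(protein, "")[[1L]]], collapse = "")
}

bind_seqs <- function(...) {
  out <- rbind(...)
  class(out) <- c("pg_seqs", "data.frame")
  rownames(out) <- NULL
  out
}

# Exhaustive merge-order oracle for the greedy assembler: explores every
# order of applying overlap edges, accepting a merge only when the two
# layout consensi agree at >= mi over their implied overlap (the same
# acceptance contract, re-implemented independently), and returns the
# set of reachable multi-read layout counts.
exhaustive_layout_counts <- function(reads, cfg) {
  cand_cfg <- cfg
  cand_cfg$mi <- max(0, cfg$mi - cfg$candidate_slack)
  edges <- find_overlaps(reads, cand_cfg)
  n <- nrow(reads)
  lens <- nchar(reads$seq)
  enc <- lapply(reads$seq, function(s) match(strsplit(s, "")[[1L]], NT))
  enc_rc <- lapply(reads$seq, function(s) match(strsplit(rc(s), "")[[1L]],
                                                NT))
  comp_map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  cons_of <- function(lay) {
    width <- max(lay$pos + lens[lay$read])
    counts <- matrix(0L, 4L, width)
    for (r in seq_len(nrow(lay))) {
      v <- if (lay$ori[[r]] > 0) enc[[lay$read[[r]]]] else
        enc_rc[[lay$read[[r]]]]
      idx <- cbind(v, lay$pos[[r]] + seq_along(v))
      counts[idx] <- counts[idx] + 1L
    }
    cov <- colSums(counts) > 0
    out <- NT[apply(counts, 2L, which.max)]
    out[!cov] <- "N"
    out
  }
  new_comp <- function(lay) {
    lay$pos <- as.integer(lay$pos - min(lay$pos))
    list(lay = lay, cons = cons_of(lay))
  }
  # state: list of comps (lay normalised to start 0, cached consensus)
  init <- lapply(seq_len(n), function(i) {
    new_comp(data.frame(read = i, pos = 0L, ori = 1L))
  })
  try_merge <- function(comps, e) {
    la <- which(vapply(comps, function(cc) e$a %in% cc$lay$read,
                       logical(1)))
    lb <- which(vapply(comps, function(cc) e$b %in% cc$lay$read,
                       logical(1)))
    if (la == lb) return(NULL)
    A <- comps[[la]]$lay; B <- comps[[lb]]$lay
    ra <- A[A$read == e$a, ]; rb <- B[B$read == e$b, ]
    sa <- ra$ori; ta <- if (sa > 0) ra$pos else ra$pos + lens[[e$a]] - 1L
    sb <- rb$ori; tb <- if (sb > 0) rb$pos else rb$pos + lens[[e$b]] - 1L
    if (e$orient > 0) { se <- 1L; te <- e$offset }
    else { se <- -1L; te <- e$offset + lens[[e$b]] - 1L }
    sA <- sa * se; tA <- sa * te + ta
    sF <- sA * sb; tF <- tA - sA * sb * tb
    Bn <- B
    t_r <- ifelse(B$ori > 0, B$pos, B$pos + lens[B$read] - 1L)
    s_n <- sF * B$ori
    t_n <- sF * t_r + tF
    Bn$ori <- s_n
    Bn$pos <- ifelse(s_n > 0, t_n, t_n - (lens[B$read] - 1L))
    # cached consensi: A starts at 0; B's placed at min(Bn$pos),
    # reverse-complemented when the transform flips it
    b0 <- min(Bn$pos)
    cb <- comps[[lb]]$cons
    if (sF < 0) cb <- rev(unname(comp_map[cb]))
    ca <- comps[[la]]$cons
    lo <- max(0L, b0)
    hi <- min(length(ca), b0 + length(cb))
    if (hi > lo) {
      xa <- ca[(lo + 1L):hi]
      xb <- cb[(lo - b0 + 1L):(hi - b0)]
      use <- xa != "N" & xb != "N"
      if (any(use) &&
          100 * sum(xa[use] == xb[use]) / sum(use) < cfg$mi - 1e-9) {
        return(NULL)
      }
    }
    comps[[la]] <- new_comp(rbind(A, Bn))
    comps[lb] <- NULL
    comps
  }
  sig <- function(comps) {
    paste(sort(vapply(comps, function(cc)
      paste(sort(cc$lay$read), collapse = "."), character(1))),
      collapse = "|")
  }
  seen <- new.env(parent = emptyenv())
  counts <- integer(0)
  recurse <- function(comps) {
    key <- sig(comps)
    if (!is.null(seen[[key]])) return(invisible())
    seen[[key]] <- TRUE
    advanced <- FALSE
    for (r in seq_len(nrow(edges))) {
      nxt <- try_merge(comps, edges[r, ])
      if (!is.null(nxt)) { advanced <- TRUE; recurse(nxt) }
    }
    if (!advanced) {
      counts <<- c(counts,
                   sum(vapply(comps, function(cc) nrow(cc$lay),
                              integer(1)) >= 2L))
    }
  }
  if (nrow(edges)) recurse(init) else counts <- 0L
  unique(counts)
}
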