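#' Simulation configuration
#'
#' Defaults reproduce the calibration conditions used throughout the
#' package: 5-fold genome coverage of 454-like shotgun reads with a
#' uniform 0.5% per-base substitution error, triplication of the gene
#' catalogue with SNV rates of 0.01 per coding base and 0.04 per
#' non-coding base.  Read lengths are Normal(400, 100) truncated at
#' 50 bp and the template length.
#'
#' @param coverage fold genome coverage of simulated reads.
#' @param error_rate per-base substitution probability in reads.
#' @param read_len_mean,read_len_sd read length distribution (bp).
#' @param ploidy_factor number of homeologous copies per input gene.
#' @param snv_coding,snv_noncoding per-base substitution probabilities
#'   applied to coding / non-coding positions when building the
#'   polyploid catalogue.
#' @param seed integer seed for all randomness.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(coverage = 5, error_rate = 0.005,
                       read_len_mean = 400, read_len_sd = 100,
                       ploidy_factor = 3L, snv_coding = 0.01,
                       snv_noncoding = 0.04, seed = 1L) {
  if (coverage <= 0) stop("coverage must be positive")
  if (error_rate < 0 || error_rate > 1) stop("error_rate must be in [0,1]")
  if (ploidy_factor < 1) stop("ploidy_factor must be >= 1")
  structure(list(coverage = coverage, error_rate = error_rate,
                 read_len_mean = read_len_mean, read_len_sd = read_len_sd,
                 ploidy_factor = as.integer(ploidy_factor),
                 snv_coding = snv_coding, snv_noncoding = snv_noncoding,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

.NT <- c("A", "C", "G", "T")

.random_nt <- function(n) {
  if (n <= 0) return("")
  paste(sample(.NT, n, replace = TRUE), collapse = "")
}

.codon_table <- function() {
  if (is.null(.pg_cache$codons_by_aa)) {
    gc <- Biostrings::GENETIC_CODE
    .pg_cache$codons_by_aa <- split(names(gc), unname(gc))
  }
  .pg_cache$codons_by_aa
}

.random_protein <- function(len) {
  aas <- setdiff(names(.codon_table()), "*")
  paste(c("M", sample(aas, len - 1L, replace = TRUE)), collapse = "")
}

.back_translate <- function(protein) {
  tab <- .codon_table()
  aa <- strsplit(protein, "", fixed = TRUE)[[1L]]
  paste(vapply(aa, function(a) {
    cs <- tab[[a]]
    if (length(cs) == 1L) cs else sample(cs, 1L)
  }, character(1)), collapse = "")
}

.translate_cds <- function(cds) .translate_str(cds)

# Substitute each position independently with probability p, uniformly
# over the three alternative nucleotides.
.mutate_seq <- function(seq, p) {
  if (p <= 0 || !nzchar(seq)) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(ch)) < p)
  for (i in hit) {
    ch[i] <- sample(setdiff(.NT, ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

# Coding-aware mutation that never introduces an in-frame stop codon,
# used for paralog/family copies that must stay translatable genes.
.mutate_cds_keep_orf <- function(cds, p) {
  if (p <= 0) return(cds)
  ch <- strsplit(cds, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(ch)) < p)
  for (i in hit) {
    alts <- sample(setdiff(.NT, ch[i]))
    codon_start <- ((i - 1L) %/% 3L) * 3L + 1L
    for (a in alts) {
      cand <- ch
      cand[i] <- a
      codon <- paste(cand[codon_start:(codon_start + 2L)], collapse = "")
      if (!codon %in% c("TAA", "TAG", "TGA")) { ch[i] <- a; break }
    }
  }
  paste(ch, collapse = "")
}

# Mutate a full gene/transcript sequence given its coding intervals
# (0-based half-open, relative to the sequence): coding positions at
# p_coding (ORF-preserving when keep_orf), the rest at p_noncoding.
.mutate_gene_seq <- function(seq, coding, p_coding, p_noncoding,
                             keep_orf = FALSE) {
  n <- nchar(seq)
  parts <- character(0)
  pos <- 0L
  coding <- coding[order(coding[, 1L]), , drop = FALSE]
  for (r in seq_len(nrow(coding))) {
    cs <- coding[r, 1L]; ce <- coding[r, 2L]
    if (cs > pos) {
      parts <- c(parts, .mutate_seq(substr(seq, pos + 1L, cs), p_noncoding))
    }
    cod <- substr(seq, cs + 1L, ce)
    parts <- c(parts, if (keep_orf) .mutate_cds_keep_orf(cod, p_coding)
               else .mutate_seq(cod, p_coding))
    pos <- ce
  }
  if (pos < n) {
    parts <- c(parts, .mutate_seq(substr(seq, pos + 1L, n), p_noncoding))
  }
  paste(parts, collapse = "")
}

# Build one gene: UTRs, CDS split by introns.  Returns the unspliced
# transcript sequence, its coding intervals (relative, 0-based
# half-open) and the protein.
.build_gene <- function(prot_len_range, intron_len_range, n_intron_range,
                        utr5_range, utr3_range) {
  plen <- sample(prot_len_range[1L]:prot_len_range[2L], 1L)
  protein <- .random_protein(plen)
  cds <- .back_translate(protein)
  n_intron <- sample(n_intron_range[1L]:n_intron_range[2L], 1L)
  n_codon <- nchar(cds) / 3L
  brk <- if (n_intron > 0 && n_codon > n_intron + 1L) {
    sort(sample(seq_len(n_codon - 1L), min(n_intron, n_codon - 1L))) * 3L
  } else integer(0)
  utr5 <- .random_nt(sample(utr5_range[1L]:utr5_range[2L], 1L))
  utr3 <- .random_nt(sample(utr3_range[1L]:utr3_range[2L], 1L))
  pieces <- character(0)
  coding <- matrix(numeric(0), ncol = 2L)
  pos <- nchar(utr5)
  pieces <- utr5
  cds_bounds <- c(0L, brk, nchar(cds))
  for (i in seq_len(length(cds_bounds) - 1L)) {
    exon <- substr(cds, cds_bounds[i] + 1L, cds_bounds[i + 1L])
    pieces <- c(pieces, exon)
    coding <- rbind(coding, c(pos, pos + nchar(exon)))
    pos <- pos + nchar(exon)
    if (i < length(cds_bounds) - 1L) {
      ilen <- sample(intron_len_range[1L]:intron_len_range[2L], 1L)
      intron <- paste0("GT", .random_nt(ilen - 4L), "AG")
      pieces <- c(pieces, intron)
      pos <- pos + nchar(intron)
    }
  }
  pieces <- c(pieces, utr3)
  list(seq = paste(pieces, collapse = ""), coding = coding,
       protein = protein)
}

#' Generate a synthetic gene space
#'
#' Builds a chromosome carrying `n_genes` genes (grouped into families of
#' the given sizes) separated by intergenic spacers, a fraction of which
#' is filled with exact copies of elements from an emitted repeat
#' library.  Genes have 5'/3' UTRs and introns; each gene's protein is
#' the translation of its spliced CDS.  Family copies beyond the first
#' are derived from the first by ORF-preserving substitution at
#' `copy_divergence_coding` per coding base (and `copy_divergence_noncoding`
#' elsewhere).
#'
#' @param n_genes total number of genes (>= 1).
#' @param family_sizes integer vector of gene-family sizes summing to
#'   `n_genes`; default is all single-copy.
#' @param prot_len_range protein length range (aa).
#' @param intron_len_range,n_intron_range intron length (bp) and count
#'   ranges per gene.
#' @param utr5_range,utr3_range UTR length ranges (bp).
#' @param intergenic_len_range intergenic spacer length range (bp).
#' @param repeat_fraction fraction of intergenic space filled with
#'   repeat-library copies.
#' @param n_repeat_elements,repeat_len_range repeat library shape.
#' @param copy_divergence_coding,copy_divergence_noncoding per-base
#'   divergence between family copies.
#' @param seed integer seed.
#' @return list of class `gene_space` with elements `chromosome`
#'   ([seq_records()], one row), `genes` (data.frame with gene_id,
#'   family_id, copy, tx_start, tx_end, protein, seq and a `coding`
#'   list-column of relative coding intervals) and `repeats`
#'   ([seq_records()]).
#' @export
generate_gene_space <- function(n_genes, family_sizes = NULL,
                                prot_len_range = c(120L, 300L),
                                intron_len_range = c(80L, 300L),
                                n_intron_range = c(0L, 3L),
                                utr5_range = c(50L, 150L),
                                utr3_range = c(100L, 250L),
                                intergenic_len_range = c(400L, 1200L),
                                repeat_fraction = 0,
                                n_repeat_elements = 5L,
                                repeat_len_range = c(300L, 2000L),
                                copy_divergence_coding = 0.03,
                                copy_divergence_noncoding = 0.06,
                                seed = 1L) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (is.null(family_sizes)) family_sizes <- rep(1L, n_genes)
  if (sum(family_sizes) != n_genes) {
    stop("family_sizes must sum to n_genes")
  }
  if (repeat_fraction < 0 || repeat_fraction > 0.95) {
    stop("repeat_fraction must be in [0, 0.95]")
  }
  if (prot_len_range[1L] < 30L) stop("proteins shorter than 30 aa are infeasible")
  .with_seed(seed, {
    repeats <- if (repeat_fraction > 0) {
      seq_records(paste0("repelem", seq_len(n_repeat_elements)),
                  vapply(seq_len(n_repeat_elements), function(i) {
                    .random_nt(sample(repeat_len_range[1L]:repeat_len_range[2L], 1L))
                  }, character(1)))
    } else {
      seq_records(character(0), character(0))
    }

    spacer <- function() {
      len <- sample(intergenic_len_range[1L]:intergenic_len_range[2L], 1L)
      if (repeat_fraction <= 0 || nrow(repeats) == 0L) {
        return(.random_nt(len))
      }
      rep_target <- round(repeat_fraction * len)
      parts <- character(0)
      plain <- len - rep_target
      while (rep_target > 0) {
        chunk_plain <- min(plain, sample(50:200, 1L))
        parts <- c(parts, .random_nt(chunk_plain))
        plain <- plain - chunk_plain
        el <- repeats$seq[[sample(nrow(repeats), 1L)]]
        if (stats::runif(1) < 0.5) el <- revcomp(el)
        take <- min(nchar(el), rep_target)
        if (take >= 30L) parts <- c(parts, substr(el, 1L, take))
        rep_target <- rep_target - take
      }
      parts <- c(parts, .random_nt(plain))
      paste(parts, collapse = "")
    }

    genes <- list()
    chrom_parts <- character(0)
    pos <- 0L
    gi <- 0L
    for (fam in seq_along(family_sizes)) {
      base <- .build_gene(prot_len_range, intron_len_range, n_intron_range,
                          utr5_range, utr3_range)
      for (cp in seq_len(family_sizes[[fam]])) {
        gi <- gi + 1L
        if (cp == 1L) {
          g <- base
        } else {
          mut <- .mutate_gene_seq(base$seq, base$coding,
                                  copy_divergence_coding,
                                  copy_divergence_noncoding,
                                  keep_orf = TRUE)
          cds <- paste(vapply(seq_len(nrow(base$coding)), function(r) {
            substr(mut, base$coding[r, 1L] + 1L, base$coding[r, 2L])
          }, character(1)), collapse = "")
          g <- list(seq = mut, coding = base$coding,
                    protein = .translate_cds(cds))
        }
        sp <- spacer()
        chrom_parts <- c(chrom_parts, sp)
        pos <- pos + nchar(sp)
        chrom_parts <- c(chrom_parts, g$seq)
        genes[[gi]] <- list(
          gene_id = sprintf("gene%04d_c%d", fam, cp),
          family_id = sprintf("fam%04d", fam),
          copy = cp, tx_start = pos, tx_end = pos + nchar(g$seq),
          protein = g$protein, seq = g$seq, coding = g$coding)
        pos <- pos + nchar(g$seq)
      }
    }
    chrom_parts <- c(chrom_parts, spacer())
    chromosome <- seq_records("chr1", paste(chrom_parts, collapse = ""))

    gdf <- data.frame(
      gene_id = vapply(genes, `[[`, character(1), "gene_id"),
      family_id = vapply(genes, `[[`, character(1), "family_id"),
      copy = vapply(genes, `[[`, integer(1), "copy"),
      tx_start = vapply(genes, `[[`, integer(1), "tx_start"),
      tx_end = vapply(genes, `[[`, integer(1), "tx_end"),
      protein = vapply(genes, `[[`, character(1), "protein"),
      seq = vapply(genes, `[[`, character(1), "seq"),
      stringsAsFactors = FALSE)
    gdf$coding <- lapply(genes, `[[`, "coding")
    structure(list(chromosome = chromosome, genes = gdf, repeats = repeats),
              class = "gene_space")
  })
}

#' Extract unspliced transcripts from a gene space
#'
#' @param gs a [generate_gene_space()] result.
#' @return list with `records` ([seq_records()], one per gene, full
#'   unspliced transcript) and `coding` (named list of relative coding
#'   interval matrices, 0-based half-open).
#' @export
gene_transcripts <- function(gs) {
  list(records = seq_records(gs$genes$gene_id, gs$genes$seq),
       coding = stats::setNames(gs$genes$coding, gs$genes$gene_id))
}

#' Simulate 454-like shotgun reads
#'
#' Samples reads from the templates proportional to template length,
#' from both strands uniformly, with lengths Normal(mean, sd) truncated
#' at 50 bp and the template length, until the total read bases reach
#' `coverage` times the total template bases (within 2%).  Each base is
#' substituted independently with probability `error_rate`.  Read ids
#' encode provenance (`template|start|strand`), which downstream modules
#' never inspect; it exists for truth tracking in tests.
#'
#' @param templates [seq_records()] templates.
#' @param cfg [sim_config()].
#' @return [seq_records()] with qualities.
#' @export
simulate_reads <- function(templates, cfg = sim_config()) {
  if (nrow(templates) == 0L) stop("templates must be non-empty")
  if (cfg$coverage <= 0) stop("coverage must be positive")
  .with_seed(cfg$seed, {
    widths <- nchar(templates$seq)
    target <- cfg$coverage * sum(widths)
    qchar <- if (cfg$error_rate > 0) {
      intToUtf8(33L + min(40L, round(-10 * log10(cfg$error_rate))))
    } else "I"
    ids <- character(0); seqs <- character(0); quals <- character(0)
    total <- 0; i <- 0L
    n_guess <- max(16L, ceiling(1.2 * target / cfg$read_len_mean))
    while (total < target) {
      tpl <- sample.int(nrow(templates), n_guess, replace = TRUE,
                        prob = widths)
      len <- round(stats::rnorm(n_guess, cfg$read_len_mean,
                                cfg$read_len_sd))
      len <- pmax(50L, pmin(len, widths[tpl]))
      start <- vapply(seq_len(n_guess), function(k) {
        sample.int(widths[tpl[k]] - len[k] + 1L, 1L) - 1L
      }, integer(1))
      strand <- sample(c("+", "-"), n_guess, replace = TRUE)
      for (k in seq_len(n_guess)) {
        if (total >= target) break
        i <- i + 1L
        s <- substr(templates$seq[tpl[k]], start[k] + 1L,
                    start[k] + len[k])
        if (strand[k] == "-") s <- revcomp(s)
        if (cfg$error_rate > 0) s <- .mutate_seq(s, cfg$error_rate)
        ids <- c(ids, sprintf("read%07d|%s|%d|%s", i,
                              templates$id[tpl[k]], start[k], strand[k]))
        seqs <- c(seqs, s)
        quals <- c(quals, strrep(qchar, len[k]))
        total <- total + len[k]
      }
    }
    # drop the final read if that lands total bases closer to target
    if (length(seqs) > 1L) {
      last <- nchar(seqs[length(seqs)])
      if (abs(total - last - target) < abs(total - target)) {
        keep <- seq_len(length(seqs) - 1L)
        ids <- ids[keep]; seqs <- seqs[keep]; quals <- quals[keep]
      }
    }
    seq_records(ids, seqs, quals)
  })
}

#' Build an in-silico polyploid gene catalogue
#'
#' Each input transcript is emitted `ploidy_factor` times; in every copy
#' each coding base is substituted with probability `snv_coding` and each
#' non-coding base with probability `snv_noncoding`, uniformly over the
#' three alternative nucleotides.
#'
#' @param transcripts [seq_records()] of (unspliced) transcripts.
#' @param coding named list (by transcript id) of 0-based half-open
#'   coding interval matrices relative to each transcript.
#' @param cfg [sim_config()].
#' @return list with `catalogue` ([seq_records()], ids
#'   `<gene>_h<copy>`), `source` (named character: catalogue id ->
#'   source transcript id) and `truth` (data.frame ogr_id,
#'   true_copies = ploidy_factor per input).
#' @export
make_polyploid_catalogue <- function(transcripts, coding,
                                     cfg = sim_config()) {
  missing_ann <- setdiff(transcripts$id, names(coding))
  if (length(missing_ann)) {
    stop("transcript without coding annotation: ", missing_ann[[1L]])
  }
  .with_seed(cfg$seed + 101L, {
    ids <- character(0); seqs <- character(0); src <- character(0)
    for (i in seq_len(nrow(transcripts))) {
      tid <- transcripts$id[[i]]
      for (j in seq_len(cfg$ploidy_factor)) {
        mut <- .mutate_gene_seq(transcripts$seq[[i]], coding[[tid]],
                                cfg$snv_coding, cfg$snv_noncoding)
        ids <- c(ids, sprintf("%s_h%d", tid, j))
        seqs <- c(seqs, mut)
        src <- c(src, tid)
      }
    }
    truth <- data.frame(ogr_id = transcripts$id,
                        true_copies = cfg$ploidy_factor,
                        stringsAsFactors = FALSE)
    list(catalogue = seq_records(ids, seqs),
         source = stats::setNames(src, ids), truth = truth)
  })
}

#' Collapse redundant sequences
#'
#' Greedy longest-first clustering: each sequence joins the first
#' existing representative to which its global alignment identity is at
#' least `level`; otherwise it founds a new representative.  Only
#' representatives are returned.
#'
#' @param records [seq_records()] of nucleotide sequences.
#' @param level identity level in (0, 1], e.g. 0.97, 0.99, 1.00.
#' @return [seq_records()] subset of representatives, with an attribute
#'   `members` (named list: representative id -> member ids).
#' @export
collapse_redundancy <- function(records, level) {
  if (level <= 0 || level > 1) stop("level must be in (0, 1]")
  if (nrow(records) == 0L) return(records)
  ord <- order(-nchar(records$seq), records$id)
  reps <- integer(0)
  members <- list()
  for (i in ord) {
    placed <- FALSE
    for (r in reps) {
      # length prefilter: identity is at most len ratio under global alignment
      if (nchar(records$seq[[i]]) < level * nchar(records$seq[[r]]) - 2) next
      aln <- align_pairs(records$seq[[i]], records$seq[[r]], 1L, 1L,
                         type = "nt", mode = "global", gap = 2)
      if (aln$matches / aln$aln_len >= level - 1e-9) {
        members[[records$id[[r]]]] <- c(members[[records$id[[r]]]],
                                        records$id[[i]])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      members[[records$id[[i]]]] <- records$id[[i]]
    }
  }
  out <- records[sort(reps), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "members") <- members
  out
}

#' Effective copy-number truth after redundancy collapsing
#'
#' Counts, per source transcript, the catalogue copies that remain
#' distinguishable at a given identity level: copies are collapsed with
#' [collapse_redundancy()] before counting, so that copies an assembler
#' could never separate at its overlap-identity threshold are not
#' counted as distinct truth.
#'
#' @param catalogue result of [make_polyploid_catalogue()].
#' @param level identity level in (0, 1]; `NULL` skips collapsing.
#' @return data.frame (ogr_id, true_copies).
#' @export
truth_table <- function(catalogue, level = NULL) {
  src <- catalogue$source
  ids <- unique(unname(src))
  counts <- vapply(ids, function(tid) {
    copies <- names(src)[src == tid]
    if (is.null(level)) return(length(copies))
    recs <- catalogue$catalogue[catalogue$catalogue$id %in% copies, ,
                                drop = FALSE]
    nrow(collapse_redundancy(recs, level))
  }, integer(1))
  data.frame(ogr_id = ids, true_copies = unname(counts),
             stringsAsFactors = FALSE)
}
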