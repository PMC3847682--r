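test_that("repeat masking enforces the 100 bp repeat-free rule", {
  set.seed(41)
  rep_el <- rand_nt(400L)
  lib <- seq_records("rep1", rep_el)

  fully <- seq_records("r1", substr(rep_el, 50L, 349L))
  expect_equal(nrow(mask_repeats(fully, lib)), 0L)

  # 300 bp read: clean 120 | repeat 50 | clean 130
  mixed <- seq_records("r2", paste0(rand_nt(120L),
                                    substr(rep_el, 100L, 149L),
                                    rand_nt(130L)))
  out <- mask_repeats(mixed, lib)
  expect_equal(nrow(out), 1L)
  expect_gte(nchar(out$seq), 100L)

  # longest clean run 99 bp -> removed
  short <- seq_records("r3", paste0(rand_nt(99L),
                                    substr(rep_el, 1L, 51L)))
  expect_equal(nrow(mask_repeats(short, lib)), 0L)

  # idempotence on survivors
  again <- mask_repeats(out, lib)
  expect_equal(again$seq, out$seq)

  empty_lib <- seq_records(character(0), character(0))
  expect_warning(thru <- mask_repeats(mixed, empty_lib), "pass-through")
  expect_equal(thru$seq, mixed$seq)

  expect_error(mask_repeats(mixed, lib, k = 8L), "k must be")
})

test_that("translated alignment recovers peptides in all frames", {
  set.seed(42)
  pep <- random_protein(50L)
  read <- back_translate1(pep)
  prot <- paste0(random_protein(20L), pep, random_protein(20L))

  hits <- translated_align(read, prot)
  best <- hits[which.max(hits$score), ]
  expect_equal(best$pct_identity, 100)
  expect_equal(best$aln_len, 50L)
  expect_equal(best$frame, 1L)
  expect_equal(c(best$q_start, best$q_end), c(0L, 150L))
  expect_equal(c(best$s_start, best$s_end), c(20L, 70L))

  hits_rc <- translated_align(rc(read), prot)
  best_rc <- hits_rc[which.max(hits_rc$score), ]
  expect_equal(best_rc$pct_identity, 100)
  expect_lt(best_rc$frame, 0L)
  expect_equal(c(best_rc$s_start, best_rc$s_end), c(20L, 70L))

  # 5 substituted residues in 50 -> 90% identity
  pep_mut <- strsplit(pep, "")[[1L]]
  swap <- c(A = "V", C = "W", D = "K", E = "R", F = "G", G = "F",
            H = "E", I = "Q", K = "D", L = "N", M = "Y", N = "L",
            P = "T", Q = "I", R = "E", S = "H", T = "P", V = "A",
            W = "C", Y = "M")
  pos <- c(10L, 20L, 30L, 40L, 45L)
  pep_mut[pos] <- swap[pep_mut[pos]]
  prot_mut <- paste(pep_mut, collapse = "")
  h2 <- translated_align(read, prot_mut)
  b2 <- h2[which.max(h2$score), ]
  expect_equal(b2$aln_len, 50L)
  expect_equal(b2$pct_identity, 90)

  expect_error(translated_align("AC", prot), "codon")
})

test_that("hit filters are inclusive minima with per-species thresholds", {
  mk <- function(len, id, subject = "s1") {
    h <- empty_hits()
    h[1L, ] <- list("q", subject, id, len, 0L, 0L, 0L, len * 3L, 0L,
                    len, 1L, 100)
    h
  }
  cfg <- binning_config(min_aln_len_aa = 30L,
                        identity_threshold = c(default = 70, rice = 75))
  expect_equal(nrow(filter_hits(mk(29L, 100), cfg)), 0L)
  expect_equal(nrow(filter_hits(mk(30L, 70), cfg)), 1L)
  expect_equal(nrow(filter_hits(mk(45L, 69.9), cfg)), 0L)
  expect_equal(nrow(filter_hits(mk(45L, 74), cfg,
                                c(s1 = "rice"))), 0L)
  expect_equal(nrow(filter_hits(mk(45L, 75), cfg,
                                c(s1 = "rice"))), 1L)
  cfg2 <- binning_config(identity_threshold = c(rice = 75))
  expect_error(filter_hits(mk(45L, 80), cfg2, c(s1 = "maize")),
               "unknown species")
})

test_that("first-best-hit assignment is exclusive and deterministic", {
  h <- empty_hits()
  h[1L, ] <- list("r1", "OGR1", 90, 40L, 4L, 0L, 0L, 120L, 0L, 40L, 1L, 80)
  h[2L, ] <- list("r1", "OGR2", 95, 40L, 2L, 0L, 0L, 120L, 0L, 40L, 1L, 75)
  h[3L, ] <- list("r2", "OGRb", 90, 40L, 4L, 0L, 0L, 120L, 0L, 40L, 1L, 60)
  h[4L, ] <- list("r2", "OGRa", 90, 40L, 4L, 0L, 0L, 120L, 0L, 40L, 1L, 60)
  bins <- assign_fbh(h)
  asn <- setNames(bins$assignments$ogr_id, bins$assignments$read_id)
  expect_equal(unname(asn["r1"]), "OGR1") # higher score wins
  expect_equal(unname(asn["r2"]), "OGRa") # full tie -> lexicographic
  expect_equal(sum(lengths(bins$bins)), 2L)

  none <- assign_fbh(empty_hits())
  expect_equal(nrow(none$assignments), 0L)
})

test_that("error-free reads from single-copy genes bin to their gene", {
  gs <- generate_gene_space(8, seed = 43)
  tx <- gene_transcripts(gs)
  reads <- simulate_reads(tx$records,
                          sim_config(coverage = 3, error_rate = 0,
                                     seed = 44))
  ogrs <- seq_records(gs$genes$gene_id, gs$genes$protein)
  bins <- bin_reads(reads, ogrs, binning_config(repeat_filter = FALSE))
  asn <- bins$assignments
  # bins partition the assigned reads
  expect_equal(sum(lengths(bins$bins)), nrow(asn))
  expect_equal(anyDuplicated(asn$read_id), 0L)
  # truth from provenance ids: coding-region reads >= 90 bp must hit home
  src <- vapply(strsplit(asn$read_id, "|", fixed = TRUE), `[[`,
                character(1), 2L)
  expect_gte(mean(asn$ogr_id == src), 0.99)
  # reads wholly inside a gene's coding span and long enough are binned
  hit30 <- function(g) {
    iv <- g$coding[[1L]]
    starts <- as.integer(vapply(strsplit(reads$id, "|", fixed = TRUE),
                                `[[`, character(1), 3L))
    origin <- vapply(strsplit(reads$id, "|", fixed = TRUE), `[[`,
                     character(1), 2L)
    inside <- origin == g$gene_id &
      starts >= iv[1L, 1L] & starts + nchar(reads$seq) <= iv[1L, 2L] &
      nchar(reads$seq) >= 90L
    if (!any(inside)) return(NA_real_)
    mean(reads$id[inside] %in% asn$read_id)
  }
  fr <- stats::na.omit(vapply(seq_len(nrow(gs$genes)), function(i) {
    hit30(gs$genes[i, ])
  }, numeric(1)))
  expect_gte(mean(fr), 0.99)
})
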