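test_that("gene space generation is deterministic and translatable", {
  gs1 <- generate_gene_space(3, seed = 42)
  gs2 <- generate_gene_space(3, seed = 42)
  expect_identical(gs1, gs2)

  gs <- generate_gene_space(1, repeat_fraction = 0, seed = 7)
  expect_equal(nrow(gs$genes), 1L)
  expect_equal(nrow(gs$repeats), 0L)
  g <- gs$genes[1L, ]
  cds <- paste(apply(g$coding[[1L]], 1L, function(iv) {
    substr(g$seq, iv[[1L]] + 1L, iv[[2L]])
  }), collapse = "")
  expect_equal(nchar(cds) %% 3L, 0L)
  # independent oracle: Biostrings translation of the spliced CDS
  expect_equal(as.character(Biostrings::translate(Biostrings::DNAString(cds))),
               g$protein)
  # the transcript is embedded at the recorded chromosome coordinates
  expect_equal(substr(gs$chromosome$seq, g$tx_start + 1L, g$tx_end),
               g$seq)
})

test_that("repeat fraction of a repeat-rich chromosome matches the dial", {
  gs <- generate_gene_space(50, repeat_fraction = 0.5,
                            intergenic_len_range = c(8000L, 12000L),
                            seed = 13)
  # independent masking oracle: exact 20-mer membership scan
  k <- 20L
  lib <- unique(unlist(lapply(c(gs$repeats$seq, rc(gs$repeats$seq)),
                              function(s) {
    substring(s, 1:(nchar(s) - k + 1L), k:nchar(s))
  })))
  chrom <- gs$chromosome$seq
  n <- nchar(chrom)
  kmers <- substring(chrom, 1:(n - k + 1L), k:n)
  hit <- which(kmers %in% lib)
  masked <- logical(n)
  for (h in hit) masked[h:(h + k - 1L)] <- TRUE
  frac <- mean(masked)
  expect_gt(frac, 0.4)
  expect_lt(frac, 0.6)
})

test_that("simulated reads respect coverage, length and strand contracts", {
  set.seed(3)
  tpl <- seq_records("t1", rand_nt(10000L))
  cfg <- sim_config(coverage = 5, error_rate = 0, seed = 21)
  reads <- simulate_reads(tpl, cfg)
  ratio <- sum(nchar(reads$seq)) / (5 * 10000)
  expect_gt(ratio, 0.98)
  expect_lt(ratio, 1.02)
  expect_equal(nrow(reads), 125L, tolerance = 0.25)
  # error-free reads are exact substrings on one strand
  ok <- vapply(reads$seq, function(s) {
    grepl(s, tpl$seq, fixed = TRUE) || grepl(rc(s), tpl$seq, fixed = TRUE)
  }, logical(1))
  expect_true(all(ok))
  expect_true(all(nchar(reads$seq) >= 50L))
})

test_that("read error rate is uniform at the configured level", {
  set.seed(4)
  tpl <- seq_records("t1", rand_nt(100000L))
  cfg <- sim_config(coverage = 10, error_rate = 0.005, seed = 22)
  reads <- simulate_reads(tpl, cfg)
  # provenance ids are test-only truth: compare each read to its origin
  meta <- strsplit(reads$id, "|", fixed = TRUE)
  mism <- 0L; tot <- 0L
  for (i in seq_len(nrow(reads))) {
    start <- as.integer(meta[[i]][[3L]])
    strand <- meta[[i]][[4L]]
    s <- reads$seq[[i]]
    if (strand == "-") s <- rc(s)
    orig <- substr(tpl$seq, start + 1L, start + nchar(s))
    a <- strsplit(s, "")[[1L]]
    b <- strsplit(orig, "")[[1L]]
    mism <- mism + sum(a != b)
    tot <- tot + length(a)
  }
  rate <- mism / tot
  sd3 <- 3 * sqrt(0.005 * 0.995 / tot)
  expect_gt(rate, 0.005 - max(sd3, 5e-4))
  expect_lt(rate, 0.005 + max(sd3, 5e-4))
})

test_that("polyploid catalogue replication and SNV dosage", {
  tx <- seq_records(c("t1", "t2"), c(rand_nt(300L), rand_nt(400L)))
  coding <- list(t1 = matrix(c(0L, 300L), 1L),
                 t2 = matrix(c(0L, 400L), 1L))
  cfg0 <- sim_config(ploidy_factor = 1L, snv_coding = 0,
                     snv_noncoding = 0, seed = 1)
  out <- make_polyploid_catalogue(tx, coding, cfg0)
  expect_equal(out$catalogue$seq, tx$seq)

  set.seed(6)
  tx10 <- seq_records(sprintf("t%02d", 1:10),
                      replicate(10, rand_nt(500L)))
  coding10 <- setNames(replicate(10, matrix(c(0L, 500L), 1L),
                                 simplify = FALSE), tx10$id)
  out3 <- make_polyploid_catalogue(tx10, coding10, sim_config(seed = 2))
  expect_equal(nrow(out3$catalogue), 30L)
  expect_true(all(out3$truth$true_copies == 3L))

  # binomial substitution dosage on a long coding sequence
  big <- seq_records("big", rand_nt(100002L))
  cfgc <- sim_config(ploidy_factor = 1L, snv_coding = 0.01,
                     snv_noncoding = 0.04, seed = 3)
  mut <- make_polyploid_catalogue(big, list(big = matrix(c(0L, 100002L), 1L)),
                                  cfgc)
  nsub <- sum(strsplit(mut$catalogue$seq, "")[[1L]] !=
                strsplit(big$seq, "")[[1L]])
  expect_gt(nsub, 1000 - 100)
  expect_lt(nsub, 1000 + 100)

  expect_error(make_polyploid_catalogue(tx, coding["t1"], cfg0),
               "coding annotation")
})

test_that("redundancy collapsing joins by global identity level", {
  s <- rand_nt(100L)
  two <- seq_records(c("a", "b"), c(s, s))
  expect_equal(nrow(collapse_redundancy(two, 1.0)), 1L)

  s2 <- sub_base(s, c(30L, 60L)) # 2 mismatches -> 98% identity
  pair <- seq_records(c("a", "b"), c(s, s2))
  expect_equal(nrow(collapse_redundancy(pair, 0.99)), 2L)
  expect_equal(nrow(collapse_redundancy(pair, 0.97)), 1L)

  none <- seq_records(character(0), character(0))
  expect_equal(nrow(collapse_redundancy(none, 0.99)), 0L)
})

test_that("catalogue copies diverge at the expected coding rate", {
  set.seed(8)
  tx <- seq_records("t1", rand_nt(30000L))
  coding <- list(t1 = matrix(c(0L, 30000L), 1L))
  out <- make_polyploid_catalogue(tx, coding, sim_config(seed = 9))
  a <- strsplit(out$catalogue$seq[[1L]], "")[[1L]]
  b <- strsplit(out$catalogue$seq[[2L]], "")[[1L]]
  div <- mean(a != b)
  # two independently mutated copies at p = 0.01 each
  expected <- 2 * 0.01 * (1 - 0.01) - 2 * 0.01 * 0.01 / 3
  sd3 <- 3 * sqrt(expected * (1 - expected) / 30000)
  expect_gt(div, expected - sd3)
  expect_lt(div, expected + sd3)
})
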