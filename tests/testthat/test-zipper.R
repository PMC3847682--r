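# ordered reference panel with nt queries derived from its genes
make_synteny_panel <- function(n = 40L, seed = 81L) {
  set.seed(seed)
  prots <- vapply(seq_len(n), function(i) random_protein(160L),
                  character(1))
  cds <- vapply(prots, back_translate1, character(1), USE.NAMES = FALSE)
  list(reference = seq_records(sprintf("rg%03d", seq_len(n)), prots),
       cds = cds)
}

test_that("synteny blocks follow the sliding-window density rule", {
  panel <- make_synteny_panel()
  # queries hit genes 10-13 (4 of a 5-gene window) and nothing else
  q <- seq_records(sprintf("q%d", 1:4),
                   vapply(panel$cds[10:13], even_mutate, character(1)))
  bl <- detect_synteny(q, panel$reference, window = 5L, min_density = 3L)
  expect_equal(nrow(bl), 1L)
  expect_lte(bl$start_idx, 10L)
  expect_gte(bl$end_idx, 13L)
  expect_equal(bl$n_genes_hit, 4L)

  # scattered hits (1 per 20 genes) never reach the density
  q2 <- seq_records(c("s1", "s2"),
                    vapply(panel$cds[c(1L, 21L)], even_mutate,
                           character(1)))
  bl2 <- detect_synteny(q2, panel$reference, window = 5L,
                        min_density = 3L)
  expect_equal(nrow(bl2), 0L)

  # identity below the threshold is ignored entirely
  noisy <- vapply(panel$cds[10:13], function(s) {
    sub_base(s, seq(2L, nchar(s), by = 4L)) # ~25% nt divergence
  }, character(1))
  bl3 <- detect_synteny(seq_records(sprintf("n%d", 1:4), noisy),
                        panel$reference, identity_min = 70,
                        window = 5L, min_density = 3L)
  expect_equal(nrow(bl3), 0L)

  expect_error(detect_synteny(q, panel$reference,
                              gene_order = c("rg001", "rg002")),
               "permutation")
})

test_that("marker anchoring requires reciprocal best hits", {
  panel <- make_synteny_panel()
  markers <- data.frame(
    marker_id = c("m1", "m2", "m3"),
    chromosome = "1H",
    cm_position = c(10, 20, 30),
    seq = c(substr(panel$cds[[5L]], 1L, 240L),
            substr(panel$cds[[7L]], 31L, 150L), # short partial hit to rg007
            rand_nt(200L)), # no hit at all
    stringsAsFactors = FALSE)
  # m9 outcompetes m2 on gene rg007
  markers <- rbind(markers, data.frame(
    marker_id = "m9", chromosome = "1H", cm_position = 40,
    seq = substr(panel$cds[[7L]], 1L, 300L), stringsAsFactors = FALSE))
  anchors <- anchor_markers(markers, panel$reference)
  expect_true(all(c("m1", "m9") %in% anchors$marker_id))
  expect_equal(anchors$gene_id[anchors$marker_id == "m1"], "rg005")
  expect_false("m2" %in% anchors$marker_id) # reciprocity fails
  expect_false("m3" %in% anchors$marker_id) # no hit
})

test_that("zipper construction projects genes between marker anchors", {
  ord <- sprintf("r%d", 1:12)
  mm <- data.frame(marker_id = c("m1", "m2"), chromosome = "1H",
                   cm_position = c(10, 20), seq = c("ACGT", "ACGT"),
                   stringsAsFactors = FALSE)
  anchors <- list(ref = data.frame(marker_id = c("m1", "m2"),
                                   gene_id = c("r5", "r9"),
                                   stringsAsFactors = FALSE))
  zip <- build_zipper(mm, anchors, list(ref = ord),
                      ngs_anchors = c(ngs1 = "r7"))
  expect_equal(zip$ref, c("r5", "r6", "r7", "r8", "r9"))
  expect_equal(zip$marker_id, c("m1", NA, NA, NA, "m2"))
  expect_equal(zip$anchored_ngs[zip$ref == "r7"], "ngs1")
  expect_false(any(zip$inverted))
  expect_equal(zip$position_index, 1:5)

  # inverted anchors keep marker order, reverse the gene run, set flag
  anchors_inv <- list(ref = data.frame(marker_id = c("m1", "m2"),
                                       gene_id = c("r9", "r5"),
                                       stringsAsFactors = FALSE))
  zinv <- build_zipper(mm, anchors_inv, list(ref = ord))
  expect_equal(zinv$marker_id[c(1L, 5L)], c("m1", "m2"))
  expect_equal(zinv$ref, c("r9", "r8", "r7", "r6", "r5"))
  expect_true(any(zinv$inverted))

  # lower-ranked reference only fills intervals the top rank cannot
  anchors2 <- list(top = data.frame(marker_id = "m1", gene_id = "t3",
                                    stringsAsFactors = FALSE),
                   alt = data.frame(marker_id = c("m1", "m2"),
                                    gene_id = c("a2", "a6"),
                                    stringsAsFactors = FALSE))
  z2 <- build_zipper(mm, anchors2,
                     list(top = sprintf("t%d", 1:8),
                          alt = sprintf("a%d", 1:8)),
                     rank = c("top", "alt"))
  expect_equal(z2$alt[!is.na(z2$alt)], c("a2", "a3", "a4", "a5", "a6"))
})

test_that("end-to-end zipper recovers a locally shuffled gene order", {
  set.seed(82)
  panel <- make_synteny_panel(n = 50L, seed = 83L)
  n <- 50L
  # reference order: true order with ~10% adjacent swaps
  ref_order <- seq_len(n)
  for (i in seq(4L, 46L, by = 10L)) {
    ref_order[c(i, i + 1L)] <- ref_order[c(i + 1L, i)]
  }
  reference <- seq_records(panel$reference$id[ref_order],
                           panel$reference$seq[ref_order])
  midx <- seq(1L, n, by = 3L)
  markers <- data.frame(
    marker_id = sprintf("m%02d", seq_along(midx)), chromosome = "1H",
    cm_position = as.numeric(midx),
    seq = substr(panel$cds[midx], 1L, 300L), stringsAsFactors = FALSE)
  ngs <- seq_records(sprintf("ngs%03d", seq_len(n)),
                     vapply(panel$cds, even_mutate, character(1)))
  zip <- genome_zipper(markers, list(ref = reference), ngs,
                       window = 5L, min_density = 3L)

  # marker order is preserved exactly as a sub-sequence of rows
  mrows <- zip[!is.na(zip$marker_id), ]
  expect_equal(mrows$marker_id, markers$marker_id)
  expect_true(all(diff(mrows$cm) >= 0))

  # every anchored NGS id occurs exactly once; genes once per column
  ngs_ids <- unlist(strsplit(zip$anchored_ngs[nzchar(zip$anchored_ngs)],
                             ",", fixed = TRUE))
  expect_equal(anyDuplicated(ngs_ids), 0L)
  placed <- zip$ref[!is.na(zip$ref)]
  expect_equal(anyDuplicated(placed), 0L)

  # >= 90% of pairwise order relations among placed genes are correct
  tp <- as.integer(sub("rg", "", placed))
  conc <- 0L; tot <- 0L
  for (i in seq_along(tp)) {
    for (j in seq_len(i - 1L)) {
      tot <- tot + 1L
      if (tp[[j]] < tp[[i]]) conc <- conc + 1L
    }
  }
  expect_gte(conc / tot, 0.9)
})
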