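test_that("similarity graph edges follow normalised score and cutoff", {
  set.seed(31)
  p <- random_protein(120L)
  twins <- seq_records(c("a", "b"), c(p, p))
  g <- all_vs_all_protein_similarity(twins, seed_k = 0L)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$weight, 1, tolerance = 1e-9)

  # empirical null: unrelated random proteins stay below the cutoff
  rand <- seq_records(c("x", "y"),
                      c(random_protein(100L), random_protein(100L)))
  g0 <- all_vs_all_protein_similarity(rand, seed_k = 0L)
  expect_equal(nrow(g0$edges), 0L)

  expect_error(all_vs_all_protein_similarity(twins[1L, , drop = FALSE]),
               "at least 2")
})

test_that("graph keeps only pairs above the cutoff", {
  set.seed(32)
  a <- random_protein(150L)
  b <- paste0(substr(a, 1L, 100L), random_protein(50L)) # shares 100 aa with a
  c <- paste0(random_protein(50L), substr(b, 101L, 150L),
              random_protein(50L)) # shares 50 aa with b only
  recs <- seq_records(c("A", "B", "C"), c(a, b, c))
  g <- all_vs_all_protein_similarity(recs, cutoff = 0.3, seed_k = 0L)
  pairs <- paste(g$edges$from, g$edges$to)
  expect_true("A B" %in% pairs)
  expect_true("B C" %in% pairs)
  expect_false("A C" %in% pairs)
})

test_that("Markov clustering splits components and weak bridges", {
  tri2 <- list(nodes = letters[1:6],
               edges = data.frame(
                 from = c("a", "b", "c", "d", "e", "f"),
                 to = c("b", "c", "a", "e", "f", "d"),
                 weight = rep(1, 6), stringsAsFactors = FALSE))
  cl <- markov_cluster(tri2)
  expect_length(cl, 2L)
  expect_setequal(cl[[1L]]$members, c("a", "b", "c"))
  expect_setequal(cl[[2L]]$members, c("d", "e", "f"))

  single <- list(nodes = "a",
                 edges = data.frame(from = character(0),
                                    to = character(0),
                                    weight = numeric(0)))
  expect_length(markov_cluster(single), 1L)

  # barbell: two 4-cliques joined by one weak edge
  cl4 <- function(v) t(combn(v, 2L))
  e1 <- cl4(c("a", "b", "c", "d")); e2 <- cl4(c("e", "f", "g", "h"))
  edges <- data.frame(from = c(e1[, 1L], e2[, 1L], "d"),
                      to = c(e1[, 2L], e2[, 2L], "e"),
                      weight = c(rep(1, 12), 0.1),
                      stringsAsFactors = FALSE)
  barbell <- list(nodes = letters[1:8], edges = edges)
  clb <- markov_cluster(barbell, inflation = 1.5)
  expect_length(clb, 2L)
  expect_setequal(clb[[1L]]$members, c("a", "b", "c", "d"))
  expect_setequal(clb[[2L]]$members, c("e", "f", "g", "h"))
})

test_that("clustering is a partition refining connected components", {
  set.seed(33)
  for (trial in 1:5) {
    n <- 12L
    nodes <- sprintf("n%02d", 1:n)
    m <- matrix(stats::runif(n * n) < 0.2, n, n)
    m[lower.tri(m, diag = TRUE)] <- FALSE
    idx <- which(m, arr.ind = TRUE)
    edges <- data.frame(from = nodes[idx[, 1L]], to = nodes[idx[, 2L]],
                        weight = stats::runif(nrow(idx), 0.3, 1),
                        stringsAsFactors = FALSE)
    g <- list(nodes = nodes, edges = edges)
    cl <- markov_cluster(g)
    members <- unlist(lapply(cl, `[[`, "members"))
    expect_setequal(members, nodes) # partition: union = node set
    expect_equal(anyDuplicated(members), 0L) # disjoint
    # component oracle via igraph
    ig <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                        vertices = nodes)
    comp <- igraph::components(ig)$membership
    for (grp in cl) {
      expect_length(unique(comp[grp$members]), 1L)
    }
  }
})

test_that("clustering recovers simulated gene families", {
  gs <- generate_gene_space(9, family_sizes = c(3L, 3L, 3L),
                            copy_divergence_coding = 0.08, seed = 34)
  recs <- seq_records(gs$genes$gene_id, gs$genes$protein)
  cl <- markov_cluster(all_vs_all_protein_similarity(recs))
  expect_length(cl, 3L)
  fams <- vapply(cl, function(g) {
    length(unique(gs$genes$family_id[match(g$members,
                                           gs$genes$gene_id)]))
  }, integer(1))
  expect_true(all(fams == 1L))
})

test_that("OGR selection follows contigs, then length, then id", {
  groups <- list(structure(list(group_id = "OG1",
                                members = c("g1", "g2"),
                                representative = NA_character_),
                           class = "ortho_group"),
                 structure(list(group_id = "OG2",
                                members = c("h1", "h2"),
                                representative = NA_character_),
                           class = "ortho_group"),
                 structure(list(group_id = "OG3",
                                members = c("k1", "k2"),
                                representative = NA_character_),
                           class = "ortho_group"))
  assoc <- list(g1 = c("c1", "c2", "c3"), g2 = c("c4", "c5", "c6", "c7",
                                                 "c8"),
                h1 = c("c1", "c2", "c3", "c4"),
                h2 = c("c5", "c6", "c7", "c8"))
  lens <- c(g1 = 200L, g2 = 180L, h1 = 200L, h2 = 350L, k1 = 100L,
            k2 = 120L)
  out <- select_ogr(groups, assoc, lens)
  expect_equal(out[[1L]]$representative, "g2") # most contigs
  expect_equal(out[[2L]]$representative, "h2") # tie -> longest protein
  expect_true(is.na(out[[3L]]$representative)) # no associations
  expect_equal(attr(out, "n_excluded"), 1L)
})
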