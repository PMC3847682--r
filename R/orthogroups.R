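#' All-vs-all protein similarity graph
#'
#' Seeded local alignment (amino-acid k-mer seeds, BLOSUM62 extension)
#' between every pair of proteins.  Edge weights are raw local scores
#' normalised by the self-alignment score of the shorter sequence, so a
#' weight of 1 means one protein is (at least) contained in the other at
#' full score.  Pairs below `cutoff` get no edge; the graph is
#' undirected with the weight being the maximum over both directions.
#'
#' @param proteins [seq_records()] of >= 2 proteins.
#' @param cutoff minimum normalised score for an edge.
#' @param seed_k amino-acid seed length; set to 0 to force all pairs.
#' @return list of class `similarity_graph`: `nodes` (ids), `edges`
#'   (data.frame from, to, weight).
#' @export
all_vs_all_protein_similarity <- function(proteins, cutoff = 0.3,
                                          seed_k = 4L) {
  if (nrow(proteins) < 2L) stop("need at least 2 proteins")
  n <- nrow(proteins)
  self <- align_pairs(proteins$seq, proteins$seq, seq_len(n), seq_len(n),
                      type = "aa", mode = "local")$score
  if (seed_k > 0L) {
    cand <- .kmer_candidates(proteins$seq, proteins$seq, k = seed_k,
                             min_share = 2L, top_n = n)
    cand <- cand[cand$qid < cand$sid]
    qi <- cand$qid; si <- cand$sid
  } else {
    pr <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
    qi <- pr[, 1L]; si <- pr[, 2L]
  }
  if (!length(qi)) {
    return(structure(list(nodes = proteins$id,
                          edges = data.frame(from = character(0),
                                             to = character(0),
                                             weight = numeric(0))),
                     class = "similarity_graph"))
  }
  aln <- align_pairs(proteins$seq, proteins$seq, qi, si,
                     type = "aa", mode = "local")
  wnorm <- aln$score / pmin(self[qi], self[si])
  keep <- wnorm >= cutoff
  edges <- data.frame(from = proteins$id[qi[keep]],
                      to = proteins$id[si[keep]],
                      weight = wnorm[keep], stringsAsFactors = FALSE)
  structure(list(nodes = proteins$id, edges = edges),
            class = "similarity_graph")
}

#' Markov clustering of a similarity graph
#'
#' Classic MCL iteration: expansion (matrix squaring) alternating with
#' inflation (elementwise power and column re-normalisation) on the
#' column-stochastic transition matrix (self-loops of weight 1 added),
#' until the matrix change falls below `eps`.  Clusters are read off the
#' converged matrix by attractor rows.
#'
#' @param graph [all_vs_all_protein_similarity()] result (or any list
#'   with `nodes` and `edges`).
#' @param inflation inflation exponent (> 1).
#' @param max_iter iteration cap; non-convergence returns the current
#'   hard clustering with a warning.
#' @param eps convergence threshold on the max absolute change.
#' @return list of `ortho_group` lists: `group_id`, `members`
#'   (gene ids), `representative` (NA until [select_ogr()]).
#' @export
markov_cluster <- function(graph, inflation = 1.5, max_iter = 100L,
                           eps = 1e-8) {
  nodes <- graph$nodes
  n <- length(nodes)
  if (n == 0L) stop("empty graph")
  M <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(graph$edges)) {
    fi <- match(graph$edges$from, nodes)
    ti <- match(graph$edges$to, nodes)
    M[cbind(fi, ti)] <- graph$edges$weight
    M[cbind(ti, fi)] <- graph$edges$weight
  }
  diag(M) <- 1
  normalise <- function(m) sweep(m, 2L, colSums(m), "/")
  M <- normalise(M)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M
    M2 <- normalise(M2^inflation)
    M2[M2 < 1e-12] <- 0
    M2 <- normalise(M2)
    if (max(abs(M2 - M)) < eps) { M <- M2; converged <- TRUE; break }
    M <- M2
  }
  if (!converged) {
    warning("Markov clustering did not converge after ", max_iter,
            " iterations; returning current hard clustering")
  }
  # hard clustering: each node joins the attractor with maximal mass in
  # its column; attractors sharing nodes merge (overlap resolution)
  attractor <- apply(M, 2L, which.max)
  groups <- split(nodes, attractor)
  ord <- order(vapply(groups, function(g) min(match(g, nodes)),
                      integer(1)))
  groups <- groups[ord]
  lapply(seq_along(groups), function(i) {
    structure(list(group_id = sprintf("OG%04d", i),
                   members = sort(groups[[i]]),
                   representative = NA_character_),
              class = "ortho_group")
  })
}

#' Select orthologous-group representatives
#'
#' The representative of a group is the member gene concentrating the
#' most distinct associated contigs; ties are broken by the longest
#' protein, then lexicographically smallest gene id.  Groups whose
#' members have no contig associations at all are flagged
#' representative-less (excluded from downstream binning).
#'
#' @param groups list of `ortho_group` (from [markov_cluster()]).
#' @param contig_associations named list: gene id -> character vector of
#'   associated contig ids.
#' @param protein_lengths named integer vector of protein lengths (aa)
#'   covering every member.
#' @return list of `ortho_group` with `representative` set (or `NA` for
#'   excluded groups); attribute `n_excluded` counts the latter.
#' @export
select_ogr <- function(groups, contig_associations, protein_lengths) {
  n_excluded <- 0L
  out <- lapply(groups, function(g) {
    missing_len <- setdiff(g$members, names(protein_lengths))
    if (length(missing_len)) {
      stop("protein length unknown for: ", missing_len[[1L]])
    }
    n_contigs <- vapply(g$members, function(m) {
      length(unique(contig_associations[[m]]))
    }, integer(1))
    if (all(n_contigs == 0L)) {
      n_excluded <<- n_excluded + 1L
      g$representative <- NA_character_
      return(g)
    }
    ord <- order(-n_contigs, -protein_lengths[g$members], g$members)
    g$representative <- g$members[[ord[[1L]]]]
    g
  })
  attr(out, "n_excluded") <- n_excluded
  out
}
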