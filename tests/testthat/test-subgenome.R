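# three synthetic progenitor pools derived from common ancestors at a
# controlled divergence, plus derived "sub-assemblies" of known origin
make_panel <- function(n_per_class = 24L, n_ref = 30L, div = 0.02,
                       seed = 71L) {
  set.seed(seed)
  anc <- replicate(n_ref, back_translate1(random_protein(220L)))
  mut <- function(seqs, p) {
    vapply(seqs, function(s) {
      npos <- stats::rbinom(1L, nchar(s), p)
      if (npos == 0L) return(s)
      sub_base(s, sample(nchar(s), npos))
    }, character(1), USE.NAMES = FALSE)
  }
  A <- seq_records(sprintf("A%02d", seq_len(n_ref)), mut(anc, div))
  B <- seq_records(sprintf("B%02d", seq_len(n_ref)), mut(anc, div))
  D <- seq_records(sprintf("D%02d", seq_len(n_ref)), mut(anc, div))
  subs <- bind_seqs(
    seq_records(sprintf("sa%02d", seq_len(n_per_class)),
                mut(A$seq[seq_len(n_per_class)], 0.005)),
    seq_records(sprintf("sb%02d", seq_len(n_per_class)),
                mut(B$seq[seq_len(n_per_class)], 0.005)),
    seq_records(sprintf("sd%02d", seq_len(n_per_class)),
                mut(D$seq[seq_len(n_per_class)], 0.005)))
  list(progenitors = list(A = A, B = B, D = D), subs = subs,
       truth = rep(c("A", "B", "D"), each = n_per_class),
       ancestors = anc)
}

# the default panel, its training set and fitted model are reused
# across blocks (deterministic: fixed seeds throughout)
.fixture <- new.env()
get_panel <- function() {
  if (is.null(.fixture$panel)) .fixture$panel <- make_panel()
  .fixture$panel
}
get_train <- function() {
  if (is.null(.fixture$train)) {
    p <- get_panel()
    .fixture$train <- build_training_set(p$subs, p$progenitors,
                                         p$progenitors)
  }
  .fixture$train
}
get_model <- function() {
  if (is.null(.fixture$model)) {
    .fixture$model <- train_and_validate(get_train(), k = 5L, seed = 3L)
  }
  .fixture$model
}
get_feats <- function() {
  if (is.null(.fixture$feats)) {
    p <- get_panel()
    .fixture$feats <- extract_features(p$subs, p$progenitors)
  }
  .fixture$feats
}

test_that("feature extraction requires hits to all three progenitors", {
  panel <- get_panel()
  expect_error(extract_features(panel$subs, panel$progenitors[1:2]),
               "exactly 3")

  feats <- get_feats()
  expect_equal(nrow(feats), nrow(panel$subs))
  expect_setequal(names(feats)[-1L],
                  c("identity_A", "score_A", "identity_B", "score_B",
                    "identity_D", "score_D"))
  # an A-derived sub-assembly is most similar to the A pool
  arows <- grepl("^sa", feats$subassembly_id)
  expect_true(all(feats$identity_A[arows] >= feats$identity_B[arows]))
  expect_true(all(feats$identity_A[arows] >= feats$identity_D[arows]))

  # a sequence unrelated to every pool is excluded
  set.seed(72)
  alien <- bind_seqs(panel$subs,
                     seq_records("alien", rand_nt(600L)))
  f2 <- extract_features(alien, panel$progenitors)
  expect_false("alien" %in% f2$subassembly_id)
  expect_gte(attr(f2, "n_excluded"), 1L)
})

test_that("training sets are labelled by best hit with ties dropped", {
  panel <- get_panel()
  train <- get_train()
  expect_equal(nlevels(train$label), 3L)
  expect_true(all(table(train$label) >= 20L))
  m <- match(train$subassembly_id, panel$subs$id)
  expect_gte(mean(as.character(train$label) == panel$truth[m]), 0.99)

  # a sequence at equal distance to two partitions is dropped
  tie_seq <- panel$ancestors[[1L]]
  with_tie <- bind_seqs(panel$subs[1:6, ],
                        seq_records("tie", tie_seq))
  part <- list(A = seq_records("refA", tie_seq),
               B = seq_records("refB", tie_seq),
               D = seq_records("refD", sub_base(tie_seq, 1:30)))
  tr2 <- build_training_set(with_tie, part, panel$progenitors)
  expect_false("tie" %in% tr2$subassembly_id)
  expect_gte(attr(tr2, "n_ambiguous"), 1L)

  expect_error(build_training_set(panel$subs[0L, ], panel$progenitors,
                                  panel$progenitors), "empty")
})

test_that("cross-validation separates classes and guards its inputs", {
  panel <- get_panel()
  train <- get_train()
  model <- get_model()
  expect_true(all(model$cv$per_class$precision == 1))
  expect_true(all(model$cv$per_class$recall == 1))

  expect_error(train_and_validate(train, k = 1L), "k must be")
  expect_error(train_and_validate(train, k = 50L), "smallest class")

  # permutation null: recall collapses to chance
  perm <- train
  set.seed(73)
  perm$label <- sample(perm$label)
  m0 <- train_and_validate(perm, k = 5L, seed = 3L)
  rec <- m0$cv$per_class$recall
  n_cl <- min(table(perm$label))
  ci <- 4 * sqrt((1 / 3) * (2 / 3) / n_cl)
  expect_true(all(abs(rec - 1 / 3) < ci))
})

test_that("classification partitions input and rejects ambiguity", {
  panel <- get_panel()
  model <- get_model()
  feats <- get_feats()
  res <- classify(model, feats)
  expect_equal(nrow(res), nrow(feats))
  expect_true(all(res$label %in% c("A", "B", "D", "unclassified")))
  m <- match(res$subassembly_id, panel$subs$id)
  conf <- res$label != "unclassified"
  expect_gte(mean(res$label[conf] == panel$truth[m][conf]), 0.95)
  # probabilities sum to 1
  expect_equal(rowSums(res[, c("p_A", "p_B", "p_D")]),
               rep(1, nrow(res)), tolerance = 1e-6)

  # equal-similarity feature rows fall below the threshold
  tie <- feats[1L, ]
  tie$subassembly_id <- "tie"
  tie[, c("identity_A", "identity_B", "identity_D")] <-
    mean(unlist(feats[, c("identity_A", "identity_B", "identity_D")]))
  tie[, c("score_A", "score_B", "score_D")] <-
    mean(unlist(feats[, c("score_A", "score_B", "score_D")]))
  res_tie <- classify(model, tie)
  expect_equal(res_tie$label, "unclassified")

  # as divergence to the pools vanishes, rejection takes over: the
  # shared ancestors are equidistant from all three progenitor pools
  anc_feats <- extract_features(
    seq_records(paste0("anc", 1:20), panel$ancestors[1:20]),
    panel$progenitors)
  res_anc <- classify(model, anc_feats)
  expect_gte(mean(res_anc$label == "unclassified"), 0.5)

  # monotone rejection in the threshold
  n_un <- vapply(c(0.4, 0.6, 0.8, 0.95), function(th) {
    sum(classify(model, feats, threshold = th)$label == "unclassified")
  }, integer(1))
  expect_true(all(diff(n_un) >= 0L))

  # classification summary covers all categories
  summ <- classification_summary(res)
  expect_equal(summ$count[[1L]], nrow(res))
  expect_equal(sum(summ$count[-1L]), nrow(res))
})
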