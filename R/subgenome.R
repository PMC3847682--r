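#' Similarity features against three progenitor sets
#'
#' For every sub-assembly, the best nucleotide local-alignment hit in
#' each progenitor set yields two features: percent identity and the
#' alignment score normalised by the sub-assembly's self-alignment
#' score.  Only sub-assemblies with a hit in EVERY progenitor set are
#' retained; the number excluded is reported in attribute `n_excluded`.
#'
#' @param subassemblies [seq_records()] of sub-assembly sequences.
#' @param progenitor_sets named list of exactly three [seq_records()]
#'   (e.g. `A`, `B`, `D`), one per sub-genome donor.
#' @param min_score minimum raw alignment score to count as a hit.
#' @param seed_k nucleotide seed length for candidate selection.
#' @param seed_top candidates per progenitor set to align.
#' @return data.frame: `subassembly_id` plus, per progenitor `P`,
#'   `identity_P` and `score_P`.
#' @export
extract_features <- function(subassemblies, progenitor_sets,
                             min_score = 30, seed_k = 12L,
                             seed_top = 3L) {
  if (length(progenitor_sets) != 3L || is.null(names(progenitor_sets))) {
    stop("progenitor_sets must be a named list of exactly 3 sequence sets")
  }
  n <- nrow(subassemblies)
  if (n == 0L) {
    out <- data.frame(subassembly_id = character(0))
    for (p in names(progenitor_sets)) {
      out[[paste0("identity_", p)]] <- numeric(0)
      out[[paste0("score_", p)]] <- numeric(0)
    }
    attr(out, "n_excluded") <- 0L
    return(out)
  }
  self_score <- nchar(subassemblies$seq) # +1 match scoring: self = length
  feat <- list(subassembly_id = subassemblies$id)
  has_hit <- matrix(FALSE, n, 3L)
  for (pi in seq_along(progenitor_sets)) {
    pname <- names(progenitor_sets)[[pi]]
    pset <- progenitor_sets[[pi]]
    ident <- rep(NA_real_, n)
    score <- rep(NA_real_, n)
    cand <- .kmer_candidates(subassemblies$seq, pset$seq, k = seed_k,
                             min_share = 2L, top_n = seed_top)
    if (nrow(cand)) {
      aln <- align_pairs(subassemblies$seq, pset$seq, cand$qid, cand$sid,
                         type = "nt", mode = "local")
      ok <- aln$score >= min_score
      if (any(ok)) {
        dt <- data.table::data.table(qid = cand$qid[ok],
                                     score = aln$score[ok],
                                     ident = aln$pct_identity[ok])
        data.table::setorderv(dt, c("qid", "score", "ident"),
                              c(1L, -1L, -1L))
        best <- dt[!duplicated(dt$qid)]
        ident[best$qid] <- best$ident
        score[best$qid] <- best$score / self_score[best$qid]
        has_hit[best$qid, pi] <- TRUE
      }
    }
    feat[[paste0("identity_", pname)]] <- ident
    feat[[paste0("score_", pname)]] <- score
  }
  out <- as.data.frame(feat, stringsAsFactors = FALSE)
  keep <- rowSums(has_hit) == 3L
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_excluded") <- sum(!keep)
  res
}

#' Build a labelled training set from a classified reference partition
#'
#' Mirrors training-set construction from chromosome-sorted reference
#' sequence: each sequence is labelled by the partition (A/B/D) holding
#' its best nucleotide hit, sequences tying between partitions are
#' dropped, and the label is joined with the sequence's similarity
#' features against the progenitor sets.
#'
#' @param seqs [seq_records()] sequences to label.
#' @param reference_partition named list of three [seq_records()]
#'   defining the labelled reference classes.
#' @param progenitor_sets passed to [extract_features()].
#' @param min_score minimum hit score.
#' @return labelled feature data.frame (columns of [extract_features()]
#'   plus `label`); attribute `n_ambiguous` counts dropped ties.
#' @export
build_training_set <- function(seqs, reference_partition,
                               progenitor_sets, min_score = 30) {
  if (nrow(seqs) == 0L) stop("empty labelled sequence set")
  ref_feat <- extract_features(seqs, reference_partition,
                               min_score = min_score)
  classes <- names(reference_partition)
  idcols <- paste0("identity_", classes)
  sims <- as.matrix(ref_feat[, idcols, drop = FALSE])
  best <- apply(sims, 1L, max)
  is_tie <- rowSums(sims == best) > 1L
  labels <- classes[apply(sims, 1L, which.max)]
  keep_ids <- ref_feat$subassembly_id[!is_tie]
  labels <- labels[!is_tie]
  feats <- extract_features(
    seqs[seqs$id %in% keep_ids, , drop = FALSE], progenitor_sets,
    min_score = min_score)
  m <- match(feats$subassembly_id, keep_ids)
  feats$label <- factor(labels[m], levels = classes)
  attr(feats, "n_ambiguous") <- sum(is_tie)
  feats
}

.feature_cols <- function(features) {
  grep("^(identity|score)_", names(features), value = TRUE)
}

.stratified_folds <- function(y, k, seed = 1L) {
  .with_seed(seed, {
    fold <- integer(length(y))
    for (cl in levels(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold
  })
}

.fit_classifier <- function(method, X, y) {
  switch(method,
    svm = e1071::svm(X, y, probability = TRUE, kernel = "radial"),
    nb = e1071::naiveBayes(X, y),
    logistic = {
      if (!requireNamespace("nnet", quietly = TRUE)) {
        stop("the logistic method needs the nnet package")
      }
      df <- data.frame(X, .y = y)
      nnet::multinom(.y ~ ., data = df, trace = FALSE)
    },
    tree = {
      if (!requireNamespace("rpart", quietly = TRUE)) {
        stop("the tree method needs the rpart package")
      }
      df <- data.frame(X, .y = y)
      rpart::rpart(.y ~ ., data = df, method = "class")
    },
    stop("unknown classifier method: ", method))
}

.predict_prob <- function(method, fit, X, classes) {
  p <- switch(method,
    svm = {
      pr <- stats::predict(fit, X, probability = TRUE)
      attr(pr, "probabilities")
    },
    nb = stats::predict(fit, X, type = "raw"),
    logistic = {
      pr <- stats::predict(fit, data.frame(X), type = "probs")
      if (is.null(dim(pr))) { # two-class edge case
        cbind(1 - pr, pr)
      } else pr
    },
    tree = stats::predict(fit, data.frame(X), type = "prob"))
  p <- as.matrix(p)
  p[, classes, drop = FALSE]
}

#' Train and cross-validate a sub-genome classifier
#'
#' Stratified k-fold cross-validation of a probability-calibrated
#' classifier on the similarity features, then a final refit on the
#' full data.  The default is a support vector machine; logistic
#' regression, naive Bayes and a decision tree are available for
#' comparison, scored by macro F1 (the precision/recall compromise).
#'
#' @param features labelled feature data.frame from
#'   [build_training_set()].
#' @param k number of folds; must not exceed the smallest class.
#' @param method one of `"svm"`, `"logistic"`, `"nb"`, `"tree"`.
#' @param probability_threshold minimum winning-class probability for a
#'   confident call in [classify()].
#' @param seed fold-shuffling seed.
#' @return list of class `subgenome_classifier`: the fitted `model`,
#'   `method`, `classes`, `feature_cols`, `probability_threshold` and
#'   `cv` (per-class precision/recall/F1 plus `macro_f1`).
#' @export
train_and_validate <- function(features, k = 10L, method = "svm",
                               probability_threshold = 0.6, seed = 1L) {
  if (is.null(features$label)) stop("features must carry a label column")
  y <- droplevels(factor(features$label))
  if (nlevels(y) < 2L) stop("need at least two classes")
  if (k < 2L) stop("k must be >= 2")
  if (k > min(table(y))) {
    stop("k exceeds the smallest class size (",
         min(table(y)), ")")
  }
  cols <- .feature_cols(features)
  X <- as.matrix(features[, cols, drop = FALSE])
  fold <- .stratified_folds(y, k, seed)
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (f in seq_len(k)) {
    tr <- fold != f
    fit <- .fit_classifier(method, X[tr, , drop = FALSE], y[tr])
    pr <- .predict_prob(method, fit, X[!tr, , drop = FALSE], levels(y))
    pred[!tr] <- levels(y)[apply(pr, 1L, which.max)]
  }
  per_class <- do.call(rbind, lapply(levels(y), function(cl) {
    tp <- sum(pred == cl & y == cl)
    prec <- if (sum(pred == cl) > 0) tp / sum(pred == cl) else 0
    rec <- if (sum(y == cl) > 0) tp / sum(y == cl) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(class = cl, precision = prec, recall = rec, f1 = f1,
               stringsAsFactors = FALSE)
  }))
  cv <- list(per_class = per_class, macro_f1 = mean(per_class$f1),
             accuracy = mean(pred == y))
  final <- .fit_classifier(method, X, y)
  structure(list(model = final, method = method, classes = levels(y),
                 feature_cols = cols,
                 probability_threshold = probability_threshold,
                 cv = cv),
            class = "subgenome_classifier")
}

#' Classify sub-assemblies into sub-genomes
#'
#' Assigns each feature row the class with maximal predicted
#' probability, or `"unclassified"` when that probability falls below
#' the classifier's probability threshold — the rejection rule for
#' sub-assemblies matching all progenitors about equally well.
#'
#' @param model [train_and_validate()] result.
#' @param features feature data.frame from [extract_features()].
#' @param threshold optional override of the stored threshold.
#' @return data.frame: `subassembly_id`, `label`, one probability
#'   column per class.
#' @export
classify <- function(model, features, threshold = NULL) {
  if (is.null(threshold)) threshold <- model$probability_threshold
  if (nrow(features) == 0L) {
    out <- data.frame(subassembly_id = character(0),
                      label = character(0), stringsAsFactors = FALSE)
    for (cl in model$classes) out[[paste0("p_", cl)]] <- numeric(0)
    return(out)
  }
  X <- as.matrix(features[, model$feature_cols, drop = FALSE])
  pr <- .predict_prob(model$method, model$model, X, model$classes)
  win <- apply(pr, 1L, which.max)
  pmax_ <- pr[cbind(seq_len(nrow(pr)), win)]
  label <- ifelse(pmax_ >= threshold, model$classes[win], "unclassified")
  out <- data.frame(subassembly_id = features$subassembly_id,
                    label = label, stringsAsFactors = FALSE)
  for (i in seq_along(model$classes)) {
    out[[paste0("p_", model$classes[[i]])]] <- pr[, i]
  }
  out
}

#' Summarise a classification like a category table
#'
#' @param classified [classify()] output.
#' @return data.frame (category, count, percent) with one row per class
#'   plus `unclassified` and a leading `used for classification` row.
#' @export
classification_summary <- function(classified) {
  n <- nrow(classified)
  cats <- c(sort(setdiff(unique(classified$label), "unclassified")),
            "unclassified")
  counts <- vapply(cats, function(cl) sum(classified$label == cl),
                   integer(1))
  data.frame(
    category = c("used for classification", paste0("classified as ", cats)),
    count = c(n, counts),
    percent = round(100 * c(n, counts) / max(n, 1L), 1L),
    stringsAsFactors = FALSE)
}
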