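# Panel validation by hybrid sampling and a combined voting classifier.
#
# Balanced datasets are built from the training split by SMOTE
# over-sampling of the minority (normal) class and k-means under-sampling
# of the majority (tumor) class. Each balanced dataset trains a Gaussian
# naive-Bayes member and an RBF support-vector-machine member; a sample's
# score is the fraction of all members voting tumor (flat pooling), its
# label the majority vote with ties toward tumor. Performance is summarized
# by rank-based (Mann-Whitney) ROC/AUC on the train, test and complete sets.

#' Stratified train/test split
#'
#' @param m a labeled [expression_matrix()].
#' @param train_frac fraction of each class assigned to training
#'   (default 0.8).
#' @param seed RNG seed.
#' @return list with integer index vectors `train` and `test` (disjoint,
#'   exhaustive, class proportions preserved within one sample).
#' @export
train_test_split <- function(m, train_frac = 0.8, seed = 1) {
  stopifnot(inherits(m, "ExpressionMatrix"), train_frac > 0, train_frac < 1)
  if (is.null(m$labels)) stop("class labels required", call. = FALSE)
  with_seed(seed, {
    train <- integer(0)
    for (cl in unique(m$labels)) {
      idx <- which(m$labels == cl)
      n_tr <- round(train_frac * length(idx))
      if (n_tr < 1L || n_tr >= length(idx)) {
        stop("class '", cl, "' too small to stratify into an ",
             train_frac, "/", 1 - train_frac, " split", call. = FALSE)
      }
      train <- c(train, sample(idx, n_tr))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(m$labels), train))
  })
}

#' SMOTE over-sampling of minority vectors
#'
#' Each synthetic vector is `x + lambda * (x_nn - x)` for a random minority
#' sample `x`, one of its `k_neighbors` nearest minority neighbors `x_nn`
#' (Euclidean), and `lambda ~ U(0, 1)`; coordinates therefore stay between
#' the two parents.
#'
#' @param x minority samples x features matrix (more than `k_neighbors`
#'   rows).
#' @param n_target number of synthetic vectors to produce.
#' @param k_neighbors neighborhood size (default 5).
#' @param seed RNG seed.
#' @return `n_target` x features matrix of synthetic vectors.
#' @export
smote_oversample <- function(x, n_target, k_neighbors = 5, seed = 1) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n <= 1L) stop("SMOTE needs at least 2 minority samples", call. = FALSE)
  if (n <= k_neighbors) {
    stop("minority count (", n, ") must exceed k_neighbors (", k_neighbors,
         ")", call. = FALSE)
  }
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  nn <- do.call(rbind, lapply(seq_len(n), function(i)
    order(d[i, ])[seq_len(k_neighbors)]))
  with_seed(seed, {
    base <- sample(n, n_target, replace = TRUE)
    pick <- nn[cbind(base, sample(k_neighbors, n_target, replace = TRUE))]
    lambda <- stats::runif(n_target)
    syn <- x[base, , drop = FALSE] +
      lambda * (x[pick, , drop = FALSE] - x[base, , drop = FALSE])
    rownames(syn) <- sprintf("syn%04d", seq_len(n_target))
    syn
  })
}

#' k-means under-sampling of majority vectors
#'
#' Runs k-means with `k = n_target` clusters and returns, per centroid, the
#' nearest real sample (medoid rule), so representatives stay in the
#' observed value space. Duplicate medoids are replaced by the next-nearest
#' unused sample. With `centroids = TRUE` the raw centroids are returned
#' instead.
#'
#' @param x majority samples x features matrix (`nrow(x) >= n_target`).
#' @param n_target number of representatives.
#' @param seed RNG seed for the k-means initialization.
#' @param centroids return centroid vectors instead of medoid indices.
#' @return integer vector of `n_target` distinct row indices into `x`
#'   (or a centroid matrix when `centroids = TRUE`).
#' @export
kmeans_undersample <- function(x, n_target, seed = 1, centroids = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < n_target) {
    stop("majority count (", nrow(x), ") is below n_target (", n_target,
         ")", call. = FALSE)
  }
  if (!centroids && nrow(x) == n_target) return(seq_len(n_target))
  km <- with_seed(seed, stats::kmeans(x, centers = n_target,
                                      iter.max = 50, nstart = 1))
  if (centroids) return(km$centers)
  used <- logical(nrow(x))
  reps <- integer(n_target)
  for (c in seq_len(n_target)) {
    d2 <- colSums((t(x) - km$centers[c, ])^2)
    ord <- order(d2)
    reps[c] <- ord[which(!used[ord])[1L]]
    used[reps[c]] <- TRUE
  }
  reps
}

#' Build balanced hybrid datasets from a training split
#'
#' Each dataset holds `size/2` SMOTE-synthetic minority (normal) vectors and
#' `size/2` k-means medoid representatives of the majority (tumor) class,
#' drawn under an independent derived seed.
#'
#' @param m a labeled [expression_matrix()].
#' @param samples sample indices to draw from (typically the training
#'   split).
#' @param genes panel gene identifiers (default all).
#' @param n_datasets number of balanced datasets (default 9).
#' @param size total samples per dataset, even (default 100).
#' @param k_neighbors SMOTE neighborhood size (default 5; capped below the
#'   minority count).
#' @param seed master seed.
#' @return list of `HybridDataset` lists: `x` (size x genes matrix), `y`
#'   (labels), `provenance` (`"synthetic"` / `"cluster-representative"`),
#'   `seed`.
#' @export
build_hybrid_datasets <- function(m, samples, genes = NULL, n_datasets = 9,
                                  size = 100, k_neighbors = 5, seed = 1) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (size %% 2L != 0L) stop("dataset size must be even", call. = FALSE)
  if (is.null(genes)) genes <- rownames(m$values)
  labs <- m$labels[samples]
  min_idx <- samples[labs == "normal"]
  maj_idx <- samples[labs == "tumor"]
  half <- size %/% 2L
  if (length(maj_idx) < half) {
    stop("tumor training count (", length(maj_idx),
         ") is below the per-class dataset size (", half, ")",
         call. = FALSE)
  }
  k_nn <- min(k_neighbors, length(min_idx) - 1L)
  min_x <- t(m$values[genes, min_idx, drop = FALSE])
  maj_x <- t(m$values[genes, maj_idx, drop = FALSE])
  lapply(seq_len(n_datasets), function(d) {
    s <- derive_seed(seed, paste0("hybrid", d))
    syn <- smote_oversample(min_x, half, k_neighbors = k_nn,
                            seed = derive_seed(s, "smote"))
    reps <- kmeans_undersample(maj_x, half, seed = derive_seed(s, "kmeans"))
    x <- rbind(maj_x[reps, , drop = FALSE], syn)
    list(x = x,
         y = c(rep("tumor", half), rep("normal", half)),
         provenance = c(rep("cluster-representative", half),
                        rep("synthetic", half)),
         seed = s)
  })
}

#' Train the combined naive-Bayes + SVM voting classifier
#'
#' Fits, per balanced dataset, one Gaussian naive-Bayes member and one
#' RBF-kernel SVM member on the panel features (two members per dataset).
#' Features that are constant within a dataset are dropped for the
#' naive-Bayes member (their class-conditional density is degenerate) and
#' logged.
#'
#' @param datasets list of hybrid datasets from [build_hybrid_datasets()].
#' @return a `VotingClassifier` list: `members` (each with `type`, `fit`,
#'   `features`), `genes`.
#' @export
train_voting_classifier <- function(datasets) {
  stopifnot(length(datasets) >= 1L)
  genes <- colnames(datasets[[1L]]$x)
  fnames <- paste0("f", seq_along(genes))
  members <- list()
  for (d in datasets) {
    x <- d$x
    colnames(x) <- fnames
    y <- factor(d$y, levels = c("normal", "tumor"))
    const <- apply(x, 2L, function(col) max(col) == min(col))
    if (any(const)) {
      td_log(sum(const), " constant feature(s) dropped for the naive-Bayes",
             " member", level = "WARN")
    }
    nb <- e1071::naiveBayes(x[, !const, drop = FALSE], y)
    sv <- e1071::svm(x, y, kernel = "radial")
    members <- c(members,
                 list(list(type = "nb", fit = nb, features = fnames[!const]),
                      list(type = "svm", fit = sv, features = fnames)))
  }
  structure(list(members = members, genes = genes),
            class = "VotingClassifier")
}

#' Predict by pooled member voting
#'
#' A sample's score is the fraction of all member classifiers voting tumor;
#' the label is tumor iff the score is at least 0.5 (ties toward tumor).
#'
#' @param clf a [train_voting_classifier()] result.
#' @param m an [expression_matrix()] containing the panel genes (or a
#'   samples x genes matrix over the panel).
#' @param samples sample identifiers or indices (default all).
#' @return list with `labels` (character) and `scores` (tumor-vote
#'   fraction in \[0, 1\]).
#' @export
predict_vote <- function(clf, m, samples = NULL) {
  stopifnot(inherits(clf, "VotingClassifier"))
  x <- if (inherits(m, "ExpressionMatrix")) {
    v <- m$values[clf$genes, , drop = FALSE]
    if (!is.null(samples)) v <- v[, samples, drop = FALSE]
    t(v)
  } else {
    as.matrix(m)[, clf$genes, drop = FALSE]
  }
  colnames(x) <- paste0("f", seq_along(clf$genes))
  df <- as.data.frame(x)
  votes <- vapply(clf$members, function(mem) {
    p <- predict(mem$fit, df[, mem$features, drop = FALSE])
    as.character(p) == "tumor"
  }, logical(nrow(x)))
  if (nrow(x) == 1L) votes <- matrix(votes, nrow = 1L)
  scores <- rowMeans(votes)
  list(labels = ifelse(scores >= 0.5, "tumor", "normal"),
       scores = unname(scores))
}

#' Rank-based ROC curve and AUC
#'
#' AUC is the Mann-Whitney normalization of the score ranking with mid-rank
#' tie correction; curve points are emitted at every unique threshold.
#'
#' @param scores numeric scores, higher meaning more tumor-like.
#' @param labels true labels (`"tumor"` positive, `"normal"` negative).
#' @param split tag recorded on the result (`"train"`, `"test"`,
#'   `"complete"`).
#' @return a `RocResult` list: `thresholds`, `tpr`, `fpr`, `auc`, `split`.
#' @export
roc_auc <- function(scores, labels, split = "complete") {
  pos <- labels == "tumor"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present to compute ROC/AUC", call. = FALSE)
  }
  r <- rank(scores)  # mid-ranks: handles ties exactly
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores[pos] >= t) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores[!pos] >= t) / n0, numeric(1))
  structure(list(thresholds = c(Inf, thr), tpr = c(0, tpr),
                 fpr = c(0, fpr), auc = auc, split = split),
            class = "RocResult")
}

#' Evaluate a gene panel end to end
#'
#' Stratified 80/20 split, hybrid balanced datasets from the training split,
#' combined NB + SVM voting classifier, and ROC/AUC plus accuracy on the
#' train, test and complete sample sets.
#'
#' @inheritParams build_hybrid_datasets
#' @param panel character vector of panel gene identifiers.
#' @param train_frac training fraction (default 0.8).
#' @return list with `auc` and `accuracy` (named `train`/`test`/`complete`),
#'   `roc` (list of `RocResult`), `classifier`, and `split`.
#' @export
evaluate_panel <- function(m, panel, train_frac = 0.8, n_datasets = 9,
                           size = 100, k_neighbors = 5, seed = 1) {
  stopifnot(inherits(m, "ExpressionMatrix"), length(panel) >= 1L)
  sp <- train_test_split(m, train_frac = train_frac,
                         seed = derive_seed(seed, "split"))
  datasets <- build_hybrid_datasets(m, samples = sp$train, genes = panel,
                                    n_datasets = n_datasets, size = size,
                                    k_neighbors = k_neighbors,
                                    seed = derive_seed(seed, "hybrid"))
  clf <- train_voting_classifier(datasets)
  sets <- list(train = sp$train, test = sp$test,
               complete = seq_along(m$labels))
  roc <- list(); auc <- accuracy <- numeric(0)
  for (nm in names(sets)) {
    pv <- predict_vote(clf, m, samples = sets[[nm]])
    truth <- m$labels[sets[[nm]]]
    roc[[nm]] <- roc_auc(pv$scores, truth, split = nm)
    auc[nm] <- roc[[nm]]$auc
    accuracy[nm] <- mean(pv$labels == truth)
  }
  list(auc = auc, accuracy = accuracy, roc = roc, classifier = clf,
       split = sp)
}
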