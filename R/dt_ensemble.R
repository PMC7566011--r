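# Ensemble of decision trees on balanced resamples with perturbation-based
# feature importance.
#
# Each "tree" is a tree-induction procedure on one bootstrap-balanced subset
# (all minority samples + an equal-size bootstrap of the majority). Inside a
# subset, a stratified CV measures, per fold, the validation accuracy before
# (ACC_ik) and after (ACCF_ijk) perturbing gene j; the per-tree importance is
# the fold mean
#   FI_ij = sum_k (ACC_ik - ACCF_ijk) / CV.
# A full-subset tree votes on every sample; the ensemble label is the
# majority vote and each tree is weighted by its consistency with it:
#   TreeWeighted_i = [sum_j I(Tree_ij = Ensemble_j) / S] * Acc_Ensemble.
# Final per-gene importance is the weighted sum over trees:
#   FI_j = sum_i FI_ij * TreeWeighted_i,
# and DEGs are the genes with positive FI_j.

default_tree_control <- function() rpart::rpart.control(xval = 0)

# Fit one classification tree on a samples x genes matrix. Feature names are
# sanitized to f1..fG so arbitrary gene identifiers survive the formula
# interface; the original identifiers are kept alongside.
td_fit_tree <- function(x, y, control = default_tree_control()) {
  genes <- colnames(x)
  df <- as.data.frame(x)
  colnames(df) <- paste0("f", seq_along(genes))
  df$.y <- factor(y, levels = c("normal", "tumor"))
  if (length(unique(y)) < 2L) {
    stop("degenerate subset: only one class present", call. = FALSE)
  }
  fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                      control = control)
  structure(list(fit = fit, genes = genes), class = "td_tree")
}

td_predict <- function(tree, x) {
  df <- as.data.frame(x[, tree$genes, drop = FALSE])
  colnames(df) <- paste0("f", seq_along(tree$genes))
  as.character(predict(tree$fit, newdata = df, type = "class"))
}

# genes actually used in the tree's splits
td_used_genes <- function(tree) {
  vars <- setdiff(unique(as.character(tree$fit$frame$var)), "<leaf>")
  tree$genes[match(vars, paste0("f", seq_along(tree$genes)))]
}

#' Build bootstrap-balanced training subsets
#'
#' Each subset keeps every minority-class sample and draws an equal-size
#' bootstrap (with replacement) from the majority class, yielding exactly
#' balanced class counts.
#'
#' @param m a labeled [expression_matrix()].
#' @param n_trees number of subsets / trees (default 500).
#' @param seed master seed; subset `i` uses a derived per-tree seed.
#' @return list of `BalancedSubset` lists: `idx` (sample indices into the
#'   columns of `m`), `seed`.
#' @export
build_balanced_subsets <- function(m, n_trees = 500, seed = 1) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (is.null(m$labels)) stop("class labels required", call. = FALSE)
  tab <- table(m$labels)
  if (length(tab) < 2L) stop("both classes must be present", call. = FALSE)
  minority <- names(which.min(tab))
  n_min <- min(tab)
  if (n_min < 2L) stop("minority class has fewer than 2 samples",
                       call. = FALSE)
  min_idx <- which(m$labels == minority)
  maj_idx <- which(m$labels != minority)
  lapply(seq_len(n_trees), function(i) {
    s <- derive_seed(seed, paste0("subset", i))
    idx <- with_seed(s, c(min_idx, sample(maj_idx, n_min, replace = TRUE)))
    list(idx = idx, seed = s)
  })
}

#' Fit a decision tree on a balanced subset
#'
#' @param m a labeled [expression_matrix()].
#' @param subset a `BalancedSubset` (from [build_balanced_subsets()]) or an
#'   integer vector of sample indices.
#' @param genes gene identifiers to use as features (default all).
#' @param control an [rpart::rpart.control()] (default: no internal CV,
#'   otherwise standard Gini defaults).
#' @return a fitted tree (class `td_tree`) mapping a gene-value vector to a
#'   label in `{tumor, normal}` via [predict_tree()].
#' @export
fit_tree <- function(m, subset, genes = NULL,
                     control = default_tree_control()) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  idx <- if (is.list(subset)) subset$idx else subset
  if (is.null(genes)) genes <- rownames(m$values)
  x <- t(m$values[genes, idx, drop = FALSE])
  td_fit_tree(x, m$labels[idx], control = control)
}

#' Predict sample labels with a fitted tree
#'
#' @param tree a `td_tree` from [fit_tree()].
#' @param m an [expression_matrix()] containing the tree's genes.
#' @param samples sample identifiers or indices (default all).
#' @return character vector of predicted labels.
#' @export
predict_tree <- function(tree, m, samples = NULL) {
  v <- m$values
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  td_predict(tree, t(v))
}

#' Perturbation-based feature importance of one tree
#'
#' Within one balanced subset, runs a stratified `cv`-fold cross-validation.
#' For fold k a tree is grown on the training part and its validation
#' accuracy `ACC_ik` recorded; gene j's validation values are then replaced
#' by the gene's training-part mean (`perturb = "mean"`) or permuted within
#' the fold (`perturb = "permute"`) and the perturbed accuracy `ACCF_ijk`
#' recorded. The importance is the fold mean of `ACC_ik - ACCF_ijk`, which
#' may be negative. Genes never used by any fold's tree score exactly 0.
#'
#' @inheritParams fit_tree
#' @param cv number of stratified folds (default 5).
#' @param seed RNG seed for fold assignment (and permutation draws).
#' @param perturb perturbation operator, `"mean"` (default) or `"permute"`.
#' @return named numeric vector: `FI_ij` for every gene j in tree i.
#' @export
perturbation_importance <- function(m, subset, genes = NULL, cv = 5,
                                    seed = 1,
                                    perturb = c("mean", "permute"),
                                    control = default_tree_control()) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  perturb <- match.arg(perturb)
  idx <- if (is.list(subset)) subset$idx else subset
  if (is.null(genes)) genes <- rownames(m$values)
  x <- t(m$values[genes, idx, drop = FALSE])
  y <- m$labels[idx]
  td_perturbation_importance(x, y, cv = cv, seed = seed, perturb = perturb,
                             control = control)
}

td_perturbation_importance <- function(x, y, cv = 5, seed = 1,
                                       perturb = "mean",
                                       control = default_tree_control()) {
  genes <- colnames(x)
  groups <- rownames(x)
  n_distinct <- if (is.null(groups)) table(y)
                else table(y[!duplicated(groups)])
  if (min(n_distinct) < cv) {
    stop("cv = ", cv, " exceeds the per-class fold capacity of the subset",
         call. = FALSE)
  }
  # folds are grouped by sample identity: a bootstrap-duplicated sample
  # never straddles the training/validation split of a fold
  folds <- stratified_folds(y, cv, seed = seed, groups = groups)
  fi <- stats::setNames(numeric(length(genes)), genes)
  for (k in seq_len(cv)) {
    tr <- folds != k
    va <- !tr
    fit_k <- td_fit_tree(x[tr, , drop = FALSE], y[tr], control = control)
    base_pred <- td_predict(fit_k, x[va, , drop = FALSE])
    acc <- mean(base_pred == y[va])
    used <- td_used_genes(fit_k)
    for (g in used) {
      xp <- x[va, , drop = FALSE]
      if (perturb == "mean") {
        xp[, g] <- mean(x[tr, g])
      } else {
        xp[, g] <- with_seed(derive_seed(seed, paste0("perm", k, g)),
                             sample(xp[, g]))
      }
      accf <- mean(td_predict(fit_k, xp) == y[va])
      fi[g] <- fi[g] + (acc - accf) / cv
    }
  }
  fi
}

#' Majority-vote ensemble prediction
#'
#' Every tree votes on every sample; the ensemble label is the modal vote,
#' with ties broken toward the majority (tumor) class. The ensemble
#' accuracy is computed against the true labels.
#'
#' @param trees list of fitted trees from [fit_tree()].
#' @param m a labeled [expression_matrix()].
#' @return an `EnsemblePrediction` list: `tree_labels` (tree x sample
#'   character matrix), `ensemble` (named character vector), `accuracy`.
#' @export
ensemble_predict <- function(trees, m) {
  stopifnot(length(trees) >= 1L, inherits(m, "ExpressionMatrix"))
  x <- t(m$values)
  tree_labels <- t(vapply(trees, function(tr) td_predict(tr, x),
                          character(nrow(x))))
  colnames(tree_labels) <- colnames(m$values)
  votes_tumor <- colSums(tree_labels == "tumor")
  ensemble <- ifelse(votes_tumor >= length(trees) / 2, "tumor", "normal")
  names(ensemble) <- colnames(m$values)
  acc <- if (is.null(m$labels)) NA_real_ else mean(ensemble == m$labels)
  structure(list(tree_labels = tree_labels, ensemble = ensemble,
                 accuracy = acc),
            class = "EnsemblePrediction")
}

#' Consistency weight of each tree
#'
#' `TreeWeighted_i = [sum_j I(Tree_ij = Ensemble_j) / S] * Acc_Ensemble`:
#' the tree's agreement fraction with the ensemble vote, scaled by the
#' ensemble accuracy. Always in \[0, 1\].
#'
#' @param pred an `EnsemblePrediction` from [ensemble_predict()].
#' @return numeric vector of weights, one per tree.
#' @export
tree_weights <- function(pred) {
  stopifnot(inherits(pred, "EnsemblePrediction"))
  if (ncol(pred$tree_labels) == 0L) stop("no samples", call. = FALSE)
  agree <- rowMeans(pred$tree_labels ==
                      matrix(pred$ensemble, nrow = nrow(pred$tree_labels),
                             ncol = ncol(pred$tree_labels), byrow = TRUE))
  agree * pred$accuracy
}

#' @rdname tree_weights
#' @param i tree index.
#' @export
tree_weight <- function(pred, i) tree_weights(pred)[i]

#' Weighted combination of per-tree importances
#'
#' `FI_j = sum_i FI_ij * TreeWeighted_i`.
#'
#' @param fi_matrix trees x genes importance matrix (`FI_ij`).
#' @param weights per-tree weights (`TreeWeighted_i`).
#' @return named numeric vector `FI_j`.
#' @export
combine_importance <- function(fi_matrix, weights) {
  if (!is.matrix(fi_matrix) || nrow(fi_matrix) != length(weights)) {
    stop("dimension mismatch: fi_matrix has ", nrow(fi_matrix),
         " trees but ", length(weights), " weights were given",
         call. = FALSE)
  }
  colSums(fi_matrix * weights)
}

#' Run the full balanced-ensemble importance procedure
#'
#' Builds `n_trees` balanced subsets, computes every tree's perturbation
#' importance vector and full-subset vote, derives consistency weights and
#' combines them into the final per-gene importance `FI_j`.
#'
#' @inheritParams build_balanced_subsets
#' @inheritParams perturbation_importance
#' @param genes gene identifiers to rank (default all rows of `m`).
#' @param sampling `"bootstrap"` (default: bootstrap under-sampling of the
#'   majority) or `"hybrid"` (SMOTE over-sampling + k-means under-sampling
#'   per tree, via the hybrid sampler).
#' @return an `EnsembleImportance` list: `fi_matrix` (trees x genes),
#'   `weights`, `fi` (named `FI_j`), `prediction` (the
#'   `EnsemblePrediction`), `n_trees`, `seed`.
#' @examples
#' sim <- generate_expression(synthetic_spec(n_genes = 60, n_informative = 4,
#'                                           n_redundant = 0, n_major = 60,
#'                                           n_minor = 15, effect_size = 3,
#'                                           seed = 3))
#' imp <- dt_ensemble_importance(sim$matrix, n_trees = 10, seed = 3)
#' head(sort(imp$fi, decreasing = TRUE))
#' @export
dt_ensemble_importance <- function(m, genes = NULL, n_trees = 500, cv = 5,
                                   seed = 1, perturb = c("mean", "permute"),
                                   sampling = c("bootstrap", "hybrid"),
                                   control = default_tree_control()) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  perturb <- match.arg(perturb)
  sampling <- match.arg(sampling)
  if (is.null(genes)) genes <- rownames(m$values)

  if (sampling == "bootstrap") {
    subsets <- build_balanced_subsets(m, n_trees = n_trees, seed = seed)
    train_sets <- lapply(subsets, function(s) {
      list(x = t(m$values[genes, s$idx, drop = FALSE]),
           y = m$labels[s$idx], seed = s$seed)
    })
  } else {
    n_min <- min(table(m$labels))
    hybrid <- build_hybrid_datasets(m, samples = seq_len(ncol(m$values)),
                                    genes = genes, n_datasets = n_trees,
                                    size = 2L * n_min, seed = seed)
    train_sets <- lapply(hybrid, function(h) {
      list(x = h$x, y = h$y, seed = h$seed)
    })
  }

  trees <- vector("list", n_trees)
  fi_matrix <- matrix(0, nrow = n_trees, ncol = length(genes),
                      dimnames = list(NULL, genes))
  for (i in seq_len(n_trees)) {
    ts <- train_sets[[i]]
    trees[[i]] <- td_fit_tree(ts$x, ts$y, control = control)
    fi_matrix[i, ] <- td_perturbation_importance(
      ts$x, ts$y, cv = cv, seed = derive_seed(ts$seed, "cv"),
      perturb = perturb, control = control)
  }
  pred <- ensemble_predict(trees, em_subset(m, genes = genes))
  w <- tree_weights(pred)
  structure(list(fi_matrix = fi_matrix, weights = w,
                 fi = combine_importance(fi_matrix, w),
                 prediction = pred, n_trees = n_trees, seed = seed),
            class = "EnsembleImportance")
}

#' Select DEGs by positive final importance
#'
#' Genes whose combined importance exceeds the numeric tolerance are
#' returned in decreasing importance order, annotated up-/down-regulated in
#' tumor by the sign of the tumor-minus-normal mean difference. Negative
#' importances (possible under the fold-mean definition) are excluded and
#' their count logged.
#'
#' @param imp an `EnsembleImportance` (or a named `FI_j` vector).
#' @param m the labeled [expression_matrix()] used for the ensemble (for
#'   regulation direction).
#' @param tol strictly-positive threshold (default 1e-12).
#' @return a `data.frame`: `gene_id`, `fi`, `direction` (`"up"`/`"down"`),
#'   `rank`. Empty (zero rows) when nothing scores above tolerance.
#' @export
select_degs <- function(imp, m, tol = 1e-12) {
  fi <- if (inherits(imp, "EnsembleImportance")) imp$fi else imp
  n_neg <- sum(fi < 0)
  if (n_neg > 0) td_log(n_neg, " gene(s) with negative importance excluded")
  keep <- fi > tol
  fi <- sort(fi[keep], decreasing = TRUE)
  if (!length(fi)) {
    td_log("no gene has positive ensemble importance", level = "WARN")
    return(data.frame(gene_id = character(0), fi = numeric(0),
                      direction = character(0), rank = integer(0),
                      stringsAsFactors = FALSE))
  }
  tum <- rowMeans(m$values[names(fi), m$labels == "tumor", drop = FALSE])
  nor <- rowMeans(m$values[names(fi), m$labels == "normal", drop = FALSE])
  data.frame(gene_id = names(fi), fi = unname(fi),
             direction = ifelse(tum >= nor, "up", "down"),
             rank = seq_along(fi), row.names = NULL,
             stringsAsFactors = FALSE)
}
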