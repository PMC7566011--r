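# Balanced-subset tree ensemble: subset balance, tree fitting, the
# perturbation importance, consistency weights, weighted combination and
# DEG selection.

test_that("balanced subsets take all minority plus a majority bootstrap", {
  m <- shifted_em(n_tumor = 40, n_normal = 5, seed = 1)
  subs <- build_balanced_subsets(m, n_trees = 20, seed = 1)
  expect_length(subs, 20)
  for (s in subs) {
    labs <- m$labels[s$idx]
    expect_equal(sum(labs == "tumor"), 5L)
    expect_equal(sum(labs == "normal"), 5L)
    # every minority sample present exactly once
    expect_setequal(names(labs)[labs == "normal"],
                    names(m$labels)[m$labels == "normal"])
  }
  expect_identical(build_balanced_subsets(m, n_trees = 20, seed = 1), subs)
  expect_false(identical(build_balanced_subsets(m, 20, seed = 2), subs))
  # nearly every majority sample appears somewhere across many subsets
  seen <- unique(unlist(lapply(
    build_balanced_subsets(m, n_trees = 200, seed = 3),
    function(s) s$idx)))
  expect_gte(length(intersect(seen, which(m$labels == "tumor"))), 39)
})

test_that("a separable gene yields a perfect training tree", {
  m <- shifted_em(n_genes = 5, n_signal = 1, shift = 10, seed = 2)
  subs <- build_balanced_subsets(m, n_trees = 1, seed = 2)
  tree <- fit_tree(m, subs[[1]])
  pred <- predict_tree(tree, m, samples = subs[[1]]$idx)
  expect_equal(mean(pred == m$labels[subs[[1]]$idx]), 1)
  # determinism on a probe set
  expect_identical(predict_tree(fit_tree(m, subs[[1]]), m),
                   predict_tree(tree, m))
})

test_that("perturbation importance matches an explicit fold-by-fold
          recomputation and zeroes unused genes", {
  m <- shifted_em(n_genes = 8, n_tumor = 30, n_normal = 20,
                  n_signal = 2, shift = 4, seed = 3)
  # plant a constant gene: it can never be used in a split
  v <- m$values
  v["g008", ] <- 0.5
  m <- expression_matrix(v, labels = m$labels)
  idx <- seq_len(ncol(m$values))
  fi <- perturbation_importance(m, idx, cv = 5, seed = 11)
  expect_identical(unname(fi["g008"]), 0)
  # independent recomputation of FI for the signal genes, same folds
  x <- t(m$values[, idx])
  y <- m$labels[idx]
  folds <- treeDEG:::stratified_folds(y, 5, seed = 11)
  for (g in c("g001", "g002")) {
    expect_equal(unname(fi[g]), oracle_perturbation_fi(x, y, folds, g),
                 tolerance = 1e-12)
  }
  # perturbing a strong separator costs accuracy
  expect_gt(fi["g001"] + fi["g002"], 0.2)
  expect_error(perturbation_importance(m, c(1:4, 31:34), cv = 5, seed = 1),
               "fold capacity")
})

test_that("ensemble vote is the per-sample majority with ties to tumor", {
  m <- shifted_em(n_genes = 4, n_signal = 1, shift = 10,
                  n_tumor = 20, n_normal = 20, seed = 4)
  tree_a <- fit_tree(m, seq_len(40))
  flipped <- expression_matrix(m$values,
                               labels = ifelse(m$labels == "tumor",
                                               "normal", "tumor"))
  tree_b <- fit_tree(flipped, seq_len(40))
  # agreeing ensemble equals any single tree
  pred_same <- ensemble_predict(list(tree_a, tree_a, tree_a), m)
  expect_identical(unname(pred_same$ensemble),
                   predict_tree(tree_a, m))
  # two opposite trees tie on every sample: tie rule says tumor
  pred_tie <- ensemble_predict(list(tree_a, tree_b), m)
  expect_true(all(pred_tie$ensemble == "tumor"))
  # 2-vs-1 majority follows the two
  pred_maj <- ensemble_predict(list(tree_a, tree_a, tree_b), m)
  expect_identical(pred_maj$ensemble, pred_same$ensemble)
})

test_that("tree weights are agreement times ensemble accuracy", {
  ens <- rep(c("tumor", "normal"), each = 50)
  tl <- rbind(ens,                                  # full agreement
              c(ens[1:90], rep("tumor", 10)),       # 90/100 agreement
              ifelse(ens == "tumor", "normal", "tumor"))  # zero agreement
  rownames(tl) <- NULL
  pred <- structure(list(tree_labels = tl,
                         ensemble = stats::setNames(ens, paste0("s", 1:100)),
                         accuracy = 0.95),
                    class = "EnsemblePrediction")
  w <- tree_weights(pred)
  expect_equal(w, c(0.95, 0.855, 0))
  expect_equal(tree_weight(pred, 2), 0.855)
  expect_equal(oracle_tree_weight(tl[2, ], ens, 0.95), 0.855)
  pred$accuracy <- 1
  expect_equal(tree_weights(pred)[1], 1)  # upper bound attained
})

test_that("weighted combination matches the brute-force double loop", {
  expect_equal(unname(combine_importance(rbind(c(0.2, 0), c(0.1, 0)),
                                         c(0.5, 1.0))),
               c(0.2, 0))
  # single tree with weight 1 is the identity
  fi1 <- matrix(c(0.3, -0.1, 0), 1)
  expect_equal(unname(combine_importance(fi1, 1)), c(0.3, -0.1, 0))
  expect_error(combine_importance(fi1, c(1, 2)), "mismatch")
  for (i in 1:100) {
    set.seed(i)
    tn <- sample(2:8, 1); g <- sample(2:10, 1)
    fi <- matrix(rnorm(tn * g), tn)
    w <- runif(tn)
    expect_equal(unname(combine_importance(fi, w)), oracle_combine(fi, w),
                 tolerance = 1e-12)
  }
})

test_that("DEG selection keeps positive importances in rank order with
          regulation direction", {
  m <- shifted_em(n_genes = 3, n_signal = 1, shift = 2, seed = 5)
  fi <- c(g001 = 0.2, g002 = 0, g003 = 0.01)
  degs <- select_degs(fi, m)
  expect_identical(degs$gene_id, c("g001", "g003"))
  expect_identical(degs$rank, 1:2)
  expect_identical(degs$direction[1], "up")     # planted tumor shift
  # downregulated gene flagged by the sign of the mean difference
  v <- m$values
  v["g003", m$labels == "normal"] <- v["g003", m$labels == "normal"] + 5
  degs2 <- select_degs(fi, expression_matrix(v, labels = m$labels))
  expect_identical(degs2$direction[degs2$gene_id == "g003"], "down")
  # all-zero importance: empty selection
  expect_equal(nrow(quiet(select_degs(c(g001 = 0, g002 = 0), m))), 0L)
  # negative importances are excluded
  expect_equal(nrow(quiet(select_degs(c(g001 = -0.3, g002 = 0), m))), 0L)
})

test_that("the full ensemble is deterministic and satisfies the
          weighted-sum identity", {
  m <- shifted_em(n_genes = 15, n_signal = 2, shift = 3,
                  n_tumor = 40, n_normal = 12, seed = 6)
  imp <- dt_ensemble_importance(m, n_trees = 15, seed = 9)
  imp2 <- dt_ensemble_importance(m, n_trees = 15, seed = 9)
  expect_identical(imp$fi, imp2$fi)
  expect_true(all(imp$weights >= 0 & imp$weights <= 1))
  expect_equal(unname(imp$fi),
               oracle_combine(imp$fi_matrix, imp$weights),
               tolerance = 1e-12)
  # the planted separators carry the importance mass
  top <- names(sort(imp$fi, decreasing = TRUE))[1:2]
  expect_setequal(top, c("g001", "g002"))
})

test_that("hybrid-sampling mode trains on SMOTE + medoid datasets", {
  m <- shifted_em(n_genes = 10, n_signal = 2, shift = 3,
                  n_tumor = 40, n_normal = 12, seed = 7)
  imp <- quiet(dt_ensemble_importance(m, n_trees = 5, seed = 3,
                                      sampling = "hybrid"))
  expect_length(imp$fi, 10)
  expect_gt(max(imp$fi[c("g001", "g002")]), 0)
})
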