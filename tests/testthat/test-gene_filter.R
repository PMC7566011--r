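# Fisher ratio, classified information index, Spearman redundancy filter:
# hand-computed cases, oracle agreement, invariances, and the no-surviving-
# redundant-pair post-condition.

two_class_em <- function(x1, x2) {
  v <- rbind(c(x1, x2))
  dimnames(v) <- list("g1", paste0("s", seq_len(ncol(v))))
  expression_matrix(v, labels = c(rep("tumor", length(x1)),
                                  rep("normal", length(x2))))
}

test_that("class statistics match hand computation and swap symmetry", {
  m <- two_class_em(c(1, 2, 3), c(4, 5, 6))
  st <- class_stats(m)
  expect_equal(st$mu1, 2)
  expect_equal(st$var1, 1)   # unbiased (n-1) variance
  expect_equal(st$mu2, 5)
  # identical values give zero variance
  st0 <- class_stats(two_class_em(c(2, 2, 2), c(1, 2, 3)))
  expect_equal(st0$var1, 0)
  # swapping class labels swaps the class slots
  m_sw <- two_class_em(c(4, 5, 6), c(1, 2, 3))
  st_sw <- class_stats(m_sw)
  expect_equal(st_sw$mu1, st$mu2)
  expect_equal(st_sw$var1, st$var2)
  # population variance switch
  expect_equal(class_stats(m, var_method = "population")$var1, 2 / 3)
  # a class below 2 samples is an error
  expect_error(class_stats(two_class_em(1, c(1, 2))), "at least 2")
})

test_that("Fisher ratio: hand value, degenerate cases, affine invariance", {
  st <- class_stats(two_class_em(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(unname(fisher_ratio(st)), 4.5)  # (2-5)^2/(1+1)
  # zero numerator
  st_eq <- class_stats(two_class_em(c(1, 2, 3), c(3, 2, 1)))
  expect_equal(unname(fisher_ratio(st_eq)), 0)
  # zero variance with distinct means ranks on top
  st_inf <- class_stats(two_class_em(c(2, 2, 2), c(5, 5, 5)))
  expect_identical(unname(fisher_ratio(st_inf)), Inf)
  # invariant under x -> a x + b on both classes
  a <- 3.7; b <- -1.2
  st_t <- class_stats(two_class_em(a * c(1, 2, 3) + b + 10,
                                   a * c(4, 5, 6) + b + 10))
  expect_equal(unname(fisher_ratio(st_t)), 4.5)
})

test_that("Fisher selection keeps the boundary score", {
  sc <- c(a = 0.4, b = 0.5, c = 0.6)
  expect_setequal(fisher_select(sc, 0.5), c("b", "c"))
  expect_error(fisher_select(c(a = 0, b = 0), 0.5), "threshold")
  expect_setequal(fisher_select(sc, 0), names(sc))
})

test_that("classified information index: hand values and degenerate cases", {
  # equal means, equal SDs: both terms vanish
  st0 <- class_stats(two_class_em(c(0, 1, 2), c(2, 1, 0)))
  expect_equal(unname(classified_information_index(st0)), 0)
  # mean difference 2, sd1=sd2=1 -> 0.5 (means 5 and 7)
  m1 <- two_class_em(c(4, 5, 6), c(6, 7, 8))
  expect_equal(unname(classified_information_index(class_stats(m1))), 0.5)
  # equal means, sd 1 vs 2: nonzero despite zero mean difference
  x1 <- c(4, 5, 6); x2 <- c(3, 5, 7)
  st2 <- class_stats(two_class_em(x1, x2))
  expect_equal(unname(classified_information_index(st2)),
               0.5 * log(5 / 4), tolerance = 1e-12)
  expect_equal(unname(classified_information_index(st2)), 0.11157,
               tolerance = 1e-4)
  # zero class SD scores Inf
  st_d <- class_stats(two_class_em(c(1, 1, 1), c(1, 2, 3)))
  expect_identical(unname(quiet(classified_information_index(st_d))), Inf)
})

test_that("both scores agree with brute-force oracles on random inputs", {
  for (i in 1:300) {
    set.seed(i)
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    x1 <- runif(n1, 0, 10)
    x2 <- runif(n2, 0, 10) + runif(1, 0, 3)
    st <- class_stats(two_class_em(x1, x2))
    expect_equal(unname(fisher_ratio(st)), oracle_fisher_ratio(x1, x2),
                 tolerance = 1e-12)
    expect_equal(unname(classified_information_index(st)),
                 oracle_cii(x1, x2), tolerance = 1e-12)
  }
})

test_that("scores are invariant to sample order and label swap", {
  m <- shifted_em(n_genes = 10, seed = 2)
  st <- class_stats(m)
  perm <- withr::with_seed(1, sample(ncol(m$values)))
  m_p <- expression_matrix(m$values[, perm], labels = m$labels[perm])
  expect_equal(fisher_ratio(class_stats(m_p)), fisher_ratio(st))
  flip <- ifelse(m$labels == "tumor", "normal", "tumor")
  m_f <- expression_matrix(m$values, labels = flip)
  expect_equal(fisher_ratio(class_stats(m_f)), fisher_ratio(st))
  expect_equal(classified_information_index(class_stats(m_f)),
               classified_information_index(st))
})

test_that("Spearman matrix matches rank-based hand computation", {
  v <- rbind(c(1, 2, 3, 4), c(1, 3, 2, 4), c(4, 3, 2, 1))
  m <- tiny_em(v)
  rho <- spearman_matrix(m)
  expect_equal(rho["g1", "g2"], 0.8)
  expect_equal(rho["g1", "g3"], -1)
  expect_equal(rho["g2", "g1"], rho["g1", "g2"])  # symmetry
  # strictly increasing pair
  expect_equal(spearman_matrix(tiny_em(rbind(1:5, (1:5)^3)))["g1", "g2"], 1)
  # constant gene handled as zero correlation with a warning
  expect_warning(rho_c <- spearman_matrix(tiny_em(rbind(1:4, rep(2, 4)))),
                 "constant")
  expect_equal(rho_c["g1", "g2"], 0)
  # oracle agreement on random vectors (with ties)
  for (i in 1:100) {
    set.seed(i)
    a <- sample(1:6, 10, replace = TRUE)
    b <- runif(10, 0, 5)
    rho_i <- spearman_matrix(tiny_em(rbind(a, b)))["g1", "g2"]
    expect_equal(rho_i, oracle_spearman(a, b), tolerance = 1e-12)
  }
})

test_that("redundancy filter removes the lower-CII member of each pair", {
  # no pair above threshold: identity
  rho <- diag(3); dimnames(rho) <- list(letters[1:3], letters[1:3])
  expect_identical(redundancy_filter(rho, c(a = 1, b = 2, c = 3)),
                   letters[1:3])
  # duplicated gene: the lower-CII copy goes
  rho2 <- matrix(c(1, 1, 1, 1), 2, 2,
                 dimnames = list(c("a", "b"), c("a", "b")))
  expect_identical(redundancy_filter(rho2, c(a = 0.5, b = 0.3)), "a")
  expect_identical(redundancy_filter(rho2, c(a = 0.3, b = 0.5)), "b")
  # CII tie: lexicographically later identifier is deleted
  expect_identical(redundancy_filter(rho2, c(a = 0.4, b = 0.4)), "a")
  # clique of three: only the top-CII gene survives
  rho3 <- matrix(0.9, 3, 3); diag(rho3) <- 1
  dimnames(rho3) <- list(letters[1:3], letters[1:3])
  expect_identical(redundancy_filter(rho3, c(a = 0.5, b = 0.3, c = 0.2)),
                   "a")
})

test_that("no retained pair exceeds the correlation threshold", {
  for (seed in 1:20) {
    spec <- synthetic_spec(n_genes = 60, n_informative = 8,
                           n_redundant = 20, n_major = 60, n_minor = 20,
                           redundancy_rho = 0.85, n_subtype_genes = 0,
                           dropout_rate = 0, seed = seed)
    m <- generate_expression(spec)$matrix
    st <- class_stats(m)
    cii <- classified_information_index(st)
    rho <- spearman_matrix(m)
    kept <- redundancy_filter(rho, cii, rho_threshold = 0.7)
    sub <- abs(rho[kept, kept])
    diag(sub) <- 0
    expect_lte(max(sub), 0.7)
  }
})

test_that("planted informative genes outrank noise genes", {
  spec <- synthetic_spec(n_genes = 300, n_informative = 15,
                         n_redundant = 0, n_major = 150, n_minor = 40,
                         effect_size = 2, n_subtype_genes = 5, seed = 13)
  sim <- generate_expression(spec)
  pp <- quiet(preprocess(sim$matrix, seed = 13))
  fr <- fisher_ratio(class_stats(pp$matrix))
  inf <- intersect(sim$truth$informative_gene_ids, names(fr))
  noise <- setdiff(names(fr), c(inf, unlist(sim$truth$subtype_gene_sets)))
  expect_gt(median(fr[inf]), median(fr[noise]))
  expect_gt(min(fr[inf]), stats::quantile(fr[noise], 0.99))
})
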