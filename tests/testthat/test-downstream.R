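# Subtype clustering, representative genes, PCA, survival statistics,
# methylation correlation and mutation enrichment.

test_that("well-separated subtype blobs are recovered almost perfectly", {
  skip_if_not_installed("mclust")
  # constructed input: 3 Gaussian blobs over 8 genes, plus normals
  withr::with_seed(1, {
    centers <- matrix(c(0, 0, 5, 5, 0, 5, 5, 0,
                        5, 0, 0, 5, 5, 0, 0, 5,
                        0, 5, 0, 0, 5, 5, 0, 0), 3, 8, byrow = TRUE)
    truth_lab <- rep(1:3, times = c(30, 25, 20))
    x <- t(centers[truth_lab, ] + matrix(rnorm(75 * 8, sd = 0.4), 75, 8))
    x <- cbind(x, matrix(abs(rnorm(8 * 10)), 8, 10))
    x <- x - min(x)
    dimnames(x) <- list(paste0("g", 1:8),
                        c(paste0("t", 1:75), paste0("n", 1:10)))
    m <- expression_matrix(x, labels = c(rep("tumor", 75),
                                         rep("normal", 10)))
  })
  asg <- cluster_subtypes(m, k = 3)
  expect_length(asg$subtype, 75)        # normals excluded
  expect_setequal(unique(asg$subtype), 1:3)
  expect_gte(mclust::adjustedRandIndex(asg$subtype, truth_lab), 0.9)
  # dispersion profiled over the whole k range
  expect_equal(asg$dispersion$k, 2:8)
  expect_true(all(diff(asg$dispersion$within_ss) <= 1e-9))
  expect_error(cluster_subtypes(m, k = 1), "outside")
  # a duplicated sample lands in the same cluster as its twin
  x2 <- cbind(x, t76 = x[, "t1"])
  m2 <- expression_matrix(x2, labels = c(rep("tumor", 75),
                                         rep("normal", 10), "tumor"))
  asg2 <- cluster_subtypes(m2, k = 3)
  expect_equal(unname(asg2$subtype["t76"]), unname(asg2$subtype["t1"]))
})

test_that("a pluggable clustering backend is honored", {
  m <- shifted_em(n_tumor = 30, n_normal = 5, seed = 2)
  fake <- function(x, k) rep_len(seq_len(k), nrow(x))
  asg <- cluster_subtypes(m, k = 2, method = fake)
  expect_identical(unname(asg$subtype),
                   rep_len(1:2, 30))
  expect_identical(asg$method, "custom")
})

test_that("representative genes surface the planted subtype markers", {
  spec <- synthetic_spec(n_genes = 300, n_informative = 10,
                         n_redundant = 0, n_major = 150, n_minor = 20,
                         n_subtype_genes = 8, seed = 17)
  sim <- generate_expression(spec)
  asg <- structure(list(subtype = sim$truth$subtype_of_sample, k = 3,
                        method = "truth", dispersion = NULL),
                   class = "SubtypeAssignment")
  reps <- representative_genes(sim$matrix, asg, top_n = 20)
  expect_named(reps, c("1", "2", "3"))
  for (s in 1:3) {
    markers <- sim$truth$subtype_gene_sets[[s]]
    hits <- intersect(reps[[as.character(s)]]$gene_id, markers)
    expect_gte(length(hits), 7)
    expect_true(!is.unsorted(reps[[as.character(s)]]$p))
  }
  # top_n beyond the gene count returns the full ranked list
  all_ranked <- representative_genes(sim$matrix, asg, top_n = 1e6)
  expect_equal(nrow(all_ranked[["1"]]), nrow(sim$matrix$values))
})

test_that("PCA scores capture planted 1-D structure and are rotation
          invariant in spectrum", {
  withr::with_seed(3, {
    t_axis <- seq(0, 10, length.out = 40)
    x <- rbind(t_axis, 2 * t_axis, -t_axis) +
      matrix(rnorm(120, sd = 0.1), 3, 40)
    x <- x - min(x)
    dimnames(x) <- list(paste0("g", 1:3), paste0("s", 1:40))
  })
  m <- expression_matrix(x)
  pc <- pca_scores(m, genes = rownames(x))
  expect_gte(pc$explained_variance_ratio[1], 0.9)
  # orthogonal rotation of the gene space preserves the spectrum
  q <- qr.Q(qr(withr::with_seed(4, matrix(rnorm(9), 3, 3))))
  xr <- q %*% (x - rowMeans(x)); xr <- xr - min(xr)
  dimnames(xr) <- dimnames(x)
  pc_r <- pca_scores(expression_matrix(xr), genes = rownames(xr))
  expect_equal(pc_r$explained_variance_ratio,
               pc$explained_variance_ratio, tolerance = 1e-9)
  # duplicate samples land on identical coordinates
  xd <- cbind(x, "s41" = x[, 1])
  pc_d <- pca_scores(expression_matrix(xd), genes = rownames(x))
  expect_equal(pc_d$scores["s41", ], pc_d$scores["s1", ])
})

test_that("log-rank statistic matches the textbook oracle", {
  # identical groups (duplicated data): statistic 0, p = 1
  surv_dup <- data.frame(sample_id = paste0("s", 1:20),
                         time_days = rep(c(1, 2, 3, 4, 6), 4),
                         event = rep(c(1, 0, 1, 1, 0), 4))
  g_dup <- rep(1:2, each = 10)
  lr <- logrank_test(surv_dup, g_dup)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)
  # random small datasets against the oracle
  for (i in 1:40) {
    set.seed(i)
    n <- sample(12:30, 1)
    k <- sample(2:3, 1)
    surv <- data.frame(sample_id = paste0("s", 1:n),
                       time_days = sample(1:15, n, replace = TRUE),
                       event = rbinom(n, 1, 0.7))
    g <- sample(seq_len(k), n, replace = TRUE)
    if (length(unique(g)) < k || sum(surv$event) == 0) next
    if (any(tapply(surv$event, g, sum) == 0)) next
    lr <- logrank_test(surv, g)
    orc <- oracle_logrank(surv$time_days, surv$event, g)
    expect_equal(lr$statistic, orc$statistic, tolerance = 1e-10)
    expect_equal(lr$p, orc$p, tolerance = 1e-10)
    expect_equal(lr$df, orc$df)
  }
  expect_error(logrank_test(data.frame(sample_id = "a", time_days = 1,
                                       event = 0),
                            1), "2 groups")
})

test_that("Kaplan-Meier estimator follows the product-limit form", {
  surv <- data.frame(sample_id = paste0("s", 1:3),
                     time_days = c(1, 2, 3), event = 1L)
  km <- km_curve(surv)
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # all censored: flat at 1
  km0 <- km_curve(data.frame(sample_id = paste0("s", 1:4),
                             time_days = 1:4, event = 0L))
  expect_true(all(km0$surv == 1))
  # censoring after the last event leaves the curve unchanged at events
  s1 <- data.frame(sample_id = paste0("s", 1:4),
                   time_days = c(1, 2, 3, 9), event = c(1, 1, 1, 0))
  s2 <- data.frame(sample_id = paste0("s", 1:4),
                   time_days = c(1, 2, 3, 99), event = c(1, 1, 1, 0))
  expect_equal(km_curve(s1)$surv[1:3], km_curve(s2)$surv[1:3])
  expect_error(km_curve(data.frame(sample_id = "a", time_days = -1,
                                   event = 1)), "negative")
  # oracle agreement on random data
  for (i in 1:25) {
    set.seed(i)
    n <- sample(5:25, 1)
    time <- sample(1:12, n, replace = TRUE)
    event <- rbinom(n, 1, 0.6)
    if (sum(event) == 0) next
    km <- km_curve(data.frame(sample_id = seq_len(n), time_days = time,
                              event = event))
    orc <- oracle_km(time, event)
    expect_equal(km$surv[km$n_event > 0], orc$surv, tolerance = 1e-12)
  }
})

test_that("expression-methylation correlation flags monotone repression", {
  m <- shifted_em(n_genes = 4, n_tumor = 40, n_normal = 10, seed = 5)
  # meth = monotone decreasing transform of expression
  meth <- rbind(1 / (1 + m$values["g001", ]),
                withr::with_seed(6, runif(50)))
  rownames(meth) <- c("g001", "g002")
  colnames(meth) <- colnames(m$values)
  res <- methylation_correlation(m, meth)
  expect_setequal(res$gene_id, c("g001", "g002"))   # g003/g004 omitted
  expect_equal(res$rho[res$gene_id == "g001"], -1)
  expect_true(res$negative_flag[res$gene_id == "g001"])
  expect_false(res$negative_flag[res$gene_id == "g002"])
  # independent methylation rarely flagged (null simulation)
  withr::with_seed(7, {
    null_meth <- matrix(runif(20 * 50), 20, 50,
                        dimnames = list(sprintf("g%03d", 11:30),
                                        colnames(m$values)))
    mm <- expression_matrix(matrix(abs(rnorm(20 * 50)) + 0.1, 20, 50,
                                   dimnames = dimnames(null_meth)))
  })
  res_null <- methylation_correlation(mm, null_meth)
  expect_gte(mean(!res_null$negative_flag), 0.9)
})

test_that("mutation enrichment matches the hypergeometric oracle and finds
          planted enrichment", {
  # hand table [[10,5],[2,40]]
  st <- stats::setNames(rep(c(1L, 2L), c(15, 42)), paste0("s", 1:57))
  mut <- matrix(0L, 2, 57, dimnames = list(c("gA", "gB"), names(st)))
  mut["gA", c(paste0("s", 1:10), paste0("s", 16:17))] <- 1L
  res <- mutation_enrichment(mut, st)
  row_a <- res[res$gene == "gA" & res$subtype == "1", ]
  expect_equal(c(row_a$n_mut_in, row_a$n_wild_in, row_a$n_mut_out,
                 row_a$n_wild_out), c(10, 5, 2, 40))
  expect_equal(row_a$p, oracle_fisher_exact(10, 5, 2, 40),
               tolerance = 1e-12)
  # never-mutated gene: p = 1, still reported
  expect_true(all(res$p[res$gene == "gB"] == 1))
  # pairwise mode covers every subtype pair
  st3 <- stats::setNames(rep(1:3, each = 10), paste0("s", 1:30))
  mut3 <- matrix(rbinom(60, 1, 0.3), 2, 30,
                 dimnames = list(c("gA", "gB"), names(st3)))
  res_p <- mutation_enrichment(mut3, st3, mode = "pairwise")
  expect_setequal(unique(res_p$subtype),
                  c("1_vs_2", "1_vs_3", "2_vs_3"))
  # planted enrichment at cohort scale reaches BH significance
  spec <- synthetic_spec(n_genes = 20, n_informative = 2, n_redundant = 0,
                         n_subtype_genes = 2, n_major = 350, n_minor = 2,
                         seed = 8)
  sim <- generate_expression(spec)
  mm <- generate_mutations(sim$truth, spec)
  res_s <- quiet(mutation_enrichment(mm, sim$truth$subtype_of_sample))
  enr <- sim$truth$enriched_mutation_genes
  for (g in names(enr)) {
    hit <- res_s[res_s$gene == g & res_s$subtype == enr[[g]], ]
    expect_lt(hit$q, 0.05)
  }
})
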