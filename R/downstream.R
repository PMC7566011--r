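# Downstream characterization of a selected gene panel: tumor subtype
# clustering, per-subtype representative genes, PCA, Kaplan-Meier survival
# with the log-rank test, expression-methylation correlation, and
# per-subtype mutation enrichment by Fisher's exact test.

#' Cluster tumor samples into molecular subtypes
#'
#' Clusters tumor samples on panel-gene expression. The default backend is
#' deterministic agglomerative clustering with Ward linkage on Euclidean
#' distances; any function `(matrix, k) -> integer labels` can be plugged
#' in instead. Within-cluster dispersion (total within-cluster sum of
#' squares) is reported for every k in `k_range` so the cluster-count
#' choice can be audited.
#'
#' @param m a labeled [expression_matrix()].
#' @param panel gene identifiers to cluster on.
#' @param k number of subtypes to assign (default 3).
#' @param k_range candidate cluster counts to profile (default 2:8).
#' @param method `"ward"` (default) or a function `(x, k)` returning a
#'   label per row of the samples x genes matrix `x`.
#' @param seed RNG seed forwarded to a custom clustering function.
#' @return a `SubtypeAssignment` list: `subtype` (named integer vector over
#'   tumor samples, values in 1..k), `k`, `method`, `dispersion`
#'   (data.frame of k and within-cluster sum of squares).
#' @export
cluster_subtypes <- function(m, panel = NULL, k = 3, k_range = 2:8,
                             method = "ward", seed = 1) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (!k %in% k_range) {
    stop("k = ", k, " is outside the profiled range ",
         min(k_range), "..", max(k_range), call. = FALSE)
  }
  if (is.null(m$labels)) stop("class labels required", call. = FALSE)
  tumor <- names(m$labels)[m$labels == "tumor"]
  if (length(tumor) < k) stop("fewer tumor samples than clusters",
                              call. = FALSE)
  if (is.null(panel)) panel <- rownames(m$values)
  x <- t(m$values[panel, tumor, drop = FALSE])

  cut_at <- if (is.function(method)) {
    meth_tag <- "custom"
    function(kk) with_seed(seed, as.integer(method(x, kk)))
  } else {
    meth_tag <- "ward"
    hc <- stats::hclust(stats::dist(x), method = "ward.D2")
    function(kk) unname(stats::cutree(hc, k = kk))
  }

  wss <- function(lab) {
    sum(vapply(split(seq_len(nrow(x)), lab), function(ii) {
      xc <- x[ii, , drop = FALSE]
      sum(sweep(xc, 2L, colMeans(xc))^2)
    }, numeric(1)))
  }
  disp <- data.frame(k = k_range,
                     within_ss = vapply(k_range,
                                        function(kk) wss(cut_at(kk)),
                                        numeric(1)))
  lab <- cut_at(k)
  names(lab) <- tumor
  structure(list(subtype = lab, k = k, method = meth_tag,
                 dispersion = disp),
            class = "SubtypeAssignment")
}

# vectorized Welch two-sided t-test of group A vs group B per gene row
welch_rows <- function(xa, xb) {
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t_stat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  # zero variance in both groups: no test; equal means get p = 1
  degen <- se2 == 0
  p[degen] <- 1
  t_stat[degen] <- 0
  data.frame(t = t_stat, p = p)
}

#' Representative genes of each subtype
#'
#' Per subtype, a Welch two-sided t-test of the subtype against all other
#' tumor samples, over every gene in the matrix; the `top_n` genes with the
#' lowest p-values are returned. Lists of different subtypes may overlap.
#' Genes with zero variance in both groups are assigned p = 1 and logged.
#'
#' @param m an [expression_matrix()] (all genes, tumor samples present).
#' @param assignment a [cluster_subtypes()] result.
#' @param top_n genes to keep per subtype (default 100; clipped to the gene
#'   count).
#' @return named list (one element per subtype) of data.frames
#'   `gene_id`, `t`, `p`, ordered by ascending p.
#' @export
representative_genes <- function(m, assignment, top_n = 100) {
  stopifnot(inherits(m, "ExpressionMatrix"),
            inherits(assignment, "SubtypeAssignment"))
  st <- assignment$subtype
  if (any(table(st) < 2L)) {
    stop("every subtype needs at least 2 samples", call. = FALSE)
  }
  out <- list()
  for (s in sort(unique(st))) {
    a <- names(st)[st == s]
    b <- names(st)[st != s]
    res <- welch_rows(m$values[, a, drop = FALSE],
                      m$values[, b, drop = FALSE])
    n_degen <- sum(res$p == 1 & res$t == 0)
    if (n_degen > 0) {
      td_log(n_degen, " zero-variance gene(s) assigned p = 1 for subtype ",
             s, level = "WARN")
    }
    ord <- order(res$p)
    keep <- utils::head(ord, min(top_n, nrow(res)))
    out[[as.character(s)]] <- data.frame(gene_id = rownames(m$values)[keep],
                                         t = res$t[keep], p = res$p[keep],
                                         row.names = NULL,
                                         stringsAsFactors = FALSE)
  }
  out
}

#' PCA scores of samples on a gene set
#'
#' Centered (unscaled) principal component analysis of samples on the given
#' genes; returns the first two component scores (fewer if the matrix has
#' lower rank) and the explained-variance ratios of all components.
#'
#' @param m an [expression_matrix()].
#' @param genes gene identifiers to use (at least 2).
#' @param samples sample subset (default all).
#' @return list with `scores` (samples x components matrix) and
#'   `explained_variance_ratio`.
#' @export
pca_scores <- function(m, genes, samples = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"), length(genes) >= 2L)
  v <- m$values[genes, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  if (ncol(v) < 3L) stop("need at least 3 samples", call. = FALSE)
  pc <- stats::prcomp(t(v), center = TRUE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  n_comp <- min(2L, ncol(pc$x))
  list(scores = pc$x[, seq_len(n_comp), drop = FALSE],
       explained_variance_ratio = evr)
}

#' k-group log-rank test
#'
#' Standard log-rank comparison of survival across groups: observed minus
#' expected events per group under the hypergeometric model at each
#' distinct event time, with the usual variance estimate; the statistic is
#' chi-square with k - 1 degrees of freedom.
#'
#' @param surv a survival table: `sample_id`, `time_days`, `event`.
#' @param groups group label per row of `surv`, or a `SubtypeAssignment`
#'   matched by sample identifier.
#' @return list with `statistic`, `df`, `p`.
#' @export
logrank_test <- function(surv, groups) {
  if (inherits(groups, "SubtypeAssignment")) {
    groups <- groups$subtype[surv$sample_id]
  }
  if (any(is.na(groups))) {
    bad <- sum(is.na(groups))
    td_log(bad, " survival record(s) without a group dropped",
           level = "WARN")
    surv <- surv[!is.na(groups), , drop = FALSE]
    groups <- groups[!is.na(groups)]
  }
  if (length(unique(groups)) < 2L) stop("need at least 2 groups",
                                        call. = FALSE)
  if (sum(surv$event) == 0L) stop("no events: log-rank test undefined",
                                  call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time_days, event) ~ g,
                           data = data.frame(time_days = surv$time_days,
                                             event = surv$event,
                                             g = factor(groups)))
  df <- length(sd$n) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE))
}

#' Kaplan-Meier product-limit curve
#'
#' @param surv a survival table: `sample_id`, `time_days`, `event`.
#' @return data.frame of the step function: `time`, `n_risk`, `n_event`,
#'   `surv` (right-continuous, non-increasing, starts at 1).
#' @export
km_curve <- function(surv) {
  if (nrow(surv) == 0L) stop("empty survival table", call. = FALSE)
  if (any(surv$time_days < 0)) stop("negative survival times",
                                    call. = FALSE)
  sf <- survival::survfit(survival::Surv(surv$time_days, surv$event) ~ 1)
  data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
             surv = sf$surv)
}

#' Spearman correlation of expression with methylation
#'
#' For every gene present in both matrices, the Spearman correlation and
#' two-sided p-value over samples shared by both (inner join on sample
#' identifier); genes with a correlation below `flag_threshold` are flagged
#' as negatively regulated. Genes with fewer than 3 matched samples are
#' skipped with a log line; genes absent from the methylation matrix are
#' omitted.
#'
#' @param expr an [expression_matrix()] (typically restricted to the DEG
#'   panel).
#' @param meth methylation beta-value matrix, genes x samples.
#' @param flag_threshold negative-correlation flag cut-off (default -0.3).
#' @return data.frame: `gene_id`, `rho`, `p`, `negative_flag`.
#' @export
methylation_correlation <- function(expr, meth, flag_threshold = -0.3) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  genes <- intersect(rownames(expr$values), rownames(meth))
  shared <- intersect(colnames(expr$values), colnames(meth))
  out <- data.frame(gene_id = character(0), rho = numeric(0),
                    p = numeric(0), negative_flag = logical(0),
                    stringsAsFactors = FALSE)
  for (g in genes) {
    e <- expr$values[g, shared]
    b <- meth[g, shared]
    ok <- !is.na(e) & !is.na(b)
    if (sum(ok) < 3L) {
      td_log("gene ", g, " skipped: fewer than 3 matched samples",
             level = "WARN")
      next
    }
    ct <- suppressWarnings(stats::cor.test(e[ok], b[ok],
                                           method = "spearman",
                                           exact = FALSE))
    out <- rbind(out, data.frame(gene_id = g, rho = unname(ct$estimate),
                                 p = ct$p.value,
                                 negative_flag =
                                   unname(ct$estimate) < flag_threshold,
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Mutation enrichment per subtype by Fisher's exact test
#'
#' Groupwise mode tests, per gene and subtype, the 2x2 table (mutated vs
#' wild) x (this subtype vs rest); pairwise mode tests every subtype pair.
#' Two-sided Fisher's exact p-values are Benjamini-Hochberg adjusted within
#' the mode; a gene never mutated gets p = 1 with no test. Results are
#' sorted by ascending p.
#'
#' @param mut binary mutation matrix, genes x samples.
#' @param assignment a [cluster_subtypes()] result (or named integer vector
#'   of subtype per sample).
#' @param mode `"groupwise"` (default) or `"pairwise"`.
#' @return data.frame of `EnrichmentResult` rows: `gene`, `subtype` (or
#'   `"a_vs_b"` pair tag), contingency counts `n_mut_in`, `n_wild_in`,
#'   `n_mut_out`, `n_wild_out`, `p`, `q`.
#' @export
mutation_enrichment <- function(mut, assignment,
                                mode = c("groupwise", "pairwise")) {
  mode <- match.arg(mode)
  st <- if (inherits(assignment, "SubtypeAssignment")) assignment$subtype
        else assignment
  shared <- intersect(colnames(mut), names(st))
  if (!length(shared)) stop("no samples shared between mutation matrix and ",
                            "subtype assignment", call. = FALSE)
  if (length(shared) < length(names(st))) {
    td_log(length(names(st)) - length(shared),
           " subtyped sample(s) lack mutation data", level = "WARN")
  }
  mut <- mut[, shared, drop = FALSE]
  st <- st[shared]
  subtypes <- sort(unique(st))

  test_one <- function(g, in_cols, out_cols, tag) {
    mg <- mut[g, ]
    a <- sum(mg[in_cols]); b <- sum(in_cols) - a
    c_ <- sum(mg[out_cols]); d <- sum(out_cols) - c_
    p <- if (a + c_ == 0L) 1
         else stats::fisher.test(matrix(c(a, b, c_, d), 2L,
                                        byrow = TRUE))$p.value
    data.frame(gene = g, subtype = tag, n_mut_in = a, n_wild_in = b,
               n_mut_out = c_, n_wild_out = d, p = p,
               stringsAsFactors = FALSE)
  }

  rows <- list()
  if (mode == "groupwise") {
    for (s in subtypes) {
      in_cols <- st == s
      for (g in rownames(mut)) {
        rows[[length(rows) + 1L]] <- test_one(g, in_cols, !in_cols,
                                              as.character(s))
      }
    }
  } else {
    for (i in seq_along(subtypes)) {
      for (j in seq_along(subtypes)) {
        if (j <= i) next
        a <- subtypes[i]; b <- subtypes[j]
        keep <- st %in% c(a, b)
        for (g in rownames(mut)) {
          in_cols <- st == a & keep
          out_cols <- st == b & keep
          rows[[length(rows) + 1L]] <- test_one(g, in_cols, out_cols,
                                                paste0(a, "_vs_", b))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), , drop = FALSE]
}
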