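# Univariate relevance and redundancy filtering.
#
# Relevance: the Fisher ratio (mu1 - mu2)^2 / (var1 + var2) — between-class
# over within-class variance — keeps genes at or above a score threshold.
# Redundancy: gene pairs with |Spearman rho| above a threshold are resolved
# by the classified information index (CII)
#   d = |mu1 - mu2| / (2 (sd1 + sd2)) + log((var1 + var2) / (2 sd1 sd2)) / 2,
# which, unlike the Fisher ratio, stays positive for equal-mean genes whose
# class variances differ; the pair member with the lower CII is discarded.

#' Per-gene per-class means and variances
#'
#' @param m a labeled [expression_matrix()] with both classes present.
#' @param var_method `"unbiased"` (n - 1 denominator, default) or
#'   `"population"` (n denominator).
#' @return a `data.frame` (class `GeneClassStats`) with one row per gene:
#'   `gene_id`, `mu1`/`var1` (tumor), `mu2`/`var2` (normal), `n1`, `n2`.
#' @export
class_stats <- function(m, var_method = c("unbiased", "population")) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  var_method <- match.arg(var_method)
  if (is.null(m$labels)) stop("class labels required", call. = FALSE)
  idx1 <- which(m$labels == "tumor")
  idx2 <- which(m$labels == "normal")
  if (length(idx1) < 2L || length(idx2) < 2L) {
    stop("each class needs at least 2 samples (tumor: ", length(idx1),
         ", normal: ", length(idx2), ")", call. = FALSE)
  }
  row_var <- function(x, mu, n) {
    ss <- rowSums((x - mu)^2)
    if (var_method == "unbiased") ss / (n - 1) else ss / n
  }
  x1 <- m$values[, idx1, drop = FALSE]
  x2 <- m$values[, idx2, drop = FALSE]
  mu1 <- rowMeans(x1); mu2 <- rowMeans(x2)
  out <- data.frame(gene_id = rownames(m$values),
                    mu1 = mu1, mu2 = mu2,
                    var1 = row_var(x1, mu1, length(idx1)),
                    var2 = row_var(x2, mu2, length(idx2)),
                    n1 = length(idx1), n2 = length(idx2),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("GeneClassStats", class(out))
  out
}

#' Fisher ratio of each gene
#'
#' `(mu1 - mu2)^2 / (var1 + var2)`: the squared class-mean difference over
#' the summed class variances. Degenerate genes with zero total variance
#' score `Inf` when the means differ and 0 when they agree.
#'
#' @param stats a [class_stats()] table.
#' @return named numeric vector of scores, one per gene.
#' @export
fisher_ratio <- function(stats) {
  num <- (stats$mu1 - stats$mu2)^2
  den <- stats$var1 + stats$var2
  score <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))
  stats::setNames(score, stats$gene_id)
}

#' Select genes at or above a Fisher-ratio threshold
#'
#' Genes scoring below the threshold are deleted; a score exactly at the
#' threshold survives.
#'
#' @param scores named scores from [fisher_ratio()].
#' @param threshold minimum retained score (default 0.5).
#' @return character vector of retained gene identifiers.
#' @export
fisher_select <- function(scores, threshold = 0.5) {
  keep <- names(scores)[scores >= threshold]
  if (!length(keep)) {
    stop("no gene reaches the Fisher-ratio threshold of ", threshold,
         "; consider lowering it", call. = FALSE)
  }
  keep
}

#' Classified information index of each gene
#'
#' Two-term distinguishability score: half the standardized mean difference
#' `|mu1 - mu2| / (sd1 + sd2)` plus half the log variance-disparity
#' `log((var1 + var2) / (2 sd1 sd2))`. The second term is positive whenever
#' the class variances differ, so the index separates equal-mean genes the
#' Fisher ratio cannot. Genes with one zero class SD get `Inf` (maximal
#' distinguishability).
#'
#' @param stats a [class_stats()] table.
#' @return named numeric vector of scores.
#' @export
classified_information_index <- function(stats) {
  sd1 <- sqrt(stats$var1); sd2 <- sqrt(stats$var2)
  d <- ifelse(sd1 * sd2 > 0,
              0.5 * abs(stats$mu1 - stats$mu2) / (sd1 + sd2) +
                0.5 * log((stats$var1 + stats$var2) / (2 * sd1 * sd2)),
              Inf)
  n_degen <- sum(!is.finite(d))
  if (n_degen > 0) {
    td_log(n_degen, " gene(s) with a zero class SD scored Inf by the ",
           "classified information index", level = "WARN")
  }
  stats::setNames(d, stats$gene_id)
}

#' Spearman correlation matrix of a gene subset
#'
#' Mid-rank (average rank for ties) Spearman correlation over all samples,
#' both classes pooled. A constant gene has undefined correlation; its
#' entries are set to 0 with a warning.
#'
#' @param m an [expression_matrix()] with at least 3 samples.
#' @param genes gene identifiers to correlate (default all).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(m, genes = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (ncol(m$values) < 3L) stop("need at least 3 samples", call. = FALSE)
  v <- if (is.null(genes)) m$values else m$values[genes, , drop = FALSE]
  rho <- suppressWarnings(stats::cor(t(v), method = "spearman"))
  if (anyNA(rho)) {
    warning("constant gene(s) produced undefined correlations; set to 0",
            call. = FALSE)
    rho[is.na(rho)] <- 0
    diag(rho) <- 1
  }
  rho
}

#' Remove redundant genes by correlation, arbitrated by the CII
#'
#' Gene pairs with `|rho|` strictly above `rho_threshold` are visited in
#' order of decreasing `|rho|`; whenever both members are still retained,
#' the one with the lower classified information index is deleted (ties:
#' the lexicographically later identifier goes). After the pass no retained
#' pair exceeds the threshold.
#'
#' @param rho symmetric Spearman matrix from [spearman_matrix()].
#' @param cii named CII scores covering the genes of `rho`.
#' @param rho_threshold redundancy cut-off on `|rho|` (default 0.7).
#' @return character vector of retained gene identifiers (in `rho` order).
#' @export
redundancy_filter <- function(rho, cii, rho_threshold = 0.7) {
  genes <- rownames(rho)
  stopifnot(!is.null(genes), all(genes %in% names(cii)))
  ut <- upper.tri(rho)
  hits <- which(ut & abs(rho) > rho_threshold, arr.ind = TRUE)
  if (nrow(hits) == 0L) return(genes)
  ord <- order(-abs(rho[hits]), genes[hits[, 1L]], genes[hits[, 2L]])
  hits <- hits[ord, , drop = FALSE]
  retained <- stats::setNames(rep(TRUE, length(genes)), genes)
  for (r in seq_len(nrow(hits))) {
    a <- genes[hits[r, 1L]]; b <- genes[hits[r, 2L]]
    if (!retained[a] || !retained[b]) next
    drop <- if (cii[a] < cii[b]) a
            else if (cii[b] < cii[a]) b
            else max(a, b)  # tie: lexicographically later id goes
    retained[drop] <- FALSE
  }
  genes[retained]
}

#' Full relevance + redundancy gene filter
#'
#' Computes class statistics, applies the Fisher-ratio threshold, then
#' removes redundant genes among the survivors by Spearman correlation and
#' the classified information index.
#'
#' @param m a labeled, preprocessed [expression_matrix()].
#' @param fisher_threshold minimum Fisher ratio (default 0.5).
#' @param rho_threshold redundancy cut-off on `|rho|` (default 0.7).
#' @param var_method variance estimator passed to [class_stats()].
#' @return a list with `table` (a `GeneScoreTable` data.frame: `gene_id`,
#'   `fisher_ratio`, `cii`, `retained_after_fisher`,
#'   `retained_after_redundancy`) and `retained` (final gene identifiers).
#' @examples
#' sim <- generate_expression(synthetic_spec(n_genes = 200, n_major = 60,
#'                                           n_minor = 20, n_informative = 8,
#'                                           n_redundant = 12, seed = 7))
#' pp <- preprocess(sim$matrix, seed = 7)
#' gf <- filter_genes(pp$matrix)
#' head(gf$retained)
#' @export
filter_genes <- function(m, fisher_threshold = 0.5, rho_threshold = 0.7,
                         var_method = "unbiased") {
  stats <- class_stats(m, var_method = var_method)
  fr <- fisher_ratio(stats)
  after_fisher <- fisher_select(fr, threshold = fisher_threshold)
  cii <- classified_information_index(stats)
  rho <- spearman_matrix(m, genes = after_fisher)
  final <- redundancy_filter(rho, cii, rho_threshold = rho_threshold)
  tab <- data.frame(gene_id = stats$gene_id,
                    fisher_ratio = unname(fr),
                    cii = unname(cii),
                    retained_after_fisher = stats$gene_id %in% after_fisher,
                    retained_after_redundancy = stats$gene_id %in% final,
                    stringsAsFactors = FALSE)
  class(tab) <- c("GeneScoreTable", class(tab))
  td_log("gene filter: ", nrow(tab), " in -> ", length(after_fisher),
         " after Fisher ratio -> ", length(final), " after redundancy")
  list(table = tab, retained = final)
}
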