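# Preprocessing: three rules applied in a fixed order —
# (1) drop genes unexpressed in over half the samples,
# (2) min-max normalize each gene to [0, 1],
# (3) replace remaining zeros by a uniform draw from (0, min_nonzero/10).
# After the full pipeline every value is strictly positive and at most 1.

#' Drop genes unexpressed in more than a given fraction of samples
#'
#' A gene is removed when its zero fraction strictly exceeds
#' `frac_threshold`; a gene with zeros in exactly half the samples survives
#' the default threshold.
#'
#' @param m an [expression_matrix()].
#' @param frac_threshold maximum tolerated zero fraction (default 0.5).
#' @return a list with `matrix` (filtered `ExpressionMatrix`) and `report`
#'   (`n_genes_in`, `n_genes_dropped`, `dropped_gene_ids`).
#' @export
filter_unexpressed <- function(m, frac_threshold = 0.5) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (nrow(m$values) == 0L || ncol(m$values) == 0L) {
    stop("empty expression matrix", call. = FALSE)
  }
  zero_frac <- rowMeans(m$values == 0)
  drop <- zero_frac > frac_threshold
  if (all(drop)) {
    stop("all ", nrow(m$values), " genes exceed the zero-fraction ",
         "threshold of ", frac_threshold, call. = FALSE)
  }
  report <- list(n_genes_in = nrow(m$values),
                 n_genes_dropped = sum(drop),
                 dropped_gene_ids = rownames(m$values)[drop])
  if (report$n_genes_dropped > 0) {
    td_log(report$n_genes_dropped, " genes dropped (unexpressed in over ",
           round(100 * frac_threshold), "% of samples)")
  }
  list(matrix = em_subset(m, genes = rownames(m$values)[!drop]),
       report = report)
}

#' Min-max normalize each gene to [0, 1]
#'
#' Per gene, `x -> (x - min) / (max - min)`, so every retained gene attains
#' both 0 and 1. Constant genes cannot be rescaled and are dropped with a
#' warning.
#'
#' @param m an [expression_matrix()].
#' @return the normalized `ExpressionMatrix`; dropped constant genes are
#'   recorded in the `"dropped_constant"` attribute.
#' @export
minmax_normalize <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  rng_min <- apply(m$values, 1L, min)
  rng_max <- apply(m$values, 1L, max)
  constant <- rng_max == rng_min
  if (any(constant)) {
    warning(sum(constant), " constant gene(s) dropped during min-max ",
            "normalization: ",
            paste(utils::head(rownames(m$values)[constant], 5),
                  collapse = ", "), call. = FALSE)
  }
  keep <- !constant
  if (!any(keep)) stop("no genes left after dropping constant genes",
                       call. = FALSE)
  v <- (m$values[keep, , drop = FALSE] - rng_min[keep]) /
    (rng_max[keep] - rng_min[keep])
  out <- expression_matrix(v, labels = m$labels)
  attr(out, "dropped_constant") <- rownames(m$values)[constant]
  out
}

#' Replace zero entries by small positive jitter
#'
#' Every zero of gene `g` becomes an independent uniform draw from the open
#' interval `(0, min_g / 10)`, where `min_g` is the gene's smallest non-zero
#' value. Genes with no non-zero value cannot define the interval and are an
#' error (they should have been removed by [filter_unexpressed()]).
#'
#' @param m an [expression_matrix()].
#' @param seed RNG seed for the replacement draws.
#' @return a list with `matrix` (zero-free `ExpressionMatrix`) and `report`
#'   (`n_zeros_replaced`, `seed`).
#' @export
replace_zeros <- function(m, seed = 1) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  v <- m$values
  zero_idx <- which(v == 0)
  if (length(zero_idx)) {
    all_zero <- rowSums(v != 0) == 0
    if (any(all_zero)) {
      stop("gene(s) with all-zero expression cannot be jittered: ",
           paste(utils::head(rownames(v)[all_zero], 5), collapse = ", "),
           "; run filter_unexpressed() first", call. = FALSE)
    }
    min_nz <- apply(v, 1L, function(x) min(x[x != 0]))
    rows <- ((zero_idx - 1L) %% nrow(v)) + 1L
    v[zero_idx] <- with_seed(seed, {
      u <- stats::runif(length(zero_idx), 0, min_nz[rows] / 10)
      # runif draws from [0, b); resample the measure-zero endpoint so the
      # interval is genuinely open
      while (any(u == 0)) u[u == 0] <- stats::runif(sum(u == 0), 0,
                                                    min_nz[rows][u == 0] / 10)
      u
    })
  }
  list(matrix = expression_matrix(v, labels = m$labels),
       report = list(n_zeros_replaced = length(zero_idx), seed = seed))
}

#' Run the full preprocessing pipeline
#'
#' Applies, in order: unexpressed-gene filtering, per-gene min-max
#' normalization (constant genes dropped), and zero replacement. With
#' `zeros_before_normalize = TRUE` the last two steps are swapped, so the
#' jitter interval is computed from raw rather than normalized values.
#'
#' @param m an [expression_matrix()].
#' @param frac_threshold zero-fraction threshold for gene dropping.
#' @param seed RNG seed for zero replacement.
#' @param zeros_before_normalize replace zeros before normalizing
#'   (default `FALSE`: filter, normalize, then replace).
#' @return a list with `matrix` (the preprocessed `ExpressionMatrix`, all
#'   values in (0, 1\]) and `report` (a `PreprocessReport`:
#'   `n_genes_in`, `n_genes_dropped`, `n_zeros_replaced`, `seed`).
#' @examples
#' sim <- generate_expression(synthetic_spec(n_genes = 60, n_major = 30,
#'                                           n_minor = 10, n_informative = 5,
#'                                           n_redundant = 5, seed = 1))
#' pp <- preprocess(sim$matrix, seed = 1)
#' pp$report$n_zeros_replaced
#' @export
preprocess <- function(m, frac_threshold = 0.5, seed = 1,
                       zeros_before_normalize = FALSE) {
  f <- filter_unexpressed(m, frac_threshold)
  if (zeros_before_normalize) {
    z <- replace_zeros(f$matrix, seed = seed)
    norm <- minmax_normalize(z$matrix)
    n_const <- length(attr(norm, "dropped_constant") %||% character(0))
  } else {
    norm0 <- minmax_normalize(f$matrix)
    n_const <- length(attr(norm0, "dropped_constant") %||% character(0))
    z <- replace_zeros(norm0, seed = seed)
    norm <- z$matrix
  }
  list(matrix = norm,
       report = list(n_genes_in = f$report$n_genes_in,
                     n_genes_dropped = f$report$n_genes_dropped + n_const,
                     n_zeros_replaced = z$report$n_zeros_replaced,
                     seed = seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
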