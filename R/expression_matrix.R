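# The ExpressionMatrix container: a non-negative genes x samples matrix with
# unique gene/sample identifiers and an optional per-sample tumor/normal
# label. Deliberately a light S3 wrapper around a base matrix so that every
# numeric routine can work on `m$values` directly.

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, genes as rows and samples as columns, with
#'   unique rownames (gene identifiers) and colnames (sample identifiers).
#'   Values must be non-negative; `NA` entries are coerced to 0 and counted.
#' @param labels optional per-sample class labels, `"tumor"` or `"normal"`,
#'   either in column order or named by sample identifier.
#' @return an object of class `ExpressionMatrix`: a list with elements
#'   `values` (the matrix) and `labels` (character vector or `NULL`).
#' @examples
#' x <- matrix(rexp(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' m <- expression_matrix(x, labels = c("tumor", "tumor", "normal", "normal"))
#' dim(m)
#' @export
expression_matrix <- function(values, labels = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry gene rownames and sample colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1L]
    stop("duplicate gene identifier: ", dup, call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    dup <- colnames(values)[duplicated(colnames(values))][1L]
    stop("duplicate sample identifier: ", dup, call. = FALSE)
  }
  n_na <- sum(is.na(values))
  if (n_na > 0L) {
    td_log(n_na, " missing entries coerced to 0", level = "WARN")
    values[is.na(values)] <- 0
  }
  if (any(values < 0)) {
    stop("expression values must be non-negative", call. = FALSE)
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (!is.null(names(labels))) labels <- labels[colnames(values)]
    if (length(labels) != ncol(values)) {
      stop("`labels` must cover every sample", call. = FALSE)
    }
    bad <- setdiff(unique(labels), c("tumor", "normal"))
    if (length(bad)) {
      stop("labels must be 'tumor' or 'normal'; found: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    names(labels) <- colnames(values)
  }
  structure(list(values = values, labels = labels),
            class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Subset an ExpressionMatrix by genes and/or samples
#'
#' @param m an `ExpressionMatrix`.
#' @param genes gene identifiers or row indices to keep (default all).
#' @param samples sample identifiers or column indices to keep (default all).
#' @return the subsetted `ExpressionMatrix`.
#' @export
em_subset <- function(m, genes = NULL, samples = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  v <- m$values
  if (!is.null(genes)) {
    if (is.character(genes) && !all(genes %in% rownames(v))) {
      stop("unknown gene identifier(s): ",
           paste(utils::head(setdiff(genes, rownames(v)), 3), collapse = ", "),
           call. = FALSE)
    }
    v <- v[genes, , drop = FALSE]
  }
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  expression_matrix(v, labels = if (is.null(m$labels)) NULL
                    else m$labels[colnames(v)])
}

# samples x genes data.frame view used by the classifiers
em_design <- function(m, genes = NULL, samples = NULL) {
  v <- m$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  as.data.frame(t(v))
}
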