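# File I/O for the pipeline's plain-text dialects: expression TSV/CSV
# (genes as rows, first column the gene identifier, header of sample
# identifiers), two-column label TSV, survival TSV, minimal MAF, binary
# mutation matrix TSV, and JSON for ground truth / reports / manifests.

detect_sep <- function(path, dialect = c("auto", "tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") return("\t")
  if (dialect == "csv") return(",")
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an expression matrix from TSV/CSV
#'
#' Expects genes as rows, the first column holding gene identifiers and the
#' header row holding sample identifiers. The dialect is auto-detected from
#' the extension (`.csv` = comma, else tab) and can be overridden. Missing
#' entries are coerced to 0 and counted; duplicate identifiers, ragged rows
#' and negative values are errors.
#'
#' @param path expression file.
#' @param dialect `"auto"` (default), `"tsv"` or `"csv"`.
#' @param labels_path optional two-column label file (`sample_id`, `label`
#'   in `{tumor, normal}`).
#' @return an [expression_matrix()].
#' @export
load_expression <- function(path, dialect = "auto", labels_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- detect_sep(path, dialect)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  gene_ids <- as.character(df[[1L]])
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene row: ", gene_ids[duplicated(gene_ids)][1L],
         call. = FALSE)
  }
  v <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(v)) stop("non-numeric expression values in ", path,
                           call. = FALSE)
  rownames(v) <- gene_ids
  labels <- if (!is.null(labels_path)) load_labels(labels_path) else NULL
  expression_matrix(v, labels = labels)
}

#' Write an expression matrix as TSV
#'
#' @param m an [expression_matrix()].
#' @param path output file; first column `gene_id`, then one column per
#'   sample.
#' @export
write_expression <- function(m, path) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  df <- data.frame(gene_id = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read/write sample labels
#'
#' Two-column TSV: `sample_id`, `label` in `{tumor, normal}`.
#' @param path label file.
#' @return named character vector of labels.
#' @export
load_labels <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stats::setNames(as.character(df$label), df$sample_id)
}

#' @rdname load_labels
#' @param labels named label vector.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(data.frame(sample_id = names(labels),
                                label = unname(labels)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write survival tables
#'
#' TSV with columns `sample_id`, `time_days`, `event`.
#' @param path survival file.
#' @return data.frame with those columns.
#' @export
load_survival <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "time_days", "event")
  if (!all(need %in% colnames(df))) {
    stop("survival table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  df[need]
}

#' @rdname load_survival
#' @param surv survival data.frame.
#' @export
write_survival <- function(surv, path) {
  utils::write.table(surv, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a minimal MAF into a binary mutation matrix
#'
#' Requires at least the columns `Hugo_Symbol` and `Tumor_Sample_Barcode`;
#' records are collapsed to a binary gene x sample indicator matrix.
#'
#' @param path tab-separated MAF-style file.
#' @return binary matrix, genes x samples.
#' @export
load_maf <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("Hugo_Symbol", "Tumor_Sample_Barcode")
  if (!all(need %in% colnames(df))) {
    stop("MAF must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  genes <- sort(unique(df$Hugo_Symbol))
  samples <- sort(unique(df$Tumor_Sample_Barcode))
  m <- matrix(0L, length(genes), length(samples),
              dimnames = list(genes, samples))
  m[cbind(match(df$Hugo_Symbol, genes),
          match(df$Tumor_Sample_Barcode, samples))] <- 1L
  m
}

#' Write a mutation matrix as MAF-style records and as a binary matrix
#'
#' @param mut binary mutation matrix (genes x samples).
#' @param maf_path output for the two-column MAF-style records (one row per
#'   mutated gene/sample pair).
#' @param matrix_path optional output for the full binary matrix TSV.
#' @export
write_mutations <- function(mut, maf_path, matrix_path = NULL) {
  hits <- which(mut == 1L, arr.ind = TRUE)
  utils::write.table(data.frame(Hugo_Symbol = rownames(mut)[hits[, 1L]],
                                Tumor_Sample_Barcode =
                                  colnames(mut)[hits[, 2L]]),
                     maf_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(matrix_path)) {
    utils::write.table(data.frame(gene_id = rownames(mut), mut,
                                  check.names = FALSE),
                       matrix_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(maf_path)
}

#' Write ground truth as JSON
#' @param truth ground-truth list from [generate_expression()].
#' @param path output JSON file.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
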