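#' Construct an expression matrix
#'
#' Container for a cells x genes matrix of nonnegative normalized expression
#' values (CPM/TPM/RPKM/FPKM or similar). Rows are cells, columns are genes;
#' all downstream code assumes this orientation.
#'
#' @param values Numeric matrix, m cells x n genes, with unique row names
#'   (cell ids) and column names (gene ids).
#' @param unit Free-text tag describing the expression unit (e.g. "TPM").
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `cell_ids`, `gene_ids`, `unit`.
#' @examples
#' v <- matrix(c(1, 0, 2, 3, 5, 8), nrow = 3,
#'             dimnames = list(paste0("c", 1:3), c("g1", "g2")))
#' x <- expression_matrix(v, unit = "TPM")
#' n_cells(x); n_genes(x)
#' @export
expression_matrix <- function(values, unit = "unknown") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have row names (cell ids) and column names (gene ids)")
  x <- structure(
    list(values = values,
         cell_ids = rownames(values),
         gene_ids = colnames(values),
         unit = as.character(unit)[1]),
    class = "ExpressionMatrix")
  validate_expression_matrix(x)
}

validate_expression_matrix <- function(x) {
  v <- x$values
  if (anyNA(v))
    stop("expression matrix contains missing values; they are rejected, not imputed")
  if (any(!is.finite(v)))
    stop("expression matrix contains non-finite values")
  if (any(v < 0))
    stop("expression matrix contains negative values; expected nonnegative normalized expression")
  if (anyDuplicated(x$cell_ids))
    stop("duplicate cell ids: ", paste(unique(x$cell_ids[duplicated(x$cell_ids)]), collapse = ", "))
  if (anyDuplicated(x$gene_ids))
    stop("duplicate gene ids: ", paste(unique(x$gene_ids[duplicated(x$gene_ids)]), collapse = ", "))
  if (length(x$cell_ids) != nrow(v) || length(x$gene_ids) != ncol(v))
    stop("id lengths do not match matrix dimensions")
  x
}

#' @rdname expression_matrix
#' @param x An `ExpressionMatrix`.
#' @export
n_cells <- function(x) nrow(x$values)

#' @rdname expression_matrix
#' @export
n_genes <- function(x) ncol(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d cells x %d genes [%s]\n",
              n_cells(x), n_genes(x), x$unit))
  invisible(x)
}

#' Read an expression matrix from delimited text or MatrixMarket
#'
#' CSV/TSV files must carry a header row of gene ids and a first column of
#' cell ids (when `orientation = "genes_by_cells"`, the roles are swapped and
#' the matrix is transposed on read). MatrixMarket input needs companion
#' one-id-per-line name files for the rows and columns of the sparse matrix.
#'
#' @param path Path to the matrix file.
#' @param format One of `"csv"`, `"tsv"`, `"mtx"`. Defaults to a guess from
#'   the file extension.
#' @param orientation `"cells_by_genes"` (default) if rows of the file are
#'   cells, `"genes_by_cells"` if rows are genes.
#' @param gene_file,cell_file For `format = "mtx"`: paths to the gene and cell
#'   name files; default `genes.txt` / `cells.txt` next to `path`.
#' @param unit Expression-unit tag stored on the result.
#' @return An [expression_matrix()] in the internal cells x genes orientation.
#' @export
read_expression <- function(path,
                            format = c("csv", "tsv", "mtx"),
                            orientation = c("cells_by_genes", "genes_by_cells"),
                            gene_file = NULL, cell_file = NULL,
                            unit = "unknown") {
  if (missing(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx",
                     stop("cannot guess format from extension of ", path,
                          "; pass `format` explicitly"))
  }
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)

  if (format == "mtx") {
    if (is.null(gene_file)) gene_file <- file.path(dirname(path), "genes.txt")
    if (is.null(cell_file)) cell_file <- file.path(dirname(path), "cells.txt")
    if (!file.exists(gene_file)) stop("gene name file not found: ", gene_file)
    if (!file.exists(cell_file)) stop("cell name file not found: ", cell_file)
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(gene_file)
    cells <- readLines(cell_file)
    if (orientation == "genes_by_cells") {
      if (nrow(m) != length(genes) || ncol(m) != length(cells))
        stop("mtx dimensions do not match name files (genes x cells expected)")
      dimnames(m) <- list(genes, cells)
      m <- t(m)
    } else {
      if (nrow(m) != length(cells) || ncol(m) != length(genes))
        stop("mtx dimensions do not match name files (cells x genes expected)")
      dimnames(m) <- list(cells, genes)
    }
    return(expression_matrix(m, unit = unit))
  }

  sep <- if (format == "csv") "," else "\t"
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                      check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("parse error reading ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  bad <- which(!vapply(df, is.numeric, logical(1)))
  if (length(bad))
    stop("non-numeric column(s) in ", path, ": ",
         paste(colnames(df)[bad], collapse = ", "))
  m <- as.matrix(df)
  if (orientation == "genes_by_cells") m <- t(m)
  expression_matrix(m, unit = unit)
}

#' Write an expression matrix as CSV (cells x genes, header = gene ids)
#'
#' @param x An `ExpressionMatrix`.
#' @param path Output path.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  # fixed %.17g formatting so a CSV round-trip reproduces doubles exactly
  vchr <- matrix(sprintf("%.17g", x$values), nrow = nrow(x$values))
  df <- data.frame(cell_id = x$cell_ids, vchr,
                   check.names = FALSE, row.names = NULL)
  colnames(df) <- c("cell_id", x$gene_ids)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Log-transform an expression matrix
#'
#' Elementwise `log(1 + v)`. The unit tag is suffixed with `"+log1p"`.
#'
#' @param x An `ExpressionMatrix`.
#' @return A transformed `ExpressionMatrix`.
#' @export
log_transform <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  v <- log1p(x$values)
  dimnames(v) <- dimnames(x$values)
  expression_matrix(v, unit = paste0(x$unit, "+log1p"))
}

#' Drop genes expressed in too few cells
#'
#' Optional coarse filter (default threshold 0 keeps everything): a gene is
#' kept if it is nonzero in at least `min_cells` cells.
#'
#' @param x An `ExpressionMatrix`.
#' @param min_cells Minimum number of cells with nonzero expression.
#' @export
filter_min_cells <- function(x, min_cells = 0) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (min_cells <= 0) return(x)
  keep <- colSums(x$values > 0) >= min_cells
  if (!any(keep)) stop("min_cells filter removed every gene")
  expression_matrix(x$values[, keep, drop = FALSE], unit = x$unit)
}

#' Construct a gene set
#'
#' An ordered list of selected gene ids with aligned selection scores
#' (typically MDA). Kept sorted by descending score, ties broken by gene id.
#'
#' @param gene_ids Character vector of gene ids (no duplicates).
#' @param scores Numeric vector aligned to `gene_ids`.
#' @return Object of class `GeneSet`.
#' @export
gene_set <- function(gene_ids = character(), scores = numeric()) {
  gene_ids <- as.character(gene_ids)
  scores <- as.numeric(scores)
  if (length(gene_ids) != length(scores))
    stop("gene_ids and scores must align")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids in gene set")
  ord <- order(-scores, gene_ids)
  structure(list(gene_ids = gene_ids[ord], scores = scores[ord]),
            class = "GeneSet")
}

#' @export
print.GeneSet <- function(x, ...) {
  cat(sprintf("GeneSet: %d genes\n", length(x$gene_ids)))
  if (length(x$gene_ids)) {
    k <- min(5L, length(x$gene_ids))
    cat(paste(sprintf("  %s\t%.5g", x$gene_ids[seq_len(k)],
                      x$scores[seq_len(k)]), collapse = "\n"), "\n")
    if (length(x$gene_ids) > k) cat("  ...\n")
  }
  invisible(x)
}

#' @export
length.GeneSet <- function(x) length(x$gene_ids)

#' Write a gene set as two-column TSV
#'
#' Columns `gene_id` and `score`, in descending score order (ties by gene id).
#' An empty gene set writes the header only.
#'
#' @param gs A `GeneSet`.
#' @param path Output path.
#' @export
write_gene_set <- function(gs, path) {
  stopifnot(inherits(gs, "GeneSet"))
  df <- data.frame(gene_id = gs$gene_ids, score = gs$scores)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gene set written by [write_gene_set()]
#' @param path Path to the TSV.
#' @export
read_gene_set <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  gene_set(df$gene_id, df$score)
}

#' Read / write per-cell labels
#'
#' Two-column CSV with header `cell_id,label`. Returns a character vector
#' named by cell id.
#'
#' @param path Path to the CSV.
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (ncol(df) < 2) stop("label file needs columns cell_id,label: ", path)
  stats::setNames(as.character(df[[2]]), df[[1]])
}

#' @rdname read_labels
#' @param labels Character/factor vector of labels, named by cell id.
#' @export
write_labels <- function(labels, path) {
  df <- data.frame(cell_id = if (is.null(names(labels)))
    seq_along(labels) else names(labels),
    label = as.character(labels))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
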