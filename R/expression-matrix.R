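#' Expression matrix with sample metadata
#'
#' The central data container of the pipeline: a genes x samples matrix of
#' (typically log2-scale) expression values plus a sample sheet describing
#' tissue of origin, tumor/normal condition and patient pairing.
#'
#' @param values Numeric matrix, genes in rows (rownames are gene ids),
#'   samples in columns (colnames are sample ids).
#' @param samples Data frame with columns `sample_id`, `tissue`, `condition`
#'   (one of `"tumor"`, `"normal"`) and `patient_id`, one row per column of
#'   `values`, in column order.
#' @param check Validate pairing invariants (each patient carries exactly one
#'   tumor and one normal sample). Disable for partially-built objects.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   and `samples`.
#' @export
#' @examples
#' v <- matrix(rnorm(8), 2, 4, dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
#' sm <- data.frame(sample_id = paste0("s", 1:4),
#'                  tissue = "gastric",
#'                  condition = rep(c("tumor", "normal"), 2),
#'                  patient_id = rep(c("p1", "p2"), each = 2))
#' em <- expr_matrix(v, sm)
expr_matrix <- function(values, samples, check = TRUE) {
  if (!is.matrix(values) || !is.numeric(values)) abort("values must be a numeric matrix")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    abort("values must carry unique rownames (gene ids)")
  req <- c("sample_id", "tissue", "condition", "patient_id")
  if (!all(req %in% names(samples))) {
    abort("sample sheet must contain columns: ", paste(req, collapse = ", "))
  }
  samples <- as.data.frame(samples)[, req]
  if (nrow(samples) != ncol(values)) abort("sample sheet rows must match matrix columns")
  if (is.null(colnames(values))) colnames(values) <- samples$sample_id
  if (!identical(colnames(values), as.character(samples$sample_id)))
    abort("matrix colnames must equal sample sheet sample_id, in order")
  if (!all(samples$condition %in% c("tumor", "normal")))
    abort("condition must be 'tumor' or 'normal'")
  if (check) {
    key <- paste(samples$patient_id, samples$condition)
    if (anyDuplicated(key)) abort("(patient_id, condition) pairs must be unique")
    tab <- table(samples$patient_id, samples$condition)
    if (ncol(tab) == 2 && !all(tab == 1L))
      abort("each patient must have exactly one tumor and one normal sample")
  }
  structure(list(values = values, samples = samples), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%d tissue(s))\n",
              nrow(x$values), ncol(x$values), length(unique(x$samples$tissue))))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by samples and/or genes
#'
#' @param x An `expr_matrix`.
#' @param genes Optional character vector of gene ids to keep.
#' @param tissue Optional tissue label(s) to keep.
#' @param condition Optional condition to keep (`"tumor"` / `"normal"`).
#' @return A new `expr_matrix` (pairing invariants are not re-enforced since
#'   a condition subset deliberately breaks pairing).
#' @export
subset_expr <- function(x, genes = NULL, tissue = NULL, condition = NULL) {
  keep <- rep(TRUE, ncol(x$values))
  if (!is.null(tissue)) keep <- keep & x$samples$tissue %in% tissue
  if (!is.null(condition)) keep <- keep & x$samples$condition %in% condition
  v <- x$values[, keep, drop = FALSE]
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(v))
    if (length(missing)) abort("genes absent from matrix: ", paste(utils::head(missing, 3), collapse = ", "))
    v <- v[genes, , drop = FALSE]
  }
  expr_matrix(v, x$samples[keep, , drop = FALSE], check = FALSE)
}

#' Read / write an expression matrix as TSV
#'
#' The matrix is a plain gene x sample TSV with gene ids in the first column;
#' the sample sheet is a four-column TSV (`sample_id`, `tissue`, `condition`,
#' `patient_id`).
#'
#' @param matrix_path,samples_path File paths.
#' @param x An `expr_matrix`.
#' @return `read_expr_tsv` returns an `expr_matrix`; `write_expr_tsv`
#'   invisibly returns the input.
#' @export
read_expr_tsv <- function(matrix_path, samples_path) {
  tab <- utils::read.delim(matrix_path, check.names = FALSE, stringsAsFactors = FALSE)
  v <- as.matrix(tab[, -1, drop = FALSE])
  rownames(v) <- tab[[1]]
  sm <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  expr_matrix(v, sm)
}

#' @rdname read_expr_tsv
#' @export
write_expr_tsv <- function(x, matrix_path, samples_path) {
  tab <- data.frame(gene_id = rownames(x$values), x$values, check.names = FALSE)
  utils::write.table(tab, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$samples, samples_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}
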