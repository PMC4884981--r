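# Normalization, reshaping and the clustering distance used throughout.

#' Quantile-normalize a matrix, optionally within sample groups
#'
#' Within each group of columns, every column is forced onto the common
#' distribution given by the cross-column mean of order statistics.  The
#' default grouping is per tissue when an [expr_matrix()] is supplied, since
#' normalization is carried out separately for each tissue type; pass
#' `grouping = NULL` on a plain matrix (or a single-level factor) for a
#' global normalization.
#'
#' @param x Numeric matrix (genes x samples) or an `expr_matrix`.
#' @param grouping Factor/vector over columns defining normalization groups;
#'   defaults to the sample tissues for an `expr_matrix` and to one global
#'   group for a plain matrix.  Each group needs >= 2 columns.
#' @return Object of the same type as `x` with normalized values.
#' @export
#' @examples
#' quantile_normalize(cbind(a = c(1, 2, 3), b = c(4, 5, 6)))
quantile_normalize <- function(x, grouping = NULL) {
  if (inherits(x, "expr_matrix")) {
    if (is.null(grouping)) grouping <- x$samples$tissue
    out <- x
    out$values <- quantile_normalize(x$values, grouping)
    return(out)
  }
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)
    abort("non-finite intensity at [", bad[1, 1], ",", bad[1, 2], "] (",
          nrow(bad), " cell(s) total)")
  }
  if (is.null(grouping)) grouping <- rep(1L, ncol(x))
  if (length(grouping) != ncol(x)) abort("grouping must have one entry per column")
  out <- x
  for (g in unique(grouping)) {
    cols <- which(grouping == g)
    if (length(cols) < 2) abort("group '", g, "' has fewer than 2 samples")
    m <- x[, cols, drop = FALSE]
    ranks <- apply(m, 2, rank, ties.method = "first")
    ref <- rowMeans(apply(m, 2, sort))
    for (j in seq_along(cols)) out[, cols[j]] <- ref[ranks[, j]]
  }
  out
}

#' Log2-transform positive intensities
#'
#' @param x Numeric matrix of intensities.
#' @param floor Optional positive floor substituted for values `<= 0`; by
#'   default non-positive values are an error.
#' @return Elementwise `log2(x)`.
#' @export
log2_transform <- function(x, floor = NULL) {
  stopifnot_finite(x, "intensity matrix")
  if (any(x <= 0)) {
    if (is.null(floor)) {
      abort(sum(x <= 0), " non-positive value(s); supply `floor` to clamp them")
    }
    if (floor <= 0) abort("floor must be positive")
    x[x <= 0] <- floor
  }
  log2(x)
}

#' Collapse probe-level values to gene level
#'
#' @param probe_matrix Numeric matrix, probes in rows (rownames = probe ids).
#' @param probe_to_gene Named character vector mapping probe id -> gene id
#'   (at most one gene per probe).  Probes absent from the map are dropped
#'   with a message.
#' @param method Summary per gene and sample: `"mean"` (default), `"median"`
#'   or `"max"`.
#' @return Gene x sample matrix.
#' @export
collapse_probes <- function(probe_matrix, probe_to_gene, method = c("mean", "median", "max")) {
  method <- match.arg(method)
  if (length(probe_to_gene) == 0) abort("empty probe-to-gene mapping")
  if (is.null(names(probe_to_gene))) abort("probe_to_gene must be named by probe id")
  mapped <- intersect(rownames(probe_matrix), names(probe_to_gene))
  dropped <- nrow(probe_matrix) - length(mapped)
  if (dropped > 0) message(dropped, " unmapped probe(s) dropped")
  if (length(mapped) == 0) abort("no probes map to any gene")
  m <- probe_matrix[mapped, , drop = FALSE]
  gene <- probe_to_gene[mapped]
  fun <- switch(method, mean = mean, median = stats::median, max = max)
  out <- do.call(rbind, lapply(split(seq_along(gene), gene), function(idx) {
    apply(m[idx, , drop = FALSE], 2, fun)
  }))
  out[order(rownames(out)), , drop = FALSE]
}

#' Center each gene row on its median
#'
#' Even-length rows use the midpoint (mean-of-two-middle-values) median
#' convention of [stats::median()].
#'
#' @param x Numeric matrix (genes x rows) or `expr_matrix`.
#' @return Same type as `x`, every row with median 0.
#' @export
median_center <- function(x) {
  if (inherits(x, "expr_matrix")) {
    x$values <- median_center(x$values)
    return(x)
  }
  stopifnot_finite(x, "matrix")
  x - apply(x, 1, stats::median)
}

#' Centered Pearson correlation distance
#'
#' `d = 1 - r`, the distance used for hierarchical clustering of expression
#' profiles; ranges over `[0, 2]`.
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return Distance in `[0, 2]`.
#' @export
#' @examples
#' centered_pearson_distance(c(1, 2, 3), c(1, 3, 2))  # 0.5
centered_pearson_distance <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) abort("vectors must have equal length >= 3")
  stopifnot_finite(c(x, y), "input vectors")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    abort("zero-variance vector: correlation distance undefined")
  1 - stats::cor(x, y)
}

#' Complete-linkage hierarchical clustering under correlation distance
#'
#' Rows of `x` are the items; pairwise distances are `1 - r` (centered
#' Pearson), the merge criterion is complete linkage (maximum inter-cluster
#' distance).  Agglomeration is delegated to [stats::hclust()], which is
#' deterministic for a fixed distance matrix.
#'
#' @param x Numeric matrix with >= 2 rows; every row needs nonzero variance.
#' @param distance `"pearson"` (default) or `"euclidean"` (fallback used for
#'   short rows where a correlation is undefined).
#' @return An [stats::hclust] tree.
#' @export
hierarchical_cluster <- function(x, distance = c("pearson", "euclidean")) {
  distance <- match.arg(distance)
  if (nrow(x) < 2) abort("need >= 2 items to cluster")
  if (distance == "pearson") {
    if (ncol(x) < 3) abort("pearson distance needs >= 3 columns; use distance = 'euclidean'")
    sds <- apply(x, 1, stats::sd)
    if (any(sds == 0)) {
      abort("zero-variance row(s): ", paste(utils::head(rownames(x)[sds == 0], 3), collapse = ", "))
    }
    d <- stats::as.dist(1 - stats::cor(t(x)))
  } else {
    d <- stats::dist(x)
  }
  stats::hclust(d, method = "complete")
}

#' Export a merge tree in Newick text form
#'
#' @param hc An [stats::hclust] tree.
#' @param path Optional output file; when `NULL` the Newick string is
#'   returned.
#' @return Newick string (invisibly when written to `path`).
#' @export
write_tree_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}
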