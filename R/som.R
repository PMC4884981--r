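# Batch self-organizing map on a hexagonal lattice, tissue-specific unit
# selection and unit-gene enrichment.

# Cartesian positions of units on a hex (offset) lattice, row-major ids.
hex_positions <- function(rows, cols) {
  r <- rep(seq_len(rows), each = cols)
  c <- rep(seq_len(cols), times = rows)
  cbind(x = c + 0.5 * ((r - 1) %% 2), y = (r - 1) * sqrt(3) / 2)
}

#' Train a batch self-organizing map on gene expression profiles
#'
#' Genes are the observations and samples the features.  Prototypes are
#' initialized from a seeded sample of the data rows and updated with batch
#' rule: each prototype becomes the Gaussian-neighborhood-weighted mean of
#' all observations, with neighborhood width `sigma` decaying linearly from
#' `max(rows, cols) / 2` to 0.5 over the epochs.  Training is deterministic
#' for a fixed seed; the per-epoch quantization error (mean distance of each
#' observation to its best-matching unit) is recorded in `qe_history`.
#'
#' @param x Numeric matrix (genes x samples), finite.
#' @param rows,cols Grid dimensions (default 13 x 9; `rows * cols >= 4`).
#' @param epochs Training epochs (default 50).
#' @param sigma0,sigma_final Start/end neighborhood widths (lattice units);
#'   `sigma0` defaults to `max(rows, cols) / 2`.
#' @param seed Integer seed for prototype initialization.
#' @return A `som_grid`: `rows`, `cols`, `prototypes` (units x features,
#'   unit ids row-major from 1), `positions`, `qe_history`.
#' @export
train_som <- function(x, rows = 13, cols = 9, epochs = 50,
                      sigma0 = NULL, sigma_final = 0.5, seed = 1) {
  if (!all(is.finite(x))) abort("non-finite values in SOM input")
  n_units <- rows * cols
  if (n_units < 4) abort("grid must have rows * cols >= 4")
  if (nrow(x) < n_units) warning("fewer genes than units; some units will be empty")
  if (is.null(sigma0)) sigma0 <- max(rows, cols) / 2
  pos <- hex_positions(rows, cols)
  # squared lattice distances between units
  d2 <- as.matrix(stats::dist(pos))^2
  proto <- local_seed(seed, {
    x[sample(seq_len(nrow(x)), n_units, replace = nrow(x) < n_units), , drop = FALSE]
  })
  rownames(proto) <- NULL
  qe <- numeric(epochs)
  sigmas <- seq(sigma0, sigma_final, length.out = epochs)
  for (e in seq_len(epochs)) {
    bmu <- nearest_prototype(x, proto)
    qe[e] <- mean(sqrt(rowSums((x - proto[bmu$unit, , drop = FALSE])^2)))
    h <- exp(-d2 / (2 * sigmas[e]^2))        # units x units neighborhood
    # batch update: weighted mean of observations per unit
    hb <- h[, bmu$unit, drop = FALSE]        # units x observations
    denom <- rowSums(hb)
    num <- hb %*% x
    upd <- denom > 0
    proto[upd, ] <- num[upd, , drop = FALSE] / denom[upd]
  }
  structure(list(rows = rows, cols = cols, prototypes = proto, positions = pos,
                 qe_history = qe, sigma = c(sigma0, sigma_final), epochs = epochs),
            class = "som_grid")
}

# BMU of each row of x against prototypes; ties go to the lowest unit id.
nearest_prototype <- function(x, proto) {
  # squared distances via the expansion ||a-b||^2 = ||a||^2 - 2ab + ||b||^2
  cross <- x %*% t(proto)
  d2 <- outer(rowSums(x^2), rep(1, nrow(proto))) - 2 * cross +
    outer(rep(1, nrow(x)), rowSums(proto^2))
  d2[d2 < 0] <- 0
  unit <- max.col(-d2, ties.method = "first")
  list(unit = unit, dist = sqrt(d2[cbind(seq_len(nrow(x)), unit)]))
}

#' Assign each gene to its best-matching unit
#'
#' @param grid A [train_som()] grid.
#' @param x Numeric matrix (genes x samples) with the grid's feature
#'   dimensionality.
#' @return Data frame: `gene_id`, `unit`, `distance`.
#' @export
assign_bmu <- function(grid, x) {
  if (ncol(x) != ncol(grid$prototypes)) abort("feature dimension mismatch")
  b <- nearest_prototype(x, grid$prototypes)
  data.frame(gene_id = rownames(x), unit = b$unit, distance = b$dist,
             stringsAsFactors = FALSE)
}

#' Per-unit, per-tissue overall expression summaries
#'
#' For every non-empty unit and every tissue: the mean over member genes of
#' each gene's mean expression across that tissue's samples.  Also records
#' the per-sample unit mean profile used by the rank test of
#' [select_specific_units()].
#'
#' @param assignments Data frame from [assign_bmu()].
#' @param em The [expr_matrix()] the genes were taken from (values may be
#'   the raw log2 matrix even if the SOM was trained on centered data).
#' @return A `unit_summary` list: `tissue_means` (unit x tissue),
#'   `sample_means` (unit x sample), `members` (list of gene ids per unit),
#'   `tissues` (per-sample labels).
#' @export
unit_tissue_means <- function(assignments, em) {
  units <- sort(unique(assignments$unit))
  sm <- em$samples
  sample_means <- t(vapply(units, function(u) {
    g <- assignments$gene_id[assignments$unit == u]
    colMeans(em$values[g, , drop = FALSE])
  }, numeric(ncol(em$values))))
  rownames(sample_means) <- units
  tissues <- unique(sm$tissue)
  tissue_means <- vapply(tissues, function(t) {
    rowMeans(sample_means[, sm$tissue == t, drop = FALSE])
  }, numeric(length(units)))
  if (length(units) == 1) tissue_means <- matrix(tissue_means, 1, dimnames = list(units, tissues))
  structure(list(tissue_means = tissue_means, sample_means = sample_means,
                 members = stats::setNames(
                   lapply(units, function(u) assignments$gene_id[assignments$unit == u]),
                   units),
                 tissues = sm$tissue, units = units),
            class = "unit_summary")
}

#' Select tissue-specific SOM units
#'
#' A unit is called specific for tissue `t` iff its mean expression in `t`
#' exceeds every other tissue's mean by at least `delta` log2 units AND a
#' one-sided Wilcoxon rank test of the unit's per-sample mean expression
#' (samples of `t` vs all other samples) has `p < alpha`.  At most one
#' tissue per unit by construction (the margin condition can hold for one
#' tissue only).
#'
#' @param summary A [unit_tissue_means()] result.
#' @param delta Margin in log2 units (default 1.0).
#' @param alpha Rank-test significance level (default 0.05).
#' @return Named list tissue -> integer vector of selected unit ids.
#' @export
select_specific_units <- function(summary, delta = 1.0, alpha = 0.05) {
  tm <- summary$tissue_means
  if (ncol(tm) < 2) abort("need >= 2 tissues")
  out <- stats::setNames(vector("list", ncol(tm)), colnames(tm))
  for (i in seq_len(nrow(tm))) {
    best <- which.max(tm[i, ])
    if (all(tm[i, best] - tm[i, -best] >= delta)) {
      t <- colnames(tm)[best]
      in_t <- summary$tissues == t
      pv <- suppressWarnings(stats::wilcox.test(
        summary$sample_means[i, in_t], summary$sample_means[i, !in_t],
        alternative = "greater"))$p.value
      if (pv < alpha) out[[t]] <- c(out[[t]], summary$units[i])
    }
  }
  lapply(out, function(v) if (is.null(v)) integer(0) else v)
}

#' Term overrepresentation for unit gene lists
#'
#' Upper-tail hypergeometric test per term with BH adjustment, retaining
#' terms with `q < q_max` (default 0.1).  Shares its machinery with
#' [target_set_overrepresentation()].
#'
#' @param gene_list Character vector of unit member genes.
#' @param term_sets Named list term -> gene ids.
#' @param universe Tested gene universe.
#' @param q_max BH q-value cutoff for the returned table.
#' @return Data frame (`set`, `overlap`, `set_size`, `list_size`, `p`, `q`)
#'   restricted to `q < q_max`.
#' @export
enrich_unit_genes <- function(gene_list, term_sets, universe, q_max = 0.1) {
  if (!length(term_sets)) abort("term table is empty")
  if (!length(intersect(gene_list, universe))) abort("gene list disjoint from universe")
  res <- target_set_overrepresentation(gene_list, term_sets, universe)
  res[res$q < q_max, , drop = FALSE]
}
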