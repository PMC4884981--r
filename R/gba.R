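# Guilt-by-association functional inference: per-lncRNA correlation-ranked
# weighted-KS gene-set enrichment, plus the cis-correlation comparison.

#' Pearson correlation with a two-tailed p-value
#'
#' p is derived from `t = r * sqrt((n - 2) / (1 - r^2))` against a t
#' distribution with `n - 2` df; `|r| = 1` yields `p = 0`.
#'
#' @param x,y Numeric vectors, length >= 3, finite, nonzero variance.
#' @return List with elements `r` and `p`.
#' @export
pearson_r_with_p <- function(x, y) {
  n <- length(x)
  if (n != length(y) || n < 3) abort("vectors must have equal length >= 3")
  stopifnot_finite(c(x, y), "input vectors")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) abort("zero-variance vector")
  r <- stats::cor(x, y)
  if (abs(r) >= 1) return(list(r = r, p = 0))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), n - 2))
}

#' Rank all PCGs by correlation with one lncRNA
#'
#' Every PCG is ranked in descending order of its Pearson correlation with
#' the lncRNA's expression over all samples; ties break by gene id.  PCGs
#' with undefined correlation (constant rows) are excluded with a message.
#'
#' @param lnc_values Numeric vector of the lncRNA's expression over samples.
#' @param pcg_matrix Numeric matrix (PCGs x samples), columns aligned with
#'   `lnc_values` (names checked when both are named).
#' @param lnc_id Identifier recorded in the profile.
#' @return A `ranked_profile` list: `lnc_id`, `gene_ids` (descending by r),
#'   `r` (the signed weights), `N`.
#' @export
rank_by_correlation <- function(lnc_values, pcg_matrix, lnc_id = "lnc") {
  if (length(lnc_values) != ncol(pcg_matrix)) abort("sample count mismatch")
  if (!is.null(names(lnc_values)) && !is.null(colnames(pcg_matrix)) &&
      !identical(names(lnc_values), colnames(pcg_matrix)))
    abort("sample columns misaligned between lncRNA vector and PCG matrix")
  sds <- apply(pcg_matrix, 1, stats::sd)
  if (any(sds == 0)) {
    message(sum(sds == 0), " constant PCG(s) excluded from ranking")
    pcg_matrix <- pcg_matrix[sds > 0, , drop = FALSE]
  }
  r <- as.vector(stats::cor(t(pcg_matrix), lnc_values))
  names(r) <- rownames(pcg_matrix)
  o <- order(-r, names(r))
  structure(list(lnc_id = lnc_id, gene_ids = names(r)[o], r = unname(r[o]),
                 N = length(r)), class = "ranked_profile")
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walking down the ranked list, hits advance `P_hit` by `|r|^p / N_R`
#' (`N_R` = sum of `|r|^p` over set members) and misses advance `P_miss` by
#' `1 / (N - N_H)`; the enrichment score is the signed maximum deviation of
#' `P_hit - P_miss`.
#'
#' @param profile A [rank_by_correlation()] profile.
#' @param gene_set Character vector of PCG ids (after intersection with the
#'   ranked universe, must satisfy `1 <= N_H < N`).
#' @param p Weight exponent (default 1; 0 gives the classic unweighted KS).
#' @return List with `ES`, `argmax` (index of the extreme deviation), `N_H`,
#'   `N_R`.
#' @export
enrichment_score <- function(profile, gene_set, p = 1) {
  hits <- profile$gene_ids %in% gene_set
  N <- profile$N
  N_H <- sum(hits)
  if (N_H == 0 || N_H == N) abort("gene set must hit some but not all of the ranked universe")
  w <- abs(profile$r)^p
  N_R <- sum(w[hits])
  if (N_R == 0) abort("all hit weights are zero; enrichment score undefined")
  p_hit <- cumsum(ifelse(hits, w / N_R, 0))
  p_miss <- cumsum(ifelse(hits, 0, 1 / (N - N_H)))
  dev <- p_hit - p_miss
  i <- which.max(abs(dev))
  list(ES = dev[i], argmax = i, N_H = N_H, N_R = N_R)
}

#' Normalize an enrichment score by gene-set label permutation
#'
#' Random same-size gene sets are drawn from the ranked universe; NES is
#' `ES / mean(|perm ES|)` over permutations of matching sign, and the
#' nominal p is the fraction of same-sign permutation scores at least as
#' extreme.  When no permutation matches the sign, p is reported as
#' `1 / n_perm` with `flagged = TRUE`.
#'
#' @inheritParams enrichment_score
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return List with `ES`, `NES`, `p`, `flagged`.
#' @export
normalize_es <- function(profile, gene_set, p = 1, n_perm = 1000, seed = 1) {
  if (n_perm < 100) abort("n_perm must be >= 100")
  es <- enrichment_score(profile, gene_set, p)$ES
  N_H <- sum(profile$gene_ids %in% gene_set)
  perm <- local_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      enrichment_score(profile, sample(profile$gene_ids, N_H), p)$ES
    }, numeric(1))
  })
  same <- perm[sign(perm) == sign(es)]
  if (length(same) == 0) {
    return(list(ES = es, NES = es / max(abs(perm), .Machine$double.eps),
                p = 1 / n_perm, flagged = TRUE))
  }
  list(ES = es, NES = es / mean(abs(same)),
       p = mean(abs(same) >= abs(es)), flagged = FALSE)
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file (tab-separated: set name, description, members).
#' @param universe Optional character vector; sets are intersected with it.
#' @param min_size,max_size Size filter applied after universe intersection;
#'   sets outside the range are dropped with a message.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path, universe = NULL, min_size = 10, max_size = 500) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    stats::setNames(list(f[-(1:2)]), f[1])
  })
  sets <- unlist(sets, recursive = FALSE)
  filter_gene_sets(sets, universe, min_size, max_size)
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @export
filter_gene_sets <- function(sets, universe = NULL, min_size = 10, max_size = 500) {
  if (!is.null(universe)) sets <- lapply(sets, intersect, y = universe)
  keep <- lengths(sets) >= min_size & lengths(sets) <= max_size
  if (any(!keep)) message(sum(!keep), " gene set(s) outside [", min_size, ", ",
                          max_size, "] dropped")
  sets[keep]
}

#' NES matrix over lncRNAs and gene sets, with clustered orders
#'
#' Computes a ranked profile per lncRNA from its correlation with all PCGs
#' over all samples, scores every gene set (NES by gene-set permutation),
#' and clusters rows and columns of the resulting matrix with
#' [hierarchical_cluster()].
#'
#' @param em An [expr_matrix()] over all samples.
#' @param lnc_ids lncRNAs to profile (>= 2, rows of `em`).
#' @param pcg_ids PCG universe (rows of `em`).
#' @param gene_sets Named list of PCG sets (>= 2 after filtering).
#' @param weight_p Weight exponent for [enrichment_score()].
#' @param n_perm,seed Permutation parameters for [normalize_es()].
#' @return List with `NES`, `ES` and `p` matrices (lncRNA x set) and
#'   `row_order` / `col_order` from clustering (identity orders when a
#'   dimension is too small to cluster).
#' @export
enrichment_matrix <- function(em, lnc_ids, pcg_ids, gene_sets, weight_p = 1,
                              n_perm = 200, seed = 1) {
  if (length(lnc_ids) < 2 || length(gene_sets) < 2) abort("need >= 2 lncRNAs and >= 2 gene sets")
  pm <- em$values[pcg_ids, , drop = FALSE]
  nes <- es <- pv <- matrix(NA_real_, length(lnc_ids), length(gene_sets),
                            dimnames = list(lnc_ids, names(gene_sets)))
  for (i in seq_along(lnc_ids)) {
    prof <- rank_by_correlation(em$values[lnc_ids[i], ], pm, lnc_ids[i])
    for (j in seq_along(gene_sets)) {
      # seed depends on the gene set only, so identical expression profiles
      # yield identical NES rows
      ne <- normalize_es(prof, gene_sets[[j]], p = weight_p, n_perm = n_perm,
                         seed = seed + j)
      nes[i, j] <- ne$NES; es[i, j] <- ne$ES; pv[i, j] <- ne$p
    }
  }
  cl_order <- function(m) {
    ok <- tryCatch(hierarchical_cluster(m, distance = if (ncol(m) >= 3) "pearson" else "euclidean"),
                   error = function(e) NULL)
    if (is.null(ok)) seq_len(nrow(m)) else ok$order
  }
  list(NES = nes, ES = es, p = pv,
       row_order = cl_order(nes), col_order = cl_order(t(nes)))
}

#' Compare cis correlations of DE lncRNAs against background
#'
#' One-sided Mann-Whitney U test of whether the lncRNA-neighbor expression
#' correlations of (common) DE lncRNAs are stochastically greater than the
#' genome-wide background correlations.
#'
#' @param de_pairs_r,background_pairs_r Numeric vectors of Pearson r values.
#' @return List with `U` (number of (de, background) pairs where de > bg,
#'   ties counting half) and one-sided `p`.
#' @export
cis_correlation_test <- function(de_pairs_r, background_pairs_r) {
  if (!length(de_pairs_r) || !length(background_pairs_r)) abort("both vectors must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(de_pairs_r, background_pairs_r,
                                            alternative = "greater"))
  list(U = unname(wt$statistic), p = wt$p.value)
}
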