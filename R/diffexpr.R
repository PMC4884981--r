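# Per-tissue differential expression and the common up/down intersection.

#' Two-tailed Student's t-test for one gene
#'
#' Unpaired mode is the pooled-variance two-sample t with
#' `df = n1 + n2 - 2`; paired mode is a one-sample t on the per-patient
#' differences (vectors must be patient-aligned).  A zero-variance
#' degenerate case returns `t = 0, p = 1` with a warning rather than
#' failing.
#'
#' @param tumor_values,normal_values Numeric vectors (log2 scale), length
#'   >= 2 each; equal length in paired mode.
#' @param mode `"unpaired"` (default) or `"paired"`.
#' @return List with elements `t` and `p`.
#' @export
#' @examples
#' gene_t_test(c(3, 4, 5), c(1, 2, 3))  # t = 2.449, p ~ 0.0705
gene_t_test <- function(tumor_values, normal_values, mode = c("unpaired", "paired")) {
  mode <- match.arg(mode)
  if (length(tumor_values) < 2 || length(normal_values) < 2) abort("need >= 2 values per group")
  stopifnot_finite(c(tumor_values, normal_values), "expression values")
  if (mode == "paired") {
    if (length(tumor_values) != length(normal_values))
      abort("paired mode requires equal-length, patient-aligned vectors")
    d <- tumor_values - normal_values
    if (stats::sd(d) == 0) {
      if (all(d == 0)) { warning("zero-variance differences; returning t = 0, p = 1"); return(list(t = 0, p = 1)) }
      warning("zero-variance differences; returning t = 0, p = 1")
      return(list(t = 0, p = 1))
    }
    tt <- mean(d) / (stats::sd(d) / sqrt(length(d)))
    df <- length(d) - 1
  } else {
    n1 <- length(tumor_values); n2 <- length(normal_values)
    sp2 <- ((n1 - 1) * stats::var(tumor_values) + (n2 - 1) * stats::var(normal_values)) / (n1 + n2 - 2)
    if (sp2 == 0) { warning("zero pooled variance; returning t = 0, p = 1"); return(list(t = 0, p = 1)) }
    tt <- (mean(tumor_values) - mean(normal_values)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  list(t = tt, p = 2 * stats::pt(-abs(tt), df))
}

# Vectorized pooled/paired t over matrix rows; same math as gene_t_test.
row_t_test <- function(tumor, normal, mode = "unpaired") {
  if (mode == "paired") {
    d <- tumor - normal
    n <- ncol(d)
    m <- rowMeans(d)
    s <- sqrt(rowSums((d - m)^2) / (n - 1))
    degenerate <- s == 0
    tt <- ifelse(degenerate, 0, m / (s / sqrt(n)))
    df <- n - 1
  } else {
    n1 <- ncol(tumor); n2 <- ncol(normal)
    m1 <- rowMeans(tumor); m2 <- rowMeans(normal)
    v1 <- rowSums((tumor - m1)^2) / (n1 - 1)
    v2 <- rowSums((normal - m2)^2) / (n2 - 1)
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    degenerate <- se == 0
    tt <- ifelse(degenerate, 0, (m1 - m2) / se)
    df <- n1 + n2 - 2
  }
  p <- ifelse(degenerate, 1, 2 * stats::pt(-abs(tt), df))
  if (any(degenerate))
    warning(sum(degenerate), " gene(s) with zero variance reported t = 0, p = 1 (ns)")
  list(t = tt, p = p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values `min_{j >= i} p_(j) * n / j`, capped at 1.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted vector in input order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    abort("p-values must lie in [0, 1]")
  n <- length(p_values)
  o <- order(p_values, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p_values[o]))[ro]
}

#' Call differential expression for one tissue
#'
#' Fold change is the linear-scale ratio `2^(mean_tumor - mean_normal)` of
#' log2 means; a gene is `up` iff `fold_change > fc_threshold` and
#' `fdr < alpha`, `down` iff `fold_change < 1 / fc_threshold` and
#' `fdr < alpha`, otherwise `ns` (both thresholds strict).  By default FDR
#' is computed separately within the PCG and lncRNA strata of the tissue's
#' tested universe; `stratify = FALSE` pools all genes.
#'
#' @param em An [expr_matrix()] restricted to (or containing) one tissue.
#' @param tissue Tissue label to test (required when `em` holds several).
#' @param alpha FDR threshold (default 0.05).
#' @param fc_threshold Linear fold-change threshold (default 1.5).
#' @param mode `"unpaired"` (default) or `"paired"` t-test.
#' @param biotype Optional named character vector gene id -> biotype used
#'   for stratified FDR; defaults to a single stratum.
#' @param stratify Adjust PCGs and lncRNAs separately (default `TRUE` when
#'   `biotype` is given).
#' @return Data frame of per-gene results: `gene_id`, `biotype`, `tissue`,
#'   `mean_log2_tumor`, `mean_log2_normal`, `fold_change`, `t`, `p_value`,
#'   `fdr`, `direction`.
#' @export
call_de <- function(em, tissue = NULL, alpha = 0.05, fc_threshold = 1.5,
                    mode = c("unpaired", "paired"), biotype = NULL, stratify = TRUE) {
  mode <- match.arg(mode)
  if (is.null(tissue)) {
    tissue <- unique(em$samples$tissue)
    if (length(tissue) != 1) abort("matrix holds several tissues; specify `tissue`")
  }
  sm <- em$samples
  keep <- sm$tissue == tissue
  if (!any(keep & sm$condition == "tumor") || !any(keep & sm$condition == "normal"))
    abort("tissue '", tissue, "' lacks tumor or normal samples")
  sm <- sm[keep, , drop = FALSE]
  v <- em$values[, keep, drop = FALSE]
  if (mode == "paired") {
    ti <- which(sm$condition == "tumor")
    ni <- which(sm$condition == "normal")
    pats <- intersect(sm$patient_id[ti], sm$patient_id[ni])
    if (length(pats) < 2) abort("paired mode needs >= 2 complete patient pairs")
    tum <- v[, ti[match(pats, sm$patient_id[ti])], drop = FALSE]
    nrm <- v[, ni[match(pats, sm$patient_id[ni])], drop = FALSE]
  } else {
    tum <- v[, sm$condition == "tumor", drop = FALSE]
    nrm <- v[, sm$condition == "normal", drop = FALSE]
  }
  tres <- row_t_test(tum, nrm, mode)
  mt <- rowMeans(tum); mn <- rowMeans(nrm)
  fc <- 2^(mt - mn)
  bt <- if (is.null(biotype)) rep("all", nrow(v)) else unname(biotype[rownames(v)])
  bt[is.na(bt)] <- "all"
  fdr <- numeric(nrow(v))
  strata <- if (stratify) bt else rep("all", nrow(v))
  for (s in unique(strata)) {
    i <- strata == s
    fdr[i] <- bh_fdr(tres$p[i])
  }
  direction <- ifelse(fdr < alpha & fc > fc_threshold, "up",
                      ifelse(fdr < alpha & fc < 1 / fc_threshold, "down", "ns"))
  data.frame(gene_id = rownames(v), biotype = bt, tissue = tissue,
             mean_log2_tumor = mt, mean_log2_normal = mn, fold_change = fc,
             t = tres$t, p_value = tres$p, fdr = fdr, direction = direction,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Intersect per-tissue DE calls into common up/down sets
#'
#' A gene enters `common_up` iff its direction is `up` in every tissue's
#' result; likewise `down`.  Genes with conflicting or missing calls are
#' excluded.
#'
#' @param per_tissue_results List (>= 2) of [call_de()] data frames, one per
#'   tissue.
#' @return A `common_de_sets` list: `common_up_pcg`, `common_down_pcg`,
#'   `common_up_lnc`, `common_down_lnc` (character vectors; genes with
#'   biotype other than pcg/lncrna land in the pcg slots' complement and are
#'   reported under `common_up_other`/`common_down_other` when present).
#' @export
intersect_common <- function(per_tissue_results) {
  if (length(per_tissue_results) < 2) abort("need results from >= 2 tissues")
  dirs <- lapply(per_tissue_results, function(r) stats::setNames(r$direction, r$gene_id))
  genes <- Reduce(intersect, lapply(dirs, names))
  dmat <- vapply(dirs, function(d) d[genes], character(length(genes)))
  if (length(genes) == 1) dmat <- matrix(dmat, nrow = 1)
  all_up <- genes[apply(dmat == "up", 1, all)]
  all_down <- genes[apply(dmat == "down", 1, all)]
  bt <- stats::setNames(per_tissue_results[[1]]$biotype, per_tissue_results[[1]]$gene_id)
  out <- list(
    common_up_pcg = sort(all_up[bt[all_up] == "pcg"]),
    common_down_pcg = sort(all_down[bt[all_down] == "pcg"]),
    common_up_lnc = sort(all_up[bt[all_up] == "lncrna"]),
    common_down_lnc = sort(all_down[bt[all_down] == "lncrna"]))
  other_up <- setdiff(all_up, c(out$common_up_pcg, out$common_up_lnc))
  other_down <- setdiff(all_down, c(out$common_down_pcg, out$common_down_lnc))
  if (length(other_up)) out$common_up_other <- sort(other_up)
  if (length(other_down)) out$common_down_other <- sort(other_down)
  structure(out, class = "common_de_sets")
}

#' @export
print.common_de_sets <- function(x, ...) {
  cat("common DE sets:",
      sprintf("%s=%d", names(x), lengths(x)), "\n")
  invisible(x)
}
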