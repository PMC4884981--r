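# Tri-color ceRNA network: typed nodes (lncRNA / mRNA / miRNA), typed edges
# (targeting, genomic neighbor, expression correlation) and minimal-motif
# enumeration.

#' Build a tri-color lncRNA-mRNA-miRNA network
#'
#' For every lncRNA context with a neighbor PCG present in the matrix, a
#' `neighbor` edge is added, and a `coexpr` edge iff the Pearson correlation
#' over all samples satisfies `r > r_min` and `p < p_max` (both strict).
#' Targeting edges are copied from the miRNA-target table restricted to the
#' network's RNAs.  Isolated nodes are dropped and nodes/edges are stored in
#' canonical (type, id) order, so shuffled inputs yield identical networks.
#'
#' @param contexts Data frame from [classify_lncrnas()] (typically restricted
#'   to the common DE-lncRNAs).
#' @param em An [expr_matrix()] over all samples.
#' @param targets miRNA-target data frame (`mirna_id`, `target_id`, `score`),
#'   or `NULL` for none.
#' @param r_min,p_max Coexpression thresholds (defaults 0.45 and 0.01).
#' @return A `tricolor_network`: list with `nodes` (`id`, `type`) and
#'   `edges` (`from`, `to`, `type`, `r`, `p`, `score`).
#' @export
build_network <- function(contexts, em, targets = NULL, r_min = 0.45, p_max = 0.01) {
  ctx <- contexts[!is.na(contexts$neighbor_pcg_id), , drop = FALSE]
  edges <- list()
  present <- rownames(em$values)
  skipped <- 0
  for (i in seq_len(nrow(ctx))) {
    l <- ctx$lnc_id[i]; g <- ctx$neighbor_pcg_id[i]
    if (!(l %in% present) || !(g %in% present)) { skipped <- skipped + 1; next }
    edges[[length(edges) + 1]] <- data.frame(from = l, to = g, type = "neighbor",
                                             r = NA_real_, p = NA_real_, score = NA_real_,
                                             stringsAsFactors = FALSE)
    cp <- pearson_r_with_p(em$values[l, ], em$values[g, ])
    if (cp$r > r_min && cp$p < p_max) {
      edges[[length(edges) + 1]] <- data.frame(from = l, to = g, type = "coexpr",
                                               r = cp$r, p = cp$p, score = NA_real_,
                                               stringsAsFactors = FALSE)
    }
  }
  if (skipped > 0) message(skipped, " lncRNA-neighbor pair(s) skipped: gene absent from matrix")
  ed <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(0), to = character(0), type = character(0),
               r = numeric(0), p = numeric(0), score = numeric(0))
  lncs <- unique(ed$from); mrnas <- unique(ed$to)
  if (!is.null(targets) && nrow(targets)) {
    tg <- targets[targets$target_id %in% c(lncs, mrnas), , drop = FALSE]
    if (nrow(tg)) {
      ed <- rbind(ed, data.frame(from = tg$mirna_id, to = tg$target_id,
                                 type = "targeting", r = NA_real_, p = NA_real_,
                                 score = tg$score, stringsAsFactors = FALSE))
    }
  }
  node_ids <- unique(c(ed$from, ed$to))
  type <- ifelse(node_ids %in% lncs, "lncrna",
                 ifelse(node_ids %in% mrnas, "mrna", "mirna"))
  nodes <- data.frame(id = node_ids, type = type, stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$type, nodes$id), , drop = FALSE]
  ed <- ed[order(ed$type, ed$from, ed$to), , drop = FALSE]
  rownames(nodes) <- rownames(ed) <- NULL
  structure(list(nodes = nodes, edges = ed), class = "tricolor_network")
}

#' @export
print.tricolor_network <- function(x, ...) {
  cat(sprintf("tricolor_network: %d nodes (%s), %d edges (%s)\n",
              nrow(x$nodes), paste(names(table(x$nodes$type)), table(x$nodes$type),
                                   sep = "=", collapse = ", "),
              nrow(x$edges), paste(names(table(x$edges$type)), table(x$edges$type),
                                   sep = "=", collapse = ", ")))
  invisible(x)
}

#' Enumerate minimal ceRNA submotifs
#'
#' A motif is a triple (miRNA m, lncRNA l, mRNA g) such that m targets both
#' l and g, and l and g are connected by both a neighbor edge and a
#' coexpression edge.  Results are sorted by (mirna, lnc, mrna).
#'
#' @param network A [build_network()] result.
#' @return Data frame with columns `mirna_id`, `lnc_id`, `mrna_id`, `r`, `p`.
#' @export
find_motifs <- function(network) {
  ed <- network$edges
  nb <- ed[ed$type == "neighbor", c("from", "to")]
  cx <- ed[ed$type == "coexpr", c("from", "to", "r", "p")]
  tg <- ed[ed$type == "targeting", c("from", "to")]
  pairs <- merge(nb, cx, by = c("from", "to"))
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    m_l <- tg$from[tg$to == pairs$from[i]]
    m_g <- tg$from[tg$to == pairs$to[i]]
    both <- intersect(m_l, m_g)
    if (length(both)) {
      out[[length(out) + 1]] <- data.frame(
        mirna_id = sort(both), lnc_id = pairs$from[i], mrna_id = pairs$to[i],
        r = pairs$r[i], p = pairs$p[i], stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(mirna_id = character(0), lnc_id = character(0),
               mrna_id = character(0), r = numeric(0), p = numeric(0))
  res <- res[order(res$mirna_id, res$lnc_id, res$mrna_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Per-node degree split by edge type
#'
#' @param network A `tricolor_network`.
#' @return Data frame: `id`, `type`, one column per edge type, `total`.
#' @export
degree_table <- function(network) {
  ed <- network$edges
  etypes <- c("targeting", "neighbor", "coexpr")
  out <- network$nodes
  for (et in etypes) {
    e <- ed[ed$type == et, ]
    cnt <- table(c(e$from, e$to))
    out[[et]] <- as.integer(ifelse(out$id %in% names(cnt), cnt[out$id], 0L))
  }
  out$total <- out$targeting + out$neighbor + out$coexpr
  out
}

#' Hypergeometric overrepresentation of miRNA target sets
#'
#' Upper-tail hypergeometric test of each miRNA's target set against a gene
#' list within a universe, BH-adjusted across miRNAs.
#'
#' @param gene_list Character vector (e.g. neighbor PCGs of up-regulated
#'   lncRNAs), subset of `universe`.
#' @param target_sets Named list of character vectors (per-miRNA targets).
#' @param universe Character vector, the tested gene universe (non-empty).
#' @return Data frame: `set`, `overlap`, `set_size`, `list_size`, `p`, `q`.
#' @export
target_set_overrepresentation <- function(gene_list, target_sets, universe) {
  if (!length(universe)) abort("empty universe")
  gene_list <- intersect(gene_list, universe)
  N <- length(universe); n <- length(gene_list)
  rows <- lapply(names(target_sets), function(s) {
    set <- intersect(target_sets[[s]], universe)
    k <- length(intersect(gene_list, set))
    p <- stats::phyper(k - 1, length(set), N - length(set), n, lower.tail = FALSE)
    data.frame(set = s, overlap = k, set_size = length(set), list_size = n,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out[order(out$p, out$set), , drop = FALSE]
}

#' Export a tri-color network as SIF or GraphML
#'
#' SIF rows are `node <relation> node` with relations `targets`, `neighbor`
#' and `coexpr`; GraphML carries node `type` and edge `type`/`r`/`p`/`score`
#' attributes (written via igraph).
#'
#' @param network A `tricolor_network`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_network_sif <- function(network, path) {
  rel <- c(targeting = "targets", neighbor = "neighbor", coexpr = "coexpr")
  lines <- sprintf("%s\t%s\t%s", network$edges$from,
                   rel[network$edges$type], network$edges$to)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_network_sif
#' @export
write_network_graphml <- function(network, path) {
  g <- igraph::graph_from_data_frame(network$edges, directed = TRUE,
                                     vertices = network$nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
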