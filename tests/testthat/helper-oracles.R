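# Independent brute-force oracles and small fixture builders shared across
# the suite.  Each oracle is coded directly from the defining formula, on a
# separate code path from the implementation it checks.

# --- weighted-KS enrichment score: literal running-sum loop -----------------
oracle_es <- function(ranked_ids, signed_r, set, p = 1) {
  N <- length(ranked_ids)
  in_set <- ranked_ids %in% set
  n_h <- sum(in_set)
  n_r <- sum(abs(signed_r[in_set])^p)
  best <- 0; run <- 0
  for (i in seq_len(N)) {
    if (in_set[i]) run <- run + abs(signed_r[i])^p / n_r
    else run <- run - 1 / (N - n_h)
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# --- BH step-up by its definition: min over j >= i of p_(j) * n / j ---------
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  sp <- p[o]
  adj <- numeric(n)
  for (i in seq_len(n)) adj[i] <- min(1, min(sp[i:n] * n / (i:n)))
  adj[order(o)]
}

# --- hypergeometric upper tail by explicit summation ------------------------
oracle_hyper_tail <- function(k, K, N, n) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# --- Mann-Whitney U by O(n^2) pair counting ---------------------------------
oracle_mwu <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) u <- u + (xi > yj) + 0.5 * (xi == yj)
  u
}

# --- genomic-context classification: naive scan straight from the rules ----
oracle_classify <- function(lnc, pcgs) {
  ov_len <- function(s1, e1, s2, e2) max(0, min(e1, e2) - max(s1, s2))
  anti <- sense_ex <- sense_in <- FALSE
  lnc_ex <- exon_blocks(lnc)
  for (j in seq_len(nrow(pcgs))) {
    if (pcgs$chrom[j] != lnc$chrom) next
    if (ov_len(lnc$start, lnc$end, pcgs$start[j], pcgs$end[j]) == 0) next
    if (lnc$strand != "." && pcgs$strand[j] != lnc$strand) { anti <- TRUE; next }
    pe <- exon_blocks(pcgs[j, ])
    eo <- 0
    for (a in seq_len(nrow(lnc_ex))) for (b in seq_len(nrow(pe)))
      eo <- eo + ov_len(lnc_ex[a, 1], lnc_ex[a, 2], pe[b, 1], pe[b, 2])
    if (eo > 0) sense_ex <- TRUE else sense_in <- TRUE
  }
  if (anti) return("antisense")
  if (sense_ex) return("sense_exonic")
  if (sense_in) return("intronic")
  "intergenic"
}

oracle_neighbor <- function(lnc, cls, pcgs) {
  ov_len <- function(s1, e1, s2, e2) max(0, min(e1, e2) - max(s1, s2))
  gap_len <- function(s1, e1, s2, e2) max(0, max(s1, s2) - min(e1, e2))
  cand <- pcgs[pcgs$chrom == lnc$chrom, , drop = FALSE]
  if (nrow(cand) == 0) return(NA_character_)
  lnc_ex <- exon_blocks(lnc)
  sc <- numeric(nrow(cand)); dist <- numeric(nrow(cand))
  for (j in seq_len(nrow(cand))) {
    ov <- ov_len(lnc$start, lnc$end, cand$start[j], cand$end[j])
    dist[j] <- if (ov > 0) 0 else gap_len(lnc$start, lnc$end, cand$start[j], cand$end[j])
    opp <- lnc$strand == "." || cand$strand[j] != lnc$strand
    same <- lnc$strand == "." || cand$strand[j] == lnc$strand
    sc[j] <- switch(cls,
      intergenic = -dist[j],
      antisense = if (opp) ov else -Inf,
      intronic = if (same) ov else -Inf,
      sense_exonic = {
        if (!same) -Inf else {
          pe <- exon_blocks(cand[j, ]); eo <- 0
          for (a in seq_len(nrow(lnc_ex))) for (b in seq_len(nrow(pe)))
            eo <- eo + ov_len(lnc_ex[a, 1], lnc_ex[a, 2], pe[b, 1], pe[b, 2])
          eo
        }
      })
  }
  ok <- which(is.finite(sc))
  if (!length(ok)) return(NA_character_)
  best <- ok[sc[ok] == max(sc[ok])]
  if (length(best) > 1) best <- best[dist[best] == min(dist[best])]
  if (length(best) > 1) best <- best[order(cand$gene_id[best])]
  cand$gene_id[best[1]]
}

# random annotation with no placement guarantees, for oracle-equivalence tests
random_annotation <- function(n_pcg, n_lnc, chrom_len = 2e5, seed = 1) {
  withr::with_seed(seed, {
    mk <- function(id, biotype) {
      start <- sample.int(chrom_len - 6000, 1)
      len <- sample(500:5000, 1)
      end <- start + len
      n_ex <- if (biotype == "pcg") sample(2:3, 1) else sample(1:2, 1)
      cuts <- sort(sample(seq(start, end - 50, by = 50), 2 * n_ex))
      es <- cuts[seq(1, 2 * n_ex, 2)]
      ee <- cuts[seq(2, 2 * n_ex, 2)]
      ee[n_ex] <- end; es[1] <- start
      ok <- ee > es
      data.frame(gene_id = id, chrom = "chr1", start = start, end = end,
                 strand = sample(c("+", "-"), 1), biotype = biotype,
                 exon_starts = paste(es[ok], collapse = ","),
                 exon_sizes = paste(ee[ok] - es[ok], collapse = ","),
                 stringsAsFactors = FALSE)
    }
    rows <- c(lapply(sprintf("P%03d", seq_len(n_pcg)), mk, biotype = "pcg"),
              lapply(sprintf("L%03d", seq_len(n_lnc)), mk, biotype = "lncrna"))
    gene_annotation(do.call(rbind, rows))
  })
}

# random tri-color network (data-frame form accepted by find_motifs)
random_network <- function(n_mirna = 5, n_lnc = 6, n_mrna = 6, seed = 1) {
  withr::with_seed(seed, {
    lncs <- sprintf("L%02d", seq_len(n_lnc))
    mrnas <- sprintf("G%02d", seq_len(n_mrna))
    mirnas <- sprintf("m%02d", seq_len(n_mirna))
    ed <- list()
    for (l in lncs) {
      g <- sample(mrnas, 1)
      ed[[length(ed) + 1]] <- data.frame(from = l, to = g, type = "neighbor",
                                         r = NA, p = NA, score = NA)
      if (runif(1) < 0.7)
        ed[[length(ed) + 1]] <- data.frame(from = l, to = g, type = "coexpr",
                                           r = runif(1, 0.5, 0.9), p = 1e-4, score = NA)
    }
    for (m in mirnas) for (t in c(lncs, mrnas)) if (runif(1) < 0.3)
      ed[[length(ed) + 1]] <- data.frame(from = m, to = t, type = "targeting",
                                         r = NA, p = NA, score = 160)
    ed <- do.call(rbind, ed)
    nodes <- data.frame(id = c(lncs, mrnas, mirnas),
                        type = rep(c("lncrna", "mrna", "mirna"),
                                   c(n_lnc, n_mrna, n_mirna)))
    structure(list(nodes = nodes, edges = ed), class = "tricolor_network")
  })
}

oracle_motifs <- function(network) {
  ed <- network$edges
  out <- list()
  mirnas <- network$nodes$id[network$nodes$type == "mirna"]
  lncs <- network$nodes$id[network$nodes$type == "lncrna"]
  mrnas <- network$nodes$id[network$nodes$type == "mrna"]
  has_edge <- function(f, t, ty) any(ed$from == f & ed$to == t & ed$type == ty)
  for (m in mirnas) for (l in lncs) for (g in mrnas) {
    if (has_edge(m, l, "targeting") && has_edge(m, g, "targeting") &&
        has_edge(l, g, "neighbor") && has_edge(l, g, "coexpr"))
      out[[length(out) + 1]] <- c(m, l, g)
  }
  if (!length(out)) return(character(0))
  sort(vapply(out, paste, character(1), collapse = "|"))
}

# O(n^3) complete-linkage agglomeration, returning merge heights in order
oracle_complete_linkage_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- Inf; bi <- bj <- 0
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      h <- max(d[clusters[[i]], clusters[[j]]])
      if (h < best) { best <- h; bi <- i; bj <- j }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# small paired-design fixture used by several files
toy_expr <- function(n_genes = 20, pairs = 4, tissues = c("tA", "tB"), seed = 1,
                     baseline = 8, sd = 0.5) {
  sim <- simulate_expression(
    make_annotation(n_pcg = max(2, ceiling(n_genes * 0.7)),
                    n_lnc = floor(n_genes * 0.3), seed = seed),
    study_design(tissues = tissues, pairs_per_tissue = pairs, noise_sd = sd,
                 baseline_mean = baseline, seed = seed),
    truth_spec(n_up_pcg = 0, n_down_pcg = 0, n_up_lnc = 0, n_down_lnc = 0,
               de_effect = 0, block_elevation = 0, n_cis = 0, n_cerna = 0))
  sim$expr
}
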