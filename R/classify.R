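#' Classify a lncRNA by genomic context relative to protein-coding genes
#'
#' Decision rules, in priority order:
#' 1. locus overlap with an opposite-strand PCG -> `antisense`
#' 2. exon overlap with a same-strand PCG -> `sense_exonic`
#' 3. locus overlap with a same-strand PCG but no exon overlap -> `intronic`
#' 4. no PCG overlap -> `intergenic`
#'
#' Antisense takes priority when a lncRNA overlaps PCGs on both strands,
#' mirroring common lncRNA taxonomies (configurable via `antisense_first`).
#' Unstranded (`.`) lncRNAs cannot be antisense; they are classified by exon
#' vs intron overlap only and flagged downstream.
#'
#' @param lnc Single-row `gene_annotation` slice (the lncRNA).
#' @param pcgs `gene_annotation` rows of biotype `"pcg"`.
#' @param antisense_first Give opposite-strand overlap priority over
#'   same-strand relations (default `TRUE`).
#' @return One of `"intergenic"`, `"antisense"`, `"intronic"`,
#'   `"sense_exonic"`.
#' @export
classify_lncrna <- function(lnc, pcgs, antisense_first = TRUE) {
  if (nrow(pcgs) == 0) return("intergenic")
  same_chrom <- pcgs$chrom == lnc$chrom
  ov <- rep(0, nrow(pcgs))
  idx <- which(same_chrom)
  if (length(idx)) {
    ov[idx] <- pmax(0, pmin(lnc$end, pcgs$end[idx]) - pmax(lnc$start, pcgs$start[idx]))
  }
  hit <- which(ov > 0)
  if (!length(hit)) return("intergenic")

  unstranded <- lnc$strand == "."
  anti <- if (unstranded) integer(0) else hit[pcgs$strand[hit] != lnc$strand]
  sense <- if (unstranded) hit else hit[pcgs$strand[hit] == lnc$strand]

  if (antisense_first && length(anti)) return("antisense")

  if (length(sense)) {
    lnc_ex <- exon_blocks(lnc)
    exon_ov <- vapply(sense, function(j) {
      pe <- exon_blocks(pcgs[j, ])
      sum(vapply(seq_len(nrow(lnc_ex)), function(k)
        blocks_overlap(lnc_ex[k, 1], lnc_ex[k, 2], pe), numeric(1)))
    }, numeric(1))
    if (any(exon_ov > 0)) return("sense_exonic")
    return("intronic")
  }
  if (length(anti)) return("antisense")  # only reachable with antisense_first = FALSE fallback
  "intergenic"
}

#' Assign the class-specific neighbor PCG of a lncRNA
#'
#' Neighbor semantics per class: nearest PCG by boundary-to-boundary distance
#' (intergenic); opposite-strand PCG with maximal locus overlap (antisense);
#' host, i.e. maximally overlapping same-strand, PCG (intronic); same-strand
#' PCG with maximal exon overlap (sense_exonic).  Ties are broken by smaller
#' distance then lexicographically smaller gene id.
#'
#' @inheritParams classify_lncrna
#' @param context_class Class previously computed by [classify_lncrna()].
#' @return A one-row data frame (`lnc_id`, `context_class`, `neighbor_pcg_id`,
#'   `distance`, `flag`); `neighbor_pcg_id` is `NA` and `flag` is
#'   `"no_pcg_on_chrom"` when no PCG shares the chromosome.
#' @export
assign_neighbor <- function(lnc, context_class, pcgs) {
  out <- data.frame(lnc_id = lnc$gene_id, context_class = context_class,
                    neighbor_pcg_id = NA_character_, distance = NA_real_,
                    flag = if (lnc$strand == ".") "unstranded" else "",
                    stringsAsFactors = FALSE)
  cand <- pcgs[pcgs$chrom == lnc$chrom, , drop = FALSE]
  if (nrow(cand) == 0) {
    out$flag <- trimws(paste(out$flag, "no_pcg_on_chrom"))
    return(out)
  }
  ov <- pmax(0, pmin(lnc$end, cand$end) - pmax(lnc$start, cand$start))
  gap <- pmax(0, pmax(lnc$start, cand$start) - pmin(lnc$end, cand$end))
  dist <- ifelse(ov > 0, 0, gap)

  score <- switch(context_class,
    intergenic = -dist,                      # maximize -distance
    antisense = ifelse(if (lnc$strand == ".") TRUE else cand$strand != lnc$strand, ov, -Inf),
    intronic = ifelse(if (lnc$strand == ".") TRUE else cand$strand == lnc$strand, ov, -Inf),
    sense_exonic = {
      lnc_ex <- exon_blocks(lnc)
      vapply(seq_len(nrow(cand)), function(j) {
        if (lnc$strand != "." && cand$strand[j] != lnc$strand) return(-Inf)
        pe <- exon_blocks(cand[j, ])
        sum(vapply(seq_len(nrow(lnc_ex)), function(k)
          blocks_overlap(lnc_ex[k, 1], lnc_ex[k, 2], pe), numeric(1)))
      }, numeric(1))
    },
    abort("unknown context class: ", context_class))

  ok <- which(is.finite(score) & score > -Inf)
  if (!length(ok)) {
    out$flag <- trimws(paste(out$flag, "no_eligible_pcg"))
    return(out)
  }
  best <- max(score[ok])
  tied <- ok[score[ok] == best]
  if (length(tied) > 1) {
    d <- dist[tied]
    tied <- tied[d == min(d)]
    if (length(tied) > 1) tied <- tied[order(cand$gene_id[tied])][1]
  }
  j <- tied[1]
  out$neighbor_pcg_id <- cand$gene_id[j]
  out$distance <- dist[j]
  out
}

#' Classify every lncRNA in an annotation and assign neighbors
#'
#' @param ann A `gene_annotation` containing PCGs and lncRNAs.
#' @param antisense_first See [classify_lncrna()].
#' @return Data frame (one row per lncRNA): `lnc_id`, `context_class`,
#'   `neighbor_pcg_id`, `distance`, `flag`.  Empty (zero-row) when the
#'   annotation contains no lncRNAs.
#' @export
classify_lncrnas <- function(ann, antisense_first = TRUE) {
  pcgs <- ann[ann$biotype == "pcg", , drop = FALSE]
  lncs <- ann[ann$biotype == "lncrna", , drop = FALSE]
  if (nrow(lncs) == 0) {
    return(data.frame(lnc_id = character(0), context_class = character(0),
                      neighbor_pcg_id = character(0), distance = numeric(0),
                      flag = character(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(lncs)), function(i) {
    cl <- classify_lncrna(lncs[i, ], pcgs, antisense_first = antisense_first)
    assign_neighbor(lncs[i, ], cl, pcgs)
  })
  do.call(rbind, rows)
}
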