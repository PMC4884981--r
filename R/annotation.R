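#' Gene annotation table
#'
#' Strand-aware genomic loci with exon blocks and a biotype, the substrate of
#' lncRNA genomic-context classification.  All coordinates are 0-based
#' half-open (BED convention): a locus `[start, end)` covers bases
#' `start .. end - 1`.
#'
#' @param df Data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (`"+"`, `"-"` or `"."`), `biotype` (`"pcg"` or `"lncrna"`),
#'   `exon_starts` and `exon_sizes` (comma-separated integers; exon starts are
#'   absolute chromosome coordinates).
#' @return A `gene_annotation` data frame.
#' @export
gene_annotation <- function(df) {
  req <- c("gene_id", "chrom", "start", "end", "strand", "biotype",
           "exon_starts", "exon_sizes")
  if (!all(req %in% names(df))) abort("annotation needs columns: ", paste(req, collapse = ", "))
  df <- as.data.frame(df)[, req]
  if (anyDuplicated(df$gene_id)) abort("gene ids must be unique")
  if (any(df$start >= df$end)) abort("start must be < end for every gene")
  if (!all(df$strand %in% c("+", "-", "."))) abort("strand must be '+', '-' or '.'")
  if (!all(df$biotype %in% c("pcg", "lncrna"))) abort("biotype must be 'pcg' or 'lncrna'")
  for (i in seq_len(nrow(df))) {
    ex <- exon_blocks(df[i, ])
    if (nrow(ex) == 0) abort("gene ", df$gene_id[i], " has no exons")
    if (any(ex[, 1] >= ex[, 2])) abort("gene ", df$gene_id[i], " has a zero/negative-width exon")
    if (ex[1, 1] < df$start[i] || ex[nrow(ex), 2] > df$end[i])
      abort("gene ", df$gene_id[i], ": exons not contained in locus")
    if (nrow(ex) > 1 && any(ex[-1, 1] < ex[-nrow(ex), 2]))
      abort("gene ", df$gene_id[i], ": exons overlap or are unsorted")
  }
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Exon blocks of one annotation row
#'
#' @param gene A single-row slice of a `gene_annotation`.
#' @return Two-column integer matrix of absolute half-open `[start, end)`
#'   exon intervals, sorted by start.
#' @export
exon_blocks <- function(gene) {
  s <- as.numeric(strsplit(as.character(gene$exon_starts), ",", fixed = TRUE)[[1]])
  w <- as.numeric(strsplit(as.character(gene$exon_sizes), ",", fixed = TRUE)[[1]])
  if (length(s) != length(w)) abort("exon_starts / exon_sizes length mismatch")
  cbind(start = s, end = s + w)
}

#' Base-pair overlap of two half-open intervals
#'
#' @param a_start,a_end,b_start,b_end Interval coordinates, half-open.
#'   Vectorized over the second interval.
#' @param same_chrom Logical; `FALSE` forces zero overlap (different
#'   chromosomes never overlap).
#' @return Non-negative overlap width(s) in base pairs.  Adjacent intervals
#'   (`a_end == b_start`) overlap by 0.
#' @export
#' @examples
#' interval_overlap(0, 10, 10, 20)  # 0: half-open adjacency
#' interval_overlap(0, 10, 5, 8)    # 3
interval_overlap <- function(a_start, a_end, b_start, b_end, same_chrom = TRUE) {
  if (any(a_start >= a_end) || any(b_start >= b_end)) abort("malformed interval (start >= end)")
  ov <- pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start))
  ov * as.numeric(same_chrom)
}

# overlap of an interval with a set of exon blocks (matrix [start,end))
blocks_overlap <- function(start, end, blocks) {
  if (nrow(blocks) == 0) return(0)
  sum(pmax(0, pmin(end, blocks[, 2]) - pmax(start, blocks[, 1])))
}

#' Read / write annotation as BED12 plus a biotype table
#'
#' BED12 stores exon blocks with starts relative to the locus start; the
#' biotype sidecar is a two-column TSV (`gene_id`, `biotype`).
#'
#' @param ann A `gene_annotation`.
#' @param bed_path,biotype_path File paths.
#' @return `read_annotation_bed12` returns a `gene_annotation`;
#'   `write_annotation_bed12` invisibly returns its input.
#' @export
write_annotation_bed12 <- function(ann, bed_path, biotype_path) {
  rel <- vapply(seq_len(nrow(ann)), function(i) {
    ex <- exon_blocks(ann[i, ])
    paste(ex[, 1] - ann$start[i], collapse = ",")
  }, character(1))
  sizes <- ann$exon_sizes
  nblocks <- vapply(strsplit(sizes, ","), length, integer(1))
  bed <- data.frame(ann$chrom, ann$start, ann$end, ann$gene_id, 0L, ann$strand,
                    ann$start, ann$end, "0,0,0", nblocks, sizes, rel)
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(gene_id = ann$gene_id, biotype = ann$biotype),
                     biotype_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(ann)
}

#' @rdname write_annotation_bed12
#' @export
read_annotation_bed12 <- function(bed_path, biotype_path) {
  bed <- utils::read.delim(bed_path, header = FALSE, stringsAsFactors = FALSE)
  bt <- utils::read.delim(biotype_path, stringsAsFactors = FALSE)
  abs_starts <- vapply(seq_len(nrow(bed)), function(i) {
    rel <- as.numeric(strsplit(as.character(bed[i, 12]), ",")[[1]])
    paste(rel + bed[i, 2], collapse = ",")
  }, character(1))
  df <- data.frame(gene_id = bed[[4]], chrom = bed[[1]], start = bed[[2]],
                   end = bed[[3]], strand = bed[[6]],
                   biotype = bt$biotype[match(bed[[4]], bt$gene_id)],
                   exon_starts = abs_starts, exon_sizes = as.character(bed[[11]]),
                   stringsAsFactors = FALSE)
  gene_annotation(df)
}
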