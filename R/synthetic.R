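# Synthetic-data generator: annotation, expression and miRNA-target tables
# with planted ground truth for parameter-recovery testing.

# fixed layout constants (base pairs); PCGs are laid out on one chromosome in
# regular slots so that hosted/intergenic lncRNA placement is always feasible
# when the chromosome is long enough.
.PCG_LEN <- 10000
.PCG_GAP <- 6000
.LAYOUT_OFFSET <- 2000
# PCG exon structure relative to locus start: three exons, two long introns
.PCG_EXONS <- cbind(start = c(0, 4600, 9600), end = c(400, 5000, 10000))

#' Study design for the expression simulator
#'
#' Describes the sample layout the simulator emulates: paired tumor/normal
#' samples across several tissue types, log2-scale intensities with additive
#' Gaussian noise.  Defaults mirror a four-tissue design of 20/20/16/20
#' patient pairs.
#'
#' @param tissues Unique, non-empty tissue labels.
#' @param pairs_per_tissue Number of patient pairs per tissue (scalar or one
#'   value per tissue); at least 2 each.
#' @param noise_sd Additive Gaussian noise SD in log2 units (> 0).
#' @param baseline_mean Baseline log2 intensity.
#' @param seed Integer seed controlling all simulator randomness.
#' @return A `study_design` list.
#' @export
study_design <- function(tissues = c("gastric", "colon", "liver", "lung"),
                         pairs_per_tissue = c(20, 20, 16, 20),
                         noise_sd = 0.5, baseline_mean = 8, seed = 1) {
  if (length(tissues) == 0 || anyDuplicated(tissues)) abort("tissues must be non-empty and unique")
  if (length(pairs_per_tissue) == 1) pairs_per_tissue <- rep(pairs_per_tissue, length(tissues))
  if (length(pairs_per_tissue) != length(tissues)) abort("pairs_per_tissue must match tissues")
  if (any(pairs_per_tissue < 2)) abort("need at least 2 pairs per tissue")
  if (!is.numeric(noise_sd) || noise_sd <= 0) abort("noise_sd must be > 0")
  structure(list(tissues = as.character(tissues),
                 pairs_per_tissue = as.integer(pairs_per_tissue),
                 noise_sd = noise_sd, baseline_mean = baseline_mean,
                 seed = as.integer(seed)), class = "study_design")
}

#' Planted-effect specification for the expression simulator
#'
#' Defaults state the simulated world used throughout the test-suite:
#' common differential expression at log2 effect 1.5 in tumor samples of all
#' tissues, tissue-specific blocks elevated by 2.0 log2 units in all samples
#' of one tissue, and cis lncRNA-neighbor pairs sharing a latent factor
#' calibrated to Pearson r = 0.8.  Every planted gene carries exactly one
#' role.
#'
#' @param n_up_pcg,n_down_pcg,n_up_lnc,n_down_lnc Counts of common-DE genes
#'   per biotype and direction.
#' @param de_effect Log2 shift applied to tumor samples (0 disables the role).
#' @param block_genes_per_tissue Genes per tissue-specific block.
#' @param block_elevation Log2 elevation of block genes in all samples
#'   (tumor and normal) of their tissue (0 disables).
#' @param n_cis Number of cis-correlated (lncRNA, neighbor-PCG) pairs.
#' @param cis_r Target Pearson correlation of cis pairs (0 < r <= 1).
#' @param n_cerna Number of cis pairs additionally wired as ceRNA triples
#'   with a shared miRNA (must be <= `n_cis`).
#' @param gene_sd Optional named vector of per-gene noise SDs overriding the
#'   design's homoscedastic `noise_sd`.
#' @return A `truth_spec` list.
#' @export
truth_spec <- function(n_up_pcg = 30, n_down_pcg = 30, n_up_lnc = 10, n_down_lnc = 10,
                       de_effect = 1.5, block_genes_per_tissue = 15,
                       block_elevation = 2.0, n_cis = 10, cis_r = 0.8,
                       n_cerna = 5, gene_sd = NULL) {
  if (n_cerna > n_cis) abort("n_cerna must be <= n_cis")
  if (!is.null(cis_r) && (cis_r <= 0 || cis_r > 1)) abort("cis_r must be in (0, 1]")
  if (!all(is.finite(c(de_effect, block_elevation)))) abort("effect sizes must be finite")
  structure(as.list(environment()), class = "truth_spec")
}

largest_remainder <- function(n, props) {
  raw <- n * props
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a synthetic single-chromosome gene annotation
#'
#' Lays out `n_pcg` three-exon protein-coding loci in regular slots and
#' places `n_lnc` lncRNAs so that each realizes its intended genomic-context
#' class: intergenic lncRNAs in inter-locus gaps (or a tail region),
#' antisense lncRNAs inside a host locus on the opposite strand, intronic
#' lncRNAs wholly within a host intron on the same strand, and sense-exonic
#' lncRNAs overlapping a host exon on the same strand.  The intended class of
#' every lncRNA is recorded in the `intended_class` attribute for round-trip
#' testing.
#'
#' @param n_pcg Number of PCGs (>= 1).
#' @param n_lnc Number of lncRNAs (>= 0).
#' @param class_mix Named proportions over
#'   `c("intergenic", "antisense", "intronic", "sense_exonic")`, summing to 1.
#' @param chrom_length Chromosome length in bp; an error is raised if the
#'   requested loci cannot be packed.
#' @param seed Integer seed.
#' @return A `gene_annotation` with attribute `intended_class`.
#' @export
make_annotation <- function(n_pcg = 200, n_lnc = 80,
                            class_mix = c(intergenic = 0.45, antisense = 0.25,
                                          intronic = 0.15, sense_exonic = 0.15),
                            chrom_length = 1e7, seed = 1) {
  if (!is_count(n_pcg, 1L)) abort("n_pcg must be a count >= 1")
  if (!is_count(n_lnc, 0L)) abort("n_lnc must be a count >= 0")
  classes <- c("intergenic", "antisense", "intronic", "sense_exonic")
  if (!all(names(class_mix) %in% classes)) abort("class_mix names must be the four context classes")
  mix <- stats::setNames(rep(0, 4), classes)
  mix[names(class_mix)] <- class_mix
  if (abs(sum(mix) - 1) > 1e-9) abort("class_mix must sum to 1")
  counts <- stats::setNames(largest_remainder(n_lnc, mix), classes)

  # feasibility: PCG slots plus a tail region for overflow intergenic lncRNAs
  n_gaps <- max(0L, n_pcg - 1L)
  overflow <- max(0L, counts[["intergenic"]] - n_gaps)
  pcg_span <- .LAYOUT_OFFSET + n_pcg * .PCG_LEN + n_gaps * .PCG_GAP
  tail_span <- if (overflow > 0) 2000 + overflow * 4000 else 0
  if (pcg_span + tail_span + 1000 > chrom_length) {
    abort("infeasible packing: need ", pcg_span + tail_span + 1000,
          " bp but chrom_length is ", chrom_length, class = "lncprofiler_packing")
  }

  local_seed(seed, {
    pcg_start <- .LAYOUT_OFFSET + (seq_len(n_pcg) - 1) * (.PCG_LEN + .PCG_GAP)
    pcg_strand <- sample(c("+", "-"), n_pcg, replace = TRUE)
    pcg <- data.frame(
      gene_id = sprintf("PCG%04d", seq_len(n_pcg)), chrom = "chrS",
      start = pcg_start, end = pcg_start + .PCG_LEN, strand = pcg_strand,
      biotype = "pcg",
      exon_starts = vapply(pcg_start, function(s) paste(s + .PCG_EXONS[, 1], collapse = ","), character(1)),
      exon_sizes = paste(.PCG_EXONS[, 2] - .PCG_EXONS[, 1], collapse = ","),
      stringsAsFactors = FALSE)

    lnc_rows <- list()
    intended <- character(0)
    lid <- 0
    add_lnc <- function(start, len, strand, class) {
      lid <<- lid + 1
      id <- sprintf("LNC%04d", lid)
      lnc_rows[[length(lnc_rows) + 1]] <<- data.frame(
        gene_id = id, chrom = "chrS", start = start, end = start + len,
        strand = strand, biotype = "lncrna",
        exon_starts = as.character(start), exon_sizes = as.character(len),
        stringsAsFactors = FALSE)
      intended[id] <<- class
    }

    # hosted classes cycle over PCG slots
    hosted <- rep(c("antisense", "intronic", "sense_exonic"),
                  times = counts[c("antisense", "intronic", "sense_exonic")])
    if (length(hosted)) {
      host_idx <- rep_len(seq_len(n_pcg), length(hosted))
      for (k in seq_along(hosted)) {
        s <- pcg_start[host_idx[k]]
        hs <- pcg_strand[host_idx[k]]
        cls <- hosted[k]
        if (cls == "antisense") {
          len <- sample(300:2000, 1)
          add_lnc(s + sample(1000:6000, 1), len,
                  if (hs == "+") "-" else "+", "antisense")
        } else if (cls == "intronic") {
          len <- sample(300:2000, 1)
          lo <- s + 600
          hi <- s + 4600 - len - 100        # stay inside intron 1 [400, 4600)
          add_lnc(sample(lo:hi, 1), len, hs, "intronic")
        } else {
          len <- sample(800:1500, 1)
          add_lnc(s + sample(4000:4400, 1), len, hs, "sense_exonic")
          # spans into exon 2 [4600, 5000) by construction
        }
      }
    }

    # intergenic: one per inter-locus gap, overflow in the tail
    n_ig <- counts[["intergenic"]]
    if (n_ig > 0) {
      gap_slots <- min(n_ig, n_gaps)
      if (gap_slots > 0) {
        use_gaps <- if (n_gaps > 1) sort(sample(seq_len(n_gaps), gap_slots)) else 1L
        for (g in use_gaps) {
          gap_lo <- pcg_start[g] + .PCG_LEN
          len <- sample(300:2000, 1)
          add_lnc(sample((gap_lo + 1500):(gap_lo + .PCG_GAP - 1500 - len), 1),
                  len, sample(c("+", "-"), 1), "intergenic")
        }
      }
      if (overflow > 0) {
        tail0 <- pcg_start[n_pcg] + .PCG_LEN + 2000
        for (k in seq_len(overflow)) {
          len <- sample(300:2000, 1)
          add_lnc(tail0 + (k - 1) * 4000, len, sample(c("+", "-"), 1), "intergenic")
        }
      }
    }

    df <- if (length(lnc_rows)) rbind(pcg, do.call(rbind, lnc_rows)) else pcg
    ann <- gene_annotation(df[order(df$start, df$gene_id), ])
    rownames(ann) <- NULL
    attr(ann, "intended_class") <- intended
    ann
  })
}

#' Simulate a paired tumor/normal expression matrix with planted truth
#'
#' Null genes are i.i.d. `baseline + N(0, noise_sd^2)` on the log2 scale.
#' Common-DE genes are shifted by `+/- de_effect` in the tumor samples of
#' every tissue; tissue-block genes are elevated in all samples (tumor and
#' normal) of one tissue; each cis pair (a lncRNA and its class-specific
#' neighbor PCG) shares a per-sample latent factor `f ~ N(0,1)` with loading
#' `a` chosen analytically from `r = a^2 / (a^2 + noise_sd^2)`, i.e.
#' `a = noise_sd * sqrt(r / (1 - r))` (for `r = 1` the genes take unit
#' loading so the correlation tends to 1 as `noise_sd -> 0`).  ceRNA triples
#' are cis pairs additionally assigned a miRNA; their targeting edges are
#' realized by [simulate_mirna_targets()].
#'
#' @param annotation A `gene_annotation` (e.g. from [make_annotation()]).
#' @param design A [study_design()].
#' @param spec A [truth_spec()].
#' @return List with elements `expr` (an [expr_matrix()]) and `truth`
#'   (a `planted_truth` list: `common_de`, `tissue_blocks`, `cis_pairs`,
#'   `cerna_triples`, `null_genes`).
#' @export
simulate_expression <- function(annotation, design = study_design(), spec = truth_spec()) {
  if (nrow(annotation) == 0) abort("annotation is empty")
  local_seed(design$seed, {
    # sample sheet
    sm <- do.call(rbind, lapply(seq_along(design$tissues), function(i) {
      t <- design$tissues[i]
      p <- sprintf("%s_p%02d", t, seq_len(design$pairs_per_tissue[i]))
      data.frame(sample_id = c(paste0(p, "_T"), paste0(p, "_N")),
                 tissue = t, condition = rep(c("tumor", "normal"), each = length(p)),
                 patient_id = c(p, p), stringsAsFactors = FALSE)
    }))
    genes <- annotation$gene_id
    n_s <- nrow(sm)
    sd_vec <- rep(design$noise_sd, length(genes))
    names(sd_vec) <- genes
    if (!is.null(spec$gene_sd)) sd_vec[names(spec$gene_sd)] <- spec$gene_sd

    vals <- matrix(stats::rnorm(length(genes) * n_s, mean = design$baseline_mean,
                                sd = rep(sd_vec, times = n_s)),
                   nrow = length(genes), ncol = n_s,
                   dimnames = list(genes, sm$sample_id))

    pcg_ids <- annotation$gene_id[annotation$biotype == "pcg"]
    lnc_ids <- annotation$gene_id[annotation$biotype == "lncrna"]
    used <- character(0)
    take <- function(pool, n, what) {
      pool <- setdiff(pool, used)
      if (length(pool) < n) abort("not enough free ", what, " genes to plant requested roles")
      picked <- if (n > 0) sample(pool, n) else character(0)
      used <<- c(used, picked)
      picked
    }

    # cis pairs first: they constrain both a lncRNA and its neighbor PCG
    cis <- data.frame(lnc_id = character(0), pcg_id = character(0), target_r = numeric(0))
    if (spec$n_cis > 0) {
      ctx <- classify_lncrnas(annotation)
      elig <- ctx[!is.na(ctx$neighbor_pcg_id), , drop = FALSE]
      elig <- elig[!duplicated(elig$neighbor_pcg_id), , drop = FALSE]
      if (nrow(elig) < spec$n_cis) abort("not enough lncRNAs with neighbors for requested cis pairs")
      pick <- sort(sample(seq_len(nrow(elig)), spec$n_cis))
      cis <- data.frame(lnc_id = elig$lnc_id[pick], pcg_id = elig$neighbor_pcg_id[pick],
                        target_r = spec$cis_r, stringsAsFactors = FALSE)
      used <- c(used, cis$lnc_id, cis$pcg_id)
      for (k in seq_len(nrow(cis))) {
        f <- stats::rnorm(n_s)
        for (g in c(cis$lnc_id[k], cis$pcg_id[k])) {
          a <- if (spec$cis_r >= 1) 1 else sd_vec[g] * sqrt(spec$cis_r / (1 - spec$cis_r))
          vals[g, ] <- design$baseline_mean + a * f + stats::rnorm(n_s, sd = sd_vec[g])
        }
      }
    }

    # common-DE genes: shifted in tumor samples of all tissues
    common_de <- data.frame(gene_id = character(0), direction = character(0),
                            effect = numeric(0), biotype = character(0))
    if (spec$de_effect != 0) {
      picks <- list(up = c(take(pcg_ids, spec$n_up_pcg, "pcg"), take(lnc_ids, spec$n_up_lnc, "lncrna")),
                    down = c(take(pcg_ids, spec$n_down_pcg, "pcg"), take(lnc_ids, spec$n_down_lnc, "lncrna")))
      tum <- sm$condition == "tumor"
      for (dir in names(picks)) {
        g <- picks[[dir]]
        if (length(g)) {
          shift <- if (dir == "up") spec$de_effect else -spec$de_effect
          vals[g, tum] <- vals[g, tum] + shift
          common_de <- rbind(common_de, data.frame(
            gene_id = g, direction = dir, effect = shift,
            biotype = ifelse(g %in% pcg_ids, "pcg", "lncrna"), stringsAsFactors = FALSE))
        }
      }
    }

    # tissue blocks: elevated in ALL samples of one tissue
    blocks <- data.frame(gene_id = character(0), tissue = character(0), elevation = numeric(0))
    if (spec$block_elevation != 0 && spec$block_genes_per_tissue > 0) {
      for (t in design$tissues) {
        g <- take(genes, spec$block_genes_per_tissue, "any")
        vals[g, sm$tissue == t] <- vals[g, sm$tissue == t] + spec$block_elevation
        blocks <- rbind(blocks, data.frame(gene_id = g, tissue = t,
                                           elevation = spec$block_elevation,
                                           stringsAsFactors = FALSE))
      }
    }

    # ceRNA triples: the first n_cerna cis pairs, each with its own miRNA
    cerna <- data.frame(mirna_id = character(0), lnc_id = character(0), pcg_id = character(0))
    if (spec$n_cerna > 0 && nrow(cis) >= spec$n_cerna) {
      cerna <- data.frame(mirna_id = sprintf("mir-%04d", seq_len(spec$n_cerna)),
                          lnc_id = cis$lnc_id[seq_len(spec$n_cerna)],
                          pcg_id = cis$pcg_id[seq_len(spec$n_cerna)],
                          stringsAsFactors = FALSE)
    }

    truth <- structure(list(
      common_de = common_de, tissue_blocks = blocks, cis_pairs = cis,
      cerna_triples = cerna,
      null_genes = setdiff(genes, c(used, cis$lnc_id, cis$pcg_id))),
      class = "planted_truth")
    list(expr = expr_matrix(vals, sm), truth = truth)
  })
}

#' Simulate a miRNA-target table
#'
#' Emulates the output of a sequence-based target predictor: both targeting
#' edges of every planted ceRNA triple are present, and every other
#' (miRNA, gene) pair is included independently with probability
#' `background_rate`.
#'
#' @param annotation A `gene_annotation` (its genes form the target universe).
#' @param truth A `planted_truth` (from [simulate_expression()]), or `NULL`
#'   for no planted triples.
#' @param background_rate Per-pair background edge probability in `[0, 1)`.
#' @param n_mirna miRNA universe size (planted miRNAs are drawn from the
#'   start of this universe).
#' @param seed Integer seed.
#' @return Data frame with columns `mirna_id`, `target_id`, `score`.
#' @export
simulate_mirna_targets <- function(annotation, truth = NULL, background_rate = 0.01,
                                   n_mirna = 100, seed = 1) {
  if (background_rate < 0 || background_rate >= 1) abort("background_rate must be in [0, 1)")
  mirnas <- sprintf("mir-%04d", seq_len(n_mirna))
  planted <- if (!is.null(truth) && nrow(truth$cerna_triples)) {
    with(truth$cerna_triples, data.frame(
      mirna_id = rep(mirna_id, 2), target_id = c(lnc_id, pcg_id),
      score = 180, stringsAsFactors = FALSE))
  } else {
    data.frame(mirna_id = character(0), target_id = character(0), score = numeric(0))
  }
  mirnas <- union(mirnas, planted$mirna_id)
  local_seed(seed, {
    bg <- data.frame(mirna_id = character(0), target_id = character(0), score = numeric(0))
    if (background_rate > 0) {
      grid_m <- rep(mirnas, each = nrow(annotation))
      grid_g <- rep(annotation$gene_id, times = length(mirnas))
      keep <- stats::runif(length(grid_m)) < background_rate
      bg <- data.frame(mirna_id = grid_m[keep], target_id = grid_g[keep],
                       score = round(stats::runif(sum(keep), 150, 200)),
                       stringsAsFactors = FALSE)
    }
    out <- rbind(planted, bg)
    out <- out[!duplicated(out[, c("mirna_id", "target_id")]), , drop = FALSE]
    out <- out[order(out$mirna_id, out$target_id), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Write the planted truth as a machine-readable JSON sidecar
#'
#' @param truth A `planted_truth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, dataframe = "rows", auto_unbox = FALSE)
  invisible(path)
}
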