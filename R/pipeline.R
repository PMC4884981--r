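# End-to-end orchestration: config validation, staged execution with derived
# seeds, run manifest, qPCR utility and a small CLI.

#' Build / validate a pipeline configuration
#'
#' Exactly one of `synthetic` (generation parameters) or `inputs` (file
#' paths) must be supplied.  Thresholds default to the values used
#' throughout the pipeline: DE FDR 0.05 and fold change 1.5, coexpression
#' r > 0.45 with p < 0.01, enrichment q < 0.1, SOM margin 1.0 log2.
#'
#' @param synthetic List of generator parameters (see Details) or `NULL`.
#' @param inputs List of file paths (`matrix`, `samples`, `bed`, `biotype`,
#'   `gmt`, `targets`, optional `scale` = `"log2"`/`"linear"`) or `NULL`.
#' @param thresholds Named overrides of
#'   `list(alpha = 0.05, fc = 1.5, r_min = 0.45, p_max = 0.01, q_max = 0.1,
#'   som_delta = 1.0, som_alpha = 0.05)`.
#' @param som Named overrides of `list(rows = 13, cols = 9, epochs = 50)`.
#' @param gba Named overrides of
#'   `list(n_perm = 200, max_lnc = 20, min_set = 5, max_set = 500)`.
#' @param cerna Named overrides of `list(all_lnc = FALSE)`; with `all_lnc`
#'   the network covers every classified lncRNA instead of only common
#'   DE-lncRNAs.
#' @param seed Root seed; all stage seeds are derived from it.
#'
#' @details Synthetic block fields (all optional): `n_pcg`, `n_lnc`,
#'   `class_mix`, `chrom_length`, `tissues`, `pairs_per_tissue`, `noise_sd`,
#'   `baseline_mean`, truth-spec fields (see [truth_spec()]), `n_mirna`,
#'   `background_rate`, `n_gene_sets`, `set_size`.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = NULL, inputs = NULL, thresholds = list(),
                            som = list(), gba = list(), cerna = list(), seed = 1) {
  if (is.null(synthetic) == is.null(inputs))
    abort("exactly one of `synthetic` or `inputs` must be given",
          class = "lncprofiler_config")
  thr <- utils::modifyList(list(alpha = 0.05, fc = 1.5, r_min = 0.45, p_max = 0.01,
                                q_max = 0.1, som_delta = 1.0, som_alpha = 0.05),
                           thresholds)
  if (thr$alpha <= 0 || thr$alpha >= 1 || thr$fc <= 1 || thr$r_min < 0 ||
      thr$r_min >= 1 || thr$p_max <= 0 || thr$p_max > 1)
    abort("threshold out of valid range", class = "lncprofiler_config")
  structure(list(
    synthetic = synthetic, inputs = inputs, thresholds = thr,
    som = utils::modifyList(list(rows = 13, cols = 9, epochs = 50), som),
    gba = utils::modifyList(list(n_perm = 200, max_lnc = 20, min_set = 5, max_set = 500), gba),
    cerna = utils::modifyList(list(all_lnc = FALSE), cerna),
    seed = as.integer(seed)), class = "pipeline_config")
}

#' Read a pipeline configuration from a JSON file
#'
#' @param path JSON file with the fields of [pipeline_config()].
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw[intersect(names(raw),
    c("synthetic", "inputs", "thresholds", "som", "gba", "cerna", "seed"))])
}

synthetic_stage <- function(cfg, seeds) {
  sb <- cfg$synthetic
  get <- function(name, default) if (!is.null(sb[[name]])) sb[[name]] else default
  ann_args <- list(n_pcg = get("n_pcg", 200), n_lnc = get("n_lnc", 80),
                   chrom_length = get("chrom_length", 1e7), seed = seeds$annotation)
  if (!is.null(sb$class_mix)) ann_args$class_mix <- unlist(sb$class_mix)
  ann <- do.call(make_annotation, ann_args)
  design <- study_design(
    tissues = get("tissues", c("gastric", "colon", "liver", "lung")),
    pairs_per_tissue = get("pairs_per_tissue", c(20, 20, 16, 20)),
    noise_sd = get("noise_sd", 0.5), baseline_mean = get("baseline_mean", 8),
    seed = seeds$expression)
  ts_fields <- intersect(names(sb), names(formals(truth_spec)))
  spec <- do.call(truth_spec, sb[ts_fields])
  sim <- simulate_expression(ann, design, spec)
  targets <- simulate_mirna_targets(ann, sim$truth,
                                    background_rate = get("background_rate", 0.01),
                                    n_mirna = get("n_mirna", 100),
                                    seed = seeds$targets)
  # plumbing gene sets: random PCG sets standing in for a pathway collection
  pcgs <- ann$gene_id[ann$biotype == "pcg"]
  n_sets <- get("n_gene_sets", 10); set_size <- min(get("set_size", 20), length(pcgs))
  gene_sets <- local_seed(seeds$gene_sets, {
    stats::setNames(lapply(seq_len(n_sets), function(i) sample(pcgs, set_size)),
                    sprintf("SET_%02d", seq_len(n_sets)))
  })
  list(annotation = ann, expr = sim$expr, truth = sim$truth,
       targets = targets, gene_sets = gene_sets)
}

input_stage <- function(cfg) {
  io <- cfg$inputs
  em <- read_expr_tsv(io$matrix, io$samples)
  if (identical(io$scale, "linear")) em$values <- log2_transform(em$values)
  ann <- read_annotation_bed12(io$bed, io$biotype)
  targets <- if (!is.null(io$targets)) utils::read.delim(io$targets, stringsAsFactors = FALSE) else NULL
  gene_sets <- if (!is.null(io$gmt)) read_gmt(io$gmt, min_size = cfg$gba$min_set,
                                              max_size = cfg$gba$max_set) else list()
  list(annotation = ann, expr = em, truth = NULL, targets = targets,
       gene_sets = gene_sets)
}

#' Run the full analysis pipeline
#'
#' Executes preprocess -> differential expression -> genomic-context
#' annotation -> guilt-by-association enrichment -> ceRNA network -> SOM
#' tissue specificity from a validated configuration, writing every stage's
#' output under `outdir` plus a `manifest.json` recording derived seeds and
#' gene counts at each filter.
#'
#' @param config A [pipeline_config()] (or path to a JSON config).
#' @param outdir Output directory (created if needed).
#' @return The manifest, invisibly (a named list).
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) abort("config must be a pipeline_config",
                                                  class = "lncprofiler_config")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list(annotation = config$seed * 7L + 1L, expression = config$seed * 7L + 2L,
                targets = config$seed * 7L + 3L, gene_sets = config$seed * 7L + 4L,
                gba = config$seed * 7L + 5L, som = config$seed * 7L + 6L)
  thr <- config$thresholds
  stage <- "acquire"
  manifest <- list(root_seed = config$seed, seeds = seeds, thresholds = thr)
  out <- function(...) file.path(outdir, paste0(...))
  tryCatch({
    data <- if (!is.null(config$synthetic)) synthetic_stage(config, seeds) else input_stage(config)
    ann <- data$annotation; em <- data$expr
    biotype <- stats::setNames(ann$biotype, ann$gene_id)
    write_annotation_bed12(ann, out("annotation.bed"), out("biotype.tsv"))
    if (!is.null(data$truth)) write_truth_json(data$truth, out("truth.json"))
    manifest$counts <- list(genes = nrow(em$values), samples = ncol(em$values),
                            pcg = sum(ann$biotype == "pcg"),
                            lncrna = sum(ann$biotype == "lncrna"))

    stage <- "preprocess"
    em <- quantile_normalize(em)
    write_expr_tsv(em, out("expression.tsv"), out("samples.tsv"))

    stage <- "diffexpr"
    tissues <- unique(em$samples$tissue)
    de <- lapply(tissues, function(t)
      call_de(em, t, alpha = thr$alpha, fc_threshold = thr$fc, biotype = biotype))
    names(de) <- tissues
    for (t in tissues)
      utils::write.table(de[[t]], out("de_", t, ".tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    common <- intersect_common(de)
    common_tab <- data.frame(
      gene_id = unlist(common, use.names = FALSE),
      set = rep(names(common), lengths(common)))
    utils::write.table(common_tab, out("common_de_sets.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest$counts$de_per_tissue <- lapply(de, function(r) list(
      up = sum(r$direction == "up"), down = sum(r$direction == "down")))
    manifest$counts$common <- as.list(lengths(common))

    stage <- "annotate"
    contexts <- classify_lncrnas(ann)
    utils::write.table(contexts, out("lnc_contexts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest$counts$context_classes <- as.list(table(contexts$context_class))

    stage <- "gba"
    de_lnc <- c(common$common_up_lnc, common$common_down_lnc)
    pcg_ids <- ann$gene_id[ann$biotype == "pcg"]
    gs <- filter_gene_sets(data$gene_sets, pcg_ids, config$gba$min_set, config$gba$max_set)
    gba_lnc <- utils::head(de_lnc, config$gba$max_lnc)
    if (length(gba_lnc) >= 2 && length(gs) >= 2) {
      emat <- enrichment_matrix(em, gba_lnc, pcg_ids, gs,
                                n_perm = config$gba$n_perm, seed = seeds$gba)
      utils::write.table(
        data.frame(lnc_id = rownames(emat$NES), emat$NES, check.names = FALSE),
        out("nes_matrix.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$counts$nes_matrix <- dim(emat$NES)
    } else {
      manifest$counts$nes_matrix <- c(0L, 0L)
    }
    # cis-correlation comparison: DE-lncRNA neighbor pairs vs genome-wide
    pair_r <- function(rows) vapply(seq_len(nrow(rows)), function(i) {
      l <- rows$lnc_id[i]; g <- rows$neighbor_pcg_id[i]
      if (!(l %in% rownames(em$values)) || !(g %in% rownames(em$values))) return(NA_real_)
      stats::cor(em$values[l, ], em$values[g, ])
    }, numeric(1))
    ok_ctx <- contexts[!is.na(contexts$neighbor_pcg_id), , drop = FALSE]
    bg_r <- pair_r(ok_ctx)
    de_r <- bg_r[ok_ctx$lnc_id %in% de_lnc]
    if (length(stats::na.omit(de_r)) > 0) {
      ct <- cis_correlation_test(stats::na.omit(de_r), stats::na.omit(bg_r))
      manifest$cis_test <- list(U = ct$U, p = ct$p, n_de = length(stats::na.omit(de_r)))
    }

    stage <- "cerna"
    net_ctx <- if (config$cerna$all_lnc) ok_ctx else
      ok_ctx[ok_ctx$lnc_id %in% de_lnc, , drop = FALSE]
    net <- build_network(net_ctx, em, data$targets, r_min = thr$r_min, p_max = thr$p_max)
    motifs <- find_motifs(net)
    write_network_sif(net, out("network.sif"))
    write_network_graphml(net, out("network.graphml"))
    utils::write.table(motifs, out("cerna_motifs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(degree_table(net), out("network_degrees.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest$counts$network <- list(nodes = nrow(net$nodes), edges = nrow(net$edges),
                                    motifs = nrow(motifs))

    stage <- "som_spec"
    centered <- median_center(em$values)
    grid <- train_som(centered, rows = config$som$rows, cols = config$som$cols,
                      epochs = config$som$epochs, seed = seeds$som)
    bmu <- assign_bmu(grid, centered)
    utils::write.table(bmu, out("som_units.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    summ <- unit_tissue_means(bmu, em)
    utils::write.table(
      data.frame(unit = summ$units, summ$tissue_means, check.names = FALSE),
      out("som_unit_summary.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    specific <- select_specific_units(summ, delta = thr$som_delta, alpha = thr$som_alpha)
    spec_genes <- lapply(specific, function(u)
      as.character(sort(unlist(summ$members[as.character(u)], use.names = FALSE))))
    for (t in names(spec_genes))
      writeLines(spec_genes[[t]], out("specific_genes_", t, ".txt"))
    manifest$counts$specific_units <- lapply(specific, length)
    manifest$counts$specific_genes <- lapply(spec_genes, length)
    if (length(gs) > 0) {
      enr <- lapply(names(spec_genes), function(t) {
        g <- intersect(spec_genes[[t]], ann$gene_id)
        if (!length(intersect(g, unlist(gs)))) return(NULL)
        res <- enrich_unit_genes(g, gs, ann$gene_id, q_max = thr$q_max)
        if (nrow(res) == 0) return(NULL)
        cbind(tissue = t, res)
      })
      enr <- do.call(rbind, enr[!vapply(enr, is.null, logical(1))])
      if (!is.null(enr))
        utils::write.table(enr, out("specific_enrichment.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
    }

    manifest$outputs <- sort(setdiff(list.files(outdir), "manifest.json"))
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    invisible(manifest)
  }, error = function(e) {
    abort("pipeline stage '", stage, "' failed: ", conditionMessage(e),
          class = "lncprofiler_stage")
  })
}

#' Relative expression by the 2^-ddCt method
#'
#' `2^-((ct_target_sample - ct_ref_sample) - (ct_target_calibrator -
#' ct_ref_calibrator))`: the target gene's cycle threshold is normalized to
#' a reference gene (e.g. 18S rRNA) within each sample, then to a calibrator
#' sample.
#'
#' @param ct_target_sample,ct_ref_sample,ct_target_calibrator,ct_ref_calibrator
#'   Finite Ct values (vectorized).
#' @return Relative expression (1 when ddCt = 0, 0.5 per extra cycle).
#' @export
ddct_relative_expression <- function(ct_target_sample, ct_ref_sample,
                                     ct_target_calibrator, ct_ref_calibrator) {
  stopifnot_finite(c(ct_target_sample, ct_ref_sample,
                     ct_target_calibrator, ct_ref_calibrator), "Ct values")
  2^-((ct_target_sample - ct_ref_sample) - (ct_target_calibrator - ct_ref_calibrator))
}

#' Command-line entry point
#'
#' Subcommands: `run-all` (full pipeline), `simulate` (synthetic inputs
#' only); both take `--config <json>`, `--outdir <dir>` and optional
#' `--seed <int>` (overriding the config seed).  Returns 0 on success, 2 on
#' validation errors, 1 on runtime errors; the installed `cli/lncpipe`
#' script forwards this as the process exit status.
#'
#' @param args Character vector of CLI arguments.
#' @return Integer exit code, invisibly.
#' @export
lnc_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: lncpipe <run-all|simulate> --config <json> --outdir <dir> [--seed <int>]"
  get_opt <- function(flag) {
    i <- which(args == flag)
    if (length(i) == 1 && i < length(args)) args[i + 1] else NULL
  }
  if (length(args) < 1 || !args[1] %in% c("run-all", "simulate")) {
    message(usage); return(invisible(2L))
  }
  cfg_path <- get_opt("--config"); outdir <- get_opt("--outdir")
  if (is.null(cfg_path) || is.null(outdir)) { message(usage); return(invisible(2L)) }
  code <- tryCatch({
    cfg <- read_pipeline_config(cfg_path)
    seed <- get_opt("--seed")
    if (!is.null(seed)) cfg$seed <- as.integer(seed)
    if (args[1] == "simulate") {
      if (is.null(cfg$synthetic)) abort("simulate needs a synthetic config block",
                                        class = "lncprofiler_config")
      seeds <- list(annotation = cfg$seed * 7L + 1L, expression = cfg$seed * 7L + 2L,
                    targets = cfg$seed * 7L + 3L, gene_sets = cfg$seed * 7L + 4L)
      data <- synthetic_stage(cfg, seeds)
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      write_annotation_bed12(data$annotation, file.path(outdir, "annotation.bed"),
                             file.path(outdir, "biotype.tsv"))
      write_expr_tsv(data$expr, file.path(outdir, "expression.tsv"),
                     file.path(outdir, "samples.tsv"))
      utils::write.table(data$targets, file.path(outdir, "mirna_targets.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_truth_json(data$truth, file.path(outdir, "truth.json"))
    } else {
      run_pipeline(cfg, outdir)
    }
    0L
  },
  lncprofiler_config = function(e) { message("config error: ", conditionMessage(e)); 2L },
  error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(code)
}
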