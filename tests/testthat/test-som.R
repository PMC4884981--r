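# Batch SOM training, BMU assignment, tissue-specific unit selection.

test_that("training is deterministic and beats a random-prototype baseline", {
  withr::with_seed(2, x <- matrix(rnorm(200 * 10), 200, 10,
                                  dimnames = list(sprintf("g%03d", 1:200), NULL)))
  g1 <- train_som(x, rows = 4, cols = 3, epochs = 15, seed = 7)
  g2 <- train_som(x, rows = 4, cols = 3, epochs = 15, seed = 7)
  expect_identical(g1$prototypes, g2$prototypes)

  # quantization error: trained < random init, and non-increasing trend late
  qe <- g1$qe_history
  expect_lt(qe[length(qe)], qe[1])
  late <- qe[ceiling(length(qe) / 2):length(qe)]
  expect_true(all(diff(late) <= 1e-6))
  expect_error(train_som(matrix(c(1, NA), 1), 2, 2), "non-finite")
})

test_that("a single observation's BMU prototype converges to it", {
  x <- matrix(rnorm(6), 1, 6, dimnames = list("g1", NULL))
  grid <- suppressWarnings(train_som(x, rows = 2, cols = 2, epochs = 30, seed = 1))
  b <- assign_bmu(grid, x)
  expect_lt(b$distance, 1e-6)
})

test_that("well-separated clouds map to pure BMU regions", {
  purity <- vapply(1:10, function(s) {
    withr::with_seed(s, {
      k <- 3
      centers <- matrix(rnorm(k * 8, sd = 6), k, 8)
      lab <- rep(1:k, each = 40)
      x <- centers[lab, ] + matrix(rnorm(120 * 8, sd = 0.5), 120, 8)
      rownames(x) <- sprintf("g%03d", 1:120)
    })
    grid <- train_som(x, rows = 3, cols = 3, epochs = 20, seed = s)
    b <- assign_bmu(grid, x)
    # purity: fraction of genes whose unit's majority label matches their own
    agree <- unlist(lapply(split(seq_len(120), b$unit), function(i) {
      maj <- as.integer(names(which.max(table(lab[i]))))
      lab[i] == maj
    }))
    mean(agree)
  }, numeric(1))
  expect_gte(mean(purity), 0.9)
})

test_that("BMU assignment equals the exhaustive nearest-prototype scan", {
  withr::with_seed(5, {
    x <- matrix(rnorm(80 * 6), 80, 6, dimnames = list(sprintf("g%02d", 1:80), NULL))
    grid <- train_som(x, rows = 3, cols = 3, epochs = 10, seed = 3)
    b <- assign_bmu(grid, x)
    for (i in seq_len(nrow(x))) {
      d <- apply(grid$prototypes, 1, function(p) sqrt(sum((x[i, ] - p)^2)))
      expect_equal(b$unit[i], which.min(d))   # which.min = lowest-id tie-break
      expect_equal(b$distance[i], min(d), tolerance = 1e-9)
    }
    # a gene equal to a prototype maps to that unit with distance 0
    y <- rbind(grid$prototypes[5, , drop = FALSE])
    rownames(y) <- "probe"
    expect_equal(assign_bmu(grid, y)$unit, 5)
    expect_error(assign_bmu(grid, x[, 1:3]), "dimension")
  })
})

test_that("unit tissue means match hand arithmetic and conserve the grand mean", {
  v <- rbind(gA = c(1, 3, 5, 7), gB = c(2, 4, 6, 8))
  sm <- data.frame(sample_id = paste0("s", 1:4), tissue = rep(c("t1", "t2"), each = 2),
                   condition = c("tumor", "normal", "tumor", "normal"),
                   patient_id = c("p1", "p1", "p2", "p2"))
  colnames(v) <- sm$sample_id
  em <- expr_matrix(v, sm, check = FALSE)
  asn <- data.frame(gene_id = c("gA", "gB"), unit = c(1L, 1L), distance = 0)
  su <- unit_tissue_means(asn, em)
  # unit mean over {gA, gB}: t1 = mean(1,3,2,4) = 2.5, t2 = mean(5,7,6,8) = 6.5
  expect_equal(unname(su$tissue_means[1, ]), c(2.5, 6.5))

  # constant gene: every tissue mean equals the constant
  em2 <- expr_matrix(rbind(gC = setNames(rep(4, 4), sm$sample_id)), sm, check = FALSE)
  su2 <- unit_tissue_means(data.frame(gene_id = "gC", unit = 2L, distance = 0), em2)
  expect_true(all(su2$tissue_means == 4))

  # member-count-weighted grand mean equals matrix grand mean
  withr::with_seed(3, {
    v3 <- matrix(rnorm(40), 10, 4, dimnames = list(sprintf("g%02d", 1:10), sm$sample_id))
    em3 <- expr_matrix(v3, sm, check = FALSE)
    asn3 <- data.frame(gene_id = rownames(v3), unit = sample(1:3, 10, TRUE), distance = 0)
    su3 <- unit_tissue_means(asn3, em3)
    counts <- lengths(su3$members)
    expect_equal(sum(rowMeans(su3$sample_means) * counts) / sum(counts),
                 mean(v3))
  })
})

test_that("specific-unit selection needs margin plus rank test, monotone in delta", {
  sm <- data.frame(sample_id = sprintf("s%02d", 1:24),
                   tissue = rep(c("t1", "t2", "t3"), each = 8),
                   condition = rep(c("tumor", "normal"), 12),
                   patient_id = sprintf("p%02d", rep(1:12, each = 2)))
  withr::with_seed(8, {
    v <- matrix(rnorm(10 * 24, 8, 0.3), 10, 24,
                dimnames = list(sprintf("g%02d", 1:10), sm$sample_id))
    v[1:3, sm$tissue == "t1"] <- v[1:3, sm$tissue == "t1"] + 2  # t1 block
  })
  em <- expr_matrix(v, sm, check = FALSE)
  asn <- data.frame(gene_id = rownames(v), unit = c(1L, 1L, 1L, rep(2L, 7)),
                    distance = 0)
  su <- unit_tissue_means(asn, em)
  sel1 <- select_specific_units(su, delta = 1, alpha = 0.05)
  expect_equal(sel1$t1, 1L)
  expect_length(sel1$t2, 0)

  # all-equal means select nothing; raising delta never adds units
  sel_hi <- select_specific_units(su, delta = 3, alpha = 0.05)
  expect_true(all(lengths(sel_hi) <= lengths(sel1)))
  em_flat <- expr_matrix(matrix(8, 10, 24, dimnames = dimnames(v)), sm, check = FALSE)
  su_flat <- unit_tissue_means(asn, em_flat)
  expect_true(all(lengths(select_specific_units(su_flat, delta = 0.5)) == 0))
})

test_that("unit-gene enrichment reproduces the exact hand case", {
  u <- sprintf("u%02d", 1:10)
  # universe 10, term covers 5, list of 4 all inside: p = C(5,4)/C(10,4) = 5/210
  res <- target_set_overrepresentation(u[1:4], list(GO1 = u[1:5]), u)
  expect_equal(res$p, 5 / 210)
  full <- target_set_overrepresentation(u[1:4], list(GO1 = u), u)
  expect_equal(full$p, 1)
  kept <- enrich_unit_genes(u[1:4], list(GO1 = u[1:5], GO2 = u), u, q_max = 0.1)
  expect_equal(kept$set, "GO1")
  expect_error(enrich_unit_genes("zz", list(GO1 = u), u), "disjoint")
})

test_that("planted tissue blocks are recovered through the SOM path", {
  hits <- total <- 0
  for (s in 1:3) {
    ann <- make_annotation(n_pcg = 150, n_lnc = 50, seed = s)
    sim <- simulate_expression(ann, study_design(pairs_per_tissue = 8, seed = s * 11),
                               truth_spec(n_up_pcg = 0, n_down_pcg = 0, n_up_lnc = 0,
                                          n_down_lnc = 0, de_effect = 0,
                                          block_genes_per_tissue = 12,
                                          block_elevation = 2, n_cis = 0, n_cerna = 0))
    centered <- median_center(sim$expr$values)
    grid <- train_som(centered, rows = 5, cols = 4, epochs = 25, seed = s)
    bmu <- assign_bmu(grid, centered)
    su <- unit_tissue_means(bmu, sim$expr)
    sel <- select_specific_units(su, delta = 1, alpha = 0.05)
    for (t in unique(sim$truth$tissue_blocks$tissue)) {
      block <- sim$truth$tissue_blocks$gene_id[sim$truth$tissue_blocks$tissue == t]
      in_sel <- unlist(su$members[as.character(sel[[t]])], use.names = FALSE)
      hits <- hits + length(intersect(block, in_sel))
      total <- total + length(block)
    }
  }
  expect_gte(hits / total, 0.9)
})
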