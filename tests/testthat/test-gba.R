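# Correlation-weighted enrichment and the cis-correlation comparison.

test_that("pearson_r_with_p matches hand values and is symmetric", {
  x <- c(1, 2, 3, 4, 5)
  perfect <- pearson_r_with_p(x, 2 * x + 1)
  expect_equal(perfect$r, 1)
  expect_equal(perfect$p, 0)
  expect_equal(pearson_r_with_p(c(1, 2, 3), c(1, 3, 2))$r, 0.5)
  withr::with_seed(3, { a <- rnorm(10); b <- rnorm(10) })
  expect_equal(pearson_r_with_p(a, b), pearson_r_with_p(b, a))
  expect_error(pearson_r_with_p(c(1, 1, 1), c(1, 2, 3)), "zero-variance")
  # p agrees with cor.test
  ct <- cor.test(a, b)
  got <- pearson_r_with_p(a, b)
  expect_equal(got$p, ct$p.value, tolerance = 1e-12)
})

test_that("rank_by_correlation orders PCGs by r with deterministic ties", {
  withr::with_seed(5, {
    pm <- matrix(rnorm(50 * 12), 50, 12,
                 dimnames = list(sprintf("P%02d", 1:50), sprintf("s%02d", 1:12)))
    lnc <- pm["P07", ] + rnorm(12, sd = 1e-8)  # near-copy of P07
    prof <- rank_by_correlation(lnc, pm, "lncX")
    expect_equal(prof$gene_ids[1], "P07")
    expect_equal(prof$r[1], 1, tolerance = 1e-6)
    expect_equal(prof$N, 50)
    expect_true(all(diff(prof$r) <= 0))

    # brute-force top-10 agreement
    rs <- apply(pm, 1, cor, y = lnc)
    expect_setequal(prof$gene_ids[1:10], names(sort(-rs)[1:10]))

    # negating the lncRNA reverses the ranking (r has no exact ties here)
    rev_prof <- rank_by_correlation(-lnc, pm)
    expect_equal(rev_prof$gene_ids, rev(prof$gene_ids))
    expect_error(rank_by_correlation(lnc[1:5], pm), "mismatch")
  })
})

test_that("enrichment score hits the derived 3-gene extremes", {
  prof <- structure(list(lnc_id = "l", gene_ids = c("a", "b", "c"),
                         r = c(2, 1, 1), N = 3L), class = "ranked_profile")
  expect_equal(enrichment_score(prof, "a")$ES, 1.0)
  expect_equal(enrichment_score(prof, "c")$ES, -1.0)
  expect_error(enrichment_score(prof, character(0)), "hit some")
  expect_error(enrichment_score(prof, c("a", "b", "c")), "hit some")
})

test_that("ES equals the brute-force running sum on random instances", {
  withr::with_seed(8, {
    for (rep in 1:100) {
      N <- sample(10:80, 1)
      ids <- sprintf("g%03d", seq_len(N))
      r <- sort(rnorm(N), decreasing = TRUE)
      prof <- structure(list(lnc_id = "l", gene_ids = ids, r = r, N = N),
                        class = "ranked_profile")
      set <- sample(ids, sample(seq_len(N - 1), 1))
      p <- sample(c(0, 1), 1)
      expect_equal(enrichment_score(prof, set, p = p)$ES,
                   oracle_es(ids, r, set, p = p), tolerance = 1e-12)
    }
  })
})

test_that("ES is within [-1, 1] and antisymmetric under rank reversal", {
  withr::with_seed(13, {
    for (rep in 1:20) {
      N <- 30
      ids <- sprintf("g%02d", 1:N)
      half <- sort(abs(rnorm(N / 2)), decreasing = TRUE)
      w <- c(half, rev(half))          # palindromic |weights|
      prof <- structure(list(lnc_id = "l", gene_ids = ids, r = w, N = N),
                        class = "ranked_profile")
      # reversed ranking: gene order flipped, each gene keeps its |weight|
      rev_prof <- structure(list(lnc_id = "l", gene_ids = rev(ids), r = w, N = N),
                            class = "ranked_profile")
      set <- sample(ids, 8)
      es <- enrichment_score(prof, set)$ES
      expect_gte(es, -1); expect_lte(es, 1)
      expect_equal(enrichment_score(rev_prof, set)$ES, -es, tolerance = 1e-12)
    }
  })
})

test_that("NES normalization is centered near +/-1 and deterministic", {
  withr::with_seed(21, {
    N <- 100
    ids <- sprintf("g%03d", 1:N)
    r <- sort(rnorm(N), decreasing = TRUE)
    prof <- structure(list(lnc_id = "l", gene_ids = ids, r = r, N = N),
                      class = "ranked_profile")
    nes <- vapply(1:50, function(i)
      normalize_es(prof, sample(ids, 10), n_perm = 100, seed = i)$NES, numeric(1))
    expect_lt(abs(mean(abs(nes)) - 1), 0.1)
  })
  prof <- structure(list(lnc_id = "l", gene_ids = sprintf("g%02d", 1:40),
                         r = seq(2, -2, length.out = 40), N = 40L),
                    class = "ranked_profile")
  a <- normalize_es(prof, sprintf("g%02d", 1:6), n_perm = 200, seed = 42)
  b <- normalize_es(prof, sprintf("g%02d", 1:6), n_perm = 200, seed = 42)
  expect_identical(a, b)
  expect_error(normalize_es(prof, "g01", n_perm = 10), "n_perm")
})

test_that("a top-loaded planted set is significant", {
  # all members in the top decile of N = 200
  ids <- sprintf("g%03d", 1:200)
  r <- seq(3, -3, length.out = 200)
  prof <- structure(list(lnc_id = "l", gene_ids = ids, r = r, N = 200L),
                    class = "ranked_profile")
  hits <- sum(vapply(1:20, function(s) {
    set <- withr::with_seed(s, sample(ids[1:20], 15))
    normalize_es(prof, set, n_perm = 200, seed = s)$p < 0.05
  }, logical(1)))
  expect_gte(hits, 19)  # >= 95% of seeds
})

test_that("permutation p-values are super-uniform under the null", {
  withr::with_seed(31, {
    N <- 60
    ids <- sprintf("g%02d", 1:N)
    r <- sort(rnorm(N), decreasing = TRUE)
    prof <- structure(list(lnc_id = "l", gene_ids = ids, r = r, N = N),
                      class = "ranked_profile")
    ps <- vapply(1:300, function(i)
      normalize_es(prof, sample(ids, 8), n_perm = 100, seed = 1000 + i)$p,
      numeric(1))
    ks <- suppressWarnings(ks.test(ps, "punif"))
    # null p-values should not be anticonservative
    expect_gt(mean(ps), 0.4)
    expect_gt(ks$p.value, 1e-4)
  })
})

test_that("enrichment_matrix clusters identical lncRNAs together", {
  ann <- make_annotation(n_pcg = 40, n_lnc = 10, seed = 2)
  sim <- simulate_expression(ann, study_design(tissues = c("tA", "tB"),
                                               pairs_per_tissue = 6, seed = 3),
                             truth_spec(n_up_pcg = 0, n_down_pcg = 0, n_up_lnc = 0,
                                        n_down_lnc = 0, de_effect = 0,
                                        block_elevation = 0, n_cis = 0, n_cerna = 0))
  ex <- sim$expr
  lncs <- grep("^LNC", rownames(ex$values), value = TRUE)[1:3]
  # make lnc2 identical to lnc1
  ex$values[lncs[2], ] <- ex$values[lncs[1], ]
  pcgs <- grep("^PCG", rownames(ex$values), value = TRUE)
  sets <- list(S1 = pcgs[1:10], S2 = pcgs[11:20], S3 = pcgs[21:30])
  emat <- enrichment_matrix(ex, lncs, pcgs, sets, n_perm = 100, seed = 5)
  expect_equal(dim(emat$NES), c(3, 3))
  expect_equal(emat$NES[lncs[1], ], emat$NES[lncs[2], ])
  expect_true(all(sign(emat$NES) == sign(emat$ES)))
})

test_that("cis_correlation_test matches exact U counting and null behavior", {
  # strongly separated: tiny one-sided p
  sep <- cis_correlation_test(rep(0.9, 20), rep(0.0, 20))
  expect_lt(sep$p, 0.001)
  expect_equal(sep$U, 400)

  withr::with_seed(17, {
    for (rep in 1:10) {
      x <- rnorm(sample(5:30, 1)); y <- rnorm(sample(5:30, 1))
      expect_equal(cis_correlation_test(x, y)$U, oracle_mwu(x, y))
    }
    # identical distributions: p near uniform, here just check it is not tiny
    ps <- vapply(1:20, function(i) cis_correlation_test(rnorm(15), rnorm(15))$p,
                 numeric(1))
    expect_gt(mean(ps), 0.25)
  })
  expect_error(cis_correlation_test(numeric(0), 1), "non-empty")
})

test_that("GMT round trip with size filtering", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c(paste(c("SET_A", "desc", sprintf("g%02d", 1:12)), collapse = "\t"),
               paste(c("SET_B", "desc", "g01", "g02"), collapse = "\t"),
               paste(c("SET_C", "desc", sprintf("g%02d", 5:20)), collapse = "\t")),
             path)
  suppressMessages(sets <- read_gmt(path, min_size = 5, max_size = 100))
  expect_named(sets, c("SET_A", "SET_C"))
  expect_length(sets$SET_A, 12)
  suppressMessages(
    expect_named(read_gmt(path, universe = sprintf("g%02d", 1:8), min_size = 5),
                 "SET_A"))
})
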