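# Tri-color network construction, motif enumeration, degrees, enrichment.

# deterministic fixture: 2 lncRNAs with neighbors, one correlated pair,
# one miRNA targeting both members of the correlated pair
cerna_fixture <- function(r_pair = 0.95, seed = 2) {
  withr::with_seed(seed, {
    n <- 40
    f <- rnorm(n)
    v <- rbind(
      LNC1 = 8 + f + rnorm(n, sd = 0.2),
      PCG1 = 8 + f + rnorm(n, sd = 0.2),
      LNC2 = 8 + rnorm(n),
      PCG2 = 8 + rnorm(n))
    sm <- data.frame(sample_id = sprintf("s%02d", 1:n), tissue = "tA",
                     condition = rep(c("tumor", "normal"), n / 2),
                     patient_id = sprintf("p%02d", rep(1:(n / 2), each = 2)))
    colnames(v) <- sm$sample_id
    em <- expr_matrix(v, sm, check = FALSE)
    ctx <- data.frame(lnc_id = c("LNC1", "LNC2"), context_class = "antisense",
                      neighbor_pcg_id = c("PCG1", "PCG2"), distance = 0, flag = "")
    targets <- data.frame(mirna_id = c("mirA", "mirA", "mirB"),
                          target_id = c("LNC1", "PCG1", "LNC2"), score = 160)
    list(em = em, ctx = ctx, targets = targets)
  })
}

test_that("build_network applies strict thresholds and canonical order", {
  fx <- cerna_fixture()
  net <- build_network(fx$ctx, fx$em, fx$targets)
  expect_s3_class(net, "tricolor_network")
  # LNC1-PCG1 correlated -> coexpr edge; LNC2-PCG2 independent -> none
  cx <- net$edges[net$edges$type == "coexpr", ]
  expect_equal(cx$from, "LNC1")
  expect_equal(nrow(net$edges[net$edges$type == "neighbor", ]), 2)

  # boundary: r exactly at threshold is NOT an edge (strict >)
  r_val <- cx$r
  net_b <- build_network(fx$ctx, fx$em, fx$targets, r_min = r_val)
  expect_equal(nrow(net_b$edges[net_b$edges$type == "coexpr", ]), 0)

  # no target table: only lncRNA/mRNA nodes
  net0 <- build_network(fx$ctx, fx$em, NULL)
  expect_true(all(net0$nodes$type %in% c("lncrna", "mrna")))

  # shuffled inputs give the identical canonical network
  shuf <- fx$ctx[2:1, ]
  tshuf <- fx$targets[c(3, 1, 2), ]
  expect_identical(build_network(shuf, fx$em, tshuf), net)
})

test_that("the antisense minimal ceRNA pattern yields exactly one motif", {
  fx <- cerna_fixture()
  net <- build_network(fx$ctx, fx$em, fx$targets)
  motifs <- find_motifs(net)
  expect_equal(nrow(motifs), 1)
  expect_equal(motifs$mirna_id, "mirA")
  expect_equal(motifs$lnc_id, "LNC1")
  expect_equal(motifs$mrna_id, "PCG1")
  expect_true(motifs$r > 0.45 && motifs$p < 0.01)

  # removing the coexpression edge kills the motif
  net2 <- net
  net2$edges <- net2$edges[net2$edges$type != "coexpr", ]
  expect_equal(nrow(find_motifs(net2)), 0)
})

test_that("motifs equal exhaustive enumeration on random networks", {
  for (s in 1:15) {
    net <- random_network(seed = s)
    got <- find_motifs(net)
    key <- if (nrow(got)) sort(paste(got$mirna_id, got$lnc_id, got$mrna_id,
                                     sep = "|")) else character(0)
    expect_identical(key, oracle_motifs(net), info = paste("seed", s))
  }
})

test_that("motif count is monotone non-increasing under edge deletion", {
  withr::with_seed(6, {
    net <- random_network(n_mirna = 6, n_lnc = 8, n_mrna = 8, seed = 99)
    n0 <- nrow(find_motifs(net))
    for (rep in 1:10) {
      drop <- sample(nrow(net$edges), 3)
      net2 <- net
      net2$edges <- net2$edges[-drop, ]
      expect_lte(nrow(find_motifs(net2)), n0)
    }
  })
})

test_that("every motif's nodes and five edges exist (self-validation)", {
  net <- random_network(n_mirna = 8, n_lnc = 10, n_mrna = 10, seed = 123)
  motifs <- find_motifs(net)
  ed <- net$edges
  has <- function(f, t, ty) any(ed$from == f & ed$to == t & ed$type == ty)
  for (i in seq_len(nrow(motifs))) {
    expect_true(has(motifs$mirna_id[i], motifs$lnc_id[i], "targeting"))
    expect_true(has(motifs$mirna_id[i], motifs$mrna_id[i], "targeting"))
    expect_true(has(motifs$lnc_id[i], motifs$mrna_id[i], "neighbor"))
    expect_true(has(motifs$lnc_id[i], motifs$mrna_id[i], "coexpr"))
  }
})

test_that("degree_table counts match hand counts and the handshake lemma", {
  fx <- cerna_fixture()
  net <- build_network(fx$ctx, fx$em, fx$targets)
  dt <- degree_table(net)
  # hand count: LNC1 has neighbor + coexpr + incoming targeting = 3
  expect_equal(dt$total[dt$id == "LNC1"], 3)
  expect_equal(dt$targeting[dt$id == "mirA"], 2)
  expect_equal(sum(dt$targeting[dt$type == "mirna"]),
               sum(net$edges$type == "targeting"))
  expect_equal(sum(dt$total), 2 * nrow(net$edges))
})

test_that("hypergeometric overrepresentation matches exact tail sums", {
  universe <- sprintf("u%02d", 1:10)
  # list identical to the 5-gene target set: p = 1/252
  res <- target_set_overrepresentation(universe[1:5],
                                       list(m1 = universe[1:5]), universe)
  expect_equal(res$p, 1 / 252)

  # disjoint list and set: p >= 0.5
  res2 <- target_set_overrepresentation(universe[1:3],
                                        list(m1 = universe[6:9]), universe)
  expect_gte(res2$p, 0.5)

  withr::with_seed(10, {
    for (rep in 1:30) {
      N <- sample(6:12, 1)
      u <- sprintf("x%02d", seq_len(N))
      set <- sample(u, sample(1:(N - 1), 1))
      lst <- sample(u, sample(1:(N - 1), 1))
      res <- target_set_overrepresentation(lst, list(s = set), u)
      k <- length(intersect(lst, set))
      expect_equal(res$p, oracle_hyper_tail(k, length(set), N, length(lst)),
                   tolerance = 1e-12)
    }
  })
  expect_error(target_set_overrepresentation("a", list(s = "a"), character(0)),
               "empty universe")
})

test_that("SIF and GraphML exports are loadable text", {
  fx <- cerna_fixture()
  net <- build_network(fx$ctx, fx$em, fx$targets)
  sif <- withr::local_tempfile(fileext = ".sif")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network_sif(net, sif)
  lines <- readLines(sif)
  expect_length(lines, nrow(net$edges))
  expect_true(all(grepl("\t(targets|neighbor|coexpr)\t", lines)))
  write_network_graphml(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), nrow(net$nodes))
  expect_equal(igraph::gsize(g), nrow(net$edges))
})
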