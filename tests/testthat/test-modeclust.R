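test_that("kernel similarity reproduces the hand-computed mapping sums", {
  g1 <- make_graph(c("HYDROPHOBIC", "HYDROPHOBIC"),
                   rbind(c(0, 0, 0), c(2, 0, 0)))
  g2 <- make_graph(c("HYDROPHOBIC", "HYDROPHOBIC"),
                   rbind(c(0, 0, 0), c(2.5, 0, 0)))
  ## raw k12 = 4 (size-1) + 2 * k_e(2.0, 2.5) = 5; k11 = k22 = 6
  expect_equal(smk_similarity(g1, g2), 5 / 6, tolerance = 1e-12)
  expect_equal(smk_similarity(g1, g1), 1)
  g3 <- make_graph(c("IONIC_POS", "IONIC_POS"), rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(smk_similarity(g1, g3), 0)
  empty <- make_graph(character(), matrix(numeric(0), 0, 3))
  expect_equal(smk_similarity(empty, g1), 0)
})

test_that("kernel similarity equals brute-force mapping enumeration on random graphs", {
  set.seed(7)
  for (k in 1:60) {
    g1 <- random_graph(sample(1:5, 1))
    g2 <- random_graph(sample(1:5, 1))
    expect_equal(smk_similarity(g1, g2), smk_oracle(g1, g2),
                 tolerance = 1e-9)
  }
})

test_that("kernel similarity is symmetric, bounded, and non-increasing in edge perturbation", {
  set.seed(8)
  for (k in 1:20) {
    g1 <- random_graph(sample(2:5, 1)); g2 <- random_graph(sample(2:5, 1))
    s <- smk_similarity(g1, g2)
    expect_equal(s, smk_similarity(g2, g1), tolerance = 1e-12)
    expect_gte(s, 0); expect_lte(s, 1)
  }
  ## perturbing one edge away from its counterpart only lowers similarity
  base <- make_graph(c("HB_DONOR", "HB_DONOR"), rbind(c(0, 0, 0), c(2, 0, 0)))
  sims <- sapply(seq(0, 1.4, by = 0.2), function(delta) {
    g2 <- make_graph(c("HB_DONOR", "HB_DONOR"),
                     rbind(c(0, 0, 0), c(2 + delta, 0, 0)))
    smk_similarity(base, g2)
  })
  expect_true(all(diff(sims) <= 1e-12))
})

test_that("dbscan with min_samples 2 equals eps-graph connected components", {
  d <- matrix(c(0, .1, .1, 0), 2)
  expect_equal(dbscan_precomputed(d, 0.23, 2), c(1L, 1L))
  d3 <- matrix(c(0, .1, .9, .1, 0, .9, .9, .9, 0), 3)
  lab <- dbscan_precomputed(d3, 0.23, 2)
  expect_equal(lab[1], lab[2])
  expect_equal(lab[3], 0L)
  dall <- matrix(0.9, 4, 4); diag(dall) <- 0
  expect_equal(dbscan_precomputed(dall, 0.23, 2), rep(0L, 4))
  expect_error(dbscan_precomputed(matrix(c(0, 1, 2, 0), 2), 0.5, 2),
               "symmetric")
  ## oracle equivalence on random matrices
  set.seed(9)
  for (k in 1:60) {
    n <- sample(3:12, 1)
    x <- matrix(runif(n * 2), ncol = 2)
    d <- as.matrix(dist(x))
    eps <- runif(1, 0.05, 0.5)
    expect_true(same_partition(dbscan_precomputed(d, eps, 2),
                               dbscan_oracle_min2(d, eps)))
  }
})

test_that("binding-mode counting handles copies, singletons and planted families", {
  cfg <- pipeline_config()
  g <- make_graph(c("HB_DONOR", "HB_DONOR_MID"), rbind(c(0, 0, 0), c(0, 0, 1.5)))
  expect_equal(count_binding_modes(rep(list(g), 4), cfg)$n_modes, 1L)
  ## similarity 0.5 -> distance 0.5 > eps: two singleton modes
  ga <- make_graph("HYDROPHOBIC", matrix(c(0, 0, 0), 1))
  gb <- make_graph(c("HYDROPHOBIC", "IONIC_NEG", "IONIC_NEG"),
                   rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0)))
  s <- smk_similarity(ga, gb)
  expect_lt(s, 1 - cfg$mode_eps)
  ## inclusion merge pulls them back together afterwards
  expect_equal(count_binding_modes(list(ga, gb), cfg)$n_modes, 1L)
  ## two graphs with disjoint labels: two modes
  gc_ <- make_graph("AROMATIC", matrix(c(0, 0, 0), 1))
  gd <- make_graph("HB_ACCEPTOR", matrix(c(0, 0, 0), 1))
  expect_equal(count_binding_modes(list(gc_, gd), cfg)$n_modes, 2L)
})

test_that("planted mode families are recovered for K = 1..5", {
  cfg <- pipeline_config()
  for (K in 1:5) {
    fam <- suppressWarnings(synth_mode_family(K, n_per_mode = 2,
                                              sigma = 0.05, seed = 100 + K))
    graphs <- suppressWarnings(fragverse:::family_graphs(fam$complexes))
    mc <- count_binding_modes(graphs, cfg)
    expect_equal(mc$n_modes, K, info = paste("K =", K))
    ## labels agree with the planted assignment as a partition
    expect_true(same_partition(mc$labels, fam$truth$mode,
                               noise_a = rep(FALSE, length(mc$labels)),
                               noise_b = rep(FALSE, K * 2)))
  }
})

test_that("graph inclusion embeds label-preserving within edge tolerance", {
  g <- make_graph(c("HB_DONOR", "HYDROPHOBIC"), rbind(c(0, 0, 0), c(3, 0, 0)))
  expect_true(graph_included(g, g))
  g1 <- make_graph("HB_DONOR", matrix(c(0, 0, 0), 1))
  big <- make_graph(c("HB_DONOR", "AROMATIC", "HYDROPHOBIC"),
                    rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0)))
  expect_true(graph_included(g1, big))
  a <- make_graph(c("HB_DONOR", "HB_DONOR"), rbind(c(0, 0, 0), c(2, 0, 0)))
  b <- make_graph(c("HB_DONOR", "HB_DONOR"), rbind(c(0, 0, 0), c(3, 0, 0)))
  expect_false(graph_included(a, b, edge_tol = 0.5))
  expect_true(graph_included(a, b, edge_tol = 1.5))
  empty <- make_graph(character(), matrix(numeric(0), 0, 3))
  expect_true(graph_included(empty, a))
})

test_that("inclusion merging is transitive, idempotent, and never adds modes", {
  ga <- make_graph("HB_DONOR", matrix(c(0, 0, 0), 1))
  gb <- make_graph(c("HB_DONOR", "HYDROPHOBIC"),
                   rbind(c(0, 0, 0), c(3, 0, 0)))
  gc_ <- make_graph(c("HB_DONOR", "HYDROPHOBIC", "AROMATIC"),
                    rbind(c(0, 0, 0), c(3, 0, 0), c(0, 5, 0)))
  graphs <- list(ga, gb, gc_)
  clust <- structure(list(labels = 1:3, n_modes = 3L, merged_pairs = list()),
                     class = "mode_clustering")
  merged <- merge_included_clusters(clust, graphs)
  expect_equal(merged$n_modes, 1L)
  expect_lte(merged$n_modes, clust$n_modes)
  expect_equal(merge_included_clusters(merged, graphs)$n_modes, 1L)
  ## disjoint labels: unchanged
  gd <- make_graph("IONIC_NEG", matrix(c(0, 0, 0), 1))
  ge <- make_graph("AROMATIC", matrix(c(0, 0, 0), 1))
  c2 <- structure(list(labels = 1:2, n_modes = 2L, merged_pairs = list()),
                  class = "mode_clustering")
  expect_equal(merge_included_clusters(c2, list(gd, ge))$n_modes, 2L)
})

test_that("nested mode families collapse to one mode after the merge correction", {
  fam <- suppressWarnings(synth_mode_family(2, n_per_mode = 2, sigma = 0.02,
                                            seed = 17, nested = TRUE))
  graphs <- suppressWarnings(fragverse:::family_graphs(fam$complexes))
  expect_equal(count_binding_modes(graphs, pipeline_config())$n_modes, 1L)
})

test_that("symmetry-aware RMSD ignores automorphic relabelings and rigid motion", {
  hexm <- function(rot = 0, shift = c(0, 0, 0)) {
    ring <- t(sapply(0:5, function(k)
      c(1.39 * cos(k * pi / 3 + rot), 1.39 * sin(k * pi / 3 + rot), 0)))
    ring <- sweep(ring, 2, -shift)
    molecule(data.frame(name = paste0("C", 1:6), element = "C",
                        x = ring[, 1], y = ring[, 2], z = ring[, 3]),
             data.frame(i = 1:6, j = c(2:6, 1), order = 4L))
  }
  m <- hexm()
  expect_equal(symmetry_rmsd(m, m), 0, tolerance = 1e-9)
  ## 60-degree in-plane rotation is an automorphism: RMSD 0
  expect_equal(symmetry_rmsd(m, hexm(rot = pi / 3)), 0, tolerance = 1e-7)
  expect_equal(symmetry_rmsd(m, hexm(shift = c(5, 0, 0))), 0,
               tolerance = 1e-9)
  ## different species errors
  other <- molecule(data.frame(name = c("C1", "O1"), element = c("C", "O"),
                               x = c(0, 1.4), y = 0, z = 0),
                    data.frame(i = 1, j = 2, order = 1))
  expect_error(symmetry_rmsd(m, other), "species")
})
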