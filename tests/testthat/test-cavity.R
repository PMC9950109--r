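cloud_fixture <- function(seed = 1, n = 24, label = "HB_ACCEPTOR") {
  fragverse:::with_seed(seed, {
    lattice <- as.matrix(expand.grid(seq(-4.5, 4.5, 1.5),
                                     seq(-4.5, 4.5, 1.5),
                                     seq(-4.5, 4.5, 1.5)))
    lattice <- lattice[sqrt(rowSums(lattice^2)) <= 4.6, ]
    idx <- sample.int(nrow(lattice), n)
    lab <- rep(label, n)
    lab[sample.int(n, 5)] <- "HYDROPHOBIC"
    fragverse:::new_labeled_cloud(lattice[idx, ], lab, 1.5)
  })
}

test_that("cavity clouds obey the distance, clash and lattice constraints", {
  cfg <- pipeline_config()
  set.seed(21)
  for (k in 1:3) {
    cx <- suppressWarnings(synth_complex(
      mode_templates(corpus_safe = TRUE)[[k]], validate = FALSE))
    cx <- fragverse:::add_cavity_cage(cx, k)
    lig <- cx$ligands[[1]]
    site <- extract_site(cx, lig, cfg$site_radius)
    cloud <- generate_cavity_cloud(site, lig, cfg)
    expect_gt(nrow(cloud$points), 0)
    frag <- fragverse:::heavy_coords(lig$molecule)
    dfrag <- fragverse:::cross_dist(cloud$points, frag)
    expect_true(all(apply(dfrag, 1, min) <= cfg$cavity_fragment_dist + 1e-9))
    prot <- as.matrix(site$residues[!site$residues$is_h, c("x", "y", "z")])
    dprot <- fragverse:::cross_dist(cloud$points, prot)
    expect_true(all(apply(dprot, 1, min) >= cfg$clash_dist - 1e-9))
    ## points lie on the absolute lattice
    offs <- cloud$points / cfg$grid_spacing
    expect_true(max(abs(offs - round(offs))) < 1e-9)
  }
})

test_that("point labels follow the nearest protein atom's pharmacophore", {
  ## a site made only of carboxylate oxygens labels every non-DUMMY point NEGATIVE
  cfg <- pipeline_config()
  cx <- synth_complex(mode_templates(corpus_safe = TRUE)[[3]],
                      validate = FALSE)
  cx <- fragverse:::add_cavity_cage(cx, 3L)  # ASP OD1 cage
  ## strip the probe residues, keep only the cage
  cx$protein <- cx$protein[cx$protein$resname == "ASP", ]
  lig <- cx$ligands[[1]]
  site <- extract_site(cx, lig, cfg$site_radius)
  cloud <- generate_cavity_cloud(site, lig, cfg)
  expect_gt(nrow(cloud$points), 0)
  expect_true(all(cloud$labels %in% c("NEGATIVE", "DUMMY")))
  expect_true(any(cloud$labels == "NEGATIVE"))
})

test_that("a fragment in open solvent yields an empty cloud", {
  cfg <- pipeline_config()
  mol <- molecule(data.frame(name = c("C1", "C2"), element = "C",
                             x = c(0, 1.5), y = 0, z = 0),
                  perceive_bonds = TRUE)
  prot <- data.frame(chain = "A", resno = 1L, resname = "GLY", name = "N",
                     element = "N", x = 6, y = 0, z = 0, is_h = FALSE)
  cx <- fragverse:::new_complex("OPN1", prot,
                                list(list(het_code = "LIG", copy_index = 1L,
                                          chain = "A", resno = 900L,
                                          molecule = mol)))
  site <- extract_site(cx, cx$ligands[[1]], cfg$site_radius)
  cloud <- generate_cavity_cloud(site, cx$ligands[[1]], cfg)
  expect_equal(nrow(cloud$points), 0L)
})

test_that("cloud generation is equivariant under rigid motion of the complex", {
  cfg <- pipeline_config()
  cx <- synth_complex(mode_templates(corpus_safe = TRUE)[[1]],
                      validate = FALSE)
  cx <- fragverse:::add_cavity_cage(cx, 1L)
  lig <- cx$ligands[[1]]
  site <- extract_site(cx, lig, cfg$site_radius)
  cloud <- generate_cavity_cloud(site, lig, cfg)
  ## rigid motion: same label multiset and preserved pairwise geometry,
  ## up to lattice requantization
  R <- fragverse:::with_seed(5, fragverse:::random_rotation())
  t_ <- c(3, -2, 7)
  cx2 <- cx
  m <- cx2$ligands[[1]]$molecule
  m$atoms[, c("x", "y", "z")] <-
    sweep(as.matrix(m$atoms[, c("x", "y", "z")]) %*% R, 2, -t_)
  cx2$ligands[[1]]$molecule <- m
  cx2$protein[, c("x", "y", "z")] <-
    sweep(as.matrix(cx2$protein[, c("x", "y", "z")]) %*% R, 2, -t_)
  site2 <- extract_site(cx2, cx2$ligands[[1]], cfg$site_radius)
  cloud2 <- generate_cavity_cloud(site2, cx2$ligands[[1]], cfg)
  expect_equal(nrow(cloud2$points), nrow(cloud$points), tolerance = 0.2)
  cmp <- cavity_similarity(cloud, cloud2, cfg, seed = 11)
  expect_gte(cmp$score, 0.8)
})

test_that("cavity similarity is 1 on self, 0 on disjoint labels, and recovers planted transforms", {
  cfg <- pipeline_config()
  a <- cloud_fixture(seed = 3)
  expect_equal(cavity_similarity(a, a, cfg)$score, 1)
  d1 <- fragverse:::new_labeled_cloud(matrix(rnorm(30), 10),
                                      rep("HB_DONOR", 10), 1.5)
  d2 <- fragverse:::new_labeled_cloud(matrix(rnorm(30), 10),
                                      rep("NEGATIVE", 10), 1.5)
  expect_equal(cavity_similarity(d1, d2, cfg)$score, 0)
  set.seed(23)
  for (k in 1:3) {
    a <- cloud_fixture(seed = 30 + k)
    R <- fragverse:::random_rotation()
    tr <- runif(3, -8, 8)
    b <- fragverse:::new_labeled_cloud(sweep(a$points %*% R, 2, -tr),
                                       a$labels, a$spacing)
    cmp <- cavity_similarity(a, b, cfg, seed = 40 + k)
    expect_gte(cmp$score, 0.95)
    moved <- fragverse:::apply_transform(
      if (cmp$direction == 1) a$points else b$points, cmp$transform)
    target <- if (cmp$direction == 1) b$points else a$points
    rmsd <- sqrt(mean(rowSums((moved - target)^2)))
    expect_lte(rmsd, 0.5)
  }
})

test_that("cavity similarity is stable under independent rigid motions", {
  cfg <- pipeline_config()
  a <- cloud_fixture(seed = 51)
  b <- cloud_fixture(seed = 52, label = "HB_DONOR")
  s0 <- cavity_similarity(a, b, cfg, seed = 1)$score
  set.seed(53)
  for (k in 1:3) {
    R <- fragverse:::random_rotation()
    b2 <- fragverse:::new_labeled_cloud(
      sweep(b$points %*% R, 2, -runif(3, -5, 5)), b$labels, b$spacing)
    s <- cavity_similarity(a, b2, cfg, seed = 1)$score
    expect_lte(abs(s - s0), 0.05)
  }
})

test_that("cavity counting clusters same environments and separates planted ones", {
  cfg <- pipeline_config()
  a <- cloud_fixture(seed = 61)
  expect_equal(count_cavities(rep(list(a), 3), cfg), 1L)
  for (M in c(1L, 2L, 3L)) {
    cs <- synth_cavity_set(M, n_obs = 2L * M, label_noise = 0.05,
                           seed = 70 + M)
    expect_equal(count_cavities(cs$clouds, cfg), M, info = paste("M =", M))
  }
})

test_that("overlapping subsets of one environment cluster together", {
  ## two clouds sharing roughly two thirds of one environment's points
  env <- synth_cavity_set(1, n_obs = 1, transform_mag = 0, seed = 81,
                          n_points = 30)$clouds[[1]]
  n <- nrow(env$points)
  i1 <- 1:20; i2 <- 11:30
  c1 <- fragverse:::new_labeled_cloud(env$points[i1, ], env$labels[i1], 1.5)
  c2 <- fragverse:::new_labeled_cloud(env$points[i2, ], env$labels[i2], 1.5)
  cfg <- pipeline_config()
  s <- cavity_similarity(c1, c2, cfg, seed = 5)$score
  expect_gte(s, cfg$cavity_score_threshold)
  expect_equal(count_cavities(list(c1, c2), cfg), 1L)
})
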