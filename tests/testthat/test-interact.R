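make_lig <- function(atoms, bonds = NULL) {
  list(het_code = "LIG", copy_index = 1L, chain = "A", resno = 900L,
       molecule = molecule(atoms, bonds))
}

make_site <- function(prot) {
  structure(list(residues = prot, source_entry = "TST",
                 fragment_ref = c(het_code = "LIG", copy_index = 1),
                 site_radius = 6.5, empty = nrow(prot) == 0),
            class = "protein_site")
}

test_that("a donated hydrogen bond is detected from distance and angle", {
  lig <- make_lig(data.frame(name = c("N1", "H1"), element = c("N", "H"),
                             x = c(0, 0), y = c(0, 0), z = c(0, 1.01)),
                  data.frame(i = 1, j = 2, order = 1))
  prot <- data.frame(chain = "A", resno = 1L, resname = "GLY",
                     name = c("O", "C"), element = c("O", "C"),
                     x = 0, y = 0, z = c(2.9, 4.13), is_h = FALSE)
  ints <- detect_interactions(lig, make_site(prot))
  expect_equal(nrow(ints), 1L)
  expect_equal(ints$itype, "HB_DONOR")
  expect_equal(ints$distance, 2.9)
  expect_gte(ints$angle, 120)
  ## same geometry but H pointing away: angle fails, no bond
  lig2 <- make_lig(data.frame(name = c("N1", "H1"), element = c("N", "H"),
                              x = c(0, 0), y = c(0, 0), z = c(0, -1.01)),
                   data.frame(i = 1, j = 2, order = 1))
  expect_equal(nrow(detect_interactions(lig2, make_site(prot))), 0L)
})

test_that("contacts beyond all cutoffs yield no interaction", {
  lig <- make_lig(data.frame(name = c("C1", "C2"), element = "C",
                             x = c(0, 1.5), y = 0, z = 0),
                  data.frame(i = 1, j = 2, order = 1))
  prot <- data.frame(chain = "A", resno = 1L, resname = "LEU",
                     name = "CD1", element = "C",
                     x = 0, y = 0, z = 6.0, is_h = FALSE)
  expect_equal(nrow(detect_interactions(lig, make_site(prot))), 0L)
})

test_that("an ionic contact between opposite charges is detected, not a hydrogen bond", {
  lig <- make_lig(data.frame(name = "O1", element = "O", x = 0, y = 0, z = 0,
                             charge = -1L))
  prot <- data.frame(chain = "A", resno = 1L, resname = "ARG",
                     name = "NH1", element = "N",
                     x = 0, y = 0, z = 3.5, is_h = FALSE)
  ints <- suppressWarnings(detect_interactions(lig, make_site(prot)))
  expect_equal(ints$itype, "IONIC_NEG")
  expect_equal(ints$distance, 3.5)
})

test_that("interaction graphs follow the pseudo-atom construction rules", {
  ## empty input -> empty graph
  g0 <- build_interaction_graph(NULL)
  expect_equal(nrow(g0$nodes), 0L)
  ## one H-bond: ligand node + midpoint node, one edge of half the distance
  hb <- data.frame(itype = "HB_DONOR", lig_atom = 1, prot_atom = 1,
                   distance = 3, angle = 180,
                   lx = 0, ly = 0, lz = 0, px = 0, py = 0, pz = 3)
  g1 <- build_interaction_graph(hb)
  expect_equal(nrow(g1$nodes), 2L)
  expect_equal(as.numeric(g1$nodes[2, c("x", "y", "z")]), c(0, 0, 1.5))
  expect_equal(g1$nodes$label, c("HB_DONOR", "HB_DONOR_MID"))
  expect_equal(g1$D[1, 2], 1.5)
  ## two hydrophobic contacts 4 A apart: 2 nodes, edge 4
  hp <- data.frame(itype = "HYDROPHOBIC", lig_atom = 1:2, prot_atom = 1:2,
                   distance = 4, angle = NA,
                   lx = c(0, 4), ly = 0, lz = 0, px = c(0, 4), py = 0, pz = 4)
  g2 <- build_interaction_graph(hp)
  expect_equal(nrow(g2$nodes), 2L)
  expect_equal(g2$D[1, 2], 4)
})

test_that("node count equals interactions plus hydrogen bonds", {
  set.seed(41)
  for (k in 1:5) {
    K <- sample(1:5, 1)
    cx <- suppressWarnings(synth_complex(mode_templates()[[K]]))
    site <- extract_site(cx, cx$ligands[[1]])
    ints <- suppressWarnings(detect_interactions(cx$ligands[[1]], site))
    g <- build_interaction_graph(ints)
    n_hb <- sum(ints$itype %in% c("HB_DONOR", "HB_ACCEPTOR"))
    expect_equal(nrow(g$nodes), nrow(ints) + n_hb)
  }
})

test_that("graphs are invariant under rigid motion of the whole complex", {
  set.seed(42)
  cx <- synth_complex(mode_templates()[[2]])
  site <- extract_site(cx, cx$ligands[[1]])
  g <- build_interaction_graph(detect_interactions(cx$ligands[[1]], site))
  for (k in 1:5) {
    R <- fragverse:::random_rotation()
    t_ <- runif(3, -20, 20)
    cx2 <- cx
    m <- cx2$ligands[[1]]$molecule
    xyz <- as.matrix(m$atoms[, c("x", "y", "z")]) %*% R
    m$atoms[, c("x", "y", "z")] <- sweep(xyz, 2, -t_)
    cx2$ligands[[1]]$molecule <- m
    pxyz <- as.matrix(cx2$protein[, c("x", "y", "z")]) %*% R
    cx2$protein[, c("x", "y", "z")] <- sweep(pxyz, 2, -t_)
    site2 <- extract_site(cx2, cx2$ligands[[1]])
    g2 <- build_interaction_graph(
      detect_interactions(cx2$ligands[[1]], site2))
    expect_equal(sort(g2$nodes$label), sort(g$nodes$label))
    expect_equal(sort(g2$D[upper.tri(g2$D)]), sort(g$D[upper.tri(g$D)]),
                 tolerance = 1e-8)
  }
})

test_that("detection is deterministic and independent of atom input order", {
  cx <- suppressWarnings(synth_complex(mode_templates()[[5]]))
  site <- extract_site(cx, cx$ligands[[1]])
  i1 <- suppressWarnings(detect_interactions(cx$ligands[[1]], site))
  i2 <- suppressWarnings(detect_interactions(cx$ligands[[1]], site))
  expect_identical(i1, i2)
  ## permute protein atom order
  site3 <- site
  perm <- rev(seq_len(nrow(site$residues)))
  site3$residues <- site$residues[perm, ]
  i3 <- suppressWarnings(detect_interactions(cx$ligands[[1]], site3))
  expect_equal(sort(i3$itype), sort(i1$itype))
  expect_equal(sort(round(i3$distance, 9)), sort(round(i1$distance, 9)))
})
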