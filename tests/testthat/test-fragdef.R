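test_that("the fragment definition rejects each unwanted category for its reason", {
  cases <- list(
    list(smiles = "[O-]S(=O)(=O)[O-]", reason = "polyatomic_ion"),
    list(smiles = "OCC(O)CO", reason = "crystallization_additive"),
    list(smiles = "CCCCCC", reason = "linear_aliphatic"),
    list(smiles = "FC(F)(F)F", reason = "polyhalogenated"))
  for (cs in cases) {
    v <- classify_ligand(mol_from_smiles(cs$smiles))
    expect_false(v$accepted)
    expect_true(cs$reason %in% v$reject_reasons,
                info = paste(cs$smiles, "->", paste(v$reject_reasons,
                                                    collapse = ",")))
  }
  ## thymidine (MW 242.2, 17 heavy atoms) is a valid fragment
  thy <- classify_ligand(
    mol_from_smiles("Cc1cn(C2CC(O)C(CO)O2)c(=O)[nH]c1=O"))
  expect_true(thy$accepted)
  ## HET-code blocklist: glycerol under its additive code
  gol <- classify_ligand(mol_from_smiles("OCC(O)CO", het_code = "GOL"))
  expect_true("crystallization_additive" %in% gol$reject_reasons)
  ## MW / heavy-atom limits
  big <- classify_ligand(mol_from_smiles(
    "CC(C)Cc1ccc(cc1)C(C)C(=O)OCCOC(=O)C(C)c1ccc(CC(C)C)cc1"))
  expect_true("MW>=300" %in% big$reject_reasons)
  expect_true("heavy_atoms_out_of_range" %in% big$reject_reasons)
})

test_that("classify_ligand is deterministic and idempotent", {
  m <- mol_from_smiles("Cc1ccncc1")
  v1 <- classify_ligand(m); v2 <- classify_ligand(m)
  expect_identical(v1, v2)
  expect_true(v1$accepted)
})

test_that("the multi-entry filter counts distinct entries, not copies", {
  corpus <- data.frame(entry_id = c("E1", "E2", "E1"),
                       het_code = c("AAA", "AAA", "BBB"))
  expect_equal(filter_multi_entry(corpus), "AAA")
  twice_one_entry <- data.frame(entry_id = c("E1", "E1"),
                                het_code = c("CCC", "CCC"))
  expect_equal(filter_multi_entry(twice_one_entry), character())
  expect_equal(filter_multi_entry(data.frame(entry_id = character(),
                                             het_code = character())),
               character())
})

test_that("PAINS flags fire on interference motifs and stay silent on clean molecules", {
  expect_length(pains_flags(mol_from_smiles("C")), 0L)
  expect_length(pains_flags(mol_from_smiles("Cc1ccncc1")), 0L)
  expect_true("catechol_A" %in% pains_flags(mol_from_smiles("Oc1ccccc1O")))
  expect_true("quinone_A" %in%
                pains_flags(mol_from_smiles("CC1=CC(=O)C=CC1=O")))
})

test_that("rule-of-three violations are counted and monotone", {
  expect_equal(ro3_violations(data.frame(mw = 280, hbd = 2, hba = 3,
                                         alogp = 1.5, rot_bonds = 2)), 0L)
  expect_equal(ro3_violations(data.frame(mw = 310, hbd = 4, hba = 3,
                                         alogp = 2, rot_bonds = 1)), 2L)
  expect_equal(ro3_violations(data.frame(mw = 400, hbd = 5, hba = 6,
                                         alogp = 4, rot_bonds = 7)), 5L)
  ## worsening one descriptor never lowers the count
  base <- data.frame(mw = 280, hbd = 2, hba = 3, alogp = 1.5, rot_bonds = 2)
  n0 <- ro3_violations(base)
  for (col in names(base)) {
    worse <- base
    worse[[col]] <- worse[[col]] + 10
    expect_gte(ro3_violations(worse), n0)
  }
})

test_that("plane of best fit is zero for planar rings and matches the SVD oracle", {
  hex <- t(sapply(0:5, function(k)
    c(1.39 * cos(k * pi / 3), 1.39 * sin(k * pi / 3), 0)))
  expect_equal(compute_pbf(hex), 0)
  ## symmetric conformer: plane is z = 0, mean |z| = (4*0 + 2*0.9)/6 = 0.3
  conf <- rbind(c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0),
                c(0, 0, 0.9), c(0, 0, -0.9))
  expect_equal(compute_pbf(conf), 0.3, tolerance = 1e-9)
  ## rigid-motion invariance over random rotations
  set.seed(31)
  for (k in 1:10) {
    pts <- matrix(rnorm(24), ncol = 3)
    R <- fragverse:::random_rotation()
    moved <- sweep(pts %*% R, 2, -runif(3, -10, 10))
    expect_equal(compute_pbf(moved), compute_pbf(pts), tolerance = 1e-9)
  }
  expect_true(is.na(compute_pbf(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))))
  expect_true(is.na(compute_pbf(rbind(c(0, 0, 0), c(1, 0, 0)))))
})

test_that("Murcko scaffolds keep rings and linkers, drop side chains", {
  expect_equal(murcko_scaffold(mol_from_smiles("Cc1ccccc1"))$smiles,
               "c1ccccc1")
  expect_equal(nrow(murcko_scaffold(mol_from_smiles("CCCCCC"))$atoms), 0L)
  ## acyclic substituents do not change the scaffold
  s1 <- murcko_scaffold(mol_from_smiles("CCc1ccc(O)cc1"))$smiles
  s2 <- murcko_scaffold(mol_from_smiles("NCc1ccc(CO)cc1"))$smiles
  expect_equal(s1, s2)
  ## two-ring molecule keeps the linker
  biphenyl_like <- murcko_scaffold(mol_from_smiles("Cc1ccc(Cc2ccccc2)cc1"))
  expect_equal(sum(!biphenyl_like$atoms$is_h), 13L)
})

test_that("substructure contribution is the bond ratio, 1 iff exact, chirality-aware", {
  benzene <- mol_from_smiles("c1ccccc1")
  toluene <- mol_from_smiles("Cc1ccccc1")
  expect_equal(substructure_contribution(benzene, toluene), 6 / 7)
  expect_equal(substructure_contribution(benzene, benzene), 1)
  expect_true(is.na(substructure_contribution(toluene, benzene)))
  l_ala <- mol_from_smiles("N[C@@H](C)C(=O)O")
  d_ala <- mol_from_smiles("N[C@H](C)C(=O)O")
  expect_true(is.na(substructure_contribution(l_ala, d_ala,
                                              use_chirality = TRUE)))
  expect_equal(substructure_contribution(l_ala, d_ala,
                                         use_chirality = FALSE), 1)
})

test_that("descriptor block fields are consistent counts", {
  d <- compute_descriptors(mol_from_smiles("Cc1cn(C2CC(O)C(CO)O2)c(=O)[nH]c1=O"))
  expect_equal(d$heavy_atoms, 17L)
  expect_equal(d$mw, 242.23, tolerance = 0.01)
  expect_equal(d$rings, 2L)
  expect_true(all(unlist(d[c("hbd", "hba", "pos_atoms", "neg_atoms",
                             "rot_bonds", "rings", "stereocenters")]) >= 0))
  charged <- compute_descriptors(mol_from_smiles("C[N+](C)(C)CC([O-])=O"))
  expect_equal(charged$pos_atoms, 1)
  expect_equal(charged$neg_atoms, 1)
})
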