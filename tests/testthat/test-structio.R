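test_that("a minimal PDB parses into protein residues and a ligand", {
  lines <- c(
    "HEADER    TEST PROTEIN                            04-MAY-12   TST1",
    "REMARK   2 RESOLUTION.    1.80 ANGSTROMS.",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "HETATM    4  C1  LIG A 101       5.000   5.000   5.000  1.00  0.00           C",
    "HETATM    5  O1  LIG A 101       6.430   5.000   5.000  1.00  0.00           O",
    "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  cx <- read_structure(f)
  expect_s3_class(cx, "fragverse_complex")
  expect_equal(nrow(unique(cx$protein[, c("chain", "resno")])), 1L)
  expect_length(cx$ligands, 1L)
  expect_equal(n_heavy_atoms(cx$ligands[[1]]$molecule), 2L)
  expect_equal(cx$resolution, 1.8)
  expect_equal(as.Date(cx$deposition_date), as.Date("2012-05-04"))
})

test_that("waters are excluded and a protein-free PDB errors", {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "HETATM    2  O   HOH A 201       3.000   0.000   0.000  1.00  0.00           O",
    "HETATM    3  O   HOH A 202       4.000   0.000   0.000  1.00  0.00           O",
    "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  cx <- read_structure(f)
  expect_length(cx$ligands, 0L)
  f2 <- tempfile(fileext = ".pdb")
  writeLines(lines[2:4], f2)
  expect_error(read_structure(f2), "no protein")
})

test_that("PDB and MOL2 round trips preserve heavy atoms and coordinates", {
  cx <- synth_complex(mode_templates(corpus_safe = TRUE)[[5]], "RT01", "FRG")
  for (fmt in c("pdb", "mol2")) {
    f <- tempfile(fileext = paste0(".", fmt))
    if (fmt == "pdb") write_pdb(cx, f) else write_mol2(cx, f)
    cx2 <- read_structure(f)
    expect_equal(sum(!cx2$protein$is_h), sum(!cx$protein$is_h))
    m1 <- cx$ligands[[1]]$molecule
    m2 <- cx2$ligands[[1]]$molecule
    expect_equal(n_heavy_atoms(m2), n_heavy_atoms(m1))
    expect_equal(sort(m2$atoms$element[!m2$atoms$is_h]),
                 sort(m1$atoms$element[!m1$atoms$is_h]))
    d <- fragverse:::cross_dist(fragverse:::heavy_coords(m1),
                                fragverse:::heavy_coords(m2))
    expect_lt(max(apply(d, 1, min)), 1e-3)
  }
})

test_that("mmCIF structures are read with metadata", {
  f <- tempfile(fileext = ".cif")
  writeLines(minimal_cif_lines(), f)
  cx <- suppressWarnings(read_structure(f))
  expect_equal(nrow(cx$protein), 3L)
  expect_equal(cx$ligands[[1]]$het_code, "LIG")
  expect_equal(cx$resolution, 1.8)
  expect_equal(as.Date(cx$deposition_date), as.Date("2012-05-04"))
})

test_that("extract_site keeps exactly the residues within the radius", {
  mol <- molecule(data.frame(name = c("C1", "C2"), element = "C",
                             x = c(0, -1.5), y = 0, z = 0),
                  perceive_bonds = TRUE)
  prot <- data.frame(
    chain = "A", resno = c(1L, 2L), resname = "GLY",
    name = "N", element = "N",
    x = c(5, 8), y = 0, z = 0, is_h = FALSE)
  cx <- fragverse:::new_complex("TST1", prot,
                                list(list(het_code = "LIG", copy_index = 1L,
                                          chain = "A", resno = 900L,
                                          molecule = mol)))
  site <- extract_site(cx, cx$ligands[[1]], 6.5)
  expect_equal(unique(site$residues$resno), 1L)
  empty <- extract_site(cx, cx$ligands[[1]], 0.1)
  expect_true(empty$empty)
})

test_that("extract_site is monotone in the radius", {
  cx <- synth_complex(mode_templates()[[4]], "MON1", "FRG")
  radii <- c(2, 4, 6.5, 9)
  keys <- lapply(radii, function(r) {
    s <- extract_site(cx, cx$ligands[[1]], r)
    unique(paste(s$residues$chain, s$residues$resno))
  })
  for (k in seq_len(length(radii) - 1))
    expect_true(all(keys[[k]] %in% keys[[k + 1]]))
})

test_that("classify_rscc matches the density-fit classes at the boundaries", {
  expect_equal(classify_rscc(0.95), "FIT")
  expect_equal(classify_rscc(0.90), "PARTIAL")
  expect_equal(classify_rscc(0.80), "PARTIAL")
  expect_equal(classify_rscc(0.79), "POOR")
  expect_error(classify_rscc(1.2), "-1")
  ## partition property: exactly one class everywhere on a grid
  grid <- seq(-1, 1, by = 0.005)
  cls <- classify_rscc(grid)
  expect_true(all(cls %in% c("FIT", "PARTIAL", "POOR")))
  expect_false(any(is.na(cls)))
})

test_that("validation RSCC parsing averages site residues and reads the ligand", {
  res <- data.frame(chain = "A", resno = 1:3, resname = "ALA",
                    rscc = c(0.8, 0.9, 1.0))
  f <- write_validation_xml(tempfile(fileext = ".xml"), res,
                            ligand = list(chain = "A", resno = 101L,
                                          resname = "LIG", rscc = 0.85))
  site <- structure(list(residues = data.frame(chain = "A", resno = 1:3),
                         empty = FALSE), class = "protein_site")
  lig <- list(het_code = "LIG", copy_index = 1L, resno = 101L)
  rep <- parse_validation_rscc(f, site, lig)
  expect_equal(rep$site_mean_rscc, 0.9)
  expect_equal(rep$ligand_rscc, 0.85)
  expect_equal(rep$quality_class, "PARTIAL")
  ## residue absent from the file shrinks the denominator
  site4 <- structure(list(residues = data.frame(chain = "A", resno = 1:4),
                          empty = FALSE), class = "protein_site")
  expect_equal(parse_validation_rscc(f, site4, lig)$site_mean_rscc, 0.9)
  ## ligand absent -> NA, never 0
  f2 <- write_validation_xml(tempfile(fileext = ".xml"), res)
  rep2 <- parse_validation_rscc(f2, site, lig)
  expect_true(is.na(rep2$ligand_rscc))
})

test_that("hydrogen placement protonates donors and is idempotent", {
  ## ligand hydroxyl oxygen: exactly one H at the standard O-H length
  mol <- molecule(data.frame(name = c("C1", "C2", "O1"),
                             element = c("C", "C", "O"),
                             x = c(0, 1.5, 2.2), y = c(0, 0, 1.2), z = 0),
                  perceive_bonds = TRUE)
  prot <- data.frame(chain = "A", resno = 1L, resname = "GLY", name = "N",
                     element = "N", x = 15, y = 0, z = 0, is_h = FALSE)
  cx <- fragverse:::new_complex(
    "HYD1", prot, list(list(het_code = "ETO", copy_index = 1L, chain = "A",
                            resno = 900L, molecule = mol)))
  cxH <- ensure_hydrogens(cx)
  m <- cxH$ligands[[1]]$molecule
  hs <- which(m$atoms$is_h)
  expect_length(hs, 1L)
  oi <- which(m$atoms$element == "O")
  d <- sqrt(sum((as.numeric(m$atoms[oi, c("x", "y", "z")]) -
                   as.numeric(m$atoms[hs, c("x", "y", "z")]))^2))
  expect_equal(d, 0.96, tolerance = 1e-6)
  ## idempotence
  cxH2 <- ensure_hydrogens(cxH)
  expect_equal(nrow(cxH2$ligands[[1]]$molecule$atoms), nrow(m$atoms))
  expect_equal(sum(cxH2$protein$is_h), sum(cxH$protein$is_h))
})

test_that("a mid-chain backbone amide nitrogen receives exactly one hydrogen", {
  ## GLY-GLY dipeptide backbone with realistic bond geometry
  prot <- data.frame(
    chain = "A", resno = c(1L, 1L, 1L, 2L, 2L, 2L),
    resname = "GLY",
    name = c("N", "CA", "C", "N", "CA", "C"),
    element = c("N", "C", "C", "N", "C", "C"),
    x = c(0.00, 1.46, 2.20, 3.53, 4.45, 5.90),
    y = c(0.00, 0.00, 1.25, 1.20, 2.35, 2.20),
    z = 0, is_h = FALSE)
  mol <- molecule(data.frame(name = c("C1", "C2"), element = "C",
                             x = c(20, 21.5), y = 0, z = 0),
                  perceive_bonds = TRUE)
  cx <- fragverse:::new_complex(
    "DIP1", prot, list(list(het_code = "LIG", copy_index = 1L, chain = "A",
                            resno = 900L, molecule = mol)))
  cxH <- ensure_hydrogens(cx)
  h2 <- cxH$protein[cxH$protein$resno == 2L & cxH$protein$is_h, ]
  ## residue 2's N is mid-chain (bonded to its CA and residue 1's C)
  n2 <- cxH$protein[cxH$protein$resno == 2L & cxH$protein$name == "N", ]
  d <- sqrt((h2$x - n2$x)^2 + (h2$y - n2$y)^2 + (h2$z - n2$z)^2)
  expect_equal(sum(d < 1.2), 1L)
})
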