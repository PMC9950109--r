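# Independent oracles and small fixture builders shared across tests.

# interaction graph straight from node labels + coordinates
make_graph <- function(labels, coords) {
  coords <- matrix(coords, ncol = 3)
  ints <- NULL
  g <- list(nodes = data.frame(x = coords[, 1], y = coords[, 2],
                               z = coords[, 3], label = labels),
            D = if (nrow(coords)) fragverse:::cross_dist(coords, coords) else
              matrix(numeric(0), 0, 0))
  class(g) <- "interaction_graph"
  g
}

random_graph <- function(n, label_pool = c("HB_DONOR", "HB_ACCEPTOR",
                                           "HYDROPHOBIC", "AROMATIC")) {
  make_graph(sample(label_pool, n, replace = TRUE),
             matrix(runif(n * 3, 0, 6), ncol = 3))
}

# brute-force subgraph-matching-kernel: enumerate every subset of g1 nodes
# (size 1..max_nodes) and every injective assignment into g2, multiply edge
# kernels over all mapped node pairs
smk_oracle_raw <- function(g1, g2, max_nodes = 3L, dmax = 1.0) {
  n1 <- nrow(g1$nodes); n2 <- nrow(g2$nodes)
  if (n1 == 0L || n2 == 0L) return(0)
  ke <- function(d1, d2) max(0, 1 - abs(d1 - d2) / dmax)
  inj_seqs <- function(pool, s) {
    if (s == 0L) return(list(integer()))
    out <- list()
    for (p in pool) for (rest in inj_seqs(setdiff(pool, p), s - 1L))
      out[[length(out) + 1L]] <- c(p, rest)
    out
  }
  total <- 0
  for (s in seq_len(min(max_nodes, n1, n2))) {
    subs <- utils::combn(n1, s)
    assigns <- inj_seqs(seq_len(n2), s)
    for (c1 in seq_len(ncol(subs))) {
      idx1 <- subs[, c1]
      for (idx2 in assigns) {
        if (any(g1$nodes$label[idx1] != g2$nodes$label[idx2])) next
        w <- 1
        if (s >= 2L) for (p in 1:(s - 1)) for (q in (p + 1):s)
          w <- w * ke(g1$D[idx1[p], idx1[q]], g2$D[idx2[p], idx2[q]])
        total <- total + w
      }
    }
  }
  total
}

smk_oracle <- function(g1, g2, max_nodes = 3L, dmax = 1.0) {
  k12 <- smk_oracle_raw(g1, g2, max_nodes, dmax)
  if (k12 == 0) return(0)
  k12 / sqrt(smk_oracle_raw(g1, g1, max_nodes, dmax) *
               smk_oracle_raw(g2, g2, max_nodes, dmax))
}

# DBSCAN oracle at min_samples = 2: connected components of the eps graph,
# isolated vertices are noise (label 0)
dbscan_oracle_min2 <- function(d, eps) {
  n <- nrow(d)
  adj <- d <= eps
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  sizes <- table(comp)
  labels <- integer(n)
  next_id <- 0L
  for (cc in names(sizes)[sizes >= 2]) {
    next_id <- next_id + 1L
    labels[comp == as.integer(cc)] <- next_id
  }
  labels
}

# label-invariant partition comparison
same_partition <- function(a, b, noise_a = a == 0, noise_b = b == 0) {
  if (any(noise_a != noise_b)) return(FALSE)
  a2 <- a[!noise_a]; b2 <- b[!noise_b]
  if (length(a2) == 0L) return(TRUE)
  identical(as.integer(factor(a2, levels = unique(a2))),
            as.integer(factor(b2, levels = unique(b2))))
}

# Smith-Waterman score oracle (Gotoh affine gaps; a gap of length L costs
# open + L * extend, matching the package's convention)
sw_oracle_score <- function(s1, s2, mat, open = 10, extend = 0.5) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b)
  M <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F_ <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    E[i + 1, j + 1] <- max(E[i + 1, j] - extend,
                           M[i + 1, j] - open - extend)
    F_[i + 1, j + 1] <- max(F_[i, j + 1] - extend,
                            M[i, j + 1] - open - extend)
    M[i + 1, j + 1] <- max(0,
                           M[i, j] + mat[a[i], b[j]],
                           E[i + 1, j + 1], F_[i + 1, j + 1])
    best <- max(best, M[i + 1, j + 1])
  }
  best
}

random_peptide <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

# minimal mmCIF fixture text
minimal_cif_lines <- function() {
  c("data_TEST",
    "_refine.ls_d_res_high 1.80",
    "_pdbx_database_status.recvd_initial_deposition_date 2012-05-04",
    "loop_", "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
    "_atom_site.Cartn_z", "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . ALA A 1 1 ? 0.000 0.000 0.000 1.00 10.00 ? 1 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 1 ? 1.458 0.000 0.000 1.00 10.00 ? 1 ALA A CA 1",
    "ATOM 3 C C . ALA A 1 1 ? 2.009 1.420 0.000 1.00 10.00 ? 1 ALA A C 1",
    "HETATM 4 C C1 . LIG B 2 . ? 5.000 5.000 5.000 1.00 10.00 ? 101 LIG A C1 1",
    "HETATM 5 O O1 . LIG B 2 . ? 6.450 5.000 5.000 1.00 10.00 ? 101 LIG A O1 1")
}

# wwPDB-style validation XML fixture
write_validation_xml <- function(path, residues, ligand = NULL) {
  lines <- c("<wwPDB-validation-information>", "<Entry>")
  for (k in seq_len(nrow(residues)))
    lines <- c(lines, sprintf(
      '<ModelledSubgroup chain="%s" resnum="%d" resname="%s" rscc="%.3f"/>',
      residues$chain[k], residues$resno[k], residues$resname[k],
      residues$rscc[k]))
  if (!is.null(ligand))
    lines <- c(lines, sprintf(
      '<ModelledSubgroup chain="%s" resnum="%d" resname="%s" rscc="%.3f"/>',
      ligand$chain, ligand$resno, ligand$resname, ligand$rscc))
  lines <- c(lines, "</Entry>", "</wwPDB-validation-information>")
  writeLines(lines, path)
  path
}
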