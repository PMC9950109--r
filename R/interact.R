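## Protein-fragment interaction detection and interaction-graph encoding.
##
## Four interaction classes are detected from geometry: hydrogen bonds
## (ligand donating or accepting), ionic bonds, aromatic stacking and
## hydrophobic contacts. Each detected interaction places a typed pseudo-atom
## on the ligand interacting atom (ring centroid for aromatic stacking);
## hydrogen bonds add a second pseudo-atom halfway to the protein partner to
## encode directionality. The pseudo-atoms form a complete graph whose edges
## carry Euclidean lengths — the binding-mode fingerprint.

#' Geometric interaction rules
#'
#' Distance/angle thresholds for interaction detection. Defaults emulate the
#' customary geometric-rule settings of interaction fingerprinting tools:
#' hydrogen bond donor-acceptor heavy-atom distance <= 3.5 Angstrom with
#' D-H...A angle >= 120 degrees; ionic contacts between opposite formal
#' charges <= 4.0 Angstrom; aromatic ring-centroid distance <= 5.0 Angstrom
#' with interplanar angle <= 30 degrees (parallel) or in [60, 90] (T-shaped);
#' hydrophobic contacts between apolar carbon/sulfur atoms <= 4.5 Angstrom.
#'
#' @param hb_dist,hb_angle hydrogen-bond thresholds (Angstrom, degrees).
#' @param ionic_dist ionic heavy-atom distance cutoff.
#' @param aromatic_dist ring centroid-centroid cutoff.
#' @param aromatic_parallel_max,aromatic_tshape_min interplanar angle limits.
#' @param hydrophobic_dist apolar contact cutoff.
#' @return A list of class \code{"geom_rules"}.
#' @export
geom_rules <- function(hb_dist = 3.5, hb_angle = 120,
                       ionic_dist = 4.0,
                       aromatic_dist = 5.0,
                       aromatic_parallel_max = 30,
                       aromatic_tshape_min = 60,
                       hydrophobic_dist = 4.5) {
  r <- list(hb_dist = hb_dist, hb_angle = hb_angle, ionic_dist = ionic_dist,
            aromatic_dist = aromatic_dist,
            aromatic_parallel_max = aromatic_parallel_max,
            aromatic_tshape_min = aromatic_tshape_min,
            hydrophobic_dist = hydrophobic_dist)
  stopifnot(all(unlist(r) > 0))
  class(r) <- "geom_rules"
  r
}

ITYPES <- c("HB_DONOR", "HB_ACCEPTOR", "IONIC_POS", "IONIC_NEG",
            "AROMATIC", "HYDROPHOBIC")

PROT_NEG_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
PROT_POS_ATOMS <- list(LYS = "NZ", ARG = c("NH1", "NH2", "NE"))
PROT_RING_ATOMS <- list(
  PHE = list(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")),
  TYR = list(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")),
  HIS = list(c("CG", "ND1", "CE1", "NE2", "CD2")),
  TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
             c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3")))

## protein polar typing by atom name; backbone N/O handled explicitly
protein_atom_roles <- function(res) {
  nm <- res$name; rn <- res$resname; el <- res$element
  donor <- (nm == "N" & el == "N") |
    (rn == "SER" & nm == "OG") | (rn == "THR" & nm == "OG1") |
    (rn == "TYR" & nm == "OH") | (rn == "CYS" & nm == "SG") |
    (rn == "ASN" & nm == "ND2") | (rn == "GLN" & nm == "NE2") |
    (rn == "HIS" & nm %in% c("ND1", "NE2")) |
    (rn == "LYS" & nm == "NZ") |
    (rn == "ARG" & nm %in% c("NE", "NH1", "NH2")) |
    (rn == "TRP" & nm == "NE1")
  acceptor <- (nm %in% c("O", "OXT") & el == "O") |
    (rn == "ASP" & nm %in% c("OD1", "OD2")) |
    (rn == "GLU" & nm %in% c("OE1", "OE2")) |
    (rn == "ASN" & nm == "OD1") | (rn == "GLN" & nm == "OE1") |
    (rn == "SER" & nm == "OG") | (rn == "THR" & nm == "OG1") |
    (rn == "TYR" & nm == "OH") |
    (rn == "HIS" & nm %in% c("ND1", "NE2")) |
    (rn == "MET" & nm == "SD")
  neg <- rep(FALSE, nrow(res)); pos <- rep(FALSE, nrow(res))
  for (r in names(PROT_NEG_ATOMS))
    neg <- neg | (rn == r & nm %in% PROT_NEG_ATOMS[[r]])
  neg <- neg | nm == "OXT"
  for (r in names(PROT_POS_ATOMS))
    pos <- pos | (rn == r & nm %in% PROT_POS_ATOMS[[r]])
  aromatic <- rep(FALSE, nrow(res))
  for (r in names(PROT_RING_ATOMS))
    aromatic <- aromatic | (rn == r & nm %in% unlist(PROT_RING_ATOMS[[r]]))
  list(donor = donor, acceptor = acceptor, neg = neg, pos = pos,
       aromatic = aromatic)
}

## hydrophobic protein atoms: apolar carbons (not backbone C/CA/O-adjacent
## carbonyl carbon, not ring carbons counted separately) and S
protein_hydrophobic <- function(res, roles) {
  cb_like <- res$element == "C" &
    !(res$name %in% c("C", "CA")) & !roles$aromatic
  ## exclude carbons directly bonded to N/O within the residue (polar carbons)
  polar_c <- rep(FALSE, nrow(res))
  reskey <- paste(res$chain, res$resno)
  for (rk in unique(reskey)) {
    idx <- which(reskey == rk)
    sub <- res[idx, , drop = FALSE]
    heavy <- sub$element != "H"
    if (sum(heavy) < 2) next
    xyz <- as.matrix(sub[heavy, c("x", "y", "z")])
    d <- cross_dist(xyz, xyz)
    isC <- sub$element[heavy] == "C"
    isNO <- sub$element[heavy] %in% c("N", "O")
    for (ci in which(isC)) {
      if (any(isNO & d[ci, ] > 0.4 & d[ci, ] < 1.7))
        polar_c[idx[heavy][ci]] <- TRUE
    }
  }
  s_atoms <- res$element == "S"
  (cb_like & !polar_c) | s_atoms
}

## ligand atom typing from the molecule
ligand_atom_roles <- function(mol) {
  a <- mol$atoms; b <- mol$bonds
  has_h <- vapply(seq_len(nrow(a)), function(i) {
    nb <- c(b$j[b$i == i], b$i[b$j == i])
    any(a$element[nb] == "H")
  }, logical(1))
  donor <- a$element %in% c("N", "O") & has_h & !a$is_h
  acceptor <- a$element %in% c("N", "O") & !a$is_h & a$charge <= 0
  pos <- a$charge > 0 & !a$is_h
  neg <- a$charge < 0 & !a$is_h
  arom_rings <- mol_aromatic_rings(mol)
  arom_atoms <- rep(FALSE, nrow(a))
  if (length(arom_rings)) arom_atoms[unlist(arom_rings)] <- TRUE
  ## apolar carbons: no N/O neighbor; sulfurs; aromatic carbons are handled
  ## by stacking detection, not hydrophobic contacts
  hydroph <- vapply(seq_len(nrow(a)), function(i) {
    if (a$is_h[i]) return(FALSE)
    if (!(a$element[i] %in% c("C", "S"))) return(FALSE)
    if (arom_atoms[i]) return(FALSE)
    nb <- c(b$j[b$i == i], b$i[b$j == i])
    !any(a$element[nb] %in% c("N", "O"))
  }, logical(1))
  list(donor = donor, acceptor = acceptor, pos = pos, neg = neg,
       hydrophobic = hydroph, aromatic_rings = arom_rings,
       has_h = has_h)
}

#' Detect protein-fragment interactions
#'
#' Applies the geometric rules of [geom_rules()] to one ligand instance and
#' its binding site. Ionic contacts take precedence over hydrogen bonds for
#' the same atom pair; aromatic carbons engage through stacking, not
#' hydrophobic contacts; adjacent hydrophobic ligand atoms contacting the
#' same residue are collapsed to the closest pair. If the ligand carries no
#' hydrogens, hydrogen-bond detection falls back to heavy-atom distances only
#' (with a warning).
#'
#' @param ligand a ligand instance (element of \code{complex$ligands}).
#' @param site the matching \code{protein_site}.
#' @param rules a \code{geom_rules} object.
#' @return data.frame with columns \code{itype}, \code{lig_atom},
#'   \code{prot_atom}, \code{distance}, \code{angle}, and the anchor
#'   coordinates \code{lx,ly,lz} (ligand) and \code{px,py,pz} (protein).
#' @export
detect_interactions <- function(ligand, site, rules = geom_rules()) {
  mol <- ligand$molecule
  res <- site$residues
  empty <- data.frame(itype = character(), lig_atom = integer(),
                      prot_atom = integer(), distance = numeric(),
                      angle = numeric(), lx = numeric(), ly = numeric(),
                      lz = numeric(), px = numeric(), py = numeric(),
                      pz = numeric())
  if (nrow(res) == 0L || nrow(mol$atoms) == 0L) return(empty)
  lroles <- ligand_atom_roles(mol)
  proles <- protein_atom_roles(res)
  phobic_p <- protein_hydrophobic(res, proles)
  la <- mol$atoms
  lig_xyz <- as.matrix(la[, c("x", "y", "z")])
  prot_xyz <- as.matrix(res[, c("x", "y", "z")])
  prot_heavy <- !res$is_h
  D <- cross_dist(lig_xyz, prot_xyz)
  out <- list()
  add <- function(itype, li, pi_, dist, angle = NA_real_,
                  lpos = NULL, ppos = NULL) {
    lpos <- lpos %||% lig_xyz[li, ]
    ppos <- ppos %||% prot_xyz[pi_, ]
    out[[length(out) + 1L]] <<- data.frame(
      itype = itype, lig_atom = li %||% NA_integer_,
      prot_atom = pi_ %||% NA_integer_, distance = dist, angle = angle,
      lx = lpos[1], ly = lpos[2], lz = lpos[3],
      px = ppos[1], py = ppos[2], pz = ppos[3])
  }
  lig_has_h <- any(la$is_h)
  b0 <- mol$bonds
  ## donor candidates in the no-hydrogen fallback: any N, plus O atoms that
  ## are neither carbonyl-like nor negatively charged
  fallback_donors <- which(!la$is_h & (
    la$element == "N" & la$charge >= 0 |
      la$element == "O" & la$charge >= 0 &
      vapply(seq_len(nrow(la)), function(i) {
        if (la$element[i] != "O") return(FALSE)
        nb <- c(b0$j[b0$i == i], b0$i[b0$j == i])
        hv <- nb[la$element[nb] != "H"]
        if (length(hv) != 1L) return(length(hv) == 0L)
        dd <- sqrt(sum((as.numeric(la[i, c("x", "y", "z")]) -
                          as.numeric(la[hv, c("x", "y", "z")]))^2))
        !(la$element[hv] == "C" && dd < 1.28)
      }, logical(1))))
  if (!lig_has_h && length(fallback_donors))
    warning("ligand ", ligand$het_code,
            " has no hydrogens; hydrogen bonds use heavy-atom distances only")

  ionic_pairs <- matrix(numeric(0), ncol = 2)
  ## --- ionic ---
  for (li in which(lroles$neg)) {
    for (pi_ in which(proles$pos & prot_heavy)) {
      if (D[li, pi_] <= rules$ionic_dist) {
        add("IONIC_NEG", li, pi_, D[li, pi_])
        ionic_pairs <- rbind(ionic_pairs, c(li, pi_))
      }
    }
  }
  for (li in which(lroles$pos)) {
    for (pi_ in which(proles$neg & prot_heavy)) {
      if (D[li, pi_] <= rules$ionic_dist) {
        add("IONIC_POS", li, pi_, D[li, pi_])
        ionic_pairs <- rbind(ionic_pairs, c(li, pi_))
      }
    }
  }
  is_ionic_pair <- function(li, pi_) {
    nrow(ionic_pairs) > 0 &&
      any(ionic_pairs[, 1] == li & ionic_pairs[, 2] == pi_)
  }

  ## --- hydrogen bonds, ligand donating ---
  b <- mol$bonds
  donor_set <- if (lig_has_h) which(lroles$donor) else fallback_donors
  for (li in donor_set) {
    h_idx <- {
      nb <- c(b$j[b$i == li], b$i[b$j == li])
      nb[la$element[nb] == "H"]
    }
    for (pi_ in which(proles$acceptor & prot_heavy)) {
      d <- D[li, pi_]
      if (d > rules$hb_dist || is_ionic_pair(li, pi_)) next
      ok <- if (!lig_has_h || length(h_idx) == 0L) TRUE else {
        any(vapply(h_idx, function(hi) {
          vec_angle(lig_xyz[li, ] - lig_xyz[hi, ],
                    prot_xyz[pi_, ] - lig_xyz[hi, ]) >= rules$hb_angle
        }, logical(1)))
      }
      if (ok) add("HB_DONOR", li, pi_, d,
                  angle = if (length(h_idx)) max(vapply(h_idx, function(hi)
                    vec_angle(lig_xyz[li, ] - lig_xyz[hi, ],
                              prot_xyz[pi_, ] - lig_xyz[hi, ]),
                    numeric(1))) else NA_real_)
    }
  }
  ## --- hydrogen bonds, ligand accepting ---
  prot_h <- which(res$is_h)
  for (li in which(lroles$acceptor)) {
    for (pi_ in which(proles$donor & prot_heavy)) {
      d <- D[li, pi_]
      if (d > rules$hb_dist || is_ionic_pair(li, pi_)) next
      hd <- if (length(prot_h)) {
        cand <- prot_h[cross_dist(prot_xyz[pi_, , drop = FALSE],
                                  prot_xyz[prot_h, , drop = FALSE])[1, ] < 1.3]
        cand
      } else integer()
      ok <- if (length(hd) == 0L) TRUE else {
        any(vapply(hd, function(hi) {
          vec_angle(prot_xyz[pi_, ] - prot_xyz[hi, ],
                    lig_xyz[li, ] - prot_xyz[hi, ]) >= rules$hb_angle
        }, logical(1)))
      }
      if (ok) add("HB_ACCEPTOR", li, pi_, d)
    }
  }

  ## --- aromatic stacking (anchored on the ligand ring centroid) ---
  prot_rings <- list()
  reskey <- paste(res$chain, res$resno)
  for (rk in unique(reskey)) {
    sub_idx <- which(reskey == rk)
    rn <- res$resname[sub_idx[1]]
    if (!rn %in% names(PROT_RING_ATOMS)) next
    for (ring_names in PROT_RING_ATOMS[[rn]]) {
      ri <- sub_idx[match(ring_names, res$name[sub_idx])]
      if (any(is.na(ri))) next
      prot_rings[[length(prot_rings) + 1L]] <- ri
    }
  }
  for (lring in lroles$aromatic_rings) {
    lc <- colMeans(lig_xyz[lring, , drop = FALSE])
    ln <- ring_normal(lig_xyz[lring, , drop = FALSE])
    for (pring in prot_rings) {
      pc <- colMeans(prot_xyz[pring, , drop = FALSE])
      d <- sqrt(sum((lc - pc)^2))
      if (d > rules$aromatic_dist) next
      pn <- ring_normal(prot_xyz[pring, , drop = FALSE])
      ang <- vec_angle(ln, pn)
      ang <- min(ang, 180 - ang)
      if (ang <= rules$aromatic_parallel_max ||
          (ang >= rules$aromatic_tshape_min && ang <= 90)) {
        add("AROMATIC", lring[1], pring[1], d, angle = ang,
            lpos = lc, ppos = pc)
      }
    }
  }

  ## --- hydrophobic, collapsed per residue over adjacent ligand atoms ---
  cand <- list()
  for (li in which(lroles$hydrophobic)) {
    for (pi_ in which(phobic_p & prot_heavy)) {
      d <- D[li, pi_]
      if (d <= rules$hydrophobic_dist)
        cand[[length(cand) + 1L]] <- c(li, pi_, d)
    }
  }
  if (length(cand)) {
    cm <- do.call(rbind, cand)
    resof <- reskey[cm[, 2]]
    for (rk in unique(resof)) {
      rows <- which(resof == rk)
      lis <- unique(cm[rows, 1])
      ## connected components of the ligand bond graph restricted to lis
      comp <- stats::setNames(seq_along(lis), lis)
      if (nrow(b)) for (e in seq_len(nrow(b))) {
        bi <- as.character(b$i[e]); bj <- as.character(b$j[e])
        if (bi %in% names(comp) && bj %in% names(comp)) {
          old <- comp[[bj]]; comp[comp == old] <- comp[[bi]]
        }
      }
      for (cc in unique(comp)) {
        members <- as.integer(names(comp)[comp == cc])
        sub <- cm[rows[cm[rows, 1] %in% members], , drop = FALSE]
        best <- sub[which.min(sub[, 3]), ]
        add("HYDROPHOBIC", as.integer(best[1]), as.integer(best[2]), best[3])
      }
    }
  }
  if (length(out) == 0L) return(empty)
  ans <- do.call(rbind, out)
  rownames(ans) <- NULL
  ans[order(ans$itype, ans$lig_atom, ans$prot_atom), , drop = FALSE]
}

#' Build an interaction graph from detected interactions
#'
#' Each interaction contributes one pseudo-atom at the ligand anchor labeled
#' with its type; each hydrogen bond contributes a second pseudo-atom at the
#' exact midpoint of the ligand and protein interacting atoms (label suffixed
#' \code{_MID}). The graph is complete: every unordered node pair is an edge
#' labeled with its Euclidean length.
#'
#' @param interactions data.frame from [detect_interactions()].
#' @return An object of class \code{"interaction_graph"} with \code{nodes}
#'   (data.frame x, y, z, label) and \code{D} (full edge-length matrix).
#' @export
build_interaction_graph <- function(interactions) {
  nodes <- list()
  if (!is.null(interactions) && nrow(interactions) > 0L) {
    for (k in seq_len(nrow(interactions))) {
      r <- interactions[k, ]
      nodes[[length(nodes) + 1L]] <- data.frame(
        x = r$lx, y = r$ly, z = r$lz, label = r$itype)
      if (r$itype %in% c("HB_DONOR", "HB_ACCEPTOR")) {
        nodes[[length(nodes) + 1L]] <- data.frame(
          x = (r$lx + r$px) / 2, y = (r$ly + r$py) / 2,
          z = (r$lz + r$pz) / 2, label = paste0(r$itype, "_MID"))
      }
    }
  }
  nodes <- if (length(nodes)) do.call(rbind, nodes) else
    data.frame(x = numeric(), y = numeric(), z = numeric(),
               label = character())
  rownames(nodes) <- NULL
  D <- if (nrow(nodes)) cross_dist(nodes[, c("x", "y", "z")],
                                   nodes[, c("x", "y", "z")]) else
    matrix(numeric(0), 0, 0)
  g <- list(nodes = nodes, D = D)
  class(g) <- "interaction_graph"
  g
}

#' @export
print.interaction_graph <- function(x, ...) {
  n <- nrow(x$nodes)
  cat(sprintf("<interaction_graph: %d node(s), %d edge(s)>\n",
              n, n * (n - 1) / 2))
  if (n) print(table(x$nodes$label))
  invisible(x)
}

## number of graph nodes
graph_size <- function(g) nrow(g$nodes)

#' Serialize an interaction graph as JSON
#'
#' @param g an \code{interaction_graph}.
#' @param path optional output file; if NULL the JSON string is returned.
#' @export
write_interaction_graph <- function(g, path = NULL) {
  obj <- list(nodes = g$nodes, edges = if (graph_size(g) > 1) {
    idx <- which(upper.tri(g$D), arr.ind = TRUE)
    data.frame(i = idx[, 1], j = idx[, 2], length = g$D[idx])
  } else data.frame(i = integer(), j = integer(), length = numeric()))
  js <- jsonlite::toJSON(obj, dataframe = "rows", digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Write interaction pseudo-atoms as MOL2
#'
#' Pseudo-atoms are exported with label-encoded atom names so the files
#' mirror the per-complex interaction-pseudoatom deposit layout.
#'
#' @param g an \code{interaction_graph}.
#' @param path output file path.
#' @export
write_pseudoatoms_mol2 <- function(g, path) {
  lab <- abbreviate(gsub("_", "", g$nodes$label), 6)
  mol <- molecule(data.frame(
    name = paste0(lab, seq_len(graph_size(g))), element = "C",
    x = g$nodes$x, y = g$nodes$y, z = g$nodes$z))
  write_mol2(mol, path, name = "interaction_pseudoatoms")
}
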