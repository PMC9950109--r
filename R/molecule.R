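## Lightweight small-molecule container used throughout the package.
##
## A molecule holds an atom table (element, coordinates, formal charge,
## aromatic flag, name, hydrogen flag) and a bond table (i, j, order with
## order 4 denoting aromatic). Chemistry-heavy operations (SMILES parsing,
## canonicalization, SMARTS matching, additive descriptors) are delegated to
## ChemmineR/ChemmineOB; graph work uses igraph.

COVALENT_RADII <- c(
  H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07,
  F = 0.57, Cl = 1.02, Br = 1.20, I = 1.39, B = 0.84, Se = 1.20
)

METALS <- c("LI", "NA", "K", "RB", "CS", "MG", "CA", "SR", "BA", "MN", "FE",
            "CO", "NI", "CU", "ZN", "CD", "HG", "AL", "GA", "PB", "PT", "PD",
            "AG", "AU", "W", "MO", "V", "CR", "TI", "RU", "RH", "IR", "OS")

#' Construct a molecule
#'
#' @param atoms data.frame with columns \code{name}, \code{element},
#'   \code{x}, \code{y}, \code{z} and optionally \code{charge} (formal,
#'   integer, default 0) and \code{aromatic} (logical, default FALSE).
#' @param bonds data.frame with columns \code{i}, \code{j} (1-based atom
#'   indices) and \code{order} (1, 2, 3, or 4 for aromatic). May be empty.
#' @param smiles optional SMILES string for the molecule.
#' @param het_code optional PDB chemical component identifier.
#' @param perceive_bonds if TRUE and \code{bonds} is empty, bonds are
#'   inferred from interatomic distances and covalent radii.
#' @return An object of class \code{"molecule"}.
#' @export
molecule <- function(atoms, bonds = NULL, smiles = NULL, het_code = NULL,
                     perceive_bonds = FALSE) {
  stopifnot(is.data.frame(atoms),
            all(c("name", "element", "x", "y", "z") %in% names(atoms)))
  if (is.null(atoms$charge)) atoms$charge <- rep(0L, nrow(atoms))
  if (is.null(atoms$aromatic)) atoms$aromatic <- rep(FALSE, nrow(atoms))
  atoms$element <- normalize_element(atoms$element)
  atoms$is_h <- atoms$element == "H"
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("atom coordinates must be finite")
  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0L) {
    bonds <- if (perceive_bonds) perceive_bonds_by_distance(atoms) else
      data.frame(i = integer(), j = integer(), order = integer())
  }
  bonds <- as.data.frame(bonds)
  mol <- list(atoms = atoms, bonds = bonds, smiles = smiles,
              het_code = het_code)
  class(mol) <- "molecule"
  mol
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule%s: %d atoms (%d heavy), %d bonds%s>\n",
              if (!is.null(x$het_code)) paste0(" ", x$het_code) else "",
              nrow(x$atoms), n_heavy_atoms(x), nrow(x$bonds),
              if (!is.null(x$smiles)) paste0(", ", x$smiles) else ""))
  invisible(x)
}

normalize_element <- function(el) {
  el <- as.character(el)
  paste0(toupper(substr(el, 1, 1)), tolower(substring(el, 2)))
}

#' Number of heavy (non-hydrogen) atoms
#' @param mol a molecule.
#' @export
n_heavy_atoms <- function(mol) sum(!mol$atoms$is_h)

heavy_coords <- function(mol) {
  as.matrix(mol$atoms[!mol$atoms$is_h, c("x", "y", "z")])
}

## Distance-based bond perception (covalent radii + 0.45 A slack).
perceive_bonds_by_distance <- function(atoms) {
  n <- nrow(atoms)
  if (n < 2L) return(data.frame(i = integer(), j = integer(), order = integer()))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rad <- COVALENT_RADII[atoms$element]
  rad[is.na(rad)] <- 1.4  # generous default for exotic elements
  d <- cross_dist(xyz, xyz)
  cutoff <- outer(rad, rad, "+") + 0.45
  hit <- which(d > 0.4 & d <= cutoff, arr.ind = TRUE)
  hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
  if (nrow(hit) == 0L)
    return(data.frame(i = integer(), j = integer(), order = integer()))
  ## crude order assignment: short C=O / C=N flagged as double
  ord <- rep(1L, nrow(hit))
  for (k in seq_len(nrow(hit))) {
    e <- sort(atoms$element[hit[k, ]])
    dk <- d[hit[k, 1], hit[k, 2]]
    if (identical(e, c("C", "O")) && dk < 1.28) ord[k] <- 2L
  }
  data.frame(i = as.integer(hit[, 1]), j = as.integer(hit[, 2]), order = ord)
}

## igraph view of the heavy-atom bond graph; vertex attribute "element",
## edge attribute "order".
mol_graph <- function(mol, heavy_only = TRUE) {
  keep <- if (heavy_only) which(!mol$atoms$is_h) else seq_len(nrow(mol$atoms))
  idx <- match(seq_len(nrow(mol$atoms)), keep)
  b <- mol$bonds
  b <- b[b$i %in% keep & b$j %in% keep, , drop = FALSE]
  g <- igraph::make_empty_graph(n = length(keep), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "element", value = mol$atoms$element[keep])
  g <- igraph::set_vertex_attr(g, "charge", value = mol$atoms$charge[keep])
  if (nrow(b) > 0L)
    g <- igraph::add_edges(g, rbind(idx[b$i], idx[b$j]),
                           attr = list(order = b$order))
  g
}

## Ring perception: cycle basis of the heavy-atom bond graph. Returns a list
## of integer vectors (heavy-atom indices into mol$atoms).
mol_rings <- function(mol, max_size = 8L) {
  heavy <- which(!mol$atoms$is_h)
  g <- mol_graph(mol, heavy_only = TRUE)
  if (igraph::ecount(g) == 0L) return(list())
  ## edges outside a spanning forest each close one fundamental cycle
  tree <- igraph::mst(g)
  tm <- igraph::as_edgelist(tree)
  gm <- igraph::as_edgelist(g)
  key <- function(m) paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  extra <- which(!(key(gm) %in% key(tm)))
  rings <- list()
  for (e in extra) {
    u <- gm[e, 1]; v <- gm[e, 2]
    sp <- suppressWarnings(igraph::shortest_paths(tree, from = u, to = v))
    path <- as.integer(sp$vpath[[1]])
    if (length(path) >= 3L && length(path) <= max_size)
      rings[[length(rings) + 1L]] <- heavy[path]
  }
  rings
}

## Planarity of a set of atom positions: RMS distance to least-squares plane.
ring_planarity <- function(xyz) {
  xyz <- as.matrix(xyz)
  c0 <- colMeans(xyz)
  m <- sweep(xyz, 2, c0)
  sv <- svd(m)
  sqrt(mean((m %*% sv$v[, 3])^2))
}

ring_normal <- function(xyz) {
  m <- sweep(as.matrix(xyz), 2, colMeans(xyz))
  svd(m)$v[, 3]
}

## Aromatic rings: 5-6 membered, C/N/O/S only, near-planar (or explicitly
## flagged aromatic when the molecule came from SMILES).
mol_aromatic_rings <- function(mol) {
  rings <- mol_rings(mol)
  keep <- list()
  for (r in rings) {
    if (!(length(r) %in% c(5L, 6L))) next
    els <- mol$atoms$element[r]
    if (!all(els %in% c("C", "N", "O", "S"))) next
    if (all(mol$atoms$aromatic[r])) {
      keep[[length(keep) + 1L]] <- r
      next
    }
    xyz <- as.matrix(mol$atoms[r, c("x", "y", "z")])
    if (ring_planarity(xyz) < 0.12) keep[[length(keep) + 1L]] <- r
  }
  keep
}

## ---- ChemmineR/ChemmineOB bridge -------------------------------------------

#' Parse a SMILES string into a molecule
#'
#' Uses OpenBabel (via ChemmineR/ChemmineOB) for parsing, aromaticity
#' perception and canonicalization. Coordinates are the toolkit's 2D layout;
#' use crystallographic conformers for any 3D descriptor.
#'
#' @param smiles a single SMILES string.
#' @param het_code optional chemical component id to attach.
#' @return A \code{molecule}.
#' @export
mol_from_smiles <- function(smiles, het_code = NULL) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  txt <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", smiles),
    error = function(e) stop("unparseable SMILES '", smiles, "': ",
                             conditionMessage(e)))
  if (!nzchar(txt) || !grepl("V2000", txt))
    stop("unparseable SMILES '", smiles, "'")
  mol_from_v2000(txt, smiles = smiles, het_code = het_code)
}

## minimal V2000 reader for the OpenBabel exchange text (the general SDF
## container in ChemmineR rejects bond-free molecules such as methane)
mol_from_v2000 <- function(text, smiles = NULL, het_code = NULL) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  natoms <- as.integer(substr(counts, 1, 3))
  nbonds <- as.integer(substr(counts, 4, 6))
  al <- lines[4 + seq_len(natoms)]
  atoms <- data.frame(
    element = normalize_element(trimws(substr(al, 32, 34))),
    x = as.numeric(substr(al, 1, 10)),
    y = as.numeric(substr(al, 11, 20)),
    z = as.numeric(substr(al, 21, 30)),
    charge = 0L, aromatic = FALSE, stringsAsFactors = FALSE)
  atoms$name <- paste0(atoms$element, seq_len(natoms))
  bonds <- if (nbonds > 0) {
    bl <- lines[4 + natoms + seq_len(nbonds)]
    data.frame(i = as.integer(substr(bl, 1, 3)),
               j = as.integer(substr(bl, 4, 6)),
               order = as.integer(substr(bl, 7, 9)))
  } else data.frame(i = integer(), j = integer(), order = integer())
  for (cl in grep("^M  CHG", lines, value = TRUE)) {
    fields <- as.integer(strsplit(trimws(substr(cl, 7, nchar(cl))),
                                  "\\s+")[[1]])
    n <- fields[1]
    for (k in seq_len(n))
      atoms$charge[fields[2 * k]] <- fields[2 * k + 1]
  }
  mol <- molecule(atoms, bonds, smiles = smiles, het_code = het_code)
  arom_idx <- unique(unlist(mol_aromatic_rings_from_orders(mol)))
  if (length(arom_idx)) mol$atoms$aromatic[arom_idx] <- TRUE
  mol
}

mol_from_sdfset <- function(sdf, smiles = NULL, het_code = NULL) {
  sd <- if (methods::is(sdf, "SDFset")) sdf[[1]] else sdf
  ab <- ChemmineR::atomblock(sd)
  if (is.null(dim(ab))) ab <- matrix(ab, nrow = 1,
                                     dimnames = list(names(ab), NULL))
  bb <- ChemmineR::bondblock(sd)
  if (is.null(dim(bb))) {
    bb <- if (length(bb) >= 3) matrix(bb, nrow = 1) else
      matrix(numeric(0), 0, 3)
  }
  el <- gsub("_.*$", "", rownames(ab))
  atoms <- data.frame(
    name = rownames(ab), element = el,
    x = ab[, 1], y = ab[, 2],
    z = if (ncol(ab) >= 3) ab[, 3] else 0,
    charge = 0L, aromatic = FALSE, stringsAsFactors = FALSE)
  ## formal charges from the atom block charge column (SDF convention:
  ## 0 none, 1:+3, 2:+2, 3:+1, 5:-1, 6:-2, 7:-3)
  if (ncol(ab) >= 5) {
    chg_code <- ab[, 5]
    map <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)
    atoms$charge <- ifelse(chg_code == 0, 0L,
                           map[as.character(chg_code)])
    atoms$charge[is.na(atoms$charge)] <- 0L
  }
  bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                      order = as.integer(bb[, 3]))
  rownames(atoms) <- NULL
  mol <- molecule(atoms, bonds, smiles = smiles, het_code = het_code)
  ## aromatic flags: atoms on rings with all order-4 bonds, or perceived
  arom_idx <- unique(unlist(mol_aromatic_rings_from_orders(mol)))
  if (length(arom_idx)) mol$atoms$aromatic[arom_idx] <- TRUE
  mol
}

## rings whose bonds all carry SDF aromatic order (4) — used right after
## parsing, before planarity information exists.
mol_aromatic_rings_from_orders <- function(mol) {
  rings <- mol_rings(mol)
  bkey <- paste(pmin(mol$bonds$i, mol$bonds$j), pmax(mol$bonds$i, mol$bonds$j))
  Filter(Negate(is.null), lapply(rings, function(r) {
    n <- length(r)
    pairs <- cbind(r, r[c(2:n, 1)])
    k <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
    ord <- mol$bonds$order[match(k, bkey)]
    if (all(!is.na(ord)) && all(ord == 4L)) r else NULL
  }))
}

## Serialize a molecule as SDF V2000 text (single record).
mol_to_sdf_text <- function(mol, title = "fragverse") {
  a <- mol$atoms; b <- mol$bonds
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                    nrow(a), nrow(b))
  atom_lines <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                        a$x, a$y, a$z, toupper(a$element))
  bond_lines <- if (nrow(b)) sprintf("%3d%3d%3d  0  0  0  0", b$i, b$j, b$order)
                else character()
  chg <- which(a$charge != 0)
  chg_lines <- if (length(chg))
    sprintf("M  CHG%3d%s", length(chg),
            paste0(sprintf("%4d%4d", chg, a$charge[chg]), collapse = ""))
  else character()
  paste(c(title, "  fragverse", "", counts, atom_lines, bond_lines,
          chg_lines, "M  END", "$$$$"), collapse = "\n")
}

## Molecule -> ChemmineR SDFset (via temp file round trip).
mol_to_sdfset <- function(mol) {
  if (!is.null(mol$smiles))
    return(suppressWarnings(ChemmineR::smiles2sdf(mol$smiles)))
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(mol_to_sdf_text(mol), tf)
  ChemmineR::read.SDFset(tf)
}

## OpenBabel property block (MW, logP, TPSA, HBA1/2, HBD, canonical SMILES
## with and without stereo), computed with OB's descriptor appenders so that
## bond-free molecules work too.
mol_ob_props <- function(mol) {
  src <- if (!is.null(mol$smiles)) list(fmt = "SMI", text = mol$smiles)
  else list(fmt = "SDF", text = mol_to_sdf_text(mol))
  out <- ChemmineOB::convertFormat(
    src$fmt, "SMI", src$text,
    options = data.frame(names = "append",
                         args = "MW logP TPSA HBA1 HBA2 HBD"))
  fields <- strsplit(trimws(out), "[\t ]+")[[1]]
  n <- length(fields)
  smi <- ChemmineOB::convertFormat(src$fmt, "CAN", src$text)
  smi <- strsplit(trimws(smi), "[\t ]")[[1]][1]
  ## stereo-free canonical SMILES: drop chiral/cis-trans marks, recanonicalize
  stripped <- gsub("@|/|\\\\", "", smi)
  smi_ns <- tryCatch({
    out2 <- ChemmineOB::convertFormat("SMI", "CAN", stripped)
    strsplit(trimws(out2), "[\t ]")[[1]][1]
  }, error = function(e) stripped)
  list(MW = as.numeric(fields[n - 5]), logP = as.numeric(fields[n - 4]),
       TPSA = as.numeric(fields[n - 3]), HBA1 = as.numeric(fields[n - 2]),
       HBA2 = as.numeric(fields[n - 1]), HBD = as.numeric(fields[n]),
       cansmi = smi, cansmiNS = smi_ns)
}

## Canonical SMILES via OpenBabel.
mol_canonical_smiles <- function(mol, stereo = TRUE) {
  p <- mol_ob_props(mol)
  if (stereo) p$cansmi else p$cansmiNS
}

## Count of SMARTS matches in a molecule (unique matches). Bond-free
## molecules cannot be held in the general SDF container; for those, only
## single-atom charge patterns can match and they are counted from the
## formal charges directly.
mol_smarts_count <- function(mol, smarts) {
  res <- tryCatch({
    sdf <- mol_to_sdfset(mol)
    as.numeric(ChemmineR::smartsSearchOB(sdf, smarts, uniqueMatches = TRUE))
  }, error = function(e) NULL)
  if (!is.null(res)) return(res)
  if (smarts == "[*+]") return(sum(mol$atoms$charge > 0))
  if (smarts == "[*-]") return(sum(mol$atoms$charge < 0))
  0
}
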