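## Fragment definition, occurrence and PAINS filters, and the chemistry
## characterization of selected fragments.

REJECT_REASONS <- c("MW>=300", "heavy_atoms_out_of_range", "monosaccharide",
                    "organometallic", "prosthetic_group",
                    "crystallization_additive", "polyatomic_ion",
                    "polyhalogenated", "linear_aliphatic")

HALOGENS <- c("F", "Cl", "Br", "I")

## packaged HET-code blocklist (sc-PDB-style exclusion categories)
het_blocklist <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "het_blocklist.csv",
                          package = "fragverse")
      cache <<- utils::read.csv(path, stringsAsFactors = FALSE)
    }
    cache
  }
})

#' Classify a ligand against the fragment definition
#'
#' A fragment is a small molecular compound: molecular weight below 300 Da,
#' 2-18 heavy atoms, and none of: monosaccharide, organometallic compound,
#' prosthetic group, crystallization additive, simple polyatomic ion,
#' small polyhalogenated compound, linear aliphatic compound. Unwanted
#' categories are detected by a configurable HET-code blocklist plus SMARTS /
#' graph heuristics; every violated rule is reported independently.
#'
#' @param mol a \code{molecule} (with SMILES or parsable structure).
#' @param config a [pipeline_config()] carrying the MW / heavy-atom limits.
#' @return An object of class \code{"fragment_verdict"}: \code{accepted}
#'   flag and \code{reject_reasons} character vector.
#' @export
classify_ligand <- function(mol, config = pipeline_config()) {
  reasons <- character()
  props <- mol_ob_props(mol)
  heavy <- n_heavy_atoms(mol)
  if (props$MW >= config$mw_max) reasons <- c(reasons, "MW>=300")
  if (heavy < config$heavy_min || heavy > config$heavy_max)
    reasons <- c(reasons, "heavy_atoms_out_of_range")
  bl <- het_blocklist()
  if (!is.null(mol$het_code) && mol$het_code %in% bl$het_code)
    reasons <- c(reasons, bl$category[match(mol$het_code, bl$het_code)])
  els <- mol$atoms$element[!mol$atoms$is_h]
  if (any(toupper(els) %in% METALS)) reasons <- c(reasons, "organometallic")
  ## monosaccharide heuristic: single 5-6 ring with one ring O and >= 3
  ## hydroxyls on ring carbons
  if (!("monosaccharide" %in% reasons) &&
      mol_smarts_count(mol, "[OX2H][CX4]1[OX2][CX4][CX4]([OX2H])[CX4]1") +
      mol_smarts_count(mol,
                       "[CX4]1([OX2H])[OX2][CX4][CX4]([OX2H])[CX4]([OX2H])[CX4]1") > 0)
    reasons <- c(reasons, "monosaccharide")
  ## crystallization additive heuristic: acyclic polyalcohol (glycerol-like)
  ## or short glycol chain, C/O only
  if (!("crystallization_additive" %in% reasons) &&
      all(els %in% c("C", "O")) && length(mol_rings(mol)) == 0L &&
      mol_smarts_count(mol, "[OX2H]") >= 2 && heavy <= 10)
    reasons <- c(reasons, "crystallization_additive")
  ## polyatomic ion: sulfate/phosphate/carbonate-like, or a bare carboxylate
  if (!("polyatomic_ion" %in% reasons)) {
    ion_smarts <- c("[SX4](=O)(=O)([OX1,OX2H])[OX1,OX2H]",
                    "[PX4](=O)([OX1,OX2H])([OX1,OX2H])[OX1,OX2H]",
                    "[CX3](=O)([OX1,OX2H])[OX1,OX2H]")
    hits <- vapply(ion_smarts, function(s) mol_smarts_count(mol, s),
                   numeric(1))
    ## a *simple* ion: the motif accounts for (almost) the whole molecule
    if (any(hits > 0) && heavy <= 6) reasons <- c(reasons, "polyatomic_ion")
  }
  if (length(els) > 0) {
    nhal <- sum(els %in% HALOGENS)
    if (heavy <= 6 && nhal / heavy >= 0.5)
      reasons <- c(reasons, "polyhalogenated")
  }
  ## linear aliphatic: acyclic, unbranched, carbon/hydrogen only
  if (all(els == "C") && length(mol_rings(mol)) == 0L && heavy >= 2) {
    g <- mol_graph(mol)
    if (max(igraph::degree(g)) <= 2) reasons <- c(reasons, "linear_aliphatic")
  }
  verdict <- list(accepted = length(reasons) == 0L,
                  reject_reasons = unique(reasons))
  class(verdict) <- "fragment_verdict"
  verdict
}

#' @export
print.fragment_verdict <- function(x, ...) {
  if (x$accepted) cat("<fragment_verdict: accepted>\n")
  else cat("<fragment_verdict: rejected (",
           paste(x$reject_reasons, collapse = ", "), ")>\n", sep = "")
  invisible(x)
}

#' Keep fragments present in more than one structure entry
#'
#' @param corpus data.frame (or list of pairs) with columns \code{entry_id}
#'   and \code{het_code}; one row per ligand instance.
#' @return Character vector of HET codes seen in >= 2 distinct entries.
#' @examples
#' filter_multi_entry(data.frame(entry_id = c("E1", "E2", "E1"),
#'                               het_code = c("AAA", "AAA", "BBB")))
#' @export
filter_multi_entry <- function(corpus) {
  if (is.list(corpus) && !is.data.frame(corpus))
    corpus <- do.call(rbind, lapply(corpus, function(p)
      data.frame(entry_id = p[[1]], het_code = p[[2]])))
  if (nrow(corpus) == 0L) return(character())
  tab <- unique(corpus[, c("entry_id", "het_code")])
  counts <- table(tab$het_code)
  sort(names(counts)[counts >= 2])
}

## packaged PAINS SMARTS catalog (curated public-family subset)
pains_catalog <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "pains_smarts.tsv",
                          package = "fragverse")
      cat_ <- utils::read.delim(path, stringsAsFactors = FALSE)
      ## malformed SMARTS must fail at load, not per molecule
      probe <- ChemmineR::smiles2sdf("c1ccccc1O")
      for (k in seq_len(nrow(cat_))) {
        ok <- tryCatch({
          ChemmineR::smartsSearchOB(probe, cat_$smarts[k],
                                    uniqueMatches = TRUE)
          TRUE
        }, error = function(e) FALSE)
        if (!ok) stop("malformed PAINS SMARTS in catalog: ",
                      cat_$rule_id[k])
      }
      cache <<- cat_
    }
    cache
  }
})

#' Flag pan-assay interference (PAINS) motifs
#'
#' Substructure search against the packaged PAINS SMARTS catalog (a curated
#' subset of the public A/B/C families). An empty result means clean.
#'
#' @param mol a \code{molecule}.
#' @return Character vector of matched rule ids (possibly empty).
#' @export
pains_flags <- function(mol) {
  cat_ <- pains_catalog()
  sdf <- tryCatch(mol_to_sdfset(mol), error = function(e) NULL)
  ## bond-free molecules cannot carry any multi-atom interference motif
  if (is.null(sdf) || nrow(mol$bonds) == 0L) return(character())
  hits <- vapply(cat_$smarts, function(s)
    as.numeric(ChemmineR::smartsSearchOB(sdf, s, uniqueMatches = TRUE)),
    numeric(1))
  cat_$rule_id[hits > 0]
}

#' Compute the fragment descriptor block
#'
#' Molecular weight, logP, topological polar surface area, H-bond donor and
#' acceptor counts (atomic-contribution schemes of the chemistry toolkit),
#' formally charged atom counts, rotatable bonds, ring count (cyclomatic),
#' specified stereocenters, heavy atoms, and — when a 3D conformer is
#' supplied — the plane of best fit.
#'
#' @param mol a \code{molecule}.
#' @param conformer optional n x 3 matrix of heavy-atom coordinates for the
#'   PBF (defaults to the molecule's own coordinates when they span 3D).
#' @return A one-row data.frame of class \code{"descriptor_block"}.
#' @export
compute_descriptors <- function(mol, conformer = NULL) {
  p <- mol_ob_props(mol)
  rotb <- mol_smarts_count(mol, "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]")
  pos <- mol_smarts_count(mol, "[*+]")
  neg <- mol_smarts_count(mol, "[*-]")
  g <- mol_graph(mol)
  rings <- igraph::ecount(g) - igraph::vcount(g) +
    igraph::components(g)$no
  stereo <- length(gregexpr("[A-Za-z]@", p$cansmi)[[1]])
  if (identical(gregexpr("[A-Za-z]@", p$cansmi)[[1]][1], -1L)) stereo <- 0L
  if (is.null(conformer)) {
    xyz <- heavy_coords(mol)
    if (nrow(xyz) >= 3 && diff(range(xyz[, 3])) > 1e-6) conformer <- xyz
  }
  pbf <- if (!is.null(conformer)) compute_pbf(conformer) else NA_real_
  d <- data.frame(
    mw = p$MW, alogp = p$logP, tpsa = p$TPSA,
    hbd = p$HBD, hba = p$HBA1,
    pos_atoms = pos, neg_atoms = neg, rot_bonds = rotb,
    rings = max(0L, rings), stereocenters = stereo,
    heavy_atoms = n_heavy_atoms(mol), pbf = pbf)
  class(d) <- c("descriptor_block", "data.frame")
  d
}

#' Count rule-of-three violations
#'
#' The rule of three for fragment libraries: MW <= 300, H-bond donors <= 3,
#' H-bond acceptors <= 3, logP <= 3, rotatable bonds <= 3. Returns how many
#' of the five limits are crossed.
#'
#' @param d a \code{descriptor_block} (or any list with mw, hbd, hba, alogp,
#'   rot_bonds).
#' @param limits the five limits, as in [pipeline_config()]\code{$ro3}.
#' @return Integer in [0, 5].
#' @examples
#' ro3_violations(data.frame(mw = 310, hbd = 4, hba = 3, alogp = 2,
#'                           rot_bonds = 1))
#' @export
ro3_violations <- function(d, limits = pipeline_config()$ro3) {
  sum(d$mw > limits$mw, d$hbd > limits$hbd, d$hba > limits$hba,
      d$alogp > limits$logp, d$rot_bonds > limits$rotb)
}

#' Plane of best fit (PBF)
#'
#' Mean absolute distance of heavy atoms to their least-squares plane: 0 for
#' flat conformers, larger for three-dimensional ones. Invariant under rigid
#' motion.
#'
#' @param conformer n x 3 matrix of heavy-atom coordinates (n >= 3, not all
#'   collinear).
#' @return PBF in Angstrom, or \code{NA} for degenerate input.
#' @examples
#' hex <- t(sapply(0:5, function(k)
#'   c(1.39 * cos(k * pi / 3), 1.39 * sin(k * pi / 3), 0)))
#' compute_pbf(hex)  # 0: planar
#' @export
compute_pbf <- function(conformer) {
  xyz <- as.matrix(conformer)
  if (nrow(xyz) < 3L) return(NA_real_)
  m <- sweep(xyz, 2, colMeans(xyz))
  sv <- svd(m)
  if (sv$d[2] < 1e-8) return(NA_real_)  # collinear
  mean(abs(m %*% sv$v[, 3]))
}

#' Bemis-Murcko scaffold
#'
#' Ring systems plus connecting linkers with side chains removed
#' (terminal atoms are pruned iteratively; exocyclic atoms attached by a
#' double bond are retained, as in the frameworks convention). Acyclic
#' molecules have an empty scaffold.
#'
#' @param mol a \code{molecule}.
#' @return A \code{molecule} holding the scaffold (0 atoms when acyclic),
#'   with its canonical SMILES in \code{$smiles}.
#' @export
murcko_scaffold <- function(mol) {
  a <- mol$atoms; b <- mol$bonds
  keep <- which(!a$is_h)
  b <- b[b$i %in% keep & b$j %in% keep, , drop = FALSE]
  alive <- rep(FALSE, nrow(a)); alive[keep] <- TRUE
  repeat {
    deg <- integer(nrow(a))
    dbl <- logical(nrow(a))
    for (e in seq_len(nrow(b))) {
      if (!alive[b$i[e]] || !alive[b$j[e]]) next
      deg[b$i[e]] <- deg[b$i[e]] + 1L
      deg[b$j[e]] <- deg[b$j[e]] + 1L
      if (b$order[e] >= 2L && b$order[e] != 4L) {
        dbl[b$i[e]] <- TRUE; dbl[b$j[e]] <- TRUE
      }
    }
    prune <- alive & deg <= 1L & !dbl
    if (!any(prune)) break
    alive[prune] <- FALSE
  }
  idx <- which(alive)
  if (length(idx) == 0L || length(mol_rings(mol)) == 0L) {
    empty <- molecule(data.frame(name = character(), element = character(),
                                 x = numeric(), y = numeric(), z = numeric()))
    empty$smiles <- ""
    return(empty)
  }
  remap <- match(seq_len(nrow(a)), idx)
  bk <- b[b$i %in% idx & b$j %in% idx, , drop = FALSE]
  scaffold <- molecule(a[idx, c("name", "element", "x", "y", "z", "charge",
                                "aromatic")],
                       data.frame(i = remap[bk$i], j = remap[bk$j],
                                  order = bk$order),
                       het_code = mol$het_code)
  scaffold$smiles <- tryCatch(mol_canonical_smiles(scaffold),
                              error = function(e) NA_character_)
  scaffold
}

#' Substructure contribution of a fragment to a superstructure
#'
#' If the query is a substructure of the target (chirality respected when
#' \code{use_chirality}), returns the fraction of bonds in the query over
#' the number of bonds in the target; 1 indicates an exact match. Returns
#' \code{NA} when the query does not embed.
#'
#' @param query,target \code{molecule} objects (neutralized, canonical
#'   tautomer assumed).
#' @param use_chirality respect stereocenters during matching.
#' @return Ratio in (0, 1], or \code{NA} for no match.
#' @export
substructure_contribution <- function(query, target, use_chirality = TRUE) {
  qsmi <- query$smiles %||% mol_canonical_smiles(query)
  if (!use_chirality) {
    qsmi <- mol_canonical_smiles(query, stereo = FALSE)
  }
  tsdf <- mol_to_sdfset(target)
  nmatch <- tryCatch(
    as.numeric(ChemmineR::smartsSearchOB(tsdf, qsmi, uniqueMatches = TRUE)),
    error = function(e) 0)
  if (nmatch == 0) return(NA_real_)
  qb <- n_heavy_bonds(query); tb <- n_heavy_bonds(target)
  if (tb == 0L) return(NA_real_)
  qb / tb
}

n_heavy_bonds <- function(mol) {
  h <- which(mol$atoms$is_h)
  sum(!(mol$bonds$i %in% h) & !(mol$bonds$j %in% h))
}
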