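## Structure input/output: complexes, binding sites, validation data.

AA20 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")
WATERS <- c("HOH", "WAT", "DOD", "H2O")

new_complex <- function(entry_id, protein, ligands,
                        resolution = NA_real_, deposition_date = NA) {
  stopifnot(is.data.frame(protein))
  x <- list(entry_id = entry_id, resolution = resolution,
            deposition_date = deposition_date,
            protein = protein, ligands = ligands)
  class(x) <- "fragverse_complex"
  x
}

#' @export
print.fragverse_complex <- function(x, ...) {
  nres <- nrow(unique(x$protein[, c("chain", "resno")]))
  cat(sprintf("<complex %s: %d protein residues, %d ligand instance(s)%s>\n",
              x$entry_id, nres, length(x$ligands),
              if (!is.na(x$resolution))
                sprintf(", %.2f A", x$resolution) else ""))
  for (lig in x$ligands)
    cat(sprintf("  %s copy %d (%d heavy atoms)\n", lig$het_code,
                lig$copy_index, n_heavy_atoms(lig$molecule)))
  invisible(x)
}

#' Read a protein-fragment structure
#'
#' Parses a structure file into a complex: the amino-acid protein residues
#' (waters and non-amino-acid polymer components are excluded) and one ligand
#' instance per copy of each non-polymer chemical component with at least two
#' heavy atoms. Single-atom HETATM groups (metals, halide ions) are skipped.
#' Resolution and deposition date are read from the header when present.
#'
#' @param path file path.
#' @param format one of \code{"auto"}, \code{"pdb"}, \code{"cif"},
#'   \code{"mol2"}; \code{"auto"} infers from the extension.
#' @param entry_id accession to record; defaults to the file base name.
#' @return An object of class \code{"fragverse_complex"}.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif", "mol2"),
                           entry_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", ent = "pdb", cif = "cif",
                     mmcif = "cif", mol2 = "mol2",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  if (is.null(entry_id))
    entry_id <- toupper(tools::file_path_sans_ext(basename(path)))
  if (format == "mol2") return(read_structure_mol2(path, entry_id))
  parsed <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE)
    else suppressWarnings(bio3d::read.cif(path, verbose = FALSE)),
    error = function(e) stop("parse error in ", basename(path), ": ",
                             conditionMessage(e)))
  at <- parsed$atom
  at <- at[!(at$resid %in% WATERS), , drop = FALSE]
  el <- at$elesy
  if (is.null(el) || all(is.na(el)) || all(el == ""))
    el <- gsub("[0-9']", "", substr(trimws(at$elety), 1, 2))
  el[is.na(el) | el == ""] <- gsub("[0-9']", "",
                                   substr(trimws(at$elety[is.na(el) | el == ""]),
                                          1, 1))
  at$element <- normalize_element(el)
  prot <- at[at$type == "ATOM" & at$resid %in% AA20, , drop = FALSE]
  if (nrow(prot) == 0L)
    stop("no protein chain found in ", basename(path))
  protein <- data.frame(
    chain = prot$chain, resno = prot$resno, resname = prot$resid,
    name = trimws(prot$elety), element = prot$element,
    x = prot$x, y = prot$y, z = prot$z,
    is_h = prot$element == "H", stringsAsFactors = FALSE)
  het <- at[at$type == "HETATM" & !(at$resid %in% AA20), , drop = FALSE]
  ligands <- build_ligand_instances(het)
  meta <- scan_structure_metadata(path, format)
  new_complex(entry_id, protein, ligands,
              resolution = meta$resolution,
              deposition_date = meta$deposition_date)
}

build_ligand_instances <- function(het) {
  ligands <- list()
  if (nrow(het) == 0L) return(ligands)
  key <- paste(het$resid, het$chain, het$resno, sep = "|")
  copy_counter <- list()
  for (k in unique(key)) {
    grp <- het[key == k, , drop = FALSE]
    if (sum(grp$element != "H") < 2L) next  # metals / single-atom ions
    code <- toupper(grp$resid[1])
    atoms <- data.frame(
      name = trimws(grp$elety), element = grp$element,
      x = grp$x, y = grp$y, z = grp$z,
      charge = if (!is.null(grp$charge) && !all(is.na(grp$charge)))
        ifelse(is.na(grp$charge), 0L, as.integer(round(grp$charge))) else 0L,
      stringsAsFactors = FALSE)
    mol <- molecule(atoms, het_code = code, perceive_bonds = TRUE)
    idx <- (copy_counter[[code]] <- (copy_counter[[code]] %||% 0L) + 1L)
    ligands[[length(ligands) + 1L]] <- list(
      het_code = code, copy_index = idx,
      chain = grp$chain[1], resno = grp$resno[1], molecule = mol)
  }
  ligands
}

`%||%` <- function(a, b) if (is.null(a)) b else a

scan_structure_metadata <- function(path, format) {
  lines <- readLines(path, warn = FALSE)
  resolution <- NA_real_; date <- NA
  if (format == "pdb") {
    r <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
    if (length(r)) {
      m <- regmatches(r[1], regexpr("[0-9]+\\.[0-9]+", r[1]))
      if (length(m)) resolution <- as.numeric(m)
    }
    h <- grep("^HEADER", lines, value = TRUE)
    if (length(h) && nchar(h[1]) >= 59) {
      ds <- trimws(substr(h[1], 51, 59))
      d <- suppressWarnings(as.Date(ds, format = "%d-%b-%y"))
      if (!is.na(d) && format(d, "%Y") > "2050") d <- d - 36525  # 2-digit year
      date <- d
    }
  } else {
    r <- grep("_refine\\.ls_d_res_high", lines, value = TRUE)
    if (length(r)) {
      m <- regmatches(r[1], regexpr("[0-9]+\\.?[0-9]*\\s*$", r[1]))
      if (length(m)) resolution <- as.numeric(trimws(m))
    }
    dl <- grep("_pdbx_database_status\\.recvd_initial_deposition_date",
               lines, value = TRUE)
    if (length(dl)) {
      m <- regmatches(dl[1], regexpr("[0-9]{4}-[0-9]{2}-[0-9]{2}", dl[1]))
      if (length(m)) date <- as.Date(m)
    }
  }
  list(resolution = resolution, deposition_date = date)
}

read_structure_mol2 <- function(path, entry_id) {
  parsed <- tryCatch(bio3d::read.mol2(path),
                     error = function(e) stop("parse error in ",
                                              basename(path), ": ",
                                              conditionMessage(e)))
  at <- parsed$atom
  el <- normalize_element(gsub("\\..*$", "", at$elety))
  resid <- toupper(as.character(at$resid))
  resid <- gsub("[0-9]+$", "", resid)
  at$element <- el
  keepres <- resid %in% AA20
  protein <- data.frame(
    chain = rep("A", sum(keepres)), resno = at$resno[keepres],
    resname = resid[keepres],
    name = at$elena[keepres], element = el[keepres],
    x = at$x[keepres], y = at$y[keepres], z = at$z[keepres],
    is_h = el[keepres] == "H", stringsAsFactors = FALSE)
  ligands <- list()
  lig <- at[!keepres & !(resid %in% WATERS), , drop = FALSE]
  if (nrow(lig)) {
    lig$resid_clean <- resid[!keepres & !(resid %in% WATERS)]
    key <- paste(lig$resid_clean, lig$resno)
    copy <- 0L
    for (k in unique(key)) {
      grp <- lig[key == k, , drop = FALSE]
      if (sum(grp$element != "H") < 2L) next
      atoms <- data.frame(name = grp$elena, element = grp$element,
                          x = grp$x, y = grp$y, z = grp$z,
                          stringsAsFactors = FALSE)
      bonds <- NULL
      if (!is.null(parsed$bond) && nrow(parsed$bond) > 0L) {
        sel <- parsed$bond$origin %in% grp$eleno &
          parsed$bond$target %in% grp$eleno
        if (any(sel)) {
          bb <- parsed$bond[sel, , drop = FALSE]
          ord <- suppressWarnings(as.integer(bb$type))
          ord[is.na(ord)] <- 4L  # "ar" / "am"
          bonds <- data.frame(i = match(bb$origin, grp$eleno),
                              j = match(bb$target, grp$eleno), order = ord)
        }
      }
      mol <- molecule(atoms, bonds, het_code = substr(k, 1, 3),
                      perceive_bonds = is.null(bonds))
      copy <- copy + 1L
      ligands[[length(ligands) + 1L]] <- list(
        het_code = toupper(grp$resid_clean[1]), copy_index = copy,
        chain = "A", resno = grp$resno[1], molecule = mol)
    }
  }
  if (nrow(protein) == 0L && length(ligands) == 0L)
    stop("no protein or ligand atoms found in ", basename(path))
  new_complex(entry_id, protein, ligands)
}

#' Write atoms as a TRIPOS MOL2 file
#'
#' Writes a molecule, a binding site, or a whole complex as MOL2, matching
#' the per-entity export layout (one file per fragment instance, one per
#' site).
#'
#' @param x a \code{molecule}, \code{protein_site} or
#'   \code{fragverse_complex}.
#' @param path output file path.
#' @param name molecule name recorded in the file.
#' @return Invisibly, \code{path}.
#' @export
write_mol2 <- function(x, path, name = NULL) {
  if (inherits(x, "molecule")) {
    a <- x$atoms
    tab <- data.frame(name = a$name, element = a$element,
                      x = a$x, y = a$y, z = a$z,
                      resno = 1L, resname = x$het_code %||% "LIG",
                      charge = as.numeric(a$charge))
    bonds <- x$bonds
    name <- name %||% (x$het_code %||% "molecule")
  } else if (inherits(x, "protein_site")) {
    r <- x$residues
    tab <- data.frame(name = r$name, element = r$element,
                      x = r$x, y = r$y, z = r$z,
                      resno = match(paste(r$chain, r$resno),
                                    unique(paste(r$chain, r$resno))),
                      resname = r$resname, charge = 0)
    bonds <- perceive_bonds_by_distance(
      data.frame(element = r$element, x = r$x, y = r$y, z = r$z))
    name <- name %||% paste0(x$source_entry, "_site")
  } else if (inherits(x, "fragverse_complex")) {
    p <- x$protein
    tab <- data.frame(name = p$name, element = p$element,
                      x = p$x, y = p$y, z = p$z,
                      resno = match(paste(p$chain, p$resno),
                                    unique(paste(p$chain, p$resno))),
                      resname = p$resname, charge = 0)
    off <- nrow(tab); bonds <- NULL
    for (lig in x$ligands) {
      a <- lig$molecule$atoms
      tab <- rbind(tab, data.frame(
        name = a$name, element = a$element, x = a$x, y = a$y, z = a$z,
        resno = max(tab$resno) + 1L, resname = lig$het_code,
        charge = as.numeric(a$charge)))
      b <- lig$molecule$bonds
      if (nrow(b)) bonds <- rbind(bonds, data.frame(
        i = b$i + off, j = b$j + off, order = b$order))
      off <- nrow(tab)
    }
    name <- name %||% x$entry_id
  } else stop("unsupported object for write_mol2")
  if (is.null(bonds)) bonds <- data.frame(i = integer(), j = integer(),
                                          order = integer())
  ord_str <- as.character(bonds$order)
  ord_str[bonds$order == 4] <- "ar"
  lines <- c(
    "@<TRIPOS>MOLECULE", name,
    sprintf("%5d %5d %5d 0 0", nrow(tab), nrow(bonds),
            length(unique(tab$resno))),
    "SMALL", "USER_CHARGES", "",
    "@<TRIPOS>ATOM",
    sprintf("%7d %-8s %9.4f %9.4f %9.4f %-5s %5d %-8s %9.4f",
            seq_len(nrow(tab)), tab$name, tab$x, tab$y, tab$z,
            tab$element, tab$resno,
            paste0(tab$resname, tab$resno), tab$charge),
    "@<TRIPOS>BOND",
    if (nrow(bonds)) sprintf("%6d %5d %5d %s", seq_len(nrow(bonds)),
                             bonds$i, bonds$j, ord_str) else character())
  writeLines(lines, path)
  invisible(path)
}

#' Extract the amino-acid binding site of a ligand
#'
#' Returns exactly the amino-acid residues having at least one heavy atom
#' within \code{site_radius} of any ligand heavy atom. An empty site is
#' returned flagged (\code{empty = TRUE}) rather than as an error: such an
#' entry is unusable for interaction detection and is quarantined upstream.
#'
#' @param complex a \code{fragverse_complex}.
#' @param ligand one of \code{complex$ligands}.
#' @param site_radius inclusion radius in Angstrom (default 6.5).
#' @return An object of class \code{"protein_site"}.
#' @export
extract_site <- function(complex, ligand, site_radius = 6.5) {
  stopifnot(inherits(complex, "fragverse_complex"), site_radius > 0)
  prot <- complex$protein
  lig_xyz <- heavy_coords(ligand$molecule)
  if (nrow(prot) == 0L || nrow(lig_xyz) == 0L) {
    residues <- prot[0, , drop = FALSE]
  } else {
    heavy <- !prot$is_h
    d <- cross_dist(as.matrix(prot[heavy, c("x", "y", "z")]), lig_xyz)
    near <- apply(d, 1, min) <= site_radius
    hit <- unique(prot[heavy, c("chain", "resno")][near, , drop = FALSE])
    keep <- paste(prot$chain, prot$resno) %in% paste(hit$chain, hit$resno)
    residues <- prot[keep, , drop = FALSE]
  }
  site <- list(residues = residues, source_entry = complex$entry_id,
               fragment_ref = c(het_code = ligand$het_code,
                                copy_index = ligand$copy_index),
               site_radius = site_radius,
               empty = nrow(residues) == 0L)
  class(site) <- "protein_site"
  site
}

#' @export
print.protein_site <- function(x, ...) {
  nres <- nrow(unique(x$residues[, c("chain", "resno")]))
  cat(sprintf("<site of %s copy %s in %s: %d residue(s)%s>\n",
              x$fragment_ref[["het_code"]], x$fragment_ref[["copy_index"]],
              x$source_entry, nres, if (x$empty) " [EMPTY]" else ""))
  invisible(x)
}

## residue-level count helper
site_n_residues <- function(site) {
  nrow(unique(site$residues[, c("chain", "resno")]))
}

#' Classify a real-space correlation coefficient
#'
#' Maps RSCC values to model-quality classes: \code{FIT} for RSCC > 0.9,
#' \code{PARTIAL} for 0.8 <= RSCC <= 0.9, \code{POOR} for RSCC < 0.8
#' (both class boundaries belong to PARTIAL).
#'
#' @param rscc numeric vector of RSCC values in [-1, 1].
#' @return Character vector of classes ("FIT", "PARTIAL", "POOR").
#' @examples
#' classify_rscc(c(0.95, 0.9, 0.79))
#' @export
classify_rscc <- function(rscc) {
  if (any(!is.na(rscc) & (rscc < -1 | rscc > 1)))
    stop("RSCC values must lie in [-1, 1]")
  ifelse(is.na(rscc), NA_character_,
         ifelse(rscc > 0.9, "FIT", ifelse(rscc >= 0.8, "PARTIAL", "POOR")))
}

#' Parse per-residue RSCC from a wwPDB-style validation XML file
#'
#' Reads \code{ModelledSubgroup} records, takes the ligand RSCC directly from
#' the record matching the ligand instance, and averages the RSCC of the site
#' residues found in the file (residues absent from the file are excluded
#' from the mean, shrinking the denominator). A ligand absent from the file
#' yields \code{NA}, never 0.
#'
#' @param xml_path path to the validation XML file.
#' @param site a \code{protein_site}.
#' @param ligand the matching ligand instance.
#' @return A list of class \code{"rscc_report"}: \code{ligand_rscc},
#'   \code{site_mean_rscc}, \code{quality_class}.
#' @export
parse_validation_rscc <- function(xml_path, site, ligand) {
  doc <- xml2::read_xml(xml_path)
  nodes <- xml2::xml_find_all(doc, "//ModelledSubgroup")
  tab <- data.frame(
    chain = xml2::xml_attr(nodes, "chain"),
    resnum = as.integer(xml2::xml_attr(nodes, "resnum")),
    resname = xml2::xml_attr(nodes, "resname"),
    rscc = as.numeric(xml2::xml_attr(nodes, "rscc")),
    stringsAsFactors = FALSE)
  sres <- unique(site$residues[, c("chain", "resno")])
  m <- match(paste(sres$chain, sres$resno),
             paste(tab$chain, tab$resnum))
  site_rscc <- tab$rscc[m[!is.na(m)]]
  site_mean <- if (length(site_rscc)) mean(site_rscc, na.rm = TRUE) else NA_real_
  lig_sel <- tab$resname == ligand$het_code &
    (is.na(tab$resnum) | is.null(ligand$resno) | tab$resnum == ligand$resno)
  lig_rscc <- if (any(lig_sel, na.rm = TRUE))
    tab$rscc[which(lig_sel)[1]] else NA_real_
  rep <- list(ligand_rscc = lig_rscc, site_mean_rscc = site_mean,
              quality_class = classify_rscc(lig_rscc))
  class(rep) <- "rscc_report"
  rep
}

## ---- hydrogen placement -----------------------------------------------------

H_BOND_LENGTH <- c(N = 1.01, O = 0.96, S = 1.34)

#' Add missing polar hydrogens to a complex
#'
#' Template-free, valence-based placement: each nitrogen, oxygen or sulfur
#' whose perceived bonds leave open valence receives hydrogens at standard
#' bond lengths (N-H 1.01, O-H 0.96, S-H 1.34 Angstrom), directed away from
#' the mean of its heavy-atom neighbors. Carbonyl-like oxygens (bond length
#' < 1.28 Angstrom to carbon) and negatively charged oxygens get none.
#' Aromatic ring nitrogens default to the unprotonated (pyridine-like) state;
#' protonation-sensitive cases need a per-entry override. Idempotent: atoms
#' that already carry hydrogens are left untouched, and residues with
#' unrecognized connectivity pass through unchanged with a warning.
#'
#' @param complex a \code{fragverse_complex}.
#' @return The complex with explicit polar hydrogens.
#' @export
ensure_hydrogens <- function(complex) {
  stopifnot(inherits(complex, "fragverse_complex"))
  complex$ligands <- lapply(complex$ligands, function(lig) {
    lig$molecule <- add_polar_hydrogens(lig$molecule)
    lig
  })
  complex$protein <- add_protein_hydrogens(complex$protein)
  complex
}

## target H count for one heavy atom given neighbors and charge
polar_h_count <- function(element, charge, orders, aromatic, carbonyl_like) {
  nb <- sum(ifelse(orders == 4L, 1.5, orders))
  if (element == "N") {
    if (aromatic) return(0L)  # pyridine-like default
    val <- 3 + charge
    return(max(0L, as.integer(round(val - nb))))
  }
  if (element == "O") {
    if (carbonyl_like || charge < 0) return(0L)
    return(max(0L, as.integer(round(2 + charge - nb))))
  }
  if (element == "S") {
    if (length(orders) >= 2 || charge < 0) return(0L)
    return(if (length(orders) == 1 && orders[1] == 1L) 1L else 0L)
  }
  0L
}

place_hydrogens <- function(pos, neighbor_pos, n_h, length_h) {
  if (nrow(neighbor_pos) == 0L) {
    dirs <- list(c(0, 0, 1), c(0.94, 0, -0.33), c(-0.47, 0.82, -0.33))
  } else {
    away <- -colMeans(sweep(neighbor_pos, 2, pos, function(a, b) a - b))
    if (sqrt(sum(away^2)) < 1e-8) away <- c(0, 0, 1)
    u <- unit_vector(away)
    o1 <- orthogonal_vector(u)
    o2 <- pracma_cross(u, o1)
    dirs <- list(u,
                 unit_vector(u * cos(1.2) + o1 * sin(1.2)),
                 unit_vector(u * cos(1.2) + o1 * sin(1.2) * cos(2.09) +
                               o2 * sin(1.2) * sin(2.09)))
  }
  t(vapply(seq_len(n_h),
           function(k) pos + length_h * dirs[[((k - 1) %% 3) + 1]],
           numeric(3)))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

add_polar_hydrogens <- function(mol) {
  a <- mol$atoms; b <- mol$bonds
  new_atoms <- list(); new_bonds <- list()
  for (i in which(a$element %in% c("N", "O", "S"))) {
    nb_idx <- c(b$j[b$i == i], b$i[b$j == i])
    if (any(a$element[nb_idx] == "H")) next  # already protonated
    orders <- c(b$order[b$i == i], b$order[b$j == i])
    heavy_nb <- nb_idx[a$element[nb_idx] != "H"]
    carbonyl <- FALSE
    if (a$element[i] == "O" && length(heavy_nb) == 1L) {
      d <- sqrt(sum((as.numeric(a[i, c("x", "y", "z")]) -
                       as.numeric(a[heavy_nb, c("x", "y", "z")]))^2))
      carbonyl <- a$element[heavy_nb] == "C" &&
        (d < 1.28 || any(orders == 2L))
    }
    nh <- polar_h_count(a$element[i], a$charge[i], orders,
                        isTRUE(a$aromatic[i]), carbonyl)
    if (nh == 0L) next
    pos <- as.numeric(a[i, c("x", "y", "z")])
    npos <- as.matrix(a[heavy_nb, c("x", "y", "z"), drop = FALSE])
    hxyz <- place_hydrogens(pos, npos, nh, H_BOND_LENGTH[[a$element[i]]])
    for (k in seq_len(nh)) {
      new_atoms[[length(new_atoms) + 1L]] <- data.frame(
        name = paste0("H", a$name[i], k), element = "H",
        x = hxyz[k, 1], y = hxyz[k, 2], z = hxyz[k, 3],
        charge = 0L, aromatic = FALSE, is_h = TRUE,
        stringsAsFactors = FALSE)
      new_bonds[[length(new_bonds) + 1L]] <- data.frame(
        i = i, j = nrow(a) + length(new_atoms), order = 1L)
    }
  }
  if (length(new_atoms)) {
    mol$atoms <- rbind(a, do.call(rbind, new_atoms))
    mol$bonds <- rbind(b, do.call(rbind, new_bonds))
  }
  mol
}

## per-residue hydrogen placement for the protein table; peptide N gets the
## previous residue's carbonyl C as an extra neighbor
add_protein_hydrogens <- function(prot) {
  if (nrow(prot) == 0L) return(prot)
  reskey <- paste(prot$chain, prot$resno)
  resids <- unique(reskey)
  out <- list()
  for (rk in resids) {
    idx <- which(reskey == rk)
    res <- prot[idx, , drop = FALSE]
    atoms <- data.frame(name = res$name, element = res$element,
                        x = res$x, y = res$y, z = res$z,
                        charge = 0L, aromatic = FALSE,
                        stringsAsFactors = FALSE)
    ## known charged side chains keep their protonation count correct
    atoms$charge[res$resname == "LYS" & res$name == "NZ"] <- 1L
    mol <- tryCatch(molecule(atoms, perceive_bonds = TRUE),
                    error = function(e) NULL)
    if (is.null(mol)) {
      warning("residue ", rk, " passed through unprotonated")
      out[[length(out) + 1L]] <- res
      next
    }
    ## backbone N of a mid-chain residue: add virtual neighbor (previous C)
    prev <- prot[prot$chain == res$chain[1] &
                   prot$resno == res$resno[1] - 1L &
                   prot$name == "C", , drop = FALSE]
    ni <- which(mol$atoms$name == "N")
    if (length(ni) == 1L && nrow(prev) == 1L) {
      d <- sqrt(sum((c(mol$atoms$x[ni], mol$atoms$y[ni], mol$atoms$z[ni]) -
                       c(prev$x, prev$y, prev$z))^2))
      if (d < 1.6) {
        mol$atoms <- rbind(mol$atoms, data.frame(
          name = "C_prev", element = "C", x = prev$x, y = prev$y, z = prev$z,
          charge = 0L, aromatic = FALSE, is_h = FALSE))
        mol$bonds <- rbind(mol$bonds, data.frame(
          i = ni, j = nrow(mol$atoms), order = 1L))
      }
    }
    if (res$resname[1] == "PRO" && length(ni) == 1L) {
      ## proline N carries no H; mark as saturated via aromatic flag trick
      mol$atoms$aromatic[ni] <- TRUE
    }
    molH <- add_polar_hydrogens(mol)
    added <- molH$atoms[-seq_len(nrow(mol$atoms)), , drop = FALSE]
    added <- added[added$name != "C_prev", , drop = FALSE]
    res_out <- res
    if (nrow(added)) {
      res_out <- rbind(res, data.frame(
        chain = res$chain[1], resno = res$resno[1],
        resname = res$resname[1], name = added$name,
        element = "H", x = added$x, y = added$y, z = added$z,
        is_h = TRUE, stringsAsFactors = FALSE))
    }
    out[[length(out) + 1L]] <- res_out
  }
  do.call(rbind, out)
}
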