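## Synthetic complexes, graph families, cavity clouds and mini-corpora with
## planted ground truth. Synthetic "proteins" are minimal residue probes
## (single functional atoms positioned to realize exactly the requested
## interactions) plus, for corpora, a non-interacting cage of polar atoms
## that encloses the fragment and defines the cavity environment. Every
## downstream computation consumes geometry, not fold, so probes suffice.

## ---- single complexes -------------------------------------------------------

#' Build a minimal synthetic complex realizing a list of interactions
#'
#' Constructs a fragment (anchor atoms, explicit polar hydrogens, aromatic
#' rings where needed) and single-atom probe residues such that
#' [detect_interactions()] on the result returns exactly the requested
#' interaction types. Construction is validated by running the detector; an
#' infeasible geometry raises an error.
#'
#' @param interaction_spec data.frame with columns \code{itype} and the
#'   ligand / protein anchor coordinates \code{lx,ly,lz,px,py,pz}.
#' @param entry_id,het_code identifiers for the complex and its fragment.
#' @param validate run the closed-loop check (default TRUE).
#' @return A \code{fragverse_complex} with one ligand instance.
#' @export
synth_complex <- function(interaction_spec, entry_id = "SYN001",
                          het_code = "FRG", validate = TRUE) {
  spec <- as.data.frame(interaction_spec)
  lig_atoms <- list(); lig_bonds <- list(); prot <- list()
  resno <- 0L
  counter <- new.env(); assign("n", 0L, counter)
  aname <- function(el) {
    n <- get("n", counter) + 1L
    assign("n", n, counter)
    paste0(el, n)
  }
  add_lig <- function(el, pos, charge = 0L, aromatic = FALSE) {
    lig_atoms[[length(lig_atoms) + 1L]] <<- data.frame(
      name = aname(el), element = el, x = pos[1], y = pos[2], z = pos[3],
      charge = charge, aromatic = aromatic, stringsAsFactors = FALSE)
    length(lig_atoms)
  }
  add_bond <- function(i, j, order = 1L) {
    lig_bonds[[length(lig_bonds) + 1L]] <<- data.frame(i = i, j = j,
                                                       order = order)
  }
  add_res <- function(resname, atoms) {
    resno <<- resno + 1L
    prot[[length(prot) + 1L]] <<- data.frame(
      chain = "A", resno = resno, resname = resname,
      name = atoms$name, element = atoms$element,
      x = atoms$x, y = atoms$y, z = atoms$z,
      is_h = atoms$element == "H", stringsAsFactors = FALSE)
  }
  for (k in seq_len(nrow(spec))) {
    l <- as.numeric(spec[k, c("lx", "ly", "lz")])
    p <- as.numeric(spec[k, c("px", "py", "pz")])
    u <- unit_vector(p - l)
    it <- spec$itype[k]
    if (it == "HB_DONOR") {
      ## ligand N-H donating to a backbone carbonyl O probe
      ni <- add_lig("N", l)
      hi <- add_lig("H", l + 1.01 * u)
      add_bond(ni, hi)
      add_res("GLY", data.frame(name = c("O", "C"), element = c("O", "C"),
                                x = c(p[1], p[1] + 1.23 * u[1]),
                                y = c(p[2], p[2] + 1.23 * u[2]),
                                z = c(p[3], p[3] + 1.23 * u[3])))
    } else if (it == "HB_ACCEPTOR") {
      ## ligand carbonyl O accepting from a backbone N-H probe
      oi <- add_lig("O", l)
      ci <- add_lig("C", l - 1.23 * u)
      add_bond(oi, ci, order = 2L)
      hp <- p + 1.01 * unit_vector(l - p)
      add_res("GLY", data.frame(name = c("N", "H"), element = c("N", "H"),
                                x = c(p[1], hp[1]), y = c(p[2], hp[2]),
                                z = c(p[3], hp[3])))
    } else if (it == "IONIC_NEG") {
      add_lig("O", l, charge = -1L)
      add_res("ARG", data.frame(name = "NH1", element = "N",
                                x = p[1], y = p[2], z = p[3]))
    } else if (it == "IONIC_POS") {
      add_lig("N", l, charge = 1L)
      cp <- p + 1.25 * u
      add_res("GLU", data.frame(name = c("OE1", "CD"), element = c("O", "C"),
                                x = c(p[1], cp[1]), y = c(p[2], cp[2]),
                                z = c(p[3], cp[3])))
    } else if (it == "AROMATIC") {
      ## parallel-stacked benzene / phenylalanine rings
      o1 <- orthogonal_vector(u); o2 <- pracma_cross(u, o1)
      first <- NULL
      ring_idx <- integer(6)
      for (m in 0:5) {
        ang <- m * pi / 3
        pos <- l + 1.39 * (cos(ang) * o1 + sin(ang) * o2)
        ring_idx[m + 1] <- add_lig("C", pos, aromatic = TRUE)
      }
      for (m in 1:6) add_bond(ring_idx[m], ring_idx[(m %% 6) + 1], order = 4L)
      phe_names <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
      ppos <- t(vapply(0:5, function(m) {
        ang <- m * pi / 3
        p + 1.39 * (cos(ang) * o1 + sin(ang) * o2)
      }, numeric(3)))
      add_res("PHE", data.frame(name = phe_names, element = "C",
                                x = ppos[, 1], y = ppos[, 2], z = ppos[, 3]))
    } else if (it == "HYDROPHOBIC") {
      add_lig("C", l)
      add_res("LEU", data.frame(name = "CD1", element = "C",
                                x = p[1], y = p[2], z = p[3]))
    } else stop("unknown interaction type: ", it)
  }
  if (nrow(spec) == 0L) {
    ## fragment far from a lone polar probe: zero interactions
    add_lig("C", c(0, 0, 0)); add_lig("C", c(1.5, 0, 0))
    add_bond(1L, 2L)
    add_res("GLY", data.frame(name = "N", element = "N",
                              x = 20, y = 20, z = 20))
  }
  atoms <- do.call(rbind, lig_atoms)
  if (sum(atoms$element != "H") < 2L) {
    ## companion carbon bonded to the first anchor keeps the instance valid
    ## (bonded so it stays out of the apolar contact set)
    comp <- as.numeric(atoms[1, c("x", "y", "z")]) + c(0, -3, 0)
    lig_atoms[[length(lig_atoms) + 1L]] <- data.frame(
      name = aname("C"), element = "C", x = comp[1], y = comp[2],
      z = comp[3], charge = 0L, aromatic = FALSE)
    add_bond(1L, length(lig_atoms))
    atoms <- do.call(rbind, lig_atoms)
  }
  bonds <- if (length(lig_bonds)) do.call(rbind, lig_bonds) else NULL
  mol <- molecule(atoms, bonds, het_code = het_code)
  protein <- do.call(rbind, prot)
  cx <- new_complex(entry_id, protein,
                    list(list(het_code = het_code, copy_index = 1L,
                              chain = "A", resno = 900L, molecule = mol)),
                    resolution = 1.5,
                    deposition_date = as.Date("2015-01-01"))
  if (validate) {
    site <- extract_site(cx, cx$ligands[[1]])
    got <- detect_interactions(cx$ligands[[1]], site)
    if (!identical(sort(as.character(got$itype)),
                   sort(as.character(spec$itype))))
      stop("infeasible interaction geometry: requested {",
           paste(sort(spec$itype), collapse = ","), "} but detected {",
           paste(sort(got$itype), collapse = ","), "}")
  }
  cx
}

## ---- binding-mode families --------------------------------------------------

itx <- function(itype, l, p) {
  data.frame(itype = itype, lx = l[1], ly = l[2], lz = l[3],
             px = p[1], py = p[2], pz = p[3])
}

#' Binding-mode interaction templates
#'
#' Five interaction layouts with pairwise-distinct label multisets, so the
#' kernel similarity between any two templates stays well below the
#' clustering threshold while same-template graphs under small jitter stay
#' well above it. The \code{corpus_safe} set avoids formal charges (which do
#' not survive a plain coordinate-file round trip).
#'
#' @param corpus_safe use the charge-free template set.
#' @return List of interaction-spec data.frames.
#' @export
mode_templates <- function(corpus_safe = FALSE) {
  if (corpus_safe) {
    list(
      rbind(itx("HB_DONOR", c(0, 0, 0), c(0, 2.7, 0)),
            itx("HB_DONOR", c(7, 0, 0), c(7, 2.9, 0))),
      rbind(itx("HB_ACCEPTOR", c(0, 0, 0), c(0, 0, 2.7)),
            itx("HB_ACCEPTOR", c(7, 0, 0), c(7, 0, 2.9))),
      rbind(itx("HYDROPHOBIC", c(0, 0, 0), c(0, 0, 3.6)),
            itx("HYDROPHOBIC", c(7, 0, 0), c(7, 0, 3.8))),
      rbind(itx("AROMATIC", c(0, 0, 0), c(0, 0, 3.8)),
            itx("HYDROPHOBIC", c(8, 0, 0), c(8, 0, 3.6))),
      rbind(itx("HB_DONOR", c(0, 0, 0), c(0, 2.7, 0)),
            itx("HB_ACCEPTOR", c(8, 0, 0), c(8, 0, 2.9)),
            itx("HYDROPHOBIC", c(16, 0, 0), c(16, 0, 3.6)))
    )
  } else {
    list(
      rbind(itx("HYDROPHOBIC", c(0, 0, 0), c(0, 0, 3.6)),
            itx("HYDROPHOBIC", c(7, 0, 0), c(7, 0, 3.8))),
      rbind(itx("HB_DONOR", c(0, 0, 0), c(0, 2.7, 0)),
            itx("HB_DONOR", c(7, 0, 0), c(7, 2.9, 0))),
      rbind(itx("HB_ACCEPTOR", c(0, 0, 0), c(0, 0, 2.7)),
            itx("HB_ACCEPTOR", c(7, 0, 0), c(7, 0, 2.9))),
      rbind(itx("IONIC_NEG", c(0, 0, 0), c(0, 0, 3.4)),
            itx("AROMATIC", c(8, 0, 0), c(8, 0, 3.8))),
      rbind(itx("IONIC_POS", c(0, 0, 0), c(0, 3.4, 0)),
            itx("HYDROPHOBIC", c(7, 0, 0), c(7, 0, 3.6)))
    )
  }
}

jitter_spec <- function(spec, sigma) {
  if (sigma <= 0) return(spec)
  cols <- c("lx", "ly", "lz", "px", "py", "pz")
  spec[cols] <- spec[cols] + matrix(stats::rnorm(nrow(spec) * 6, 0, sigma),
                                    nrow(spec))
  spec
}

#' Generate a synthetic family of complexes with K planted binding modes
#'
#' Each mode uses a distinct interaction template; each observation is the
#' template with independent coordinate jitter. With \code{nested = TRUE}
#' mode k uses the first k interactions of the richest template, so every
#' mode's graph embeds in the next — the inclusion-merge correction collapses
#' them to one mode.
#'
#' @param K number of planted modes (1-5).
#' @param n_per_mode observations per mode.
#' @param sigma coordinate jitter standard deviation, Angstrom.
#' @param seed RNG seed.
#' @param nested build inclusion-nested modes (see above).
#' @param corpus_safe use the charge-free templates.
#' @return list(complexes, truth) where truth is a data.frame with one row
#'   per complex (\code{obs}, \code{mode}).
#' @export
synth_mode_family <- function(K, n_per_mode = 2L, sigma = 0.05, seed = 1L,
                              nested = FALSE, corpus_safe = FALSE) {
  stopifnot(K >= 1L, K <= 5L, n_per_mode >= 1L)
  tmpl <- mode_templates(corpus_safe)
  if (nested) {
    base <- tmpl[[length(tmpl)]]
    stopifnot(K <= nrow(base))
    tmpl <- lapply(seq_len(K), function(k) base[seq_len(k), , drop = FALSE])
  }
  with_seed(seed, {
    complexes <- list(); truth <- list()
    obs <- 0L
    for (k in seq_len(K)) for (r in seq_len(n_per_mode)) {
      obs <- obs + 1L
      spec <- jitter_spec(tmpl[[k]], sigma)
      complexes[[obs]] <- synth_complex(
        spec, entry_id = sprintf("SYN%03d", obs),
        het_code = "FRG")
      truth[[obs]] <- data.frame(obs = obs, mode = k)
    }
    list(complexes = complexes, truth = do.call(rbind, truth))
  })
}

## interaction graphs of a list of complexes (single-ligand each)
family_graphs <- function(complexes, config = pipeline_config()) {
  lapply(complexes, function(cx) {
    lig <- cx$ligands[[1]]
    site <- extract_site(cx, lig, config$site_radius)
    build_interaction_graph(detect_interactions(lig, site))
  })
}

## ---- cavity-environment sets ------------------------------------------------

ENV_PRIMARY_LABELS <- c("HB_ACCEPTOR", "HB_DONOR", "NEGATIVE", "AROMATIC",
                        "HYDROPHOBIC")

#' Generate labeled cavity clouds with M planted environments
#'
#' Environment m is a fixed set of lattice points (spacing 1.5 A) inside a
#' sphere, 80\% labeled with the environment's primary label and 20\% DUMMY;
#' primary labels are pairwise distinct, so cross-environment score is
#' bounded by the DUMMY fraction (0.2 < 0.47) while same-environment
#' observations are rigid copies (score ~1, minus label noise).
#'
#' @param M number of environments (1-5).
#' @param n_obs number of observations (assigned round-robin).
#' @param transform_mag translation magnitude of the random rigid motions.
#' @param label_noise fraction of point labels flipped per observation.
#' @param seed RNG seed.
#' @param n_points points per environment template.
#' @return list(clouds, truth) with truth columns \code{obs}, \code{cavity}.
#' @export
synth_cavity_set <- function(M, n_obs = 2L * M, transform_mag = 10,
                             label_noise = 0, seed = 1L, n_points = 26L) {
  stopifnot(M >= 1L, M <= 5L, n_obs >= M)
  with_seed(seed, {
    lattice <- as.matrix(expand.grid(seq(-4.5, 4.5, 1.5),
                                     seq(-4.5, 4.5, 1.5),
                                     seq(-4.5, 4.5, 1.5)))
    lattice <- lattice[sqrt(rowSums(lattice^2)) <= 4.6, ]
    templates <- lapply(seq_len(M), function(m) {
      idx <- sample.int(nrow(lattice), n_points)
      pts <- lattice[idx, , drop = FALSE]
      lab <- rep(ENV_PRIMARY_LABELS[m], n_points)
      lab[sample.int(n_points, round(0.2 * n_points))] <- "DUMMY"
      list(points = pts, labels = lab)
    })
    clouds <- list(); truth <- list()
    for (i in seq_len(n_obs)) {
      m <- ((i - 1L) %% M) + 1L
      tp <- templates[[m]]
      R <- random_rotation()
      t_ <- stats::runif(3, -transform_mag, transform_mag)
      pts <- sweep(tp$points %*% R, 2, -t_)
      lab <- tp$labels
      if (label_noise > 0) {
        nflip <- round(label_noise * length(lab))
        if (nflip > 0) {
          fl <- sample.int(length(lab), nflip)
          lab[fl] <- vapply(lab[fl], function(old)
            sample(setdiff(CLOUD_LABELS, old), 1), character(1))
        }
      }
      clouds[[i]] <- new_labeled_cloud(pts, lab, 1.5)
      truth[[i]] <- data.frame(obs = i, cavity = m)
    }
    list(clouds = clouds, truth = do.call(rbind, truth))
  })
}

## ---- corpora ----------------------------------------------------------------

## fibonacci sphere directions
sphere_directions <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

CAGE_RECIPES <- list(
  list(resname = "GLY", atom = "O", element = "O", standoff = 5.0),
  list(resname = "GLY", atom = "N", element = "N", standoff = 5.6),
  list(resname = "ASP", atom = "OD1", element = "O", standoff = 5.0),
  list(resname = "LYS", atom = "NZ", element = "N", standoff = 5.6),
  list(resname = "SER", atom = "OG", element = "O", standoff = 5.3)
)

## enclose the fragment of a complex in a cage of non-interacting polar
## atoms defining cavity environment `env`
add_cavity_cage <- function(cx, env, n_cage = 64L) {
  recipe <- CAGE_RECIPES[[env]]
  frag <- heavy_coords(cx$ligands[[1]]$molecule)
  centroid <- colMeans(frag)
  dirs <- sphere_directions(n_cage)
  resno0 <- max(cx$protein$resno)
  rows <- lapply(seq_len(n_cage), function(k) {
    u <- dirs[k, ]
    t_ <- max((frag %*% u) - sum(centroid * u)) + recipe$standoff
    pos <- centroid + t_ * u
    data.frame(chain = "A", resno = resno0 + k, resname = recipe$resname,
               name = recipe$atom, element = recipe$element,
               x = pos[1], y = pos[2], z = pos[3], is_h = FALSE,
               stringsAsFactors = FALSE)
  })
  cx$protein <- rbind(cx$protein, do.call(rbind, rows))
  cx
}

#' Synthetic corpus specification
#'
#' Describes a mini-corpus: \code{n_versatile} fragments with planted
#' \code{K} binding modes and \code{M} cavity environments observed in
#' \code{n_obs} entries each, plus one decoy per requested category:
#' a single-entry fragment, a fragment-definition reject (sulfate), a
#' single-mode fragment, a single-cavity fragment, and a PAINS-bearing
#' (catechol) fragment that is otherwise versatile.
#'
#' @param n_versatile number of planted versatile fragments.
#' @param K,M planted mode / cavity counts for the versatile fragments.
#' @param n_obs observations (entries) per fragment.
#' @param sigma coordinate jitter, Angstrom.
#' @param decoys character vector among \code{"single_entry"},
#'   \code{"unwanted"}, \code{"single_mode"}, \code{"single_cavity"},
#'   \code{"pains"}.
#' @param seed RNG seed.
#' @return list of class \code{"synthetic_spec"}.
#' @export
synthetic_spec <- function(n_versatile = 3L, K = 2L, M = 2L, n_obs = 4L,
                           sigma = 0.05,
                           decoys = c("single_entry", "unwanted",
                                      "single_mode", "single_cavity",
                                      "pains"),
                           seed = 1L) {
  stopifnot(K >= 1L, K <= 5L, M >= 1L, M <= 5L,
            n_obs >= max(K, M), sigma >= 0)
  sp <- list(n_versatile = as.integer(n_versatile), K = as.integer(K),
             M = as.integer(M), n_obs = as.integer(n_obs), sigma = sigma,
             decoys = decoys, seed = as.integer(seed))
  class(sp) <- "synthetic_spec"
  sp
}

VERSATILE_SMILES <- c("Cc1ccncc1", "CCc1ccccn1", "COc1ccccc1C=O",
                      "CC(=O)Nc1ccncc1", "OCC1OC(O)C(O)C1O")

#' Generate a synthetic corpus on disk
#'
#' Writes one PDB file per entry (protein probes + cage + fragment HETATM),
#' a \code{ligands.csv} manifest (het_code, smiles) and a \code{truth.csv}
#' ground-truth table. Deterministic under a fixed seed.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created).
#' @return list(dir, truth) invisibly; truth has one row per fragment with
#'   het_code, K, M, versatile, expected_reject_step.
#' @export
synth_corpus <- function(spec, dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(file.path(dir, "entries"), recursive = TRUE,
             showWarnings = FALSE)
  frag_rows <- list(); lig_rows <- list()
  entry_counter <- new.env(); assign("n", 0L, entry_counter)
  next_entry <- function() {
    n <- get("n", entry_counter) + 1L
    assign("n", n, entry_counter)
    sprintf("SN%04d", n)
  }
  write_fragment <- function(het, smiles, K, M, n_obs, sigma, seedk,
                             single_entry = FALSE) {
    tmpl <- mode_templates(corpus_safe = TRUE)
    with_seed(seedk, {
      if (single_entry) {
        ## two copies of the fragment in one entry, far apart
        eid <- next_entry()
        cx1 <- synth_complex(jitter_spec(tmpl[[1]], sigma), eid, het)
        cx1 <- add_cavity_cage(cx1, 1L)
        spec2 <- jitter_spec(tmpl[[1]], sigma)
        spec2[, c("lx", "px")] <- spec2[, c("lx", "px")] + 40
        spec2[, c("ly", "py")] <- spec2[, c("ly", "py")] + 40
        cx2 <- synth_complex(spec2, eid, het)
        cx2 <- add_cavity_cage(cx2, 1L)
        cx2$protein$resno <- cx2$protein$resno + max(cx1$protein$resno)
        cx1$protein <- rbind(cx1$protein, cx2$protein)
        lig2 <- cx2$ligands[[1]]
        lig2$copy_index <- 2L
        lig2$resno <- 901L
        cx1$ligands <- c(cx1$ligands, list(lig2))
        write_pdb(cx1, file.path(dir, "entries", paste0(eid, ".pdb")))
        return(invisible(NULL))
      }
      for (i in seq_len(n_obs)) {
        k <- ((i - 1L) %% K) + 1L
        m <- ((i - 1L) %% M) + 1L
        eid <- next_entry()
        cx <- synth_complex(jitter_spec(tmpl[[k]], sigma), eid, het)
        cx <- add_cavity_cage(cx, m)
        write_pdb(cx, file.path(dir, "entries", paste0(eid, ".pdb")))
      }
    })
    invisible(NULL)
  }
  with_seed(spec$seed, {
    seeds <- sample.int(1e6, spec$n_versatile + 5L)
  })
  si <- 0L
  for (v in seq_len(spec$n_versatile)) {
    si <- si + 1L
    het <- sprintf("V%02d", v)
    smi <- VERSATILE_SMILES[((v - 1L) %% length(VERSATILE_SMILES)) + 1L]
    write_fragment(het, smi, spec$K, spec$M, spec$n_obs, spec$sigma,
                   seeds[si])
    lig_rows[[length(lig_rows) + 1L]] <- data.frame(het_code = het,
                                                    smiles = smi)
    frag_rows[[length(frag_rows) + 1L]] <- data.frame(
      het_code = het, K = spec$K, M = spec$M, versatile = TRUE,
      expected_reject_step = NA_integer_)
  }
  decoy_def <- list(
    single_entry = list(het = "DS1", smiles = "Cc1ccco1", step = 2L,
                        K = 1L, M = 1L),
    unwanted = list(het = "DU1", smiles = "[O-]S(=O)(=O)[O-]", step = 1L,
                    K = 1L, M = 1L),
    single_mode = list(het = "DM1", smiles = "CCOC(=O)C1CC1", step = 3L,
                       K = 1L, M = spec$M),
    single_cavity = list(het = "DC1", smiles = "Cc1ccc(N)nc1", step = 4L,
                         K = spec$K, M = 1L),
    pains = list(het = "DP1", smiles = "Oc1ccccc1O", step = 5L,
                 K = spec$K, M = spec$M))
  for (d in spec$decoys) {
    si <- si + 1L
    dd <- decoy_def[[d]]
    write_fragment(dd$het, dd$smiles, dd$K, dd$M,
                   n_obs = if (d == "single_entry") 1L else spec$n_obs,
                   spec$sigma, seeds[si],
                   single_entry = d == "single_entry")
    lig_rows[[length(lig_rows) + 1L]] <- data.frame(het_code = dd$het,
                                                    smiles = dd$smiles)
    frag_rows[[length(frag_rows) + 1L]] <- data.frame(
      het_code = dd$het, K = dd$K, M = dd$M, versatile = FALSE,
      expected_reject_step = dd$step)
  }
  truth <- do.call(rbind, frag_rows)
  utils::write.csv(do.call(rbind, lig_rows),
                   file.path(dir, "ligands.csv"), row.names = FALSE)
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(list(dir = dir, truth = truth))
}

#' Write a complex as a PDB file
#'
#' Minimal fixed-column PDB writer (HEADER with deposition date, REMARK 2
#' resolution, ATOM records for the protein, HETATM for ligand instances).
#'
#' @param complex a \code{fragverse_complex}.
#' @param path output file path.
#' @export
write_pdb <- function(complex, path) {
  lines <- character()
  date_str <- if (!is.na(complex$deposition_date[1]))
    toupper(format(as.Date(complex$deposition_date), "%d-%b-%y")) else
      "01-JAN-15"
  lines <- c(lines, sprintf("%-50s%9s   %s", "HEADER    SYNTHETIC COMPLEX",
                            date_str, substr(complex$entry_id, 1, 4)))
  if (!is.na(complex$resolution))
    lines <- c(lines, sprintf(
      "REMARK   2 RESOLUTION. %7.2f ANGSTROMS.", complex$resolution))
  fmt_atom <- function(record, serial, name, resname, chain, resno,
                       x, y, z, element) {
    nm <- if (nchar(name) < 4L) sprintf(" %-3s", name) else
      sprintf("%-4s", substr(name, 1, 4))
    sprintf("%-6s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            record, serial, nm, resname, chain, resno, x, y, z, 1, 0,
            toupper(element))
  }
  serial <- 0L
  p <- complex$protein
  for (i in seq_len(nrow(p))) {
    serial <- serial + 1L
    lines <- c(lines, fmt_atom("ATOM", serial, p$name[i], p$resname[i],
                               p$chain[i], p$resno[i], p$x[i], p$y[i],
                               p$z[i], p$element[i]))
  }
  for (lig in complex$ligands) {
    a <- lig$molecule$atoms
    for (i in seq_len(nrow(a))) {
      serial <- serial + 1L
      lines <- c(lines, fmt_atom("HETATM", serial, a$name[i], lig$het_code,
                                 lig$chain %||% "A", lig$resno %||% 900L,
                                 a$x[i], a$y[i], a$z[i], a$element[i]))
    }
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}
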