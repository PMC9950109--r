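## Five-step versatile-fragment selection pipeline:
##   1) remove molecules that do not meet the fragment definition,
##   2) remove fragments present in a single entry,
##   3) remove fragments with a single binding mode,
##   4) remove fragments bound only in mutually similar cavities,
##   5) remove PAINS-bearing fragments.
## Steps run lazily per fragment: a fragment rejected at step k never enters
## the computation of step k+1.

#' Run the versatile-fragment pipeline over a structure corpus
#'
#' The corpus directory holds structure files (\code{entries/*.pdb|cif|mol2},
#' or directly in the directory) and optionally a \code{ligands.csv} manifest
#' (columns het_code, smiles) supplying fragment chemistry. Entries with
#' resolution >= 3 A or deposition date before 2000-01-01 are dropped at
#' ingestion when that metadata is present; absent metadata passes with a
#' warning. Per-entry failures are quarantined and reported, never silently
#' dropped.
#'
#' @param corpus_dir corpus directory.
#' @param config a [pipeline_config()].
#' @param min_date,max_resolution ingestion filters.
#' @return An object of class \code{"pipeline_report"}: \code{records}
#'   (one row per fragment), \code{survivors} (per-step counts),
#'   \code{instances}, \code{complexes}, \code{quarantined}, \code{config}.
#' @export
run_pipeline <- function(corpus_dir, config = pipeline_config(),
                         min_date = as.Date("2000-01-01"),
                         max_resolution = 3.0) {
  entry_dir <- if (dir.exists(file.path(corpus_dir, "entries")))
    file.path(corpus_dir, "entries") else corpus_dir
  files <- list.files(entry_dir, pattern = "\\.(pdb|ent|cif|mmcif|mol2)$",
                      full.names = TRUE)
  if (length(files) == 0L) {
    return(empty_report(config, corpus_dir))
  }
  manifest <- NULL
  mpath <- file.path(corpus_dir, "ligands.csv")
  if (file.exists(mpath))
    manifest <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  quarantined <- list()
  complexes <- list()
  for (f in sort(files)) {
    cx <- tryCatch(read_structure(f), error = function(e) e)
    if (inherits(cx, "error")) {
      quarantined[[length(quarantined) + 1L]] <- data.frame(
        entry_id = basename(f), stage = "ingest",
        reason = conditionMessage(cx))
      next
    }
    if (!is.na(cx$resolution) && cx$resolution >= max_resolution) {
      quarantined[[length(quarantined) + 1L]] <- data.frame(
        entry_id = cx$entry_id, stage = "ingest",
        reason = sprintf("resolution %.2f >= %.1f A", cx$resolution,
                         max_resolution))
      next
    }
    if (!is.na(cx$deposition_date[1]) &&
        as.Date(cx$deposition_date) < min_date) {
      quarantined[[length(quarantined) + 1L]] <- data.frame(
        entry_id = cx$entry_id, stage = "ingest",
        reason = "deposited before 2000-01-01")
      next
    }
    if (is.na(cx$resolution) && is.na(cx$deposition_date[1]))
      warning("entry ", cx$entry_id,
              " carries no resolution/date metadata; passed through",
              call. = FALSE)
    complexes[[cx$entry_id]] <- cx
  }
  instances <- do.call(rbind, lapply(complexes, function(cx)
    if (length(cx$ligands)) data.frame(
      entry_id = cx$entry_id,
      het_code = vapply(cx$ligands, `[[`, "", "het_code"),
      copy_index = vapply(cx$ligands, `[[`, 0L, "copy_index"))
    else NULL))
  if (is.null(instances) || nrow(instances) == 0L)
    return(empty_report(config, corpus_dir, quarantined))
  rownames(instances) <- NULL
  hets <- sort(unique(instances$het_code))

  chem_mol <- function(het) {
    if (!is.null(manifest) && het %in% manifest$het_code)
      return(mol_from_smiles(manifest$smiles[match(het, manifest$het_code)],
                             het_code = het))
    first <- which(instances$het_code == het)[1]
    cx <- complexes[[instances$entry_id[first]]]
    lig <- Filter(function(l) l$het_code == het, cx$ligands)[[1]]
    lig$molecule
  }

  records <- list()
  protonated <- new.env()
  get_complex_h <- function(eid) {
    if (is.null(protonated[[eid]]))
      protonated[[eid]] <- suppressWarnings(ensure_hydrogens(complexes[[eid]]))
    protonated[[eid]]
  }
  multi_ok <- filter_multi_entry(instances)

  for (het in hets) {
    mol <- tryCatch(chem_mol(het), error = function(e) e)
    rows <- instances[instances$het_code == het, , drop = FALSE]
    rec <- list(het_code = het,
                smiles = NA_character_,
                n_entries = length(unique(rows$entry_id)),
                n_instances = nrow(rows),
                n_binding_modes = NA_integer_, n_cavities = NA_integer_,
                pains_flags = "", ro3_violations = NA_integer_,
                scaffold = NA_character_, versatile = FALSE,
                step_rejected_at = NA_integer_, reject_reasons = "")
    desc <- NULL
    if (inherits(mol, "error")) {
      quarantined[[length(quarantined) + 1L]] <- data.frame(
        entry_id = het, stage = "chemistry", reason = conditionMessage(mol))
      rec$step_rejected_at <- 1L
      rec$reject_reasons <- "unparseable"
      records[[het]] <- rec
      next
    }
    rec$smiles <- mol$smiles %||%
      tryCatch(mol_canonical_smiles(mol), error = function(e) NA_character_)
    ## step 1: fragment definition
    verdict <- classify_ligand(mol, config)
    if (!verdict$accepted) {
      rec$step_rejected_at <- 1L
      rec$reject_reasons <- paste(verdict$reject_reasons, collapse = ";")
      records[[het]] <- rec
      next
    }
    desc <- tryCatch(compute_descriptors(mol), error = function(e) NULL)
    if (!is.null(desc)) {
      rec$ro3_violations <- ro3_violations(desc, config$ro3)
      sc <- tryCatch(murcko_scaffold(mol), error = function(e) NULL)
      rec$scaffold <- if (is.null(sc)) NA_character_ else sc$smiles
      rec <- c(rec, as.list(desc))
    }
    ## step 2: multi-entry occurrence
    if (!(het %in% multi_ok)) {
      rec$step_rejected_at <- 2L
      records[[het]] <- rec
      next
    }
    ## step 3: binding modes
    lig_sites <- list()
    for (r in seq_len(nrow(rows))) {
      cx <- get_complex_h(rows$entry_id[r])
      lig <- Filter(function(l) l$het_code == het &&
                      l$copy_index == rows$copy_index[r], cx$ligands)[[1]]
      site <- extract_site(cx, lig, config$site_radius)
      if (site$empty) {
        quarantined[[length(quarantined) + 1L]] <- data.frame(
          entry_id = rows$entry_id[r], stage = "site",
          reason = paste0("empty site for ", het))
        next
      }
      lig_sites[[length(lig_sites) + 1L]] <- list(lig = lig, site = site,
                                                  entry = rows$entry_id[r])
    }
    if (length(lig_sites) < 2L) {
      rec$step_rejected_at <- 3L
      records[[het]] <- rec
      next
    }
    graphs <- lapply(lig_sites, function(ls)
      build_interaction_graph(detect_interactions(ls$lig, ls$site)))
    modes <- count_binding_modes(graphs, config)
    rec$n_binding_modes <- modes$n_modes
    if (modes$n_modes < 2L) {
      rec$step_rejected_at <- 3L
      records[[het]] <- rec
      next
    }
    ## step 4: binding cavities
    clouds <- lapply(lig_sites, function(ls)
      generate_cavity_cloud(ls$site, ls$lig, config))
    keep <- vapply(clouds, function(cl) nrow(cl$points) > 0L, logical(1))
    for (bad in which(!keep))
      quarantined[[length(quarantined) + 1L]] <- data.frame(
        entry_id = lig_sites[[bad]]$entry, stage = "cavity",
        reason = paste0("empty cavity cloud for ", het))
    clouds <- clouds[keep]
    if (length(clouds) < 2L) {
      rec$step_rejected_at <- 4L
      records[[het]] <- rec
      next
    }
    ncav <- count_cavities(clouds, config, seed = config$random_seed)
    rec$n_cavities <- ncav
    if (ncav < 2L) {
      rec$step_rejected_at <- 4L
      records[[het]] <- rec
      next
    }
    ## step 5: PAINS
    flags <- pains_flags(mol)
    rec$pains_flags <- paste(flags, collapse = ";")
    if (length(flags)) {
      rec$step_rejected_at <- 5L
      records[[het]] <- rec
      next
    }
    rec$versatile <- TRUE
    records[[het]] <- rec
  }
  desc_cols <- c("mw", "alogp", "tpsa", "hbd", "hba", "pos_atoms",
                 "neg_atoms", "rot_bonds", "rings", "stereocenters",
                 "heavy_atoms", "pbf")
  rec_df <- do.call(rbind, lapply(records, function(r) {
    for (dc in desc_cols) if (is.null(r[[dc]])) r[[dc]] <- NA_real_
    as.data.frame(r[c("het_code", "smiles", "n_entries", "n_instances",
                      "n_binding_modes", "n_cavities", "pains_flags",
                      "ro3_violations", "scaffold", "versatile",
                      "step_rejected_at", "reject_reasons", desc_cols)],
                  stringsAsFactors = FALSE)
  }))
  rownames(rec_df) <- NULL
  sra <- rec_df$step_rejected_at
  survivors <- c(
    input = nrow(rec_df),
    step1 = sum(is.na(sra) | sra > 1L),
    step2 = sum(is.na(sra) | sra > 2L),
    step3 = sum(is.na(sra) | sra > 3L),
    step4 = sum(is.na(sra) | sra > 4L),
    step5 = sum(is.na(sra)))
  report <- list(records = rec_df, survivors = survivors,
                 instances = instances, complexes = complexes,
                 quarantined = if (length(quarantined))
                   do.call(rbind, quarantined) else NULL,
                 config = config, corpus_dir = corpus_dir)
  class(report) <- "pipeline_report"
  report
}

empty_report <- function(config, corpus_dir, quarantined = list()) {
  report <- list(
    records = data.frame(
      het_code = character(), smiles = character(), n_entries = integer(),
      n_instances = integer(), n_binding_modes = integer(),
      n_cavities = integer(), pains_flags = character(),
      ro3_violations = integer(), scaffold = character(),
      versatile = logical(), step_rejected_at = integer(),
      reject_reasons = character(), mw = numeric(), alogp = numeric(),
      tpsa = numeric(), hbd = numeric(), hba = numeric(),
      pos_atoms = numeric(), neg_atoms = numeric(), rot_bonds = numeric(),
      rings = numeric(), stereocenters = numeric(), heavy_atoms = numeric(),
      pbf = numeric()),
    survivors = c(input = 0L, step1 = 0L, step2 = 0L, step3 = 0L,
                  step4 = 0L, step5 = 0L),
    instances = data.frame(entry_id = character(), het_code = character(),
                           copy_index = integer()),
    complexes = list(),
    quarantined = if (length(quarantined)) do.call(rbind, quarantined) else
      NULL,
    config = config, corpus_dir = corpus_dir)
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  fragments in: %d\n", x$survivors[["input"]]))
  labels <- c("fragment definition", "multi-entry", ">=2 binding modes",
              ">=2 cavities", "PAINS-free")
  for (k in 1:5)
    cat(sprintf("  after step %d (%s): %d\n", k, labels[k],
                x$survivors[[paste0("step", k)]]))
  if (any(x$records$versatile))
    cat("  versatile:", paste(x$records$het_code[x$records$versatile],
                              collapse = ", "), "\n")
  if (!is.null(x$quarantined))
    cat(sprintf("  quarantined: %d item(s)\n", nrow(x$quarantined)))
  invisible(x)
}

#' Export the deposit-style result bundle
#'
#' Writes the five CSV tables (versatile fragments with SMILES, mode and
#' cavity counts; post-step-2 fragments; entry information; RSCC scores;
#' substructure-search results) and per-instance MOL2 files (fragment and
#' site) under \code{dir}. Tables that need inputs the run did not have
#' (validation XML, external catalogs) are written with headers only.
#'
#' @param report a \code{pipeline_report}.
#' @param dir output directory (created).
#' @param validation_dir optional directory of per-entry validation XML
#'   files named \code{<entry_id>.xml} for the RSCC table.
#' @param catalog optional named list of \code{molecule} targets for the
#'   substructure search table.
#' @return Invisibly, \code{dir}.
#' @export
export_deposit <- function(report, dir, validation_dir = NULL,
                           catalog = NULL) {
  dir.create(file.path(dir, "mol2"), recursive = TRUE, showWarnings = FALSE)
  rec <- report$records
  v <- rec[!is.na(rec$versatile) & rec$versatile, , drop = FALSE]
  utils::write.csv(
    v[, c("het_code", "smiles", "n_binding_modes", "n_cavities",
          "ro3_violations")],
    file.path(dir, "versatile_fragments.csv"), row.names = FALSE)
  post2 <- rec[is.na(rec$step_rejected_at) | rec$step_rejected_at > 2L, ,
               drop = FALSE]
  utils::write.csv(post2[, c("het_code", "smiles")],
                   file.path(dir, "post_step2_fragments.csv"),
                   row.names = FALSE)
  entries <- do.call(rbind, lapply(report$complexes, function(cx)
    data.frame(entry_id = cx$entry_id,
               resolution = cx$resolution,
               deposition_date = as.character(cx$deposition_date))))
  if (is.null(entries))
    entries <- data.frame(entry_id = character(), resolution = numeric(),
                          deposition_date = character())
  utils::write.csv(entries, file.path(dir, "entries.csv"), row.names = FALSE)
  ## RSCC table
  rscc_rows <- list()
  if (!is.null(validation_dir)) {
    for (i in seq_len(nrow(report$instances))) {
      eid <- report$instances$entry_id[i]
      xmlf <- file.path(validation_dir, paste0(eid, ".xml"))
      if (!file.exists(xmlf)) next
      cx <- report$complexes[[eid]]
      lig <- Filter(function(l) l$het_code == report$instances$het_code[i] &&
                      l$copy_index == report$instances$copy_index[i],
                    cx$ligands)[[1]]
      site <- extract_site(cx, lig, report$config$site_radius)
      rr <- parse_validation_rscc(xmlf, site, lig)
      rscc_rows[[length(rscc_rows) + 1L]] <- data.frame(
        entry_id = eid, het_code = lig$het_code,
        copy_index = lig$copy_index, ligand_rscc = rr$ligand_rscc,
        site_mean_rscc = rr$site_mean_rscc,
        quality_class = rr$quality_class %||% NA_character_)
    }
  }
  rscc <- if (length(rscc_rows)) do.call(rbind, rscc_rows) else
    data.frame(entry_id = character(), het_code = character(),
               copy_index = integer(), ligand_rscc = numeric(),
               site_mean_rscc = numeric(), quality_class = character())
  utils::write.csv(rscc, file.path(dir, "rscc_scores.csv"),
                   row.names = FALSE)
  ## substructure search of versatile fragments in a catalog
  sub_rows <- list()
  if (!is.null(catalog) && nrow(v)) {
    for (h in v$het_code) {
      q <- mol_from_smiles(v$smiles[v$het_code == h], het_code = h)
      for (tn in names(catalog)) {
        ratio <- substructure_contribution(q, catalog[[tn]])
        if (!is.na(ratio))
          sub_rows[[length(sub_rows) + 1L]] <- data.frame(
            query_het = h, target = tn, bond_ratio = ratio,
            exact_match = ratio == 1)
      }
    }
  }
  subs <- if (length(sub_rows)) do.call(rbind, sub_rows) else
    data.frame(query_het = character(), target = character(),
               bond_ratio = numeric(), exact_match = logical())
  utils::write.csv(subs, file.path(dir, "substructure_search.csv"),
                   row.names = FALSE)
  ## per-instance MOL2 exports
  for (i in seq_len(nrow(report$instances))) {
    eid <- report$instances$entry_id[i]
    cx <- report$complexes[[eid]]
    lig <- Filter(function(l) l$het_code == report$instances$het_code[i] &&
                    l$copy_index == report$instances$copy_index[i],
                  cx$ligands)[[1]]
    stem <- sprintf("%s_%s_%d", eid, lig$het_code, lig$copy_index)
    write_mol2(lig$molecule, file.path(dir, "mol2",
                                       paste0(stem, "_ligand.mol2")))
    site <- extract_site(cx, lig, report$config$site_radius)
    if (!site$empty)
      write_mol2(site, file.path(dir, "mol2", paste0(stem, "_site.mol2")))
  }
  invisible(dir)
}
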